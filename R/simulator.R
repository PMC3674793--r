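#' Simulation recipes
#'
#' Bundles the parameters of one synthetic dataset: an identity reference
#' of `n` conserved blocks, `k` inversions of a chosen class applied to it,
#' fragmentation into `m` contigs, optional stripping of
#' inversion-signature pairs down to one member, optional block deletion at
#' contig borders, and (for nucleotide emission) a per-block sequence
#' length. A seed is mandatory: every stage is reproducible.
#'
#' @param n number of conserved blocks (`n >= m >= 1`).
#' @param k number of inversions (`k >= 0`).
#' @param klass inversion class: `"symmetric"`, `"nested"`, `"safe"`,
#'   `"generic"`.
#' @param m number of contigs.
#' @param seed integer RNG seed.
#' @param drop_pair_members number of IS pairs to strip to a single member
#'   during fragmentation.
#' @param block_len bp per block for nucleotide emission (`>= 50`).
#' @param gap_blocks number of blocks deleted at contig borders.
#' @return A list of class `simulation_recipe`.
#' @export
simulation_recipe <- function(n, k, klass = c("safe", "symmetric", "nested", "generic"),
                              m, seed, drop_pair_members = 0L, block_len = 500L,
                              gap_blocks = 0L) {
  klass <- match.arg(klass)
  n <- as.integer(n); k <- as.integer(k); m <- as.integer(m)
  if (missing(seed) || is.na(as.integer(seed))) stop("a seed is mandatory")
  if (n < 1L || m < 1L || n < m) stop("need n >= m >= 1")
  if (k < 0L) stop("k must be non-negative")
  if (block_len < 50L) stop("block_len must be at least 50 bp")
  structure(list(n = n, k = k, klass = klass, m = m, seed = as.integer(seed),
                 drop_pair_members = as.integer(drop_pair_members),
                 block_len = as.integer(block_len),
                 gap_blocks = as.integer(gap_blocks)),
            class = "simulation_recipe")
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Sample a seeded inversion series of a given class
#'
#' Draws `k` inversions legal for the recipe's class and applies them in
#' order to the identity permutation. Symmetric inversions share the
#' genome centre (`j = n - i + 1`); nested windows shrink strictly, with
#' enough room reserved to reach depth `k`; safe inversions are drawn
#' strictly inside a strip of length at least 3 of the current permutation
#' (interior strips, so positions 1 and `n` are never inverted and every
#' signature created is a member of a pair); generic inversions are
#' uniform. Safe sampling restarts from scratch (continuing the RNG
#' stream) if fragmentation of the strips leaves no room, so the result is
#' still deterministic in the seed.
#'
#' @param recipe a [simulation_recipe()].
#' @return A list with `series` (data frame `i`, `j`) and `perm` (the
#'   resulting [signed_permutation()]).
#' @export
sample_inversion_series <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  n <- recipe$n; k <- recipe$k
  if (recipe$klass == "nested" && k > (n + 1L) %/% 2L) {
    stop("a nested series of depth ", k, " is impossible for n = ", n)
  }
  if (recipe$klass == "safe" && k > 0L && n < 5L) {
    stop("safe inversions need an interior strip of length >= 3; n = ", n, " is too small")
  }
  set.seed(recipe$seed)
  series <- switch(recipe$klass,
    symmetric = {
      i <- if (k > 0L) vapply(seq_len(k), function(z) sample_one(seq_len((n + 1L) %/% 2L)), integer(1)) else integer(0)
      data.frame(i = i, j = n + 1L - i)
    },
    nested = sample_nested(n, k),
    generic = {
      i <- integer(k); j <- integer(k)
      for (z in seq_len(k)) {
        i[z] <- sample_one(seq_len(n))
        j[z] <- sample_one(i[z]:n)
      }
      data.frame(i = i, j = j)
    },
    safe = sample_safe(n, k)
  )
  p <- identity_permutation(n)
  for (r in seq_len(nrow(series))) p <- apply_inversion(p, series$i[r], series$j[r])
  list(series = series, perm = p)
}

sample_nested <- function(n, k) {
  i <- integer(k); j <- integer(k)
  lo <- 0L; hi <- n + 1L
  for (z in seq_len(k)) {
    room <- k - z  # further nesting levels needed below this window
    cand <- list()
    for (a in (lo + 1L):(hi - 1L)) for (b in a:(hi - 1L)) {
      if ((b - a + 1L - 1L) %/% 2L >= room || room == 0L) {
        if (room == 0L || (b - a) >= 2L * room) cand[[length(cand) + 1L]] <- c(a, b)
      }
    }
    cand <- Filter(function(w) room == 0L || (w[2] - w[1]) >= 2L * room, cand)
    if (length(cand) == 0L) stop("nested sampling ran out of room (internal)")
    w <- cand[[sample_one(seq_along(cand))]]
    i[z] <- w[1]; j[z] <- w[2]
    lo <- w[1]; hi <- w[2]
  }
  data.frame(i = i, j = j)
}

sample_safe <- function(n, k, max_tries = 100L) {
  for (try in seq_len(max_tries)) {
    p <- seq_len(n)
    i <- integer(k); j <- integer(k)
    stuck <- FALSE
    for (z in seq_len(k)) {
      st <- find_strips(signed_permutation(p))  # interior strips
      elig <- st[st[, "end"] - st[, "start"] >= 2L, , drop = FALSE]
      if (nrow(elig) == 0L) { stuck <- TRUE; break }
      # choose a strip weighted by its number of legal windows, then a window
      wts <- vapply(seq_len(nrow(elig)), function(r) {
        w <- elig[r, "end"] - elig[r, "start"] - 1L
        w * (w + 1L) / 2
      }, numeric(1))
      r <- sample_one(rep(seq_len(nrow(elig)), times = wts))
      a <- elig[r, "start"]; b <- elig[r, "end"]
      ii <- sample_one((a + 1L):(b - 1L))
      jj <- sample_one(ii:(b - 1L))
      p[ii:jj] <- -rev(p[ii:jj])
      i[z] <- ii; j[z] <- jj
    }
    if (!stuck) return(data.frame(i = i, j = j))
  }
  stop("could not sample a safe series of length ", k, " for n = ", n)
}

#' Fragment a query permutation into contigs with ground truth
#'
#' Cuts positions `1..n` into `m` consecutive intervals at random cut
#' points, reverse-complements each contig independently with probability
#' 1/2, and shuffles contig ids; the returned [true_layout()] records the
#' original order and orientations. Cut points are drawn subject to the
#' algorithm's working conditions: block 1 stays at a contig boundary
#' oriented so the search can start there, and every
#' inversion-signature pair keeps at least one member strictly inside a
#' contig — except for `drop_pair_members` pairs, which are deliberately
#' cut down to a single member. With `gap_blocks > 0`, that many blocks
#' are deleted at interval borders and the survivors densely renumbered,
#' so both genomes remain permutations of `1..n'`.
#'
#' @param perm the query [signed_permutation()].
#' @param recipe a [simulation_recipe()]; its RNG stream is assumed
#'   already seeded (as by [sample_inversion_series()]); call
#'   `set.seed()` yourself when using this function stand-alone.
#' @return A list with `contigs` (a [block_contig_set()]), `truth` (a
#'   [true_layout()]) and `perm` (the possibly renumbered query
#'   permutation).
#' @export
fragment_permutation <- function(perm, recipe) {
  p <- as_perm(perm)
  n <- length(p)
  m <- recipe$m
  stopifnot(m <= n)
  pos1 <- which(abs(p) == 1L)
  s1 <- sign(p[pos1])
  prs <- find_is_pairs(p)$pairs
  n_pairs <- nrow(prs)
  d <- recipe$drop_pair_members
  if (d > n_pairs) stop("cannot drop ", d, " pair members: only ", n_pairs, " IS pairs exist")

  # a cut at position q separates positions q and q+1; the IS member whose
  # breakpoint sits at q is inside a contig iff q is not cut
  req_a4 <- integer(0)  # keeps block 1 at a usable contig boundary
  if (s1 > 0L && pos1 > 1L) req_a4 <- pos1 - 1L
  if (s1 < 0L && pos1 < n) req_a4 <- pos1
  dropped <- if (d > 0L) seq_len(n_pairs)[sample.int(n_pairs, d)] else integer(0)
  required <- req_a4
  keep_pos <- integer(0)   # breakpoint positions that must stay uncut
  for (z in seq_len(n_pairs)) {
    members <- c(prs$pos1[z], prs$pos2[z])
    if (z %in% dropped) {
      cut_member <- sample_one(members)
      required <- c(required, cut_member)
      keep_pos <- c(keep_pos, setdiff(members, cut_member))
    } else if (d > 0L) {
      # with deliberate dropping in play, keep all other pairs fully intact so
      # that exactly d pairs end up with a single member inside the contigs
      keep_pos <- c(keep_pos, members)
    }
  }
  required <- unique(required)
  if (length(required) > m - 1L && length(req_a4) > 0L && req_a4 %in% required &&
      !(req_a4 %in% c(prs$pos1, prs$pos2))) {
    required <- setdiff(required, req_a4)  # start handled by normalize_start instead
  }
  if (length(intersect(required, keep_pos)) > 0L) {
    stop("conflicting cut constraints; choose fewer drop_pair_members")
  }
  if (m - 1L < length(required)) {
    stop("m = ", m, " contigs cannot accommodate ", length(required), " forced cuts")
  }

  # protect one randomly chosen member of every intact pair outright, so a
  # valid cut set exists by construction whenever m leaves enough room
  for (z in seq_len(n_pairs)) {
    if (z %in% dropped) next
    members <- setdiff(c(prs$pos1[z], prs$pos2[z]), required)
    if (length(members) > 0L) keep_pos <- c(keep_pos, sample_one(members))
  }
  keep_pos <- unique(keep_pos)
  pool <- setdiff(seq_len(n - 1L), c(required, keep_pos))
  extra <- m - 1L - length(required)
  if (extra > length(pool)) {
    stop("cannot cut ", m, " contigs out of ", n,
         " blocks while keeping a member of every inversion-signature pair ",
         "inside a contig")
  }
  cuts <- sort(c(required, pool[sample.int(length(pool), extra)]))

  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)

  if (recipe$gap_blocks > 0L) {
    # delete blocks at interval borders (never block 1, never emptying a contig)
    edge_pos <- setdiff(unique(c(starts, ends)), pos1)
    edge_pos <- edge_pos[ends[findInterval(edge_pos, starts)] -
                           starts[findInterval(edge_pos, starts)] >= 1L]
    g <- min(recipe$gap_blocks, length(edge_pos))
    del <- if (g > 0L) edge_pos[sample.int(length(edge_pos), g)] else integer(0)
    keep <- setdiff(seq_len(n), del)
    # dense renumbering by reference order
    newlab <- integer(n)
    newlab[sort(abs(p[keep]))] <- seq_along(keep)
    p <- sign(p[keep]) * newlab[abs(p[keep])]
    # recompute interval memberships on surviving positions
    member <- findInterval(keep, starts)
    starts <- which(!duplicated(member))
    ends <- c(starts[-1L] - 1L, length(keep))
    if (length(starts) != m) stop("gap deletion emptied a contig; use fewer gap_blocks")
    n <- length(keep)
  }

  flips <- sample(c(TRUE, FALSE), m, replace = TRUE)
  ids <- sample(m)  # interval z gets contig id ids[z]
  contigs <- vector("list", m)
  for (z in seq_len(m)) {
    seg <- p[starts[z]:ends[z]]
    contigs[[ids[z]]] <- if (flips[z]) -rev(seg) else seg
  }
  bcs <- block_contig_set(contigs, n = n)
  truth <- true_layout(ids, ifelse(flips, "-", "+"),
                       lengths = vapply(contigs, length, integer(1)) * recipe$block_len,
                       circular = TRUE, names = bcs$names)
  list(contigs = bcs, truth = truth, perm = signed_permutation(p))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Emit a synthetic dataset to disk
#'
#' Writes the nucleotide-level realisation of a simulated genome: a
#' reference FASTA (blocks `1..n` as independent random sequences of
#' `block_len` bp, concatenated in order), a contigs multi-FASTA (oriented
#' block sequences concatenated per contig), a ground-truth match table in
#' the alignment dialect of [parse_match_table()], the block-level contig
#' file, the true layout table and a manifest recording the recipe.
#'
#' @param perm the query [signed_permutation()] (after fragmentation).
#' @param contigs a [block_contig_set()].
#' @param truth a [true_layout()].
#' @param recipe a [simulation_recipe()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
emit_synthetic_dataset <- function(perm, contigs, truth, recipe, out_dir) {
  stopifnot(inherits(contigs, "block_contig_set"), inherits(recipe, "simulation_recipe"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir)
  }
  n <- contigs$n
  L <- recipe$block_len
  set.seed(recipe$seed + 1L)  # sequence stream, decoupled from structure stream
  block_seq <- vapply(seq_len(n), function(b) random_dna(L), character(1))

  files <- c(reference = file.path(out_dir, "reference.fasta"),
             contigs = file.path(out_dir, "contigs.fasta"),
             coords = file.path(out_dir, "matches.coords"),
             blocks = file.path(out_dir, "contigs.blocks"),
             layout = file.path(out_dir, "true_layout.tsv"),
             manifest = file.path(out_dir, "manifest.txt"))

  ref <- Biostrings::DNAStringSet(paste(block_seq, collapse = ""))
  names(ref) <- "reference"
  Biostrings::writeXStringSet(ref, files["reference"], width = 70L)

  contig_seqs <- character(contigs$m)
  coords_rows <- list()
  for (c_id in seq_len(contigs$m)) {
    v <- contigs$contigs[[c_id]]
    offset <- 0L
    pieces <- character(length(v))
    for (z in seq_along(v)) {
      b <- abs(v[z])
      s <- block_seq[b]
      if (v[z] < 0L) {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      pieces[z] <- s
      qs <- offset + 1L; qe <- offset + L
      if (v[z] < 0L) { tmp <- qs; qs <- qe; qe <- tmp }
      coords_rows[[length(coords_rows) + 1L]] <- sprintf(
        "%d\t%d\t%d\t%d\t%d\t%.2f\t%s",
        (b - 1L) * L + 1L, b * L, qs, qe, L, 100, contigs$names[c_id])
      offset <- offset + L
    }
    contig_seqs[c_id] <- paste(pieces, collapse = "")
  }
  ctg <- Biostrings::DNAStringSet(contig_seqs)
  names(ctg) <- contigs$names
  Biostrings::writeXStringSet(ctg, files["contigs"], width = 70L)
  writeLines(unlist(coords_rows), files["coords"])
  write_block_file(contigs, files["blocks"])
  write_true_layout(truth, files["layout"])
  writeLines(c(sprintf("n\t%d", n), sprintf("k\t%d", recipe$k),
               sprintf("class\t%s", recipe$klass), sprintf("m\t%d", recipe$m),
               sprintf("seed\t%d", recipe$seed),
               sprintf("drop_pair_members\t%d", recipe$drop_pair_members),
               sprintf("block_len\t%d", recipe$block_len),
               sprintf("gap_blocks\t%d", recipe$gap_blocks),
               sprintf("query_perm\t%s", format_signed(as_perm(perm)))),
             files["manifest"])
  invisible(files)
}

#' Run a full simulation from a recipe
#'
#' Convenience pipeline: sample the inversion series, fragment into
#' contigs, and optionally emit the nucleotide-level dataset.
#'
#' @param recipe a [simulation_recipe()].
#' @param out_dir if non-`NULL`, [emit_synthetic_dataset()] is called.
#' @return A list with `series`, `perm`, `contigs`, `truth`, and `files`
#'   (when emitted).
#' @export
simulate_dataset <- function(recipe, out_dir = NULL) {
  sim <- sample_inversion_series(recipe)
  frag <- fragment_permutation(sim$perm, recipe)
  out <- list(series = sim$series, perm = frag$perm, contigs = frag$contigs,
              truth = frag$truth)
  if (!is.null(out_dir)) {
    out$files <- emit_synthetic_dataset(frag$perm, frag$contigs, frag$truth,
                                        recipe, out_dir)
  }
  out
}
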