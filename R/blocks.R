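#' Parse a whole-genome alignment match table
#'
#' Reads the tab-separated match table relating a reference replicon to
#' draft contigs, in the `show-coords -T` style dialect: at least seven
#' columns per row, in the order `ref_start`, `ref_end`, `qry_start`,
#' `qry_end`, `length`, `identity_pct`, `qry_id`. Coordinates are 1-based
#' inclusive; a query interval with `qry_end < qry_start` encodes the minus
#' strand. Header or banner lines (non-numeric coordinate fields) are
#' skipped automatically; rows that mix numeric and non-numeric coordinates
#' raise an error naming the line.
#'
#' @param path path to the table, or a character vector of lines.
#' @return A data frame of matches with columns `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end`, `length`, `identity_pct`, `qry_id`, `strand`.
#' @export
parse_match_table <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  empty <- data.frame(ref_start = integer(0), ref_end = integer(0),
                      qry_start = integer(0), qry_end = integer(0),
                      length = integer(0), identity_pct = numeric(0),
                      qry_id = character(0), strand = character(0),
                      stringsAsFactors = FALSE)
  rows <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw)) next
    fields <- strsplit(raw, "\t|\\s+")[[1]]
    coord <- suppressWarnings(as.numeric(fields[seq_len(min(4L, length(fields)))]))
    if (all(is.na(coord))) next  # header / banner line
    if (length(fields) < 7L || anyNA(coord)) {
      stop("malformed match-table row at line ", ln, ": ", raw)
    }
    len <- suppressWarnings(as.numeric(fields[5]))
    idy <- suppressWarnings(as.numeric(fields[6]))
    if (is.na(len) || is.na(idy)) {
      stop("non-numeric length or identity at line ", ln, ": ", raw)
    }
    rows[[ln]] <- data.frame(ref_start = as.integer(coord[1]),
                             ref_end = as.integer(coord[2]),
                             qry_start = as.integer(coord[3]),
                             qry_end = as.integer(coord[4]),
                             length = as.integer(len), identity_pct = idy,
                             qry_id = fields[7], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  if (any(out$ref_start > out$ref_end)) {
    bad <- which(out$ref_start > out$ref_end)[1]
    stop("reference interval reversed in match ", bad, "; reference coordinates must ascend")
  }
  out$strand <- ifelse(out$qry_end < out$qry_start, "-", "+")
  rownames(out) <- NULL
  out
}

interval_overlap <- function(a1, a2, b1, b2) {
  lo <- pmax(pmin(a1, a2), pmin(b1, b2))
  hi <- pmin(pmax(a1, a2), pmax(b1, b2))
  pmax(0L, hi - lo + 1L)
}

#' Greedy one-to-one filtering of alignment matches
#'
#' Reduces a match table to a non-repeated, one-to-one set of conserved
#' segments, emulating the effect of LIS-based one-to-one delta filtering:
#' matches shorter than `min_match_len` are dropped, the remainder are
#' scanned in order of descending length (ties broken by ascending
#' `ref_start`, then lexicographic `qry_id`) and a match is kept unless it
#' overlaps an already-kept match by more than `max_overlap_frac` of the
#' shorter of the two intervals, on either the reference axis or the query
#' axis of the same contig.
#'
#' @param matches data frame from [parse_match_table()].
#' @param max_overlap_frac maximum tolerated overlap fraction in `[0, 1]`.
#' @param min_match_len matches shorter than this many bp are dropped first.
#' @return The kept matches, sorted by ascending `ref_start`.
#' @export
filter_one_to_one <- function(matches, max_overlap_frac = 0.5, min_match_len = 100L) {
  stopifnot(max_overlap_frac >= 0, max_overlap_frac <= 1)
  m <- matches[matches$length >= min_match_len, , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  ord <- order(-m$length, m$ref_start, m$qry_id)
  m <- m[ord, , drop = FALSE]
  kept <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    ok <- TRUE
    ki <- which(kept)
    if (length(ki) > 0L) {
      shorter <- pmin(m$length[i], m$length[ki])
      ref_ov <- interval_overlap(m$ref_start[i], m$ref_end[i],
                                 m$ref_start[ki], m$ref_end[ki])
      same <- m$qry_id[ki] == m$qry_id[i]
      qry_ov <- ifelse(same,
                       interval_overlap(m$qry_start[i], m$qry_end[i],
                                        m$qry_start[ki], m$qry_end[ki]),
                       0L)
      if (any(ref_ov > max_overlap_frac * shorter) ||
          any(qry_ov > max_overlap_frac * shorter)) ok <- FALSE
    }
    kept[i] <- ok
  }
  out <- m[kept, , drop = FALSE]
  out <- out[order(out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Block-level contig sets
#'
#' The block-level representation of a draft genome: each contig is an
#' ordered vector of signed block integers (a substring of the query
#' permutation, possibly reverse-complemented), and each block `1..n`
#' occurs in exactly one contig, exactly once.
#'
#' @param contigs list of integer vectors, one per contig.
#' @param names optional character vector of contig names (default
#'   `contig_1..contig_m`).
#' @param n total number of blocks (default: inferred).
#' @param block_coords optional data frame of per-block coordinates.
#' @return An object of class `block_contig_set` with fields `contigs`,
#'   `names`, `m`, `n`, `block_coords`.
#' @examples
#' block_contig_set(list(c(1, 2), c(-4, -3)))
#' @export
block_contig_set <- function(contigs, names = NULL, n = NULL, block_coords = NULL) {
  contigs <- lapply(contigs, as.integer)
  m <- length(contigs)
  if (m == 0L) stop("a block contig set needs at least one contig")
  all_blocks <- unlist(contigs)
  if (length(all_blocks) == 0L || any(all_blocks == 0L) || anyNA(all_blocks)) {
    stop("contig blocks must be non-zero integers")
  }
  a <- abs(all_blocks)
  if (is.null(n)) n <- length(a)
  n <- as.integer(n)
  if (length(a) != n || !setequal(a, seq_len(n)) || anyDuplicated(a)) {
    stop("each block of 1..", n, " must appear in exactly one contig, exactly once ",
         "(duplicated or missing conserved blocks violate the unique-block assumption)")
  }
  if (is.null(names)) names <- paste0("contig_", seq_len(m))
  if (length(names) != m || anyDuplicated(names)) {
    stop("contig names must be unique and match the number of contigs")
  }
  structure(list(contigs = contigs, names = as.character(names), m = m, n = n,
                 block_coords = block_coords),
            class = "block_contig_set")
}

#' @export
print.block_contig_set <- function(x, ...) {
  cat("block_contig_set:", x$m, "contigs,", x$n, "conserved blocks\n")
  for (k in seq_len(min(x$m, 10L))) {
    cat(sprintf("  %s: %s\n", x$names[k], format_signed(x$contigs[[k]])))
  }
  if (x$m > 10L) cat("  ...\n")
  invisible(x)
}

#' Build the block-level representation from filtered matches
#'
#' Numbers the conserved blocks `1..n` by ascending reference start, so the
#' reference genome reads as the identity permutation, and assembles each
#' contig's signed block list ordered by ascending contig coordinate
#' (`min(qry_start, qry_end)`); minus-strand matches contribute negative
#' blocks. Residual duplicate evidence — two kept matches covering
#' overlapping regions of one contig — is resolved by keeping the longer
#' match, with a warning.
#'
#' @param matches one-to-one filtered matches ([filter_one_to_one()]).
#' @return A [block_contig_set()] whose `block_coords` field maps every
#'   block to its reference and contig intervals.
#' @export
build_block_permutation <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0L) stop("no conserved blocks: empty match set")
  m <- matches[order(matches$ref_start), , drop = FALSE]
  # residual same-contig duplicates: keep the longer
  drop <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (drop[i]) next
    js <- which(!drop & m$qry_id == m$qry_id[i] & seq_len(nrow(m)) != i)
    for (j in js) {
      ov <- interval_overlap(m$qry_start[i], m$qry_end[i], m$qry_start[j], m$qry_end[j])
      if (ov > 0.5 * min(m$length[i], m$length[j])) {
        loser <- if (m$length[j] <= m$length[i]) j else i
        drop[loser] <- TRUE
        warning("duplicate block evidence on contig ", m$qry_id[i],
                "; keeping the longer match")
      }
    }
  }
  m <- m[!drop, , drop = FALSE]
  m <- m[order(m$ref_start), , drop = FALSE]
  n <- nrow(m)
  m$block <- seq_len(n)
  contig_names <- unique(m$qry_id)
  contigs <- vector("list", length(contig_names))
  for (k in seq_along(contig_names)) {
    rows <- m[m$qry_id == contig_names[k], , drop = FALSE]
    rows <- rows[order(pmin(rows$qry_start, rows$qry_end)), , drop = FALSE]
    contigs[[k]] <- ifelse(rows$strand == "+", rows$block, -rows$block)
  }
  coords <- data.frame(block = m$block, ref_start = m$ref_start, ref_end = m$ref_end,
                       contig = m$qry_id, qry_start = m$qry_start, qry_end = m$qry_end,
                       strand = m$strand, stringsAsFactors = FALSE)
  coords <- coords[order(coords$block), , drop = FALSE]
  rownames(coords) <- NULL
  block_contig_set(contigs, names = contig_names, n = n, block_coords = coords)
}

#' Read and write block-level contig files
#'
#' One contig per line, `name: +5 -4 +7`; the name part is optional on
#' input (lines then get default names).
#'
#' @param path file path.
#' @return `read_block_file()`: a [block_contig_set()].
#' @export
read_block_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty block file ", path)
  names <- character(length(lines))
  contigs <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (grepl(":", ln, fixed = TRUE)) {
      parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
      names[k] <- trimws(parts[1])
      body <- trimws(paste(parts[-1], collapse = ":"))
    } else {
      names[k] <- paste0("contig_", k)
      body <- ln
    }
    toks <- strsplit(body, "\\s+")[[1]]
    vals <- suppressWarnings(as.integer(sub("^\\+", "", toks)))
    if (anyNA(vals)) stop("non-integer block token on line ", k, " of ", path)
    contigs[[k]] <- vals
  }
  block_contig_set(contigs, names = names)
}

#' @rdname read_block_file
#' @param contigs a [block_contig_set()].
#' @export
write_block_file <- function(contigs, path) {
  lines <- vapply(seq_len(contigs$m), function(k) {
    paste0(contigs$names[k], ": ", format_signed(contigs$contigs[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_block_file
#' @export
write_block_coords <- function(contigs, path) {
  if (is.null(contigs$block_coords)) stop("this block_contig_set carries no block coordinates")
  utils::write.table(contigs$block_coords, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
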