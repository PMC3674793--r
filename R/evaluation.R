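#' True contig layouts
#'
#' The ground-truth ordering and orientation of the contigs along the
#' completed query genome, used to score predicted scaffolds. Prokaryotic
#' replicons are circular by default, in which case the wrap-around
#' junction between the last and first contig also counts as an adjacency.
#'
#' @param contig integer contig ids in true genome order.
#' @param orientation character vector of `"+"`/`"-"`, same length.
#' @param lengths per-contig length in bp, indexed by contig id; defaults
#'   to unit lengths.
#' @param circular is the replicon circular?
#' @param names optional contig names indexed by contig id.
#' @return An object of class `true_layout`.
#' @export
true_layout <- function(contig, orientation, lengths = NULL, circular = TRUE,
                        names = NULL) {
  contig <- as.integer(contig)
  m <- length(contig)
  stopifnot(m >= 1L, length(orientation) == m, all(orientation %in% c("+", "-")))
  if (anyDuplicated(contig)) stop("each contig must appear exactly once in the true layout")
  if (is.null(lengths)) lengths <- rep(1, max(contig))
  if (any(lengths[contig] <= 0)) stop("contig lengths must be positive")
  if (is.null(names)) names <- paste0("contig_", seq_len(max(contig)))
  structure(list(contig = contig, orientation = as.character(orientation),
                 lengths = as.numeric(lengths), circular = isTRUE(circular),
                 names = as.character(names)),
            class = "true_layout")
}

#' @export
print.true_layout <- function(x, ...) {
  cat("true_layout (", if (x$circular) "circular" else "linear", "): ",
      paste0(x$orientation, x$names[x$contig], collapse = " "), "\n", sep = "")
  invisible(x)
}

# oriented adjacency keys of a layout (contig, orientation vectors);
# includes the wrap pair when circular
adjacency_keys <- function(contig, orientation, circular) {
  m <- length(contig)
  from <- seq_len(if (circular) m else m - 1L)
  to <- if (circular) c(seq_len(m)[-1L], 1L) else seq_len(m)[-1L]
  paste0(contig[from], orientation[from], ">", contig[to], orientation[to])
}

reversed_keys <- function(contig, orientation, circular) {
  flip <- c("+" = "-", "-" = "+")
  adjacency_keys(rev(contig), unname(flip[rev(orientation)]), circular)
}

pred_layout <- function(pred) {
  if (inherits(pred, "scaffold_set")) flatten_scaffolds(pred)
  else as.data.frame(pred)
}

check_same_contigs <- function(layout, truth) {
  a <- sort(as.integer(layout$contig)); b <- sort(as.integer(truth$contig))
  if (!identical(a, b)) {
    stop("predicted and true contig sets differ; only in prediction: {",
         paste(setdiff(a, b), collapse = ","), "}, only in truth: {",
         paste(setdiff(b, a), collapse = ","), "}")
  }
}

# logical vector: which candidate adjacencies of the concatenated predicted
# layout occur in the truth (directly or reversed)
correct_adjacency_flags <- function(layout, truth) {
  truth_keys <- c(adjacency_keys(truth$contig, truth$orientation, truth$circular),
                  reversed_keys(truth$contig, truth$orientation, truth$circular))
  cand <- adjacency_keys(layout$contig, layout$orientation, truth$circular)
  cand %in% truth_keys
}

#' Count correct contig adjacencies
#'
#' A contig adjacency of the predicted scaffold set is correct when the
#' same oriented pair of contigs is consecutive in the completed query
#' genome (or its reverse complement). The predicted scaffolds are first
#' concatenated in creation order into a single layout; for circular truth
#' the wrap-around junction is also a candidate, so a fully correct
#' single-scaffold result on a circular replicon with `m` contigs scores
#' `m` of `m`.
#'
#' @param pred a `scaffold_set` (or a data frame with `contig` and
#'   `orientation` columns).
#' @param truth a [true_layout()] over the same contigs.
#' @return A list with `correct`, `total` and the logical `flags` per
#'   candidate junction.
#' @export
count_correct_adjacencies <- function(pred, truth) {
  stopifnot(inherits(truth, "true_layout"))
  layout <- pred_layout(pred)
  check_same_contigs(layout, truth)
  flags <- correct_adjacency_flags(layout, truth)
  list(correct = sum(flags), total = length(flags), flags = flags)
}

#' Length-weighted genome coverage of a scaffold set
#'
#' Each contig contributes its full length when both of its ends sit in
#' correct adjacencies of the concatenated predicted layout, half its
#' length when exactly one end does, and nothing otherwise; coverage is
#' the contributed length divided by the total contig length. In the
#' linear case the outermost ends of the concatenation have no adjacency
#' and count as incorrect.
#'
#' @inheritParams count_correct_adjacencies
#' @return Coverage fraction in `[0, 1]`.
#' @export
compute_coverage <- function(pred, truth) {
  stopifnot(inherits(truth, "true_layout"))
  layout <- pred_layout(pred)
  check_same_contigs(layout, truth)
  flags <- correct_adjacency_flags(layout, truth)
  m <- nrow(layout)
  # junction k sits between layout position k and k+1 (k = m is the wrap)
  right_ok <- if (truth$circular) flags else c(flags, FALSE)
  left_ok <- if (truth$circular) c(flags[m], flags[-m]) else c(FALSE, flags)
  w <- (as.numeric(left_ok) + as.numeric(right_ok)) / 2
  len <- truth$lengths[layout$contig]
  sum(w * len) / sum(len)
}

#' Score a scaffold set against the true layout
#'
#' Convenience wrapper computing both quality measures: the number of
#' correct contig adjacencies and the length-weighted genome coverage.
#'
#' @inheritParams count_correct_adjacencies
#' @return An object of class `evaluation_report` with fields
#'   `correct_adjacencies`, `total_adjacencies`, `coverage`.
#' @export
evaluate_scaffolds <- function(pred, truth) {
  adj <- count_correct_adjacencies(pred, truth)
  structure(list(correct_adjacencies = adj$correct,
                 total_adjacencies = adj$total,
                 coverage = compute_coverage(pred, truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%d of %d contig adjacencies correct; genome coverage %.3f\n",
              x$correct_adjacencies, x$total_adjacencies, x$coverage))
  invisible(x)
}

#' Derive the true contig layout from a query permutation
#'
#' Walks the query permutation left to right and matches, at each point,
#' the contig whose block list (forward or reverse-complemented) spells
#' the next stretch of the permutation. The contigs must tile the
#' permutation exactly.
#'
#' @param perm the query [signed_permutation()].
#' @param contigs a [block_contig_set()] over the same blocks.
#' @param lengths,circular passed to [true_layout()].
#' @return A [true_layout()].
#' @export
layout_from_permutation <- function(perm, contigs, lengths = NULL, circular = TRUE) {
  p <- as_perm(perm)
  n <- length(p)
  stopifnot(contigs$n == n)
  index <- build_block_index(contigs)
  pos <- 1L
  ids <- integer(0); ors <- character(0)
  while (pos <= n) {
    c_id <- index$contig[abs(p[pos])]
    v <- contigs$contigs[[c_id]]
    len <- length(v)
    if (pos + len - 1L > n) stop("contig ", contigs$names[c_id],
                                 " overruns the permutation at position ", pos)
    slice <- p[pos:(pos + len - 1L)]
    if (identical(slice, v)) {
      ors <- c(ors, "+")
    } else if (identical(slice, -rev(v))) {
      ors <- c(ors, "-")
    } else {
      stop("contig ", contigs$names[c_id],
           " does not tile the permutation at position ", pos)
    }
    ids <- c(ids, c_id)
    pos <- pos + len
  }
  true_layout(ids, ors, lengths = lengths, circular = circular,
              names = contigs$names)
}

#' Read and write true-layout tables
#'
#' Tab-separated with header: `rank`, `contig_name`, `orientation`,
#' `length`; circularity is recorded as a `# circular: true/false` comment
#' on the first line.
#'
#' @param path file path.
#' @param names optional full contig name set for id recovery.
#' @return `read_true_layout()`: a [true_layout()].
#' @export
read_true_layout <- function(path, names = NULL) {
  lines <- readLines(path, warn = FALSE)
  circular <- TRUE
  if (length(lines) > 0L && grepl("^#\\s*circular:", lines[1])) {
    circular <- grepl("true", lines[1], ignore.case = TRUE)
    lines <- lines[-1L]
  }
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), , drop = FALSE]
  if (is.null(names)) names <- tab$contig_name
  ids <- match(tab$contig_name, names)
  if (anyNA(ids)) stop("layout contig names not found in contig name set")
  lengths <- rep(1, length(names))
  if (!is.null(tab$length)) lengths[ids] <- tab$length
  true_layout(ids, tab$orientation, lengths = lengths, circular = circular,
              names = names)
}

#' @rdname read_true_layout
#' @param truth a [true_layout()].
#' @export
write_true_layout <- function(truth, path) {
  stopifnot(inherits(truth, "true_layout"))
  tab <- data.frame(rank = seq_along(truth$contig),
                    contig_name = truth$names[truth$contig],
                    orientation = truth$orientation,
                    length = truth$lengths[truth$contig])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# circular: ", tolower(as.character(truth$circular))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
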