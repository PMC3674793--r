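#' FASTA input and output
#'
#' Thin wrappers around Biostrings keeping sequences as plain named
#' character vectors. Input is uppercased; duplicate record names and
#' empty records are rejected. The writer wraps at 70 columns.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stop("duplicate record names in FASTA ", path)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("empty record in FASTA ", path)
  names(seqs) <- nm
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware reverse complement (so `N` maps to `N`).
#'
#' @param s a single nucleotide string.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("ACGTN")  # "NACGT"
#' @export
reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write scaffold sequence outputs
#'
#' Serializes a scaffold set as an ordered table
#' ([write_scaffold_tsv()]), as gapped FASTA — per scaffold, the contig
#' sequences joined by runs of `gap_size` `N`s, minus-oriented contigs
#' reverse-complemented — and optionally as AGP 2.0 (component rows plus
#' `N` gap rows with gap type `scaffold`, linkage `no`).
#'
#' @param scaffolds a `scaffold_set`.
#' @param seqs named character vector of contig sequences (required for
#'   FASTA/AGP output; every placed contig must be present).
#' @param prefix output path prefix; writes `<prefix>.scaffolds.tsv`,
#'   `<prefix>.scaffolds.fasta` and optionally `<prefix>.agp`.
#' @param gap_size number of `N`s between joined contigs (`>= 0`).
#' @param agp also write AGP 2.0?
#' @return Invisibly, the named vector of files written.
#' @export
write_scaffold_outputs <- function(scaffolds, seqs = NULL, prefix,
                                   gap_size = 100L, agp = FALSE) {
  stopifnot(inherits(scaffolds, "scaffold_set"), gap_size >= 0L)
  files <- c(tsv = paste0(prefix, ".scaffolds.tsv"))
  write_scaffold_tsv(scaffolds, files["tsv"])
  if (is.null(seqs)) return(invisible(files))

  gap <- strrep("N", gap_size)
  out_seqs <- character(0)
  agp_rows <- list()
  for (s in seq_along(scaffolds$scaffolds)) {
    sc <- scaffolds$scaffolds[[s]]
    missing <- setdiff(sc$name, names(seqs))
    if (length(missing) > 0L) {
      stop("no sequence for contig(s): ", paste(missing, collapse = ", "))
    }
    parts <- vapply(seq_len(nrow(sc)), function(r) {
      s0 <- seqs[[sc$name[r]]]
      if (sc$orientation[r] == "-") reverse_complement(s0) else s0
    }, character(1))
    sid <- sprintf("scaffold_%d", s)
    out_seqs[sid] <- paste(parts, collapse = gap)
    pos <- 0L; part_no <- 0L
    for (r in seq_len(nrow(sc))) {
      len <- nchar(parts[r])
      part_no <- part_no + 1L
      agp_rows[[length(agp_rows) + 1L]] <- sprintf(
        "%s\t%d\t%d\t%d\tW\t%s\t1\t%d\t%s",
        sid, pos + 1L, pos + len, part_no, sc$name[r], len, sc$orientation[r])
      pos <- pos + len
      if (r < nrow(sc) && gap_size > 0L) {
        part_no <- part_no + 1L
        agp_rows[[length(agp_rows) + 1L]] <- sprintf(
          "%s\t%d\t%d\t%d\tN\t%d\tscaffold\tno\tna",
          sid, pos + 1L, pos + gap_size, part_no, gap_size)
        pos <- pos + gap_size
      }
    }
  }
  files["fasta"] <- paste0(prefix, ".scaffolds.fasta")
  write_fasta(out_seqs, files["fasta"])
  if (agp) {
    files["agp"] <- paste0(prefix, ".agp")
    writeLines(c("##agp-version\t2.0", unlist(agp_rows)), files["agp"])
  }
  invisible(files)
}
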