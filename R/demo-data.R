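#' The 40-block demonstration genome
#'
#' A small worked dataset shipped with the package: a circular query genome
#' of 40 conserved blocks that differs from its reference by seven safe
#' inversions, assembled into nine contigs. One inversion-signature pair
#' has neither member inside a contig, so the scaffolder recovers the
#' contig order completely but misorients two contigs — a compact
#' illustration of both the algorithm and its failure mode, scoring 7 of 9
#' correct adjacencies.
#'
#' @return `demo_contig_set()`: the nine contigs as a
#'   [block_contig_set()]. `demo_query_permutation()`: the true query
#'   genome as a [signed_permutation()].
#' @examples
#' scaffold_contigs(demo_contig_set())
#' @export
demo_contig_set <- function() {
  read_block_file(system.file("extdata", "demo40", "contigs.blocks",
                              package = "sigscaf", mustWork = TRUE))
}

#' @rdname demo_contig_set
#' @export
demo_query_permutation <- function() {
  read_permutation(system.file("extdata", "demo40", "query_perm.txt",
                               package = "sigscaf", mustWork = TRUE))
}
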