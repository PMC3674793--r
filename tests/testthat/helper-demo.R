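# The 40-block, 9-contig demonstration genome, constructed in code so the
# tests do not depend on the shipped extdata copies.

demo_contigs_list <- function() {
  list(c(-23, -22, 19, 20),
       c(-15, -14, 12, 13, -11),
       c(34, 35),
       c(36, 37, 38, 39, 40),
       c(-3, -2, -1),
       c(5, 6, 7, 8),
       c(31, 32, 33, -30, -29),
       c(-28, -27, 26, -25, -24, 4),
       c(21, -18, -17, -16, 9, 10))
}

demo_contigs <- function() block_contig_set(demo_contigs_list())

demo_perm <- function() {
  signed_permutation(c(1, 2, 3, -23, -22, 19, 20, 21, -18, -17, -16, 9, 10,
                       11, -13, -12, 14, 15, -8, -7, -6, -5, -4, 24, 25, -26,
                       27, 28, -35, -34, 31, 32, 33, -30, -29, 36, 37, 38,
                       39, 40))
}

# the seven signature pairs of the demonstration permutation, as
# (left1, right1, left2, right2)
demo_pairs <- function() {
  rbind(c(3, -23, -4, 24),
        c(-22, 19, 21, -18),
        c(-16, 9, 15, -8),
        c(11, -13, -12, 14),
        c(25, -26, -26, 27),
        c(28, -35, -29, 36),
        c(-34, 31, 33, -30))
}

# draw a feasible safe-simulation recipe; m is capped at n - k so that one
# member of every signature pair can be kept inside a contig
draw_safe_recipe <- function(seed) {
  set.seed(seed * 7L)
  n <- sample(20:200, 1)
  k <- sample(1:10, 1)
  m <- sample(2:min(30L, n - k), 1)
  simulation_recipe(n = n, k = k, klass = "safe", m = m, seed = seed)
}
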