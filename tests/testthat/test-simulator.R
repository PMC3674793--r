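test_that("recipes validate their parameters", {
  expect_error(simulation_recipe(n = 5, k = 1, m = 10, seed = 1), "n >= m")
  expect_error(simulation_recipe(n = 5, k = 1, m = 2), "seed")
  expect_error(simulation_recipe(n = 5, k = -1, m = 2, seed = 1), "non-negative")
  expect_error(simulation_recipe(n = 5, k = 1, m = 2, seed = 1, block_len = 10),
               "block_len")
})

test_that("sampled series respect their class and are seed-reproducible", {
  for (klass in c("symmetric", "nested", "safe", "generic")) {
    rec <- simulation_recipe(n = 30, k = 4, klass = klass, m = 5, seed = 42)
    a <- sample_inversion_series(rec)
    b <- sample_inversion_series(rec)
    expect_identical(a, b)
    expect_equal(nrow(a$series), 4)
    cls <- classify_series(30, a$series)
    ranks <- c(symmetric = 1, nested = 2, safe = 3, generic = 4)
    expect_lte(ranks[[cls]], ranks[[klass]])
  }
  # k = 0 leaves the identity
  rec0 <- simulation_recipe(n = 10, k = 0, klass = "safe", m = 3, seed = 1)
  expect_equal(sample_inversion_series(rec0)$perm, identity_permutation(10))
  # impossible nesting depth is rejected before sampling
  expect_error(sample_inversion_series(
    simulation_recipe(n = 6, k = 5, klass = "nested", m = 2, seed = 1)),
    "impossible")
})

test_that("symmetric series order-independence holds for sampled series", {
  rec <- simulation_recipe(n = 20, k = 5, klass = "symmetric", m = 4, seed = 8)
  sim <- sample_inversion_series(rec)
  set.seed(99)
  for (z in 1:5) {
    ord <- sample(nrow(sim$series))
    p <- identity_permutation(20)
    for (r in ord) p <- apply_inversion(p, sim$series$i[r], sim$series$j[r])
    expect_equal(p, sim$perm)
  }
})

test_that("fragmentation tiles the permutation and records the truth", {
  rec <- simulation_recipe(n = 40, k = 5, klass = "safe", m = 7, seed = 3)
  sim <- simulate_dataset(rec)
  expect_equal(sim$contigs$m, 7)
  # truth layout re-spells the permutation
  spelled <- unlist(lapply(seq_along(sim$truth$contig), function(r) {
    v <- sim$contigs$contigs[[sim$truth$contig[r]]]
    if (sim$truth$orientation[r] == "-") -rev(v) else v
  }))
  expect_equal(spelled, unclass(sim$perm))

  # single-contig case: the one contig is the permutation up to orientation
  rec1 <- simulation_recipe(n = 12, k = 2, klass = "safe", m = 1, seed = 4)
  sim1 <- simulate_dataset(rec1)
  v <- sim1$contigs$contigs[[1]]
  expect_true(identical(v, unclass(sim1$perm)) ||
                identical(-rev(v), unclass(sim1$perm)))
  rep1 <- evaluate_scaffolds(scaffold_contigs(sim1$contigs), sim1$truth)
  expect_equal(rep1$coverage, 1)
})

test_that("every signature pair keeps at least one member inside a contig", {
  member_inside <- function(contigs, left, right) {
    any(vapply(contigs$contigs, function(v) {
      if (length(v) < 2) return(FALSE)
      fwd <- any(v[-length(v)] == left & v[-1] == right)
      rev_ <- any(v[-length(v)] == -right & v[-1] == -left)
      fwd || rev_
    }, logical(1)))
  }
  for (seed in 1:20) {
    sim <- simulate_dataset(draw_safe_recipe(seed))
    prs <- find_is_pairs(sim$perm)$pairs
    for (z in seq_len(nrow(prs))) {
      expect_true(member_inside(sim$contigs, prs$left1[z], prs$right1[z]) ||
                    member_inside(sim$contigs, prs$left2[z], prs$right2[z]))
    }
  }
})

test_that("drop_pair_members strips exactly d pairs down to one member", {
  member_inside <- function(contigs, left, right) {
    any(vapply(contigs$contigs, function(v) {
      if (length(v) < 2) return(FALSE)
      any(v[-length(v)] == left & v[-1] == right) ||
        any(v[-length(v)] == -right & v[-1] == -left)
    }, logical(1)))
  }
  for (seed in c(2, 5, 11)) {
    rec <- simulation_recipe(n = 60, k = 6, klass = "safe", m = 10, seed = seed,
                             drop_pair_members = 2)
    sim <- simulate_dataset(rec)
    prs <- find_is_pairs(sim$perm)$pairs
    inside <- vapply(seq_len(nrow(prs)), function(z) {
      member_inside(sim$contigs, prs$left1[z], prs$right1[z]) +
        member_inside(sim$contigs, prs$left2[z], prs$right2[z])
    }, numeric(1))
    expect_equal(sum(inside == 1), 2)
    expect_equal(sum(inside == 2), nrow(prs) - 2)
  }
})

test_that("gap deletion renumbers the surviving blocks densely", {
  rec <- simulation_recipe(n = 50, k = 4, klass = "safe", m = 6, seed = 13,
                           gap_blocks = 3)
  sim <- simulate_dataset(rec)
  expect_equal(sim$contigs$n, 47)
  expect_setequal(abs(unlist(sim$contigs$contigs)), 1:47)
  expect_setequal(abs(unclass(sim$perm)), 1:47)
})

test_that("emitted datasets are reproducible and internally consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  rec <- simulation_recipe(n = 15, k = 2, klass = "safe", m = 4, seed = 7,
                           block_len = 60)
  s1 <- simulate_dataset(rec, out_dir = d1)
  s2 <- simulate_dataset(rec, out_dir = d2)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]))
  }
  ref <- read_fasta(s1$files[["reference"]])
  expect_equal(nchar(ref[[1]]), 15 * 60)
  ctg <- read_fasta(s1$files[["contigs"]])
  expect_equal(sum(nchar(ctg)), 15 * 60)
  # block-level files agree with the in-memory objects
  expect_equal(read_block_file(s1$files[["blocks"]])$contigs, s1$contigs$contigs)
  back <- read_true_layout(s1$files[["layout"]], names = s1$contigs$names)
  expect_equal(back$contig, s1$truth$contig)
})
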