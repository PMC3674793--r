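test_that("signed permutations validate their invariants", {
  expect_equal(unclass(identity_permutation(4)), 1:4)
  expect_error(signed_permutation(c(1, 1, 2)), "permutation")
  expect_error(signed_permutation(c(1, 0, 2)), "non-zero")
  expect_error(signed_permutation(c(1, 5)), "permutation")
  expect_error(identity_permutation(0), "positive")
})

test_that("apply_inversion reverses, flips signs, and is an involution", {
  expect_equal(unclass(apply_inversion(identity_permutation(8), 1, 8)),
               -(8:1))
  # three symmetric inversions on the identity of size 8
  p <- identity_permutation(8)
  p <- apply_inversion(p, 3, 6)
  p <- apply_inversion(p, 4, 5)
  p <- apply_inversion(p, 2, 7)
  expect_equal(unclass(p), c(1, -7, 3, -5, -4, 6, -2, 8))

  set.seed(42)
  for (z in 1:20) {
    n <- sample(2:12, 1)
    q <- signed_permutation(sample(n) * sample(c(-1, 1), n, replace = TRUE))
    i <- sample(n, 1); j <- (i:n)[sample.int(n - i + 1L, 1)]
    expect_equal(apply_inversion(apply_inversion(q, i, j), i, j), q)
    expect_setequal(abs(unclass(apply_inversion(q, i, j))), 1:n)
  }
  expect_error(apply_inversion(identity_permutation(5), 0, 3), "out of range")
  expect_error(apply_inversion(identity_permutation(5), 2, 6), "out of range")
})

test_that("breakpoints and strips follow the adjacency rule", {
  expect_length(find_breakpoints(identity_permutation(5)), 0)
  expect_equal(find_strips(identity_permutation(5)),
               cbind(start = 1L, end = 5L))
  expect_equal(find_breakpoints(signed_permutation(c(2, 1))), 1L)
  expect_equal(find_strips(signed_permutation(c(2, 1))),
               cbind(start = c(1L, 2L), end = c(1L, 2L)))
  # a reversed run is internally adjacent: [-2, -1, +3]
  p <- signed_permutation(c(-2, -1, 3))
  expect_equal(find_breakpoints(p), 2L)
  sigs <- find_signatures(p)
  expect_equal(nrow(sigs), 1)
  expect_equal(sigs$left, -1)
  expect_equal(sigs$right, 3)
})

test_that("strips partition the positions and contain no interior breakpoint", {
  set.seed(7)
  for (z in 1:25) {
    n <- sample(2:15, 1)
    p <- signed_permutation(sample(n) * sample(c(-1, 1), n, replace = TRUE))
    st <- find_strips(p)
    expect_equal(unlist(lapply(seq_len(nrow(st)),
                               function(r) st[r, "start"]:st[r, "end"])),
                 1:n)
    bp <- find_breakpoints(p)
    for (r in seq_len(nrow(st))) {
      interior <- if (st[r, "start"] < st[r, "end"])
        st[r, "start"]:(st[r, "end"] - 1L) else integer(0)
      expect_length(intersect(interior, bp), 0)
    }
    # every signature is a breakpoint
    expect_true(all(find_signatures(p)$pos %in% bp))
  }
})

test_that("partner_signature is the pairing involution", {
  expect_equal(partner_signature(list(left = -16, right = 9)),
               list(left = 15L, right = -8L))
  expect_equal(partner_signature(list(left = 3, right = -23)),
               list(left = -4L, right = 24L))
  for (l in c(-9, 4, 12)) for (r in c(-3, 7)) {
    expect_equal(partner_signature(partner_signature(list(left = l, right = r))),
                 list(left = as.integer(l), right = as.integer(r)))
  }
})

test_that("a single interior inversion creates exactly one signature pair", {
  p <- apply_inversion(identity_permutation(8), 3, 6)
  res <- find_is_pairs(p)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$left1, 2)
  expect_equal(res$pairs$right1, -6)
  expect_equal(res$pairs$left2, -3)
  expect_equal(res$pairs$right2, 7)
  expect_equal(nrow(res$unpaired), 0)

  # boundary inversion: one signature, no pair
  for (ij in list(c(1, 4), c(5, 8))) {
    b <- find_is_pairs(apply_inversion(identity_permutation(8), ij[1], ij[2]))
    expect_equal(nrow(b$pairs), 0)
    expect_equal(nrow(b$unpaired), 1)
  }
  set.seed(11)
  for (z in 1:20) {
    n <- sample(5:15, 1)
    i <- sample(2:(n - 1), 1); j <- sample(i:(n - 1), 1)
    res <- find_is_pairs(apply_inversion(identity_permutation(n), i, j))
    expect_equal(nrow(res$pairs), 1)
    expect_equal(nrow(res$unpaired), 0)
  }
  expect_equal(nrow(find_is_pairs(identity_permutation(9))$pairs), 0)
})

test_that("series classification returns the most restrictive class", {
  expect_equal(classify_series(8, list(c(3, 6), c(4, 5), c(2, 7))), "symmetric")
  expect_equal(classify_series(8, list(c(1, 7), c(3, 6), c(5, 5))), "nested")
  expect_equal(classify_series(8, list(c(8, 8), c(1, 2), c(4, 6), c(5, 5))), "safe")
  expect_equal(classify_series(8, list(c(1, 5), c(1, 4), c(2, 3), c(7, 7), c(3, 7))),
               "generic")
  expect_equal(classify_series(5, list()), "symmetric")
  expect_error(classify_series(4, list(c(1, 5))), "out of range")
})

test_that("symmetric series commute: any order gives the same permutation", {
  set.seed(13)
  for (z in 1:30) {
    n <- sample(3:10, 1)
    k <- sample(1:4, 1)
    i <- sample(seq_len((n + 1) %/% 2), k, replace = TRUE)
    apply_series <- function(idx) {
      p <- identity_permutation(n)
      for (ii in idx) p <- apply_inversion(p, ii, n + 1 - ii)
      p
    }
    expect_equal(apply_series(i), apply_series(i[sample.int(length(i))]))
  }
})

test_that("reachable-set oracle confirms the class containment chain", {
  expect_error(enumerate_reachable(8, "generic"), "n must be <= 7")
  p1 <- enumerate_reachable(3, "symmetric")
  expect_true("-3 -2 -1" %in% p1)  # via the full symmetric reversal
  expect_true("1 -2 3" %in% p1)    # via the centre inversion
  expect_length(enumerate_reachable(2, "generic"), 8)  # all signed size-2 perms
  for (n in 3:5) {
    sets <- lapply(c("symmetric", "nested", "safe", "generic"),
                   function(k) enumerate_reachable(n, k))
    for (z in 1:3) {
      expect_true(all(sets[[z]] %in% sets[[z + 1]]))
      expect_lt(length(sets[[z]]), length(sets[[z + 1]]))
    }
  }
})

test_that("permutation text round-trips and accepts optional plus signs", {
  path <- withr::local_tempfile(fileext = ".txt")
  p <- signed_permutation(c(3, -1, 2))
  write_permutation(p, path)
  expect_equal(read_permutation(path), p)
  writeLines("1 -3 +2", path)
  expect_equal(unclass(read_permutation(path)), c(1L, -3L, 2L))
  writeLines("1 x 2", path)
  expect_error(read_permutation(path), "non-integer")
})
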