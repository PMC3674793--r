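#' Signed permutations over conserved blocks
#'
#' A pair of single-replicon genomes is represented by signed permutations of
#' the conserved blocks they share: the reference genome is the identity
#' permutation `[+1, +2, ..., +n]` and the query genome is a signed
#' permutation `pi` of `1..n`, the sign encoding the strand on which a block
#' lies. All rearrangement reasoning in this package happens on these
#' vectors.
#'
#' @param values integer vector of signed block labels; each of `1..n` must
#'   appear exactly once in absolute value and no entry may be zero.
#' @return An integer vector of class `signed_permutation`.
#' @examples
#' signed_permutation(c(1, -3, 2))
#' identity_permutation(5)
#' @export
signed_permutation <- function(values) {
  values <- as.integer(values)
  n <- length(values)
  if (n == 0L) stop("a signed permutation must contain at least one block")
  if (anyNA(values) || any(values == 0L)) {
    stop("signed permutation entries must be non-zero integers")
  }
  a <- abs(values)
  if (any(a > n) || anyDuplicated(a)) {
    stop("absolute values must be a permutation of 1..", n)
  }
  structure(values, class = "signed_permutation")
}

#' @rdname signed_permutation
#' @param n number of conserved blocks.
#' @export
identity_permutation <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  signed_permutation(seq_len(n))
}

#' @export
print.signed_permutation <- function(x, ...) {
  cat("signed permutation over", length(x), "blocks:\n")
  cat(format_signed(unclass(x)), "\n")
  invisible(x)
}

format_signed <- function(v) {
  paste(ifelse(v >= 0, paste0("+", v), as.character(v)), collapse = " ")
}

as_perm <- function(perm) {
  if (inherits(perm, "signed_permutation")) return(unclass(perm))
  unclass(signed_permutation(perm))
}

#' Apply an inversion to a signed permutation
#'
#' The inversion `rho(i, j)` reverses the order and flips the signs of the
#' blocks at positions `i..j`, modelling a genomic inversion on the strand
#' level. Applying the same inversion twice restores the input.
#'
#' @param perm a [signed_permutation()] (or coercible vector).
#' @param i,j 1-based inclusive start and end positions, `1 <= i <= j <= n`.
#' @return The rearranged `signed_permutation`; the input is not modified.
#' @examples
#' apply_inversion(identity_permutation(8), 1, 8)
#' @export
apply_inversion <- function(perm, i, j) {
  p <- as_perm(perm)
  n <- length(p)
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || i < 1L || i > n) stop("inversion start i = ", i, " out of range 1..", n)
  if (is.na(j) || j < 1L || j > n) stop("inversion end j = ", j, " out of range 1..", n)
  if (i > j) stop("inversion start i = ", i, " exceeds end j = ", j)
  p[i:j] <- -rev(p[i:j])
  signed_permutation(p)
}

#' Breakpoints and strips of a signed permutation
#'
#' Consecutive blocks `(pi_i, pi_{i+1})` form an adjacency when
#' `pi_i == pi_{i+1} - 1`, and a breakpoint otherwise. A strip is a maximal
#' run of positions free of interior breakpoints. Breakpoints are interior
#' only: the two genome ends do not count.
#'
#' @param perm a [signed_permutation()].
#' @return `find_breakpoints()`: integer vector of positions `i`
#'   (`1 <= i < n`) such that `(pi_i, pi_{i+1})` is a breakpoint.
#'   `find_strips()`: a two-column integer matrix (`start`, `end`) of the
#'   strips, left to right, partitioning `1..n`.
#' @examples
#' find_breakpoints(signed_permutation(c(2, 1)))
#' find_strips(identity_permutation(5))
#' @export
find_breakpoints <- function(perm) {
  p <- as_perm(perm)
  n <- length(p)
  if (n == 1L) return(integer(0))
  which(p[-n] != p[-1L] - 1L)
}

#' @rdname find_breakpoints
#' @export
find_strips <- function(perm) {
  p <- as_perm(perm)
  n <- length(p)
  bp <- find_breakpoints(p)
  starts <- c(1L, bp + 1L)
  ends <- c(bp, n)
  cbind(start = starts, end = ends)
}

#' Inversion signatures of a signed permutation
#'
#' An inversion signature (IS) is a breakpoint whose two blocks carry
#' different signs; it marks one end of an inversion. Two ISs
#' `(l1, r1)` and `(l2, r2)` are an IS pair — the two ends of the same
#' inversion — when `l1 == -l2 - 1` and `r1 == -r2 + 1` (the relation is
#' symmetric and involutive).
#'
#' @param perm a [signed_permutation()].
#' @return A data frame with one row per signature: `pos` (position of the
#'   left block), `left` and `right` (the signed block values), ordered left
#'   to right.
#' @examples
#' find_signatures(apply_inversion(identity_permutation(8), 3, 6))
#' @export
find_signatures <- function(perm) {
  p <- as_perm(perm)
  n <- length(p)
  bp <- find_breakpoints(p)
  if (length(bp) == 0L) {
    return(data.frame(pos = integer(0), left = integer(0), right = integer(0)))
  }
  keep <- sign(p[bp]) != sign(p[bp + 1L])
  bp <- bp[keep]
  data.frame(pos = bp, left = p[bp], right = p[bp + 1L])
}

#' The paired signature pattern of an inversion signature
#'
#' Given one end of an inversion, predicts the block pattern at the other
#' end: the partner of `(l, r)` is `(-l - 1, -r + 1)`. Applying the function
#' twice returns the original pattern.
#'
#' @param sig a list or one-row data frame with elements `left` and `right`.
#' @return A list with elements `left` and `right`; no position is attached
#'   (the partner is a pattern, not an occurrence).
#' @examples
#' partner_signature(list(left = -16, right = 9))  # (+15, -8)
#' @export
partner_signature <- function(sig) {
  l <- as.integer(sig$left); r <- as.integer(sig$right)
  list(left = -l - 1L, right = -r + 1L)
}

#' Find all inversion-signature pairs in a permutation
#'
#' Enumerates the IS occurrences of `perm` and matches them under the
#' pairing relation of [partner_signature()]. Each unordered pair is
#' reported once; signatures whose partner pattern does not occur are
#' returned separately.
#'
#' @param perm a [signed_permutation()].
#' @return A list with `pairs` (data frame: `pos1,left1,right1,pos2,left2,right2`,
#'   `pos1 < pos2`) and `unpaired` (data frame as [find_signatures()]).
#' @examples
#' find_is_pairs(apply_inversion(identity_permutation(8), 3, 6))
#' @export
find_is_pairs <- function(perm) {
  sigs <- find_signatures(perm)
  k <- nrow(sigs)
  empty <- data.frame(pos1 = integer(0), left1 = integer(0), right1 = integer(0),
                      pos2 = integer(0), left2 = integer(0), right2 = integer(0))
  if (k == 0L) return(list(pairs = empty, unpaired = sigs))
  key <- paste(sigs$left, sigs$right)
  partner_key <- paste(-sigs$left - 1L, -sigs$right + 1L)
  mate <- match(partner_key, key)
  paired <- !is.na(mate)
  first <- paired & seq_len(k) < ifelse(is.na(mate), 0L, mate)
  pairs <- if (any(first)) {
    a <- which(first); b <- mate[first]
    data.frame(pos1 = sigs$pos[a], left1 = sigs$left[a], right1 = sigs$right[a],
               pos2 = sigs$pos[b], left2 = sigs$left[b], right2 = sigs$right[b])
  } else empty
  list(pairs = pairs, unpaired = sigs[!paired, , drop = FALSE])
}

# Strips of the permutation framed by sentinels 0 and n+1; returned as
# position intervals over 0..n+1. Used for the "safe" class check so that
# inversions touching the genome ends can act on the terminal strips.
framed_strips <- function(p) {
  n <- length(p)
  v <- c(0L, p, n + 1L)
  bp <- which(v[-(n + 2L)] != v[-1L] - 1L)  # framed index of left member
  starts <- c(1L, bp + 1L)
  ends <- c(bp, n + 2L)
  cbind(start = starts - 1L, end = ends - 1L)  # back to positions 0..n+1
}

series_matrix <- function(series) {
  if (is.data.frame(series)) {
    m <- cbind(as.integer(series$i), as.integer(series$j))
  } else if (is.matrix(series)) {
    m <- cbind(as.integer(series[, 1]), as.integer(series[, 2]))
  } else {
    m <- do.call(rbind, lapply(series, function(x) as.integer(x[1:2])))
    if (is.null(m)) m <- matrix(integer(0), ncol = 2)
  }
  colnames(m) <- c("i", "j")
  m
}

#' Classify a series of inversions
#'
#' Inversion series fall into four progressively broader classes. A series
#' is *symmetric* when every inversion `rho(i, j)` satisfies `n = i + j - 1`
#' (all windows share the genome centre); *nested* when each inversion lies
#' strictly inside the previous one; *safe* when, applied in order starting
#' from the identity, every inversion acts strictly inside a strip of the
#' current permutation (strips taken with terminal sentinels `0` and `n+1`,
#' so inversions touching the genome ends can act on terminal strips); and
#' *generic* otherwise. The most restrictive class that holds is returned;
#' an empty series is vacuously symmetric.
#'
#' @param n number of blocks.
#' @param series inversions, as a list of `c(i, j)`, a two-column matrix, or
#'   a data frame with columns `i` and `j`.
#' @return One of `"symmetric"`, `"nested"`, `"safe"`, `"generic"`.
#' @examples
#' classify_series(8, list(c(3, 6), c(4, 5), c(2, 7)))  # symmetric
#' classify_series(8, list(c(1, 7), c(3, 6), c(5, 5)))  # nested
#' @export
classify_series <- function(n, series) {
  n <- as.integer(n)
  s <- series_matrix(series)
  k <- nrow(s)
  if (k > 0L) {
    if (any(s[, "i"] < 1L) || any(s[, "j"] > n) || any(s[, "i"] > s[, "j"])) {
      stop("inversion out of range for n = ", n)
    }
  }
  if (k == 0L || all(n == s[, "i"] + s[, "j"] - 1L)) return("symmetric")
  if (k == 1L || all(s[-k, "i"] < s[-1L, "i"] & s[-1L, "j"] < s[-k, "j"])) {
    return("nested")
  }
  if (is_safe_series(n, s)) return("safe")
  "generic"
}

is_safe_series <- function(n, s) {
  p <- seq_len(n)
  for (r in seq_len(nrow(s))) {
    i <- s[r, "i"]; j <- s[r, "j"]
    st <- framed_strips(p)
    if (!any(st[, "start"] < i & j < st[, "end"])) return(FALSE)
    p[i:j] <- -rev(p[i:j])
  }
  TRUE
}

# All single inversions legal from permutation p under a class regime.
# For "nested", legality depends on the previous window, handled separately.
safe_moves <- function(p) {
  st <- framed_strips(p)
  out <- list()
  for (r in seq_len(nrow(st))) {
    a <- st[r, "start"]; b <- st[r, "end"]
    if (b - a < 2L) next
    for (i in (a + 1L):(b - 1L)) for (j in i:(b - 1L)) {
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

#' Exhaustively enumerate permutations reachable under an inversion class
#'
#' Brute-force closure of the identity permutation under series of
#' inversions of one class, for small `n` only. Serves as an independent
#' oracle for the class containments `P1(n) <= P2(n) <= P3(n) <= P4(n)`
#' (symmetric, nested, safe, generic). Safe series use sentinel-framed
#' strips (see [classify_series()]); nested series track the shrinking
#' window during the search.
#'
#' @param n number of blocks; guarded to `n <= 7`.
#' @param klass one of `"symmetric"`, `"nested"`, `"safe"`, `"generic"`.
#' @return A character vector of reachable permutations, each encoded as a
#'   space-separated signed string (sorted); the identity is always present.
#' @examples
#' length(enumerate_reachable(3, "generic"))  # all 48 signed permutations
#' @export
enumerate_reachable <- function(n, klass = c("symmetric", "nested", "safe", "generic")) {
  n <- as.integer(n)
  klass <- match.arg(klass)
  if (n > 7L) stop("enumerate_reachable is an exhaustive oracle; n must be <= 7")
  if (n < 1L) stop("n must be a positive integer")
  key <- function(p) paste(p, collapse = " ")
  id <- seq_len(n)

  if (klass == "nested") {
    seen <- new.env(parent = emptyenv())
    assign(key(id), TRUE, envir = seen)
    visited <- new.env(parent = emptyenv())
    recurse <- function(p, i0, j0) {
      vkey <- paste(key(p), i0, j0)
      if (exists(vkey, envir = visited, inherits = FALSE)) return(invisible())
      assign(vkey, TRUE, envir = visited)
      if (j0 - i0 < 2L) return(invisible())
      for (i in (i0 + 1L):(j0 - 1L)) for (j in i:(j0 - 1L)) {
        q <- p; q[i:j] <- -rev(q[i:j])
        assign(key(q), TRUE, envir = seen)
        recurse(q, i, j)
      }
      invisible()
    }
    recurse(id, 0L, n + 1L)
    return(sort(ls(envir = seen)))
  }

  moves_of <- switch(klass,
    symmetric = function(p) {
      lapply(seq_len((n + 1L) %/% 2L), function(i) c(i, n + 1L - i))
    },
    safe = safe_moves,
    generic = function(p) {
      out <- list()
      for (i in seq_len(n)) for (j in i:n) out[[length(out) + 1L]] <- c(i, j)
      out
    }
  )
  seen <- new.env(parent = emptyenv())
  assign(key(id), TRUE, envir = seen)
  frontier <- list(id)
  while (length(frontier) > 0L) {
    nxt <- list()
    for (p in frontier) {
      for (mv in moves_of(p)) {
        q <- p
        q[mv[1]:mv[2]] <- -rev(q[mv[1]:mv[2]])
        k <- key(q)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
  }
  sort(ls(envir = seen))
}

#' Read and write plain-text signed permutations
#'
#' One line of whitespace-separated signed integers, e.g. `"+3 -23 +1"`;
#' a leading `+` is optional on input and always written on output.
#'
#' @param path file path.
#' @return `read_permutation()`: a [signed_permutation()].
#' @export
read_permutation <- function(path) {
  line <- readLines(path, warn = FALSE)
  line <- line[nzchar(trimws(line))]
  if (length(line) == 0L) stop("no permutation found in ", path)
  toks <- strsplit(trimws(line[1]), "\\s+")[[1]]
  vals <- suppressWarnings(as.integer(sub("^\\+", "", toks)))
  if (anyNA(vals)) stop("non-integer token in permutation file ", path)
  signed_permutation(vals)
}

#' @rdname read_permutation
#' @param perm a [signed_permutation()].
#' @export
write_permutation <- function(perm, path) {
  writeLines(format_signed(as_perm(perm)), path)
  invisible(path)
}
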