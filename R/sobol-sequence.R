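# Sobol' low-discrepancy sequence (Joe-Kuo direction numbers, Gray-code
# order, 30-bit precision). No quasi-Monte-Carlo generator ships with the
# R stack this package depends on, so the sequence is generated here; the
# first dimension is the van der Corput sequence in base 2.

.SOBOL_MAXBIT <- 30L
.SOBOL_POLY <- c(1L, 3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L,
                 61L, 67L, 91L, 97L)
.SOBOL_VINIT <- list(
  1L, 1L, c(1L, 3L), c(1L, 3L, 1L), c(1L, 1L, 1L), c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L), c(1L, 1L, 5L, 5L, 17L), c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L), c(1L, 1L, 5L, 1L, 1L), c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L), c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L), c(1L, 3L, 1L, 13L, 27L, 49L))

sobol_directions <- function(dim, nbits = .SOBOL_MAXBIT) {
  if (dim > length(.SOBOL_POLY))
    stop("Sobol' sequence implemented up to ", length(.SOBOL_POLY),
         " dimensions")
  V <- matrix(0L, nrow = nbits, ncol = dim)
  for (j in seq_len(dim)) {
    p <- .SOBOL_POLY[j]
    s <- floor(log2(p))
    m <- integer(nbits)
    m[seq_along(.SOBOL_VINIT[[j]])] <- .SOBOL_VINIT[[j]]
    if (s == 0L) {
      m[] <- 1L
    } else if (nbits > s) {
      a <- integer(max(s - 1L, 0L))
      if (s >= 2L)
        for (i in 1:(s - 1L)) a[i] <- bitwAnd(bitwShiftR(p, s - i), 1L)
      for (k in (s + 1L):nbits) {
        val <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        if (s >= 2L)
          for (i in 1:(s - 1L))
            if (a[i] == 1L) val <- bitwXor(val, bitwShiftL(m[k - i], i))
        m[k] <- val
      }
    }
    V[, j] <- bitwShiftL(m, nbits - seq_len(nbits))
  }
  V
}

#' Points of the Sobol' low-discrepancy sequence
#'
#' Unit-hypercube quasi-random points in Gray-code order. Consecutive
#' blocks of `2^m` points aligned at multiples of `2^m` are digital nets,
#' so skipping the first `n` points of a power-of-two request preserves
#' the balance properties. An optional seeded binary digital shift (XOR of
#' every point with a fixed random bit vector per dimension) randomises
#' the sequence without disturbing those properties.
#'
#' @param n number of points.
#' @param dim dimension (up to 16).
#' @param skip number of initial points to drop (the sequence starts at
#'   the origin, which is inconvenient under inverse-CDF transforms).
#' @param seed optional integer; when given, applies a random digital
#'   shift drawn from it.
#' @return An `n` x `dim` matrix in `[0, 1)`.
#' @export
sobol_points <- function(n, dim, skip = 0L, seed = NULL) {
  stopifnot(n >= 1, dim >= 1, skip >= 0)
  V <- sobol_directions(dim)
  total <- n + skip
  out <- matrix(0, nrow = n, ncol = dim)
  x <- integer(dim)
  if (skip == 0L) out[1, ] <- 0
  i <- 1L
  while (i < total) {
    c_ <- 1L
    ii <- i
    while (bitwAnd(ii, 1L) == 0L) {
      ii <- bitwShiftR(ii, 1L)
      c_ <- c_ + 1L
    }
    x <- bitwXor(x, V[c_, ])
    if (i >= skip) out[i - skip + 1L, ] <- x
    i <- i + 1L
  }
  if (!is.null(seed)) {
    shift <- with_seed(seed, sample.int(2L^.SOBOL_MAXBIT, dim) - 1L)
    for (j in seq_len(dim))
      out[, j] <- bitwXor(as.integer(out[, j]), shift[j])
  }
  out / 2^.SOBOL_MAXBIT
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
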