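# Vectorized double-double ("compensated") arithmetic.
#
# A double-double number x is represented as an unevaluated sum x = hi + lo
# with |lo| <= ulp(hi)/2, giving ~31-32 significant decimal digits. All
# operations below are the classical error-free-transformation algorithms
# (Dekker 1971; Knuth TAOCP vol 2) and are vectorized over R double vectors.
# They rely on IEEE-754 round-to-nearest double arithmetic without fused
# contraction, which is what R guarantees for its vector arithmetic.
#
# The representation used throughout is a list with components $hi and $lo
# (equal-length double vectors). This kernel backs the high-precision mode of
# the infinite-population engine, where genotype frequencies spanning >30
# orders of magnitude in relative size must survive summation and
# normalization.

#' Construct a double-double vector
#' @param hi high-order parts (double vector).
#' @param lo low-order parts (defaults to 0).
#' @return a `dd` object: `list(hi, lo)`.
#' @keywords internal
dd <- function(hi, lo = 0) {
  lo <- rep_len(lo, length(hi))
  structure(list(hi = as.double(hi), lo = as.double(lo)), class = "dd")
}

is_dd <- function(x) inherits(x, "dd")

dd_len <- function(x) length(x$hi)

# error-free sum of two doubles: a + b = s + e exactly
two_sum <- function(a, b) {
  s <- a + b
  bb <- s - a
  e <- (a - (s - bb)) + (b - bb)
  list(s = s, e = e)
}

# error-free sum when |a| >= |b|
quick_two_sum <- function(a, b) {
  s <- a + b
  e <- b - (s - a)
  list(s = s, e = e)
}

# Dekker split constant for 53-bit doubles
.dd_split <- 134217729  # 2^27 + 1

# error-free product: a * b = p + e exactly
two_prod <- function(a, b) {
  p <- a * b
  aa <- .dd_split * a
  ahi <- aa - (aa - a)
  alo <- a - ahi
  bb <- .dd_split * b
  bhi <- bb - (bb - b)
  blo <- b - bhi
  e <- ((ahi * bhi - p) + ahi * blo + alo * bhi) + alo * blo
  list(p = p, e = e)
}

#' @keywords internal
dd_add <- function(x, y) {
  s <- two_sum(x$hi, y$hi)
  e <- s$e + x$lo + y$lo
  r <- quick_two_sum(s$s, e)
  dd(r$s, r$e)
}

#' @keywords internal
dd_neg <- function(x) dd(-x$hi, -x$lo)

#' @keywords internal
dd_sub <- function(x, y) dd_add(x, dd_neg(y))

#' @keywords internal
dd_mul <- function(x, y) {
  p <- two_prod(x$hi, y$hi)
  e <- p$e + x$hi * y$lo + x$lo * y$hi
  r <- quick_two_sum(p$p, e)
  dd(r$s, r$e)
}

# multiply by a plain double vector
#' @keywords internal
dd_mul_d <- function(x, d) {
  p <- two_prod(x$hi, d)
  e <- p$e + x$lo * d
  r <- quick_two_sum(p$p, e)
  dd(r$s, r$e)
}

#' @keywords internal
dd_div <- function(x, y) {
  q1 <- x$hi / y$hi
  r <- dd_sub(x, dd_mul_d(y, q1))
  q2 <- r$hi / y$hi
  r <- dd_sub(r, dd_mul_d(y, q2))
  q3 <- r$hi / y$hi
  s <- quick_two_sum(q1, q2)
  t <- two_sum(s$s, q3)
  e <- t$e + s$e
  u <- quick_two_sum(t$s, e)
  dd(u$s, u$e)
}

# sum of a dd vector to a length-1 dd (sequential compensated accumulation)
#' @keywords internal
dd_sum <- function(x) {
  n <- dd_len(x)
  acc_hi <- 0
  acc_lo <- 0
  hi <- x$hi
  lo <- x$lo
  for (i in seq_len(n)) {
    s <- two_sum(acc_hi, hi[i])
    e <- s$e + acc_lo + lo[i]
    r <- quick_two_sum(s$s, e)
    acc_hi <- r$s
    acc_lo <- r$e
  }
  dd(acc_hi, acc_lo)
}

# elementwise subset / assignment helpers
#' @keywords internal
dd_subset <- function(x, idx) dd(x$hi[idx], x$lo[idx])

#' @keywords internal
dd_to_double <- function(x) x$hi + x$lo

#' @keywords internal
dd_abs_max <- function(x) max(abs(x$hi + x$lo))
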