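# Deterministic infinite-population dynamics.
#
# Genotype frequencies evolve by mutation (single-step matrix M1 or the
# all-orders operator M_inf summed from the geometric series), selection, and
# the uniform-crossover recombination quadratic map. The engine is written
# against a small arithmetic backend so the same algorithms run either on
# machine doubles or on double-double ("high-precision") numbers carrying
# ~31-32 significant digits; the latter honors the requirement that frequencies
# spanning more than 30 orders of magnitude relative to the modal genotype are
# not lost to roundoff.

# ---- arithmetic backends ---------------------------------------------------

backend_double <- list(
  from = function(x) as.double(x),
  to = function(x) x,
  add = function(x, y) x + y,
  sub = function(x, y) x - y,
  mul = function(x, y) x * y,
  scale = function(x, d) x * d,
  div = function(x, y) x / y,
  sum = function(x) sum(x),
  subset = function(x, idx) x[idx],
  assign = function(x, idx, v) { x[idx] <- v; x },
  abs_max = function(x) max(abs(x)),
  tol = 1e-15
)

backend_dd <- list(
  from = function(x) dd(as.double(x)),
  to = dd_to_double,
  add = dd_add,
  sub = dd_sub,
  mul = dd_mul,
  scale = dd_mul_d,
  div = dd_div,
  sum = dd_sum,
  subset = dd_subset,
  assign = function(x, idx, v) { x$hi[idx] <- v$hi; x$lo[idx] <- v$lo; x },
  abs_max = dd_abs_max,
  tol = 1e-32
)

get_backend <- function(precision = c("double", "dd")) {
  switch(match.arg(precision), double = backend_double, dd = backend_dd)
}

# ---- adjacency and mutation operators --------------------------------------

#' Hypercube adjacency matrix
#'
#' Symmetric 0/1 matrix of size `2^L` with entry `(a, b) = 1` iff the
#' genotypes differ at exactly one locus. Every row and column sums to `L`.
#'
#' @param L number of loci.
#' @return a base `matrix`.
#' @export
adjacency_matrix <- function(L) {
  if (L < 1 || L != floor(L)) stop("L must be a positive integer")
  n <- 2^L
  A <- matrix(0, n, n)
  nidx <- neighbor_idx(L)
  for (i in seq_len(L)) {
    A[cbind(seq_len(n), nidx[, i])] <- 1
  }
  A
}

#' Mutation operator matrix
#'
#' Column-stochastic mutation matrices on the hypercube:
#' \describe{
#'   \item{`order = 1`}{`M1 = (1 - mu) I + (mu / L) A` — single mutations
#'     only.}
#'   \item{`order = Inf`}{`M_inf = (1 - mu) (I - (mu / L) A)^{-1}`, the summed
#'     geometric series `(1 - mu) sum_m ((mu / L) A)^m`, which converges for
#'     `mu < 1` and allows arbitrarily many mutations per generation. Exactly
#'     column-stochastic: columns of `(mu/L) A` sum to `mu`, so columns of the
#'     inverse sum to `1 / (1 - mu)`.}
#'   \item{finite `order = k`}{the series truncated after `m = k`, then
#'     renormalized; truncation leaves every column summing to
#'     `1 - mu^(k+1)`, so the renormalization is the scalar division by that
#'     value.}
#' }
#'
#' @param L number of loci.
#' @param mu mutation probability, `0 <= mu < 1`.
#' @param order positive integer, or `Inf`.
#' @return object of class `mutation_operator`: list with `L`, `mu`, `order`,
#'   `matrix`.
#' @export
mutation_operator <- function(L, mu, order = 1) {
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1) (series diverges at 1)")
  if (!(is.infinite(order) || (order >= 1 && order == floor(order)))) {
    stop("order must be a positive integer or Inf")
  }
  n <- 2^L
  A <- adjacency_matrix(L)
  I <- diag(n)
  M <- if (is.infinite(order)) {
    (1 - mu) * solve(I - (mu / L) * A)
  } else if (order == 1) {
    (1 - mu) * I + (mu / L) * A
  } else {
    term <- I
    S <- I
    for (m in seq_len(order)) {
      term <- (mu / L) * (A %*% term)
      S <- S + term
    }
    (1 - mu) * S / (1 - mu^(order + 1))
  }
  structure(list(L = L, mu = mu, order = order, matrix = M),
            class = "mutation_operator")
}

# Matrix-free application of the mutation operator to a backend vector.
# order = Inf solves (I - (mu/L) A) y = (1 - mu) p by fixed-point iteration
# (contraction ratio mu); finite order applies the truncated series and the
# scalar renormalization.
apply_mutation <- function(p, L, mu, order, nidx, b) {
  if (mu == 0) return(p)
  bsum_nb <- function(x) {
    acc <- b$subset(x, nidx[, 1])
    for (i in 2:L) acc <- b$add(acc, b$subset(x, nidx[, i]))
    acc
  }
  if (L == 1) bsum_nb <- function(x) b$subset(x, nidx[, 1])
  if (order == 1) {
    # the canonical single-step operator (1 - mu) I + (mu / L) A
    return(b$add(b$scale(p, 1 - mu), b$scale(bsum_nb(p), mu / L)))
  }
  if (is.infinite(order)) {
    rhs <- b$scale(p, 1 - mu)
    y <- rhs
    maxit <- max(20L, ceiling(log(b$tol * 1e-2) / log(mu)) + 5L)
    for (it in seq_len(maxit)) {
      y_new <- b$add(rhs, b$scale(bsum_nb(y), mu / L))
      delta <- b$abs_max(b$sub(y_new, y))
      y <- y_new
      if (delta <= b$tol * b$abs_max(y)) break
    }
    y
  } else {
    term <- p
    acc <- p
    for (m in seq_len(order)) {
      term <- b$scale(bsum_nb(term), mu / L)
      acc <- b$add(acc, term)
    }
    b$scale(acc, (1 - mu) / (1 - mu^(order + 1)))
  }
}

# ---- recombination map -----------------------------------------------------

popcounts <- function(L) {
  g <- seq_len(2^L) - 1L
  pc <- integer(2^L)
  for (i in seq_len(L) - 1L) pc <- pc + bitwAnd(bitwShiftR(g, i), 1L)
  pc
}

# Walsh-Hadamard transform (unnormalized butterflies), backend-generic.
wht <- function(x, L, b) {
  n <- 2^L
  for (i in seq_len(L) - 1L) {
    bit <- bitwShiftL(1L, i)
    g <- seq_len(n) - 1L
    lo <- which(bitwAnd(g, bit) == 0L)
    hi <- lo + bit
    xl <- b$subset(x, lo)
    xh <- b$subset(x, hi)
    x <- b$assign(x, lo, b$add(xl, xh))
    x <- b$assign(x, hi, b$sub(xl, xh))
  }
  x
}

# Disjoint (subset) self-convolution s_k = sum_{j subset k} x_j x_{k \ j}
# by the ranked zeta/Moebius transform, O(L^2 2^L) backend vector operations.
subset_self_convolution <- function(x, L, b) {
  n <- 2^L
  pc <- popcounts(L)
  zero <- b$from(numeric(n))
  # ranked slices, zeta-transformed
  zr <- vector("list", L + 1L)
  for (r in 0:L) {
    f <- zero
    sel <- which(pc == r)
    f <- b$assign(f, sel, b$subset(x, sel))
    for (i in seq_len(L) - 1L) {
      bit <- bitwShiftL(1L, i)
      g <- seq_len(n) - 1L
      hi <- which(bitwAnd(g, bit) != 0L)
      f <- b$assign(f, hi, b$add(b$subset(f, hi), b$subset(f, hi - bit)))
    }
    zr[[r + 1L]] <- f
  }
  out <- zero
  for (r in 0:L) {
    h <- zero
    for (i in 0:r) {
      h <- b$add(h, b$mul(zr[[i + 1L]], zr[[r - i + 1L]]))
    }
    # Moebius inversion
    for (i in seq_len(L) - 1L) {
      bit <- bitwShiftL(1L, i)
      g <- seq_len(n) - 1L
      hi <- which(bitwAnd(g, bit) != 0L)
      h <- b$assign(h, hi, b$sub(b$subset(h, hi), b$subset(h, hi - bit)))
    }
    sel <- which(pc == r)
    out <- b$assign(out, sel, b$subset(h, sel))
  }
  out
}

recombination_map_backend <- function(p, L, b) {
  n <- 2^L
  pc <- popcounts(L)
  phat <- wht(p, L, b)
  s <- subset_self_convolution(phat, L, b)
  qhat <- b$scale(s, 2^(-pc))
  q <- wht(qhat, L, b)
  b$scale(q, 1 / n)
}

# Brute-force uniform-crossover kernel: independent oracle for small L.
# T(g | a, b) = prod_i [a_i = b_i ? 1{g_i = a_i} : 1/2].
recombination_map_brute <- function(p, L) {
  n <- 2^L
  q <- numeric(n)
  for (a in seq_len(n) - 1L) {
    for (bb in seq_len(n) - 1L) {
      w <- p[a + 1L] * p[bb + 1L]
      if (w == 0) next
      D <- bitwXor(a, bb)
      fixed <- bitwAnd(a, bitwAnd(bitwNot(D), n - 1L))
      # enumerate submasks of D
      s <- D
      nd <- sum(bitwAnd(bitwShiftR(D, seq_len(L) - 1L), 1L))
      share <- w / 2^nd
      repeat {
        g <- bitwOr(fixed, s)
        q[g + 1L] <- q[g + 1L] + share
        if (s == 0L) break
        s <- bitwAnd(s - 1L, D)
      }
    }
  }
  q
}

#' Uniform-crossover recombination map on genotype frequencies
#'
#' The deterministic (infinite-population) recombination operator
#' `Q(p)_g = sum_{a,b} T(g | a, b) p_a p_b`, where the uniform-crossover
#' kernel `T` inherits each offspring locus from either parent with equal
#' probability. `Q` fixes every point mass and every linkage-equilibrium
#' (product) distribution, and preserves all single-locus marginal allele
#' frequencies exactly.
#'
#' The default method evaluates `Q` in the Walsh basis, where
#' `qhat_k = 2^{-|k|} sum_{j subset k} phat_j phat_{k XOR j}`, via a ranked
#' subset convolution in `O(L^2 2^L)` vector operations. `method = "brute"`
#' is the direct triple-loop sum over parent pairs, practical only for small
#' `L`, kept as an independent cross-check.
#'
#' @param p frequency vector of length `2^L`.
#' @param L number of loci.
#' @param method `"walsh"` or `"brute"`.
#' @return recombined frequency vector.
#' @export
recombination_map <- function(p, L, method = c("walsh", "brute")) {
  stopifnot(length(p) == 2^L)
  method <- match.arg(method)
  if (method == "brute") {
    recombination_map_brute(p, L)
  } else {
    recombination_map_backend(p, L, backend_double)
  }
}

# ---- the infinite-population engine ----------------------------------------

#' One generation of infinite-population dynamics
#'
#' Applies mutation, selection, and (a fraction `r` of) recombination to a
#' frequency vector, then renormalizes. Mirrors the substep order of the
#' finite engine.
#'
#' @param p frequency vector of length `2^L`.
#' @param land a `fitness_landscape`.
#' @param mu mutation probability.
#' @param r recombining fraction.
#' @param mut_order mutation operator order (`1`, a positive integer, or
#'   `Inf` for the geometric-series operator).
#' @return list with `p` (next frequencies) and `simplex_dev` (absolute
#'   deviation of the pre-normalization total mass from 1).
#' @export
step_infinite <- function(p, land, mu, r, mut_order = Inf) {
  L <- land$params$L
  b <- backend_double
  st <- step_infinite_backend(b$from(p), land$F, L, mu, r, mut_order,
                              neighbor_idx(L), b)
  list(p = b$to(st$p), simplex_dev = st$dev)
}

step_infinite_backend <- function(p, F, L, mu, r, mut_order, nidx, b) {
  Fb <- b$from(F)
  p <- apply_mutation(p, L, mu, mut_order, nidx, b)
  w <- b$sum(b$mul(p, Fb))
  if (b$to(w) <= 0) stop("mean fitness is zero: selection undefined")
  p <- b$div(b$mul(p, Fb), w)
  if (r > 0) {
    q <- recombination_map_backend(p, L, b)
    # mix as p + r (q - p): conserves mass even though fl(1-r) + fl(r) != 1
    p <- if (r == 1) q else b$add(p, b$scale(b$sub(q, p), r))
    # the Walsh evaluation can leave roundoff-scale negatives where q_g ~ 0
    pd <- b$to(p)
    neg <- which(pd < 0)
    if (length(neg)) {
      if (min(pd[neg]) < -1e6 * b$tol) stop("recombination produced negative mass")
      p <- b$assign(p, neg, b$from(numeric(length(neg))))
    }
  }
  tot <- b$sum(p)
  dev <- abs(b$to(b$sub(tot, b$from(1))))
  p <- b$div(p, tot)
  list(p = p, dev = dev)
}

#' Run an infinite-population trajectory
#'
#' Deterministic evolution of genotype frequencies from a monomorphic start.
#' In high-precision mode (`precision = "dd"`) all state arithmetic uses
#' double-double numbers (~31-32 significant digits), so that after the first
#' generation every genotype carries a strictly positive frequency that is not
#' rounded away even when it is > 30 orders of magnitude below the mode.
#'
#' @param land a `fitness_landscape`.
#' @param mu mutation probability.
#' @param r recombining fraction.
#' @param t_max number of generations.
#' @param start initial genotype (default: the reference sequence).
#' @param precision `"double"` or `"dd"`.
#' @param mut_order mutation operator order (default `Inf`).
#' @param keep_frequencies attach the per-generation frequency matrix.
#' @param L_cap refuse `L` beyond this in high-precision mode (cost guard).
#' @return an `evo_trajectory` data frame (see [run_finite()]); attribute
#'   `"max_simplex_dev"` records the largest pre-normalization mass deviation
#'   across the run, and `"final_p"` the final frequency vector (doubles).
#' @export
run_infinite <- function(land, mu, r, t_max, start = NULL,
                         precision = c("double", "dd"), mut_order = Inf,
                         keep_frequencies = FALSE, L_cap = 12L) {
  precision <- match.arg(precision)
  L <- land$params$L
  if (precision == "dd" && L > L_cap) {
    stop("L exceeds the high-precision cap (", L_cap, ")")
  }
  stopifnot(t_max >= 0)
  if (is.null(start)) {
    start <- if (land$params$model == "nk") 0L else land$params$sigma_star
  }
  check_genotype(start, L)
  b <- get_backend(precision)
  n <- 2^L
  nidx <- neighbor_idx(L)
  dist <- if (land$params$model == "nk") NULL else
    all_distances(L, land$params$sigma_star)
  is_max <- logical(n); is_max[local_maxima(land) + 1L] <- TRUE
  dp_like <- list(theta_trap = 0.95, theta_escape = 0.5)

  p0 <- numeric(n); p0[start + 1L] <- 1
  p <- b$from(p0)
  acc <- traj_alloc(t_max + 1L)
  freq <- if (keep_frequencies) matrix(0, t_max + 1L, n) else NULL
  max_dev <- 0
  cc <- land$params$c %||% 0
  pd <- b$to(p)
  trap_genotype <- update_trap(NA_integer_, pd, is_max, dp_like)
  traj_record(acc, 1L, 0L, pd, land$F, cc, dist, trap_genotype,
              FALSE, present_tol = 1e-12)
  if (keep_frequencies) freq[1L, ] <- pd
  for (t in seq_len(t_max)) {
    st <- step_infinite_backend(p, land$F, L, mu, r, mut_order, nidx, b)
    p <- st$p
    max_dev <- max(max_dev, st$dev)
    pd <- b$to(p)
    trap_genotype <- update_trap(trap_genotype, pd, is_max, dp_like)
    traj_record(acc, t + 1L, t, pd, land$F, cc, dist, trap_genotype,
                FALSE, present_tol = 1e-12)
    if (keep_frequencies) freq[t + 1L, ] <- pd
  }
  structure(traj_finalize(acc), class = c("evo_trajectory", "data.frame"),
            landscape_params = land$params,
            dynamics_params = list(N = Inf, mu = mu, r = r,
                                   mut_order = mut_order,
                                   precision = precision),
            engine = "infinite", frequencies = freq,
            max_simplex_dev = max_dev, final_p = pd)
}
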