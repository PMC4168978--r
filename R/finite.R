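# Finite-population Wright-Fisher dynamics with a recombining fraction r.
#
# One generation = mutation -> selection -> Poisson sampling -> recombination.
# Mutation and selection act deterministically on genotype frequencies
# (fractions of the population); stochasticity enters through the Poisson
# resampling and through recombination, which replaces a Poisson(r*N) number
# of individuals by uniform-crossover offspring of random parents.

#' Dynamics parameter set
#'
#' @param N population size (integer >= 1).
#' @param mu genome-wide per-generation mutation probability in `[0, 1]`; a
#'   mutating individual moves to one of its `L` single-mutant neighbors
#'   (probability `mu / L` each).
#' @param r recombining fraction in `[0, 1]`: expected fraction of the
#'   population replaced each generation by uniform-crossover offspring of two
#'   randomly chosen parents.
#' @param theta_trap frequency threshold above which a population concentrated
#'   on a local fitness maximum is considered trapped.
#' @param theta_escape threshold below which the trapped genotype's frequency
#'   must fall to register an escape; must be `< theta_trap`.
#' @param seed optional RNG seed used by [run_finite()].
#' @return an object of class `dynamics_params`. The mutation supply `N * mu`
#'   is reported as a derived field.
#' @export
dynamics_params <- function(N, mu, r, theta_trap = 0.95, theta_escape = 0.5,
                            seed = NULL) {
  if (N < 1 || N != floor(N)) stop("N must be a positive integer")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  if (!(theta_trap > 0 && theta_trap < 1 && theta_escape > 0 &&
        theta_escape < 1)) stop("trapping thresholds must be in (0, 1)")
  if (theta_escape >= theta_trap) stop("theta_escape must be < theta_trap")
  structure(list(N = as.integer(N), mu = mu, r = r,
                 mutation_supply = N * mu,
                 theta_trap = theta_trap, theta_escape = theta_escape,
                 seed = seed),
            class = "dynamics_params")
}

#' Finite population state
#'
#' @param counts vector of `2^L` non-negative integer genotype occupancies.
#' @param t generation counter.
#' @return object of class `finite_population` with fields `counts`, `N`, `t`.
#' @export
finite_population <- function(counts, t = 0L) {
  if (any(counts < 0 | counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(list(counts = as.numeric(counts), N = sum(counts),
                 t = as.integer(t)),
            class = "finite_population")
}

# 1-based neighbor index table: column i gives, for each genotype, the index
# of the genotype with locus i flipped.
neighbor_idx <- function(L) {
  g <- seq_len(2^L) - 1L
  vapply(seq_len(L) - 1L,
         function(i) bitwXor(g, bitwShiftL(1L, i)) + 1L,
         integer(2^L))
}

# sum of p over the L hypercube neighbors of each genotype
neighbor_sum <- function(p, nidx) {
  acc <- 0
  for (i in seq_len(ncol(nidx))) acc <- acc + p[nidx[, i]]
  acc
}

#' Mutation substep on genotype frequencies
#'
#' `p' = (1 - mu) p + (mu / L) A p`, with `A` the hypercube adjacency matrix:
#' a fraction `mu` of each genotype class moves to its single-mutant
#' neighbors, split equally. Mass is conserved exactly.
#'
#' @param p frequency vector of length `2^L`.
#' @param mu genome-wide mutation probability.
#' @param L number of loci.
#' @return mutated frequency vector.
#' @export
mutation_step <- function(p, mu, L) {
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  stopifnot(length(p) == 2^L)
  if (mu == 0) return(p)
  (1 - mu) * p + (mu / L) * neighbor_sum(p, neighbor_idx(L))
}

#' Selection substep on genotype frequencies
#'
#' `p'_g = p_g F_g / sum_h p_h F_h`: each genotype class is rescaled by its
#' fitness relative to the population mean fitness.
#'
#' @param p frequency vector.
#' @param land a `fitness_landscape` (or a bare fitness vector of matching
#'   length).
#' @return post-selection frequency vector.
#' @export
selection_step <- function(p, land) {
  F <- if (inherits(land, "fitness_landscape")) land$F else land
  stopifnot(length(p) == length(F))
  w <- sum(p * F)
  if (w <= 0) stop("mean fitness is zero: selection undefined")
  p * F / w
}

#' Poisson resampling substep
#'
#' Each genotype count is drawn independently from Poisson(`N * p_g`), then
#' the total is restored to exactly `N`: excess individuals are removed
#' uniformly at random, missing individuals are added by sampling genotypes
#' proportionally to the sampled counts (or to `p` if all sampled counts are
#' zero).
#'
#' @param p frequency vector.
#' @param N target population size.
#' @param seed optional seed (default: current RNG stream).
#' @return a [finite_population()] with total exactly `N`.
#' @export
sampling_step <- function(p, N, seed = NULL) {
  if (N < 1) stop("N must be >= 1")
  with_seed(seed, {
    counts <- stats::rpois(length(p), N * p)
    finite_population(normalize_counts(counts, N, p))
  })
}

# sample from the elements of x (never from 1:x, unlike base sample())
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# restore sum(counts) to exactly N (see sampling_step)
normalize_counts <- function(counts, N, p) {
  tot <- sum(counts)
  if (tot > N) {
    idx <- rep.int(seq_along(counts), counts)
    keep <- sample_vec(idx, N)
    counts <- tabulate(keep, nbins = length(counts))
  } else if (tot < N) {
    prob <- if (tot > 0) counts else p
    add <- sample.int(length(counts), N - tot, replace = TRUE, prob = prob)
    counts <- counts + tabulate(add, nbins = length(counts))
  }
  counts
}

#' Uniform crossover of two genotypes
#'
#' Each locus of the offspring is taken from the first or the second parent
#' with probability 1/2, independently across loci; shared loci are inherited
#' with certainty. Vectorized: `a` and `b` may be vectors (recycled), and `n`
#' independent offspring are drawn for each pair position.
#'
#' @param a,b parent genotype indices.
#' @param L number of loci.
#' @param n number of offspring per element (default: the common length of
#'   `a` and `b`).
#' @param seed optional seed.
#' @return integer vector of offspring genotype indices.
#' @export
uniform_crossover <- function(a, b, L, n = max(length(a), length(b)),
                              seed = NULL) {
  check_genotype(a, L)
  check_genotype(b, L)
  with_seed(seed, {
    a <- rep_len(as.integer(a), n)
    b <- rep_len(as.integer(b), n)
    mask <- sample.int(2^L, n, replace = TRUE) - 1L
    bitwOr(bitwAnd(a, mask), bitwAnd(b, bitwAnd(bitwNot(mask), 2^L - 1L)))
  })
}

#' Recombination substep
#'
#' Draws `k ~ Poisson(r * N)` (truncated at `N`; `k = N` exactly when
#' `r = 1`), removes `k` individuals chosen uniformly without replacement,
#' and replaces each by a uniform-crossover offspring of two parents drawn
#' independently and uniformly from the pre-replacement population
#' (self-pairing allowed). Population size is unchanged.
#'
#' @param pop a [finite_population()].
#' @param r recombining fraction in `[0, 1]`.
#' @param L number of loci.
#' @param seed optional seed.
#' @return the recombined `finite_population` (same `t`).
#' @export
recombination_step <- function(pop, r, L, seed = NULL) {
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  stopifnot(inherits(pop, "finite_population"), length(pop$counts) == 2^L)
  if (r == 0) return(pop)
  with_seed(seed, {
    N <- pop$N
    k <- if (r == 1) N else min(stats::rpois(1, r * N), N)
    if (k == 0) {
      pop
    } else {
      counts <- pop$counts
      n <- length(counts)
      survivors <- if (k < N) {
        idx <- rep.int(seq_len(n), counts)
        tabulate(sample_vec(idx, N - k), nbins = n)
      } else 0
      # parents: two independent uniform draws from the pre-replacement
      # population, i.e. genotypes sampled proportionally to counts
      pa <- sample.int(n, k, replace = TRUE, prob = counts)
      pb <- sample.int(n, k, replace = TRUE, prob = counts)
      off <- uniform_crossover(pa - 1L, pb - 1L, L, n = k)
      newc <- survivors + tabulate(off + 1L, nbins = n)
      finite_population(newc, t = pop$t)
    }
  })
}

#' One full Wright-Fisher generation
#'
#' Applies, in order, [mutation_step()] and [selection_step()] on the
#' frequency vector `counts / N`, then [sampling_step()] and
#' [recombination_step()], and advances the generation counter.
#'
#' @param pop a [finite_population()].
#' @param land a `fitness_landscape`.
#' @param dp a [dynamics_params()].
#' @param seed optional seed (default: current stream).
#' @return the next-generation `finite_population` (size exactly `N`).
#' @export
step_finite <- function(pop, land, dp, seed = NULL) {
  stopifnot(inherits(pop, "finite_population"),
            inherits(land, "fitness_landscape"),
            inherits(dp, "dynamics_params"))
  L <- land$params$L
  with_seed(seed, {
    p <- mutation_step(pop$counts / pop$N, dp$mu, L)
    p <- selection_step(p, land)
    nxt <- sampling_step(p, dp$N)
    nxt <- recombination_step(nxt, dp$r, L)
    nxt$t <- pop$t + 1L
    nxt
  })
}

# Preallocated per-generation record accumulator (an environment, so the
# per-row writes do not copy whole columns).
traj_alloc <- function(n) {
  acc <- new.env(parent = emptyenv())
  acc$t <- integer(n)
  acc$mean_fitness <- numeric(n)
  acc$max_fitness <- numeric(n)
  acc$entropy <- numeric(n)
  acc$additive_variance <- numeric(n)
  acc$modal_genotype <- integer(n)
  acc$modal_frequency <- numeric(n)
  acc$trapped <- logical(n)
  acc$reset_flag <- logical(n)
  acc
}

# record observables for frequency vector p; `F` fitness values, `cc` the
# additive slope, `dist` precomputed distances to the reference (NULL for
# models without one).
traj_record <- function(acc, row, t, p, F, cc, dist, trap_genotype,
                        reset_flag, present_tol = 0) {
  acc$t[row] <- t
  acc$mean_fitness[row] <- sum(p * F)
  acc$max_fitness[row] <- max(F[p > present_tol])
  pos <- p > 0
  acc$entropy[row] <- -sum(p[pos] * log(p[pos]))
  acc$additive_variance[row] <- if (is.null(dist)) NA_real_ else {
    m <- sum(p * dist)
    cc^2 * (sum(p * dist^2) - m^2)
  }
  m <- which.max(p)
  acc$modal_genotype[row] <- m - 1L
  acc$modal_frequency[row] <- p[m]
  acc$trapped[row] <- !is.na(trap_genotype)
  acc$reset_flag[row] <- reset_flag
  invisible(acc)
}

traj_finalize <- function(acc) {
  data.frame(t = acc$t, mean_fitness = acc$mean_fitness,
             max_fitness = acc$max_fitness, entropy = acc$entropy,
             additive_variance = acc$additive_variance,
             modal_genotype = acc$modal_genotype,
             modal_frequency = acc$modal_frequency,
             trapped = acc$trapped, reset_flag = acc$reset_flag)
}

# Shared trajectory loop for the finite engine (static landscape or seascape).
# `resets`: logical vector of length t_max; `reset_draw`: function(land) giving
# the replacement landscape when resets[t] is TRUE (pre-drawn for seascapes).
run_finite_impl <- function(land, dp, t_max, start, seed,
                            resets = NULL, reset_lands = NULL,
                            keep_frequencies = FALSE) {
  L <- land$params$L
  n <- 2^L
  check_genotype(start, L)
  nidx <- neighbor_idx(L)
  land_state <- land
  F <- land_state$F
  cc <- land_state$params$c %||% 0
  dist <- if (land$params$model == "nk") NULL else
    all_distances(L, land$params$sigma_star)
  is_max <- logical(n); is_max[local_maxima(land_state) + 1L] <- TRUE
  acc <- traj_alloc(t_max + 1L)
  freq <- if (keep_frequencies) matrix(0, t_max + 1L, n) else NULL
  reset_count <- 0L
  N <- dp$N
  mu <- dp$mu
  r <- dp$r
  mask_max <- 2L^L - 1L

  with_seed(seed, {
    counts <- numeric(n)
    counts[start + 1L] <- N
    p <- counts / N
    trap_genotype <- update_trap(NA_integer_, p, is_max, dp)
    traj_record(acc, 1L, 0L, p, F, cc, dist, trap_genotype, FALSE)
    if (keep_frequencies) freq[1L, ] <- p
    for (t in seq_len(t_max)) {
      did_reset <- FALSE
      if (!is.null(resets) && resets[t]) {
        reset_count <- reset_count + 1L
        land_state <- reset_lands[[reset_count]]
        F <- land_state$F
        cc <- land_state$params$c %||% 0
        dist <- if (land_state$params$model == "nk") NULL else
          all_distances(L, land_state$params$sigma_star)
        is_max <- logical(n)
        is_max[local_maxima(land_state) + 1L] <- TRUE
        trap_genotype <- NA_integer_
        did_reset <- TRUE
      }
      # one generation, inlined for speed
      p <- counts / N
      if (mu > 0) {
        nb <- p[nidx[, 1]]
        if (L > 1) for (i in 2:L) nb <- nb + p[nidx[, i]]
        p <- (1 - mu) * p + (mu / L) * nb
      }
      w <- sum(p * F)
      if (w <= 0) stop("mean fitness is zero: selection undefined")
      p <- p * F / w
      counts <- stats::rpois(n, N * p)
      counts <- normalize_counts(counts, N, p)
      if (r > 0) {
        k <- if (r == 1) N else min(stats::rpois(1, r * N), N)
        if (k > 0) {
          if (k < N) {
            idx <- rep.int(seq_len(n), counts)
            survivors <- tabulate(sample_vec(idx, N - k), nbins = n)
          } else {
            survivors <- 0
          }
          pa <- sample.int(n, k, replace = TRUE, prob = counts) - 1L
          pb <- sample.int(n, k, replace = TRUE, prob = counts) - 1L
          cmask <- sample.int(n, k, replace = TRUE) - 1L
          off <- bitwOr(bitwAnd(pa, cmask),
                        bitwAnd(pb, bitwAnd(bitwNot(cmask), mask_max)))
          counts <- survivors + tabulate(off + 1L, nbins = n)
        }
      }
      p <- counts / N
      trap_genotype <- update_trap(trap_genotype, p, is_max, dp)
      traj_record(acc, t + 1L, t, p, F, cc, dist, trap_genotype, did_reset)
      if (keep_frequencies) freq[t + 1L, ] <- p
    }
  })
  structure(traj_finalize(acc), class = c("evo_trajectory", "data.frame"),
            landscape_params = land$params, dynamics_params = dp,
            seed = seed, engine = "finite", frequencies = freq)
}

# trapping state machine: enter when the modal genotype is a local maximum
# with frequency >= theta_trap; leave when that genotype's frequency falls
# below theta_escape.
update_trap <- function(trap_genotype, p, is_max, dp) {
  if (is.na(trap_genotype)) {
    m <- which.max(p)
    if (is_max[m] && p[m] >= dp$theta_trap) return(m - 1L)
    return(NA_integer_)
  }
  if (p[trap_genotype + 1L] < dp$theta_escape) return(NA_integer_)
  trap_genotype
}

#' Run a finite-population trajectory
#'
#' Initializes the whole population at `start` (default: the landscape's
#' reference sequence) and iterates [step_finite()] for `t_max` generations,
#' recording per-generation observables.
#'
#' @param land a `fitness_landscape`.
#' @param dp a [dynamics_params()].
#' @param t_max number of generations.
#' @param start initial genotype index.
#' @param seed RNG seed (default `dp$seed`).
#' @param keep_frequencies if `TRUE`, attach the full `(t_max + 1) x 2^L`
#'   frequency matrix as attribute `"frequencies"` (needed by
#'   [detect_trap_escape()]).
#' @return an `evo_trajectory`: a data frame with one row per generation
#'   (`t = 0 .. t_max`) and columns `t`, `mean_fitness`, `max_fitness`,
#'   `entropy`, `additive_variance`, `modal_genotype`, `modal_frequency`,
#'   `trapped`, `reset_flag`.
#' @export
run_finite <- function(land, dp, t_max, start = NULL, seed = dp$seed,
                       keep_frequencies = FALSE) {
  stopifnot(t_max >= 0)
  if (is.null(start)) {
    start <- if (land$params$model == "nk") 0L else land$params$sigma_star
  }
  run_finite_impl(land, dp, t_max, start, seed,
                  keep_frequencies = keep_frequencies)
}

#' @export
print.evo_trajectory <- function(x, ...) {
  eng <- attr(x, "engine")
  cat(sprintf("Evolutionary trajectory (%s engine): %d generations\n",
              eng, nrow(x) - 1L))
  cat(sprintf("  mean fitness %.4g -> %.4g; final entropy %.4g\n",
              x$mean_fitness[1], x$mean_fitness[nrow(x)],
              x$entropy[nrow(x)]))
  if (any(x$trapped)) {
    cat(sprintf("  trapped in %d of %d generations\n",
                sum(x$trapped), nrow(x)))
  }
  invisible(x)
}
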