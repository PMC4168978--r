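# Fitness seascapes: stochastic resets of the random landscape component and
# of the reference sequence, modelling a fluctuating environment.

#' Seascape parameter set
#'
#' @param p_reset per-generation probability that the landscape is reset.
#' @param mode `"soft"` (the new reference sequence is a uniform single-mutant
#'   neighbor of the old one, so the fitness gradient direction is mostly
#'   preserved) or `"hard"` (the new reference sequence is uniform over all
#'   genotypes).
#' @param base a [landscape_params()] object of the RMF family describing the
#'   landscape distribution that resets redraw from.
#' @return object of class `seascape_params`; `expected_epoch = 1 / p_reset`
#'   (generations between resets) is reported as a derived field.
#' @export
seascape_params <- function(p_reset, mode = c("soft", "hard"), base) {
  mode <- match.arg(mode)
  if (p_reset < 0 || p_reset > 1) stop("p_reset must be in [0, 1]")
  stopifnot(inherits(base, "landscape_params"))
  if (base$model == "nk") stop("seascapes are defined for the RMF family")
  structure(list(p_reset = p_reset, mode = mode, base = base,
                 expected_epoch = if (p_reset > 0) 1 / p_reset else Inf),
            class = "seascape_params")
}

#' Reset a fitness landscape
#'
#' Redraws all random fitness components `eta` i.i.d. from the same
#' exponential law and moves the reference sequence: softly (uniform among the
#' `L` single-mutant neighbors of the old reference) or hard (uniform over all
#' `2^L` genotypes). `c`, `lambda`, and `L` are unchanged.
#'
#' @param land a `fitness_landscape` of the RMF family.
#' @param mode `"soft"` or `"hard"`.
#' @param seed optional seed (default: current RNG stream).
#' @return a fresh `fitness_landscape`.
#' @export
reset_landscape <- function(land, mode = c("soft", "hard"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(land, "fitness_landscape"))
  p <- land$params
  if (p$model == "nk") stop("seascapes are defined for the RMF family")
  with_seed(seed, {
    L <- p$L
    new_star <- if (mode == "soft") {
      bitwXor(p$sigma_star,
              bitwShiftL(1L, sample.int(L, 1L) - 1L))
    } else {
      sample.int(2^L, 1L) - 1L
    }
    eta <- if (p$lambda > 0) -p$lambda * log(stats::runif(2^L)) else numeric(2^L)
    new_params <- p
    new_params$sigma_star <- as.integer(new_star)
    new_params$seed <- NULL
    structure(list(params = new_params,
                   F = p$c * all_distances(L, new_star) + eta,
                   eta = eta),
              class = "fitness_landscape")
  })
}

#' Run a finite-population trajectory on a seascape
#'
#' Identical to [run_finite()] except that before each generation the
#' landscape is replaced via [reset_landscape()] with probability `p_reset`
#' (independent Bernoulli draws). All environmental randomness — the initial
#' landscape (unless `land` is supplied), the reset times, and the replacement
#' landscapes — is drawn up front from a dedicated environment stream seeded
#' by `env_seed`, so paired runs (`r > 0` vs `r = 0`) given the same
#' `env_seed` experience identical environments while their dynamics streams
#' stay independent.
#'
#' @param dp a [dynamics_params()].
#' @param sp a [seascape_params()].
#' @param t_max number of generations.
#' @param start initial genotype (default: the initial landscape's reference
#'   sequence).
#' @param seed dynamics RNG seed (default `dp$seed`).
#' @param env_seed environment RNG seed (default: current stream).
#' @param land optional pre-generated initial landscape (otherwise generated
#'   from `sp$base` on the environment stream).
#' @param keep_frequencies attach the full frequency matrix.
#' @return an `evo_trajectory` with `reset_flag` marking generations preceded
#'   by a reset; the initial landscape is attached as attribute
#'   `"initial_landscape"`.
#' @export
run_seascape <- function(dp, sp, t_max, start = NULL, seed = dp$seed,
                         env_seed = NULL, land = NULL,
                         keep_frequencies = FALSE) {
  stopifnot(inherits(dp, "dynamics_params"), inherits(sp, "seascape_params"),
            t_max >= 0)
  env <- with_seed(env_seed, {
    land0 <- if (is.null(land)) {
      generate_landscape(sp$base, seed = NULL)
    } else land
    resets <- stats::runif(t_max) < sp$p_reset
    lands <- vector("list", sum(resets))
    cur <- land0
    for (k in seq_len(sum(resets))) {
      cur <- reset_landscape(cur, sp$mode, seed = NULL)
      lands[[k]] <- cur
    }
    list(land0 = land0, resets = resets, lands = lands)
  })
  if (is.null(start)) start <- env$land0$params$sigma_star
  traj <- run_finite_impl(env$land0, dp, t_max, start, seed,
                          resets = env$resets, reset_lands = env$lands,
                          keep_frequencies = keep_frequencies)
  attr(traj, "seascape_params") <- sp
  attr(traj, "initial_landscape") <- env$land0
  traj
}

#' Stationary advantage on a seascape
#'
#' Arithmetic mean of a mean-fitness difference series over a time window,
#' used to quantify the long-run (stationary) advantage of recombination in a
#' fluctuating environment. The default window averages generations 5000 to
#' 20000.
#'
#' @param delta numeric `delta_F` series (generation `t` at position `t + 1`),
#'   or a data frame with columns `t` and `delta_F`.
#' @param window closed generation window `c(t_lo, t_hi)`.
#' @return the windowed mean.
#' @export
stationary_advantage <- function(delta, window = c(5000, 20000)) {
  if (is.data.frame(delta)) {
    tt <- delta$t
    x <- delta$delta_F
  } else {
    x <- as.numeric(delta)
    tt <- seq_along(x) - 1L
  }
  if (window[1] > window[2]) stop("invalid window")
  keep <- tt >= window[1] & tt <= window[2]
  if (window[1] < min(tt) || window[2] > max(tt)) {
    stop("window outside the series range")
  }
  mean(x[keep])
}
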