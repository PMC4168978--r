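# Paired-ensemble experiment harness.
#
# The central design: for each run, one landscape realization is drawn, and a
# recombining (r = cfg$dynamics$r) and a non-recombining (r = 0) population
# evolve on that same realization from the same starting genotype, with
# independent dynamics streams. Differences (delta_F, delta_S, delta_Fmax,
# P_plus) are averaged over runs. On seascapes the paired runs additionally
# share the environment stream, so both experience identical reset times and
# replacement landscapes.

#' Experiment configuration
#'
#' @param landscape a [landscape_params()] object (its `seed` field is ignored
#'   here; per-run landscape seeds come from the master-seed schedule).
#' @param dynamics a [dynamics_params()] object; `dynamics$r` is the
#'   recombining arm, the paired arm always runs at `r = 0`.
#' @param t_max number of generations per run.
#' @param n_runs number of landscape realizations (pairs).
#' @param master_seed master seed of the counter-based schedule (see
#'   [derive_seed()]).
#' @param seascape optional [seascape_params()]; when given, runs use
#'   [run_seascape()] with a shared per-run environment stream.
#' @param sweep optional `list(param = <name>, values = <vector>)` with
#'   `param` one of `"r"`, `"lambda"`, `"mu"`, `"N"`, `"L"`, `"c"`,
#'   `"p_reset"`.
#' @param start_mode `"reference"` (start monomorphic at the reference
#'   sequence) or `"random"` (a uniform random genotype, shared within each
#'   pair; used e.g. to compare static landscapes against hard-reset
#'   seascapes).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(landscape, dynamics, t_max, n_runs, master_seed,
                              seascape = NULL, sweep = NULL,
                              start_mode = c("reference", "random")) {
  stopifnot(inherits(landscape, "landscape_params"),
            inherits(dynamics, "dynamics_params"),
            t_max >= 0, n_runs >= 1)
  start_mode <- match.arg(start_mode)
  if (!is.null(seascape)) stopifnot(inherits(seascape, "seascape_params"))
  if (!is.null(sweep)) {
    if (!is.list(sweep) || is.null(sweep$param) || is.null(sweep$values)) {
      stop("sweep must be list(param = , values = )")
    }
    if (!sweep$param %in% c("r", "lambda", "mu", "N", "L", "c", "p_reset")) {
      stop("unrecognized sweep parameter: ", sweep$param)
    }
    if (sweep$param == "p_reset" && is.null(seascape)) {
      stop("p_reset sweep requires a seascape configuration")
    }
  }
  structure(list(landscape = landscape, dynamics = dynamics,
                 seascape = seascape, t_max = as.integer(t_max),
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed), sweep = sweep,
                 start_mode = start_mode),
            class = "experiment_config")
}

# role indices of the seed schedule
.role_landscape <- 1L
.role_dyn_r <- 2L
.role_dyn_nr <- 3L
.role_env <- 4L
.role_start <- 5L

#' Run a paired ensemble
#'
#' For each of `n_runs` runs: draw one landscape realization from the run's
#' landscape seed, then evolve a recombining (`r = cfg$dynamics$r`) and a
#' non-recombining (`r = 0`) population on that same realization from the same
#' monomorphic start, with independent dynamics seeds. Aggregates the paired
#' differences with [delta_series()]. Fully reproducible from
#' `cfg$master_seed`.
#'
#' @param cfg an [experiment_config()].
#' @param detect_traps if `TRUE`, trajectories are run with their frequency
#'   matrices kept and trapping/escape events (at the thresholds in
#'   `cfg$dynamics`) are collected per run and arm. Static landscapes only.
#' @return object of class `paired_ensemble`: list with `config`, `delta`
#'   (the [delta_series()] data frame), `summary` (an [advantage_summary()]),
#'   `events_r` / `events_nr` (when `detect_traps`), and `seeds` (the per-run
#'   seed schedule).
#' @export
paired_ensemble <- function(cfg, detect_traps = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (detect_traps && !is.null(cfg$seascape)) {
    stop("trap detection is defined for static landscapes")
  }
  n <- cfg$n_runs
  seeds <- t(vapply(seq_len(n), function(k) {
    vapply(1:5, function(role) derive_seed(cfg$master_seed, k, role),
           integer(1))
  }, integer(5)))
  colnames(seeds) <- c("landscape", "dyn_r", "dyn_nr", "env", "start")
  dp_r <- cfg$dynamics
  dp_nr <- cfg$dynamics
  dp_nr$r <- 0
  runs_r <- vector("list", n)
  runs_nr <- vector("list", n)
  ev_r <- list(); ev_nr <- list()
  for (k in seq_len(n)) {
    if (is.null(cfg$seascape)) {
      land <- generate_landscape(cfg$landscape, seed = seeds[k, "landscape"])
      start <- pick_start(cfg, land, seeds[k, "start"])
      runs_r[[k]] <- run_finite(land, dp_r, cfg$t_max, start = start,
                                seed = seeds[k, "dyn_r"],
                                keep_frequencies = detect_traps)
      runs_nr[[k]] <- run_finite(land, dp_nr, cfg$t_max, start = start,
                                 seed = seeds[k, "dyn_nr"],
                                 keep_frequencies = detect_traps)
      if (detect_traps) {
        er <- detect_trap_escape(runs_r[[k]], land,
                                 cfg$dynamics$theta_trap,
                                 cfg$dynamics$theta_escape)
        en <- detect_trap_escape(runs_nr[[k]], land,
                                 cfg$dynamics$theta_trap,
                                 cfg$dynamics$theta_escape)
        if (nrow(er)) ev_r[[length(ev_r) + 1L]] <- cbind(run = k, er)
        if (nrow(en)) ev_nr[[length(ev_nr) + 1L]] <- cbind(run = k, en)
        attr(runs_r[[k]], "frequencies") <- NULL
        attr(runs_nr[[k]], "frequencies") <- NULL
      }
    } else {
      land0 <- generate_landscape(cfg$seascape$base,
                                  seed = seeds[k, "landscape"])
      start <- pick_start(cfg, land0, seeds[k, "start"])
      runs_r[[k]] <- run_seascape(dp_r, cfg$seascape, cfg$t_max,
                                  start = start, seed = seeds[k, "dyn_r"],
                                  env_seed = seeds[k, "env"], land = land0)
      runs_nr[[k]] <- run_seascape(dp_nr, cfg$seascape, cfg$t_max,
                                   start = start, seed = seeds[k, "dyn_nr"],
                                   env_seed = seeds[k, "env"], land = land0)
    }
  }
  delta <- delta_series(runs_r, runs_nr)
  structure(list(config = cfg, delta = delta,
                 summary = advantage_summary(delta),
                 events_r = if (detect_traps) bind_events(ev_r) else NULL,
                 events_nr = if (detect_traps) bind_events(ev_nr) else NULL,
                 seeds = seeds),
            class = "paired_ensemble")
}

bind_events <- function(lst) {
  if (length(lst) == 0) {
    return(data.frame(run = integer(0), genotype = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      distance_from_start = integer(0)))
  }
  do.call(rbind, lst)
}

pick_start <- function(cfg, land, start_seed) {
  if (cfg$start_mode == "random") {
    with_seed(start_seed, sample.int(2^land$params$L, 1L) - 1L)
  } else {
    land$params$sigma_star
  }
}

#' @export
print.paired_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Paired ensemble: %d pairs, %d generations (r = %g vs r = 0)\n",
              x$config$n_runs, x$config$t_max, x$config$dynamics$r))
  cat(sprintf("  max advantage delta_F = %.4g at t = %d; t_zero = %s\n",
              s$delta_max, s$t_max,
              if (is.na(s$t_zero)) "none" else as.character(s$t_zero)))
  cat(sprintf("  final delta_F = %.4g, final P_plus = %.3f\n",
              x$delta[nrow(x$delta), "delta_F"],
              x$delta[nrow(x$delta), "P_plus"]))
  invisible(x)
}

#' Run a parameter sweep of paired ensembles
#'
#' One paired ensemble per sweep value. All ensembles share the master-seed
#' schedule, so run `k` uses the same landscape realization seed at every
#' sweep value: differences across values isolate the swept parameter.
#'
#' @param cfg an [experiment_config()] with `sweep` set.
#' @param detect_traps passed to [paired_ensemble()].
#' @return named list of `paired_ensemble` objects, keyed by sweep value.
#' @export
sweep_ensemble <- function(cfg, detect_traps = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(cfg$sweep)) stop("cfg$sweep is not set")
  vals <- cfg$sweep$values
  out <- vector("list", length(vals))
  names(out) <- as.character(vals)
  for (i in seq_along(vals)) {
    cfg_i <- apply_sweep_value(cfg, cfg$sweep$param, vals[i])
    cfg_i$sweep <- NULL
    out[[i]] <- paired_ensemble(cfg_i, detect_traps = detect_traps)
  }
  out
}

apply_sweep_value <- function(cfg, param, value) {
  lp <- cfg$landscape
  dp <- cfg$dynamics
  sp <- cfg$seascape
  switch(param,
    r = { dp <- dynamics_params(dp$N, dp$mu, value, dp$theta_trap,
                                dp$theta_escape, dp$seed) },
    mu = { dp <- dynamics_params(dp$N, value, dp$r, dp$theta_trap,
                                 dp$theta_escape, dp$seed) },
    N = { dp <- dynamics_params(value, dp$mu, dp$r, dp$theta_trap,
                                dp$theta_escape, dp$seed) },
    lambda = { lp <- modify_landscape_params(lp, lambda = value) },
    c = { lp <- modify_landscape_params(lp, c = value) },
    L = { lp <- modify_landscape_params(lp, L = value) },
    p_reset = { sp <- seascape_params(value, sp$mode, sp$base) }
  )
  if (!is.null(sp) && param %in% c("lambda", "c", "L")) {
    sp <- seascape_params(sp$p_reset, sp$mode, lp)
  }
  experiment_config(lp, dp, cfg$t_max, cfg$n_runs, cfg$master_seed,
                    seascape = sp, sweep = cfg$sweep,
                    start_mode = cfg$start_mode)
}

modify_landscape_params <- function(lp, L = lp$L, c = lp$c,
                                    lambda = lp$lambda) {
  landscape_params(L = L, model = lp$model, c = c, lambda = lambda,
                   sigma_star = if (L == lp$L) lp$sigma_star else 0L,
                   nk_K = lp$nk_K, nk_meanlog = lp$nk_meanlog,
                   nk_sdlog = lp$nk_sdlog, seed = lp$seed)
}

#' Deterministic test fixtures
#'
#' Tiny landscapes with hand-computed properties:
#' \describe{
#'   \item{`two_locus_valley`}{`L = 2`, `F(00) = 1`, `F(01) = F(10) = 0.5`,
#'     `F(11) = 2`: a fitness valley with a local maximum at 00 and the global
#'     maximum at 11.}
#'   \item{`additive_L3`}{`L = 3` additive with `c = 1`: single maximum 111
#'     with fitness 3.}
#'   \item{`two_peak_L3`}{`L = 3` with peaks at 000 (fitness 2) and 111
#'     (fitness 3), all other genotypes in `{0.5, 1.2}`.}
#' }
#'
#' @param name fixture identifier.
#' @return list with `landscape` (a `fitness_landscape`) and `expected`
#'   (`local_maxima`, plus worked `entropy` / `additive_variance` examples).
#' @export
make_fixture <- function(name = c("two_locus_valley", "additive_L3",
                                  "two_peak_L3")) {
  name <- match.arg(name)
  if (name == "two_locus_valley") {
    params <- landscape_params(2, "rmf", c = 0.5, lambda = 1)
    F <- c(1, 0.5, 0.5, 2)
    eta <- F - 0.5 * all_distances(2, 0L)  # 1 0 0 1
    land <- structure(list(params = params, F = F, eta = eta),
                      class = "fitness_landscape")
    expected <- list(
      local_maxima = c(0L, 3L),
      # p = (1/2, 0, 0, 1/2): distances {0, 2} equally weighted
      p_example = c(0.5, 0, 0, 0.5),
      entropy = log(2),
      additive_variance = 0.5^2 * 1  # c^2 * Var({0,2} @ 1/2) = 0.25
    )
  } else if (name == "additive_L3") {
    params <- landscape_params(3, "additive", c = 1)
    land <- generate_landscape(params)
    expected <- list(
      local_maxima = 7L,
      p_example = rep(1 / 8, 8),
      entropy = 3 * log(2),
      additive_variance = 3 / 4  # c^2 * Var(Binomial(3, 1/2))
    )
  } else {
    params <- landscape_params(3, "hoc", lambda = 1)
    F <- c(2, 0.5, 0.5, 1.2, 0.5, 1.2, 1.2, 3)
    land <- structure(list(params = params, F = F, eta = F),
                      class = "fitness_landscape")
    expected <- list(
      local_maxima = c(0L, 7L),
      p_example = c(0.5, 0, 0, 0, 0, 0, 0, 0.5),
      entropy = log(2),
      additive_variance = 0  # c = 0: no heritable additive component
    )
  }
  list(landscape = land, expected = expected)
}
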