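# Summary statistics and event detectors for evolutionary trajectories.

#' Shannon entropy of a genotype frequency distribution
#'
#' `S = -sum_g p_g ln p_g` (natural log, with `0 ln 0 := 0`). Zero for a
#' monomorphic population; maximal (`L ln 2`) for the uniform distribution
#' over all `2^L` genotypes.
#'
#' @param p frequency vector.
#' @return entropy in nats.
#' @export
entropy <- function(p) {
  if (any(p < 0)) stop("negative frequencies")
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Additive genetic variance
#'
#' The variance of the heritable (additive) fitness component in the
#' population. In the Rough Mount Fuji family the heritable part of fitness is
#' `c * d(g, sigma*)`, so `V_A = c^2 * Var_p[d(g, sigma*)]` (population
#' variance of the Hamming distance to the reference sequence, scaled to
#' squared fitness units). The raw distance variance is returned as attribute
#' `"distance_variance"`.
#'
#' @param p frequency vector of length `2^L`.
#' @param land a `fitness_landscape` of the RMF family (NK landscapes carry no
#'   reference sequence and are rejected).
#' @return additive variance (fitness^2 units).
#' @export
additive_variance <- function(p, land) {
  stopifnot(inherits(land, "fitness_landscape"))
  if (land$params$model == "nk") {
    stop("additive variance needs a reference sequence (RMF-family model)")
  }
  L <- land$params$L
  stopifnot(length(p) == 2^L)
  d <- all_distances(L, land$params$sigma_star)
  m <- sum(p * d)
  v <- sum(p * (d - m)^2)
  structure(land$params$c^2 * v, distance_variance = v)
}

#' Fitness velocity
#'
#' Per-generation rate of mean-fitness change, `v(t) = Fbar(t) - Fbar(t-1)`,
#' optionally smoothed with a centered moving average. Crossings of the
#' velocities of a recombining and a non-recombining population correspond to
#' local extrema of their mean-fitness difference.
#'
#' @param fbar numeric series of mean fitness values (length >= 2).
#' @param window moving-average window (1 = raw first differences).
#' @return numeric vector of length `length(fbar) - 1`; smoothed entries that
#'   lack a full window are `NA`.
#' @export
velocity <- function(fbar, window = 1L) {
  if (length(fbar) < 2) stop("series shorter than 2")
  if (window < 1) stop("window must be >= 1")
  v <- diff(fbar)
  if (window > 1) {
    v <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  }
  v
}

#' Detect trapping and escape events
#'
#' A trapping event opens when the modal genotype is a local fitness maximum
#' and its frequency reaches `theta_trap`; it closes (an escape) at the first
#' later generation where that genotype's frequency falls below
#' `theta_escape`. Events are non-overlapping and chronologically ordered.
#' The trajectory must carry its full frequency matrix
#' (`keep_frequencies = TRUE` in [run_finite()] / [run_infinite()]), since the
#' escape condition refers to the trapped genotype's own frequency, not the
#' modal one.
#'
#' @param traj an `evo_trajectory` with the `"frequencies"` attribute.
#' @param land the `fitness_landscape` the trajectory ran on.
#' @param theta_trap,theta_escape thresholds in `(0, 1)`,
#'   `theta_escape < theta_trap`.
#' @return data frame with columns `genotype`, `t_start`, `t_end` (`NA` if
#'   unresolved at the end of the series), `distance_from_start`.
#' @export
detect_trap_escape <- function(traj, land, theta_trap = 0.95,
                               theta_escape = 0.5) {
  stopifnot(inherits(traj, "evo_trajectory"))
  if (!(theta_trap > 0 && theta_trap < 1 && theta_escape > 0 &&
        theta_escape < 1) || theta_escape >= theta_trap) {
    stop("need 0 < theta_escape < theta_trap < 1")
  }
  freq <- attr(traj, "frequencies")
  if (is.null(freq)) {
    stop("trajectory lacks frequencies; rerun with keep_frequencies = TRUE")
  }
  L <- land$params$L
  is_max <- logical(2^L); is_max[local_maxima(land) + 1L] <- TRUE
  start <- traj$modal_genotype[1]
  ev_g <- integer(0); ev_s <- integer(0); ev_e <- integer(0)
  open_g <- NA_integer_
  for (row in seq_len(nrow(traj))) {
    if (is.na(open_g)) {
      m <- traj$modal_genotype[row]
      if (is_max[m + 1L] && traj$modal_frequency[row] >= theta_trap) {
        open_g <- m
        ev_g <- c(ev_g, m); ev_s <- c(ev_s, traj$t[row])
        ev_e <- c(ev_e, NA_integer_)
      }
    } else if (freq[row, open_g + 1L] < theta_escape) {
      ev_e[length(ev_e)] <- traj$t[row]
      open_g <- NA_integer_
    }
  }
  data.frame(genotype = ev_g, t_start = ev_s, t_end = ev_e,
             distance_from_start = if (length(ev_g)) {
               hamming_distance(ev_g, rep(start, length(ev_g)), L)
             } else integer(0))
}

#' Escape fraction of an ensemble
#'
#' Ratio of escape events to trapping events within a horizon: trappings are
#' counted if opened by generation `horizon`, escapes if also closed by then.
#' With no trapping events the ratio is undefined and `NA` is returned.
#'
#' @param events data frame of trap events (rows from [detect_trap_escape()]
#'   across an ensemble, `rbind`-ed).
#' @param horizon generation cutoff (default `Inf`).
#' @param baseline optional unnormalized escape fraction of a matched `r = 0`
#'   ensemble; when given, the value is divided by it.
#' @return a number in `[0, 1]` (before normalization), or `NA` if undefined.
#' @export
escape_fraction <- function(events, horizon = Inf, baseline = NULL) {
  opened <- events$t_start <= horizon
  n_t <- sum(opened)
  if (n_t == 0) return(NA_real_)
  n_e <- sum(opened & !is.na(events$t_end) & events$t_end <= horizon)
  f <- n_e / n_t
  if (!is.null(baseline)) f <- f / baseline
  f
}

#' Distance of the first trapping event
#'
#' Hamming distance from the starting genotype to the genotype of the
#' chronologically first trapping event.
#'
#' @param events data frame from [detect_trap_escape()].
#' @param start starting genotype index.
#' @param L number of loci.
#' @return integer distance, or `NA` if there are no events.
#' @export
first_trap_distance <- function(events, start, L) {
  if (nrow(events) == 0) return(NA_integer_)
  g <- events$genotype[which.min(events$t_start)]
  hamming_distance(g, start, L)
}

#' Paired-ensemble difference series
#'
#' Run-averaged differences between paired recombining and non-recombining
#' trajectories evolved on the same landscape realizations:
#' `delta_F(t) = <Fbar_r(t) - Fbar_nr(t)>`, analogously `delta_S` (entropy)
#' and `delta_Fmax` (fittest present genotype), and
#' `P_plus(t)`, the fraction of pairs in which the recombining population has
#' the higher mean fitness (exact ties count 1/2, so identical pairs sit at
#' the null value 0.5). Standard errors of `delta_F` across pairs are
#' included.
#'
#' @param runs_r,runs_nr equal-length lists of `evo_trajectory` objects with
#'   identical generation grids.
#' @return data frame with columns `t`, `delta_F`, `se_delta_F`, `delta_S`,
#'   `se_delta_S`, `delta_Fmax`, `P_plus`, `n_pairs` (the `se_*` columns are
#'   standard errors across pairs).
#' @export
delta_series <- function(runs_r, runs_nr) {
  stopifnot(length(runs_r) == length(runs_nr), length(runs_r) >= 1)
  n <- length(runs_r)
  tt <- runs_r[[1]]$t
  for (k in seq_len(n)) {
    if (nrow(runs_r[[k]]) != length(tt) || nrow(runs_nr[[k]]) != length(tt)) {
      stop("trajectory length mismatch")
    }
  }
  dF <- vapply(seq_len(n),
               function(k) runs_r[[k]]$mean_fitness - runs_nr[[k]]$mean_fitness,
               numeric(length(tt)))
  dS <- vapply(seq_len(n),
               function(k) runs_r[[k]]$entropy - runs_nr[[k]]$entropy,
               numeric(length(tt)))
  dM <- vapply(seq_len(n),
               function(k) runs_r[[k]]$max_fitness - runs_nr[[k]]$max_fitness,
               numeric(length(tt)))
  dF <- matrix(dF, nrow = length(tt))
  dS <- matrix(dS, nrow = length(tt))
  dM <- matrix(dM, nrow = length(tt))
  pplus <- rowMeans((dF > 0) + 0.5 * (dF == 0))
  se <- apply(dF, 1, stats::sd) / sqrt(n)
  se_s <- apply(dS, 1, stats::sd) / sqrt(n)
  structure(
    data.frame(t = tt, delta_F = rowMeans(dF), se_delta_F = se,
               delta_S = rowMeans(dS), se_delta_S = se_s,
               delta_Fmax = rowMeans(dM), P_plus = pplus, n_pairs = n),
    # per-pair mean-fitness differences (t x n_pairs), for windowed
    # per-run statistics
    delta_F_runs = dF)
}

#' Summary of the transitory advantage
#'
#' Locates the maximum of a mean-fitness difference series: the generation
#' `t_max` of the (earliest) maximum, the maximal advantage `delta_max`, and
#' `t_zero`, the first generation after `t_max` at which the difference is
#' `<= 0` (`NA` if it stays positive within the horizon).
#'
#' @param delta a numeric `delta_F` series, or a data frame with columns `t`
#'   and `delta_F` (as from [delta_series()]).
#' @param horizon optional last generation to consider.
#' @return list with `t_max`, `delta_max`, `t_zero`.
#' @export
advantage_summary <- function(delta, horizon = NULL) {
  if (is.data.frame(delta)) {
    tt <- delta$t
    x <- delta$delta_F
  } else {
    x <- as.numeric(delta)
    tt <- seq_along(x) - 1L
  }
  if (!is.null(horizon)) {
    keep <- tt <= horizon
    tt <- tt[keep]; x <- x[keep]
  }
  if (length(x) == 0) stop("empty series")
  i <- which.max(x)
  after <- which(tt > tt[i] & x <= 0)
  list(t_max = tt[i], delta_max = x[i],
       t_zero = if (length(after)) tt[min(after)] else NA_integer_)
}

#' Coefficient of variation of off-peak population size
#'
#' Over all (run, generation) pairs at which the most populated genotype is a
#' local fitness maximum, collects the number of individuals *not* on that
#' genotype (a proxy for the number of valley mutants available for escape)
#' and returns the sample coefficient of variation (sd / mean) of that
#' collection.
#'
#' @param trajs list of finite-engine `evo_trajectory` objects.
#' @param land the shared `fitness_landscape` (or a list of landscapes, one
#'   per trajectory).
#' @return the coefficient of variation.
#' @export
offpeak_cv <- function(trajs, land) {
  lands <- if (inherits(land, "fitness_landscape")) {
    rep(list(land), length(trajs))
  } else land
  vals <- numeric(0)
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    dpk <- attr(tr, "dynamics_params")
    L <- lands[[k]]$params$L
    is_max <- logical(2^L); is_max[local_maxima(lands[[k]]) + 1L] <- TRUE
    on_peak <- is_max[tr$modal_genotype + 1L]
    vals <- c(vals, dpk$N * (1 - tr$modal_frequency[on_peak]))
  }
  if (length(vals) == 0) stop("no generations with the mode on a local maximum")
  if (mean(vals) == 0) return(0)
  stats::sd(vals) / mean(vals)
}
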