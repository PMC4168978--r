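# Plain-text output formats: TSV bodies with the configuration echoed as
# JSON header comment lines prefixed "#".

json_header <- function(x) {
  paste0("# ", jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

unclass_params <- function(p) {
  if (is.null(p)) return(NULL)
  out <- unclass(p)
  out[!vapply(out, is.null, logical(1))]
}

#' Write a trajectory to TSV
#'
#' One row per generation with columns `t`, `mean_fitness`, `max_fitness`,
#' `entropy`, `additive_variance`, `modal_genotype_bits`, `modal_frequency`,
#' `trapped_flag`, `reset_flag`. The landscape and dynamics configuration are
#' echoed as `#`-prefixed JSON header lines.
#'
#' @param traj an `evo_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "evo_trajectory"))
  lp <- attr(traj, "landscape_params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    json_header(list(engine = attr(traj, "engine"),
                     landscape = unclass_params(lp),
                     dynamics = unclass_params(attr(traj, "dynamics_params")),
                     seascape = unclass_params(attr(traj, "seascape_params")),
                     seed = attr(traj, "seed"))),
    paste(c("t", "mean_fitness", "max_fitness", "entropy",
            "additive_variance", "modal_genotype_bits", "modal_frequency",
            "trapped_flag", "reset_flag"), collapse = "\t")
  ), con)
  body <- data.frame(
    t = traj$t,
    mean_fitness = sprintf("%.17g", traj$mean_fitness),
    max_fitness = sprintf("%.17g", traj$max_fitness),
    entropy = sprintf("%.17g", traj$entropy),
    additive_variance = ifelse(is.na(traj$additive_variance), "NA",
                               sprintf("%.17g", traj$additive_variance)),
    modal_genotype_bits = genotype_bits(traj$modal_genotype, lp$L),
    modal_frequency = sprintf("%.17g", traj$modal_frequency),
    trapped_flag = as.integer(traj$trapped),
    reset_flag = as.integer(traj$reset_flag)
  )
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a paired-ensemble difference series to TSV
#'
#' Columns `t`, `delta_F`, `delta_S`, `delta_Fmax`, `P_plus`, `n_pairs`, with
#' the experiment configuration (including the master seed) as JSON header
#' comments.
#'
#' @param pe a `paired_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(pe, path) {
  stopifnot(inherits(pe, "paired_ensemble"))
  cfg <- pe$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    json_header(list(landscape = unclass_params(cfg$landscape),
                     dynamics = unclass_params(cfg$dynamics),
                     seascape = if (!is.null(cfg$seascape)) {
                       list(p_reset = cfg$seascape$p_reset,
                            mode = cfg$seascape$mode)
                     },
                     t_max = cfg$t_max, n_runs = cfg$n_runs,
                     master_seed = cfg$master_seed,
                     start_mode = cfg$start_mode)),
    paste(c("t", "delta_F", "delta_S", "delta_Fmax", "P_plus", "n_pairs"),
          collapse = "\t")
  ), con)
  d <- pe$delta
  body <- data.frame(t = d$t,
                     delta_F = sprintf("%.17g", d$delta_F),
                     delta_S = sprintf("%.17g", d$delta_S),
                     delta_Fmax = sprintf("%.17g", d$delta_Fmax),
                     P_plus = sprintf("%.17g", d$P_plus),
                     n_pairs = d$n_pairs)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write trapping/escape events to TSV
#'
#' Columns `run_id`, `genotype_bits`, `t_start`, `t_end`, `distance`.
#'
#' @param events event data frame (with a `run` column, as produced by
#'   [paired_ensemble()] with `detect_traps = TRUE`).
#' @param L number of loci (for the bit-string column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, L, path) {
  df <- data.frame(
    run_id = if ("run" %in% names(events)) events$run
             else rep(NA_integer_, nrow(events)),
    genotype_bits = if (nrow(events)) genotype_bits(events$genotype, L)
                    else character(0),
    t_start = events$t_start, t_end = events$t_end,
    distance = events$distance_from_start
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
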