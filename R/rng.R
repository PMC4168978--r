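#' Evaluate code with a temporary RNG seed
#'
#' Sets the global RNG to `seed`, evaluates `code`, and restores the previous
#' RNG state afterwards, so library calls do not perturb a caller's stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Counter-based seed schedule
#'
#' Derives reproducible role seeds for run `run` of an ensemble from a master
#' seed. Roles: 1 = landscape, 2 = dynamics (recombining), 3 = dynamics
#' (non-recombining), 4 = environment (seascape resets). The derivation is
#' counter-based (it depends only on `master`, `run`, `role`), so an ensemble
#' can be extended with more runs without re-running earlier ones.
#'
#' All arithmetic stays below 2^53 and the result below 2^31, so the schedule
#' is exact in double precision and valid as an R integer seed.
#'
#' @param master master seed (non-negative integer).
#' @param run run counter (integer >= 1).
#' @param role role counter (integer >= 1).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, run, role = 1L) {
  stopifnot(length(master) == 1L, length(run) == 1L, length(role) == 1L,
            master >= 0, run >= 1, role >= 1)
  key <- (abs(master) + 7919 * run + 131 * role) %% 2147483647
  with_seed(as.integer(key), sample.int(2147483646L, 1L))
}
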