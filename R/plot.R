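# Base-graphics plot methods.

#' Plot an evolutionary trajectory
#'
#' Mean fitness (solid) and fitness of the fittest present genotype (dashed)
#' against time; generations preceded by a seascape reset are marked by
#' vertical ticks.
#'
#' @param x an `evo_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.evo_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$mean_fitness, type = "l",
                 xlab = "generation t", ylab = "fitness", ...)
  graphics::lines(x$t, x$max_fitness, lty = 2)
  if (any(x$reset_flag)) {
    graphics::abline(v = x$t[x$reset_flag], col = "grey80")
  }
  graphics::legend("bottomright", c("mean fitness", "max fitness"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Plot a paired-ensemble difference series
#'
#' The run-averaged mean-fitness advantage of recombination
#' `delta_F(t)` with a +/- 1 SE band, and `P_plus(t)` on a secondary panel.
#'
#' @param x a `paired_ensemble`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.paired_ensemble <- function(x, ...) {
  d <- x$delta
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(d$t, d$delta_F, type = "l",
                 xlab = "generation t", ylab = expression(Delta * F), ...)
  graphics::lines(d$t, d$delta_F + d$se_delta_F, col = "grey70")
  graphics::lines(d$t, d$delta_F - d$se_delta_F, col = "grey70")
  graphics::abline(h = 0, lty = 3)
  graphics::plot(d$t, d$P_plus, type = "l", ylim = c(0, 1),
                 xlab = "generation t", ylab = expression(P["+"]))
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
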