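# summary/plot methods for the model object.

#' Summarise an invasion model
#'
#' Equilibria and stability of the invaded system at the model's
#' parameter values, plus the scenario-region label at its
#' `(alpha, beta)` point.
#'
#' @param object an [invasion_model()].
#' @param ... unused.
#' @return A `summary.invasion_model` list: `params`, `equilibria`,
#'   `stability`, `cell` (the [classify_cell()] row) and
#'   `region3_boundary`.
#' @export
summary.invasion_model <- function(object, ...) {
  out <- list(params = coef(object),
              equilibria = equilibria(object),
              stability = stability(object),
              cell = classify_cell(object$alpha, object$beta, object),
              region3_boundary = region3_boundary(object))
  class(out) <- "summary.invasion_model"
  out
}

#' @export
print.summary.invasion_model <- function(x, ...) {
  cat("Three-species invasion model summary\n\n")
  cat("Equilibria:\n")
  eq <- x$equilibria
  eq[c("X", "Y", "Z", "existence_margin")] <-
    lapply(eq[c("X", "Y", "Z", "existence_margin")], signif, digits = 6)
  print(eq, row.names = FALSE)
  cat("\nStability:\n")
  st <- x$stability
  st[c("lambda1", "lambda2", "lambda3", "margin")] <-
    lapply(st[c("lambda1", "lambda2", "lambda3", "margin")],
           signif, digits = 6)
  print(st, row.names = FALSE)
  cat(sprintf("\nScenario region at (alpha = %g, beta = %g): %s (stable: %s)\n",
              x$cell$alpha, x$cell$beta, x$cell$region, x$cell$stable_set))
  cat(sprintf("Region I/III predation-ratio boundary alpha = r/(c d) = %g\n",
              x$region3_boundary))
  invisible(x)
}

#' Plot the native predator's equilibrium response to predation rate
#'
#' Draws `y_s(d) = r (d - d*/2)/d^2` over a range of predation rates,
#' marking the maximising rate `d* = 2q/(Kp)` and the model's own `d`.
#'
#' @param x an [invasion_model()].
#' @param d_range range of predation rates (default `d*/10` to `10 d*`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.invasion_model <- function(x, d_range = NULL, ...) {
  dstar <- optimal_predation_rate(x)
  if (is.null(d_range)) d_range <- c(dstar / 10, 10 * dstar)
  dd <- seq(d_range[1], d_range[2], length.out = 400)
  ys <- predator_density_vs_d(x, dd)
  graphics::plot(dd, ys, type = "l", xlab = "predation rate d (1/(indiv. year))",
                 ylab = "native predator equilibrium density y_s", ...)
  graphics::abline(v = dstar, lty = 2)
  graphics::abline(v = x$d, lty = 3, col = "grey40")
  graphics::mtext(sprintf("d* = %g", dstar), side = 3, adj = 0, cex = 0.8)
  invisible(x)
}
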