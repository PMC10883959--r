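# Impact of exotic presence on native densities: the trophic-cascade
# style ratios R1 = X/x_s and R2 = Y/y_s, their variation over the
# (alpha, beta) plane, and a qualitative outcome table.

#' Impact ratios of exotic presence on native densities
#'
#' Simulates the invaded system and compares the long-run native
#' densities against the native coexistence equilibrium `(x_s, y_s)`
#' that the community occupies when the exotic is absent:
#' `R1 = X / x_s`, `R2 = Y / y_s`, with `X`, `Y` the trailing-window
#' means of the run.  `R1 > 1` means the prey is denser with the exotic
#' present; `R2 < 1` means the native predator is depressed.  The
#' baseline is analytic, not simulated: the coexistence equilibrium of
#' the native system is globally attracting whenever it exists, so a
#' paired baseline run would add only noise.
#'
#' @param m an [invasion_model()].
#' @param init initial densities, default `(15, 10, 2)` (the reference
#'   impact analyses' choice).
#' @param t_end,n_save simulation horizon and saved points.
#' @param eps_extinct,eps_persist outcome-classification thresholds,
#'   see [classify_outcome()].
#' @return A one-row data frame: `alpha`, `beta`, `s`, `R1`, `R2`,
#'   `outcome`, `X_final`, `Y_final`, `Z_final` (trailing-window means).
#' @examples
#' m <- fixture("mink", alpha = 0.6, beta = 0.5)
#' impact_ratios(m)   # prey up (R1 > 1), native predator down (R2 < 1)
#' @export
impact_ratios <- function(m, init = c(15, 10, 2), t_end = 5000,
                          n_save = 500, eps_extinct = 1e-4,
                          eps_persist = 1e-2) {
  stopifnot(inherits(m, "invasion_model"))
  nat <- native_equilibria(m)
  exy <- nat[nat$label == "EXY" & nat$exists, , drop = FALSE]
  if (nrow(exy) != 1L)
    stop("impact ratios need the exotic-absent baseline (x_s, y_s); ",
         "the native coexistence equilibrium does not exist", call. = FALSE)
  tr <- integrate_model(m, init, t_end = t_end, n_save = n_save)
  mu <- trailing_means(tr)
  data.frame(alpha = m$alpha, beta = m$beta, s = m$s,
             R1 = mu[["X"]] / exy$X, R2 = mu[["Y"]] / exy$Y,
             outcome = classify_outcome(tr, eps_extinct, eps_persist),
             X_final = mu[["X"]], Y_final = mu[["Y"]], Z_final = mu[["Z"]],
             stringsAsFactors = FALSE)
}

#' Impact ratios over an (alpha, beta) grid
#'
#' [impact_ratios()] at every grid cell, repeated for each exotic
#' intrinsic growth rate in `s_values`; deterministic.
#'
#' @param m an [invasion_model()] (its `alpha`, `beta`, `s` are
#'   overridden per cell).
#' @param grid a [grid_spec()].
#' @param s_values exotic growth rates to sweep (default `0.2`).
#' @param ... passed to [impact_ratios()].
#' @return A data frame with one row per (cell, s) combination.
#' @export
impact_grid <- function(m, grid = grid_spec(), s_values = 0.2, ...) {
  stopifnot(inherits(grid, "grid_spec"), all(s_values > 0))
  rows <- vector("list",
                 length(grid$alpha) * length(grid$beta) * length(s_values))
  k <- 0L
  for (sv in s_values) for (a in grid$alpha) for (b in grid$beta) {
    k <- k + 1L
    rows[[k]] <- impact_ratios(set_params(m, alpha = a, beta = b, s = sv),
                               ...)
  }
  do.call(rbind, rows)
}

#' Qualitative outcome table for selected (alpha, beta) pairs
#'
#' Reproduces the qualitative reading of the impact analysis: for each
#' pair, the prey response is `"increase"` when `R1 > 1`, `"collapse"`
#' when the final prey density falls below 1 individual (an order of
#' magnitude under the baseline, bordering extinction), and
#' `"decrease"` otherwise; the native predator's fate is `"extinct"`
#' below `eps_extinct`, `"declines"` when `R2 < 1`, else `"persists"`.
#' Final densities are attached so a collapse with a tiny positive
#' equilibrium is distinguishable from thresholded extinction.
#'
#' @param m an [invasion_model()] (its `alpha`, `beta` are overridden).
#' @param pairs a two-column matrix or data frame of (alpha, beta)
#'   pairs; default the six reference pairs
#'   (0.6,0.5), (0.7,2), (1.2,0.5), (1.5,2), (4,2), (8,2).
#' @param eps_extinct extinction threshold (default `1e-4`).
#' @param ... passed to [impact_ratios()].
#' @return A data frame: `alpha`, `beta`, `R1`, `R2`, `prey_response`,
#'   `predator_fate`, `X_final`, `Y_final`, `Z_final`, `outcome`.
#' @examples
#' \donttest{
#' table5_summary(fixture("mink", alpha = 1, beta = 1))
#' }
#' @export
table5_summary <- function(m, pairs = NULL, eps_extinct = 1e-4, ...) {
  stopifnot(inherits(m, "invasion_model"))
  if (is.null(pairs))
    pairs <- rbind(c(0.6, 0.5), c(0.7, 2), c(1.2, 0.5),
                   c(1.5, 2), c(4, 2), c(8, 2))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, nrow(pairs) >= 1)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    im <- impact_ratios(set_params(m, alpha = pairs[i, 1],
                                   beta = pairs[i, 2]),
                        eps_extinct = eps_extinct, ...)
    prey <- if (im$R1 > 1) "increase"
            else if (im$X_final < 1) "collapse"
            else "decrease"
    pred <- if (im$Y_final < eps_extinct) "extinct"
            else if (im$R2 < 1) "declines"
            else "persists"
    cbind(im[c("alpha", "beta", "R1", "R2")],
          data.frame(prey_response = prey, predator_fate = pred,
                     stringsAsFactors = FALSE),
          im[c("X_final", "Y_final", "Z_final", "outcome")])
  })
  do.call(rbind, rows)
}
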