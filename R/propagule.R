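# Minimum propagule size Z* for establishment of the exotic predator
# introduced into the native system at its coexistence equilibrium.

#' Does a propagule of size z0 establish?
#'
#' Simulates the invaded system from `(x_s, y_s, z0)` - the native
#' coexistence equilibrium plus an exotic propagule - and reports
#' whether the exotic persists: trailing-window mean of `Z` above
#' `eps_persist`.  The construction presupposes that the native
#' coexistence equilibrium exists (`p d K > q`).
#'
#' @param m an [invasion_model()].
#' @param z0 propagule size (initial exotic density), `z0 >= 0`.
#' @param t_end,n_save,eps_persist simulation horizon, saved points and
#'   persistence threshold.
#' @return `TRUE` if the exotic establishes.
#' @examples
#' m <- set_params(fixture("theoretical", alpha = 1, beta = 1), b = 0.04)
#' establishes(m, 20)    # TRUE: converges to the prey-exotic state
#' establishes(m, 0.01)  # FALSE: returns to the native equilibrium
#' @export
establishes <- function(m, z0, t_end = 5000, n_save = 500,
                        eps_persist = 1e-2) {
  stopifnot(inherits(m, "invasion_model"), z0 >= 0)
  nat <- native_equilibria(m)
  exy <- nat[nat$label == "EXY" & nat$exists, , drop = FALSE]
  if (nrow(exy) != 1L)
    stop("the native coexistence equilibrium does not exist (p d K <= q); ",
         "a propagule cannot enter the native system at equilibrium",
         call. = FALSE)
  tr <- integrate_model(m, c(exy$X, exy$Y, z0), t_end = t_end,
                        n_save = n_save)
  if (!isTRUE(attr(tr, "solver_ok")))
    stop("solver failure during establishment probe", call. = FALSE)
  unname(trailing_means(tr)[["Z"]] > eps_persist)
}

#' Minimum propagule size for establishment
#'
#' Finds the smallest exotic propagule `Z*` from which the exotic
#' establishes when introduced into the native system at equilibrium.
#' An ascending geometric scan of 20 propagule sizes over
#' `[1e-3, z_max]` locates the first establishing value; bisection then
#' narrows the failing/establishing bracket to width `tol`.  If even
#' `z0 = 1e-3` establishes (the native equilibrium is unstable to
#' exotic invasion), `Z*` is effectively zero and reported as `tol`.
#' If no scanned size up to `z_max` establishes, `z_star` is `NA`
#' (sentinel for "not establishable") - kept distinct from a tiny `Z*`,
#' which means the opposite (any positive propagule grows).  Optionally
#' `fig7_coding = TRUE` recodes the sentinel as 0, the convention of the
#' reference grayscale map.
#'
#' Establishment is assumed monotone in `z0` for the bisection; the scan
#' verifies this and sets `monotone_ok = FALSE` (with a warning) if an
#' establishing size precedes a failing one.
#'
#' @param m an [invasion_model()].
#' @param z_max largest propagule size probed (default 50).
#' @param tol bracket width at which bisection stops (default `1e-3`).
#' @param fig7_coding report non-establishment as `z_star = 0` instead
#'   of `NA`.
#' @param ... passed to [establishes()] (e.g. `t_end`).
#' @return A one-row data frame of class `propagule_result`: `alpha`,
#'   `beta`, `z_star`, `bracket_lo` (largest failing size),
#'   `bracket_hi` (smallest establishing size), `monotone_ok`,
#'   `establishable`.
#' @examples
#' m <- set_params(fixture("theoretical", alpha = 1, beta = 1), b = 0.04)
#' min_propagule(m, t_end = 2000)
#' @export
min_propagule <- function(m, z_max = 50, tol = 1e-3, fig7_coding = FALSE,
                          ...) {
  stopifnot(inherits(m, "invasion_model"), z_max > 1e-3, tol > 0)
  z_grid <- exp(seq(log(1e-3), log(z_max), length.out = 20))
  est <- vapply(z_grid, function(z) establishes(m, z, ...), logical(1))

  first <- which(est)[1]
  monotone_ok <- TRUE
  if (!is.na(first) && first < length(est) && any(!est[first:length(est)])) {
    monotone_ok <- FALSE
    warning("establishment is not monotone in propagule size on the scan; ",
            "bisection bracket may be unreliable", call. = FALSE)
  }

  if (is.na(first)) {
    res <- data.frame(alpha = m$alpha, beta = m$beta,
                      z_star = if (fig7_coding) 0 else NA_real_,
                      bracket_lo = z_max, bracket_hi = NA_real_,
                      monotone_ok = monotone_ok, establishable = FALSE)
  } else if (first == 1L) {
    res <- data.frame(alpha = m$alpha, beta = m$beta, z_star = tol,
                      bracket_lo = 0, bracket_hi = z_grid[1],
                      monotone_ok = monotone_ok, establishable = TRUE)
  } else {
    lo <- z_grid[first - 1L]; hi <- z_grid[first]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (establishes(m, mid, ...)) hi <- mid else lo <- mid
    }
    res <- data.frame(alpha = m$alpha, beta = m$beta, z_star = (lo + hi) / 2,
                      bracket_lo = lo, bracket_hi = hi,
                      monotone_ok = monotone_ok, establishable = TRUE)
  }
  class(res) <- c("propagule_result", "data.frame")
  res
}

#' Minimum propagule size over an (alpha, beta) grid
#'
#' [min_propagule()] at every cell of the grid; deterministic.
#'
#' @param m an [invasion_model()] (its `alpha`, `beta` are overridden).
#' @param grid a [grid_spec()].
#' @param ... passed to [min_propagule()].
#' @return A data frame with one `propagule_result` row per cell.
#' @export
zstar_grid <- function(m, grid = grid_spec(), ...) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- vector("list", length(grid$alpha) * length(grid$beta))
  k <- 0L
  for (a in grid$alpha) for (b in grid$beta) {
    k <- k + 1L
    rows[[k]] <- min_propagule(set_params(m, alpha = a, beta = b), ...)
  }
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  out
}
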