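# Classification of the (alpha, beta) predation/competition plane into
# establishment-scenario regions, including bistable overlaps.

#' Specify a rectangular (alpha, beta) grid
#'
#' Evenly spaced, inclusive of both ends.  The default spans
#' \[0.05, 2.5\] at 101 points per axis, covering the span of the
#' reference scenario maps.
#'
#' @param alpha_min,alpha_max,alpha_n range and size of the alpha axis.
#' @param beta_min,beta_max,beta_n range and size of the beta axis.
#' @return A `grid_spec` list with the two point vectors.
#' @examples
#' grid_spec(alpha_n = 11, beta_n = 11)
#' @export
grid_spec <- function(alpha_min = 0.05, alpha_max = 2.5, alpha_n = 101,
                      beta_min = 0.05, beta_max = 2.5, beta_n = 101) {
  stopifnot(alpha_min > 0, beta_min > 0, alpha_min < alpha_max,
            beta_min < beta_max, alpha_n >= 2, beta_n >= 2)
  structure(list(alpha = seq(alpha_min, alpha_max, length.out = alpha_n),
                 beta = seq(beta_min, beta_max, length.out = beta_n)),
            class = "grid_spec")
}

#' Classify one point of the (alpha, beta) plane
#'
#' Assembles the set of simultaneously stable attractors at
#' `(alpha, beta)` - `EXY` / `EXZ` / `EZ` from the analytic predicates
#' ([classify_analytic()]), the admissible interior `ES` from eigenvalue
#' classification - and maps it to a scenario region:
#' `{EXY}` alone is region I (exotic cannot grow); overlaps of `EXY`
#' with `EXZ` or `EZ` are the bistable regions `I+II` / `I+III`, where
#' the outcome depends on the propagule size; without `EXY`, a stable
#' `ES` is region IV, a stable `EXZ` region II, a stable `EZ` region
#' III; any other combination is `"other"`.  Cells with any margin
#' within `tol_marginal` of zero are flagged `marginal`.
#'
#' @param alpha,beta exotic-to-native predation and competition ratios.
#' @param m an [invasion_model()] whose `alpha`, `beta` are overridden.
#' @param tol_marginal marginal band on analytic margins (default `1e-6`).
#' @param eigen_tol eigenvalue marginal band for `ES` (default `1e-7`).
#' @return A one-row data frame: `alpha`, `beta`, `stable_set`
#'   (comma-separated), `region`, `marginal`.
#' @examples
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' classify_cell(1, 1, set_params(m, b = 0.04))   # bistable I+II
#' @export
classify_cell <- function(alpha, beta, m, tol_marginal = 1e-6,
                          eigen_tol = 1e-7) {
  stopifnot(alpha > 0, beta > 0)
  m <- set_params(m, alpha = alpha, beta = beta)
  stable <- character(0)
  marginal <- FALSE

  exy_exists <- m$p * m$d * m$K - m$q
  if (abs(exy_exists) <= tol_marginal) marginal <- TRUE
  if (exy_exists > tol_marginal) {
    a <- classify_analytic("EXY", m, tol = tol_marginal)
    if (a$class == "marginal") marginal <- TRUE
    if (a$class == "stable") stable <- c(stable, "EXY")
  }

  exz_exists <- m$r - m$alpha * m$d * m$c
  if (abs(exz_exists) <= tol_marginal) marginal <- TRUE
  if (exz_exists > tol_marginal) {
    a <- classify_analytic("EXZ", m, tol = tol_marginal)
    if (a$class == "marginal") marginal <- TRUE
    if (a$class == "stable") stable <- c(stable, "EXZ")
  }

  a <- classify_analytic("EZ", m, tol = tol_marginal)
  if (a$class == "marginal") marginal <- TRUE
  if (a$class == "stable") stable <- c(stable, "EZ")

  ints <- interior_equilibria(m)
  if (nrow(ints)) {
    adm <- ints[ints$admissible & ints$exists, , drop = FALSE]
    if (any(ints$marginal)) marginal <- TRUE
    if (nrow(adm)) {
      num <- classify_numeric(adm[1, , drop = FALSE], m, tol = eigen_tol)
      if (num$class == "marginal") marginal <- TRUE
      if (num$class == "stable") stable <- c(stable, "ES")
    }
  }

  data.frame(alpha = alpha, beta = beta,
             stable_set = paste(stable, collapse = ","),
             region = region_from_set(stable), marginal = marginal,
             stringsAsFactors = FALSE)
}

region_from_set <- function(stable) {
  if ("EXY" %in% stable) {
    if (setequal(stable, "EXY")) return("I")
    if (setequal(stable, c("EXY", "EXZ"))) return("I+II")
    if (setequal(stable, c("EXY", "EZ"))) return("I+III")
    return("other")
  }
  if ("ES" %in% stable && setequal(stable, "ES")) return("IV")
  if (setequal(stable, "EXZ")) return("II")
  if (setequal(stable, "EZ")) return("III")
  "other"
}

#' Scan a grid of the (alpha, beta) plane
#'
#' [classify_cell()] at every grid point, row-major (alpha outer, beta
#' inner); deterministic and pointwise, so refining the grid never
#' changes the label of an existing non-marginal point.
#'
#' @param m an [invasion_model()] (its `alpha`, `beta` are overridden).
#' @param grid a [grid_spec()].
#' @param ... passed to [classify_cell()].
#' @return A data frame of class `scenario_grid` with one row per cell.
#' @examples
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' sc <- scenario_scan(m, grid_spec(alpha_n = 9, beta_n = 9))
#' table(sc$region)
#' @export
scenario_scan <- function(m, grid = grid_spec(), ...) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- vector("list", length(grid$alpha) * length(grid$beta))
  k <- 0L
  for (a in grid$alpha) for (b in grid$beta) {
    k <- k + 1L
    rows[[k]] <- classify_cell(a, b, m, ...)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_grid", "data.frame")
  out
}

#' @export
plot.scenario_grid <- function(x, ...) {
  al <- sort(unique(x$alpha)); be <- sort(unique(x$beta))
  lv <- c("I", "II", "III", "IV", "I+II", "I+III", "other")
  z <- matrix(match(x$region, lv), nrow = length(al), byrow = TRUE)
  cols <- c("grey85", "steelblue", "firebrick", "forestgreen",
            "lightblue", "salmon", "white")
  graphics::image(al, be, z, col = cols[sort(unique(as.vector(z)))],
                  xlab = expression(alpha), ylab = expression(beta), ...)
  graphics::legend("topright", legend = lv[sort(unique(as.vector(z)))],
                   fill = cols[sort(unique(as.vector(z)))], bty = "n",
                   bg = "white")
  invisible(x)
}

#' Predation-ratio boundary between regions I and III
#'
#' The threshold `alpha = r / (c d)`: above it the exotic's predation
#' pressure at its guaranteed capacity `c` exceeds the prey's intrinsic
#' growth, the prey-present state `EXZ` ceases to exist and the
#' exotic-only state `EZ` becomes stable.  Decreasing in `d`.
#'
#' @param m an [invasion_model()].
#' @return \code{r / (c * d)}.
#' @examples
#' region3_boundary(fixture("theoretical", alpha = 1, beta = 1))  # 1.2
#' region3_boundary(fixture("mink", alpha = 1, beta = 1))         # 240
#' @export
region3_boundary <- function(m) {
  stopifnot(inherits(m, "invasion_model"))
  m$r / (m$c * m$d)
}
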