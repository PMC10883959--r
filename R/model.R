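#' Construct a three-species invasion model
#'
#' Bundles the eleven positive parameters of the invasion model into a
#' classed object used by every analysis function in the package.  All
#' rates are per year and densities in individuals; `alpha` and `beta`
#' are the unitless proportionality constants relating the exotic
#' predator's predation rate (`alpha * d`) and the competition pressure
#' it exerts on the native predator (`beta * b`) to the corresponding
#' native coefficients.
#'
#' @param r intrinsic growth rate of the native prey (1/year).
#' @param s intrinsic growth rate of the exotic predator (1/year).
#' @param K carrying capacity of the native prey (individuals).
#' @param c carrying-capacity floor of the exotic predator guaranteed by
#'   alternative food (individuals).
#' @param n enlarger of the exotic predator's carrying capacity
#'   (individuals * year); the prey-dependent capacity is
#'   `kappa(X) = n * alpha * d * X + c`.
#' @param b competition coefficient acting on the exotic predator
#'   (1/(individuals * year)); the native predator suffers `beta * b`.
#' @param d predation rate of the native predator
#'   (1/(individuals * year)); the exotic predator predates at `alpha * d`.
#' @param p conversion efficiency of prey intake into new native
#'   predators (unitless).
#' @param q mortality rate of the native predator (1/year).
#' @param alpha ratio of exotic to native predation rates (unitless).
#' @param beta ratio of exotic-on-native to native-on-exotic competition
#'   coefficients (unitless).
#'
#' @return An object of class `invasion_model`: a named list of the
#'   eleven validated parameters.
#' @seealso [fixture()] for the canonical parameter sets, [equilibria()],
#'   [stability()], [simulate.invasion_model()].
#' @examples
#' m <- invasion_model(r = 1.2, s = 0.2, K = 100, c = 10, n = 2,
#'                     b = 0.01, d = 0.1, p = 0.05, q = 0.05,
#'                     alpha = 1, beta = 1)
#' coef(m)
#' @export
invasion_model <- function(r, s, K, c, n, b, d, p, q, alpha, beta) {
  pars <- list(r = r, s = s, K = K, c = c, n = n, b = b, d = d,
               p = p, q = q, alpha = alpha, beta = beta)
  validate_params(pars)
  structure(pars, class = "invasion_model")
}

param_names <- c("r", "s", "K", "c", "n", "b", "d", "p", "q",
                 "alpha", "beta")

validate_params <- function(pars) {
  for (nm in param_names) {
    v <- pars[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L)
      stop("parameter '", nm, "' must be a single numeric value",
           call. = FALSE)
    if (!is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be strictly positive and finite, got ",
           format(v), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
coef.invasion_model <- function(object, ...) {
  unlist(object[param_names])
}

#' @export
print.invasion_model <- function(x, ...) {
  cat("Three-species invasion model (native prey, native predator,",
      "exotic generalist predator)\n")
  cat("Parameters (rates per year, densities in individuals):\n")
  print(signif(coef(x), 6))
  cat(sprintf("Exotic predation rate alpha*d = %g; competition on native beta*b = %g\n",
              x$alpha * x$d, x$beta * x$b))
  invisible(x)
}

#' Update parameters of an invasion model
#'
#' Returns a copy of the model with the named parameters replaced;
#' convenient for sweeps over `alpha`, `beta` or `s`.
#'
#' @param m an [invasion_model()].
#' @param ... named replacement values among the eleven parameters.
#' @return An `invasion_model`.
#' @examples
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' set_params(m, alpha = 0.5, b = 0.04)
#' @export
set_params <- function(m, ...) {
  stopifnot(inherits(m, "invasion_model"))
  repl <- list(...)
  bad <- setdiff(names(repl), param_names)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m[names(repl)] <- repl
  validate_params(m)
  structure(m[param_names], class = "invasion_model")
}

#' Canonical parameter fixtures
#'
#' The two parameter sets used throughout the package's reference
#' analyses: a "theoretical" set (`c = 10`, `n = 2`) used for scenario
#' maps and propagule-size analyses, and a "mink" set (`c = 0.05`,
#' `n = 3`) based on American mink (*Mustela vison*) life history, used
#' for the impact-ratio analyses.  Both share \code{r = 1.2}, `s = 0.2`,
#' `K = 100`, `p = 0.05`, `q = 0.05`, `d = 0.1` and `b = 0.01`.
#' `alpha` and `beta` have no canonical value and must be supplied.
#'
#' @param name `"theoretical"` or `"mink"`.
#' @param alpha,beta predation and competition ratios of the exotic
#'   relative to the native predator.
#' @return An [invasion_model()].
#' @examples
#' fixture("mink", alpha = 0.6, beta = 0.5)
#' @export
fixture <- function(name = c("theoretical", "mink"), alpha, beta) {
  name <- match.arg(name)
  base <- list(r = 1.2, s = 0.2, K = 100, p = 0.05, q = 0.05,
               d = 0.1, b = 0.01)
  extra <- switch(name,
                  theoretical = list(c = 10,   n = 2),
                  mink        = list(c = 0.05, n = 3))
  do.call(invasion_model, c(base, extra, list(alpha = alpha, beta = beta)))
}

#' Documented sampling ranges for the model parameters
#'
#' Closed intervals (or point values) for each parameter, defaulting to
#' the ranges used for the mink-based simulations: \code{r = 1.2}, `s = 0.2`,
#' `K` in \[100, 200\], `d` in \[0.1, 0.3\], `n = 3`, `c = 0.05`, `b` in
#' \[0.001, 0.01\], `p` in \[0.025, 0.05\], `q` in \[0.05, 0.1\].
#' `alpha` and `beta` default to (0, 2.5].
#'
#' @param ... named two-element numeric vectors (or scalars for point
#'   values) overriding individual default ranges.
#' @return A named list of length-2 numeric ranges, class `param_ranges`.
#' @examples
#' param_ranges(alpha = c(0, 3), beta = c(0, 3))
#' @export
param_ranges <- function(...) {
  rng <- list(r = c(1.2, 1.2), s = c(0.2, 0.2), K = c(100, 200),
              c = c(0.05, 0.05), n = c(3, 3), b = c(0.001, 0.01),
              d = c(0.1, 0.3), p = c(0.025, 0.05), q = c(0.05, 0.1),
              alpha = c(0, 2.5), beta = c(0, 2.5))
  over <- list(...)
  bad <- setdiff(names(over), names(rng))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(over)) {
    v <- as.numeric(over[[nm]])
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2] || v[2] <= 0)
      stop("invalid range for '", nm, "'", call. = FALSE)
    rng[[nm]] <- v
  }
  structure(rng, class = "param_ranges")
}

#' Sample parameter records from documented ranges
#'
#' Draws each parameter independently and uniformly from its interval
#' (point values stay fixed).  Sampling is reproducible: identical
#' `(ranges, n, seed)` give identical output.  The caller's RNG state is
#' left untouched.
#'
#' @param n number of parameter records.
#' @param seed integer seed (default 20240222).
#' @param ranges a [param_ranges()] list.
#' @return A data frame with `n` rows and the eleven parameter columns;
#'   every row satisfies the positivity invariants of [invasion_model()].
#' @examples
#' head(sample_params(5))
#' @export
sample_params <- function(n, seed = 20240222, ranges = param_ranges()) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  out <- lapply(ranges, function(rg) {
    if (rg[1] == rg[2]) rep(rg[1], n) else stats::runif(n, rg[1], rg[2])
  })
  as.data.frame(out)
}

#' Turn one sampled record into an invasion model
#'
#' @param row a one-row data frame or named list/vector holding the
#'   eleven parameters (e.g. a row of [sample_params()]).
#' @return An [invasion_model()].
#' @export
as_invasion_model <- function(row) {
  row <- as.list(row)
  do.call(invasion_model, row[param_names])
}
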