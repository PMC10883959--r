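# Local stability: analytic predicates for the boundary equilibria and
# numerical eigenvalue classification, cross-validated against each
# other.  The interior equilibrium has no closed-form predicate here;
# it is classified numerically, with P'(X_s) < 0 as a screening
# necessary condition.

#' Analytic stability classification of a labelled equilibrium
#'
#' Evaluates the closed-form stability inequality for a boundary
#' equilibrium of the invaded system:
#' \itemize{
#'   \item `E0`, `EX`: always unstable (the exotic can always grow at
#'     `EX` since its transversal rate there is `s > 0`);
#'   \item `EXY`: stable iff `s - b r (p d K - q) / (d^2 K p) < 0`,
#'     i.e. the exotic's growth rate is below its competition mortality
#'     `b y_s` at the native equilibrium;
#'   \item `EXZ`: stable iff
#'     `alpha d^2 K (c p + alpha n q) +
#'      (beta b (c + alpha d K n) - p d K + q) r > 0`;
#'   \item `EZ`: stable iff \code{r < alpha c d} (exotic predation pressure
#'     at capacity `c` exceeds the prey's growth rate);
#'   \item `ES`: no printed predicate; returns `"unavailable"`.
#' }
#' The margin is the signed slack of the inequality (its row's own sign
#' convention); `|margin| <= tol` is reported `"marginal"`.
#'
#' In the two-species native system (`model = "native"`) the prey-only
#' state is instead stable iff `p d K < q`, and the coexistence state
#' `EXY` is stable whenever it exists.
#'
#' @param label one of `"E0"`, `"EX"`, `"EXY"`, `"EXZ"`, `"EZ"`, `"ES"`.
#' @param m an [invasion_model()].
#' @param tol marginal band on the analytic margin (default `1e-6`).
#' @param model `"full"` (three-species system) or `"native"`
#'   (two-species system, labels `E0`, `EX`, `EXY` only).
#' @return A list with `class` (`"stable"`, `"unstable"`, `"marginal"`
#'   or `"unavailable"`) and `margin` (`NA` for unconditional rows).
#' @examples
#' m <- fixture("theoretical", alpha = 2, beta = 1)
#' classify_analytic("EZ", m)   # stable: r = 1.2 < alpha c d = 2
#' @export
classify_analytic <- function(label, m, tol = 1e-6,
                              model = c("full", "native")) {
  stopifnot(inherits(m, "invasion_model"))
  model <- match.arg(model)
  ys <- m$r * (m$p * m$d * m$K - m$q) / (m$d^2 * m$K * m$p)
  if (model == "native") {
    res <- switch(label,
      E0 = list(class = "unstable", margin = NA_real_),
      EX = {
        mg <- m$p * m$d * m$K - m$q      # > 0: invadable by the predator
        list(class = if (mg > 0) "unstable" else "stable", margin = mg)
      },
      EXY = list(class = "stable", margin = NA_real_),
      stop("label '", label, "' has no native-model condition",
           call. = FALSE)
    )
    if (is.finite(res$margin) && abs(res$margin) <= tol)
      res$class <- "marginal"
    return(res)
  }
  res <- switch(label,
    E0 = list(class = "unstable", margin = NA_real_),
    EX = list(class = "unstable", margin = NA_real_),  # exotic grows at s > 0
    EXY = {
      mg <- m$s - m$b * ys               # < 0: exotic cannot grow
      list(class = if (mg < 0) "stable" else "unstable", margin = mg)
    },
    EXZ = {
      kapK <- m$c + m$alpha * m$d * m$K * m$n
      mg <- m$alpha * m$d^2 * m$K * (m$c * m$p + m$alpha * m$n * m$q) +
        (m$beta * m$b * kapK - m$p * m$d * m$K + m$q) * m$r
      list(class = if (mg > 0) "stable" else "unstable", margin = mg)
    },
    EZ = {
      mg <- m$r - m$alpha * m$c * m$d    # < 0: prey cannot re-invade
      list(class = if (mg < 0) "stable" else "unstable", margin = mg)
    },
    ES = list(class = "unavailable", margin = NA_real_),
    stop("unknown equilibrium label: ", label, call. = FALSE)
  )
  if (is.finite(res$margin) && abs(res$margin) <= tol)
    res$class <- "marginal"
  res
}

#' Numerical eigenvalue classification of an equilibrium
#'
#' Computes the eigenvalues of the closed-form [jacobian()] at the
#' equilibrium and classifies it as `"stable"` when every real part is
#' below `-tol`, `"unstable"` when some real part exceeds `+tol`, and
#' `"marginal"` otherwise.
#'
#' @param eq a one-row equilibrium data frame (from [equilibria()] and
#'   friends) or a named numeric state of length 3 (length 2 for
#'   `model = "native"`).
#' @param m an [invasion_model()].
#' @param tol marginal band on eigenvalue real parts (default `1e-7`).
#' @param model `"full"` (3x3 Jacobian) or `"native"` (2x2 Jacobian of
#'   the two-species system).
#' @return A list with `eigen_real_parts` (decreasing), `class` and
#'   `max_re`.
#' @examples
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' exy <- subset(boundary_equilibria(set_params(m, b = 0.04)), label == "EXY")
#' classify_numeric(exy, set_params(m, b = 0.04))
#' @export
classify_numeric <- function(eq, m, tol = 1e-7,
                             model = c("full", "native")) {
  stopifnot(inherits(m, "invasion_model"))
  model <- match.arg(model)
  state <- if (is.data.frame(eq)) {
    stopifnot(nrow(eq) == 1L, isTRUE(eq$exists))
    c(eq$X, eq$Y, eq$Z)
  } else as.numeric(eq)
  J <- if (model == "native") native_jacobian(state[1:2], m)
       else jacobian(state[1:3], m)
  ev <- eigen(J, only.values = TRUE)$values
  re <- sort(Re(ev), decreasing = TRUE)
  if (any(!is.finite(re))) stop("non-finite eigenvalues", call. = FALSE)
  cls <- if (max(re) > tol) "unstable"
         else if (max(re) < -tol) "stable"
         else "marginal"
  list(eigen_real_parts = re, class = cls, max_re = max(re))
}

#' Stability table for all equilibria of a model
#'
#' Classifies every existing equilibrium both analytically (printed
#' inequalities) and numerically (Jacobian eigenvalues) and reports
#' whether the two agree.  For the interior equilibrium the analytic
#' class is `"unavailable"`; the necessary condition `P'(X_s) < 0`
#' appears in the `admissible` column of [interior_equilibria()].
#'
#' @param m an [invasion_model()].
#' @param tol eigenvalue marginal band (default `1e-7`).
#' @param analytic_tol analytic-margin marginal band (default `1e-6`).
#' @return A data frame with one row per existing equilibrium: `label`,
#'   `lambda1..lambda3` (eigenvalue real parts, decreasing),
#'   `numeric_class`, `analytic_class`, `margin` and `agree` (`NA` when
#'   either side is marginal or unavailable).
#' @examples
#' stability(fixture("theoretical", alpha = 1, beta = 1))
#' @export
stability <- function(m, tol = 1e-7, analytic_tol = 1e-6) {
  eqs <- equilibria(m)
  eqs <- eqs[eqs$exists, , drop = FALSE]
  rows <- lapply(seq_len(nrow(eqs)), function(i) {
    eq <- eqs[i, , drop = FALSE]
    num <- classify_numeric(eq, m, tol = tol)
    ana <- classify_analytic(eq$label, m, tol = analytic_tol)
    comparable <- !identical(ana$class, "unavailable") &&
      !identical(ana$class, "marginal") && num$class != "marginal"
    data.frame(label = eq$label,
               lambda1 = num$eigen_real_parts[1],
               lambda2 = num$eigen_real_parts[2],
               lambda3 = if (length(num$eigen_real_parts) > 2)
                 num$eigen_real_parts[3] else NA_real_,
               numeric_class = num$class,
               analytic_class = ana$class,
               margin = ana$margin,
               agree = if (comparable) num$class == ana$class else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
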