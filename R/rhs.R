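# Right-hand sides of the native (two-species) and invaded
# (three-species) systems, the prey-dependent carrying capacity, and the
# closed-form Jacobian of the full system.

# Densities are nonnegative by construction; adaptive solvers can
# overshoot slightly below zero, so components in (-1e-9, 0) are clamped
# to 0 and anything more negative is an error.
clamp_state <- function(state, what = "state") {
  if (!is.numeric(state) || any(!is.finite(state)))
    stop(what, " must be finite numeric", call. = FALSE)
  neg <- state < 0
  if (any(state < -1e-9))
    stop(what, " has negative component(s): ",
         paste(signif(state[neg], 6), collapse = ", "), call. = FALSE)
  state[neg] <- 0
  state
}

#' Prey-dependent carrying capacity of the exotic predator
#'
#' `kappa(X) = n * alpha * d * X + c`: linear and increasing in the prey
#' density `X`, with floor `c` (the capacity guaranteed by alternative
#' food) when prey is absent.
#'
#' @param X prey density (vectorised), `X >= 0`.
#' @param m an [invasion_model()].
#' @return Carrying capacity (individuals), `>= c`.
#' @examples
#' m <- fixture("theoretical", alpha = 0.505, beta = 1)
#' carrying_capacity(c(0, 100), m)
#' @export
carrying_capacity <- function(X, m) {
  stopifnot(inherits(m, "invasion_model"))
  X <- clamp_state(X, "X")
  m$n * m$alpha * m$d * X + m$c
}

#' Right-hand side of the native predator-prey system
#'
#' The two-species baseline: logistic prey growth reduced by predation,
#' and a specialist predator converting prey intake with efficiency `p`
#' and dying at rate `q` without prey:
#' \deqn{dx/dt = r x (1 - x/K) - d x y, \quad dy/dt = p d x y - q y.}
#'
#' @param state numeric length 2, densities `(x, y)`.
#' @param m an [invasion_model()] (only `r`, `K`, `d`, `p`, `q` enter).
#' @return Named numeric length 2: `(dx, dy)` in individuals/year.
#' @examples
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' native_rhs(c(10, 10.8), m)   # coexistence equilibrium: both zero
#' @export
native_rhs <- function(state, m) {
  stopifnot(inherits(m, "invasion_model"), length(state) == 2L)
  state <- clamp_state(state)
  x <- state[[1]]; y <- state[[2]]
  c(dx = m$r * x * (1 - x / m$K) - m$d * x * y,
    dy = m$p * m$d * x * y - m$q * y)
}

#' Right-hand side of the three-species invaded system
#'
#' Adds the exotic generalist predator `Z` to the native pair: the prey
#' suffers extra predation `alpha d X Z`, the native predator suffers
#' competition `beta b Y Z`, and the exotic grows logistically with
#' prey-dependent capacity [carrying_capacity()] while losing `b Z Y` to
#' competition.  With `Z = 0` the system reduces exactly to
#' [native_rhs()].
#'
#' @param state numeric length 3, densities `(X, Y, Z)`.
#' @param m an [invasion_model()].
#' @return Named numeric length 3: `(dX, dY, dZ)` in individuals/year.
#' @examples
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' m <- set_params(m, b = 0.04)
#' full_rhs(c(10, 10.8, 1), m)
#' @export
full_rhs <- function(state, m) {
  stopifnot(inherits(m, "invasion_model"), length(state) == 3L)
  state <- clamp_state(state)
  X <- state[[1]]; Y <- state[[2]]; Z <- state[[3]]
  f <- m$r * X * (1 - X / m$K) - m$d * X * Y
  g <- m$p * m$d * X * Y - m$q * Y
  kap <- m$n * m$alpha * m$d * X + m$c
  c(dX = f - m$alpha * m$d * X * Z,
    dY = g - m$beta * m$b * Y * Z,
    dZ = m$s * Z * (1 - Z / kap) - m$b * Z * Y)
}

#' Jacobian of the three-species system
#'
#' Closed-form partial derivatives of [full_rhs()] at a state (not
#' finite differences); used by the numerical stability classifier.
#'
#' @param state numeric length 3, densities `(X, Y, Z)`.
#' @param m an [invasion_model()].
#' @return A 3x3 numeric matrix.
#' @export
jacobian <- function(state, m) {
  stopifnot(inherits(m, "invasion_model"), length(state) == 3L)
  state <- clamp_state(state)
  X <- state[[1]]; Y <- state[[2]]; Z <- state[[3]]
  kap <- m$n * m$alpha * m$d * X + m$c
  matrix(c(
    m$r - 2 * m$r * X / m$K - m$d * Y - m$alpha * m$d * Z,
    -m$d * X,
    -m$alpha * m$d * X,

    m$p * m$d * Y,
    m$p * m$d * X - m$q - m$beta * m$b * Z,
    -m$beta * m$b * Y,

    m$s * Z^2 * m$n * m$alpha * m$d / kap^2,
    -m$b * Z,
    m$s * (1 - 2 * Z / kap) - m$b * Y
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
}

# 2x2 Jacobian of the native system, for classifying its equilibria.
native_jacobian <- function(state, m) {
  state <- clamp_state(state)
  x <- state[[1]]; y <- state[[2]]
  matrix(c(m$r - 2 * m$r * x / m$K - m$d * y, -m$d * x,
           m$p * m$d * y,                     m$p * m$d * x - m$q),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("x", "y"), c("x", "y")))
}
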