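# Closed-form equilibria of the native and invaded systems, the interior
# quadratic P(theta) governing three-species coexistence, and the
# response of the native predator's equilibrium density to its predation
# rate d.

# Existence margins within 1e-9 (relative) of zero are flagged marginal:
# float-safe reporting of the pdK = q and r = alpha*c*d degeneracies.
.margin_tol <- 1e-9

eq_row <- function(label, X, Y, Z, exists, margin) {
  scale <- max(1, abs(X), abs(Y), abs(Z), abs(margin), na.rm = TRUE)
  data.frame(label = label, X = X, Y = Y, Z = Z, exists = exists,
             existence_margin = margin,
             marginal = is.finite(margin) && abs(margin) < .margin_tol * scale,
             stringsAsFactors = FALSE)
}

#' Equilibria of the native predator-prey system
#'
#' The two-species system has the extinction state `E0 = (0, 0)`, the
#' prey-only state `EX = (K, 0)` and, when `p d K > q`, the coexistence
#' state `EXY = (q/(d p), r (p d K - q) / (d^2 K p))`.  When
#' `p d K = q`, `EX` and `EXY` coincide and only `EX` is reported.
#'
#' @param m an [invasion_model()].
#' @return A data frame with columns `label`, `X`, `Y`, `Z` (always 0
#'   here), `exists`, `existence_margin` (signed slack `p d K - q` for
#'   `EXY`, `NA` for unconditional equilibria) and `marginal`.
#' @examples
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' native_equilibria(m)   # EXY = (10, 10.8)
#' @export
native_equilibria <- function(m) {
  stopifnot(inherits(m, "invasion_model"))
  em <- m$p * m$d * m$K - m$q
  scale <- max(1, m$p * m$d * m$K, m$q)
  out <- rbind(eq_row("E0", 0, 0, 0, TRUE, NA_real_),
               eq_row("EX", m$K, 0, 0, TRUE, NA_real_))
  if (abs(em) >= .margin_tol * scale && em > 0) {
    xs <- m$q / (m$d * m$p)
    ys <- m$r * em / (m$d^2 * m$K * m$p)
    out <- rbind(out, eq_row("EXY", xs, ys, 0, TRUE, em))
  } else if (abs(em) < .margin_tol * scale) {
    # degenerate pdK = q: EX and EXY coincide; report the boundary case
    out <- rbind(out, eq_row("EXY", m$K, 0, 0, FALSE, em))
  } else {
    out <- rbind(out, eq_row("EXY", NA_real_, NA_real_, NA_real_, FALSE, em))
  }
  out
}

#' Boundary equilibria of the three-species system
#'
#' Fixed points with at least one species absent: `E0 = (0,0,0)`,
#' `EX = (K,0,0)` and the exotic-only state `EZ = (0,0,c)` always exist;
#' `EXY` (the native coexistence state with `Z = 0`) exists iff
#' `p d K - q > 0`; the prey-exotic state
#' `EXZ = (K(r - alpha d c)/(alpha^2 d^2 K n + r), 0,
#'         r(c + n alpha d K)/(alpha^2 d^2 K n + r))`
#' exists iff \code{r - alpha d c > 0}.
#'
#' @inheritParams native_equilibria
#' @return A data frame as in [native_equilibria()].
#' @examples
#' m <- fixture("theoretical", alpha = 0.505, beta = 1)
#' boundary_equilibria(m)   # EXZ = (40.6421, 0, 14.1049)
#' @export
boundary_equilibria <- function(m) {
  stopifnot(inherits(m, "invasion_model"))
  nat <- native_equilibria(m)   # E0, EX, EXY lifted with Z = 0
  em_xz <- m$r - m$alpha * m$d * m$c
  scale_xz <- max(1, m$r, m$alpha * m$d * m$c)
  den <- m$alpha^2 * m$d^2 * m$K * m$n + m$r
  if (abs(em_xz) >= .margin_tol * scale_xz && em_xz > 0) {
    xz <- eq_row("EXZ", m$K * em_xz / den, 0,
                 m$r * (m$c + m$n * m$alpha * m$d * m$K) / den, TRUE, em_xz)
  } else if (abs(em_xz) < .margin_tol * scale_xz) {
    # degenerate r = alpha*c*d: EXZ collides with EZ
    xz <- eq_row("EXZ", 0, 0, m$c, FALSE, em_xz)
  } else {
    xz <- eq_row("EXZ", NA_real_, NA_real_, NA_real_, FALSE, em_xz)
  }
  rbind(nat, xz, eq_row("EZ", 0, 0, m$c, TRUE, NA_real_))
}

#' Interior quadratic governing three-species coexistence
#'
#' The prey coordinate `X_s` of a positive equilibrium is a root in
#' `(0, K)` of the concave-down parabola
#' `P(theta) = A0 + A1 theta + A2 theta^2` with
#' \itemize{
#'   \item `A0 = b c K (alpha d q + beta b r) - d K s (beta b c + q)`
#'   \item `A1 = alpha^2 b d^2 K n q +
#'     alpha b d K (beta b n r - d (beta n s + c p)) - beta b^2 c r +
#'     d^2 K p s`
#'   \item `A2 = -alpha b n d (alpha d^2 K p + beta b r) < 0`.
#' }
#' `A4 = alpha b (c + alpha d K n)(q - d K p) -
#' (beta b (c + alpha d K n) - d K p + q) s` carries the sign of `P(K)`
#' and enters the coexistence case analysis.
#'
#' Roots are computed with the sign-aware stable quadratic formula and
#' polished by bisection against `P` (`A2` can be tiny, making the naive
#' formula ill-conditioned).
#'
#' @inheritParams native_equilibria
#' @return An object of class `interior_quadratic`: a list with
#'   `A0`, `A1`, `A2`, `A4`, `discriminant` (`A1^2 - 4 A0 A2`),
#'   `roots_in_range` (increasing, within `(0, K)`), `case`
#'   (`"none"`, `"one"` or `"two"` positive equilibria per the printed
#'   sign conditions, `"marginal"` when a deciding quantity is within
#'   1e-9 of zero) and the polynomial `P` as a function.
#' @examples
#' iq <- interior_quadratic(fixture("theoretical", alpha = 0.505, beta = 1.086))
#' iq$A0            # about -0.16163
#' iq$roots_in_range
#' @export
interior_quadratic <- function(m) {
  stopifnot(inherits(m, "invasion_model"))
  r <- m$r; s <- m$s; K <- m$K; cc <- m$c; n <- m$n; b <- m$b
  d <- m$d; p <- m$p; q <- m$q; al <- m$alpha; be <- m$beta
  A0 <- b * cc * K * (al * d * q + be * b * r) - d * K * s * (be * b * cc + q)
  A1 <- al^2 * b * d^2 * K * n * q +
    al * b * d * K * (be * b * n * r - d * (be * n * s + cc * p)) -
    be * b^2 * cc * r + d^2 * K * p * s
  A2 <- -al * b * n * d * (al * d^2 * K * p + be * b * r)
  A4 <- al * b * (cc + al * d * K * n) * (q - d * K * p) -
    (be * b * (cc + al * d * K * n) - d * K * p + q) * s
  disc <- A1^2 - 4 * A0 * A2
  P <- function(theta) A0 + A1 * theta + A2 * theta^2

  roots <- numeric(0)
  if (disc > 0) {
    sq <- sqrt(disc)
    qq <- -(A1 + sign(A1 + (A1 == 0)) * sq) / 2
    roots <- sort(c(qq / A2, if (qq != 0) A0 / qq else -A1 / A2))
    roots <- unique(roots[is.finite(roots)])
    roots <- vapply(roots, polish_root, numeric(1), P = P)
  } else if (disc == 0) {
    roots <- -A1 / (2 * A2)
  }
  roots <- sort(roots[roots > 0 & roots < K])

  out <- list(A0 = A0, A1 = A1, A2 = A2, A4 = A4, discriminant = disc,
              roots_in_range = roots, case = prop2_case(A0, A1, A2, A4, disc),
              P = P)
  class(out) <- "interior_quadratic"
  out
}

# One bisection-polish pass: bracket the formula root by an expanding
# interval with a sign change, then hand to uniroot at tight tolerance.
polish_root <- function(x0, P) {
  h <- max(abs(x0), 1) * 1e-8
  for (i in 1:30) {
    lo <- x0 - h; hi <- x0 + h
    if (is.finite(P(lo)) && is.finite(P(hi)) && P(lo) * P(hi) <= 0) {
      return(stats::uniroot(P, c(lo, hi), tol = 1e-14)$root)
    }
    h <- h * 4
  }
  x0   # no sign change found (double root or flat); keep the formula value
}

# Case labels for the number of positive equilibria from the printed
# sign conditions on A0, A1, A2, A4 and the discriminant.  Quantities
# within 1e-9 (relative) of zero make the label "marginal".
prop2_case <- function(A0, A1, A2, A4, disc) {
  scale <- max(1, abs(A0), abs(A1), abs(A2), abs(A4))
  near0 <- function(v, sc = scale) abs(v) < 1e-9 * sc
  if (near0(A0) || near0(A4) || near0(A1) ||
      near0(disc, max(1, A1^2, abs(4 * A0 * A2))))
    return("marginal")
  if (disc < 0) return("none")
  if (A0 > 0 && A4 > 0) return("none")
  if (A0 > 0 && A4 < 0) return("one")
  if (A0 < 0 && A1 > 0 && A4 > 0) return("one")
  if (A0 < 0 && A1 > 0 && A4 < 0) return("two")
  "none"
}

#' @export
print.interior_quadratic <- function(x, ...) {
  cat("Interior quadratic P(theta) = A0 + A1 theta + A2 theta^2\n")
  cat(sprintf("  A0 = %.6g, A1 = %.6g, A2 = %.6g, A4 = %.6g\n",
              x$A0, x$A1, x$A2, x$A4))
  cat(sprintf("  discriminant = %.6g; case: %s positive equilibria\n",
              x$discriminant, x$case))
  if (length(x$roots_in_range))
    cat("  roots in (0, K):", paste(signif(x$roots_in_range, 10),
                                    collapse = ", "), "\n")
  else cat("  no roots in (0, K)\n")
  invisible(x)
}

#' Interior (three-species coexistence) equilibria
#'
#' For each root `X_s` of the interior quadratic in `(0, K)` the
#' candidate equilibrium is
#' `E_s = (X_s,
#'         s (q - p d X_s + beta b (c + n alpha d X_s)) /
#'           (beta b^2 (c + n alpha d X_s)),
#'         (p d X_s - q) / (beta b))`,
#' admissible as a positive fixed point iff
#' `beta b (c + n alpha d X_s) > p d X_s - q > 0`.  When two roots
#' qualify, only the one with `P'(X_s) < 0` (the larger) can be stable;
#' the `admissible` column flags it.
#'
#' @inheritParams native_equilibria
#' @return A data frame with columns `label` (`"ES"`), `X`, `Y`, `Z`,
#'   `exists`, `existence_margin` (minimum slack of the two existence
#'   inequalities), `marginal`, `admissible` (`P'(X_s) < 0`) and
#'   `Pprime`.  Zero rows when no root qualifies.
#' @examples
#' m <- fixture("theoretical", alpha = 0.7, beta = 0.5)
#' interior_equilibria(m)
#' @export
interior_equilibria <- function(m) {
  stopifnot(inherits(m, "invasion_model"))
  iq <- interior_quadratic(m)
  empty <- data.frame(label = character(0), X = numeric(0), Y = numeric(0),
                      Z = numeric(0), exists = logical(0),
                      existence_margin = numeric(0), marginal = logical(0),
                      admissible = logical(0), Pprime = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(iq$roots_in_range)) return(empty)
  rows <- lapply(iq$roots_in_range, function(Xs) {
    kap <- m$c + m$n * m$alpha * m$d * Xs
    m1 <- m$p * m$d * Xs - m$q                 # > 0 needed (Z_s > 0)
    m2 <- m$beta * m$b * kap - m1              # > 0 needed (Y_s > 0)
    if (!(m1 > 0 && m2 > 0)) return(NULL)
    Ys <- m$s * (m$q - m$p * m$d * Xs + m$beta * m$b * kap) /
      (m$beta * m$b^2 * kap)
    Zs <- m1 / (m$beta * m$b)
    Pp <- iq$A1 + 2 * iq$A2 * Xs
    out <- eq_row("ES", Xs, Ys, Zs, TRUE, min(m1, m2))
    out$admissible <- Pp < 0
    out$Pprime <- Pp
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # A single qualifying root is the coexistence candidate (the "one
  # positive equilibrium" case) whatever the slope; with two qualifying
  # roots the smaller (P' > 0) one is discarded as unstable.
  if (nrow(out) == 1L) out$admissible <- TRUE
  out
}

#' All equilibria of the invaded system
#'
#' Convenience wrapper binding [boundary_equilibria()] and
#' [interior_equilibria()] into one table.
#'
#' @inheritParams native_equilibria
#' @return A data frame; interior rows carry the extra `admissible` and
#'   `Pprime` columns (`NA` for boundary rows).
#' @export
equilibria <- function(m) {
  bd <- boundary_equilibria(m)
  bd$admissible <- NA
  bd$Pprime <- NA_real_
  rbind(bd, interior_equilibria(m))
}

#' Native predator equilibrium density as a function of its predation rate
#'
#' Along the coexistence equilibrium of the native system, the predator
#' density is `y_s(d) = r (d - d*/2) / d^2` with `d* = 2 q / (K p)`:
#' it rises steeply on `(0, d*)`, peaks at `d = d*` (value
#' \code{r K p / (4 q)}) and decays slowly beyond.
#'
#' @param m an [invasion_model()] supplying `r`, `K`, `p`, `q`.
#' @param d_value predation rate(s) at which to evaluate (vectorised).
#' @return `y_s(d_value)`; `NA` where the coexistence equilibrium does
#'   not exist (`p * d_value * K <= q`).
#' @seealso [optimal_predation_rate()]
#' @examples
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' predator_density_vs_d(m, 0.1)    # 10.8
#' predator_density_vs_d(m, 0.02)   # the peak, r K p / (4 q) = 30
#' @export
predator_density_vs_d <- function(m, d_value) {
  stopifnot(inherits(m, "invasion_model"), all(d_value > 0))
  dstar <- optimal_predation_rate(m)
  ys <- m$r * (d_value - dstar / 2) / d_value^2
  ys[m$p * d_value * m$K <= m$q] <- NA_real_
  ys
}

#' Predation rate maximising the native predator's equilibrium density
#'
#' @inheritParams predator_density_vs_d
#' @return `d* = 2 q / (K p)`.
#' @examples
#' optimal_predation_rate(fixture("theoretical", alpha = 1, beta = 1))  # 0.02
#' @export
optimal_predation_rate <- function(m) {
  stopifnot(inherits(m, "invasion_model"))
  2 * m$q / (m$K * m$p)
}
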