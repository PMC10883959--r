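# Closed-form equilibria, the interior quadratic and the predation-rate
# response of the native predator.

test_that("native equilibria match the closed forms and existence rules", {
  m <- theo()
  eq <- native_equilibria(m)
  exy <- eq[eq$label == "EXY", ]
  expect_true(exy$exists)
  expect_equal(c(exy$X, exy$Y), c(10, 10.8))
  # existence fails when pdK < q
  eq2 <- native_equilibria(set_params(m, d = 0.004))   # pdK = 0.02 < q
  expect_false(eq2[eq2$label == "EXY", ]$exists)
  # degenerate pdK = q: EXY coincides with EX and is reported marginal
  eq3 <- native_equilibria(set_params(m, d = m$q / (m$p * m$K)))
  exy3 <- eq3[eq3$label == "EXY", ]
  expect_false(exy3$exists)
  expect_true(exy3$marginal)
  expect_equal(exy3$X, m$K)
})

test_that("native equilibria zero the RHS across random parameter draws", {
  ps <- random_params(200, seed = 515)
  for (i in seq_len(nrow(ps))) {
    m <- as_invasion_model(ps[i, ])
    eq <- native_equilibria(m)
    eq <- eq[eq$exists, ]
    for (j in seq_len(nrow(eq)))
      expect_lt(max(abs(native_rhs(c(eq$X[j], eq$Y[j]), m))), 1e-10)
  }
})

test_that("boundary equilibria match the printed reference coordinates", {
  m <- theo(alpha = 0.505)
  bd <- boundary_equilibria(m)
  xz <- bd[bd$label == "EXZ", ]
  expect_equal(round(c(xz$X, xz$Y, xz$Z), 4), c(40.6421, 0, 14.1049))
  # alpha = beta = 1: formula evaluation cross-checked by RHS zero
  bd1 <- boundary_equilibria(theo())
  xz1 <- bd1[bd1$label == "EXZ", ]
  expect_equal(c(xz1$X, xz1$Y, xz1$Z), c(6.25, 0, 11.25))
  expect_lt(max(abs(full_rhs(c(xz1$X, xz1$Y, xz1$Z), theo()))), 1e-12)
  # EZ always present at (0, 0, c)
  ez <- bd[bd$label == "EZ", ]
  expect_true(ez$exists)
  expect_equal(c(ez$X, ez$Y, ez$Z), c(0, 0, m$c))
  # EXZ ceases to exist above the predation threshold alpha = r/(cd)
  bd2 <- boundary_equilibria(theo(alpha = 1.5))
  expect_false(bd2[bd2$label == "EXZ", ]$exists)
})

test_that("interior quadratic reproduces the printed coefficients and shape", {
  iq <- interior_quadratic(theo(alpha = 0.505, beta = 1.086))
  expect_equal(iq$A0, -0.16163, tolerance = 1e-4)
  # its root is the reference continuation point (40.625, 0.0045, 14.1)
  ie <- interior_equilibria(theo(alpha = 0.505, beta = 1.086))
  expect_equal(ie$X, 40.625, tolerance = 1e-4)
  expect_equal(ie$Y, 0.0045, tolerance = 3e-2)
  expect_equal(ie$Z, 14.1, tolerance = 1e-3)
  # A2 < 0 always; P concave down; sign(P(K)) agrees with sign(A4)
  ps <- random_params(300, seed = 616)
  for (i in seq_len(nrow(ps))) {
    m <- as_invasion_model(ps[i, ])
    iq <- interior_quadratic(m)
    expect_lt(iq$A2, 0)
    if (abs(iq$A4) > 1e-9 && abs(iq$P(m$K)) > 1e-9)
      expect_identical(sign(iq$P(m$K)), sign(iq$A4))
    expect_lte(length(iq$roots_in_range), 2L)
  }
})

test_that("interior equilibria follow the two-root admissibility rule", {
  ie <- interior_equilibria(two_root_model())
  expect_identical(nrow(ie), 2L)
  expect_identical(sum(ie$admissible), 1L)
  # the admissible root is the larger, on the falling limb of P
  expect_identical(which(ie$admissible), which.max(ie$X))
  expect_lt(ie$Pprime[ie$admissible], 0)
  # a single qualifying root is the candidate even on the rising limb
  ie1 <- interior_equilibria(theo(alpha = 0.7, beta = 0.5, b = 0.005))
  expect_identical(nrow(ie1), 1L)
  expect_true(ie1$admissible)
  expect_gt(ie1$Pprime, 0)
})

test_that("interior equilibria zero the full RHS over an (alpha, beta) grid", {
  m <- theo(b = 0.01)
  worst <- 0
  for (a in seq(0.1, 2.5, length.out = 12))
    for (b in seq(0.1, 2.5, length.out = 12)) {
      ie <- interior_equilibria(set_params(m, alpha = a, beta = b))
      for (j in seq_len(nrow(ie)))
        worst <- max(worst, abs(full_rhs(c(ie$X[j], ie$Y[j], ie$Z[j]),
                                         set_params(m, alpha = a, beta = b))))
    }
  expect_lt(worst, 1e-8)
})

test_that("root count equals a dense sign-scan of P", {
  ps <- random_params(150, seed = 717)
  for (i in seq_len(nrow(ps))) {
    m <- as_invasion_model(ps[i, ])
    iq <- interior_quadratic(m)
    th <- seq(1e-9, m$K * (1 - 1e-9), length.out = 1e4)
    scan_roots <- sum(diff(sign(iq$P(th))) != 0)
    expect_identical(length(iq$roots_in_range), as.integer(scan_roots))
  }
})

test_that("coexistence case labels follow the printed sign conditions", {
  ps <- random_params(300, seed = 818)
  for (i in seq_len(nrow(ps))) {
    m <- as_invasion_model(ps[i, ])
    iq <- interior_quadratic(m)
    if (iq$case == "marginal") next
    expect_identical(iq$case,
                     c("none", "one", "two")[length(iq$roots_in_range) + 1L])
  }
})

test_that("predator equilibrium density peaks at d* = 2q/(Kp)", {
  m <- theo()
  expect_equal(optimal_predation_rate(m), 0.02)
  expect_equal(predator_density_vs_d(m, 0.1), 10.8)
  # the peak value is r K p / (4 q) = 30
  expect_equal(predator_density_vs_d(m, 0.02), 30)
  # fine-grid argmax lands on d*
  dd <- seq(0.002, 0.2, length.out = 1e5)
  ys <- predator_density_vs_d(m, dd)
  expect_equal(dd[which.max(ys)], 0.02, tolerance = 1e-4)
  # increasing before the peak, decreasing after, tending to 0+
  ok <- !is.na(ys)
  expect_true(all(diff(ys[ok & dd < 0.02]) > 0))
  expect_true(all(diff(ys[ok & dd > 0.0201]) < 0))
  expect_lt(predator_density_vs_d(m, 1000), 2e-3)
  # flat at the peak (central difference) and absent when pdK <= q
  h <- 1e-6
  cd <- (predator_density_vs_d(m, 0.02 + h) -
         predator_density_vs_d(m, 0.02 - h)) / (2 * h)
  expect_lt(abs(cd), 1e-4)
  expect_true(is.na(predator_density_vs_d(m, 0.004)))
})
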