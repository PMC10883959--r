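# Analytic stability predicates, eigenvalue classification, and the
# agreement between the two.

test_that("Jacobian rows reproduce the transversal growth rates", {
  m <- theo(alpha = 2)
  # at E_Z = (0, 0, c) the prey row is (r - alpha c d, 0, 0)
  J <- jacobian(c(0, 0, m$c), m)
  expect_equal(unname(J[1, ]), c(m$r - m$alpha * m$d * m$c, 0, 0))
  # on the Z = 0 face the exotic's own growth entry is s - b Y
  m2 <- theo(b = 0.04)
  J2 <- jacobian(c(10, 10.8, 0), m2)
  expect_equal(J2[3, 3], m2$s - m2$b * 10.8)
})

test_that("native coexistence equilibrium is stable whenever it exists", {
  ps <- random_params(100, seed = 919)
  for (i in seq_len(nrow(ps))) {
    m <- as_invasion_model(ps[i, ])
    eq <- native_equilibria(m)
    exy <- eq[eq$label == "EXY" & eq$exists, ]
    if (!nrow(exy)) next
    num <- classify_numeric(c(exy$X, exy$Y), m, model = "native")
    expect_identical(num$class, "stable")
    expect_identical(classify_analytic("EXY", m, model = "native")$class,
                     "stable")
  }
})

test_that("extinction and prey-only states are always unstable in the full system", {
  ps <- random_params(50, seed = 1020)
  for (i in seq_len(nrow(ps))) {
    m <- as_invasion_model(ps[i, ])
    expect_identical(classify_numeric(c(0, 0, 0), m)$class, "unstable")
    expect_identical(classify_numeric(c(m$K, 0, 0), m)$class, "unstable")
    expect_identical(classify_analytic("E0", m)$class, "unstable")
    expect_identical(classify_analytic("EX", m)$class, "unstable")
  }
  # in the two-species system the prey-only state is invadable iff pdK > q
  m <- theo()
  expect_identical(classify_analytic("EX", m, model = "native")$class,
                   "unstable")
  expect_identical(classify_analytic("EX", set_params(m, d = 0.004),
                                     model = "native")$class, "stable")
})

test_that("printed inequalities give the reference margins", {
  # E_Z stable when alpha c d = 2 exceeds r = 1.2
  resz <- classify_analytic("EZ", theo(alpha = 2))
  expect_identical(resz$class, "stable")
  expect_equal(resz$margin, 1.2 - 2)
  # E_XZ condition value 1.5 > 0 at alpha = beta = 1, b = 0.04
  m <- theo(b = 0.04)
  rexz <- classify_analytic("EXZ", m)
  expect_identical(rexz$class, "stable")
  expect_equal(rexz$margin, 1.5)
  # E_XY margin s - b y_s = 0.2 - 0.432
  rexy <- classify_analytic("EXY", m)
  expect_identical(rexy$class, "stable")
  expect_equal(rexy$margin, 0.2 - 0.04 * 10.8)
  # no printed predicate for the interior equilibrium
  expect_identical(classify_analytic("ES", m)$class, "unavailable")
})

test_that("analytic and numeric classifications agree off the marginal band", {
  ps <- random_params(400, seed = 1121)
  ncomp <- 0
  for (i in seq_len(nrow(ps))) {
    m <- as_invasion_model(ps[i, ])
    eqs <- boundary_equilibria(m)
    eqs <- eqs[eqs$exists, ]
    for (j in seq_len(nrow(eqs))) {
      ana <- classify_analytic(eqs$label[j], m)
      if (!ana$class %in% c("stable", "unstable")) next
      if (is.finite(ana$margin) && abs(ana$margin) <= 1e-6) next
      num <- classify_numeric(eqs[j, ], m)
      if (num$class == "marginal") next
      ncomp <- ncomp + 1
      expect_identical(num$class, ana$class)
    }
  }
  expect_gt(ncomp, 500)   # the comparison actually exercised many cases
})

test_that("native and prey-exotic states are simultaneously stable under bistability", {
  m <- theo(b = 0.04)   # alpha = beta = 1
  st <- stability(m)
  expect_identical(st$numeric_class[st$label == "EXY"], "stable")
  expect_identical(st$numeric_class[st$label == "EXZ"], "stable")
  expect_identical(st$analytic_class[st$label == "EXY"], "stable")
  expect_identical(st$analytic_class[st$label == "EXZ"], "stable")
})

test_that("the transcritical collision r = alpha c d is reported marginal, not classified", {
  m <- theo(alpha = 1.2)   # exactly r = alpha c d
  bd <- boundary_equilibria(m)
  xz <- bd[bd$label == "EXZ", ]
  expect_false(xz$exists)
  expect_true(xz$marginal)
  expect_identical(classify_analytic("EZ", m)$class, "marginal")
})

test_that("a stable admissible interior equilibrium attracts nearby states", {
  m <- theo(alpha = 0.4, beta = 0.8, b = 0.01)
  ie <- interior_equilibria(m)
  adm <- ie[ie$admissible, ]
  expect_identical(nrow(adm), 1L)
  expect_identical(classify_numeric(adm, m)$class, "stable")
  init <- c(adm$X, adm$Y, adm$Z) * c(1.2, 0.8, 1.1)
  tr <- simulate(m, init = init, t_end = 3000, n_save = 300)
  fin <- as.data.frame(tr)[300, ]
  expect_equal(c(fin$X, fin$Y, fin$Z), c(adm$X, adm$Y, adm$Z),
               tolerance = 1e-6)
})
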