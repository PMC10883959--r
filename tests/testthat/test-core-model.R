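# Right-hand sides, carrying capacity, Jacobian and their structural
# properties.

test_that("native system vanishes at its equilibria and matches hand arithmetic", {
  m <- theo()
  # coexistence equilibrium (10, 10.8): both rates zero
  expect_equal(unname(native_rhs(c(10, 10.8), m)), c(0, 0), tolerance = 1e-12)
  # prey-only equilibrium (K, 0)
  expect_equal(unname(native_rhs(c(m$K, 0), m)), c(0, 0))
  # term-by-term hand value at (50, 5):
  # dx = 1.2*50*(1-0.5) - 0.1*50*5 = 30 - 25 = 5
  # dy = 0.05*0.1*50*5 - 0.05*5 = 1.25 - 0.25 = 1
  expect_equal(unname(native_rhs(c(50, 5), m)), c(5, 1), tolerance = 1e-12)
})

test_that("carrying capacity is linear in prey with floor c", {
  m <- theo(alpha = 0.505)
  expect_identical(carrying_capacity(0, m), m$c)
  expect_equal(carrying_capacity(100, m), 20.1)   # 2*0.505*0.1*100 + 10
  # doubling X doubles the prey-dependent part
  k1 <- carrying_capacity(37, m) - m$c
  k2 <- carrying_capacity(74, m) - m$c
  expect_equal(k2, 2 * k1, tolerance = 1e-14)
  expect_error(carrying_capacity(-1, m), "negative")
})

test_that("full system reduces to the native system on the Z = 0 face", {
  set.seed(11)
  for (i in 1:25) {
    m <- as_invasion_model(random_params(25, seed = 100 + i)[i, ])
    st <- runif(2, 0, m$K)
    expect_identical(unname(full_rhs(c(st, 0), m))[1:2],
                     unname(native_rhs(st, m)))
    expect_identical(full_rhs(c(st, 0), m)[[3]], 0)
  }
})

test_that("full RHS matches the hand-computed example and fixes E_Z", {
  m <- theo(b = 0.04)
  # X: -alpha d X Z = -1; Y: -beta b Y Z = -0.432;
  # Z: 0.2*(1 - 1/12) - 0.04*10.8 with kappa(10) = 12
  expect_equal(unname(full_rhs(c(10, 10.8, 1), m)),
               c(-1, -0.432, 0.2 * (1 - 1 / 12) - 0.04 * 10.8),
               tolerance = 1e-12)
  expect_equal(unname(full_rhs(c(0, 0, m$c), m)), c(0, 0, 0))
})

test_that("all coordinate faces are invariant", {
  set.seed(21)
  for (i in 1:20) {
    m <- as_invasion_model(random_params(20, seed = 200 + i)[i, ])
    st <- runif(3, 0, m$K)
    for (j in 1:3) {
      s0 <- st; s0[j] <- 0
      expect_identical(unname(full_rhs(s0, m))[j], 0)
    }
  }
})

test_that("at d = 2q/(Kp) the predator equation takes the optimized logistic form", {
  set.seed(31)
  for (i in 1:20) {
    m <- as_invasion_model(random_params(20, seed = 300 + i)[i, ])
    dstar <- 2 * m$q / (m$K * m$p)
    m2 <- set_params(m, d = dstar)
    x <- runif(1, 0, m$K); y <- runif(1, 0, 50)
    g <- native_rhs(c(x, y), m2)[["dy"]]
    expect_equal(g, m2$q * y * (x / (m2$K / 2) - 1),
                 tolerance = 1e-12)
  }
})

test_that("state validation clamps solver jitter and rejects bad input", {
  m <- theo()
  expect_identical(unname(native_rhs(c(-1e-10, 5), m)),
                   unname(native_rhs(c(0, 5), m)))
  expect_error(native_rhs(c(-1e-3, 5), m), "negative")
  expect_error(full_rhs(c(NaN, 1, 1), m), "finite")
  expect_error(invasion_model(r = -1, s = 0.2, K = 100, c = 10, n = 2,
                              b = 0.01, d = 0.1, p = 0.05, q = 0.05,
                              alpha = 1, beta = 1),
               "'r'")
})

test_that("closed-form Jacobian matches central finite differences", {
  set.seed(41)
  fd_jac <- function(st, m, h = 1e-6) {
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- numeric(3); e[j] <- h
      J[, j] <- (full_rhs(st + e, m) - full_rhs(st - e, m)) / (2 * h)
    }
    J
  }
  for (i in 1:15) {
    m <- as_invasion_model(random_params(15, seed = 400 + i)[i, ])
    st <- runif(3, 0.5, m$K / 2)
    expect_equal(unname(jacobian(st, m)), fd_jac(st, m), tolerance = 1e-5)
  }
})
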