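# Shared model builders for the test suite.
# NB: `...` comes first so that short parameter names like `b` or `d`
# cannot partially match `alpha`/`beta`.

theo <- function(..., alpha = 1, beta = 1) {
  m <- fixture("theoretical", alpha = alpha, beta = beta)
  if (...length()) m <- set_params(m, ...)
  m
}

mink <- function(..., alpha = 1, beta = 1) {
  m <- fixture("mink", alpha = alpha, beta = beta)
  if (...length()) m <- set_params(m, ...)
  m
}

# Seeded random parameter records over the documented ranges with
# alpha, beta in (0, 3]; returns a data frame.
random_params <- function(n, seed = 20240222, amax = 3) {
  sample_params(n, seed = seed,
                ranges = param_ranges(alpha = c(1e-6, amax),
                                      beta = c(1e-6, amax)))
}

# A parameter set whose interior quadratic has two qualifying roots in
# (0, K) (the two-positive-equilibria case); found by seeded search.
two_root_model <- function() {
  invasion_model(r = 1.2, s = 0.2, K = 158.816, c = 0.05, n = 3,
                 b = 0.009908, d = 0.125482, p = 0.027603, q = 0.083114,
                 alpha = 0.3645, beta = 1.8595)
}
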