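test_that("slab series has the correct normalisation and one-term limit", {
  expect_equal(slab_MR(1e-10, 0.005, 0, n_terms = 1), 8 / pi^2)
  # partial sums at t = 0 approach 1 (tail of sum 1/(2n+1)^2 ~ 1/(4N))
  expect_equal(slab_MR(1e-10, 0.005, 0, n_terms = 500), 1, tolerance = 5e-4)
  expect_lt(slab_MR(1e-10, 0.005, 0, n_terms = 50),
            slab_MR(1e-10, 0.005, 0, n_terms = 500))
})

test_that("slab series decreases in t and D and increases in L", {
  t <- seq(0, 2e5, length.out = 20)
  mr_t <- slab_MR(2e-10, 0.005, t)
  expect_true(all(diff(mr_t) < 0))
  D <- 10^seq(-11, -8, length.out = 10)
  mr_D <- vapply(D, function(d) slab_MR(d, 0.005, 5e4), numeric(1))
  expect_true(all(diff(mr_D) < 0))
  L <- seq(0.002, 0.02, length.out = 10)
  mr_L <- vapply(L, function(l) slab_MR(2e-10, l, 5e4), numeric(1))
  expect_true(all(diff(mr_L) > 0))
})

test_that("slab series agrees with an independent finite-difference solve", {
  mr_fd <- oracle_slab_fd_MR(2.91731e-10, 0.005, 73800)
  mr_series <- slab_MR(2.91731e-10, 0.005, 73800, n_terms = 50)
  expect_equal(mr_series, mr_fd, tolerance = 1e-4)
  # frozen value from the oracle run
  expect_equal(mr_series, 0.09681831, tolerance = 1e-6)
})

test_that("log-slope inversion recovers the diffusivity over 4 decades", {
  for (D in 10^seq(-12, -8)) {
    for (L in c(0.001, 0.005)) {
      tau <- 4 * L^2 / (pi^2 * D)           # one-term time constant
      times <- seq(0, 6 * tau, length.out = 200)
      cv <- synthesize_curve(D, L, M0 = 1.0, M_e = 0.02, times = times)
      est <- estimate_deff(cv, L = L, M_e = 0.02)
      expect_lt(abs(est$D_eff / D - 1), 0.01)
      expect_gt(est$r_squared, 0.999)
    }
  }
})

test_that("noisy recovery: median of 20 replicates within 5 percent", {
  D <- 1.63249e-10; L <- 0.005
  tau <- 4 * L^2 / (pi^2 * D)
  times <- seq(0, 5 * tau, length.out = 120)
  est <- vapply(1:20, function(seed) {
    cv <- synthesize_curve(D, L, M0 = 1.24, M_e = 0.02, times = times,
                           noise_sd = 0.01, seed = seed)
    suppressWarnings(estimate_deff(cv, L = L, M_e = 0.02)$D_eff)
  }, numeric(1))
  expect_lt(abs(median(est) / D - 1), 0.05)
})

test_that("degenerate curves are rejected by the estimator", {
  flat <- drying_curve(seq(0, 1e4, length.out = 20), rep(0.5, 20))
  expect_error(estimate_deff(flat, L = 0.005, M_e = 0.02),
               "estimation error")
  short <- drying_curve(c(0, 10, 20), c(0.5, 0.499, 0.498))
  expect_error(estimate_deff(short, L = 0.005, M_e = 0.02,
                             fit_window = list(mr_max = 0.1)),
               "fewer than 3")
  # non-positive MR points are dropped with a warning
  t <- seq(0, 4e4, length.out = 30)
  cv <- synthesize_curve(2e-10, 0.002, 1, 0, times = t)
  cv$value[30] <- 0
  expect_warning(estimate_deff(cv, L = 0.002, M_e = 0), "non-positive")
})

test_that("curve synthesis is seed-reproducible and hits its limits", {
  t <- seq(0, 5e4, length.out = 40)
  a <- synthesize_curve(2e-10, 0.005, 1.2, 0.02, t, noise_sd = 0.01, seed = 7)
  b <- synthesize_curve(2e-10, 0.005, 1.2, 0.02, t, noise_sd = 0.01, seed = 7)
  expect_identical(a, b)
  clean <- synthesize_curve(2e-10, 0.005, 1.2, 0.02, t)
  expect_equal(clean$value, 0.02 + 1.18 * slab_MR(2e-10, 0.005, t))
  # with M_e = 0 the curve decays toward bone dry
  late <- synthesize_curve(2e-10, 0.001, 1.2, 0, times = c(0, 1e7))
  expect_lt(late$value[2], 1e-6)
})

test_that("mass curves convert to dry-basis moisture", {
  cv <- drying_curve(c(0, 100, 200), c(1.83, 1.5, 1.0), kind = "mass")
  w <- moisture_from_mass(cv, m_dry = 1.0)
  expect_equal(w$value, c(0.83, 0.5, 0))
  expect_equal(moisture_from_mass(drying_curve(0:1, c(2, 2), "mass"),
                                  m_dry = 1)$value, c(1, 1))
  expect_error(moisture_from_mass(cv, m_dry = 0), "positive")
  expect_error(moisture_from_mass(cv, m_dry = 1.2), "below")
  expect_error(moisture_from_mass(w), "mass curve")
})
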