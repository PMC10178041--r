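test_that("component averages are exact for uniform fields", {
  mesh <- generate_mesh(pod_geometry(), 5e-4)
  nn <- nrow(mesh$nodes)
  st <- field_state(0, rep(300, nn), rep(0.42, nn))
  for (reg in c("shell", "kernel", "pod")) {
    expect_equal(component_average(st, mesh, reg), 0.42)
    expect_equal(component_average(st, mesh, reg, field = "T"), 300)
  }
  expect_error(component_average(st, mesh, "husk"), "unknown region")
})

test_that("whole-pod average is the dry-mass-weighted component blend", {
  # shell 1.24, kernel 0.74 with the measured densities and analytic
  # volumes give a pod mean of 0.8689 d.b.
  sim <- ref_sim()
  expect_equal(sim$curves$M_pod_db[1], 0.868859857, tolerance = 1e-6)
  mesh <- sim$mesh
  nn <- nrow(mesh$nodes)
  # nodal field uniform per side of the interface cannot be represented
  # exactly; check the weighting logic on a uniform field scaled per region
  Vk <- 4 / 3 * pi * 0.005^2 * 0.008
  Vs <- 4 / 3 * pi * 0.006^2 * 0.009 - Vk
  w_shell <- 560 * Vs / (560 * Vs + 1000 * Vk)
  expect_equal(w_shell, 0.257719715, tolerance = 1e-6)
})

test_that("component averages are linear and bounded by the field range", {
  mesh <- generate_mesh(pod_geometry(), 5e-4)
  nn <- nrow(mesh$nodes)
  set.seed(11)
  f <- runif(nn); g <- runif(nn)
  for (reg in c("shell", "kernel")) {
    af <- component_average(field_state(0, f, f), mesh, reg)
    ag <- component_average(field_state(0, g, g), mesh, reg)
    afg <- component_average(field_state(0, f, 2 * f + 3 * g), mesh, reg)
    expect_equal(afg, 2 * af + 3 * ag)
    expect_gte(af, min(f)); expect_lte(af, max(f))
  }
  # a field linear in z on the symmetric kernel averages to its midplane value
  lin <- 5 + 2 * mesh$nodes[, 2]
  expect_equal(component_average(field_state(0, lin, lin), mesh, "kernel"), 5)
})

test_that("drying rate is dry-basis points per hour", {
  cv <- drying_curve(c(0, 73800), c(0.83, 0.10))
  expect_equal(drying_rate(cv), 3.560976, tolerance = 1e-6)
  cv2 <- drying_curve(c(0, 73800), c(1.24, 0.069))
  expect_equal(drying_rate(cv2), 5.712195, tolerance = 1e-6)
  flat <- drying_curve(c(0, 3600), c(0.5, 0.5))
  expect_equal(drying_rate(flat), 0)
  expect_error(drying_rate(cv, 3600, 0), "exceed")
})

test_that("rates over concatenated intervals time-average consistently", {
  t <- seq(0, 7200, by = 600)
  cv <- drying_curve(t, 0.8 * exp(-t / 4000) + 0.02)
  r_full <- drying_rate(cv, 0, 7200)
  r1 <- drying_rate(cv, 0, 2400)
  r2 <- drying_rate(cv, 2400, 7200)
  expect_equal(r_full, (r1 * 2400 + r2 * 4800) / 7200)
})

test_that("maximum relative error compares curves as a percentage", {
  t <- seq(0, 1e4, length.out = 21)
  ref <- drying_curve(t, 0.5 * exp(-t / 5e3) + 0.1)
  expect_equal(max_relative_error(ref, ref), 0)
  sim <- drying_curve(t, ref$value * 1.1)
  expect_equal(max_relative_error(sim, ref), 10)
  # one 8 percent excursion dominates
  v <- ref$value; v[10] <- ref$value[10] * 1.08
  expect_equal(max_relative_error(drying_curve(t, v), ref), 8,
               tolerance = 1e-9)
  late <- drying_curve(t + 2e4, ref$value)
  expect_error(max_relative_error(late, ref), "overlap")
})

test_that("threshold crossing is interpolated; sentinel when not reached", {
  below <- drying_curve(c(0, 100), c(0.08, 0.05))
  expect_equal(threshold_time(below), 0)
  never <- drying_curve(c(0, 100), c(0.5, 0.4))
  expect_true(is.na(threshold_time(never)))
  # against the closed-form inversion of the one-term slab law
  D <- 2e-10; L <- 0.005; M0 <- 1.0; Me <- 0.02
  t <- seq(0, 3e5, length.out = 600)
  cv <- synthesize_curve(D, L, M0, Me, t)
  thr <- 0.1
  mr_thr <- (thr - Me) / (M0 - Me)
  t_closed <- -log(mr_thr / (8 / pi^2)) * 4 * L^2 / (pi^2 * D)
  expect_equal(threshold_time(cv, thr), t_closed, tolerance = 0.01)
})
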