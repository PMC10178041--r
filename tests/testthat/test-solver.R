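test_that("equilibrium fields are fixed points of both steps", {
  geom <- pod_geometry(mode = "kernel_only")
  mesh <- generate_mesh(geom, 5e-4)
  mats <- list(kernel = const_material(D = 1e-9, M0 = 1))
  bc <- boundary_conditions(T0 = 315.15, Ta = 315.15, h_T = 30,
                            h_m_eff = 1e-6, M_e = 0.02)
  nn <- nrow(mesh$nodes)
  st <- field_state(0, rep(315.15, nn), rep(0.02, nn))
  st1 <- step_moisture(st, mesh, mats, bc, 60)
  expect_equal(st1$M, st$M, tolerance = 1e-12)
  st2 <- step_heat(st1, mesh, mats, bc, 60, dM_dt = rep(0, nn))
  expect_equal(st2$T, st$T, tolerance = 1e-12)
  expect_error(step_heat(st1, mesh, mats, bc, 60, dM_dt = rep(NaN, nn)),
               "non-finite")
})

test_that("a sealed surface conserves total moisture exactly", {
  sim <- run_simulation(pod_geometry(), control = sim_control(
    t_end = 3600, compute_heat = FALSE), h_m_eff = 0)
  cv <- sim$curves
  expect_equal(cv$M_pod_db, rep(cv$M_pod_db[1], nrow(cv)),
               tolerance = 1e-10)
})

test_that("per-step mass balance closes within 0.1 percent", {
  expect_lt(ref_sim()$max_mass_imbalance, 1e-3)
})

test_that("moisture and temperature obey the discrete maximum principle", {
  sim <- ref_sim()
  Me <- sim$bc$M_e
  M0max <- max(vapply(sim$materials, function(m) m$M0, numeric(1)))
  for (st in sim$snapshots) {
    expect_true(all(st$M >= Me - 1e-6) && all(st$M <= M0max + 1e-6))
    expect_true(all(st$T >= sim$bc$T0 - 1e-6) &&
                  all(st$T <= sim$bc$Ta + 0.01))
  }
  cv <- sim$curves
  expect_true(all(cv$M_pod_db[-1] <= cv$M_pod_db[-nrow(cv)] + 1e-12))
})

test_that("homogeneous sphere drying matches the series solution at Fo 0.1", {
  R <- 0.006; D <- 1e-9; Fo <- 0.1
  t_end <- Fo * R^2 / D
  geom <- pod_geometry(a_kernel = R, b_kernel = R, mode = "kernel_only")
  mats <- list(kernel = const_material(D = D, M0 = 1))
  sim <- run_simulation(geom, mats,
                        control = sim_control(dt = t_end / 400,
                                              t_end = t_end,
                                              mesh_h = 2.5e-4,
                                              compute_heat = FALSE),
                        M_e = 0, h_m_eff = 1e3 * D / R)  # Bi ~ 1000
  mr <- tail(sim$curves$M_kernel_db, 1)
  expect_equal(mr, oracle_sphere_MR(Fo), tolerance = 0.01)
})

test_that("homogeneous sphere heating matches the Robin series solution", {
  R <- 0.006; k <- 0.3; cp <- 2000; rho <- 1000; hT <- 30
  alpha <- k / (rho * cp); Bi <- hT * R / k
  Fo <- 0.2; t_end <- Fo * R^2 / alpha
  geom <- pod_geometry(a_kernel = R, b_kernel = R, mode = "kernel_only")
  mats <- list(kernel = const_material(rho = rho, k = k, cp = cp,
                                       D = 1e-12, M0 = 1, h_g = 0))
  sim <- run_simulation(geom, mats,
                        control = sim_control(dt = t_end / 400,
                                              t_end = t_end,
                                              mesh_h = 2.5e-4),
                        T0 = 20, M_e = 0, h_T = hT, h_m_eff = 0)
  theta <- (tail(sim$curves$T_center_K, 1) - sim$bc$Ta) /
    (sim$bc$T0 - sim$bc$Ta)
  expect_equal(theta, oracle_robin_sphere_center(Fo, Bi), tolerance = 5e-3)
})

test_that("evaporation cools: mean temperature below the no-sink run", {
  ctrl <- sim_control(t_end = 7200)
  with_sink <- run_simulation(pod_geometry(), control = ctrl)
  mats0 <- peanut_materials()
  mats0$shell$h_g <- 0
  mats0$kernel$h_g <- 0
  no_sink <- run_simulation(pod_geometry(), materials = mats0, control = ctrl)
  d <- no_sink$curves$T_mean_K[-1] - with_sink$curves$T_mean_K[-1]
  expect_true(all(d > 0))
})

test_that("time stepping converges at first order; halving barely moves curves", {
  run_at <- function(dt) run_simulation(pod_geometry(), control = sim_control(
    dt = dt, compute_heat = FALSE))
  s120 <- run_at(120); s60 <- run_at(60); s30 <- run_at(30)
  pick <- function(s, col, by) s$curves[[col]][seq(1, nrow(s$curves), by = by)]
  for (col in c("M_shell_db", "M_kernel_db", "M_pod_db")) {
    a <- pick(s60, col, 1)
    b <- pick(s30, col, 2)
    # halving dt changes each curve by < 0.2 % (relative rms over the curve)
    expect_lt(sqrt(mean(((a - b) / b)^2)), 2e-3)
    # successive halvings shrink the change by ~2x: first-order convergence
    e1 <- max(abs(pick(s120, col, 1) - pick(s60, col, 2)) / pick(s60, col, 2))
    e2 <- max(abs(a[seq(1, length(a), by = 2)] - pick(s30, col, 4)) /
                pick(s30, col, 4))
    expect_gt(e1 / e2, 1.6)
    expect_lt(e1 / e2, 2.4)
  }
  # away from the initial fast transient the pointwise change is tiny too
  late <- s60$curves$time_s >= 7200
  a <- s60$curves$M_shell_db[late]
  b <- pick(s30, "M_shell_db", 2)[late]
  expect_lt(max(abs(a - b) / b), 2e-3)
})

test_that("long-time limits: moisture to M_e, temperature to Ta", {
  ctrl <- sim_control(dt = 600, t_end = 738000, mesh_h = 8e-4)
  sim <- run_simulation(pod_geometry(mode = "kernel_only"), control = ctrl)
  cv <- sim$curves; n <- nrow(cv)
  expect_equal(cv$M_kernel_db[n], sim$bc$M_e, tolerance = 1e-3)
  expect_lt(abs(cv$T_mean_K[n] - sim$bc$Ta), 0.01)
  # uniformly, not just in the mean
  last <- sim$snapshots[[length(sim$snapshots)]]
  expect_lt(max(abs(last$M - sim$bc$M_e)), 1e-3 * 0.72)
  expect_lt(max(abs(last$T - sim$bc$Ta)), 0.01)
})

test_that("reruns are bit-identical", {
  ctrl <- sim_control(t_end = 1800)
  a <- run_simulation(pod_geometry(), control = ctrl)
  b <- run_simulation(pod_geometry(), control = ctrl)
  expect_identical(a$curves, b$curves)
  expect_identical(a$snapshots, b$snapshots)
})
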