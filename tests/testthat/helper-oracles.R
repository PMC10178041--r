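# Independent analytic / numerical oracles used to cross-check the
# finite-element solver and the slab series.  Deliberately coded from
# the textbook solutions, not from the package internals.

# Volume-mean moisture ratio of a sphere with a fixed (equilibrium)
# surface: MR = 6/pi^2 sum exp(-n^2 pi^2 Fo)/n^2
oracle_sphere_MR <- function(Fo, n_terms = 200) {
  n <- seq_len(n_terms)
  6 / pi^2 * sum(exp(-n^2 * pi^2 * Fo) / n^2)
}

# Positive roots of 1 - b*cot(b) = Bi (Robin sphere eigenvalues)
oracle_robin_roots <- function(Bi, n = 30) {
  vapply(seq_len(n), function(k) {
    stats::uniroot(function(b) 1 - b / tan(b) - Bi,
                   c((k - 1) * pi + 1e-9, k * pi - 1e-9),
                   tol = 1e-14)$root
  }, numeric(1))
}

# Center temperature ratio (T - Ta)/(T0 - Ta) of a Robin-cooled sphere
oracle_robin_sphere_center <- function(Fo, Bi) {
  b <- oracle_robin_roots(Bi)
  Cn <- 4 * (sin(b) - b * cos(b)) / (2 * b - sin(2 * b))
  sum(Cn * exp(-b^2 * Fo))
}

# Crank-Nicolson finite-difference solution of slab drying (half slab
# [0, L], symmetric at 0, surface at equilibrium), volume-mean MR.
oracle_slab_fd_MR <- function(D, L, t_end, nx = 400, nt = 4000) {
  dx <- L / nx
  dt <- t_end / nt
  r <- D * dt / (2 * dx^2)
  n <- nx
  A <- diag(rep(1 + 2 * r, n))
  B <- diag(rep(1 - 2 * r, n))
  for (i in seq_len(n - 1)) {
    A[i, i + 1] <- -r; A[i + 1, i] <- -r
    B[i, i + 1] <- r; B[i + 1, i] <- r
  }
  A[1, 2] <- -2 * r; B[1, 2] <- 2 * r   # symmetry at x = 0
  u <- rep(1, n)
  Ainv <- solve(A)
  for (k in seq_len(nt)) u <- Ainv %*% (B %*% u)
  uu <- c(u, 0)
  (sum(uu) - 0.5 * uu[1] - 0.5 * uu[n + 1]) / nx
}

# a material with constant (moisture-independent) properties
const_material <- function(name = "kernel", rho = 1000, k = 0.3,
                           cp = 2000, D = 1e-9, M0 = 1, h_g = 0) {
  material_model(name, rho = rho, k_slope = 0, k_intercept = k,
                 cp_slope = 0, cp_intercept = cp / 1000,
                 D_eff = D, M0 = M0, h_g = h_g)
}

# Reference coupled two-component run at packaged defaults, shared
# across test files (computed once per session).
.drypod_test_cache <- new.env(parent = emptyenv())
ref_sim <- function() {
  if (is.null(.drypod_test_cache$sim))
    .drypod_test_cache$sim <- run_simulation(pod_geometry())
  .drypod_test_cache$sim
}
ref_sim_at <- function(col, t) {
  cv <- ref_sim()$curves
  stats::approx(cv$time_s, cv[[col]], xout = t)$y
}
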