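#' Boundary and initial conditions for a drying run
#'
#' @param T0 initial solid temperature (K).
#' @param Ta drying-air temperature (K).
#' @param h_T convective heat transfer coefficient (W/(m^2 K)).
#' @param h_m_eff moisture-content-basis surface mass transfer
#'   coefficient (m/s), i.e. `f_s * h_m`.
#' @param M_e equilibrium dry-basis moisture of the solid with the
#'   drying air (g/g).
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(T0, Ta, h_T, h_m_eff, M_e) {
  if (h_T < 0) stop("`h_T` must be non-negative")
  if (h_m_eff < 0) stop("`h_m_eff` must be non-negative")
  if (M_e < 0) stop("`M_e` must be non-negative")
  out <- list(T0 = T0, Ta = Ta, h_T = h_T, h_m_eff = h_m_eff, M_e = M_e)
  class(out) <- "boundary_conditions"
  out
}

#' Nodal field state at a time point
#'
#' @param t time (s).
#' @param T nodal temperature (K).
#' @param M nodal dry-basis moisture (g/g).
#' @return An object of class `field_state`.
#' @export
field_state <- function(t, T, M) {
  stopifnot(length(T) == length(M))
  structure(list(t = t, T = T, M = M), class = "field_state")
}

#' Time-stepping controls
#'
#' @param dt time step (s).
#' @param t_end termination time (s); default 73800 s = 1230 min.
#' @param mesh_h target mesh element size (m).
#' @param snapshot_times times (s) at which full nodal fields are kept.
#' @param compute_heat solve the energy equation as well as moisture
#'   (the moisture field never depends on temperature, so moisture-only
#'   runs are exact and much faster).
#' @param nu_re_exp,sh_re_exp Reynolds exponents passed to
#'   [transfer_coefficients()].
#' @return An object of class `sim_control`.
#' @export
sim_control <- function(dt = 60, t_end = 73800, mesh_h = 5e-4,
                        snapshot_times = c(0, 60, 300, 1800, 3600,
                                           7200, 14400, 36000, 72000, t_end),
                        compute_heat = TRUE,
                        nu_re_exp = 0.53, sh_re_exp = 0.5) {
  if (dt <= 0) stop("`dt` must be positive")
  if (t_end < dt) stop("`t_end` must be at least one step `dt`")
  structure(list(dt = dt, t_end = t_end, mesh_h = mesh_h,
                 snapshot_times = snapshot_times,
                 compute_heat = compute_heat,
                 nu_re_exp = nu_re_exp, sh_re_exp = sh_re_exp),
            class = "sim_control")
}

# material assigned to each region label present in the mesh
.region_materials <- function(mesh, materials) {
  regs <- unique(mesh$region)
  out <- lapply(regs, function(rg) {
    m <- materials[[rg]]
    if (is.null(m)) stop("no material supplied for region '", rg, "'")
    m
  })
  names(out) <- regs
  out
}

# element-wise constant lookup by region
.by_region <- function(mesh, materials, field) {
  vals <- vapply(materials, function(m) m[[field]], numeric(1))
  unname(vals[mesh$region])
}

# the material facing the drying air (outermost region)
.surface_region <- function(mesh) {
  if ("shell" %in% mesh$region) "shell"
  else if ("pod" %in% mesh$region) "pod"
  else "kernel"
}

# Edges carrying the convective boundary condition.  In shell_only mode
# the inner surface is exposed too: the mode emulates thin-layer drying
# of loose shells, which see the drying air on both faces.
.robin_edges <- function(mesh) {
  rbind(mesh$boundary, mesh$inner)
}

# Prepared implicit moisture operator: constant over the run because the
# effective diffusivities are region-wise constant.
.moisture_operator <- function(mesh, fp, materials, bc, dt) {
  rho_e <- .by_region(mesh, materials, "rho")
  D_e <- .by_region(mesh, materials, "D_eff")
  if (all(rho_e * D_e == 0)) stop("numerical error: all-zero diffusivity")
  K <- .stiffness(fp, rho_e * D_e)
  mass <- .lumped_mass(fp, rho_e)
  rho_s <- materials[[.surface_region(mesh)]]$rho
  bsurf <- .robin_lump(mesh, .robin_edges(mesh), rho_s * bc$h_m_eff)
  A <- K + Matrix::Diagonal(x = mass / dt + bsurf)
  list(ch = Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A),
                                         "CsparseMatrix")),
       mass = mass, bsurf = bsurf, dt = dt, Me = bc$M_e)
}

.moisture_advance <- function(op, M) {
  rhs <- op$mass * M / op$dt + op$bsurf * op$Me
  as.numeric(Matrix::solve(op$ch, rhs, system = "A"))
}

# One implicit heat step with coefficients lagged at the supplied M field.
.heat_advance <- function(mesh, fp, materials, bc, dt, T, M_lag, dM_dt) {
  Mbar <- (M_lag[fp$e[, 1]] + M_lag[fp$e[, 2]] + M_lag[fp$e[, 3]]) / 3
  k_e <- cp_e <- numeric(length(Mbar))
  for (rg in names(materials)) {
    sel <- mesh$region == rg
    k_e[sel] <- material_conductivity(materials[[rg]], pmax(Mbar[sel], 0))
    cp_e[sel] <- material_specific_heat(materials[[rg]], pmax(Mbar[sel], 0))
  }
  rho_e <- .by_region(mesh, materials, "rho")
  hg_e <- .by_region(mesh, materials, "h_g")
  K <- .stiffness(fp, k_e)
  massT <- .lumped_mass(fp, rho_e * cp_e)
  massS <- .lumped_mass(fp, rho_e * hg_e)
  bT <- .robin_lump(mesh, .robin_edges(mesh), bc$h_T)
  A <- K + Matrix::Diagonal(x = massT / dt + bT)
  rhs <- massT * T / dt + bT * bc$Ta + massS * dM_dt
  as.numeric(Matrix::solve(
    Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A),
                                 "CsparseMatrix")), rhs, system = "A"))
}

#' Advance the moisture field by one implicit step
#'
#' Solves one backward-Euler step of the axisymmetric Fickian moisture
#' diffusion equation with the convective (Robin) surface condition
#' `-D dM/dn = h_m_eff (M - M_e)` and natural zero flux on the symmetry
#' boundary.  The weak form is density-weighted so that water mass flux
#' (not merely the moisture gradient) is continuous across the
#' shell-kernel interface.
#'
#' @param state a [field_state()].
#' @param mesh an `aximesh`.
#' @param materials named list of [material_model()]s keyed by region.
#' @param bc a [boundary_conditions()].
#' @param dt time step (s).
#' @return The updated [field_state()] at `t + dt` (temperature carried
#'   over unchanged).
#' @export
step_moisture <- function(state, mesh, materials, bc, dt) {
  fp <- .fem_precompute(mesh)
  op <- .moisture_operator(mesh, fp, .region_materials(mesh, materials),
                           bc, dt)
  M_new <- .moisture_advance(op, state$M)
  field_state(state$t + dt, state$T, M_new)
}

#' Advance the temperature field by one implicit step
#'
#' Solves one backward-Euler step of the energy balance
#' `rho cp(M) dT/dt = div(k(M) grad T) + rho h_g dM/dt` with the Robin
#' surface condition `-k dT/dn = h_T (T - Ta)`.  The latent term is an
#' evaporative sink while drying (`dM/dt < 0`).  Conductivity and
#' specific heat are evaluated at the lagged moisture field in `state`.
#'
#' @inheritParams step_moisture
#' @param dM_dt nodal moisture rate (1/s) over the same interval,
#'   normally from the moisture step.
#' @return The updated [field_state()] at `t + dt` (moisture unchanged).
#' @export
step_heat <- function(state, mesh, materials, bc, dt, dM_dt) {
  if (any(!is.finite(dM_dt)))
    stop("numerical error: non-finite `dM_dt`")
  fp <- .fem_precompute(mesh)
  T_new <- .heat_advance(mesh, fp, .region_materials(mesh, materials),
                         bc, dt, state$T, state$M, dM_dt)
  field_state(state$t + dt, T_new, state$M)
}

#' Run a coupled drying simulation
#'
#' Integrates the coupled moisture and heat equations over the drying
#' schedule with an operator-split loop: each interval first advances
#' moisture implicitly, then advances temperature using that interval's
#' moisture rate as the evaporative sink, with thermal properties lagged
#' one step.  Everything is deterministic; identical calls give
#' bit-identical results.
#'
#' @param geom a [pod_geometry()]; its `mode` selects two-component or
#'   single-component simulation.
#' @param materials named list of [material_model()]s (needs entries for
#'   every region in the mesh); default [peanut_materials()].
#' @param air an [hot_air_properties()] state.
#' @param control a [sim_control()].
#' @param T0 initial solid temperature (degrees C).
#' @param M_e equilibrium dry-basis moisture (g/g).
#' @param f_s surface-resistance factor applied to the air-side mass
#'   transfer coefficient; default is the packaged calibrated value
#'   (see [calibrate_surface()]).
#' @param h_T,h_m_eff optional direct overrides of the film
#'   coefficients; when given they replace the correlation values.
#' @param mesh optionally, a pre-built `aximesh` (must match `geom`).
#' @return An object of class `drying_sim` containing `curves` (a
#'   data.frame of per-step component-averaged moisture and temperature),
#'   `snapshots` (list of [field_state()]s), the `mesh`, resolved
#'   transfer coefficients `tc`, boundary conditions `bc`, inputs, and
#'   the maximum per-step relative mass-balance residual
#'   `max_mass_imbalance`.
#' @examples
#' \donttest{
#' sim <- run_simulation(pod_geometry(mode = "kernel_only"),
#'                       control = sim_control(t_end = 3600))
#' summary(sim)
#' }
#' @export
run_simulation <- function(geom, materials = peanut_materials(),
                           air = hot_air_properties(42, 0.75, 0.08),
                           control = sim_control(),
                           T0 = 20, M_e = 0.02, f_s = NULL,
                           h_T = NULL, h_m_eff = NULL, mesh = NULL) {
  stopifnot(inherits(geom, "pod_geometry"), inherits(control, "sim_control"))
  if (is.null(f_s)) f_s <- drypod_defaults$f_s
  if (is.null(mesh)) mesh <- generate_mesh(geom, control$mesh_h)
  mats <- .region_materials(mesh, materials)
  tc <- transfer_coefficients(air, equivalent_diameter(geom), f_s,
                              nu_re_exp = control$nu_re_exp,
                              sh_re_exp = control$sh_re_exp)
  bc <- boundary_conditions(T0 = T0 + 273.15, Ta = air$Ta + 273.15,
                            h_T = if (is.null(h_T)) tc$h_T else h_T,
                            h_m_eff = if (is.null(h_m_eff)) tc$h_m_eff
                                      else h_m_eff,
                            M_e = M_e)
  min_M0 <- min(vapply(mats, function(m) m$M0, numeric(1)))
  if (bc$M_e >= min_M0)
    stop("`M_e` must be below the smallest component initial moisture (",
         min_M0, ")")

  fp <- .fem_precompute(mesh)
  regs <- names(mats)
  # r-weighted nodal averaging weights per region and dry-mass pod weights
  wreg <- lapply(regs, function(rg) .region_node_weights(fp, rg))
  names(wreg) <- regs
  rho_by_reg <- vapply(mats, function(m) m$rho, numeric(1))
  wpod <- Reduce(`+`, Map(function(w, rho) w * rho, wreg,
                          as.list(rho_by_reg[regs])))
  wsurf <- .robin_lump(mesh, .robin_edges(mesh), 1)
  center_node <- which.min(rowSums(mesh$nodes^2))
  wall <- Reduce(`+`, wreg)

  # Initial moisture: lumped L2 projection of the piecewise-constant
  # per-region M0 onto the nodal space, with the rho weighting of the
  # moisture equation.  Interface nodes get a dry-mass-weighted blend of
  # the two region values, so the projected field carries exactly the
  # same total water as the discontinuous initial condition.
  nn <- nrow(mesh$nodes)
  num <- den <- numeric(nn)
  for (rg in regs) {
    w <- .region_node_weights(fp, rg) * mats[[rg]]$rho
    num <- num + w * mats[[rg]]$M0
    den <- den + w
  }
  M <- num / den
  T_ <- rep(bc$T0, nn)

  nstep <- as.integer(round(control$t_end / control$dt))
  dt <- control$dt
  op <- .moisture_operator(mesh, fp, mats, bc, dt)

  avg <- function(w, x) sum(w * x) / sum(w)
  nr <- nstep + 1L
  curves <- data.frame(time_s = (0:nstep) * dt)
  for (rg in regs) curves[[paste0("M_", rg, "_db")]] <- NA_real_
  curves$M_pod_db <- NA_real_
  curves$T_mean_K <- curves$T_surface_K <- curves$T_center_K <- NA_real_
  record <- function(i) {
    for (rg in regs)
      curves[[paste0("M_", rg, "_db")]][i] <<- avg(wreg[[rg]], M)
    curves$M_pod_db[i] <<- avg(wpod, M)
    curves$T_mean_K[i] <<- avg(wall, T_)
    curves$T_surface_K[i] <<- avg(wsurf, T_)
    curves$T_center_K[i] <<- T_[center_node]
  }
  record(1L)
  # at t = 0 the field is exactly uniform per region; record the exact
  # averages rather than those of the nodal projection
  for (rg in regs) curves[[paste0("M_", rg, "_db")]][1] <- mats[[rg]]$M0
  curves$M_pod_db[1] <- sum(vapply(regs, function(rg)
    rho_by_reg[[rg]] * sum(wreg[[rg]]) * mats[[rg]]$M0, numeric(1))) /
    sum(vapply(regs, function(rg)
      rho_by_reg[[rg]] * sum(wreg[[rg]]), numeric(1)))

  snap_idx <- unique(pmin(nstep, pmax(0L, as.integer(
    round(control$snapshot_times / dt)))))
  snapshots <- list()
  if (0L %in% snap_idx) snapshots[["0"]] <- field_state(0, T_, M)

  max_imb <- 0
  for (k in seq_len(nstep)) {
    M_new <- .moisture_advance(op, M)
    if (any(!is.finite(M_new)))
      stop("divergent moisture solve at step ", k)
    # discrete mass balance: storage change vs boundary flux
    storage <- sum(op$mass * (M_new - M)) / dt
    bflux <- -sum(op$bsurf * (M_new - bc$M_e))
    denom <- max(abs(storage), abs(bflux))
    if (denom > 0)
      max_imb <- max(max_imb, abs(storage - bflux) / denom)
    dM_dt <- (M_new - M) / dt
    if (control$compute_heat) {
      T_new <- .heat_advance(mesh, fp, mats, bc, dt, T_, M, dM_dt)
      if (any(!is.finite(T_new)))
        stop("divergent heat solve at step ", k)
      T_ <- T_new
    }
    M <- M_new
    record(k + 1L)
    if (k %in% snap_idx)
      snapshots[[as.character(k * dt)]] <- field_state(k * dt, T_, M)
  }

  out <- list(curves = curves, snapshots = snapshots, mesh = mesh,
              geom = geom, materials = mats, air = air, tc = tc, bc = bc,
              control = control, max_mass_imbalance = max_imb)
  class(out) <- "drying_sim"
  out
}

#' @export
print.drying_sim <- function(x, ...) {
  cv <- x$curves
  cat(sprintf("Drying simulation (%s): %d steps of %g s (%.1f h), %d nodes\n",
              x$geom$mode, nrow(cv) - 1L, x$control$dt,
              max(cv$time_s) / 3600, nrow(x$mesh$nodes)))
  cat(sprintf("  pod-average M: %.4f -> %.4f d.b.\n",
              cv$M_pod_db[1], cv$M_pod_db[nrow(cv)]))
  if (x$control$compute_heat)
    cat(sprintf("  mean T: %.2f -> %.2f degC (air %.2f degC)\n",
                cv$T_mean_K[1] - 273.15, cv$T_mean_K[nrow(cv)] - 273.15,
                x$bc$Ta - 273.15))
  invisible(x)
}

#' @export
summary.drying_sim <- function(object, ...) {
  cv <- object$curves
  n <- nrow(cv)
  hours <- max(cv$time_s) / 3600
  rate <- (cv$M_pod_db[1] - cv$M_pod_db[n]) * 100 / hours
  cat(sprintf("Drying simulation summary (%s)\n", object$geom$mode))
  print(object$geom)
  print(object$tc)
  cat(sprintf("  duration %.1f h, dt = %g s, mesh %d nodes / %d triangles\n",
              hours, object$control$dt, nrow(object$mesh$nodes),
              nrow(object$mesh$elements)))
  cat(sprintf("  pod-average drying rate: %.3f %%/h (d.b. points per hour)\n",
              rate))
  for (nm in grep("^M_.*_db$", names(cv), value = TRUE))
    cat(sprintf("  %-12s %.4f -> %.4f d.b.\n", nm, cv[[nm]][1], cv[[nm]][n]))
  if (object$control$compute_heat)
    cat(sprintf("  max |T - Ta| at end: %.3f K\n",
                abs(cv$T_mean_K[n] - object$bc$Ta)))
  cat(sprintf("  max per-step mass-balance residual: %.2e\n",
              object$max_mass_imbalance))
  invisible(object)
}

#' @export
plot.drying_sim <- function(x, which = c("moisture", "temperature"), ...) {
  which <- match.arg(which)
  cv <- x$curves
  if (which == "moisture") {
    cols <- grep("^M_.*_db$", names(cv), value = TRUE)
    graphics::matplot(cv$time_s / 3600, cv[cols], type = "l", lty = 1,
                      xlab = "time (h)", ylab = "moisture (d.b., g/g)", ...)
    graphics::legend("topright", legend = sub("^M_(.*)_db$", "\\1", cols),
                     col = seq_along(cols), lty = 1, bty = "n")
  } else {
    cols <- c("T_center_K", "T_surface_K", "T_mean_K")
    graphics::matplot(cv$time_s / 3600, cv[cols] - 273.15, type = "l",
                      lty = 1, xlab = "time (h)",
                      ylab = "temperature (degC)", ...)
    graphics::abline(h = x$bc$Ta - 273.15, lty = 3)
    graphics::legend("bottomright", legend = c("center", "surface", "mean"),
                     col = 1:3, lty = 1, bty = "n")
  }
  invisible(x)
}
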