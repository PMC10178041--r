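#' Packaged default parameters
#'
#' `f_s` is the surface-resistance factor applied to the air-side mass
#' transfer coefficient (see [transfer_coefficients()]).  The packaged
#' value was calibrated once, with [calibrate_surface()], so that the
#' default two-component run reproduces the whole-pod simulated drying
#' rate of 3.53 %/h, and then frozen; all component-level outputs are
#' untuned predictions.  `M_e` is the equilibrium dry-basis moisture of
#' peanut at 42 degC / 8 % RH from a modified-Henderson isotherm.
#'
#' @format A list with elements `f_s`, `M_e`, `target_rate`.
#' @export
drypod_defaults <- list(
  f_s = 7.625079e-06,    # frozen output of calibrate_surface()
  M_e = 0.02,
  target_rate = 3.53
)

#' Default run configuration
#'
#' The full structured configuration of the reference drying run: air at
#' 42 degC, 0.75 m/s, 8 % RH; the 5 x 8 mm kernel in a 1 mm shell;
#' measured component densities, property laws and effective
#' diffusivities; initial temperature 20 degC; 60 s steps to 1230 min.
#'
#' @return Nested list with blocks `air`, `geometry`, `materials`, `bc`,
#'   `numerics`, `output`.
#' @export
default_config <- function() {
  list(
    air = list(Ta = 42, va = 0.75, RH = 0.08),
    geometry = list(a_kernel = 0.005, b_kernel = 0.008, t_shell = 0.001,
                    mode = "two_component"),
    materials = list(
      shell = list(rho = 560, k_slope = 0.17062, k_intercept = 0.07753,
                   cp_slope = 4.04506, cp_intercept = 2.05226,
                   D_eff = 1.63249e-10, M0 = 1.24),
      kernel = list(rho = 1000, k_slope = 0.32528, k_intercept = 0.12559,
                    cp_slope = 1.96152, cp_intercept = 1.15307,
                    D_eff = 2.91731e-10, M0 = 0.74),
      pod = list(D_eff = 5.7512e-10, M0 = 0.83)
    ),
    bc = list(T0 = 20, M_e = drypod_defaults$M_e, f_s = drypod_defaults$f_s),
    numerics = list(dt = 60, t_end = 73800, mesh_h = 5e-4,
                    nu_re_exp = 0.53, sh_re_exp = 0.5),
    output = list(snapshot_times_s = c(0, 60, 300, 1800, 3600,
                                       7200, 14400, 36000, 72000, 73800))
  )
}

# recursive merge of an override list into defaults; unknown keys error
.merge_config <- function(defaults, override, path = character()) {
  if (is.null(override)) return(list(value = defaults, overrides = character()))
  if (!is.list(override) || !is.list(defaults)) {
    return(list(value = override,
                overrides = paste(path, collapse = "$")))
  }
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop("config error: unknown key(s): ",
         paste(paste(c(path, ""), collapse = "$"), bad, sep = "",
               collapse = ", "))
  ov <- character()
  for (nm in names(override)) {
    res <- .merge_config(defaults[[nm]], override[[nm]], c(path, nm))
    defaults[[nm]] <- res$value
    ov <- c(ov, res$overrides)
  }
  list(value = defaults, overrides = ov)
}

.validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("config error: ", msg)
  chk(cfg$air$Ta >= 0 && cfg$air$Ta <= 100,
      "air$Ta must be in [0, 100] degC")
  chk(cfg$air$va >= 0, "air$va must be non-negative")
  chk(cfg$air$RH >= 0 && cfg$air$RH <= 1, "air$RH must be in [0, 1]")
  g <- cfg$geometry
  chk(all(c(g$a_kernel, g$b_kernel, g$t_shell) > 0),
      "geometry dimensions must be positive")
  chk(g$mode %in% c("two_component", "shell_only", "kernel_only",
                    "pod_homogeneous"), "unknown geometry$mode")
  for (nm in c("shell", "kernel")) {
    m <- cfg$materials[[nm]]
    chk(m$rho > 0 && m$D_eff > 0 && m$M0 > 0,
        paste0("materials$", nm, " rho, D_eff, M0 must be positive"))
  }
  chk(cfg$bc$M_e >= 0, "bc$M_e must be non-negative")
  chk(cfg$bc$f_s > 0, "bc$f_s must be positive")
  n <- cfg$numerics
  chk(n$dt > 0 && n$t_end >= n$dt, "numerics: need dt > 0, t_end >= dt")
  chk(n$mesh_h > 0, "numerics$mesh_h must be positive")
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unspecified fields take the packaged defaults ([default_config()]);
#' unknown keys and out-of-range values are rejected with explicit
#' messages.  The returned configuration carries an `overrides`
#' attribute listing every key path the file changed, which is echoed
#' into the resolved-config JSON for audit.
#'
#' @param path YAML file; an empty file yields the full default
#'   configuration.
#' @return A validated configuration list with an `overrides` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  res <- .merge_config(default_config(), user)
  cfg <- .validate_config(res$value)
  attr(cfg, "overrides") <- res$overrides
  cfg
}

# materials list (shell/kernel/pod material_model) from a config
config_materials <- function(cfg, geom = build_geometry(cfg)) {
  s <- cfg$materials$shell; k <- cfg$materials$kernel
  shell <- material_model("shell", s$rho, s$k_slope, s$k_intercept,
                          s$cp_slope, s$cp_intercept, s$D_eff, s$M0)
  kernel <- material_model("kernel", k$rho, k$k_slope, k$k_intercept,
                           k$cp_slope, k$cp_intercept, k$D_eff, k$M0)
  base <- pod_geometry(geom$a_kernel, geom$b_kernel, geom$t_shell)
  Vk <- 4 / 3 * pi * base$a_kernel^2 * base$b_kernel
  Vo <- 4 / 3 * pi * base$a_outer^2 * base$b_outer
  ms <- shell$rho * (Vo - Vk); mk <- kernel$rho * Vk
  ws <- ms / (ms + mk); wk <- mk / (ms + mk)
  pod <- material_model("pod", (ms + mk) / Vo,
                        ws * shell$k_slope + wk * kernel$k_slope,
                        ws * shell$k_intercept + wk * kernel$k_intercept,
                        ws * shell$cp_slope + wk * kernel$cp_slope,
                        ws * shell$cp_intercept + wk * kernel$cp_intercept,
                        cfg$materials$pod$D_eff, cfg$materials$pod$M0)
  list(shell = shell, kernel = kernel, pod = pod)
}

#' Run a drying simulation from a configuration
#'
#' Convenience front end used by the command-line tool: builds the
#' geometry, materials, air state and controls from a configuration
#' list and calls [run_simulation()].
#'
#' @param config configuration list (see [default_config()],
#'   [load_config()]).
#' @param compute_heat solve the energy equation too (default TRUE).
#' @return A `drying_sim`.
#' @export
simulate_drying <- function(config = default_config(), compute_heat = TRUE) {
  cfg <- .validate_config(.merge_config(default_config(), config)$value)
  geom <- build_geometry(cfg)
  n <- cfg$numerics
  ctrl <- sim_control(dt = n$dt, t_end = n$t_end, mesh_h = n$mesh_h,
                      snapshot_times = cfg$output$snapshot_times_s,
                      compute_heat = compute_heat,
                      nu_re_exp = n$nu_re_exp, sh_re_exp = n$sh_re_exp)
  run_simulation(geom,
                 materials = config_materials(cfg, geom),
                 air = hot_air_properties(cfg$air$Ta, cfg$air$va, cfg$air$RH),
                 control = ctrl,
                 T0 = cfg$bc$T0, M_e = cfg$bc$M_e, f_s = cfg$bc$f_s)
}

#' Calibrate the surface-resistance factor
#'
#' Determines the dimensionless factor `f_s` (the single free surface
#' parameter, see [transfer_coefficients()]) so that the two-component
#' default run reproduces the target whole-pod drying rate.  A
#' log-spaced bracketing sweep first verifies that the pod drying rate
#' responds monotonically to `f_s` over `bounds`, then a deterministic
#' root search (bisection via [stats::uniroot()] on `log10 f_s`) drives
#' the rate to the target.  Only the pod-level rate is targeted; all
#' component-level quantities remain held-out predictions.
#'
#' The moisture field does not depend on temperature (constant
#' diffusivities, constant surface coefficients), so calibration runs
#' integrate moisture only; the result is identical to a coupled run.
#'
#' @param config configuration (two-component defaults).
#' @param target_rate target whole-pod drying rate (%/h).
#' @param bounds search bounds for `f_s`.
#' @param tol absolute tolerance on `log10 f_s` in the root search.
#' @return An object of class `calibration_result` with `f_s`, `M_e`,
#'   the achieved `rate`, `objective` (absolute rate residual),
#'   `sweep` (the bracketing table) and a `frozen` flag (FALSE: the
#'   packaged default is the frozen copy of this result).
#' @export
calibrate_surface <- function(config = default_config(),
                              target_rate = drypod_defaults$target_rate,
                              bounds = c(1e-6, 1), tol = 1e-5) {
  cfg <- .validate_config(.merge_config(default_config(), config)$value)
  if (cfg$geometry$mode != "two_component")
    stop("calibration is defined against the two-component pod run")
  rate_of <- function(f_s) {
    cfg$bc$f_s <- f_s
    sim <- simulate_drying(cfg, compute_heat = FALSE)
    drying_rate(component_curve(sim, "pod"))
  }
  lb <- log10(bounds)
  sweep_fs <- 10^seq(lb[1], lb[2], length.out = 5)
  sweep_rate <- vapply(sweep_fs, rate_of, numeric(1))
  if (any(diff(sweep_rate) <= 0))
    stop("calibration failure: pod drying rate is not monotone in f_s ",
         "over the bounds; sweep rates: ",
         paste(sprintf("%.3f", sweep_rate), collapse = ", "))
  if (target_rate < sweep_rate[1] || target_rate > sweep_rate[5])
    stop("calibration failure: target rate ", target_rate,
         " %/h not bracketed by bounds (sweep spans ",
         sprintf("%.3f..%.3f", sweep_rate[1], sweep_rate[5]), " %/h)")
  root <- stats::uniroot(function(l) rate_of(10^l) - target_rate,
                         interval = lb, tol = tol)
  f_s <- 10^root$root
  achieved <- rate_of(f_s)
  out <- list(f_s = f_s, M_e = cfg$bc$M_e, rate = achieved,
              target = target_rate,
              objective = abs(achieved - target_rate),
              sweep = data.frame(f_s = sweep_fs, rate = sweep_rate),
              frozen = FALSE)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Surface calibration: f_s = %.6e (M_e = %g d.b.)\n",
              x$f_s, x$M_e))
  cat(sprintf("  pod drying rate %.4f %%/h vs target %.4f (residual %.2e)\n",
              x$rate, x$target, x$objective))
  invisible(x)
}
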