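#' Hot-air properties at a drying-air temperature
#'
#' Evaluates the drying-medium property correlations (density, specific
#' heat, thermal conductivity, dynamic viscosity, and vapour diffusivity
#' in air) at the air temperature `Ta`.  The correlations are quadratic
#' polynomials in temperature expressed in degrees Celsius; any Kelvin
#' state held by the solver is converted at this boundary.
#'
#' @param Ta air temperature (degrees C); must lie in [0, 100].
#' @param va air velocity (m/s).
#' @param RH relative humidity (fraction, 0-1).
#' @return An object of class `air_state` with fields `Ta` (degC), `va`,
#'   `RH`, `rho_a` (kg/m^3), `c_a` (J/(kg K)), `k_a` (W/(m K)),
#'   `mu_a` (Pa s), `D_a` (m^2/s).
#' @examples
#' air <- hot_air_properties(42, 0.75, 0.08)
#' air$rho_a  # ~1.1219 kg/m^3
#' @export
hot_air_properties <- function(Ta, va = 0.75, RH = 0.08) {
  if (!is.numeric(Ta) || length(Ta) != 1L || !is.finite(Ta))
    stop("`Ta` must be a single finite number (degrees C)")
  if (Ta < 0 || Ta > 100)
    stop("`Ta` = ", Ta, " degC is outside the valid range [0, 100] degC")
  if (va < 0) stop("`va` must be non-negative")
  if (RH < 0 || RH > 1) stop("`RH` must be a fraction in [0, 1]")
  out <- list(
    Ta    = Ta,
    va    = va,
    RH    = RH,
    rho_a = 8.666e-6 * Ta^2 - 4.318e-3 * Ta + 1.288,
    c_a   = 4.834e-4 * Ta^2 - 2.218e-2 * Ta + 1007,
    k_a   = -2.401e-8 * Ta^2 + 7.554e-5 * Ta + 2.364e-2,
    mu_a  = -3.238e-11 * Ta^2 + 4.839e-8 * Ta + 1.73e-5,
    D_a   = 3.229e-10 * Ta^2 + 1.577e-7 * Ta + 2.089e-5
  )
  class(out) <- "air_state"
  out
}

#' @export
print.air_state <- function(x, ...) {
  cat("Hot-air state at", x$Ta, "degC,", x$va, "m/s, RH", x$RH, "\n")
  cat(sprintf("  rho_a = %.5f kg/m^3\n", x$rho_a))
  cat(sprintf("  c_a   = %.3f J/(kg K)\n", x$c_a))
  cat(sprintf("  k_a   = %.6f W/(m K)\n", x$k_a))
  cat(sprintf("  mu_a  = %.4e Pa s\n", x$mu_a))
  cat(sprintf("  D_a   = %.4e m^2/s\n", x$D_a))
  invisible(x)
}

#' Construct a drying-material component model
#'
#' A material component (shell, kernel, or homogenised whole pod) carries
#' its constant dry-solid density, linear moisture laws for thermal
#' conductivity and specific heat, an effective moisture diffusivity, its
#' initial dry-basis moisture, and the latent heat of vaporisation.
#' Thermal conductivity is `k = k_slope * M + k_intercept` in W/(m K);
#' specific heat is `cp = cp_slope * M + cp_intercept` in kJ/(kg K)
#' (converted to J/(kg K) on evaluation).  Both laws are clamped at the
#' initial moisture `M0` so they are never extrapolated above the wettest
#' state the material can be in.
#'
#' @param name component id: "shell", "kernel" or "pod".
#' @param rho dry-solid density (kg/m^3).
#' @param k_slope,k_intercept thermal conductivity law (W/(m K) per d.b. unit).
#' @param cp_slope,cp_intercept specific heat law (kJ/(kg K) per d.b. unit).
#' @param D_eff effective moisture diffusivity (m^2/s).
#' @param M0 initial dry-basis moisture (g/g).
#' @param h_g latent heat of vaporisation (J/kg).
#' @return An object of class `material_model`.
#' @export
material_model <- function(name, rho, k_slope, k_intercept,
                           cp_slope, cp_intercept, D_eff, M0,
                           h_g = 2256267) {
  stopifnot(is.character(name), length(name) == 1L)
  if (rho <= 0) stop("dry-solid density `rho` must be positive")
  if (D_eff <= 0) stop("`D_eff` must be positive")
  if (M0 < 0) stop("`M0` must be non-negative")
  if (k_intercept <= 0 || k_slope * M0 + k_intercept <= 0)
    stop("conductivity law must be positive on [0, M0]")
  if (cp_intercept <= 0 || cp_slope * M0 + cp_intercept <= 0)
    stop("specific-heat law must be positive on [0, M0]")
  out <- list(name = name, rho = rho,
              k_slope = k_slope, k_intercept = k_intercept,
              cp_slope = cp_slope, cp_intercept = cp_intercept,
              D_eff = D_eff, M0 = M0, h_g = h_g)
  class(out) <- "material_model"
  out
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("Material '%s': rho = %g kg/m^3, D_eff = %.4e m^2/s, M0 = %g d.b.\n",
              x$name, x$rho, x$D_eff, x$M0))
  cat(sprintf("  k(M)  = %.5f M + %.5f  W/(m K)\n", x$k_slope, x$k_intercept))
  cat(sprintf("  cp(M) = %.5f M + %.5f  kJ/(kg K)\n", x$cp_slope, x$cp_intercept))
  invisible(x)
}

#' Built-in peanut component materials
#'
#' Returns the default shell, kernel, and homogenised-pod material models.
#' Shell and kernel use the fitted linear conductivity / specific-heat
#' laws and the component effective diffusivities; the pod material uses
#' the whole-pod effective diffusivity with dry-mass-weighted mixtures of
#' the shell and kernel property laws and a volume-weighted mixture
#' density, the weights coming from the component volumes of `geom`.
#'
#' @param geom a [pod_geometry()] used to derive pod mixture weights.
#' @return Named list with elements `shell`, `kernel`, `pod`.
#' @export
peanut_materials <- function(geom = pod_geometry()) {
  shell <- material_model("shell", rho = 560,
                          k_slope = 0.17062, k_intercept = 0.07753,
                          cp_slope = 4.04506, cp_intercept = 2.05226,
                          D_eff = 1.63249e-10, M0 = 1.24)
  kernel <- material_model("kernel", rho = 1000,
                           k_slope = 0.32528, k_intercept = 0.12559,
                           cp_slope = 1.96152, cp_intercept = 1.15307,
                           D_eff = 2.91731e-10, M0 = 0.74)
  Vk <- 4 / 3 * pi * geom$a_kernel^2 * geom$b_kernel
  Vo <- 4 / 3 * pi * geom$a_outer^2 * geom$b_outer
  Vs <- Vo - Vk
  ms <- shell$rho * Vs          # component dry masses
  mk <- kernel$rho * Vk
  ws <- ms / (ms + mk)
  wk <- mk / (ms + mk)
  pod <- material_model("pod", rho = (ms + mk) / Vo,
                        k_slope = ws * shell$k_slope + wk * kernel$k_slope,
                        k_intercept = ws * shell$k_intercept + wk * kernel$k_intercept,
                        cp_slope = ws * shell$cp_slope + wk * kernel$cp_slope,
                        cp_intercept = ws * shell$cp_intercept + wk * kernel$cp_intercept,
                        D_eff = 5.7512e-10, M0 = 0.83)
  list(shell = shell, kernel = kernel, pod = pod)
}

.check_moisture <- function(M) {
  if (any(!is.finite(M))) stop("moisture contains non-finite values")
  if (any(M < 0)) stop("dry-basis moisture must be non-negative")
}

#' Moisture-dependent thermal conductivity
#'
#' Evaluates the linear conductivity law of a material, clamped at the
#' material's initial moisture `M0` (no extrapolation above the wettest
#' physically admissible state).
#'
#' @param material a [material_model()].
#' @param M dry-basis moisture (g/g), vectorised.
#' @return Thermal conductivity in W/(m K).
#' @export
material_conductivity <- function(material, M) {
  .check_moisture(M)
  Mc <- pmin(M, material$M0)
  material$k_slope * Mc + material$k_intercept
}

#' Moisture-dependent specific heat
#'
#' Evaluates the linear specific-heat law of a material (stated in
#' kJ/(kg K)) and returns SI units, J/(kg K).  Clamped at `M0` like
#' [material_conductivity()].
#'
#' @inheritParams material_conductivity
#' @return Specific heat in J/(kg K).
#' @export
material_specific_heat <- function(material, M) {
  .check_moisture(M)
  Mc <- pmin(M, material$M0)
  (material$cp_slope * Mc + material$cp_intercept) * 1000
}

#' Convective heat and mass transfer coefficients
#'
#' Computes film coefficients for a sphere-equivalent particle in a
#' forced air stream from the Nusselt and Sherwood correlations
#' `Nu = 2 + 0.552 Re^0.53 Pr^(1/3)` and
#' `Sh = 2 + 0.552 Re^(1/2) Sc^(1/3)`.  Both correlations floor at 2,
#' the pure-diffusion limit of a sphere in still air.  The Reynolds
#' exponents are kept as stated (0.53 for heat, 1/2 for mass) but are
#' configurable so the two can be harmonised.
#'
#' The air-side mass transfer coefficient `h_m` is on a vapour
#' concentration basis; the solver's surface flux is written in
#' dry-basis moisture, so a dimensionless surface-resistance factor
#' `f_s` rescales it to the moisture-content-basis coefficient
#' `h_m_eff = f_s * h_m` used in the Robin boundary condition.  The
#' packaged default `f_s` is calibrated once against the whole-pod
#' simulated drying rate (see [calibrate_surface()]).
#'
#' @param air an [hot_air_properties()] state.
#' @param d equivalent particle diameter (m).
#' @param f_s surface-resistance scale factor (dimensionless).
#' @param nu_re_exp Reynolds exponent in the Nusselt correlation.
#' @param sh_re_exp Reynolds exponent in the Sherwood correlation.
#' @return An object of class `transfer_coefficients` with `h_T`
#'   (W/(m^2 K)), `h_m` (m/s), `h_m_eff` (m/s), and the dimensionless
#'   groups `Re`, `Pr`, `Nu`, `Sc`, `Sh`, plus `d` and `f_s`.
#' @examples
#' tc <- transfer_coefficients(hot_air_properties(42, 0.75), d = 0.01374)
#' tc$Re   # ~600
#' tc$h_T  # ~32.6 W/(m^2 K)
#' @export
transfer_coefficients <- function(air, d, f_s = 1,
                                  nu_re_exp = 0.53, sh_re_exp = 0.5) {
  stopifnot(inherits(air, "air_state"))
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("equivalent diameter `d` must be a positive number")
  if (f_s <= 0) stop("`f_s` must be positive")
  Re <- air$va * air$rho_a * d / air$mu_a
  Pr <- air$mu_a * air$c_a / air$k_a
  Sc <- air$mu_a / (air$rho_a * air$D_a)
  Nu <- 2 + 0.552 * Re^nu_re_exp * Pr^(1 / 3)
  Sh <- 2 + 0.552 * Re^sh_re_exp * Sc^(1 / 3)
  out <- list(h_T = Nu * air$k_a / d,
              h_m = Sh * air$D_a / d,
              h_m_eff = f_s * Sh * air$D_a / d,
              Re = Re, Pr = Pr, Nu = Nu, Sc = Sc, Sh = Sh,
              d = d, f_s = f_s)
  class(out) <- "transfer_coefficients"
  out
}

#' @export
print.transfer_coefficients <- function(x, ...) {
  cat(sprintf("Transfer coefficients (d = %.4g m, f_s = %.4g):\n", x$d, x$f_s))
  cat(sprintf("  Re = %.1f, Pr = %.4f, Sc = %.4f\n", x$Re, x$Pr, x$Sc))
  cat(sprintf("  Nu = %.3f -> h_T = %.3f W/(m^2 K)\n", x$Nu, x$h_T))
  cat(sprintf("  Sh = %.3f -> h_m = %.4e m/s (h_m_eff = %.4e m/s)\n",
              x$Sh, x$h_m, x$h_m_eff))
  invisible(x)
}

#' Volume-equivalent sphere diameter of the outer pod ellipsoid
#'
#' The transfer-coefficient correlations need an equivalent particle
#' diameter; by default the diameter of the sphere with the same volume
#' as the outer ellipsoid of revolution (semi-axes a, a, b) is used.
#'
#' @param geom a [pod_geometry()].
#' @return Diameter in m (~0.01374 m for the default geometry).
#' @export
equivalent_diameter <- function(geom) {
  2 * (geom$a_outer^2 * geom$b_outer)^(1 / 3)
}
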