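#' Drying curve container
#'
#' A time series of either sample mass or averaged dry-basis moisture.
#'
#' @param t times (s), strictly increasing.
#' @param value masses (g) or dry-basis moistures (g/g), non-negative.
#' @param kind `"moisture"` or `"mass"`.
#' @param m_dry dry-matter mass (g), optional; required to convert a
#'   mass curve to moisture.
#' @return An object of class `drying_curve`.
#' @export
drying_curve <- function(t, value, kind = c("moisture", "mass"),
                         m_dry = NULL) {
  kind <- match.arg(kind)
  if (length(t) != length(value)) stop("`t` and `value` lengths differ")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (any(value < -1e-12)) stop("curve values must be non-negative")
  structure(list(t = as.numeric(t), value = as.numeric(value),
                 kind = kind, m_dry = m_dry),
            class = "drying_curve")
}

#' @export
print.drying_curve <- function(x, ...) {
  cat(sprintf("Drying curve (%s): %d points, t = %g..%g s, value %g..%g\n",
              x$kind, length(x$t), min(x$t), max(x$t),
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.drying_curve <- function(x, ...) {
  data.frame(time_s = x$t, value = x$value, kind = x$kind)
}

#' Convert a mass drying curve to dry-basis moisture
#'
#' `W_t = (m_t - m) / m` with `m` the dry-matter mass.
#'
#' @param curve a mass-kind [drying_curve()].
#' @param m_dry dry-matter mass (g); defaults to the curve's own.
#' @return A moisture-kind [drying_curve()].
#' @export
moisture_from_mass <- function(curve, m_dry = curve$m_dry) {
  stopifnot(inherits(curve, "drying_curve"))
  if (curve$kind != "mass") stop("`curve` must be a mass curve")
  if (is.null(m_dry) || m_dry <= 0)
    stop("`m_dry` must be a positive dry-matter mass (g)")
  if (any(curve$value < m_dry - 1e-9))
    stop("masses fall below the dry-matter mass")
  drying_curve(curve$t, pmax(0, (curve$value - m_dry) / m_dry),
               kind = "moisture", m_dry = m_dry)
}

#' Fickian slab moisture ratio series
#'
#' Moisture ratio of an infinite slab of half-thickness `L` drying from
#' both faces with a surface held at equilibrium:
#' `MR = 8/pi^2 sum_n 1/(2n+1)^2 exp(-(2n+1)^2 pi^2 D t / (4 L^2))`.
#'
#' @param D effective moisture diffusivity (m^2/s).
#' @param L slab half-thickness (m).
#' @param t time (s), vectorised.
#' @param n_terms number of series terms (>= 1).
#' @return Moisture ratio in (0, 1] (up to series truncation at t = 0).
#' @examples
#' slab_MR(2.9e-10, 0.005, 0, n_terms = 1)  # 8/pi^2
#' @export
slab_MR <- function(D, L, t, n_terms = 50) {
  if (D <= 0 || L <= 0) stop("`D` and `L` must be positive")
  if (any(t < 0)) stop("`t` must be non-negative")
  if (n_terms < 1) stop("`n_terms` must be at least 1")
  n <- 0:(n_terms - 1)
  odd <- 2 * n + 1
  out <- vapply(t, function(ti)
    8 / pi^2 * sum(exp(-odd^2 * pi^2 * D * ti / (4 * L^2)) / odd^2),
    numeric(1))
  pmin(out, 1)
}

#' Estimate effective moisture diffusivity by the log-slope method
#'
#' Fits a least-squares line to `ln MR` versus time and converts its
#' slope to a diffusivity through the one-term slab solution:
#' `ln MR = ln(8/pi^2) - D pi^2 t / (4 L^2)`, so
#' `D = -slope * 4 L^2 / pi^2`.  The one-term form only holds once the
#' higher series modes have decayed, so points with `MR` above
#' `mr_max` (default 0.6) are excluded from the fit; non-positive `MR`
#' points are dropped with a warning.
#'
#' @param curve a moisture-kind [drying_curve()].
#' @param L slab half-thickness (m).
#' @param M_e equilibrium dry-basis moisture (g/g).
#' @param M0 initial moisture; defaults to the first curve value.
#' @param fit_window list with `mr_max` (and optionally `mr_min`)
#'   bounding the moisture-ratio range used in the fit.
#' @return An object of class `deff_estimate` with fields `D_eff`
#'   (m^2/s), `slope` (1/s), `intercept`, `r_squared`, `L`, `n_points`.
#' @examples
#' cv <- synthesize_curve(1.6e-10, 0.005, 1.24, 0.02,
#'                        times = seq(0, 7e4, by = 600))
#' estimate_deff(cv, L = 0.005, M_e = 0.02)
#' @export
estimate_deff <- function(curve, L, M_e, M0 = curve$value[1],
                          fit_window = list(mr_max = 0.6, mr_min = 1e-8)) {
  stopifnot(inherits(curve, "drying_curve"))
  if (curve$kind != "moisture")
    stop("`curve` must be a moisture curve (see moisture_from_mass())")
  if (L <= 0) stop("`L` must be positive")
  if (M0 <= M_e) stop("`M0` must exceed `M_e`")
  mr <- (curve$value - M_e) / (M0 - M_e)
  if (any(mr <= 0))
    warning("dropping ", sum(mr <= 0), " points with non-positive MR")
  mr_max <- if (!is.null(fit_window$mr_max)) fit_window$mr_max else 0.6
  mr_min <- if (!is.null(fit_window$mr_min)) fit_window$mr_min else 1e-8
  keep <- is.finite(mr) & mr > mr_min & mr <= mr_max
  if (sum(keep) < 3)
    stop("estimation error: fewer than 3 usable points with MR in (",
         mr_min, ", ", mr_max, "]")
  fit <- stats::lm(log(mr[keep]) ~ curve$t[keep])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= -1e-300 ||
      abs(slope) * diff(range(curve$t[keep])) < 1e-8)
    stop("estimation error: curve shows no drying (slope ~ 0), ",
         "diffusivity undefined")
  out <- list(D_eff = -slope * 4 * L^2 / pi^2,
              slope = slope,
              intercept = unname(stats::coef(fit)[1]),
              r_squared = summary(fit)$r.squared,
              L = L, n_points = sum(keep),
              t = curve$t[keep], ln_mr = log(mr[keep]))
  class(out) <- "deff_estimate"
  out
}

#' @export
print.deff_estimate <- function(x, ...) {
  cat(sprintf("Effective diffusivity estimate: D_eff = %.5e m^2/s\n", x$D_eff))
  cat(sprintf("  ln MR slope = %.4e 1/s, intercept = %.4f, R^2 = %.5f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  L = %g m, %d points in fit window\n", x$L, x$n_points))
  invisible(x)
}

#' @export
coef.deff_estimate <- function(object, ...) {
  c(D_eff = object$D_eff, slope = object$slope,
    intercept = object$intercept)
}

#' @export
plot.deff_estimate <- function(x, ...) {
  plot(x$t / 3600, x$ln_mr, xlab = "time (h)", ylab = "ln MR", ...)
  graphics::abline(x$intercept, x$slope * 3600, col = 2)
  invisible(x)
}

#' Synthesize a slab-solution drying curve
#'
#' Generates a moisture drying curve from the slab series
#' ([slab_MR()]), optionally with multiplicative Gaussian noise, for
#' estimator testing.  The only stochastic element in the package.
#'
#' @param D diffusivity (m^2/s).
#' @param L slab half-thickness (m).
#' @param M0 initial moisture (g/g d.b.).
#' @param M_e equilibrium moisture (g/g d.b.).
#' @param times sample times (s).
#' @param noise_sd multiplicative noise standard deviation (fraction).
#' @param seed optional RNG seed for reproducibility.
#' @param n_terms series terms.
#' @return A moisture-kind [drying_curve()].
#' @export
synthesize_curve <- function(D, L, M0, M_e, times, noise_sd = 0,
                             seed = NULL, n_terms = 50) {
  if (M0 <= M_e) stop("`M0` must exceed `M_e`")
  mr <- slab_MR(D, L, times, n_terms)
  M <- M_e + (M0 - M_e) * mr
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    M <- M * (1 + stats::rnorm(length(M), sd = noise_sd))
  }
  drying_curve(times, pmax(M, 0), kind = "moisture")
}
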