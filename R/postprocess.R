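#' Axisymmetric volume-weighted component average
#'
#' Averages a nodal field over one mesh region with the solid-of-
#' revolution weight `2 pi r`: `mean = int r f dA / int r dA`.  For
#' `region = "pod"` on a two-component mesh, the whole-pod dry-basis
#' moisture is the dry-mass-weighted combination of the shell and
#' kernel means (dry mass = density x component volume), which is the
#' average a whole-pod weighing experiment measures.
#'
#' @param state a [field_state()] (or any list with `M`/`T` nodal
#'   vectors of the right length).
#' @param mesh an `aximesh`.
#' @param region region label present in the mesh, or `"pod"` for the
#'   dry-mass-weighted whole-pod moisture average.
#' @param field `"M"` (default) or `"T"`.
#' @param materials named list of [material_model()]s; needed only for
#'   the dry-mass weighting of `region = "pod"` on a composite mesh.
#' @return The averaged value (g/g d.b. for `M`, K for `T`).
#' @export
component_average <- function(state, mesh, region, field = c("M", "T"),
                              materials = peanut_materials()) {
  field <- match.arg(field)
  x <- state[[field]]
  if (length(x) != nrow(mesh$nodes))
    stop("field length does not match the mesh")
  fp <- .fem_precompute(mesh)
  regs <- unique(mesh$region)
  if (region %in% regs) {
    w <- .region_node_weights(fp, region)
  } else if (region == "pod") {
    w <- Reduce(`+`, lapply(regs, function(rg) {
      m <- materials[[rg]]
      if (is.null(m)) stop("no material for region '", rg, "'")
      m$rho * .region_node_weights(fp, rg)
    }))
  } else {
    stop("unknown region '", region, "'; mesh has: ",
         paste(regs, collapse = ", "), " (or use 'pod')")
  }
  sum(w * x) / sum(w)
}

#' Extract a component-averaged drying curve from a simulation
#'
#' @param sim a `drying_sim` from [run_simulation()].
#' @param region a region of the simulation mesh or `"pod"`.
#' @return A moisture-kind [drying_curve()].
#' @export
component_curve <- function(sim, region = "pod") {
  stopifnot(inherits(sim, "drying_sim"))
  col <- paste0("M_", region, "_db")
  if (!col %in% names(sim$curves))
    stop("no averaged curve for region '", region, "'")
  drying_curve(sim$curves$time_s, pmax(sim$curves[[col]], 0),
               kind = "moisture")
}

.curve_at <- function(curve, t) {
  if (t < min(curve$t) || t > max(curve$t))
    stop("time ", t, " s is outside the curve support [",
         min(curve$t), ", ", max(curve$t), "]")
  stats::approx(curve$t, curve$value, xout = t)$y
}

#' Average moisture-reduction rate over an interval
#'
#' Dry-basis percentage points removed per hour:
#' `(M(t_start) - M(t_end)) * 100 / hours`.
#'
#' @param curve a moisture-kind [drying_curve()].
#' @param t_start,t_end interval bounds (s); endpoints are linearly
#'   interpolated.  Defaults to the full curve span.
#' @return Rate in %/h (dry-basis percentage points per hour).
#' @examples
#' cv <- drying_curve(c(0, 73800), c(0.83, 0.10))
#' drying_rate(cv)  # ~3.56 %/h
#' @export
drying_rate <- function(curve, t_start = min(curve$t),
                        t_end = max(curve$t)) {
  stopifnot(inherits(curve, "drying_curve"))
  if (curve$kind != "moisture") stop("`curve` must be a moisture curve")
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`")
  (.curve_at(curve, t_start) - .curve_at(curve, t_end)) * 100 /
    ((t_end - t_start) / 3600)
}

#' Maximum relative error between two drying curves
#'
#' Interpolates `sim` onto the reference times inside the common time
#' support and returns `max |sim - ref| / ref * 100`.
#'
#' @param sim,ref moisture-kind [drying_curve()]s.
#' @return Maximum relative error in percent.
#' @export
max_relative_error <- function(sim, ref) {
  stopifnot(inherits(sim, "drying_curve"), inherits(ref, "drying_curve"))
  lo <- max(min(sim$t), min(ref$t))
  hi <- min(max(sim$t), max(ref$t))
  if (hi <= lo) stop("curves have no overlapping time support")
  keep <- ref$t >= lo & ref$t <= hi
  if (any(ref$value[keep] <= 0))
    stop("reference curve must be positive where compared")
  si <- stats::approx(sim$t, sim$value, xout = ref$t[keep])$y
  max(abs(si - ref$value[keep]) / ref$value[keep]) * 100
}

#' First time a drying curve crosses a moisture threshold
#'
#' Linear-interpolated first down-crossing of `threshold`; `NA` when the
#' curve never reaches it.
#'
#' @param curve a moisture-kind [drying_curve()].
#' @param threshold dry-basis moisture threshold (default 0.10, the safe
#'   storage moisture).
#' @return Crossing time (s), 0 if the curve starts at or below the
#'   threshold, or `NA_real_` if never reached.
#' @export
threshold_time <- function(curve, threshold = 0.10) {
  stopifnot(inherits(curve, "drying_curve"))
  v <- curve$value; t <- curve$t
  if (v[1] <= threshold) return(0)
  below <- which(v <= threshold)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  t[i - 1] + (v[i - 1] - threshold) / (v[i - 1] - v[i]) * (t[i] - t[i - 1])
}
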