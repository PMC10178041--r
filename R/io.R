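#' Read a drying curve from CSV
#'
#' Expects columns `time_s`, `value` and optionally `kind` (constant
#' `"moisture"` or `"mass"`) and `m_dry`.
#'
#' @param path CSV file.
#' @return A [drying_curve()].
#' @export
read_drying_curve <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("drying-curve CSV needs columns `time_s` and `value`")
  kind <- if ("kind" %in% names(d)) as.character(d$kind[1]) else "moisture"
  m_dry <- if ("m_dry" %in% names(d)) d$m_dry[1] else NULL
  drying_curve(d$time_s, d$value, kind = kind, m_dry = m_dry)
}

#' Write a drying curve to CSV
#'
#' @param curve a [drying_curve()].
#' @param path output CSV file.
#' @export
write_drying_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write simulation drying curves to CSV
#'
#' Writes the per-step component-averaged curves (time, dry-basis
#' moistures, mean/surface/center temperatures).
#'
#' @param sim a `drying_sim`.
#' @param path output CSV file.
#' @export
write_curves_csv <- function(sim, path) {
  stopifnot(inherits(sim, "drying_sim"))
  utils::write.csv(sim$curves, path, row.names = FALSE)
  invisible(path)
}

#' Write a mesh with nodal fields as an ASCII VTU file
#'
#' Minimal VTK XML UnstructuredGrid writer (triangle cells, point-data
#' scalars), readable by ParaView and meshio.
#'
#' @param mesh an `aximesh`.
#' @param path output `.vtu` file.
#' @param point_data named list of nodal vectors to attach.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 9, scientific = TRUE),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(rbind(mesh$nodes[, 1], mesh$nodes[, 2], 0))))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(mesh$elements)) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(m) * 3L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(5L, m), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
      w(num(point_data[[nm]]))
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('<CellData>')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  w(paste(as.integer(factor(mesh$region)), collapse = " "))
  w('</DataArray>')
  w('</CellData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write the field snapshots of a simulation as a VTU time series
#'
#' @param sim a `drying_sim`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_snapshots_vtu <- function(sim, dir, prefix = "fields") {
  stopifnot(inherits(sim, "drying_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (st in sim$snapshots) {
    p <- file.path(dir, sprintf("%s_t%07.0fs.vtu", prefix, st$t))
    write_vtu(sim$mesh, p, point_data = list(M_db = st$M,
                                             T_K = st$T))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write run metadata and resolved configuration as JSON
#'
#' @param sim a `drying_sim`.
#' @param path output JSON file.
#' @param config the resolved configuration used (with its `overrides`
#'   attribute), if the run came from one.
#' @export
write_run_metadata <- function(sim, path, config = NULL) {
  stopifnot(inherits(sim, "drying_sim"))
  cv <- sim$curves
  n <- nrow(cv)
  meta <- list(
    mode = sim$geom$mode,
    n_nodes = nrow(sim$mesh$nodes),
    n_elements = nrow(sim$mesh$elements),
    dt_s = sim$control$dt,
    t_end_s = sim$control$t_end,
    transfer_coefficients = sim$tc[c("Re", "Pr", "Nu", "Sc", "Sh",
                                     "h_T", "h_m", "h_m_eff", "d", "f_s")],
    pod_rate_pct_per_h = drying_rate(component_curve(sim, "pod")),
    final_M_pod_db = cv$M_pod_db[n],
    max_mass_imbalance = sim$max_mass_imbalance
  )
  if (!is.null(config)) {
    meta$resolved_config <- config
    meta$config_overrides <- as.list(attr(config, "overrides"))
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
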