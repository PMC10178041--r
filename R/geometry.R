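#' Two-component pod geometry
#'
#' Describes the axisymmetric half-section of a peanut pod: a kernel
#' ellipse (equatorial semi-axis `a_kernel`, polar semi-axis `b_kernel`)
#' nested in a shell ring of uniform thickness `t_shell`.  The outer
#' surface is the ellipse with semi-axes `a_kernel + t_shell` and
#' `b_kernel + t_shell`.  The shell-kernel gap is neglected: the two
#' regions are in perfect contact.
#'
#' @param a_kernel kernel equatorial semi-axis (m).
#' @param b_kernel kernel polar semi-axis (m).
#' @param t_shell shell thickness (m).
#' @param mode one of `"two_component"`, `"shell_only"`, `"kernel_only"`,
#'   `"pod_homogeneous"`.  Single-component modes use the same dimensions
#'   as the corresponding region of the composite; `pod_homogeneous`
#'   treats the full outer ellipse as one homogenised material.
#' @return An object of class `pod_geometry`.
#' @examples
#' g <- pod_geometry()
#' c(g$a_outer, g$b_outer)  # 0.006 0.009
#' @export
pod_geometry <- function(a_kernel = 0.005, b_kernel = 0.008,
                         t_shell = 0.001,
                         mode = c("two_component", "shell_only",
                                  "kernel_only", "pod_homogeneous")) {
  mode <- match.arg(mode)
  dims <- c(a_kernel = a_kernel, b_kernel = b_kernel, t_shell = t_shell)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all geometry dimensions must be positive and finite (got ",
         paste(names(dims)[!is.finite(dims) | dims <= 0], collapse = ", "),
         " non-positive)")
  out <- list(a_kernel = a_kernel, b_kernel = b_kernel, t_shell = t_shell,
              a_outer = a_kernel + t_shell, b_outer = b_kernel + t_shell,
              mode = mode)
  class(out) <- "pod_geometry"
  out
}

#' @export
print.pod_geometry <- function(x, ...) {
  cat(sprintf("Pod geometry (%s): kernel %g x %g mm, shell %g mm, outer %g x %g mm\n",
              x$mode, x$a_kernel * 1e3, x$b_kernel * 1e3, x$t_shell * 1e3,
              x$a_outer * 1e3, x$b_outer * 1e3))
  invisible(x)
}

#' Build a pod geometry from a configuration block
#'
#' @param config a full run configuration (see [default_config()]) or
#'   just its `geometry` block.
#' @return A [pod_geometry()].
#' @export
build_geometry <- function(config = default_config()) {
  g <- if (!is.null(config$geometry)) config$geometry else config
  pod_geometry(a_kernel = g$a_kernel, b_kernel = g$b_kernel,
               t_shell = g$t_shell, mode = g$mode)
}

# Ramanujan approximation to the ellipse perimeter
.ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Generate the axisymmetric triangular mesh
#'
#' Discretises the half-section of the pod with a structured
#' elliptical-polar triangulation: a fan of concentric scaled ellipses
#' for the kernel and a ring of blended ellipse layers for the shell,
#' conforming (shared nodes) at the shell-kernel interface.  Node
#' coordinates are `(r, z)` with the symmetry axis at `r = 0`; the mesh
#' spans the full polar angle from the south to the north pole, so its
#' only boundaries are the axis and the outer ellipse arc.
#'
#' @param geom a [pod_geometry()].
#' @param target_h target element size (m); must not exceed the shell
#'   thickness so the shell is resolved by at least two element layers.
#' @return An object of class `aximesh` with fields `nodes` (n x 2
#'   matrix of r, z in m), `elements` (m x 3 node-index triples,
#'   counter-clockwise), `region` (per-element label), `boundary`
#'   (outer-surface edge list, 2-column), `axis` (r = 0 edge list),
#'   `inner` (inner-surface edges; only for `shell_only`), `geom`,
#'   `target_h`.
#' @examples
#' mesh <- generate_mesh(pod_geometry(), target_h = 5e-4)
#' region_area(mesh, "kernel") * 1e6  # ~62.83 mm^2
#' @export
generate_mesh <- function(geom, target_h = 5e-4) {
  stopifnot(inherits(geom, "pod_geometry"))
  if (!is.numeric(target_h) || target_h <= 0)
    stop("`target_h` must be positive")
  has_shell <- geom$mode != "kernel_only"
  if (has_shell && target_h > geom$t_shell)
    stop("mesh error: `target_h` = ", target_h,
         " is too coarse to resolve the shell thickness ", geom$t_shell,
         " with >= 2 element layers")

  a_out <- if (geom$mode == "kernel_only") geom$a_kernel else geom$a_outer
  b_out <- if (geom$mode == "kernel_only") geom$b_kernel else geom$b_outer
  arc <- .ellipse_perimeter(a_out, b_out) / 2
  n_theta <- max(16L, as.integer(ceiling(arc / target_h)))
  theta <- seq(-pi / 2, pi / 2, length.out = n_theta + 1L)
  ct <- cos(theta); st <- sin(theta)
  # snap the poles exactly onto the axis
  ct[c(1L, n_theta + 1L)] <- 0
  st[1L] <- -1; st[n_theta + 1L] <- 1

  nodes <- matrix(numeric(0), ncol = 2)
  elems <- matrix(integer(0), ncol = 3)
  region <- character(0)
  iface_ring <- NULL   # node indices of the shell-kernel interface ring

  ring_ids <- function(first, j) first + (j - 1L) * (n_theta + 1L) +
    seq_len(n_theta + 1L) - 1L
  quad_tris <- function(inner, outer) {
    # inner/outer: node ids along two consecutive rings (length n_theta+1)
    i1 <- inner[-(n_theta + 1L)]; i2 <- inner[-1L]
    o1 <- outer[-(n_theta + 1L)]; o2 <- outer[-1L]
    rbind(cbind(i1, o1, o2), cbind(i1, o2, i2))
  }

  if (geom$mode != "shell_only") {
    # kernel fan: center node + n_s concentric scaled ellipses
    n_s <- max(2L, as.integer(ceiling(max(geom$a_kernel, geom$b_kernel) /
                                        target_h)))
    s <- seq_len(n_s) / n_s
    rr <- outer(s * geom$a_kernel, ct)      # n_s x (n_theta+1)
    zz <- outer(s * geom$b_kernel, st)
    nodes <- rbind(c(0, 0),
                   cbind(as.vector(t(rr)), as.vector(t(zz))))
    ring1 <- ring_ids(2L, 1L)
    fan <- cbind(1L, ring1[-(n_theta + 1L)], ring1[-1L])
    elems <- fan
    for (j in seq_len(n_s - 1L))
      elems <- rbind(elems, quad_tris(ring_ids(2L, j), ring_ids(2L, j + 1L)))
    region <- rep(if (geom$mode == "pod_homogeneous") "pod" else "kernel",
                  nrow(elems))
    iface_ring <- ring_ids(2L, n_s)
  }

  inner_edges <- NULL
  if (has_shell) {
    n_u <- max(2L, as.integer(ceiling(geom$t_shell / target_h)))
    u <- seq_len(n_u) / n_u
    inner_r <- geom$a_kernel * ct; inner_z <- geom$b_kernel * st
    outer_r <- geom$a_outer * ct;  outer_z <- geom$b_outer * st
    if (geom$mode == "shell_only") {
      # own inner ring (insulated inner surface)
      first <- nrow(nodes) + 1L
      nodes <- rbind(nodes, cbind(inner_r, inner_z))
      prev <- first + seq_len(n_theta + 1L) - 1L
      inner_edges <- cbind(prev[-(n_theta + 1L)], prev[-1L])
    } else {
      prev <- iface_ring
    }
    shell_label <- if (geom$mode == "pod_homogeneous") "pod" else "shell"
    for (l in seq_len(n_u)) {
      first <- nrow(nodes) + 1L
      nodes <- rbind(nodes,
                     cbind((1 - u[l]) * inner_r + u[l] * outer_r,
                           (1 - u[l]) * inner_z + u[l] * outer_z))
      cur <- first + seq_len(n_theta + 1L) - 1L
      elems <- rbind(elems, quad_tris(prev, cur))
      region <- c(region, rep(shell_label, 2L * n_theta))
      prev <- cur
    }
    outer_ring <- prev
  } else {
    outer_ring <- iface_ring
  }

  boundary <- cbind(outer_ring[-(n_theta + 1L)], outer_ring[-1L])
  # axis edges: radial chains at theta = -pi/2 and +pi/2 (r = 0 columns)
  on_axis <- which(abs(nodes[, 1]) < 1e-15)
  ord <- on_axis[order(nodes[on_axis, 2])]
  neg <- ord[nodes[ord, 2] < 0]; pos <- ord[nodes[ord, 2] >= 0]
  axis_edges <- rbind(
    if (length(neg) > 1L) cbind(neg[-length(neg)], neg[-1L]),
    if (length(pos) > 1L) cbind(pos[-length(pos)], pos[-1L])
  )

  mesh <- list(nodes = nodes, elements = elems, region = region,
               boundary = boundary, axis = axis_edges, inner = inner_edges,
               geom = geom, target_h = target_h)
  class(mesh) <- "aximesh"
  a <- element_areas(mesh)
  if (any(a <= 0))
    stop("internal mesh error: ", sum(a <= 0), " inverted elements")
  if (any(nodes[, 1] < -1e-12))
    stop("internal mesh error: negative radial coordinates")
  mesh
}

#' @export
print.aximesh <- function(x, ...) {
  cat(sprintf("Axisymmetric mesh (%s): %d nodes, %d triangles\n",
              x$geom$mode, nrow(x$nodes), nrow(x$elements)))
  for (reg in unique(x$region))
    cat(sprintf("  %-7s %4d elements, area %.3f mm^2, volume %.2f mm^3\n",
                reg, sum(x$region == reg), region_area(x, reg) * 1e6,
                region_volume(x, reg) * 1e9))
  invisible(x)
}

#' Signed triangle areas of a mesh
#'
#' @param mesh an `aximesh`.
#' @return Numeric vector of element areas (m^2); positive for the
#'   counter-clockwise orientation the generator guarantees.
#' @export
element_areas <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elements
  r1 <- n[e[, 1], 1]; z1 <- n[e[, 1], 2]
  r2 <- n[e[, 2], 1]; z2 <- n[e[, 2], 2]
  r3 <- n[e[, 3], 1]; z3 <- n[e[, 3], 2]
  0.5 * ((r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1))
}

.region_elems <- function(mesh, region) {
  sel <- mesh$region == region
  if (!any(sel))
    stop("unknown region '", region, "'; mesh has: ",
         paste(unique(mesh$region), collapse = ", "))
  sel
}

#' Half-section area of a mesh region
#'
#' @param mesh an `aximesh`.
#' @param region region label (`"shell"`, `"kernel"`, or `"pod"`).
#' @return Area of the region in the (r, z) half-section (m^2).
#' @export
region_area <- function(mesh, region) {
  sum(element_areas(mesh)[.region_elems(mesh, region)])
}

#' Solid-of-revolution volume of a mesh region
#'
#' Integrates `2 pi r` over the region's elements, i.e. the volume of
#' the 3D body obtained by revolving the half-section about the axis.
#'
#' @inheritParams region_area
#' @return Volume (m^3).
#' @export
region_volume <- function(mesh, region) {
  sel <- .region_elems(mesh, region)
  a <- element_areas(mesh)[sel]
  e <- mesh$elements[sel, , drop = FALSE]
  rbar <- (mesh$nodes[e[, 1], 1] + mesh$nodes[e[, 2], 1] +
             mesh$nodes[e[, 3], 1]) / 3
  sum(2 * pi * rbar * a)
}

#' @export
plot.aximesh <- function(x, col = c(kernel = "peachpuff", shell = "tan3",
                                    pod = "khaki"), border = "grey40", ...) {
  n <- x$nodes * 1e3
  plot(NA, xlim = range(n[, 1]), ylim = range(n[, 2]), asp = 1,
       xlab = "r (mm)", ylab = "z (mm)", ...)
  for (reg in unique(x$region)) {
    e <- x$elements[x$region == reg, , drop = FALSE]
    graphics::polygon(
      as.vector(t(cbind(n[e[, 1], 1], n[e[, 2], 1], n[e[, 3], 1], NA))),
      as.vector(t(cbind(n[e[, 1], 2], n[e[, 2], 2], n[e[, 3], 2], NA))),
      col = col[[reg]], border = border)
  }
  invisible(x)
}
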