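#' Unwrapped cylindrical diode-array dose map
#'
#' Emulates the sampling topology of a cylindrical diode array (ArcCHECK
#' style): dose samples on the surface of a cylinder, unwrapped to a 2-D
#' matrix with rows running along the cylinder axis (z) and columns around
#' the azimuth.  Column 1 sits at azimuth 0 (the +x direction) and the
#' azimuthal coordinate wraps: column `ncol` is adjacent to column 1.  The
#' in-plane pitch along a row is the arc length `2*pi*R/ncol`.
#'
#' This is a regular lattice, not the vendor's helical diode layout; it
#' preserves the cyclic topology the comparison metrics need.
#'
#' @param values numeric matrix of dose samples (Gy), rows = axial position,
#'   columns = azimuth.
#' @param diode_spacing axial pitch between rows (mm).
#' @param cylinder_radius cylinder radius (mm).
#' @param z0 z position of the first row (mm).
#' @param axis_xy (x, y) of the cylinder axis (mm).
#' @return object of class `detector_map`.
#' @export
detector_map <- function(values, diode_spacing, cylinder_radius,
                         z0 = 0, axis_xy = c(0, 0)) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("detector values must be finite and >= 0")
  if (diode_spacing <= 0 || cylinder_radius <= 0)
    stop("diode_spacing and cylinder_radius must be > 0")
  structure(list(
    values = values,
    diode_spacing = as.numeric(diode_spacing),
    cylinder_radius = as.numeric(cylinder_radius),
    z0 = as.numeric(z0), axis_xy = as.numeric(axis_xy),
    arc_spacing = 2 * pi * cylinder_radius / ncol(values)
  ), class = "detector_map")
}

#' @export
print.detector_map <- function(x, ...) {
  cat(sprintf(
    "<detector_map %dx%d  R=%.0f mm  axial %.1f mm  arc %.2f mm  max %.3f Gy>\n",
    nrow(x$values), ncol(x$values), x$cylinder_radius, x$diode_spacing,
    x$arc_spacing, max(x$values)))
  invisible(x)
}

same_layout <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$diode_spacing, b$diode_spacing)) &&
    isTRUE(all.equal(a$cylinder_radius, b$cylinder_radius)) &&
    isTRUE(all.equal(a$z0, b$z0))
}

#' Default detector geometry
#'
#' @param cylinder_radius cylinder radius, mm.
#' @param diode_spacing axial (and nominal azimuthal) sample pitch, mm.
#' @param n_axial number of rows; `NULL` = fit to the grid at sampling time.
#' @export
detector_spec <- function(cylinder_radius = 105, diode_spacing = 10,
                          n_axial = NULL) {
  list(cylinder_radius = cylinder_radius, diode_spacing = diode_spacing,
       n_axial = n_axial)
}

#' Sample a 3-D dose grid on a cylinder surface
#'
#' Trilinear samples of `grid` on a regular axial x azimuthal lattice on the
#' surface of a cylinder centered on the grid's (x, y) midpoint, unwrapped
#' into a [detector_map()].  Azimuth for column j is
#' `theta_j = (j-1) * 2*pi/n_col`, measured from +x towards +y, so the sample
#' position is `(x0 + R*cos(theta), y0 + R*sin(theta), z)`.  The number of
#' columns is `round(2*pi*R/diode_spacing)`.
#'
#' @param grid a [dose_grid()].
#' @param spec a [detector_spec()].
#' @return a [detector_map()].
#' @export
sample_cylinder <- function(grid, spec = detector_spec()) {
  stopifnot(inherits(grid, "dose_grid"))
  lat <- cylinder_lattice(grid, spec)
  v <- trilinear_interp(grid$values, grid$origin, grid$spacing, lat$pts)
  if (any(is.na(v))) stop("cylinder sample fell outside the grid")
  detector_map(matrix(pmax(v, 0), nrow = lat$n_axial, ncol = lat$ncols),
               diode_spacing = spec$diode_spacing,
               cylinder_radius = spec$cylinder_radius,
               z0 = lat$z0, axis_xy = lat$axis_xy)
}

# The physical sample positions of the detector lattice on a grid: column j
# at azimuth (j-1)*2*pi/ncols from +x, rows spaced by diode_spacing along z,
# centered in the grid's axial extent.
cylinder_lattice <- function(grid, spec) {
  ax <- grid_axes(grid)
  x0 <- mean(range(ax[[1]])); y0 <- mean(range(ax[[2]]))
  R <- spec$cylinder_radius
  if (x0 - R < min(ax[[1]]) - 1e-9 || x0 + R > max(ax[[1]]) + 1e-9 ||
      y0 - R < min(ax[[2]]) - 1e-9 || y0 + R > max(ax[[2]]) + 1e-9)
    stop("cylinder does not fit inside the grid extent")
  ncols <- max(4L, as.integer(round(2 * pi * R / spec$diode_spacing)))
  zmin <- min(ax[[3]]); zmax <- max(ax[[3]])
  n_axial <- spec$n_axial
  if (is.null(n_axial))
    n_axial <- max(2L, as.integer(floor((zmax - zmin) / spec$diode_spacing)) + 1L)
  zspan <- (n_axial - 1) * spec$diode_spacing
  if (zspan > zmax - zmin + 1e-9)
    stop("cylinder axial extent exceeds the grid")
  z0 <- zmin + (zmax - zmin - zspan) / 2
  theta <- (seq_len(ncols) - 1) * 2 * pi / ncols
  zz <- z0 + (seq_len(n_axial) - 1) * spec$diode_spacing
  pts <- cbind(x = rep(x0 + R * cos(theta), each = n_axial),
               y = rep(y0 + R * sin(theta), each = n_axial),
               z = rep(zz, times = ncols))
  list(pts = pts, n_axial = n_axial, ncols = ncols, z0 = z0,
       axis_xy = c(x0, y0))
}
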