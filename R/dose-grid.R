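#' Axis-aligned 3-D dose grid
#'
#' A `dose_grid` holds a 3-D scalar dose field in Gy on a regular,
#' axis-aligned lattice in physical patient coordinates (mm).  Following the
#' DICOM convention, `origin` is the physical position of the *center* of the
#' first voxel (index `[1,1,1]`) and `spacing` is the per-axis voxel pitch.
#' Two grids share a geometry frame iff they have identical origin, spacing
#' and shape; `frame_id` is a deterministic digest of those three.
#'
#' Voxels may carry an optional validity flag (used by [resample_dose()] to
#' mark points that fell outside the source extent); invalid voxels hold `NA`
#' dose and are excluded from downstream statistics.
#'
#' @param values 3-D numeric array of doses (Gy); finite and non-negative at
#'   every valid voxel.
#' @param origin numeric length 3, position of the first voxel center (mm).
#' @param spacing numeric length 3, voxel pitch (mm); strictly positive.
#' @param valid optional 3-D logical array of the same shape; `NULL` means all
#'   voxels valid.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                      valid = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("`origin` and `spacing` must have length 3")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be > 0")
  if (!is.null(valid)) {
    if (!identical(dim(valid), dim(values)))
      stop("`valid` must have the same shape as `values`")
    valid <- array(as.logical(valid), dim = dim(values))
  }
  v <- as.numeric(values)
  chk <- if (is.null(valid)) v else v[valid]
  if (any(!is.finite(chk)))
    stop("dose values must be finite at all valid voxels")
  if (any(chk < 0))
    stop("dose values must be >= 0")
  g <- structure(list(
    values  = array(v, dim = dim(values)),
    origin  = origin,
    spacing = spacing,
    valid   = valid,
    frame_id = geometry_frame_id(origin, spacing, dim(values))
  ), class = "dose_grid")
  g
}

#' CT-like scalar volume in Hounsfield units
#'
#' Same lattice conventions as [dose_grid()]; values are HU (water = 0,
#' air = -1000) and must be finite but may be negative.
#'
#' @inheritParams dose_grid
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("all spacings must be > 0")
  if (any(!is.finite(values))) stop("HU values must be finite")
  structure(list(
    values = values, origin = origin, spacing = spacing,
    frame_id = geometry_frame_id(origin, spacing, dim(values))
  ), class = "ct_volume")
}

# Deterministic digest of a grid geometry (origin, spacing, shape).
# FNV-1a 32-bit over the formatted geometry string; stable across platforms.
geometry_frame_id <- function(origin, spacing, shape) {
  s <- paste(c(sprintf("%.9g", c(origin, spacing)), as.integer(shape)),
             collapse = "|")
  fnv1a32(s)
}

fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    # xor on doubles: split into 16-bit halves to stay in integer range
    h <- bitwXor(h %/% 65536, b %/% 65536) * 65536 +
         bitwXor(h %% 65536, b %% 65536)
    # 32-bit modular multiply by the FNV prime, without double overflow
    h <- (((h %/% 65536) * p) %% 65536 * 65536 + (h %% 65536) * p) %% 4294967296
  }
  sprintf("frame-%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid %s  shape %s  spacing %s mm  max %.3f Gy>\n",
              x$frame_id, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s  shape %s  HU range [%g, %g]>\n", x$frame_id,
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel-center coordinates of a grid axis
#'
#' @param g a `dose_grid`, `ct_volume` or `voxel_mask`.
#' @return list of three numeric vectors (x, y, z voxel-center positions, mm).
#' @export
grid_axes <- function(g) {
  shp <- grid_shape(g)
  lapply(1:3, function(a) g$origin[a] + (seq_len(shp[a]) - 1) * g$spacing[a])
}

grid_shape <- function(g) {
  d <- if (!is.null(g$values)) dim(g$values) else dim(g$flags)
  d
}

#' Physical volume of one voxel in mm^3
#' @param g grid-like object with a `spacing` field.
#' @export
voxel_volume_mm3 <- function(g) prod(g$spacing)

same_frame <- function(a, b) identical(a$frame_id, b$frame_id)

# Vectorized trilinear interpolation of `values` (3-D array with geometry
# origin/spacing) at an n x 3 matrix of physical points.  Points outside the
# voxel-center hull return NA.
trilinear_interp <- function(values, origin, spacing, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- dim(values)
  # fractional voxel index (0-based)
  fx <- (pts[, 1] - origin[1]) / spacing[1]
  fy <- (pts[, 2] - origin[2]) / spacing[2]
  fz <- (pts[, 3] - origin[3]) / spacing[3]
  eps <- 1e-9
  inside <- fx >= -eps & fx <= d[1] - 1 + eps &
            fy >= -eps & fy <= d[2] - 1 + eps &
            fz >= -eps & fz <= d[3] - 1 + eps
  out <- rep(NA_real_, nrow(pts))
  if (!any(inside)) return(out)
  fx <- pmin(pmax(fx[inside], 0), d[1] - 1)
  fy <- pmin(pmax(fy[inside], 0), d[2] - 1)
  fz <- pmin(pmax(fz[inside], 0), d[3] - 1)
  i0 <- pmin(floor(fx), d[1] - 1 - (d[1] > 1)); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), d[2] - 1 - (d[2] > 1)); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(fz), d[3] - 1 - (d[3] > 1)); k0 <- pmax(k0, 0)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  i1 <- pmin(i0 + 1, d[1] - 1)
  j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  at <- function(i, j, k) values[1L + i + d[1] * (j + d[2] * k)]
  v <- at(i0, j0, k0) * (1 - tx) * (1 - ty) * (1 - tz) +
       at(i1, j0, k0) *      tx  * (1 - ty) * (1 - tz) +
       at(i0, j1, k0) * (1 - tx) *      ty  * (1 - tz) +
       at(i1, j1, k0) *      tx  *      ty  * (1 - tz) +
       at(i0, j0, k1) * (1 - tx) * (1 - ty) *      tz  +
       at(i1, j0, k1) *      tx  * (1 - ty) *      tz  +
       at(i0, j1, k1) * (1 - tx) *      ty  *      tz  +
       at(i1, j1, k1) *      tx  *      ty  *      tz
  out[inside] <- v
  out
}

#' Interpolated dose at a physical point
#'
#' Trilinear interpolation of the dose field at one or more physical points,
#' e.g. the plan isocenter.  Errors if any point lies outside the grid's
#' voxel-center hull.
#'
#' @param grid a [dose_grid()].
#' @param point_mm numeric length 3, or an n x 3 matrix of points (mm).
#' @return numeric vector of doses (Gy).
#' @export
point_dose <- function(grid, point_mm) {
  stopifnot(inherits(grid, "dose_grid"))
  pts <- matrix(as.numeric(point_mm), ncol = 3)
  v <- trilinear_interp(grid$values, grid$origin, grid$spacing, pts)
  if (any(is.na(v)))
    stop("point_dose: point outside grid extent")
  v
}

#' Resample a dose grid onto a target geometry
#'
#' Trilinear interpolation of `grid` at every voxel center of
#' `target_geometry`.  Target voxels outside the source extent are marked
#' invalid (`NA` dose) and excluded from downstream statistics.
#'
#' @param grid source [dose_grid()].
#' @param target_geometry a `dose_grid`, `ct_volume` or `voxel_mask` supplying
#'   the target origin/spacing/shape.
#' @return a [dose_grid()] on the target geometry with a `valid` flag array.
#' @export
resample_dose <- function(grid, target_geometry) {
  stopifnot(inherits(grid, "dose_grid"))
  if (same_frame(grid, target_geometry)) return(grid)
  shp <- grid_shape(target_geometry)
  ax <- grid_axes(target_geometry)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  v <- trilinear_interp(grid$values, grid$origin, grid$spacing, pts)
  valid <- array(!is.na(v), dim = shp)
  vals <- array(v, dim = shp)
  vals[!valid] <- NA_real_
  dose_grid(vals, target_geometry$origin, target_geometry$spacing,
            valid = if (all(valid)) NULL else valid)
}
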