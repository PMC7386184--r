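#' Planar contour structure set
#'
#' A `structure_set` is a named list of structures, each a stack of planar
#' polygons on grid-parallel (axial) planes, as produced by treatment-planning
#' delineation.  Each contour is a closed polygon given as an n x 2 matrix of
#' (x, y) vertices in mm together with its slice position `z` (mm).  Nested
#' contours on one slice represent holes (even-odd rule at rasterization).
#'
#' @param structures named list; each element is `list(role =, contours =)`
#'   where `role` is one of `iGTV`, `ITV`, `PTV`, `lung`, `spinal_cord`,
#'   `external`, `other` and `contours` is a list of `list(z =, xy =)`.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(structures) {
  roles <- c("iGTV", "ITV", "PTV", "lung", "spinal_cord", "external", "other")
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop("structures must be a named list")
  for (nm in names(structures)) {
    s <- structures[[nm]]
    if (is.null(s$role) || !s$role %in% roles)
      stop(sprintf("structure '%s': role must be one of %s", nm,
                   paste(roles, collapse = ", ")))
    for (ct in s$contours) {
      xy <- ct$xy
      if (!is.matrix(xy) || ncol(xy) != 2 || nrow(xy) < 3)
        stop(sprintf("structure '%s': each contour needs >= 3 (x,y) vertices", nm))
      if (is.null(ct$z) || !is.finite(ct$z))
        stop(sprintf("structure '%s': contour slice position z missing", nm))
    }
  }
  structure(list(structures = structures), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  for (nm in names(x$structures))
    cat(sprintf("  %-12s [%s]  %d contour(s)\n", nm, x$structures[[nm]]$role,
                length(x$structures[[nm]]$contours)))
  invisible(x)
}

#' Look up the structure name carrying a given role
#' @param ss a [structure_set()].
#' @param role role label to find.
#' @return structure name, or `NULL` if absent.
#' @export
structure_by_role <- function(ss, role) {
  for (nm in names(ss$structures))
    if (identical(ss$structures[[nm]]$role, role)) return(nm)
  NULL
}

#' Boolean voxel occupancy mask on a grid geometry
#'
#' @param flags 3-D logical array.
#' @param geometry grid-like object supplying origin/spacing (and shape check).
#' @return object of class `voxel_mask`.
#' @export
voxel_mask <- function(flags, geometry) {
  shp <- grid_shape(geometry)
  if (!identical(dim(flags), as.integer(shp)) && !identical(dim(flags), shp))
    stop("mask flags must match the geometry shape")
  structure(list(
    flags = array(as.logical(flags), dim = shp),
    origin = geometry$origin, spacing = geometry$spacing,
    frame_id = geometry$frame_id
  ), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask %s  %d voxels  %.2f cm^3>\n", x$frame_id,
              sum(x$flags), mask_volume_cc(x)))
  invisible(x)
}

#' Mask volume in cm^3
#' @param mask a [voxel_mask()].
#' @export
mask_volume_cc <- function(mask) sum(mask$flags) * voxel_volume_mm3(mask) / 1000

#' Set difference of two masks on the same frame
#'
#' Used e.g. for "lung minus iGTV" when scoring normal-lung dose.
#' @param a,b [voxel_mask()] objects on the same geometry frame.
#' @export
mask_difference <- function(a, b) {
  if (!same_frame(a, b)) stop("masks are on different geometry frames")
  voxel_mask(a$flags & !b$flags, a)
}

# Even-odd (crossing-number) point-in-polygon, vectorized over test points.
# Vertices on an edge follow the usual pnpoly half-open convention.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize planar contours onto a grid geometry
#'
#' A voxel belongs to the mask iff its center lies inside the structure's
#' polygon(s) on that voxel's slice, under the even-odd rule — so nested
#' contours carve holes.  Each contour must lie on (within half a slice
#' spacing of) one of the grid's slice planes.
#'
#' @param contours list of `list(z =, xy =)` planar contours, or a
#'   [structure_set()] element.
#' @param geometry grid-like object (e.g. a [dose_grid()]).
#' @return a [voxel_mask()] on `geometry`.
#' @export
rasterize_structure <- function(contours, geometry) {
  if (!is.null(contours$contours)) contours <- contours$contours
  shp <- grid_shape(geometry)
  ax <- grid_axes(geometry)
  flags <- array(FALSE, dim = shp)
  for (ct in contours) {
    kz <- which.min(abs(ax[[3]] - ct$z))
    if (abs(ax[[3]][kz] - ct$z) > geometry$spacing[3] / 2 + 1e-9)
      stop(sprintf(
        "contour plane z=%.3f mm not coincident with any grid slice", ct$z))
    xy <- ct$xy
    pg <- expand.grid(x = ax[[1]], y = ax[[2]], KEEP.OUT.ATTRS = FALSE)
    inside <- points_in_polygon(pg$x, pg$y, xy[, 1], xy[, 2])
    flags[, , kz] <- xor(flags[, , kz], matrix(inside, nrow = shp[1]))
  }
  voxel_mask(flags, geometry)
}

#' Isotropic margin expansion of a voxel mask
#'
#' Expands the mask by a physical margin: the output contains every voxel
#' whose center lies within Euclidean distance `margin_mm` of some input
#' voxel center.  The expansion is isotropic in physical millimetres, so
#' anisotropic voxel spacing is respected.  Used to grow iGTV -> ITV (3 mm)
#' and ITV -> PTV (5 mm).
#'
#' @param mask a [voxel_mask()].
#' @param margin_mm non-negative margin (mm).
#' @return expanded [voxel_mask()]; a superset of the input.
#' @export
expand_margin <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!is.finite(margin_mm) || margin_mm < 0)
    stop("margin_mm must be >= 0")
  if (margin_mm == 0 || !any(mask$flags)) return(mask)
  sp <- mask$spacing
  rad <- floor(margin_mm / sp)
  off <- expand.grid(i = -rad[1]:rad[1], j = -rad[2]:rad[2], k = -rad[3]:rad[3])
  d2 <- (off$i * sp[1])^2 + (off$j * sp[2])^2 + (off$k * sp[3])^2
  off <- off[d2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  shp <- dim(mask$flags)
  out <- array(FALSE, dim = shp)
  f <- mask$flags
  win <- function(n, s) {
    lo <- max(1, 1 + s); hi <- min(n, n + s)
    if (lo > hi) integer(0) else lo:hi
  }
  for (r in seq_len(nrow(off))) {
    i <- off$i[r]; j <- off$j[r]; k <- off$k[r]
    # destination and source index windows for a shifted copy
    di <- win(shp[1], i); dj <- win(shp[2], j); dk <- win(shp[3], k)
    if (!length(di) || !length(dj) || !length(dk)) next
    out[di, dj, dk] <- out[di, dj, dk] | f[di - i, dj - j, dk - k]
  }
  voxel_mask(out, mask)
}
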