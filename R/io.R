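#' Plain-text dose-grid I/O
#'
#' `rtverify` persists dose grids in a documented plain JSON dialect that
#' mirrors the semantics of a DICOM RT Dose object: voxel doses are stored as
#' non-negative integers together with a `dose_grid_scaling` factor (Gy per
#' stored unit), a `unit` string, the geometry (origin of the first voxel
#' center, per-axis spacing, shape) and a row of direction cosines.  Only
#' axis-aligned, identity-orientation grids are supported; anything else is
#' rejected loudly, as befits QA software.  Values are serialized in R array
#' order (first axis fastest).
#'
#' @param path file path to read.
#' @return [read_rtdose()] returns a [dose_grid()].
#' @name rtdose_io
NULL

#' @rdname rtdose_io
#' @export
read_rtdose <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$dose_grid_scaling))
    stop("dose file lacks a dose_grid_scaling tag")
  unit <- if (is.null(j$unit)) "" else toupper(j$unit)
  if (!identical(unit, "GY"))
    stop(sprintf("unsupported dose unit '%s' (expected GY)", j$unit))
  ori <- j$orientation
  if (!is.null(ori) &&
      !isTRUE(all(abs(as.numeric(ori) - c(1, 0, 0, 0, 1, 0)) < 1e-6)))
    stop("unsupported geometry: dose grid is not axis-aligned")
  shp <- as.integer(j$shape)
  vals <- array(as.numeric(j$stored_values) * as.numeric(j$dose_grid_scaling),
                dim = shp)
  dose_grid(vals, as.numeric(j$origin_mm), as.numeric(j$spacing_mm))
}

#' @rdname rtdose_io
#' @param grid a [dose_grid()] to write.
#' @param scaling Gy per stored integer unit; default chosen so the maximum
#'   dose maps near the top of the signed 32-bit range.  The write/read
#'   round-trip error is bounded by one scaling quantum.
#' @export
write_rtdose <- function(grid, path, scaling = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  if (!is.null(grid$valid) && !all(grid$valid))
    stop("cannot serialize a grid with invalid voxels")
  mx <- max(grid$values)
  if (is.null(scaling))
    scaling <- if (mx > 0) mx / (2^31 - 1) else 1e-6
  stored <- round(as.numeric(grid$values) / scaling)
  obj <- list(
    modality = "RTDOSE", unit = "GY",
    dose_grid_scaling = scaling,
    origin_mm = grid$origin, spacing_mm = grid$spacing,
    shape = dim(grid$values),
    orientation = c(1, 0, 0, 0, 1, 0),
    stored_values = stored
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname rtdose_io
#' @param ct a [ct_volume()].
#' @export
write_ctvolume <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  obj <- list(modality = "CT", unit = "HU",
              origin_mm = ct$origin, spacing_mm = ct$spacing,
              shape = dim(ct$values),
              values = round(as.numeric(ct$values), 3))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname rtdose_io
#' @export
read_ctvolume <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ct_volume(array(as.numeric(j$values), dim = as.integer(j$shape)),
            as.numeric(j$origin_mm), as.numeric(j$spacing_mm))
}

#' Structure-set JSON I/O
#'
#' Contours are stored per structure as `{z, xy}` polygon records (mm).
#' @param ss a [structure_set()].
#' @param path file path.
#' @export
write_structure_set <- function(ss, path) {
  stopifnot(inherits(ss, "structure_set"))
  obj <- lapply(ss$structures, function(s) list(
    role = s$role,
    contours = lapply(s$contours, function(ct)
      list(z = ct$z, xy = round(unclass(ct$xy), 4)))
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_structure_set
#' @export
read_structure_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  structs <- lapply(j, function(s) list(
    role = s$role,
    contours = lapply(s$contours, function(ct) list(
      z = as.numeric(ct$z),
      xy = do.call(rbind, lapply(ct$xy, as.numeric))
    ))
  ))
  names(structs) <- names(j)
  structure_set(structs)
}

#' Detector-map JSON I/O
#' @param dm a [detector_map()].
#' @param path file path.
#' @export
write_detector_map <- function(dm, path) {
  stopifnot(inherits(dm, "detector_map"))
  obj <- list(values = unclass(dm$values), diode_spacing = dm$diode_spacing,
              cylinder_radius = dm$cylinder_radius, z0 = dm$z0,
              axis_xy = dm$axis_xy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detector_map
#' @export
read_detector_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  detector_map(as.matrix(j$values), diode_spacing = j$diode_spacing,
               cylinder_radius = j$cylinder_radius, z0 = j$z0,
               axis_xy = as.numeric(j$axis_xy))
}

#' Case-bundle I/O
#'
#' A case bundle is a directory of the plain-text artifacts one verification
#' case needs.  Patient bundles hold `ct.json`, `structures.json`,
#' `ptps.json`, `stps.json` and `meta.json` (isocenter, seed); phantom
#' bundles hold `ptps.json`, `stps.json`, `measurement.json` and `meta.json`
#' (detector spec, seed).
#'
#' @param case list as returned by [make_patient_case()] or
#'   [make_phantom_case()].
#' @param dir directory to create/fill.
#' @return `dir`, invisibly; readers return the case list.
#' @export
write_case_bundle <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(case$measurement)) {
    write_rtdose(case$ptps, file.path(dir, "ptps.json"))
    write_rtdose(case$stps, file.path(dir, "stps.json"))
    write_detector_map(case$measurement, file.path(dir, "measurement.json"))
    meta <- list(mode = "phantom", detector_spec = case$detector_spec,
                 seed = case$spec$seed)
  } else {
    write_ctvolume(case$ct, file.path(dir, "ct.json"))
    write_structure_set(case$structures, file.path(dir, "structures.json"))
    write_rtdose(case$ptps, file.path(dir, "ptps.json"))
    write_rtdose(case$stps, file.path(dir, "stps.json"))
    meta <- list(mode = "patient", isocenter_mm = case$isocenter_mm,
                 prescription_gy = case$spec$prescription_gy,
                 seed = case$spec$seed)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_case_bundle
#' @export
read_case_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (identical(meta$mode, "phantom")) {
    ds <- as.list(meta$detector_spec)
    n_ax <- ds$n_axial
    list(ptps = read_rtdose(file.path(dir, "ptps.json")),
         stps = read_rtdose(file.path(dir, "stps.json")),
         measurement = read_detector_map(file.path(dir, "measurement.json")),
         detector_spec = detector_spec(
           cylinder_radius = as.numeric(ds$cylinder_radius),
           diode_spacing = as.numeric(ds$diode_spacing),
           n_axial = if (length(n_ax)) as.integer(n_ax) else NULL),
         spec = list(seed = meta$seed))
  } else {
    list(ct = read_ctvolume(file.path(dir, "ct.json")),
         structures = read_structure_set(file.path(dir, "structures.json")),
         ptps = read_rtdose(file.path(dir, "ptps.json")),
         stps = read_rtdose(file.path(dir, "stps.json")),
         isocenter_mm = as.numeric(meta$isocenter_mm),
         spec = list(seed = meta$seed,
                     prescription_gy = meta$prescription_gy))
  }
}
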