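#' Dose-comparison criteria
#'
#' A criterion is either a pure dose-difference test (e.g. DD3%: pass when
#' the absolute dose difference is at most 3% of the normalization dose) or a
#' gamma test (e.g. 3%/2 mm: pass when the generalized gamma index is at most
#' 1).  Dose differences follow the global approach: they are expressed
#' relative to a single normalization dose, by default the maximum of the
#' reference distribution.  Points where the reference dose falls below
#' `low_dose_threshold` times the normalization (default the 10% isodose)
#' are excluded from evaluation.
#'
#' @param dose_criterion dose criterion, % of normalization dose; > 0.
#' @param distance_criterion distance-to-agreement criterion, mm; required
#'   (and > 0) for gamma mode, `NULL` for dose-difference mode.
#' @param mode `"dose_difference"` or `"gamma"`.
#' @param low_dose_threshold evaluation threshold as a fraction of the
#'   normalization dose, in `[0, 1)`.
#' @return object of class `comparison_criteria`.
#' @export
comparison_criteria <- function(dose_criterion,
                                distance_criterion = NULL,
                                mode = c("dose_difference", "gamma"),
                                low_dose_threshold = 0.10) {
  mode <- match.arg(mode)
  if (!is.finite(dose_criterion) || dose_criterion <= 0)
    stop("dose_criterion must be > 0")
  if (mode == "gamma" &&
      (is.null(distance_criterion) || distance_criterion <= 0))
    stop("gamma mode needs distance_criterion > 0")
  if (low_dose_threshold < 0 || low_dose_threshold >= 1)
    stop("low_dose_threshold must be in [0, 1)")
  structure(list(dose_criterion = dose_criterion,
                 distance_criterion = distance_criterion,
                 mode = mode,
                 low_dose_threshold = low_dose_threshold),
            class = "comparison_criteria")
}

#' Parse compact criteria labels
#'
#' Accepts labels like `"dd3"`, `"dd5"`, `"g2/2"`, `"g3/2"`, `"g3/3"`.
#' @param labels character vector of labels.
#' @param low_dose_threshold forwarded to [comparison_criteria()].
#' @return named list of `comparison_criteria`.
#' @export
parse_criteria <- function(labels, low_dose_threshold = 0.10) {
  out <- lapply(labels, function(lb) {
    l <- tolower(lb)
    if (grepl("^dd[0-9.]+$", l)) {
      comparison_criteria(as.numeric(sub("^dd", "", l)),
                          low_dose_threshold = low_dose_threshold)
    } else if (grepl("^g[0-9.]+/[0-9.]+$", l)) {
      p <- as.numeric(strsplit(sub("^g", "", l), "/", fixed = TRUE)[[1]])
      comparison_criteria(p[1], p[2], mode = "gamma",
                          low_dose_threshold = low_dose_threshold)
    } else stop(sprintf("cannot parse criteria label '%s'", lb))
  })
  names(out) <- labels
  out
}

criteria_label <- function(cr) {
  if (cr$mode == "gamma")
    sprintf("g%g/%g", cr$dose_criterion, cr$distance_criterion)
  else sprintf("dd%g", cr$dose_criterion)
}

dist_values <- function(x) {
  if (inherits(x, "detector_map")) x$values
  else if (inherits(x, "dose_grid")) x$values
  else stop("expected a dose_grid or detector_map")
}

dist_valid <- function(x) {
  if (inherits(x, "dose_grid") && !is.null(x$valid)) x$valid
  else array(TRUE, dim = dim(dist_values(x)))
}

#' Normalization dose of a distribution
#'
#' The maximum dose of the reference distribution; all global dose
#' differences and gamma dose criteria are expressed relative to it.
#'
#' @param reference a [dose_grid()] or [detector_map()].
#' @return numeric scalar, Gy.
#' @export
normalization_dose <- function(reference) {
  v <- dist_values(reference)[dist_valid(reference)]
  if (!length(v)) stop("empty reference distribution")
  m <- max(v)
  if (m <= 0) stop("all-zero reference distribution has no normalization dose")
  m
}

new_comparison_map <- function(values, evaluated, criteria, geometry,
                               normalization, roles = NULL) {
  structure(list(values = values, evaluated = evaluated, criteria = criteria,
                 geometry = geometry, normalization = normalization,
                 roles = roles),
            class = "comparison_map")
}

#' @export
print.comparison_map <- function(x, ...) {
  cat(sprintf("<comparison_map %s  %d evaluated  pass %.1f%%>\n",
              criteria_label(x$criteria), sum(x$evaluated),
              tryCatch(passing_rate(x), error = function(e) NA_real_)))
  invisible(x)
}

check_same_geometry <- function(reference, evaluated) {
  if (inherits(reference, "detector_map")) {
    if (!inherits(evaluated, "detector_map") ||
        !same_layout(reference, evaluated))
      stop("mismatched detector layouts")
  } else {
    if (!inherits(evaluated, "dose_grid") || !same_frame(reference, evaluated))
      stop("geometry mismatch: resample the evaluated grid first")
  }
}

#' Global dose-difference map
#'
#' Per-point `|D_eval - D_ref| / D_norm * 100` where `D_norm` is the
#' normalization dose (reference maximum by default).  Points below the low
#' dose threshold of the reference are not evaluated.
#'
#' @param reference,evaluated two [dose_grid()]s on the same frame or two
#'   [detector_map()]s with the same layout.
#' @param criteria a dose-difference [comparison_criteria()].
#' @param normalization override for the normalization dose (Gy), e.g. a
#'   prescription dose; default [normalization_dose()] of the reference.
#' @return a `comparison_map` with values in % of the normalization dose.
#' @export
dose_difference_map <- function(reference, evaluated, criteria,
                                normalization = NULL) {
  stopifnot(inherits(criteria, "comparison_criteria"))
  check_same_geometry(reference, evaluated)
  norm <- if (is.null(normalization)) normalization_dose(reference)
          else normalization
  rv <- dist_values(reference); ev <- dist_values(evaluated)
  ok <- dist_valid(reference) & dist_valid(evaluated)
  vals <- abs(ev - rv) / norm * 100
  evaluated_flag <- ok & (rv >= criteria$low_dose_threshold * norm)
  vals[!evaluated_flag] <- NA_real_
  new_comparison_map(vals, evaluated_flag, criteria, reference, norm)
}

#' Gamma-index map
#'
#' Generalized gamma analysis with global dose normalization: for each
#' evaluated reference point the minimum over nearby evaluated-distribution
#' positions of `sqrt((dDose/dd)^2 + (dist/dc)^2)`, searched exhaustively on
#' a local fine lattice of pitch `interp_step_fraction * dc` out to
#' `search_radius_factor * dc`, with the evaluated distribution interpolated
#' linearly.  On detector maps the azimuthal axis wraps around the cylinder.
#' A point passes when gamma <= 1.
#'
#' @inheritParams dose_difference_map
#' @param criteria a gamma-mode [comparison_criteria()].
#' @param search_radius_factor search radius in units of the distance
#'   criterion.
#' @param interp_step_fraction search-lattice pitch as a fraction of the
#'   distance criterion; values >= 1 trigger a coarse-search warning.
#' @return a `comparison_map` of gamma values (dimensionless).
#' @export
gamma_map <- function(reference, evaluated, criteria,
                      search_radius_factor = 3, interp_step_fraction = 0.1,
                      normalization = NULL) {
  stopifnot(inherits(criteria, "comparison_criteria"))
  if (criteria$mode != "gamma") stop("criteria$mode must be 'gamma'")
  if (interp_step_fraction >= 1)
    warning("interp_step_fraction >= 1: coarse gamma search")
  check_same_geometry(reference, evaluated)
  norm <- if (is.null(normalization)) normalization_dose(reference)
          else normalization
  dd_abs <- criteria$dose_criterion / 100 * norm
  dc <- criteria$distance_criterion
  step <- interp_step_fraction * dc
  radius <- search_radius_factor * dc
  rv <- dist_values(reference)
  ok <- dist_valid(reference) & dist_valid(evaluated)
  evaluated_flag <- ok & (rv >= criteria$low_dose_threshold * norm)
  if (inherits(reference, "detector_map")) {
    g <- gamma_2d_cpp(reference$values, evaluated$values,
                      reference$diode_spacing, reference$arc_spacing,
                      TRUE, dd_abs, dc, step, radius,
                      matrix(evaluated_flag, nrow = nrow(rv)))
  } else {
    g <- gamma_3d_cpp(as.numeric(rv), as.numeric(dist_values(evaluated)),
                      as.integer(dim(rv)), as.numeric(reference$spacing),
                      dd_abs, dc, step, radius, as.logical(evaluated_flag))
    g <- array(g, dim = dim(rv))
  }
  new_comparison_map(g, evaluated_flag, criteria, reference, norm)
}

#' Passing rate of a comparison map
#'
#' Percentage of evaluated points that pass: dose difference at most the
#' dose criterion, or gamma at most 1.
#'
#' @param map a `comparison_map`.
#' @return percentage in `[0, 100]`.
#' @export
passing_rate <- function(map) {
  stopifnot(inherits(map, "comparison_map"))
  n <- sum(map$evaluated)
  if (n == 0) stop("no evaluated points (all below the dose threshold)")
  100 * sum(point_passes(map)) / n
}

point_passes <- function(map) {
  lim <- if (map$criteria$mode == "gamma") 1 else map$criteria$dose_criterion
  v <- map$values[map$evaluated]
  v <= lim + 1e-12
}

#' Fail points of a comparison map
#'
#' The set of evaluated point indices (linear, column-major on the map's
#' layout) whose metric exceeds the criterion.  These sets are the operands
#' of Simpson's resemblance index.
#'
#' @param map a `comparison_map`.
#' @return object of class `fail_point_set` with fields `indices`,
#'   `n_evaluated`, `criteria`, `layout_dim`.
#' @export
extract_fail_points <- function(map) {
  stopifnot(inherits(map, "comparison_map"))
  lim <- if (map$criteria$mode == "gamma") 1 else map$criteria$dose_criterion
  idx <- which(map$evaluated & !is.na(map$values) & map$values > lim + 1e-12)
  fail_point_set(idx, n_evaluated = sum(map$evaluated),
                 criteria = map$criteria, layout_dim = dim(map$values))
}

#' Compare two distributions on the detector layout
#'
#' Runs a dose-difference or gamma comparison between two [detector_map()]s
#' (3-D grids must first be sampled with [sample_cylinder()]).  Gamma
#' distance search respects the cyclic azimuth: a discrepancy at column 1
#' may be matched by a feature at the last column.
#'
#' @inheritParams gamma_map
#' @export
compare_on_detector <- function(reference, evaluated, criteria, ...) {
  if (!inherits(reference, "detector_map") ||
      !inherits(evaluated, "detector_map"))
    stop("compare_on_detector expects detector maps; sample grids first")
  if (criteria$mode == "gamma") gamma_map(reference, evaluated, criteria, ...)
  else dose_difference_map(reference, evaluated, criteria, ...)
}

#' Export a comparison map as a data frame / CSV
#'
#' One row per point with its indices, physical position, metric value,
#' evaluated flag and pass flag.
#'
#' @param map a `comparison_map`.
#' @param path optional CSV path; when given the table is also written.
#' @return data.frame, invisibly when `path` is given.
#' @export
comparison_map_table <- function(map, path = NULL) {
  dm <- dim(map$values)
  geo <- map$geometry
  if (inherits(geo, "detector_map")) {
    ij <- expand.grid(row = seq_len(dm[1]), col = seq_len(dm[2]))
    pos <- cbind(axial_mm = geo$z0 + (ij$row - 1) * geo$diode_spacing,
                 arc_mm = (ij$col - 1) * geo$arc_spacing)
  } else {
    ax <- grid_axes(geo)
    ij <- expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                      k = seq_len(dm[3]))
    pos <- cbind(x_mm = ax[[1]][ij[, 1]], y_mm = ax[[2]][ij[, 2]],
                 z_mm = ax[[3]][ij[, 3]])
  }
  lim <- if (map$criteria$mode == "gamma") 1 else map$criteria$dose_criterion
  df <- data.frame(index = seq_along(map$values), ij, pos,
                   value = as.numeric(map$values),
                   evaluated = as.logical(map$evaluated))
  df$pass <- df$evaluated & !is.na(df$value) & df$value <= lim + 1e-12
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
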