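#' Verification configuration
#'
#' Carries every knob a verification run depends on, so reports are
#' auditable: the criteria list, normalization mode, evaluation threshold,
#' DVH bin width, gamma search parameters and reference-role assignments.
#' A deterministic hash of the configuration is embedded in every report.
#'
#' @param criteria character labels understood by [parse_criteria()].
#' @param normalization `"max"` (reference maximum) or a fixed dose in Gy.
#' @param low_dose_threshold evaluation threshold (fraction of
#'   normalization).
#' @param dvh_bin_width DVH bin width, Gy.
#' @param search_radius_factor,interp_step_fraction gamma search parameters
#'   (see [gamma_map()]).
#' @param roles reference-role assignment per pattern: pattern 1 uses the
#'   primary calculation as reference; patterns 2 and 3 use the measurement.
#' @return list of class `verification_config`.
#' @export
verification_config <- function(criteria = c("dd3", "dd5", "g2/2", "g3/2",
                                             "g3/3"),
                                normalization = "max",
                                low_dose_threshold = 0.10,
                                dvh_bin_width = 0.01,
                                search_radius_factor = 3,
                                interp_step_fraction = 0.1,
                                roles = c(pattern1 = "ptps",
                                          pattern2 = "measurement",
                                          pattern3 = "measurement")) {
  cfg <- list(criteria = criteria, normalization = normalization,
              low_dose_threshold = low_dose_threshold,
              dvh_bin_width = dvh_bin_width,
              search_radius_factor = search_radius_factor,
              interp_step_fraction = interp_step_fraction, roles = roles)
  cfg$hash <- fnv1a32(jsonlite::toJSON(cfg[order(names(cfg))],
                                       auto_unbox = TRUE, digits = 10))
  class(cfg) <- "verification_config"
  cfg
}

#' Phantom-mode verification of one case
#'
#' Samples both calculated grids on the measurement's cylinder layout and
#' computes, for every configured criterion, the passing rates of the three
#' comparison patterns — pattern 1: pTPS vs sTPS (pTPS as reference),
#' pattern 2: pTPS vs measurement, pattern 3: sTPS vs measurement
#' (measurement as reference) — plus fail-point sets and the Simpson
#' resemblance of pattern 1 with patterns 2 and 3 under the dose-difference
#' criteria.
#'
#' @param case a phantom case (from [make_phantom_case()] or
#'   [read_case_bundle()]).
#' @param config a [verification_config()].
#' @return list of class `phantom_report`: `passing_rates` (pattern x
#'   criterion matrix, %), `fri` (per-criterion [fri_table()] rows),
#'   `fail_sets`, `metadata`.
#' @export
run_phantom_verification <- function(case, config = verification_config()) {
  crits <- parse_criteria(config$criteria, config$low_dose_threshold)
  dm_p <- sample_cylinder(case$ptps, case$detector_spec)
  dm_s <- sample_cylinder(case$stps, case$detector_spec)
  dm_m <- case$measurement
  has_meas <- !is.null(dm_m)
  if (!has_meas)
    warning("no measurement present: patterns 2 and 3 skipped")
  pats <- list(pattern1 = list(ref = dm_p, ev = dm_s))
  if (has_meas) {
    pats$pattern2 <- list(ref = dm_m, ev = dm_p)
    pats$pattern3 <- list(ref = dm_m, ev = dm_s)
  }
  norm_override <- if (identical(config$normalization, "max")) NULL
                   else as.numeric(config$normalization)
  rates <- matrix(NA_real_, nrow = length(pats), ncol = length(crits),
                  dimnames = list(names(pats), names(crits)))
  fail_sets <- lapply(pats, function(p) list())
  for (lb in names(crits)) {
    cr <- crits[[lb]]
    for (pn in names(pats)) {
      mp <- if (cr$mode == "gamma")
        gamma_map(pats[[pn]]$ref, pats[[pn]]$ev, cr,
                  config$search_radius_factor, config$interp_step_fraction,
                  normalization = norm_override)
      else dose_difference_map(pats[[pn]]$ref, pats[[pn]]$ev, cr,
                               normalization = norm_override)
      rates[pn, lb] <- passing_rate(mp)
      fail_sets[[pn]][[lb]] <- extract_fail_points(mp)
    }
  }
  dd_labels <- names(crits)[vapply(crits, function(cr)
    cr$mode == "dose_difference", TRUE)]
  fri <- if (has_meas && length(dd_labels))
    fri_table(fail_sets$pattern1[dd_labels], fail_sets$pattern2[dd_labels],
              fail_sets$pattern3[dd_labels], dd_labels)
  else NULL
  structure(list(
    passing_rates = rates, fri = fri, fail_sets = fail_sets,
    metadata = list(mode = "phantom", seed = case$spec$seed,
                    config_hash = config$hash, roles = config$roles)
  ), class = "phantom_report")
}

# Rasterize the case's structures onto a grid's geometry; ITV/PTV are
# derived from the iGTV by margin expansion (default 3 mm + 5 mm).
case_masks <- function(case, geometry) {
  if (!is.null(case$masks) && identical(case$masks$iGTV$frame_id,
                                        geometry$frame_id))
    igtv <- case$masks$iGTV
  else igtv <- rasterize_structure(case$structures$structures$iGTV, geometry)
  itv <- expand_margin(igtv, if (!is.null(case$spec$margin_itv_mm))
    case$spec$margin_itv_mm else 3)
  ptv <- expand_margin(itv, if (!is.null(case$spec$margin_ptv_mm))
    case$spec$margin_ptv_mm else 5)
  lung <- rasterize_structure(case$structures$structures$lung, geometry)
  cord <- rasterize_structure(case$structures$structures$spinal_cord,
                              geometry)
  list(iGTV = igtv, ITV = itv, PTV = ptv, lung = lung, spinal_cord = cord)
}

#' Patient-geometry verification of one case
#'
#' Re-rasterizes the structures on each dose grid's geometry, computes the
#' dose-volume index sets of both calculations, and derives the dosimetric
#' errors (isocenter and target D-indices) and volumetric errors (lung
#' V/Dmean indices and spinal-cord Dmax) together with PTV-size and HU
#' covariates for later correlation analysis.
#'
#' @param case a patient case (from [make_patient_case()] or
#'   [read_case_bundle()]).
#' @param config a [verification_config()].
#' @return list of class `patient_report`: `indices_ptps`, `indices_stps`,
#'   `errors` (named numeric, %), `covariates`, `metadata`.
#' @export
run_patient_verification <- function(case, config = verification_config()) {
  masks_p <- case_masks(case, case$ptps)
  masks_s <- if (same_frame(case$ptps, case$stps)) masks_p
             else case_masks(case, case$stps)
  ix_p <- dvh_index_set(case$ptps, masks_p, case$isocenter_mm,
                        config$dvh_bin_width)
  ix_s <- dvh_index_set(case$stps, masks_s, case$isocenter_mm,
                        config$dvh_bin_width)
  de_names <- c("isocenter_dose",
                paste0("iGTV_", c("D99", "D95", "Dmean", "D2", "Dmax")),
                paste0("PTV_", c("D99", "D95", "Dmean", "D2", "Dmax")))
  ve_names <- c("lung_V20Gy", "lung_V10Gy", "lung_V5Gy", "lung_Dmean",
                "cord_Dmax")
  err <- c(
    vapply(de_names, function(nm) rel_err(ix_s[[nm]], ix_p[[nm]],
                                          dosimetric_error), 1),
    vapply(ve_names, function(nm) rel_err(ix_s[[nm]], ix_p[[nm]],
                                          volume_error), 1))
  ptv_hu <- case$ct$values[masks_p$PTV$flags]
  structure(list(
    indices_ptps = ix_p, indices_stps = ix_s, errors = err,
    error_kind = c(stats::setNames(rep("DE", length(de_names)), de_names),
                   stats::setNames(rep("VE", length(ve_names)), ve_names)),
    covariates = c(ptv_size_cc = mask_volume_cc(masks_p$PTV),
                   ptv_hu_mean = mean(ptv_hu),
                   ptv_hu_sd = stats::sd(ptv_hu),
                   ptv_hu_min = min(ptv_hu)),
    metadata = list(mode = "patient", seed = case$spec$seed,
                    config_hash = config$hash,
                    prescription_gy = case$spec$prescription_gy)
  ), class = "patient_report")
}

rel_err <- function(s, p, fun) {
  if (is.null(s) || is.null(p) || is.na(s) || is.na(p) || p <= 0)
    return(NA_real_)
  fun(s, p)
}

#' Run a seeded synthetic cohort through a verification workflow
#'
#' Generates `n` cases from per-case specs (sub-seeded from `seed`) and
#' verifies each.  The phantom workflow yields passing rates and FRI
#' tables; the patient workflow yields DE/VE records.
#'
#' @param mode `"phantom"` or `"patient"`.
#' @param n number of cases.
#' @param seed cohort master seed.
#' @param config a [verification_config()].
#' @param base_spec optional base case spec.
#' @return list of per-case reports (class `cohort_reports`).
#' @export
run_cohort <- function(mode = c("phantom", "patient"), n = 20, seed = 1L,
                       config = verification_config(), base_spec = NULL) {
  mode <- match.arg(mode)
  if (mode == "phantom") {
    specs <- phantom_cohort_specs(n, seed,
                                  base = base_spec %||% phantom_case_spec())
    reports <- lapply(specs, function(s)
      run_phantom_verification(make_phantom_case(s), config))
  } else {
    specs <- patient_cohort_specs(n, seed,
                                  base = base_spec %||% patient_case_spec())
    reports <- lapply(specs, function(s)
      run_patient_verification(make_patient_case(s), config))
  }
  structure(reports, class = "cohort_reports", mode = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort summary tables
#'
#' Aggregates per-case reports into the report shapes of a verification
#' study: per pattern and criterion mean, sample SD, max and min passing
#' rates; FRI summaries excluding 100%-passing cases; per-index DE/VE mean,
#' SD, max, min, paired-t p-value and tolerance level; and correlations of
#' each target DE with PTV size and HU statistics.  Order-invariant in the
#' input reports.
#'
#' @param reports list of per-case reports (all phantom or all patient).
#' @return list of data frames (`passing_rates`, `fri` for phantom mode;
#'   `errors`, `correlations` for patient mode).
#' @export
summarize_cohort <- function(reports) {
  stopifnot(length(reports) >= 1)
  if (inherits(reports[[1]], "phantom_report")) {
    rates <- lapply(reports, `[[`, "passing_rates")
    pats <- rownames(rates[[1]]); crits <- colnames(rates[[1]])
    rows <- list()
    for (pn in pats) for (lb in crits) {
      v <- vapply(rates, function(r) r[pn, lb], 1)
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = pn, criterion = lb, n = length(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        max = max(v), min = min(v))
    }
    fri_sum <- summarize_fri(lapply(reports, `[[`, "fri"))
    list(passing_rates = do.call(rbind, rows), fri = fri_sum)
  } else {
    errs <- do.call(rbind, lapply(reports, `[[`, "errors"))
    kind <- reports[[1]]$error_kind
    rows <- lapply(colnames(errs), function(nm) {
      v <- errs[, nm]
      p <- vapply(reports, function(r) r$indices_ptps[[nm]], 1)
      s <- vapply(reports, function(r) r$indices_stps[[nm]], 1)
      tt <- tryCatch(paired_t_test(p, s),
                     error = function(e) list(p_value = NA_real_,
                                              degenerate = TRUE))
      tol <- tryCatch(tolerance_level(v), error = function(e) NULL)
      data.frame(index = nm, kind = kind[[nm]], n = sum(is.finite(v)),
                 mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v[is.finite(v)]),
                 max = suppressWarnings(max(v, na.rm = TRUE)),
                 min = suppressWarnings(min(v, na.rm = TRUE)),
                 p_value = tt$p_value,
                 degenerate = isTRUE(tt$degenerate),
                 tol_lower = if (is.null(tol)) NA_real_ else tol$lower,
                 tol_upper = if (is.null(tol)) NA_real_ else tol$upper)
    })
    covs <- do.call(rbind, lapply(reports, `[[`, "covariates"))
    target_names <- names(kind)[kind == "DE"]
    cors <- do.call(rbind, lapply(target_names, function(nm) {
      ca <- correlation_analysis(errs[, nm],
                                 covs[, c("ptv_size_cc", "ptv_hu_mean",
                                          "ptv_hu_sd"), drop = FALSE])
      ca$index <- nm
      ca
    }))
    list(errors = do.call(rbind, rows), correlations = cors)
  }
}

#' Write a cohort report to disk
#'
#' Emits `report.json` plus one CSV per summary table under
#' `<dir>/tables/`.
#'
#' @param summary result of [summarize_cohort()].
#' @param dir output directory (created if needed).
#' @param metadata optional list stored alongside the tables.
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(summary, dir, metadata = list()) {
  dir.create(file.path(dir, "tables"), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(c(list(metadata = metadata), summary),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  for (nm in names(summary))
    if (is.data.frame(summary[[nm]]))
      utils::write.csv(summary[[nm]],
                       file.path(dir, "tables", paste0(nm, ".csv")),
                       row.names = FALSE)
  invisible(dir)
}
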