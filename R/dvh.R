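#' Cumulative dose-volume histogram
#'
#' Exact voxel-counting cumulative DVH of the dose inside a structure mask:
#' `cumulative_volume[b]` is the fraction of the structure volume receiving
#' at least `dose_bins[b]` (bin left edges, uniform width).  The curve starts
#' at 1 for 0 Gy and ends at 0 one bin above the structure maximum.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [voxel_mask()] on the same frame.
#' @param bin_width histogram bin width, Gy; default 0.01 Gy keeps quantile
#'   error negligible at SBRT dose levels.
#' @param structure_label label carried into reports.
#' @return object of class `dvh` with fields `structure_label`, `dose_bins`,
#'   `cumulative_volume`, `total_volume_cc`, `bin_width`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.01,
                           structure_label = "structure") {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "voxel_mask"))
  if (!same_frame(dose, mask))
    stop("dose and mask are on different geometry frames")
  d <- dose$values[mask$flags]
  if (!length(d)) stop("empty structure mask")
  if (anyNA(d)) stop("structure mask covers invalid dose voxels")
  nb <- as.integer(floor(max(d) / bin_width)) + 2L
  edges <- (seq_len(nb) - 1) * bin_width
  # fraction receiving >= edge; findInterval counts voxels strictly below
  cnt_below <- findInterval(edges, sort(d), left.open = TRUE)
  cum <- (length(d) - cnt_below) / length(d)
  structure(list(structure_label = structure_label, dose_bins = edges,
                 cumulative_volume = cum, bin_width = bin_width,
                 total_volume_cc = mask_volume_cc(mask)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh %s  %.2f cm^3  Dmax<%.2f Gy  bin %.3g Gy>\n",
              x$structure_label, x$total_volume_cc, max(x$dose_bins),
              x$bin_width))
  invisible(x)
}

#' Dose at volume (Dp%)
#'
#' Minimum dose received by the hottest `p`% of the structure, read from the
#' cumulative curve by linear interpolation between bin edges.  `D95` is
#' `dose_at_volume(dvh, 95)`; `p = 100` is the structure minimum dose.
#'
#' @param dvh a [cumulative_dvh()].
#' @param p percent of the structure volume, in `(0, 100]`.
#' @return dose, Gy.
#' @export
dose_at_volume <- function(dvh, p) {
  if (!is.finite(p) || p <= 0 || p > 100) stop("p must be in (0, 100]")
  frac <- p / 100
  cv <- dvh$cumulative_volume
  if (frac > cv[1]) return(0)
  k <- max(which(cv >= frac))      # last bin with volume >= target
  if (k == length(cv)) return(dvh$dose_bins[k])
  v0 <- cv[k]; v1 <- cv[k + 1]
  if (v0 == v1) return(dvh$dose_bins[k])
  t <- (v0 - frac) / (v0 - v1)
  dvh$dose_bins[k] + t * dvh$bin_width
}

#' Volume at dose (VdGy)
#'
#' Percentage of the structure volume receiving at least `d` Gy, linearly
#' interpolated on the cumulative curve.
#'
#' @param dvh a [cumulative_dvh()].
#' @param d dose, Gy; >= 0.
#' @return percent of the structure volume.
#' @export
volume_at_dose <- function(dvh, d) {
  if (!is.finite(d) || d < 0) stop("d must be >= 0")
  edges <- dvh$dose_bins
  if (d >= edges[length(edges)]) return(0)
  k <- findInterval(d, edges)
  cv <- dvh$cumulative_volume
  if (k >= length(edges)) return(100 * cv[length(cv)])
  t <- (d - edges[k]) / dvh$bin_width
  100 * (cv[k] + t * (cv[k + 1] - cv[k]))
}

#' Dose-volume index set for one plan
#'
#' Computes the verification indices: interpolated isocenter dose; D99, D95,
#' Dmean, D2 and Dmax for each target (iGTV, PTV); lung V20Gy, V10Gy, V5Gy
#' and Dmean where lung means the normal lung, i.e. the lung mask minus the
#' iGTV; and the spinal-cord maximum dose.  Dmax is the hottest single voxel
#' and Dmean the arithmetic voxel mean.  Missing structures yield `NA`
#' entries (flagged, never silent zeros).
#'
#' @param dose a [dose_grid()].
#' @param masks named list of [voxel_mask()]s; recognized names `iGTV`,
#'   `PTV`, `lung`, `spinal_cord` (lung is taken as-given minus iGTV when
#'   both are present).
#' @param isocenter_mm isocenter position (mm) for the point dose, or `NULL`.
#' @param bin_width DVH bin width, Gy.
#' @return object of class `dvh_index_set`: a named list of index values
#'   (Gy for D-indices, % volume for V-indices) plus structure volumes (cc).
#' @export
dvh_index_set <- function(dose, masks, isocenter_mm = NULL,
                          bin_width = 0.01) {
  out <- list(isocenter_dose = NA_real_)
  vols <- list()
  if (!is.null(isocenter_mm))
    out$isocenter_dose <- point_dose(dose, isocenter_mm)
  target_ix <- function(mask, tag) {
    d <- dose$values[mask$flags]
    dv <- cumulative_dvh(dose, mask, bin_width, tag)
    ix <- list(dose_at_volume(dv, 99), dose_at_volume(dv, 95), mean(d),
               dose_at_volume(dv, 2), max(d))
    names(ix) <- paste0(tag, c("_D99", "_D95", "_Dmean", "_D2", "_Dmax"))
    ix
  }
  for (tag in c("iGTV", "PTV")) {
    if (!is.null(masks[[tag]]) && any(masks[[tag]]$flags)) {
      out <- c(out, target_ix(masks[[tag]], tag))
      vols[[paste0(tag, "_volume_cc")]] <- mask_volume_cc(masks[[tag]])
    } else {
      nm <- paste0(tag, c("_D99", "_D95", "_Dmean", "_D2", "_Dmax"))
      out[nm] <- NA_real_
    }
  }
  if (!is.null(masks$lung) && any(masks$lung$flags)) {
    lung <- if (!is.null(masks$iGTV)) mask_difference(masks$lung, masks$iGTV)
            else masks$lung
    dv <- cumulative_dvh(dose, lung, bin_width, "lung")
    out$lung_V20Gy <- volume_at_dose(dv, 20)
    out$lung_V10Gy <- volume_at_dose(dv, 10)
    out$lung_V5Gy <- volume_at_dose(dv, 5)
    out$lung_Dmean <- mean(dose$values[lung$flags])
    vols$lung_volume_cc <- mask_volume_cc(lung)
  } else {
    out[c("lung_V20Gy", "lung_V10Gy", "lung_V5Gy", "lung_Dmean")] <- NA_real_
  }
  if (!is.null(masks$spinal_cord) && any(masks$spinal_cord$flags)) {
    out$cord_Dmax <- max(dose$values[masks$spinal_cord$flags])
  } else out$cord_Dmax <- NA_real_
  structure(c(out, vols), class = "dvh_index_set")
}

#' Dosimetric error between secondary and primary calculations
#'
#' `DE = (D_sTPS - D_pTPS) / D_pTPS * 100` (%): negative when the secondary
#' system reports less dose than the primary.
#'
#' @param d_stps,d_ptps doses (Gy); `d_ptps` must be > 0.
#' @return percent error (vectorized).
#' @export
dosimetric_error <- function(d_stps, d_ptps) {
  if (any(!is.finite(d_ptps)) || any(d_ptps <= 0))
    stop("primary dose must be > 0")
  (d_stps - d_ptps) / d_ptps * 100
}

#' Volumetric error between secondary and primary calculations
#'
#' `VE = (V_sTPS - V_pTPS) / V_pTPS * 100` (%), applied to volume-type
#' indices such as the lung V20Gy.
#'
#' @param v_stps,v_ptps index values; `v_ptps` must be > 0.
#' @return percent error (vectorized).
#' @export
volume_error <- function(v_stps, v_ptps) {
  if (any(!is.finite(v_ptps)) || any(v_ptps <= 0))
    stop("primary volume must be > 0")
  (v_stps - v_ptps) / v_ptps * 100
}

#' Tolerance level from a cohort of errors
#'
#' The patient-specific QA tolerance band for a target index: cohort mean
#' plus/minus one sample SD (n-1 denominator).
#'
#' @param errors numeric vector of per-case errors (%), length >= 2.
#' @return list with `mean`, `sd`, `lower`, `upper`.
#' @export
tolerance_level <- function(errors) {
  errors <- errors[is.finite(errors)]
  if (length(errors) < 2) stop("need at least 2 error values")
  m <- mean(errors); s <- stats::sd(errors)
  list(mean = m, sd = s, lower = m - s, upper = m + s)
}

#' Classify a Pearson correlation coefficient
#'
#' Strength bands on the magnitude: weak `0 < |CC| < 0.4`, moderate
#' `0.4 <= |CC| < 0.8`, strong `0.8 <= |CC| <= 1` (boundaries go to the
#' higher class).
#'
#' @param cc correlation coefficient in `[-1, 1]` (or `NA`).
#' @return character label.
#' @export
cc_strength <- function(cc) {
  if (is.na(cc)) return("undefined")
  a <- abs(cc)
  if (a >= 0.8) "strong" else if (a >= 0.4) "moderate"
  else if (a > 0) "weak" else "none"
}

#' Correlation of dosimetric errors with patient covariates
#'
#' Pearson correlation of per-case DE values against each covariate (PTV
#' size, mean HU in the PTV, SD of HU in the PTV, ...), with the strength
#' classification attached.  Zero variance in either variable yields an
#' undefined-CC marker rather than a number.
#'
#' @param de_values numeric vector of per-case errors (%).
#' @param covariates named list or data.frame of equal-length numeric
#'   covariate vectors.
#' @return data.frame with columns `covariate`, `cc`, `strength`, `n`.
#' @export
correlation_analysis <- function(de_values, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(de_values))
    stop("covariates and DE values must be paired")
  rows <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    keep <- is.finite(de_values) & is.finite(x)
    n <- sum(keep)
    cc <- if (n < 3 || stats::sd(de_values[keep]) == 0 ||
              stats::sd(x[keep]) == 0) NA_real_
          else stats::cor(de_values[keep], x[keep])
    data.frame(covariate = nm, cc = cc, strength = cc_strength(cc), n = n)
  })
  do.call(rbind, rows)
}

#' Paired two-sided Student's t-test
#'
#' Wrapper used for cohort significance of per-index differences between the
#' two planning systems; identical or constant-shift-free degenerate pairs
#' (zero-variance differences) return a degenerate marker instead of a
#' p-value.
#'
#' @param ptps_values,stps_values equal-length paired samples.
#' @param alpha significance level for the flag (default 0.05).
#' @return list with `p_value`, `significant`, `degenerate`, `n`.
#' @export
paired_t_test <- function(ptps_values, stps_values, alpha = 0.05) {
  if (length(ptps_values) != length(stps_values))
    stop("samples must be paired")
  keep <- is.finite(ptps_values) & is.finite(stps_values)
  d <- stps_values[keep] - ptps_values[keep]
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  if (stats::sd(d) == 0)
    return(list(p_value = NA_real_, significant = NA, degenerate = TRUE,
                n = n))
  tt <- stats::t.test(stps_values[keep], ptps_values[keep], paired = TRUE)
  list(p_value = tt$p.value, significant = tt$p.value < alpha,
       degenerate = FALSE, n = n)
}
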