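#' Phantom-mode case specification
#'
#' Parameters of the seeded generator that emulates a homogeneous-phantom
#' QA session: a smooth multi-lobe arc dose field, a secondary calculation
#' differing from the primary by a smooth inter-algorithm perturbation, and
#' a cylindrical diode measurement differing from both by a larger, spatially
#' correlated delivery/modelling systematic plus independent diode noise.
#' With the default scales (primary-vs-secondary discrepancy smaller than
#' the TPS-vs-delivery systematic) pattern 1 (pTPS vs sTPS) agrees better
#' than patterns 2 and 3 (each TPS vs measurement), and pattern-1 fail
#' points reappear in pattern 3 — the structure the verification analysis
#' assumes.
#'
#' @param seed integer RNG seed; every draw is derived from it.
#' @param shape grid shape (voxels).
#' @param spacing_mm voxel pitch (mm); smooth phantom fields tolerate a
#'   coarse 4 mm lattice.
#' @param n_arc_lobes number of Gaussian dose lobes forming the base field.
#' @param tps_discrepancy_sd SD of the pTPS-vs-sTPS perturbation, % of the
#'   maximum dose, over the evaluated (>= 10% isodose) region.
#' @param model_error_sd SD of the shared TPS-vs-delivery systematic, %.
#' @param measurement_noise_sd SD of independent per-diode noise, %.
#' @param detector a [detector_spec()].
#' @return list of class `phantom_case_spec`.
#' @export
phantom_case_spec <- function(seed = 1L, shape = c(60, 60, 40),
                              spacing_mm = c(4, 4, 4), n_arc_lobes = 4,
                              tps_discrepancy_sd = 1.3, model_error_sd = 2.6,
                              measurement_noise_sd = 0.7,
                              detector = detector_spec()) {
  stopifnot(all(spacing_mm > 0), tps_discrepancy_sd >= 0,
            model_error_sd >= 0, measurement_noise_sd >= 0)
  structure(list(seed = as.integer(seed), shape = shape,
                 spacing_mm = spacing_mm, n_arc_lobes = n_arc_lobes,
                 tps_discrepancy_sd = tps_discrepancy_sd,
                 model_error_sd = model_error_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 detector = detector),
            class = "phantom_case_spec")
}

# Voxel-center coordinate arrays for a grid centered on the origin.
centered_axes <- function(shape, spacing) {
  lapply(1:3, function(a)
    (seq_len(shape[a]) - 1 - (shape[a] - 1) / 2) * spacing[a])
}

# Sum of n isotropic Gaussian bumps evaluated on the grid lattice.
gaussian_bumps <- function(ax, centers, sigmas, amps) {
  shp <- vapply(ax, length, 1L)
  field <- array(0, dim = shp)
  for (b in seq_len(nrow(centers))) {
    gx <- exp(-((ax[[1]] - centers[b, 1])^2) / (2 * sigmas[b]^2))
    gy <- exp(-((ax[[2]] - centers[b, 2])^2) / (2 * sigmas[b]^2))
    gz <- exp(-((ax[[3]] - centers[b, 3])^2) / (2 * sigmas[b]^2))
    field <- field + amps[b] * (gx %o% gy %o% gz)
  }
  field
}

# Smooth zero-mean random field rescaled so its SD over `region` equals
# `target_sd` (absolute units).
smooth_random_field <- function(ax, n_bumps, sigma_range, region, target_sd) {
  shp <- vapply(ax, length, 1L)
  if (target_sd <= 0) return(array(0, dim = shp))
  span <- vapply(ax, function(a) diff(range(a)), 1)
  centers <- cbind(stats::runif(n_bumps, -span[1] / 2, span[1] / 2),
                   stats::runif(n_bumps, -span[2] / 2, span[2] / 2),
                   stats::runif(n_bumps, -span[3] / 2, span[3] / 2))
  sigmas <- stats::runif(n_bumps, sigma_range[1], sigma_range[2])
  amps <- stats::rnorm(n_bumps)
  f <- gaussian_bumps(ax, centers, sigmas, amps)
  f <- f - mean(f[region])
  s <- stats::sd(f[region])
  if (s == 0) return(array(0, dim = shp))
  f * (target_sd / s)
}

#' Generate a phantom-mode comparison triplet
#'
#' Deterministic per seed.  Draw order: (1) base-field lobe parameters,
#' (2) secondary-calculation perturbation bumps, (3) delivery systematic
#' bumps, (4) per-diode measurement noise.  The base field has maximum
#' 10 Gy; perturbation scales are percentages of that maximum over the
#' evaluated (at least 10% isodose) region.
#'
#' @param spec a [phantom_case_spec()].
#' @return list with `ptps` and `stps` ([dose_grid()]s), `measurement`
#'   (a [detector_map()]), `detector_spec` and `spec`.
#' @export
make_phantom_case <- function(spec = phantom_case_spec()) {
  stopifnot(inherits(spec, "phantom_case_spec"))
  set.seed(spec$seed)
  shp <- spec$shape
  ax <- centered_axes(shp, spec$spacing_mm)
  n <- spec$n_arc_lobes
  centers <- cbind(stats::runif(n, -25, 25), stats::runif(n, -25, 25),
                   stats::runif(n, -15, 15))
  sigmas <- stats::runif(n, 28, 45)
  amps <- stats::runif(n, 0.5, 1)
  base <- gaussian_bumps(ax, centers, sigmas, amps)
  base <- base * (10 / max(base))
  region <- base >= 0.1 * max(base)

  origin <- vapply(ax, min, 1)
  ptps <- dose_grid(base, origin, spec$spacing_mm)

  # the comparisons run on the unwrapped cylinder and are normalized to the
  # detector-map maximum, so perturbation scales are calibrated there: each
  # smooth field is rescaled so its SD *over the evaluated detector samples*
  # is the requested percentage of the detector-map maximum
  lat <- cylinder_lattice(ptps, spec$detector)
  base_det <- trilinear_interp(base, origin, spec$spacing_mm, lat$pts)
  det_max <- max(base_det)
  det_eval <- base_det >= 0.1 * det_max
  calibrate <- function(field) {
    s <- stats::sd(trilinear_interp(field, origin, spec$spacing_mm,
                                    lat$pts)[det_eval])
    if (s == 0) 0 else 1 / s
  }
  pert <- smooth_random_field(ax, 6, c(15, 30), region, 1)
  pert <- pert * calibrate(pert) * spec$tps_discrepancy_sd / 100 * det_max
  syst <- smooth_random_field(ax, 5, c(25, 50), region, 1)
  syst <- syst * calibrate(syst) * spec$model_error_sd / 100 * det_max

  stps <- dose_grid(pmax(base + pert, 0), origin, spec$spacing_mm)
  truth <- dose_grid(pmax(base + syst, 0), origin, spec$spacing_mm)
  meas <- sample_cylinder(truth, spec$detector)
  noise <- stats::rnorm(length(meas$values),
                        sd = spec$measurement_noise_sd / 100 * det_max)
  meas$values <- pmax(meas$values + matrix(noise, nrow(meas$values)), 0)
  list(ptps = ptps, stps = stps, measurement = meas,
       detector_spec = spec$detector, spec = spec)
}

#' Patient-mode case specification
#'
#' Parameters of the seeded generator that emulates a lung SBRT geometry:
#' a water-HU body holding an air-like lung, a spherical solid tumor (the
#' iGTV), a posterior spinal cord, margin-derived ITV (+3 mm) and PTV
#' (+5 mm), a target-conformal primary dose normalized so the PTV D95
#' equals the prescription (default 50 Gy in 4 fractions), and a secondary
#' dose derived from the primary by a density-dependent perturbation: in
#' low-HU tissue the secondary calculation reports less dose where the dose
#' is high and spreads a small excess bath where it is low, emulating the
#' improved lateral electron-transport modelling of type-c algorithms.
#'
#' @param seed integer RNG seed.
#' @param shape,spacing_mm grid geometry (default 2.5 mm pitch; a
#'   desk-scale stand-in for the clinical 2 mm grid).
#' @param lung_hu_mean,lung_hu_sd lung HU distribution.
#' @param tumor_hu_mean,tumor_hu_sd tumor HU distribution.
#' @param tumor_radius_mm iGTV sphere radius.
#' @param margin_itv_mm,margin_ptv_mm isotropic expansion margins.
#' @param prescription_gy,fractions prescription (total dose covering 95%
#'   of the PTV).
#' @param density_coupling strength of the high-dose low-density
#'   suppression applied to the secondary grid (fraction at HU -1000).
#' @param low_dose_bath strength of the compensating low-dose enhancement.
#' @return list of class `patient_case_spec`.
#' @export
patient_case_spec <- function(seed = 1L, shape = c(56, 56, 48),
                              spacing_mm = c(2.5, 2.5, 2.5),
                              lung_hu_mean = -700, lung_hu_sd = 120,
                              tumor_hu_mean = -300, tumor_hu_sd = 80,
                              tumor_radius_mm = 8,
                              margin_itv_mm = 3, margin_ptv_mm = 5,
                              prescription_gy = 50, fractions = 4,
                              density_coupling = 0.05,
                              low_dose_bath = 0.15) {
  stopifnot(tumor_radius_mm > 0, prescription_gy > 0, all(spacing_mm > 0))
  structure(as.list(environment()), class = "patient_case_spec")
}

#' Generate a patient-mode verification case
#'
#' Deterministic per seed.  Draw order: (1) tumor-center jitter, (2) body
#' HU noise, (3) lung HU noise, (4) tumor HU noise.  Errors if the tumor
#' plus both margins does not fit inside the lung.
#'
#' @param spec a [patient_case_spec()].
#' @return list with `ct` ([ct_volume()]), `structures`
#'   ([structure_set()]), `ptps`, `stps` ([dose_grid()]s), `isocenter_mm`
#'   and `spec`.
#' @export
make_patient_case <- function(spec = patient_case_spec()) {
  stopifnot(inherits(spec, "patient_case_spec"))
  set.seed(spec$seed)
  shp <- spec$shape; sp <- spec$spacing_mm
  ax <- centered_axes(shp, sp)
  origin <- vapply(ax, min, 1)

  lung_c <- c(-25, 0, 0); lung_r <- c(32, 38, 50)
  jit <- stats::runif(3, -3, 3)
  tum_c <- lung_c + c(0, 5, 0) + jit
  r_t <- spec$tumor_radius_mm
  if (any(abs(tum_c - lung_c) + r_t + spec$margin_itv_mm +
          spec$margin_ptv_mm > lung_r))
    stop("tumor plus margins exceeds the lung extent")

  X <- array(ax[[1]], dim = shp)
  Y <- aperm(array(ax[[2]], dim = shp[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(ax[[3]], dim = shp[c(3, 1, 2)]), c(2, 3, 1))

  body <- (X / 65)^2 + (Y / 55)^2 <= 1
  lung <- ((X - lung_c[1]) / lung_r[1])^2 + ((Y - lung_c[2]) / lung_r[2])^2 +
          ((Z - lung_c[3]) / lung_r[3])^2 <= 1
  r2_t <- (X - tum_c[1])^2 + (Y - tum_c[2])^2 + (Z - tum_c[3])^2
  tumor <- r2_t <= r_t^2
  cord <- (X - 0)^2 + (Y - 45)^2 <= 4^2

  # tissue-class HU means (used for the density perturbation) + voxel noise
  hu_clean <- array(-1000, dim = shp)
  hu_clean[body] <- 20
  hu_clean[lung & body] <- spec$lung_hu_mean
  hu_clean[tumor] <- spec$tumor_hu_mean
  hu_clean[cord & body] <- 40
  sd_map <- array(0, dim = shp)
  sd_map[body & !lung] <- 15
  sd_map[lung & body & !tumor] <- spec$lung_hu_sd
  sd_map[tumor] <- spec$tumor_hu_sd
  hu <- hu_clean + sd_map * stats::rnorm(prod(shp))
  hu <- pmax(pmin(hu, 3000), -1000)
  ct <- ct_volume(array(hu, dim = shp), origin, sp)

  structures <- build_patient_contours(ax, tum_c, r_t, lung_c, lung_r)

  # primary dose: spherical sigmoid falloff around the tumor center,
  # normalized below so the PTV D95 equals the prescription
  r <- sqrt(r2_t)
  # sigmoid shoulder 4 mm outside the PTV radius: puts the PTV D95 near 80%
  # of the field maximum, i.e. an SBRT-like hot spot of ~125% of prescription
  r50 <- r_t + spec$margin_itv_mm + spec$margin_ptv_mm + 4
  dose0 <- 1 / (1 + exp((r - r50) / 3))
  ptps <- dose_grid(dose0, origin, sp)

  igtv_mask <- rasterize_structure(structures$structures$iGTV, ptps)
  itv_mask <- expand_margin(igtv_mask, spec$margin_itv_mm)
  ptv_mask <- expand_margin(itv_mask, spec$margin_ptv_mm)
  d95 <- dose_at_volume(cumulative_dvh(ptps, ptv_mask, 0.005, "PTV"), 95)
  ptps$values <- ptps$values * (spec$prescription_gy / d95)

  # secondary dose: density-dependent redistribution
  f <- pmin(pmax(-hu_clean / 1000, 0), 1)
  w_high <- ptps$values / max(ptps$values)
  stps_vals <- ptps$values *
    (1 - spec$density_coupling * f * w_high +
       spec$low_dose_bath * f * (1 - w_high))
  stps <- dose_grid(pmax(stps_vals, 0), origin, sp)

  list(ct = ct, structures = structures, ptps = ptps, stps = stps,
       isocenter_mm = tum_c, spec = spec,
       masks = list(iGTV = igtv_mask, ITV = itv_mask, PTV = ptv_mask))
}

# Planar contour stacks for the synthetic anatomy: circles for the iGTV and
# cord, ellipses for the lung and body, one polygon per intersected slice.
build_patient_contours <- function(ax, tum_c, r_t, lung_c, lung_r,
                                   n_vertices = 48) {
  circle <- function(cx, cy, r) {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  zs <- ax[[3]]
  contour_stack <- function(pred_r) {
    out <- list()
    for (z in zs) {
      g <- pred_r(z)
      if (!is.null(g)) out[[length(out) + 1L]] <- list(z = z, xy = g)
    }
    out
  }
  igtv <- contour_stack(function(z) {
    dz2 <- r_t^2 - (z - tum_c[3])^2
    if (dz2 <= 0) return(NULL)
    circle(tum_c[1], tum_c[2], sqrt(dz2))
  })
  lung_ct <- contour_stack(function(z) {
    s <- 1 - ((z - lung_c[3]) / lung_r[3])^2
    if (s <= 0.01) return(NULL)
    th <- seq(0, 2 * pi, length.out = 49)[-49]
    cbind(lung_c[1] + lung_r[1] * sqrt(s) * cos(th),
          lung_c[2] + lung_r[2] * sqrt(s) * sin(th))
  })
  cord <- contour_stack(function(z) circle(0, 45, 4))
  body <- contour_stack(function(z) {
    th <- seq(0, 2 * pi, length.out = 49)[-49]
    cbind(65 * cos(th), 55 * sin(th))
  })
  structure_set(list(
    iGTV = list(role = "iGTV", contours = igtv),
    lung = list(role = "lung", contours = lung_ct),
    spinal_cord = list(role = "spinal_cord", contours = cord),
    external = list(role = "external", contours = body)
  ))
}

#' Replace the secondary dose by an exact uniform shift
#'
#' Recovery harness: `sTPS := pTPS * (1 + shift_percent/100)` exactly, all
#' other fields untouched, so every target dosimetric error must equal
#' `shift_percent` up to numerical tolerance.
#'
#' @param base_case a patient case from [make_patient_case()].
#' @param shift_percent uniform relative shift, %; must be > -100.
#' @export
known_shift_case <- function(base_case, shift_percent) {
  if (shift_percent <= -100) stop("shift must be > -100%")
  out <- base_case
  out$stps <- dose_grid(base_case$ptps$values * (1 + shift_percent / 100),
                        base_case$ptps$origin, base_case$ptps$spacing)
  out
}

#' Draw per-case specifications for a synthetic patient cohort
#'
#' Case-to-case variation emulating a lung SBRT population: tumor radius
#' uniform on 5-13 mm, tumor HU normal around -250 (part-solid lesions),
#' lung HU normal around -700.  Sub-seeds are `seed + case index`.
#'
#' @param n number of cases (default 20 for desk-scale runtime).
#' @param seed cohort master seed.
#' @param base a [patient_case_spec()] supplying all other fields.
#' @return list of `patient_case_spec`s.
#' @export
patient_cohort_specs <- function(n = 20, seed = 1L,
                                 base = patient_case_spec()) {
  set.seed(seed)
  radii <- stats::runif(n, 5, 13)
  tum_hu <- pmin(pmax(stats::rnorm(n, -250, 100), -600), 100)
  lung_hu <- pmin(pmax(stats::rnorm(n, -700, 60), -900), -450)
  lapply(seq_len(n), function(i) {
    s <- base
    s$seed <- as.integer(seed + i)
    s$tumor_radius_mm <- radii[i]
    s$tumor_hu_mean <- tum_hu[i]
    s$lung_hu_mean <- lung_hu[i]
    s
  })
}

#' Draw per-case specifications for a synthetic phantom cohort
#'
#' @inheritParams patient_cohort_specs
#' @param base a [phantom_case_spec()].
#' @export
phantom_cohort_specs <- function(n = 20, seed = 1L,
                                 base = phantom_case_spec()) {
  lapply(seq_len(n), function(i) {
    s <- base
    s$seed <- as.integer(seed + i)
    s
  })
}
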