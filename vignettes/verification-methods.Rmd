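---
title: "Calculation-based verification of VMAT-SBRT lung plans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calculation-based verification of VMAT-SBRT lung plans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtverify)
```

## The verification problem

Patient-specific quality assurance (QA) of volumetric-modulated arc therapy
(VMAT) plans is conventionally measurement-based: the plan is delivered to a
phantom carrying a cylindrical diode array and the measured dose map is
compared against the planning system's calculation. For stereotactic body
radiotherapy (SBRT) of lung tumors this is time-consuming, and an attractive
alternative is *independent calculation-based verification*: the plan is
recalculated by a second treatment planning system (sTPS) with a different
dose engine, and the two calculations are compared — on a homogeneous
phantom geometry and, more importantly, on the patient's own CT, where
heterogeneity handling differs most between algorithm families.

`rtverify` implements the full analysis layer of such a verification
program:

1. **Phantom mode** — dose-difference (DD) and gamma-index comparisons of
   three distribution pairs on the unwrapped cylinder of a diode array:
   primary vs secondary calculation (*pattern 1*), primary vs measurement
   (*pattern 2*), secondary vs measurement (*pattern 3*), with passing
   rates above the 10% isodose and fail-point extraction.
2. **Fail-point resemblance** — Simpson's Faunal Resemblance Index (FRI)
   between fail-point sets, `FRI = |X ∩ Y| / min(|X|, |Y|)`, quantifying
   whether calculation-only comparisons predict where measurement-based QA
   would fail.
3. **Patient mode** — dose-volume histogram (DVH) indices for the internal
   gross tumor volume (iGTV), planning target volume (PTV), normal lung and
   spinal cord on both calculations, summarized as dosimetric errors
   `DE = (D_sTPS − D_pTPS)/D_pTPS × 100` and volumetric errors
   `VE = (V_sTPS − V_pTPS)/V_pTPS × 100`, with cohort tolerance levels
   (mean ± SD), paired t-tests, and Pearson correlations of the errors
   against PTV size and PTV Hounsfield-unit (HU) statistics.

No dose engine is included: the package consumes paired dose grids (and
optionally a detector measurement) and emulates them synthetically for
testing.

## Comparison metrics

**Normalization.** All dose criteria are *global*: differences are
expressed as a percentage of a single normalization dose, by default the
maximum of the reference distribution (a prescription dose can be
configured instead). The reference role is explicit and recorded: the
primary calculation for pattern 1, the measurement for patterns 2 and 3.
Symmetry is never assumed.

**Dose difference.** `DD(r) = |D_eval(r) − D_ref(r)| / D_norm × 100`; a
point passes DD3%/DD5% when the value is at most 3/5. Points where the
reference is below `low_dose_threshold` (default 0.10, the 10% isodose) are
not evaluated.

**Gamma index.** The generalized gamma with global dose normalization:

γ(r) = min over r′ of sqrt( (ΔD/δ)² + (|r′ − r|/Δd)² )

with dose criterion δ (% of normalization) and distance criterion Δd (mm);
a point passes when γ ≤ 1. The minimization is an exhaustive search over a
*local fine lattice* centered on each reference point: per-axis offsets in
multiples of `interp_step_fraction × Δd` (default 1/10) out to
`search_radius_factor × Δd` (default 3), with the evaluated distribution
interpolated bi-/tri-linearly at each candidate. The kernel (C++) visits
offsets in order of increasing distance and stops when the distance term
alone exceeds the current best γ² — a pruning that cannot change the
minimum over the identical candidate set. Because the zero offset is always
a candidate, γ ≤ DD/δ holds pointwise. On detector maps the azimuthal axis
is cyclic: the distance search wraps across the seam of the unwrapped
cylinder.

The search lattice is a numerical choice with a visible consequence: a
feature displaced by exactly one diode pitch is matched perfectly only when
the search step divides the pitch; otherwise the recovered dose is an
interpolated value and γ is slightly overestimated (at most by the lattice
resolution). The test suite pins both behaviors.

**Detector geometry.** The cylindrical array is emulated as a regular
axial × azimuthal lattice (defaults: 105 mm radius, 10 mm pitch, giving 66
columns), not the vendor's 1386-diode helical layout. This preserves the
unwrapped-cylinder topology that the comparison and the fail-point identity
need, which is all the downstream analysis uses.

## Fail points and Simpson's resemblance index

A fail-point set is the set of evaluated lattice indices exceeding a
criterion. FRI divides the intersection size by the *smaller* set size, so
it is the overlap statistic least sensitive to unequal fail counts: it is 1
whenever one set contains the other and 0 for disjoint sets. Cases where
either operand is empty (a 100% passing rate) carry no information about
co-location; they are flagged *excluded* — never coerced to 0 or 1 — and
cohort summaries report the excluded count alongside mean ± SD, max and
min. When only one operand is empty the comparison is likewise excluded,
since the quotient is undefined either way.

## DVH verification

DVHs are exact voxel-counting cumulative histograms with a default bin
width of 0.01 Gy — at SBRT dose levels (~50 Gy) the quantile error from
binning is negligible, and all round-trips (`dose_at_volume` vs
`volume_at_dose`) hold within one bin. `D_x%` is the minimum dose to the
hottest x% of the structure (linear interpolation between bin edges);
`V_xGy` the percent volume at or above x Gy. `Dmax` is the hottest single
voxel (no small-volume variant) and `Dmean` the arithmetic voxel mean.
"Lung" always means normal lung: the lung mask minus the iGTV mask,
a set-difference computed after rasterizing both on the dose grid.

Structures arrive as planar contour stacks and are rasterized by
voxel-center membership under the even-odd rule (nested contours are
holes); there is no partial-volume weighting. Margins grow masks
isotropically in physical millimetres — a voxel enters the expansion when
its center lies within the margin of *some input-mask voxel center* — which
respects anisotropic spacing. Two lattice facts are worth knowing and are
asserted in the tests: (a) expansion composed in two steps is a subset of
the one-shot expansion (the intermediate point must be a lattice center),
with near-equality on convex masks; (b) the expanded digital sphere
undershoots the analytic enlarged sphere by a fraction of a voxel in
radius (about −4% in volume for r = 10 + 5 mm at 1 mm spacing). The
alternative — measuring distance to the voxel *region* rather than its
center — would trade this small systematic deficit for an overshoot; the
center rule was kept because it is exactly testable against a brute-force
distance scan.

Error metrics follow the sign convention "secondary minus primary": DE < 0
means the independent calculation reports less dose. Tolerance levels are
cohort mean ± sample SD (n − 1). Pearson correlations are classified weak
(0 < |CC| < 0.4), moderate (0.4 ≤ |CC| < 0.8) and strong (0.8 ≤ |CC| ≤ 1);
both boundaries belong to the higher class, zero variance yields an
explicit undefined marker. Paired two-sided t-tests flag significance at
p < 0.05; zero-variance differences produce a degenerate marker rather
than a p-value.

## The synthetic world

The generators produce the *stated* conditions of the verification program,
not tuned reproductions of any clinical cohort.

**Phantom triplets** (`make_phantom_case`). A base field of smooth Gaussian
lobes (maximum 10 Gy) stands in for the accumulated arc dose. The secondary
calculation differs from the primary by a smooth random field whose SD over
the evaluated detector samples is `tps_discrepancy_sd` (default 1.3% of the
detector-map maximum — inter-algorithm model error on homogeneous media is
small). The delivered ("measured") dose differs from *both* calculations by
a larger spatially correlated systematic (`model_error_sd`, default 2.6%)
plus independent per-diode noise (0.7%): delivery uncertainty exceeds
inter-algorithm disagreement. Amplitudes are calibrated on the detector
surface because that is where the comparison is normalized. These three
scales are the whole story behind the expected orderings: pattern 1 passes
best; pattern-1 fail points (where the two calculations disagree) reappear
in pattern 3 (which contains the same disagreement plus the systematic) far
more often than in pattern 2 — so FRI(1,3) ≥ FRI(1,2), which is exactly
the property that makes calculation-only QA informative about measurement
fails.

**Patient cases** (`make_patient_case`). A water-HU elliptical body holds
an air-like lung (HU ≈ −700 ± 120), a spherical solid tumor (the iGTV,
default radius 8 mm, HU ≈ −300 ± 80 — part-solid lesions dominate lung SBRT
cohorts) and a posterior spinal cord. ITV = iGTV + 3 mm and
PTV = ITV + 5 mm by isotropic expansion. The primary dose is a spherical
sigmoid falloff around the tumor, rescaled so the PTV D95 equals the
prescription (default 50 Gy in 4 fractions, the modal lung-SBRT regimen),
leaving an SBRT-like internal hot spot of ~125% of prescription. The
secondary dose applies a density-dependent redistribution:

D_s = D_p × (1 − c·f(HU)·w + e·f(HU)·(1 − w)),  f(HU) = clamp(−HU/1000, 0, 1),  w = D_p/D_max

with `density_coupling` c = 0.05 and `low_dose_bath` e = 0.15. This is a
two-parameter cartoon of what improved lateral electron-transport modelling
does in low-density tissue: dose is removed from the high-dose region
(negative target DEs, smallest at the isocenter where the tissue is most
solid) and reappears as a diffuse low-dose bath in the lung (positive lung
V5/V10/Dmean errors, near-neutral V20). Because the suppression is a
function of HU, cohorts in which tumor radius and HU vary (uniform radius
5–13 mm; tumor HU ~ N(−250, 100); lung HU ~ N(−700, 60)) show the expected
correlation structure without further assumptions: target DE correlates
positively with mean PTV HU, and more strongly with HU than with PTV size.
Default cohort size is 20 (a desk-scale stand-in for a ~50-plan clinical
audit; `n` is a parameter).

What the generator does **not** emulate: respiratory motion and 4D-CT
artifacts, beam modelling, MLC/arc deliverability, detector angular
response, dose-to-medium vs dose-to-water conventions, or any quantitative
algorithm-difference model. A green cohort test therefore establishes that
the *analysis* reproduces the sign and ordering structure the program
assumes — never that a clinical cohort would yield particular numbers.

## Numerical choices and degenerate inputs

* Grids are axis-aligned with `origin` at the first voxel **center**
  (DICOM convention); anything non-axis-aligned is rejected loudly.
* Dose files store integers with a `dose_grid_scaling` quantum (round-trip
  error ≤ 1 quantum) in a plain JSON dialect carrying the RT-Dose tags;
  missing scaling, non-Gy units and non-identity orientations are hard
  errors.
* All-zero reference distributions have no normalization dose → error;
  comparisons with zero evaluated points cannot yield a passing rate →
  error; empty masks cannot yield a DVH → error; missing structures yield
  NA-marked indices, never silent zeros.
* Resampling marks target voxels outside the source extent invalid and
  excludes them from every downstream statistic.
* Generator determinism: a single `set.seed(spec$seed)` precedes a
  documented draw order; equal seeds give bit-identical cases across
  platforms, and cohort sub-seeds are `seed + case_index`.

## Known limitations

* Fail-point intersection is exact index equality; there is no spatial
  "near-miss" tolerance.
* Gamma supports the global dose criterion only (no local-difference mode),
  and no detector corrections (angular dependence, field-size factors) are
  applied.
* The clinical tables of a real audit (passing-rate magnitudes, DE/VE
  extrema) depend on actual plans and are out of reach of the synthetic
  world by design; the package reproduces their structure, signs and
  orderings.
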