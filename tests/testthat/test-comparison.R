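make_map <- function(vals, row_sp = 5) {
  nc <- ncol(vals)
  detector_map(vals, diode_spacing = row_sp,
               cylinder_radius = nc * row_sp / (2 * pi))
}

test_that("criteria construction and label parsing", {
  cr <- parse_criteria(c("dd3", "dd5", "g2/2", "g3/2", "g3/3"))
  expect_equal(cr$dd3$dose_criterion, 3)
  expect_equal(cr$dd3$mode, "dose_difference")
  expect_equal(cr$`g3/2`$distance_criterion, 2)
  expect_equal(cr$`g3/2`$mode, "gamma")
  expect_equal(cr$dd5$low_dose_threshold, 0.10)
  expect_error(comparison_criteria(0), "> 0")
  expect_error(comparison_criteria(3, mode = "gamma"), "distance")
  expect_error(comparison_criteria(3, low_dose_threshold = 1), "0, 1")
  expect_error(parse_criteria("nope"), "parse")
})

test_that("normalization_dose is the reference maximum", {
  expect_equal(normalization_dose(uniform_grid(2)), 2)
  v <- array(1, c(4, 4, 4)); v[2, 3, 1] <- 10.5
  expect_equal(normalization_dose(dose_grid(v)), 10.5)
  expect_error(normalization_dose(uniform_grid(0)), "all-zero")
})

test_that("dose_difference_map: formula, threshold, passing rate", {
  set.seed(5)
  base <- matrix(runif(80, 1, 10), 8, 10)
  ref <- make_map(base)
  cr3 <- parse_criteria("dd3")[[1]]; cr5 <- parse_criteria("dd5")[[1]]
  # identical inputs: all zeros, 100% pass
  m0 <- dose_difference_map(ref, ref, cr3)
  expect_true(all(m0$values[m0$evaluated] == 0))
  expect_equal(passing_rate(m0), 100)
  # uniform +4% of each point: at the max the difference is 4% of norm,
  # so DD3 fails there but DD5 passes everywhere
  ev <- make_map(base * 1.04)
  m3 <- dose_difference_map(ref, ev, cr3)
  m5 <- dose_difference_map(ref, ev, cr5)
  imax <- which.max(base)
  expect_equal(m3$values[imax], 4, tolerance = 1e-9)
  expect_lt(passing_rate(m3), 100)
  expect_equal(passing_rate(m5), 100)
  # hand-checked map values: |eval - ref| / max(ref) * 100
  expect_equal(m3$values[m3$evaluated],
               (abs(base * 0.04) / max(base) * 100)[m3$evaluated])
  # low-dose exclusion: points under 10% of norm are not evaluated
  base2 <- base; base2[1:4, 1] <- 0.05 * max(base)
  r2 <- make_map(base2)
  m2 <- dose_difference_map(r2, r2, cr3)
  expect_false(any(m2$evaluated[1:4, 1]))
  expect_equal(sum(m2$evaluated), sum(base2 >= 0.1 * max(base2)))
  # shrinking the threshold never removes evaluated points
  cr_lo <- comparison_criteria(3, low_dose_threshold = 0.02)
  m_lo <- dose_difference_map(r2, r2, cr_lo)
  expect_true(all(m2$evaluated <= m_lo$evaluated))
  # geometry mismatch errors
  expect_error(dose_difference_map(ref, make_map(base[1:4, ]), cr3),
               "layout")
})

test_that("passing_rate arithmetic and empty-evaluated error", {
  vals <- matrix(5, 6, 10); vals[1, 1:3] <- 5.4   # 3 points at 8% diff
  ref <- make_map(matrix(5, 6, 10))
  m <- dose_difference_map(ref, make_map(vals), parse_criteria("dd3")[[1]])
  expect_equal(sum(m$evaluated), 60)
  expect_equal(passing_rate(m), 95.0)
  # with an external normalization no point clears the threshold
  ref0 <- make_map(matrix(c(10, rep(0.1, 59)), 6, 10))
  m0 <- dose_difference_map(ref0, ref0,
                            comparison_criteria(3, low_dose_threshold = 0.5),
                            normalization = 1000)
  expect_error(passing_rate(m0), "evaluated")
})

test_that("extract_fail_points matches per-point enumeration", {
  set.seed(9)
  base <- matrix(runif(60, 2, 9), 6, 10)
  ref <- make_map(base)
  ev <- make_map(base * 1.04)
  cr <- parse_criteria("dd3")[[1]]
  m <- dose_difference_map(ref, ev, cr)
  fp <- extract_fail_points(m)
  # oracle: enumerate |diff|/norm > 3% among evaluated points
  dd <- abs(base * 0.04) / max(base) * 100
  expected <- which(m$evaluated & dd > 3)
  expect_identical(fp$indices, expected)
  expect_equal(fp$n_evaluated, sum(m$evaluated))
  # 100% pass yields the empty set
  expect_length(extract_fail_points(dose_difference_map(ref, ref, cr))$indices,
                0)
})

test_that("gamma analytic cases: identity and uniform offset", {
  base <- matrix(6, 10, 12)
  base[5, 6] <- 8   # a peak so the field is not totally flat
  ref <- make_map(base)
  cr32 <- parse_criteria("g3/2")[[1]]
  g0 <- gamma_map(ref, ref, cr32)
  expect_true(all(g0$values[g0$evaluated] == 0))
  expect_equal(passing_rate(g0), 100)
  # spatially uniform discrepancy of 2% of norm: distance search cannot
  # help, so gamma = 2/3 everywhere under 3%/2mm
  flat <- make_map(matrix(5, 8, 10))
  off <- make_map(matrix(5, 8, 10) + 0.02 * 5)
  g <- gamma_map(flat, off, cr32)
  expect_equal(unname(g$values[g$evaluated]),
               rep(2 / 3, sum(g$evaluated)), tolerance = 1e-9)
})

test_that("1-D step profile shifted 1.5 mm matches brute-force gamma", {
  # a sharp edge moved by 1.5 mm: gamma must find the matching dose within
  # the 2 mm distance criterion instead of reporting a huge dose difference
  nr <- 1; nc <- 40; sp <- 1.5
  prof <- function(edge_col) {
    x <- (seq_len(nc) - 1) * sp
    10 / (1 + exp((x - edge_col) / 2))
  }
  ref <- detector_map(matrix(prof(24), nr, nc), diode_spacing = sp,
                      cylinder_radius = nc * sp / (2 * pi))
  ev <- detector_map(matrix(prof(25.5), nr, nc), diode_spacing = sp,
                     cylinder_radius = nc * sp / (2 * pi))
  cr <- parse_criteria("g3/2")[[1]]
  g <- gamma_map(ref, ev, cr, search_radius_factor = 3,
                 interp_step_fraction = 0.1)
  ora <- oracle_gamma_detector(ref, ev, cr, 3, 0.1)
  expect_equal(as.numeric(g$values[g$evaluated]),
               as.numeric(ora[g$evaluated]), tolerance = 1e-6)
  expect_true(all(g$values[g$evaluated] < 1))
})

test_that("gamma equals brute-force oracle on random detector pairs", {
  set.seed(21)
  cr <- parse_criteria("g3/2")[[1]]
  for (trial in 1:5) {
    pr <- random_detector_pair(12, 16, row_sp = 4, noise = 0.04)
    g <- gamma_map(pr$ref, pr$eval, cr, search_radius_factor = 2,
                   interp_step_fraction = 0.25)
    ora <- oracle_gamma_detector(pr$ref, pr$eval, cr, 2, 0.25)
    expect_equal(as.numeric(g$values[g$evaluated]),
                 as.numeric(ora[g$evaluated]), tolerance = 1e-6)
  }
})

test_that("gamma equals brute-force oracle on 3-D grids", {
  set.seed(31)
  cr <- parse_criteria("g3/2")[[1]]
  for (trial in 1:2) {
    pr <- random_grid_pair(c(10, 10, 8), c(2, 2, 2), noise = 0.04)
    g <- gamma_map(pr$ref, pr$eval, cr, search_radius_factor = 2,
                   interp_step_fraction = 0.3)
    ora <- oracle_gamma_grid(pr$ref, pr$eval, cr, 2, 0.3)
    expect_equal(as.numeric(g$values[g$evaluated]),
                 as.numeric(ora[g$evaluated]), tolerance = 1e-6)
  }
})

test_that("gamma is bounded by the scaled dose difference pointwise", {
  set.seed(41)
  for (trial in 1:3) {
    pr <- random_detector_pair(10, 14, noise = 0.05)
    cr_g <- parse_criteria("g3/2")[[1]]
    cr_d <- parse_criteria("dd3")[[1]]
    g <- gamma_map(pr$ref, pr$eval, cr_g)
    d <- dose_difference_map(pr$ref, pr$eval, cr_d)
    ev <- g$evaluated
    expect_true(all(g$values[ev] <= d$values[ev] / 3 + 1e-9))
  }
})

test_that("wrap-around: a feature shifted across the seam still matches", {
  nr <- 6; nc <- 24; sp <- 2
  R <- nc * sp / (2 * pi)
  base <- matrix(5, nr, nc)
  bump_ref <- base; bump_ref[, 1] <- 9      # feature at azimuth column 1
  bump_ev <- base; bump_ev[, nc] <- 9       # moved to the last column
  ref <- detector_map(bump_ref, diode_spacing = sp, cylinder_radius = R)
  ev <- detector_map(bump_ev, diode_spacing = sp, cylinder_radius = R)
  cr <- parse_criteria("g3/3")[[1]]
  # search step chosen to land exactly on the 2 mm column pitch so the
  # cross-seam match is found without interpolation loss
  g <- gamma_map(ref, ev, cr, interp_step_fraction = 1 / 15)
  # the columns are 2 mm apart across the seam: gamma at the feature is
  # dominated by the 2/3 distance term, far below the >20% dose difference
  expect_lt(max(g$values[, 1]), 1)
  d <- dose_difference_map(ref, ev, parse_criteria("dd5")[[1]])
  expect_gt(max(d$values[, 1], na.rm = TRUE), 5)
  # and the 2-D map agrees with the wrap-aware brute-force oracle
  ora <- oracle_gamma_detector(ref, ev, cr, 3, 1 / 15)
  expect_equal(as.numeric(g$values[g$evaluated]),
               as.numeric(ora[g$evaluated]), tolerance = 1e-6)
})

test_that("criteria monotonicity on random pairs", {
  set.seed(51)
  for (trial in 1:5) {
    pr <- random_detector_pair(10, 16, noise = 0.04)
    p <- function(lb) {
      cr <- parse_criteria(lb)[[1]]
      m <- if (cr$mode == "gamma") gamma_map(pr$ref, pr$eval, cr)
           else dose_difference_map(pr$ref, pr$eval, cr)
      passing_rate(m)
    }
    expect_gte(p("dd5"), p("dd3"))
    expect_gte(p("g3/2"), p("g2/2"))
    expect_gte(p("g3/3"), p("g3/2"))
  }
})

test_that("compare_on_detector dispatches and validates", {
  pr <- random_detector_pair(8, 12)
  m <- compare_on_detector(pr$ref, pr$eval, parse_criteria("dd3")[[1]])
  expect_s3_class(m, "comparison_map")
  expect_equal(passing_rate(compare_on_detector(pr$ref, pr$ref,
                                                parse_criteria("g3/2")[[1]])),
               100)
  expect_error(compare_on_detector(uniform_grid(1), pr$eval,
                                   parse_criteria("dd3")[[1]]),
               "sample")
})

test_that("comparison_map_table exports a consistent CSV", {
  pr <- random_detector_pair(6, 8)
  m <- dose_difference_map(pr$ref, pr$eval, parse_criteria("dd3")[[1]])
  path <- tempfile(fileext = ".csv")
  comparison_map_table(m, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), length(m$values))
  expect_equal(sum(df$evaluated), sum(m$evaluated))
  expect_equal(100 * sum(df$pass) / sum(df$evaluated), passing_rate(m))
})
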