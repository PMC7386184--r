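test_that("dose_grid enforces its invariants", {
  v <- array(1, dim = c(2, 2, 2))
  expect_s3_class(dose_grid(v, spacing = c(1, 1, 2.5)), "dose_grid")
  expect_error(dose_grid(v, spacing = c(0, 1, 1)), "spacing")
  expect_error(dose_grid(array(-1, dim = c(2, 2, 2))), ">= 0")
  expect_error(dose_grid(array(NA_real_, dim = c(2, 2, 2))), "finite")
  expect_error(dose_grid(matrix(1, 2, 2)), "3-D")
  # frame identity: equal geometry iff equal frame_id
  a <- dose_grid(v, origin = c(1, 2, 3), spacing = c(1, 1, 2))
  b <- dose_grid(v * 2, origin = c(1, 2, 3), spacing = c(1, 1, 2))
  d <- dose_grid(v, origin = c(1, 2, 3.5), spacing = c(1, 1, 2))
  expect_identical(a$frame_id, b$frame_id)
  expect_false(identical(a$frame_id, d$frame_id))
})

test_that("point_dose: voxel centers exact, ramp midpoint, outside errors", {
  vals <- array(0, dim = c(5, 4, 3))
  vals[] <- seq_len(length(vals))
  g <- dose_grid(vals, origin = c(10, -5, 0), spacing = c(2, 3, 2.5))
  ax <- grid_axes(g)
  # every voxel center reproduces its stored value exactly
  for (trial in 1:20) {
    i <- sample(5, 1); j <- sample(4, 1); k <- sample(3, 1)
    expect_identical(point_dose(g, c(ax[[1]][i], ax[[2]][j], ax[[3]][k])),
                     vals[i, j, k])
  }
  # midpoint of a linear ramp is the arithmetic mean of neighbours
  mid <- c(ax[[1]][2] + 1, ax[[2]][1], ax[[3]][1])
  expect_equal(point_dose(g, mid), (vals[2, 1, 1] + vals[3, 1, 1]) / 2)
  expect_error(point_dose(g, c(ax[[1]][1] - 1, ax[[2]][1], ax[[3]][1])),
               "outside")
})

test_that("resample_dose reproduces affine fields and flags outside points", {
  ax <- list(0:9, 0:9, 0:7)
  X <- array(ax[[1]], c(10, 10, 8))
  Y <- aperm(array(ax[[2]], c(10, 10, 8)), c(2, 1, 3))
  Z <- aperm(array(ax[[3]], c(8, 10, 10)), c(2, 3, 1))
  lin <- 2 + 0.5 * X + 0.25 * Y + 1.5 * Z
  g <- dose_grid(lin, c(0, 0, 0), c(1, 1, 1))
  # identical geometry is a no-op
  expect_identical(resample_dose(g, g), g)
  # trilinear is exact on affine fields at shifted sub-voxel targets
  tgt <- dose_grid(array(0, c(6, 6, 5)), origin = c(0.3, 1.7, 0.9),
                   spacing = c(1.2, 1.1, 1.0))
  rs <- resample_dose(g, tgt)
  axt <- grid_axes(tgt)
  expected <- 2 + 0.5 * axt[[1]][slice.index(rs$values, 1)] +
    0.25 * axt[[2]][slice.index(rs$values, 2)] +
    1.5 * axt[[3]][slice.index(rs$values, 3)]
  expect_equal(as.numeric(rs$values), as.numeric(expected), tolerance = 1e-12)
  # a target extending beyond the source marks outside voxels invalid
  big <- dose_grid(array(0, c(14, 6, 5)), origin = c(-2, 0, 0),
                   spacing = c(1, 1, 1))
  rs2 <- resample_dose(g, big)
  expect_false(is.null(rs2$valid))
  expect_true(all(is.na(rs2$values[!rs2$valid])))
  expect_false(any(rs2$valid[1:2, , ]))   # x = -2, -1 lie outside
  expect_true(all(rs2$valid[3:11, , ]))
})

test_that("rtdose round-trip preserves geometry exactly and dose to quantum", {
  set.seed(7)
  vals <- array(runif(4 * 3 * 2, 0, 55), dim = c(4, 3, 2))
  g <- dose_grid(vals, origin = c(-10, 4, 2), spacing = c(2, 2, 2.5))
  path <- tempfile(fileext = ".json")
  write_rtdose(g, path)
  g2 <- read_rtdose(path)
  expect_identical(g2$origin, g$origin)
  expect_identical(g2$spacing, g$spacing)
  q <- jsonlite::read_json(path)$dose_grid_scaling
  expect_lt(max(abs(g2$values - g$values)), q + 1e-12)
  # explicit scaling example: stored 50000 at 1e-3 Gy/unit reads as 50 Gy
  write_rtdose(g, path, scaling = 1e-3)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$stored_values[1] <- 50000
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  expect_equal(read_rtdose(path)$values[1, 1, 1], 50.0)
})

test_that("read_rtdose rejects malformed files", {
  g <- uniform_grid(2, shape = c(1, 1, 1))
  path <- tempfile(fileext = ".json")
  write_rtdose(g, path)                     # 1x1x1 degenerate grid is fine
  expect_equal(read_rtdose(path)$values[1, 1, 1], 2, tolerance = 1e-8)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$dose_grid_scaling <- NULL
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_rtdose(path), "scaling")
  j$dose_grid_scaling <- 1e-3; j$unit <- "CGY"
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_rtdose(path), "CGY")
  j$unit <- "GY"; j$orientation <- c(0, 1, 0, 1, 0, 0)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_rtdose(path), "axis-aligned")
  suppressWarnings(
    expect_error(write_rtdose(g, file.path(tempdir(), "no/such/dir/x.json"))))
})

test_that("rasterization matches winding-number oracle on voxel centers", {
  set.seed(11)
  geo <- uniform_grid(0, shape = c(24, 24, 4), spacing = c(2, 2, 2))
  ax <- grid_axes(geo)
  for (trial in 1:5) {
    poly <- random_star_polygon(mean(ax[[1]]), mean(ax[[2]]), 6, 18)
    m <- rasterize_structure(list(list(z = ax[[3]][2], xy = poly)), geo)
    ora <- outer(ax[[1]], ax[[2]], Vectorize(function(x, y)
      oracle_point_in_poly(x, y, poly[, 1], poly[, 2])))
    expect_identical(m$flags[, , 2], ora)
    expect_false(any(m$flags[, , -2]))
  }
})

test_that("rasterization handles spheres, holes, empties and bad planes", {
  # empty structure -> empty mask
  geo <- uniform_grid(0, shape = c(10, 10, 5))
  expect_equal(sum(rasterize_structure(list(), geo)$flags), 0)
  # digital sphere r = 20 mm on a 1 mm grid: volume within 2% of analytic
  geo <- uniform_grid(0, shape = c(45, 45, 45), origin = c(-22, -22, -22))
  ct <- lapply(grid_axes(geo)[[3]], function(z) {
    r2 <- 20^2 - z^2
    if (r2 <= 0) return(NULL)
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    list(z = z, xy = cbind(sqrt(r2) * cos(th), sqrt(r2) * sin(th)))
  })
  ct <- Filter(Negate(is.null), ct)
  m <- rasterize_structure(ct, geo)
  expect_equal(sum(m$flags) * 1.0, 4 / 3 * pi * 20^3, tolerance = 0.02)
  # nested contour carves a hole (even-odd rule)
  geo2 <- uniform_grid(0, shape = c(21, 21, 1), origin = c(-10, -10, 0))
  sq <- function(h) cbind(c(-h, h, h, -h), c(-h, -h, h, h))
  m2 <- rasterize_structure(list(list(z = 0, xy = sq(8)),
                                 list(z = 0, xy = sq(4))), geo2)
  expect_true(m2$flags[11 + 6, 11, 1])     # in the ring
  expect_false(m2$flags[11, 11, 1])        # in the hole
  # square on the voxel-center lattice: count = interior lattice points
  m3 <- rasterize_structure(list(list(z = 0, xy = sq(3.5))), geo2)
  expect_equal(sum(m3$flags), 7^2)
  # off-slice contour plane errors
  expect_error(rasterize_structure(list(list(z = 3.4, xy = sq(2))), geo2),
               "slice")
})

test_that("expand_margin: identity, analytic sphere, anisotropic oracle", {
  # margin 0 is the identity
  geo <- uniform_grid(0, shape = c(9, 9, 9))
  f <- array(FALSE, c(9, 9, 9)); f[4:6, 4:6, 4:6] <- TRUE
  m <- voxel_mask(f, geo)
  expect_identical(expand_margin(m, 0)$flags, m$flags)
  expect_error(expand_margin(m, -1), ">= 0")
  # sphere r = 6 + margin 3 on 1 mm grid: exact agreement with a chunked
  # brute-force union-of-balls oracle (min distance to any input center)
  geo <- uniform_grid(0, shape = c(21, 21, 21), origin = c(-10, -10, -10))
  ax <- grid_axes(geo)
  X <- array(ax[[1]], c(21, 21, 21))
  Y <- aperm(array(ax[[2]], c(21, 21, 21)), c(2, 1, 3))
  Z <- aperm(array(ax[[3]], c(21, 21, 21)), c(2, 3, 1))
  sph <- voxel_mask(X^2 + Y^2 + Z^2 <= 6^2, geo)
  grown <- expand_margin(sph, 3)
  C <- cbind(X[sph$flags], Y[sph$flags], Z[sph$flags])
  P <- cbind(as.numeric(X), as.numeric(Y), as.numeric(Z))
  mind2 <- rep(Inf, nrow(P))
  for (chunk in split(seq_len(nrow(P)), ceiling(seq_len(nrow(P)) / 2000))) {
    D <- outer(rowSums(P[chunk, ]^2), rowSums(C^2), "+") -
      2 * P[chunk, ] %*% t(C)
    mind2[chunk] <- apply(D, 1, min)
  }
  expect_identical(as.numeric(grown$flags), as.numeric(mind2 <= 9 + 1e-9))
  # single voxel, anisotropic spacing: exhaustive distance-scan oracle
  geo <- uniform_grid(0, shape = c(13, 13, 7), spacing = c(1, 1, 2.5))
  f <- array(FALSE, c(13, 13, 7)); f[7, 7, 4] <- TRUE
  g1 <- expand_margin(voxel_mask(f, geo), 5)
  ax <- grid_axes(geo)
  ora <- array(FALSE, c(13, 13, 7))
  for (i in 1:13) for (j in 1:13) for (k in 1:7)
    ora[i, j, k] <- (ax[[1]][i] - ax[[1]][7])^2 + (ax[[2]][j] - ax[[2]][7])^2 +
      (ax[[3]][k] - ax[[3]][4])^2 <= 25 + 1e-9
  expect_identical(g1$flags, ora)
})

test_that("expand_margin is monotone and composes sub-additively", {
  set.seed(3)
  geo <- uniform_grid(0, shape = c(16, 16, 10), spacing = c(2, 2, 2))
  for (trial in 1:5) {
    fa <- array(runif(prod(c(16, 16, 10))) < 0.04, c(16, 16, 10))
    fb <- fa | (array(runif(prod(c(16, 16, 10))) < 0.04, c(16, 16, 10)))
    A <- voxel_mask(fa, geo); B <- voxel_mask(fb, geo)
    expect_true(all(expand_margin(A, 4)$flags <= expand_margin(B, 4)$flags))
    expect_true(all(A$flags <= expand_margin(A, 4)$flags))
    # on a lattice, composed expansion can only lose points relative to the
    # one-shot expansion (the intermediate point must be a lattice center)
    two <- expand_margin(expand_margin(A, 3), 4)
    one <- expand_margin(A, 7)
    expect_true(all(two$flags <= one$flags))
  }
  # near-equality on a convex mask: the one-shot result exceeds the composed
  # one by at most a one-voxel boundary shell
  geo1 <- uniform_grid(0, shape = c(31, 31, 31), origin = c(-15, -15, -15))
  ax <- grid_axes(geo1)
  X <- array(ax[[1]], c(31, 31, 31))
  Y <- aperm(array(ax[[2]], c(31, 31, 31)), c(2, 1, 3))
  Z <- aperm(array(ax[[3]], c(31, 31, 31)), c(2, 3, 1))
  sph <- voxel_mask(X^2 + Y^2 + Z^2 <= 5^2, geo1)
  two <- expand_margin(expand_margin(sph, 3), 4)
  one <- expand_margin(sph, 7)
  expect_true(all(two$flags <= one$flags))
  shell <- expand_margin(two, sqrt(3) * max(geo1$spacing))
  expect_true(all(one$flags <= shell$flags))
})

test_that("mask set-difference realizes lung-minus-iGTV", {
  geo <- uniform_grid(0, shape = c(6, 6, 2))
  a <- array(FALSE, c(6, 6, 2)); a[1:4, , ] <- TRUE
  b <- array(FALSE, c(6, 6, 2)); b[3:6, , ] <- TRUE
  d <- mask_difference(voxel_mask(a, geo), voxel_mask(b, geo))
  expect_identical(d$flags, a & !b)
  other <- uniform_grid(0, shape = c(6, 6, 2), origin = c(1, 0, 0))
  expect_error(mask_difference(voxel_mask(a, geo), voxel_mask(b, other)),
               "frame")
})
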