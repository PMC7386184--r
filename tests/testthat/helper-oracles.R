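# Independent brute-force oracles used across the suite.  These deliberately
# re-derive results through different algorithms (shift-map minimisation,
# direct winding tests, sorting) than the implementation under test.

# --- gamma oracles -----------------------------------------------------------
# Shift-map formulation: for every lattice offset, interpolate the whole
# evaluated distribution at (point + offset) in one vectorized pass and fold
# a pointwise minimum of the composite metric.  Same candidate-lattice
# definition as the kernels (per-axis multiples of `step` within `radius`),
# different algorithm and code path.

oracle_offsets <- function(step, radius, ndim) {
  K <- floor(radius / step + 1e-9)
  g <- do.call(expand.grid, rep(list((-K:K) * step), ndim))
  d <- sqrt(rowSums(g^2))
  as.matrix(g[d <= radius + 1e-9, , drop = FALSE])
}

# bilinear sample of a detector map at fractional (row, col) positions given
# in physical mm; azimuth wraps, axial positions outside return NA
oracle_interp_detector <- function(vals, row_sp, col_sp, r_mm, c_mm) {
  nr <- nrow(vals); nc <- ncol(vals)
  fi <- r_mm / row_sp
  out <- rep(NA_real_, length(fi))
  ok <- fi >= -1e-9 & fi <= nr - 1 + 1e-9
  fi <- pmin(pmax(fi, 0), nr - 1)
  i0 <- pmin(floor(fi), max(nr - 2, 0)); ti <- fi - i0
  i1 <- pmin(i0 + 1, nr - 1)
  circ <- nc * col_sp
  cw <- c_mm - floor(c_mm / circ) * circ
  fj <- cw / col_sp
  j0 <- floor(fj) %% nc; tj <- fj - floor(fj)
  j1 <- (j0 + 1) %% nc
  idx <- function(i, j) vals[1 + i + nr * j]
  v <- idx(i0, j0) * (1 - ti) * (1 - tj) + idx(i1, j0) * ti * (1 - tj) +
       idx(i0, j1) * (1 - ti) * tj + idx(i1, j1) * ti * tj
  out[ok] <- v[ok]
  out
}

oracle_gamma_detector <- function(ref, eval, criteria, radius_factor, step_frac,
                                  normalization = NULL) {
  norm <- if (is.null(normalization)) max(ref$values) else normalization
  dd_abs <- criteria$dose_criterion / 100 * norm
  dc <- criteria$distance_criterion
  offs <- oracle_offsets(step_frac * dc, radius_factor * dc, 2)
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  pos_r <- (matrix(seq_len(nr), nr, nc) - 1) * ref$diode_spacing
  pos_c <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - 1) * ref$arc_spacing
  best <- matrix(Inf, nr, nc)
  for (o in seq_len(nrow(offs))) {
    de <- oracle_interp_detector(eval$values, ref$diode_spacing,
                                 ref$arc_spacing,
                                 as.numeric(pos_r) + offs[o, 1],
                                 as.numeric(pos_c) + offs[o, 2])
    g2 <- ((de - as.numeric(ref$values)) / dd_abs)^2 +
      (offs[o, 1]^2 + offs[o, 2]^2) / dc^2
    best <- pmin(best, matrix(g2, nr, nc), na.rm = TRUE)
  }
  ev <- ref$values >= criteria$low_dose_threshold * norm
  g <- sqrt(best)
  g[!ev] <- NA_real_
  g
}

oracle_interp_grid <- function(vals, spacing, x, y, z) {
  d <- dim(vals)
  f1 <- x / spacing[1]; f2 <- y / spacing[2]; f3 <- z / spacing[3]
  ok <- f1 >= -1e-9 & f1 <= d[1] - 1 + 1e-9 &
        f2 >= -1e-9 & f2 <= d[2] - 1 + 1e-9 &
        f3 >= -1e-9 & f3 <= d[3] - 1 + 1e-9
  f1 <- pmin(pmax(f1, 0), d[1] - 1)
  f2 <- pmin(pmax(f2, 0), d[2] - 1)
  f3 <- pmin(pmax(f3, 0), d[3] - 1)
  i0 <- pmin(floor(f1), max(d[1] - 2, 0)); t1 <- f1 - i0
  j0 <- pmin(floor(f2), max(d[2] - 2, 0)); t2 <- f2 - j0
  k0 <- pmin(floor(f3), max(d[3] - 2, 0)); t3 <- f3 - k0
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  at <- function(i, j, k) vals[1 + i + d[1] * (j + d[2] * k)]
  v <- at(i0, j0, k0) * (1 - t1) * (1 - t2) * (1 - t3) +
       at(i1, j0, k0) * t1 * (1 - t2) * (1 - t3) +
       at(i0, j1, k0) * (1 - t1) * t2 * (1 - t3) +
       at(i1, j1, k0) * t1 * t2 * (1 - t3) +
       at(i0, j0, k1) * (1 - t1) * (1 - t2) * t3 +
       at(i1, j0, k1) * t1 * (1 - t2) * t3 +
       at(i0, j1, k1) * (1 - t1) * t2 * t3 +
       at(i1, j1, k1) * t1 * t2 * t3
  v[!ok] <- NA_real_
  v
}

oracle_gamma_grid <- function(ref, eval, criteria, radius_factor, step_frac,
                              normalization = NULL) {
  norm <- if (is.null(normalization)) max(ref$values) else normalization
  dd_abs <- criteria$dose_criterion / 100 * norm
  dc <- criteria$distance_criterion
  offs <- oracle_offsets(step_frac * dc, radius_factor * dc, 3)
  d <- dim(ref$values)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * ref$spacing[a])
  X <- array(ax[[1]], d)
  Y <- aperm(array(ax[[2]], d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(ax[[3]], d[c(3, 1, 2)]), c(2, 3, 1))
  best <- array(Inf, d)
  for (o in seq_len(nrow(offs))) {
    de <- oracle_interp_grid(eval$values, ref$spacing,
                             as.numeric(X) + offs[o, 1],
                             as.numeric(Y) + offs[o, 2],
                             as.numeric(Z) + offs[o, 3])
    g2 <- ((de - as.numeric(ref$values)) / dd_abs)^2 +
      sum(offs[o, ]^2) / dc^2
    best <- pmin(best, array(g2, d), na.rm = TRUE)
  }
  ev <- ref$values >= criteria$low_dose_threshold * norm
  g <- sqrt(best)
  g[!ev] <- NA_real_
  g
}

# --- geometry oracles --------------------------------------------------------

# winding-number point-in-polygon (different algorithm from the even-odd
# crossing test in the implementation; equivalent for simple polygons)
oracle_point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  ang <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(vy[i] - py, vx[i] - px)
    a2 <- atan2(vy[j] - py, vx[j] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# random simple (star-shaped) polygon around a center
random_star_polygon <- function(cx, cy, rmin, rmax, n = 12) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# small helper: a uniform-dose grid
uniform_grid <- function(value, shape = c(8, 8, 8), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  dose_grid(array(value, dim = shape), origin, spacing)
}

# random smooth-ish dose pair on a shared detector layout
random_detector_pair <- function(nr = 20, nc = 20, row_sp = 5,
                                 noise = 0.03) {
  R <- nc * row_sp / (2 * pi)
  mk <- function(vals) detector_map(vals, diode_spacing = row_sp,
                                    cylinder_radius = R)
  r_pos <- (seq_len(nr) - 1) / (nr - 1)
  c_pos <- (seq_len(nc) - 1) / (nc - 1)
  base <- 5 + 4 * outer(sin(pi * r_pos), cos(2 * pi * c_pos)) +
    matrix(stats::rnorm(nr * nc, sd = 0.3), nr, nc)
  base <- pmax(base, 0)
  pert <- base * (1 + stats::rnorm(nr * nc, sd = noise)) +
    stats::rnorm(nr * nc, sd = 0.05)
  list(ref = mk(base), eval = mk(pmax(pert, 0)))
}

random_grid_pair <- function(shape = c(16, 16, 16), spacing = c(2, 2, 2),
                             noise = 0.03) {
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
  ctr <- vapply(ax, function(a) mean(range(a)), 1)
  X <- array(ax[[1]], shape)
  Y <- aperm(array(ax[[2]], shape[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(ax[[3]], shape[c(3, 1, 2)]), c(2, 3, 1))
  r2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
  base <- 10 * exp(-r2 / (2 * 12^2))
  pert <- base * (1 + array(stats::rnorm(prod(shape), sd = noise), shape))
  list(ref = dose_grid(base, rep(0, 3), spacing),
       eval = dose_grid(pmax(pert, 0), rep(0, 3), spacing))
}
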