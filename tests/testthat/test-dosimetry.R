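test_that("density calibration interpolates between pinned anchors", {
  cal <- density_calibration()
  expect_equal(hu_to_red(0, cal), 1)
  expect_equal(hu_to_red(-1000, cal), 0)
  expect_equal(hu_to_red(-500, cal), 0.5)       # midpoint between anchors
  expect_equal(hu_to_red(500, cal), (1 + 1.52) / 2)
  expect_equal(hu_to_red(-2000, cal), 0)        # clipped below
  expect_equal(hu_to_red(5000, cal), 2.5)       # clipped above
  expect_error(density_calibration(hu = c(0, -1000), red = c(1, 0)),
               "increasing")
  expect_error(density_calibration(hu = c(-1000, 0), red = c(0.2, 1)),
               "anchors")
})

test_that("beam-angle enumeration reproduces the 180-beam sweep", {
  a <- enumerate_beam_angles(181, 179, 2)
  expect_length(a, 180)
  expect_equal(anyDuplicated(a), 0)
  expect_equal(a[1], 181)
  expect_equal(a[length(a)], 179)
  expect_true(all(a >= 0 & a < 360))
  expect_equal(enumerate_beam_angles(0, 0, 2), 0)
  expect_length(enumerate_beam_angles(0, 358, 2), 180)
  expect_error(enumerate_beam_angles(0, 179, 2), "divide")
  expect_error(enumerate_beam_angles(0, 90, -1), "step")
})

test_that("EPL equals geometric depth in water and zero in air", {
  cyl <- water_cylinder(n = 41, nsl = 3, radius = 15)
  for (ang in c(0, 45, 90, 137, 200, 271)) {
    e <- compute_epl(cyl$ct, cyl$mask, list(angle = ang, iso = cyl$iso))
    expect_equal(e$epl, e$depth, tolerance = 1e-8)
    expect_lt(abs(e$depth - 15.5), 1.0)   # entry at the voxelised surface
  }
  air <- water_cylinder(n = 41, nsl = 3, radius = 15, hu_inside = -1000)
  mask <- cyl$mask   # same disc, but filled with air
  e0 <- compute_epl(air$ct, mask, list(angle = 30, iso = cyl$iso))
  expect_equal(e0$epl, 0, tolerance = 1e-12)
  expect_error(compute_epl(cyl$ct, cyl$mask, list(angle = 0, iso = c(1, 1, 1))),
               "isocenter outside")
})

test_that("a bone slab of known width adds 0.5 t to the EPL (analytic slab oracle)", {
  cyl <- water_cylinder(n = 41, nsl = 3, radius = 15)
  cal <- density_calibration(hu = c(-1000, 0, 1000), red = c(0, 1, 1.5))
  t_mm <- 4
  with_slab <- cyl$ct
  with_slab$data[6:(5 + t_mm), 21, ] <- 1000    # RED 1.5 slab on the 0-deg axis
  e_a <- compute_epl(cyl$ct, cyl$mask, list(angle = 0, iso = cyl$iso), cal)
  e_b <- compute_epl(with_slab, cyl$mask, list(angle = 0, iso = cyl$iso), cal)
  expect_equal(e_b$epl - e_a$epl, 0.5 * t_mm, tolerance = 1e-9)
  # a ray that misses the slab is unchanged
  e_c <- compute_epl(with_slab, cyl$mask, list(angle = 180, iso = cyl$iso), cal)
  expect_equal(e_c$epl - e_a$epl, 0, tolerance = 1e-9)
})

test_that("voxel-boundary traversal matches dense numerical integration", {
  set.seed(3)
  for (rep in 1:6) {
    n <- 39
    arr <- array(-1000, c(n, n, 3))
    ctr <- (n + 1) / 2
    rad <- 14
    hus <- sample(c(0, 300, 900, -200, 1500), 5)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d2 <- (i - ctr)^2 + (j - ctr)^2
      if (d2 <= rad^2) arr[i, j, ] <- hus[1 + (floor(sqrt(d2)) %% 5)]
    }
    ct <- image_volume(arr, c(1.25, 1.25, 2.5))
    mask <- body_mask(arr > -1000, c(1.25, 1.25, 2.5))
    ang <- stats::runif(1, 0, 360)
    beam <- list(angle = ang, iso = c(ctr, ctr, 2))
    got <- compute_epl(ct, mask, beam)
    ref <- epl_dense_oracle(ct, mask, ang, beam$iso)
    expect_lt(abs(got$epl - ref$epl), 0.05)
    expect_lt(abs(got$depth - ref$depth), 0.01)
    # invariant: EPL bounded by depth times the maximum RED on the ray
    expect_lte(got$epl, got$depth * max(hu_to_red(arr)) + 1e-9)
  }
})

test_that("the EPL sweep tabulates per-angle differences with summary statistics", {
  cyl <- water_cylinder(n = 41, nsl = 3, radius = 15)
  angs <- enumerate_beam_angles(181, 179, 2)
  sw <- epl_sweep(cyl$ct, cyl$ct, cyl$mask, cyl$iso, angs)
  expect_equal(nrow(sw), 180)
  expect_true(all(sw$diff == 0))
  s <- attr(sw, "summary")
  expect_equal(s$mean, 0)
  expect_equal(s$frac_within_5mm, 1)
})

test_that("gamma of identical dose slices is zero with a 100 percent pass rate", {
  set.seed(4)
  d <- matrix(stats::runif(48 * 48, 2, 10), 48, 48)
  for (cr in list(c(3, 3), c(2, 2), c(1, 1))) {
    g <- gamma_2d(d, d, dd = cr[1], dta = cr[2], norm_dose = 10, spacing = 1)
    expect_true(all(g$gamma < 1e-9))
    expect_equal(g$pass_rate, 100)
  }
})

test_that("a uniform 2 percent offset sits exactly on the gamma = 1 boundary at 2%/2mm", {
  d <- matrix(5, 40, 40)
  g <- gamma_2d(d, d + 0.02 * 10, dd = 2, dta = 2, norm_dose = 10, spacing = 1)
  expect_true(all(abs(g$gamma - 1) < 1e-9))
  expect_equal(g$pass_rate, 100)   # boundary points pass
})

test_that("a single hot pixel in a flat field gives gamma exactly 2 at 3%/3mm", {
  d <- matrix(5, 33, 33)
  ev <- d
  ev[17, 17] <- 5 + 0.06 * 10
  g <- gamma_2d(d, ev, dd = 3, dta = 3, norm_dose = 10, spacing = 1)
  expect_equal(g$gamma[17, 17], 2, tolerance = 1e-9)
  expect_equal(sum(g$gamma > 1e-9), 1)   # everywhere else identical
})

test_that("the search-disc gamma agrees with the exhaustive full-grid oracle", {
  set.seed(8)
  n <- 24
  base <- matrix(5, n, n) + outer(sin(seq(0, 3, length.out = n)),
                                  cos(seq(0, 2, length.out = n)))
  ev <- base * smooth_field2(n, n, 0.04, 81) + 0.05
  g <- gamma_2d(base, ev, dd = 3, dta = 3, norm_dose = max(base), spacing = 1,
                resample_factor = 1)   # compare on the native grid
  or <- gamma_oracle(ev, base, 0.03 * max(base), 3, spacing = 1)
  # search radius 3x DTA truncates nothing here: values must agree exactly
  expect_equal(g$gamma, or, tolerance = 1e-9)
})

test_that("gamma pass rates are monotone across the three clinical criteria", {
  set.seed(9)
  for (rep in 1:4) {
    n <- 32
    base <- matrix(8, n, n) * smooth_field2(n, n, 0.3, 100 + rep)
    ev <- base * smooth_field2(n, n, 0.035, 200 + rep)
    p <- vapply(list(c(3, 3), c(2, 2), c(1, 1)), function(cr)
      gamma_2d(base, ev, dd = cr[1], dta = cr[2], norm_dose = 8,
               spacing = 1)$pass_rate, 0)
    expect_true(p[1] >= p[2] && p[2] >= p[3])
  }
})

test_that("DVH metrics match closed forms and a sort-based oracle", {
  m <- body_mask(array(TRUE, c(10, 10, 1)))
  uni <- dose_grid(array(50, c(10, 10, 1)), prescription = 50)
  dv <- dvh_metrics(uni, m)
  expect_equal(dv$D2, 50); expect_equal(dv$D50, 50); expect_equal(dv$D98, 50)
  expect_equal(dv$Dmax, 50); expect_equal(dv$Dmean, 50)
  expect_equal(dv$V95, 100)
  # V95 flips when the uniform dose drops below 95% of the prescription
  low <- dose_grid(array(46, c(10, 10, 1)), prescription = 50)
  expect_equal(dvh_metrics(low, m)$V95, 0)

  ramp <- dose_grid(array(seq(0, 100, length.out = 100), c(10, 10, 1)),
                    prescription = 100)
  dr <- dvh_metrics(ramp, m)
  expect_equal(dr$D50, 50, tolerance = 1)
  expect_true(dr$D2 >= dr$D50 && dr$D50 >= dr$D98)

  set.seed(10)
  v <- stats::runif(321, 0, 70)
  dg <- dose_grid(array(v, c(321, 1, 1)), prescription = 60)
  msk <- body_mask(array(TRUE, c(321, 1, 1)))
  dd <- dvh_metrics(dg, msk)
  for (x in c(2, 50, 98))
    expect_equal(dd[[paste0("D", x)]], dvh_oracle_dx(v, x), tolerance = 1e-9)
  expect_equal(dd$Dmax, max(v))
  expect_equal(dd$Dmean, mean(v))
  expect_equal(dd$V95, 100 * mean(v >= 0.95 * 60))
  # permutation invariance
  dg2 <- dose_grid(array(sample(v), c(321, 1, 1)), prescription = 60)
  dd2 <- dvh_metrics(dg2, msk)
  expect_equal(dd2$D50, dd$D50)
  expect_error(dvh_metrics(dg, body_mask(array(FALSE, c(321, 1, 1)))), "empty")
})

test_that("paired comparison selects the test from normality and handles degeneracy", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_true(paired_compare(a, a)$degenerate)
  expect_equal(paired_compare(a, a)$p_value, 1)
  expect_equal(paired_compare(a, a)$statistic, 0)

  # normal-looking differences: paired t with a closed-form statistic
  set.seed(11)
  d <- stats::rnorm(20, 0.5, 1)
  b <- stats::runif(20, 5, 10)
  pc <- paired_compare(b + d, b)
  expect_match(pc$test, "paired t")
  tstat <- mean(d) / (stats::sd(d) / sqrt(20))
  expect_equal(pc$statistic, tstat, tolerance = 1e-10)
  expect_equal(pc$p_value, 2 * stats::pt(-abs(tstat), df = 19),
               tolerance = 1e-12)

  # heavily non-normal differences fall back to the signed-rank test
  dd <- c(0.01, 0.02, 0.011, 0.013, 0.012, 0.014, 0.013, 9, 12, 15)
  pc2 <- paired_compare(b[1:10] + dd, b[1:10])
  expect_match(pc2$test, "wilcoxon")
  expect_error(paired_compare(1:3, 1:4), "unequal")
  expect_error(paired_compare(1:2, 2:3), "at least 3")
})

test_that("the exact Wilcoxon p-value matches sign-assignment enumeration", {
  b <- c(10, 20, 30, 40, 50)
  a <- b + c(1, 2, 3, 4, 5)
  pc <- paired_compare(a, b, test = "wilcoxon")
  expect_match(pc$test, "exact")
  expect_equal(pc$p_value, 0.0625)
  # oracle: enumerate all 2^5 sign assignments of the ranks
  ranks <- rank(abs(a - b))
  W <- sum(ranks[(a - b) > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  null_W <- as.matrix(signs) %*% ranks
  p_exact <- 2 * min(mean(null_W >= W), mean(null_W <= W))
  expect_equal(p_exact, 2 / 32)
  expect_equal(pc$p_value, p_exact)
})
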