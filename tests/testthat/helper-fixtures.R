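# Shared fixtures and independent oracles, all generated in code.

# water cylinder CT (HU = 0 inside a disc, air outside) for ray-trace tests
water_cylinder <- function(n = 41, nsl = 3, radius = 15, spacing = c(1, 1, 1),
                           hu_inside = 0) {
  arr <- array(-1000, c(n, n, nsl))
  ctr <- (n + 1) / 2
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= radius^2) arr[i, j, ] <- hu_inside
  list(ct = image_volume(arr, spacing),
       mask = body_mask(arr > -500, spacing),
       iso = c(ctr, ctr, ceiling(nsl / 2)))
}

# a preprocessed noise-free phantom subject: CT a deterministic function of
# the MR triple; MR linearly rescaled onto the 0-4095 standard range
noise_free_subject <- function(seed, shape = c(80, 80, 32), spacing = c(3, 3, 3)) {
  cm <- contrast_model()   # noise 0, bias 0
  ph <- generate_head_phantom(shape = shape, spacing = spacing, model = cm,
                              seed = seed)
  mr <- simulate_mr(ph$labels, cm, seed = seed + 500L)
  mask <- compute_body_mask(ph$ct)
  f <- fill_background(ph$ct, mr, mask)
  f$mr$data <- f$mr$data * (4095 / 1000)
  list(ct = f$ct, mr = f$mr, mask = mask, labels = ph$labels)
}

# dense-sampling numerical line integral of RED along the beam central axis,
# independent of the voxel-boundary traversal under test
epl_dense_oracle <- function(ct, mask, angle, iso, cal = density_calibration(),
                             step = 0.001) {
  sp <- ct$spacing
  d <- dim(ct$data)
  g <- angle * pi / 180
  dirv <- c(cos(g), -sin(g))
  iso_xy <- c((iso[1] - 1) * sp[1], (iso[2] - 1) * sp[2])
  L <- sqrt((d[1] * sp[1])^2 + (d[2] * sp[2])^2) + 2 * max(sp)
  tt <- seq(0, L, by = step)
  py <- iso_xy[1] - dirv[1] * L + dirv[1] * tt
  px <- iso_xy[2] - dirv[2] * L + dirv[2] * tt
  i <- round(py / sp[1]) + 1
  j <- round(px / sp[2]) + 1
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
  msl <- mask$data[, , iso[3]]
  ctsl <- ct$data[, , iso[3]]
  inm <- rep(FALSE, length(tt))
  inm[ok] <- msl[cbind(i[ok], j[ok])]
  if (!any(inm)) stop("dense oracle: ray misses the body")
  first <- which(inm)[1]
  red <- rep(0, length(tt))
  red[ok] <- hu_to_red(ctsl[cbind(i[ok], j[ok])], cal)
  sel <- first:length(tt)
  list(depth = L - tt[first], epl = sum(red[sel]) * step)
}

# exhaustive-search gamma oracle: full O(N^2) minimisation over every
# reference point, no search-radius truncation, no upsampling
gamma_oracle <- function(evald, refd, dd_abs, dta, spacing = 1) {
  n1 <- nrow(evald); n2 <- ncol(evald)
  xs <- (seq_len(n1) - 1) * spacing
  ys <- (seq_len(n2) - 1) * spacing
  g <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    dd2 <- ((evald[i, j] - refd) / dd_abs)^2
    r2 <- outer((xs - xs[i])^2, (ys - ys[j])^2, "+") / dta^2
    g[i, j] <- sqrt(min(dd2 + r2))
  }
  g
}

# sort-based DVH oracle: D_x% via linear interpolation on the cumulative
# volume fraction of the sorted doses (type-7 definition written directly)
dvh_oracle_dx <- function(doses, x) {
  v <- sort(doses)
  n <- length(v)
  p <- 1 - x / 100
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# smooth random field in [1-amp, 1+amp] for perturbing dose slices
smooth_field2 <- function(n1, n2, amp, seed) {
  set.seed(seed)
  u <- seq(-1, 1, length.out = n1)
  v <- seq(-1, 1, length.out = n2)
  f <- matrix(0, n1, n2)
  for (i in 0:2) for (j in 0:2) {
    if (i + j == 0 || i + j > 2) next
    f <- f + stats::rnorm(1) * outer(u^i, v^j)
  }
  if (max(abs(f)) > 0) f <- f / max(abs(f)) * amp
  1 + f
}
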