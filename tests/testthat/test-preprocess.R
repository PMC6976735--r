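make_masked_volume <- function(seed = 1, shape = c(40, 40, 32)) {
  set.seed(seed)
  m <- array(FALSE, shape)
  ctr <- (shape + 1) / 2
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    if ((i - ctr[1])^2 / (0.4 * shape[1])^2 +
        (j - ctr[2])^2 / (0.4 * shape[2])^2 <= 1) m[i, j, ] <- TRUE
  vals <- array(50, shape)
  vals[m] <- sample(c(200, 500, 800), sum(m), replace = TRUE) +
    stats::rnorm(sum(m), 0, 20)
  list(mr = image_volume(abs(vals) + 1), mask = body_mask(m))
}

test_that("bias correction leaves clean input nearly untouched and preserves the masked mean", {
  mv <- make_masked_volume(1)
  out <- correct_bias_field(mv$mr, mv$mask)
  rel <- abs(out$data[mv$mask$data] - mv$mr$data[mv$mask$data]) /
    mv$mr$data[mv$mask$data]
  expect_lt(stats::median(rel), 0.01)
  expect_equal(mean(out$data[mv$mask$data]), mean(mv$mr$data[mv$mask$data]),
               tolerance = 1e-9)
})

test_that("bias correction recovers truth under a known low-order field", {
  mv <- make_masked_volume(2)
  shape <- dim(mv$mr$data)
  u <- seq(-1, 1, length.out = shape[1])
  v <- seq(-1, 1, length.out = shape[2])
  w <- seq(-1, 1, length.out = shape[3])
  logf <- 0.10 * outer(outer(u, rep(1, shape[2])), rep(1, shape[3])) +
    0.08 * outer(outer(rep(1, shape[1]), v), w) -
    0.06 * outer(outer(u, v), rep(1, shape[3]))
  field <- exp(logf)
  corrupted <- image_volume(mv$mr$data * field)
  out <- correct_bias_field(corrupted, mv$mask)
  # compare after matching the (unidentifiable) global scale to the truth
  truth <- mv$mr$data[mv$mask$data]
  got <- out$data[mv$mask$data]
  got <- got * mean(truth) / mean(got)
  expect_lt(stats::median(abs(got - truth) / truth), 0.02)
  expect_error(correct_bias_field(image_volume(array(-1, shape)), mv$mask),
               "non-positive")
})

test_that("a single-volume standardizer maps its own landmarks exactly", {
  mv <- make_masked_volume(3)
  std <- fit_intensity_standardizer(list(mr = mv$mr, mask = mv$mask))
  expect_true(all(diff(std$landmarks) > 0))
  expect_equal(std$landmarks[1], 0)
  expect_equal(std$landmarks[length(std$landmarks)], 4095)
  out <- apply_intensity_standardizer(mv$mr, mv$mask, std)
  q_in <- stats::quantile(mv$mr$data[mv$mask$data], std$probs, type = 7)
  q_out <- stats::quantile(out$data[mv$mask$data], std$probs, type = 7)
  # fixed point: each landmark percentile maps onto its standard value
  # (interior knots exact; the clipped extremes to within a tenth of an HU)
  expect_equal(unname(q_out)[2:10], unname(std$landmarks)[2:10],
               tolerance = 1e-9)
  expect_equal(unname(q_out), unname(std$landmarks), tolerance = 1e-4)
})

test_that("standard landmarks are invariant to a global linear intensity change", {
  mv <- make_masked_volume(4)
  mr2 <- image_volume(3.7 * mv$mr$data + 120)
  s1 <- fit_intensity_standardizer(list(mr = mv$mr, mask = mv$mask))
  s12 <- fit_intensity_standardizer(list(list(mr = mv$mr, mask = mv$mask),
                                         list(mr = mr2, mask = mv$mask)))
  expect_equal(s12$landmarks, s1$landmarks, tolerance = 1e-9)
})

test_that("standardized output is clipped to [0, 4095] and rank-preserving", {
  mv <- make_masked_volume(5)
  std <- fit_intensity_standardizer(list(mr = mv$mr, mask = mv$mask))
  out <- apply_intensity_standardizer(mv$mr, mv$mask, std)
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 4095)
  xin <- mv$mr$data[mv$mask$data]
  xout <- out$data[mv$mask$data]
  ord <- order(xin)
  expect_true(all(diff(xout[ord]) >= 0))
  expect_error(apply_intensity_standardizer(mv$mr, mv$mask, list()),
               "not a fitted")
  cst <- image_volume(array(5, dim(mv$mr$data)))
  expect_error(fit_intensity_standardizer(list(mr = cst, mask = mv$mask)),
               "degenerate")
})

test_that("Otsu threshold matches exhaustive between-class-variance search", {
  set.seed(6)
  v <- c(stats::rnorm(4000, 100, 12), stats::rnorm(2500, 900, 40))
  thr <- otsu_threshold(v)
  # brute-force oracle over every candidate split of the sorted values
  cand <- sort(unique(round(v)))
  bcv <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) / length(v) * length(hi) / length(v) * (mean(lo) - mean(hi))^2
  }, 0)
  best <- cand[which.max(bcv)]
  expect_lt(abs(thr - best), diff(range(v)) / 256 * 2)  # within two bins
  expect_true(thr > 100 && thr < 900)
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
})

test_that("body mask recovers a noisy ellipse with Dice >= 0.99", {
  set.seed(7)
  shape <- c(64, 64, 32)
  truth <- array(FALSE, shape)
  ctr <- (shape + 1) / 2
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) for (k in seq_len(shape[3]))
    if ((i - ctr[1])^2 / 24^2 + (j - ctr[2])^2 / 20^2 + (k - ctr[3])^2 / 13^2 <= 1)
      truth[i, j, k] <- TRUE
  img <- array(stats::rnorm(prod(shape), 0, 30), shape)
  img[truth] <- img[truth] + 1000
  mask <- compute_body_mask(image_volume(img))
  dice <- 2 * sum(mask$data & truth) / (sum(mask$data) + sum(truth))
  expect_gte(dice, 0.99)
  # exactly one connected component
  lab <- mr2sct:::label_components_cpp(mask$data, shape[1], shape[2], shape[3], 26L)
  expect_equal(max(lab), 1L)
  expect_error(compute_body_mask(image_volume(array(1, c(8, 8, 8)))),
               "degenerate")
})
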