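# separable Gaussian blur along each axis, sigma in voxels (vector of 3)
gaussian_blur3 <- function(arr, sigma_vox) {
  blur_axis <- function(a, axis, sig) {
    if (sig <= 0) return(a)
    r <- max(1L, ceiling(3 * sig))
    k <- stats::dnorm(-r:r, sd = sig)
    k <- k / sum(k)
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    n <- nrow(m)
    # replicate-pad then convolve columns
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (o in -r:r)
      out <- out + k[o + r + 1L] * mp[seq_len(n) + r + o, , drop = FALSE]
    res <- array(out, dim(ap))
    aperm(res, order(perm))
  }
  for (ax in 1:3) arr <- blur_axis(arr, ax, sigma_vox[ax])
  arr
}

#' Otsu threshold of a numeric array
#'
#' Exhaustive maximisation of the between-class variance over the bin edges
#' of a fixed-bin histogram (default 256 bins) of the input values.
#'
#' @param x Numeric vector or array with at least 2 distinct values.
#' @param nbins Number of histogram bins.
#' @return The threshold value (foreground = values > threshold).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.vector(x)
  rng <- range(v)
  if (!all(is.finite(rng)) || diff(rng) == 0)
    stop("degenerate histogram: input has fewer than 2 distinct values", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), nbins),
                nbins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  edges[which.max(sigma_b) + 1L]
}

fill_holes3 <- function(m) {
  bg <- label_components_cpp(!m, dim(m)[1], dim(m)[2], dim(m)[3], 6L)
  d <- dim(m)
  border_labels <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                            bg[, , 1], bg[, , d[3]]))
  border_labels <- setdiff(border_labels, 0L)
  holes <- bg != 0L & !(bg %in% border_labels)
  m | array(holes, d)
}

largest_component3 <- function(m) {
  lab <- label_components_cpp(m, dim(m)[1], dim(m)[2], dim(m)[3], 26L)
  if (max(lab) == 0L) return(m & FALSE)
  counts <- tabulate(lab[lab > 0L])
  array(lab == which.max(counts), dim(m))
}

#' Body mask by blurred Otsu thresholding plus morphology
#'
#' Pipeline: Gaussian blur, Otsu threshold on a 256-bin histogram of the
#' blurred image, binary closing (ball element), hole filling, and retention
#' of the largest connected component.  The result separates the patient
#' body from the surrounding air for CT or MR volumes alike.
#'
#' @param image An `image_volume` with at least two distinct values.
#' @param sigma Blur sigma in mm; `NULL` (default) uses 1 voxel per axis.
#' @param morph_radius Closing radius in voxels (default 2).
#' @return A [body_mask()] with a single connected foreground component.
#' @export
compute_body_mask <- function(image, sigma = NULL, morph_radius = 2) {
  stopifnot(is_image_volume(image))
  arr <- image$data
  if (diff(range(arr)) == 0)
    stop("degenerate histogram: constant image", call. = FALSE)
  sig_vox <- if (is.null(sigma)) c(1, 1, 1) else sigma / image$spacing
  sm <- gaussian_blur3(arr, sig_vox)
  thr <- otsu_threshold(sm)
  m <- array(sm > thr, dim(arr))
  d <- dim(m)
  if (morph_radius > 0) {
    m <- morph_ball_cpp(m, d[1], d[2], d[3], morph_radius, 1L)  # dilate
    m <- morph_ball_cpp(m, d[1], d[2], d[3], morph_radius, 0L)  # erode
    m <- array(m, d)
  }
  m <- fill_holes3(m)
  m <- largest_component3(m)
  body_mask(m, image$spacing, image$origin)
}

#' Correct a smooth multiplicative bias field
#'
#' Estimates the log of the bias field as a least-squares low-order
#' polynomial in normalised coordinates fitted to the masked log-image,
#' iterated with residual-based outlier down-weighting (Tukey biweight on
#' MAD-scaled residuals) so that tissue structure, which appears as large
#' coherent residuals, does not drag the field.  The corrected image is
#' rescaled so the masked mean intensity is preserved exactly.
#'
#' @param mr An `image_volume`, strictly positive inside the mask.
#' @param mask A [body_mask()] on the same geometry.
#' @param order Polynomial order of the log-field (default 3).
#' @param iterations Re-weighting iterations (default 2).
#' @return The corrected `image_volume`, with the estimated multiplicative
#'   field attached as attribute `"bias_field"`.
#' @export
correct_bias_field <- function(mr, mask, order = 3L, iterations = 2L) {
  stopifnot(is_image_volume(mr))
  m <- mask_array(mask, mr)
  vals <- mr$data[m]
  if (any(vals <= 0))
    stop("invalid input: non-positive intensities inside the mask", call. = FALSE)
  shape <- dim(mr$data)
  u <- seq(-1, 1, length.out = shape[1])
  v <- seq(-1, 1, length.out = shape[2])
  w <- seq(-1, 1, length.out = shape[3])
  idx <- which(m, arr.ind = TRUE)
  build_basis <- function(uu, vv, ww) {
    cols <- list()
    for (i in 0:order) for (j in 0:order) for (k in 0:order)
      if (i + j + k <= order) cols[[length(cols) + 1L]] <- uu^i * vv^j * ww^k
    do.call(cbind, cols)
  }
  A <- build_basis(u[idx[, 1]], v[idx[, 2]], w[idx[, 3]])
  b <- log(vals)
  wts <- rep(1, length(b))
  beta <- NULL
  for (it in seq_len(max(1L, iterations))) {
    fit <- stats::lm.wfit(A, b, wts)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    r <- b - A %*% beta
    s <- stats::mad(r)
    if (s <= 0) break
    z <- abs(r) / (4.685 * s)
    wts <- as.vector(ifelse(z < 1, (1 - z^2)^2, 0))
    if (all(wts == 0)) wts <- rep(1, length(b))
  }
  # evaluate the field everywhere
  full <- as.matrix(expand.grid(u = u, v = v, w = w))
  Af <- build_basis(full[, 1], full[, 2], full[, 3])
  logfield <- array(Af %*% beta, shape)
  field <- exp(logfield - mean(logfield[m]))   # masked log-mean 0
  corrected <- mr$data / field
  scale <- mean(vals) / mean(corrected[m])     # preserve masked mean exactly
  corrected <- corrected * scale
  out <- image_volume(corrected, mr$spacing, mr$origin)
  attr(out, "bias_field") <- field / scale
  out
}

.nyul_probs <- c(0.01, seq(0.1, 0.9, by = 0.1), 0.99)

#' Fit a Nyul-Udupa intensity standardizer
#'
#' Learns a standard intensity scale on \[0, 4095\] from training MR volumes:
#' each volume's masked landmark percentiles (p1, deciles, p99) are mapped
#' linearly so its \[p1, p99\] spans \[0, 4095\], and the standard-scale
#' landmarks are the mean of the mapped landmarks across volumes.
#'
#' @param training List of `list(mr = image_volume, mask = body_mask)` (a
#'   single such pair is also accepted).
#' @return Object of class `intensity_standardizer` with elements `probs`,
#'   `landmarks` (strictly increasing, landmarks\[1\] = 0,
#'   landmarks\[last\] = 4095) and `range = c(0, 4095)`.
#' @export
fit_intensity_standardizer <- function(training) {
  if (!is.null(training$mr)) training <- list(training)
  if (length(training) < 1) stop("need at least one training volume", call. = FALSE)
  mapped <- sapply(training, function(tv) {
    m <- mask_array(tv$mask, tv$mr)
    vals <- tv$mr$data[m]
    q <- stats::quantile(vals, probs = .nyul_probs, names = FALSE, type = 7)
    if (q[length(q)] - q[1] <= 0)
      stop("degenerate histogram: constant image inside mask", call. = FALSE)
    mq <- (q - q[1]) / (q[length(q)] - q[1]) * 4095
    if (any(diff(mq) <= 0))
      stop("degenerate histogram: tied landmark percentiles; ",
           "the masked intensity distribution is too discrete", call. = FALSE)
    mq
  })
  lm_std <- rowMeans(as.matrix(mapped))
  structure(list(probs = .nyul_probs, landmarks = lm_std, range = c(0, 4095)),
            class = "intensity_standardizer")
}

#' @export
print.intensity_standardizer <- function(x, ...) {
  cat("<intensity_standardizer> landmarks:",
      paste(signif(x$landmarks, 5), collapse = " "), "\n")
  invisible(x)
}

#' Apply an intensity standardizer
#'
#' Maps a volume onto the standard scale by piecewise-linear interpolation
#' between its own masked landmark percentiles and the standard landmarks,
#' with linear extension beyond the outer landmarks, then clips to
#' \[0, 4095\].  The mapping is applied to every voxel (masked landmarks,
#' whole-volume application), so background stays near 0 after masking.
#'
#' @param mr `image_volume` to standardize.
#' @param mask [body_mask()] used to compute the volume's landmarks.
#' @param std A fitted [fit_intensity_standardizer()] object.
#' @return Standardized `image_volume` with values in \[0, 4095\].
#' @export
apply_intensity_standardizer <- function(mr, mask, std) {
  if (!inherits(std, "intensity_standardizer"))
    stop("`std` is not a fitted intensity_standardizer", call. = FALSE)
  m <- mask_array(mask, mr)
  q <- stats::quantile(mr$data[m], probs = std$probs, names = FALSE, type = 7)
  if (any(diff(q) <= 0))
    stop("degenerate histogram: tied landmark percentiles in input", call. = FALSE)
  n <- length(q)
  x <- as.vector(mr$data)
  y <- numeric(length(x))
  lo <- x <= q[1]
  hi <- x >= q[n]
  mid <- !lo & !hi
  slope1 <- (std$landmarks[2] - std$landmarks[1]) / (q[2] - q[1])
  slopeN <- (std$landmarks[n] - std$landmarks[n - 1]) / (q[n] - q[n - 1])
  y[lo] <- std$landmarks[1] + (x[lo] - q[1]) * slope1
  y[hi] <- std$landmarks[n] + (x[hi] - q[n]) * slopeN
  if (any(mid))
    y[mid] <- stats::approx(q, std$landmarks, xout = x[mid])$y
  y <- pmin(pmax(y, std$range[1]), std$range[2])
  image_volume(array(y, dim(mr$data)), mr$spacing, mr$origin)
}

#' Fill background voxels with canonical values
#'
#' Outside the body mask, CT voxels are set to -1000 HU and MR voxels (all
#' channels) to 0; inside-mask voxels are untouched.
#'
#' @param ct `image_volume` in HU.
#' @param mr `multi_sequence_volume` on the same geometry.
#' @param mask [body_mask()] on the same geometry.
#' @return List with filled `ct` and `mr`.
#' @export
fill_background <- function(ct, mr, mask) {
  m <- mask_array(mask, ct)
  check_same_geometry(ct, mask)
  if (!identical(dim(mr$data)[1:3], dim(ct$data)))
    stop("invalid input: CT and MR geometries differ", call. = FALSE)
  ct2 <- ct$data
  ct2[!m] <- -1000
  mr2 <- mr$data
  for (ch in seq_len(dim(mr2)[4])) {
    sl <- mr2[, , , ch]
    sl[!m] <- 0
    mr2[, , , ch] <- sl
  }
  mrout <- mr
  mrout$data <- mr2
  list(ct = image_volume(ct2, ct$spacing, ct$origin), mr = mrout)
}
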