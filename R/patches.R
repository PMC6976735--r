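#' Sample aligned MR/CT training patch pairs
#'
#' Cuts `n` axial patch pairs (3-channel MR, 1-channel CT) at identical
#' slice/position, sampling uniformly (with replacement) over all admissible
#' top-left positions, i.e. positions where the patch lies fully inside the
#' slice and its body-voxel fraction is at least `min_body_fraction`.
#' Sampling is reproducible for a fixed seed (R's integer RNG).
#'
#' @param mr `multi_sequence_volume` (typically standardized intensities).
#' @param ct `image_volume` in HU, same geometry.
#' @param mask [body_mask()], same geometry.
#' @param n Number of pairs (0 gives an empty list).
#' @param side Patch side in pixels (default 128, the training patch size;
#'   must not exceed the slice dimensions).
#' @param min_body_fraction Minimum fraction of body voxels per patch
#'   (default 0.5).
#' @param seed Integer seed.
#' @return List of `patch_pair` objects: `list(mr = side x side x 3 array,
#'   ct = side x side matrix, slice, row, col)`.
#' @export
sample_patches <- function(mr, ct, mask, n, side = 128L,
                           min_body_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(mr, "multi_sequence_volume"), is_image_volume(ct))
  m <- mask_array(mask, ct)
  check_same_geometry(ct, mask)
  side <- as.integer(side)
  d <- dim(ct$data)
  if (side > d[1] || side > d[2])
    stop("invalid argument: patch side exceeds slice dimensions", call. = FALSE)
  if (min_body_fraction < 0 || min_body_fraction > 1)
    stop("invalid argument: min_body_fraction must be in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L) return(list())

  # admissible top-left corners per slice via 2D summed-area tables
  need <- min_body_fraction * side * side
  pos <- vector("list", d[3])
  nr <- d[1] - side + 1L
  nc <- d[2] - side + 1L
  for (k in seq_len(d[3])) {
    S <- apply(apply(m[, , k] + 0, 2, cumsum), 1, cumsum)  # transposed SAT
    S <- t(S)
    Sp <- matrix(0, d[1] + 1L, d[2] + 1L)
    Sp[-1, -1] <- S
    r0 <- seq_len(nr)
    c0 <- seq_len(nc)
    sums <- Sp[r0 + side, c0 + side, drop = FALSE] -
      Sp[r0, c0 + side, drop = FALSE] -
      Sp[r0 + side, c0, drop = FALSE] + Sp[r0, c0, drop = FALSE]
    ok <- which(sums >= need - 1e-9, arr.ind = TRUE)
    if (nrow(ok) > 0)
      pos[[k]] <- cbind(slice = k, row = ok[, 1], col = ok[, 2])
  }
  pos <- do.call(rbind, pos)
  if (is.null(pos) || nrow(pos) == 0)
    stop("sampling failure: no admissible patch position meets the body-fraction requirement",
         call. = FALSE)
  set.seed(as.integer(seed))
  pick <- sample.int(nrow(pos), n, replace = TRUE)
  lapply(pick, function(i) {
    k <- pos[i, 1]; r <- pos[i, 2]; cc <- pos[i, 3]
    rows <- r:(r + side - 1L); cols <- cc:(cc + side - 1L)
    structure(list(mr = mr$data[rows, cols, k, , drop = FALSE][, , 1, ],
                   ct = ct$data[rows, cols, k],
                   slice = k, row = r, col = cc),
              class = "patch_pair")
  })
}

# bilinear sampling of a matrix at fractional coordinates; out-of-bounds
# positions get `fill`
bilinear_sample <- function(img, ri, ci, fill) {
  d <- dim(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
    out <- rep(fill, length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  v00 <- get(r0, c0); v10 <- get(r0 + 1, c0)
  v01 <- get(r0, c0 + 1); v11 <- get(r0 + 1, c0 + 1)
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

#' Randomly augment a patch pair
#'
#' Applies one identical geometric transform -- horizontal flip (probability
#' `flip_p`), rotation, zoom and shift about the patch centre, with bilinear
#' interpolation -- to all MR channels and the CT patch.  Pixels exposed by
#' the transform are filled with the background values (MR 0, CT -1000).
#' Degenerate parameters (`flip_p = 0`, `max_shift_frac = 0`,
#' `zoom_range = c(1, 1)`, `max_rot_deg = 0`) give the identity.
#'
#' @param pair A `patch_pair` from [sample_patches()].
#' @param params List: `flip_p` (default 0.5), `max_shift_frac` (default
#'   0.1, fraction of the side), `zoom_range` (default `c(0.9, 1.1)`),
#'   `max_rot_deg` (default 10).
#' @param seed Integer seed.
#' @return The transformed `patch_pair`.
#' @export
augment_pair <- function(pair, params = list(), seed = 1L) {
  stopifnot(inherits(pair, "patch_pair"))
  p <- utils::modifyList(list(flip_p = 0.5, max_shift_frac = 0.1,
                              zoom_range = c(0.9, 1.1), max_rot_deg = 10),
                         params)
  if (p$flip_p < 0 || p$flip_p > 1 || p$max_shift_frac < 0 ||
      p$max_rot_deg < 0 || any(p$zoom_range <= 0))
    stop("augmentation parameters out of range", call. = FALSE)
  set.seed(as.integer(seed))
  side <- nrow(pair$ct)
  flip <- stats::runif(1) < p$flip_p
  shift <- stats::runif(2, -1, 1) * p$max_shift_frac * side
  zoom <- stats::runif(1, p$zoom_range[1], p$zoom_range[2])
  theta <- stats::runif(1, -1, 1) * p$max_rot_deg * pi / 180

  ctr <- (side + 1) / 2
  g <- expand.grid(r = seq_len(side), c = seq_len(side))
  # inverse map: undo shift, then zoom, then rotation, then flip
  xr <- g$r - ctr - shift[1]
  xc <- g$c - ctr - shift[2]
  xr <- xr / zoom; xc <- xc / zoom
  if (theta != 0) {
    cs <- cos(-theta); sn <- sin(-theta)
    tmp <- xr * cs - xc * sn
    xc <- xr * sn + xc * cs
    xr <- tmp
  }
  if (flip) xc <- -xc
  ri <- xr + ctr
  ci <- xc + ctr

  out <- pair
  out$ct <- matrix(bilinear_sample(pair$ct, ri, ci, fill = -1000), side, side)
  mr <- array(0, dim(pair$mr))
  for (ch in seq_len(dim(pair$mr)[3]))
    mr[, , ch] <- matrix(bilinear_sample(pair$mr[, , ch], ri, ci, fill = 0),
                         side, side)
  out$mr <- mr
  out
}
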