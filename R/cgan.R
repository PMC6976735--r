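#' Generator configuration (U-Net)
#'
#' The generator is a fully-convolutional U-Net: `depth` encoder levels of
#' strided 4x4 convolutions (stride 2, batch norm except the first level,
#' LeakyReLU 0.2), a mirrored decoder of 4x4 transposed convolutions (batch
#' norm + ReLU) with skip concatenations, and a final tanh scaled linearly
#' onto the output HU range.  Feature widths double per level, capped at
#' `8 * base_width`.
#'
#' @param in_channels Input channels (3: T1w, T2w, FLAIR).
#' @param out_channels Output channels (1: HU).
#' @param depth Encoder levels (>= 2); training patch sides must be
#'   divisible by `2^depth`.
#' @param base_width Feature maps at the first level.
#' @param norm Use batch normalization.
#' @param hu_range Output HU range mapped onto tanh's \[-1, 1\]
#'   (default `c(-1024, 3071)`, covering air to metal).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(in_channels = 3L, out_channels = 1L, depth = 5L,
                             base_width = 64L, norm = TRUE,
                             hu_range = c(-1024, 3071)) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("`depth` must be >= 2", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = depth, base_width = as.integer(base_width),
                 norm = isTRUE(norm), hu_range = as.numeric(hu_range)),
            class = "generator_config")
}

#' Discriminator configuration (PatchGAN)
#'
#' A patch-wise discriminator scoring overlapping receptive fields of the
#' concatenated (MR condition, CT candidate) image.  The layer stack (4x4
#' convolutions; `n` stride-2 layers followed by two stride-1 layers, the
#' last mapping to one logit channel) is derived from the requested
#' per-unit receptive field: the achievable receptive fields are
#' 16, 34, 70, 142, ... px and the closest one is chosen, so the default
#' request of 32 px yields an actual field of 34 px (within the +/-2 px
#' design tolerance).
#'
#' @param receptive_field Requested per-output-unit receptive field (px).
#' @param base_width Feature maps of the first layer.
#' @param in_channels Input channels (3 MR + 1 CT = 4).
#' @return Object of class `discriminator_config` with the derived `layers`
#'   and the actual `receptive_field`.
#' @export
discriminator_config <- function(receptive_field = 32L, base_width = 64L,
                                 in_channels = 4L) {
  rf_for <- function(n2) {
    r <- 4          # last k4 s1 conv
    r <- 4 + (r - 1) * 1   # penultimate k4 s1 conv
    for (i in seq_len(n2)) r <- 4 + (r - 1) * 2
    r
  }
  cand <- vapply(1:6, rf_for, numeric(1))
  n2 <- which.min(abs(cand - receptive_field))
  w <- as.integer(base_width)
  layers <- list()
  inc <- as.integer(in_channels)
  for (i in seq_len(n2)) {
    outc <- min(w * 2^(i - 1), 8L * w)
    layers[[length(layers) + 1L]] <-
      list(k = 4L, s = 2L, pad = 1L, in_c = inc, out_c = as.integer(outc),
           bn = i > 1L, act = "lrelu")
    inc <- as.integer(outc)
  }
  outc <- min(w * 2^n2, 8L * w)
  layers[[length(layers) + 1L]] <-
    list(k = 4L, s = 1L, pad = 1L, in_c = inc, out_c = as.integer(outc),
         bn = TRUE, act = "lrelu")
  layers[[length(layers) + 1L]] <-
    list(k = 4L, s = 1L, pad = 1L, in_c = as.integer(outc), out_c = 1L,
         bn = FALSE, act = "none")
  structure(list(receptive_field = cand[n2], requested = receptive_field,
                 base_width = w, in_channels = as.integer(in_channels),
                 layers = layers),
            class = "discriminator_config")
}

#' Training configuration
#'
#' Defaults follow the training protocol at full scale (500 epochs,
#' mini-batch 32, 128-px patches, 9:1 train/validation split) with the
#' usual pix2pix optimisation settings (Adam, lr 2e-4, beta1 0.5,
#' L1 weight 100).
#'
#' @param epochs,batch_size,lambda_l1,lr,beta1,beta2 Optimiser/loop settings.
#' @param lr_decay_from Epoch after which the learning rate decays linearly
#'   to zero at the final epoch (the pix2pix schedule); `Inf` disables decay.
#' @param patch_side Training patch side (px).
#' @param val_fraction Fraction of slices held out for validation (1/10).
#' @param seed Integer seed controlling initialisation, the split and
#'   shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, batch_size = 32L, lambda_l1 = 100,
                         lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         lr_decay_from = Inf, patch_side = 128L,
                         val_fraction = 0.1, seed = 1L) {
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (lambda_l1 < 0) stop("`lambda_l1` must be >= 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lambda_l1 = lambda_l1, lr = lr, beta1 = beta1, beta2 = beta2,
                 lr_decay_from = lr_decay_from,
                 patch_side = as.integer(patch_side),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Named model profiles
#'
#' `"paper"` is the full-scale configuration (depth 5, width 64, 128-px
#' patches, 500 epochs); `"desk"` is a scaled-down profile for CPU-sized
#' experiments and tests (depth 3, width 16, 64-px patches, 50 epochs).
#'
#' @param name `"paper"` or `"desk"`.
#' @return List with `gen`, `disc` and `train` configurations.
#' @export
cgan_profile <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "paper")
    list(gen = generator_config(depth = 5L, base_width = 64L),
         disc = discriminator_config(32L, 64L),
         train = train_config())
  else
    list(gen = generator_config(depth = 3L, base_width = 16L),
         disc = discriminator_config(32L, 16L),
         train = train_config(epochs = 50L, batch_size = 8L, patch_side = 64L,
                         lr = 1e-3, lr_decay_from = 25L))
}

gen_channels <- function(cfg) {
  pmin(cfg$base_width * 2^(seq_len(cfg$depth) - 1), 8L * cfg$base_width)
}

#' Build an (untrained) U-Net generator
#'
#' The network follows the classic U-Net top level -- a full-resolution 3x3
#' stem convolution whose output skips to a full-resolution 3x3 output
#' convolution -- around a pix2pix-style strided core: `depth` strided 4x4
#' encoder convolutions mirrored by 4x4 transposed convolutions with skip
#' concatenations.  Weights use He initialisation (biases zero); batch-norm
#' scale/shift start at 1/0.  The network is fully convolutional: any input
#' whose spatial sides are multiples of `2^depth` maps to an output of
#' identical spatial shape with one channel.
#'
#' @param cfg A [generator_config()].
#' @return Object of class `cgan_generator`.
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  ch <- gen_channels(cfg)
  w0 <- cfg$base_width
  stem <- list(conv = conv_init(3L, cfg$in_channels, w0), bn = NULL)
  enc <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    inc <- if (i == 1) w0 else ch[i - 1]
    enc[[i]] <- list(conv = conv_init(4L, inc, ch[i]),
                     bn = if (cfg$norm && i > 1) bn_init(ch[i]) else NULL)
  }
  dec <- vector("list", cfg$depth)
  for (i in rev(seq_len(cfg$depth))) {
    inc <- if (i == cfg$depth) ch[i] else 2L * ch[i]
    outc <- if (i == 1) w0 else ch[i - 1]
    dec[[i]] <- list(convt = convt_init(4L, inc, outc),
                     bn = if (cfg$norm) bn_init(outc) else NULL)
  }
  outl <- list(conv1 = conv_init(3L, 2L * w0, w0),
               conv2 = conv_init(3L, w0, cfg$out_channels))
  structure(list(cfg = cfg, stem = stem, enc = enc, dec = dec, out = outl),
            class = "cgan_generator")
}

gen_forward <- function(model, x, train = TRUE, keep_cache = TRUE) {
  cfg <- model$cfg
  d <- dim(x)
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0)
    stop("configuration error: input sides must be divisible by 2^depth",
         call. = FALSE)
  caches <- list(enc = vector("list", cfg$depth),
                 dec = vector("list", cfg$depth))
  cf <- conv_forward(x, model$stem$conv, 1L, 1L, keep_cache)
  lf <- lrelu_forward(cf$y)
  s0 <- lf$y
  caches$stem <- list(conv = cf$cache, neg = if (keep_cache) lf$neg else NULL)
  skips <- vector("list", cfg$depth)
  h <- s0
  for (i in seq_len(cfg$depth)) {
    cc <- list(conv = NULL, bn = NULL, neg = NULL)
    cf <- conv_forward(h, model$enc[[i]]$conv, 2L, 1L, keep_cache)
    h <- cf$y
    cc$conv <- cf$cache
    if (!is.null(model$enc[[i]]$bn)) {
      bf <- bn_forward(h, model$enc[[i]]$bn, train)
      h <- bf$y
      if (keep_cache) cc$bn <- bf$cache
      model$enc[[i]]$bn <- bf$p
    }
    lf <- lrelu_forward(h)
    h <- lf$y
    if (keep_cache) cc$neg <- lf$neg
    caches$enc[[i]] <- cc
    skips[[i]] <- h
  }
  for (i in rev(seq_len(cfg$depth))) {
    cc <- list(convt = NULL, bn = NULL, neg = NULL)
    inp <- if (i == cfg$depth) h else concat_channels(h, skips[[i]])
    tf <- convt_forward(inp, model$dec[[i]]$convt, 2L, 1L)
    h <- tf$y
    if (keep_cache) cc$convt <- tf$cache
    if (!is.null(model$dec[[i]]$bn)) {
      bf <- bn_forward(h, model$dec[[i]]$bn, train)
      h <- bf$y
      if (keep_cache) cc$bn <- bf$cache
      model$dec[[i]]$bn <- bf$p
    }
    rf <- relu_forward(h)
    h <- rf$y
    if (keep_cache) cc$neg <- rf$neg
    caches$dec[[i]] <- cc
  }
  c1 <- conv_forward(concat_channels(h, s0), model$out$conv1, 1L, 1L, keep_cache)
  l1 <- lrelu_forward(c1$y)
  c2 <- conv_forward(l1$y, model$out$conv2, 1L, 1L, keep_cache)
  y <- tanh(c2$y)
  caches$out_layer <- list(conv1 = c1$cache, neg1 = if (keep_cache) l1$neg,
                           conv2 = c2$cache)
  if (keep_cache) caches$out <- y
  list(out = y, caches = caches, model = model)
}

gen_backward <- function(model, caches, dout) {
  cfg <- model$cfg
  ch <- gen_channels(cfg)
  grads <- list(stem = NULL, enc = vector("list", cfg$depth),
                dec = vector("list", cfg$depth), out = NULL)
  skip_grads <- vector("list", cfg$depth)
  w0 <- cfg$base_width
  g <- dout * (1 - caches$out^2)   # through tanh
  c2 <- conv_backward(g, model$out$conv2, caches$out_layer$conv2)
  g <- lrelu_backward(c2$dx, caches$out_layer$neg1)
  c1 <- conv_backward(g, model$out$conv1, caches$out_layer$conv1)
  grads$out <- list(conv1 = list(W = c1$W, b = c1$b),
                    conv2 = list(W = c2$W, b = c2$b))
  g <- c1$dx[, , , seq_len(w0), drop = FALSE]
  g_stem <- c1$dx[, , , w0 + seq_len(w0), drop = FALSE]
  for (i in seq_len(cfg$depth)) {
    g <- relu_backward(g, caches$dec[[i]]$neg)
    if (!is.null(model$dec[[i]]$bn)) {
      bb <- bn_backward(g, model$dec[[i]]$bn, caches$dec[[i]]$bn)
      g <- bb$dx
      grads$dec[[i]]$bn <- list(gamma = bb$gamma, beta = bb$beta)
    }
    tb <- convt_backward(g, model$dec[[i]]$convt, caches$dec[[i]]$convt)
    grads$dec[[i]]$convt <- list(W = tb$W, b = tb$b)
    if (i == cfg$depth) {
      skip_grads[[i]] <- tb$dx
    } else {
      skip_grads[[i]] <- tb$dx[, , , ch[i] + seq_len(ch[i]), drop = FALSE]
      g <- tb$dx[, , , seq_len(ch[i]), drop = FALSE]
    }
  }
  g <- skip_grads[[cfg$depth]]
  for (i in rev(seq_len(cfg$depth))) {
    g <- lrelu_backward(g, caches$enc[[i]]$neg)
    if (!is.null(model$enc[[i]]$bn)) {
      bb <- bn_backward(g, model$enc[[i]]$bn, caches$enc[[i]]$bn)
      g <- bb$dx
      grads$enc[[i]]$bn <- list(gamma = bb$gamma, beta = bb$beta)
    }
    cb <- conv_backward(g, model$enc[[i]]$conv, caches$enc[[i]]$conv)
    grads$enc[[i]]$conv <- list(W = cb$W, b = cb$b)
    g <- if (i > 1) cb$dx + skip_grads[[i - 1]] else cb$dx
  }
  g <- g + g_stem
  g <- lrelu_backward(g, caches$stem$neg)
  sb <- conv_backward(g, model$stem$conv, caches$stem$conv, want_dx = FALSE)
  grads$stem <- list(conv = list(W = sb$W, b = sb$b))
  grads
}

#' Build an (untrained) PatchGAN discriminator
#'
#' @param cfg A [discriminator_config()].
#' @return Object of class `cgan_discriminator`.
#' @export
build_discriminator <- function(cfg) {
  stopifnot(inherits(cfg, "discriminator_config"))
  layers <- lapply(cfg$layers, function(l)
    list(conv = conv_init(l$k, l$in_c, l$out_c),
         bn = if (l$bn) bn_init(l$out_c) else NULL,
         spec = l))
  structure(list(cfg = cfg, layers = layers), class = "cgan_discriminator")
}

disc_forward <- function(model, x, train = TRUE, keep_cache = TRUE) {
  if (min(dim(x)[1:2]) < model$cfg$receptive_field)
    stop("configuration error: receptive field exceeds input side", call. = FALSE)
  caches <- vector("list", length(model$layers))
  h <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    cc <- list(conv = NULL, bn = NULL, neg = NULL)
    cf <- conv_forward(h, l$conv, l$spec$s, l$spec$pad, keep_cache)
    h <- cf$y
    cc$conv <- cf$cache
    if (!is.null(l$bn)) {
      bf <- bn_forward(h, l$bn, train)
      h <- bf$y
      if (keep_cache) cc$bn <- bf$cache
      model$layers[[i]]$bn <- bf$p
    }
    if (l$spec$act == "lrelu") {
      lf <- lrelu_forward(h)
      h <- lf$y
      if (keep_cache) cc$neg <- lf$neg
    }
    caches[[i]] <- cc
  }
  list(scores = h, caches = caches, model = model)
}

disc_backward <- function(model, caches, dscores, want_dx = TRUE) {
  grads <- vector("list", length(model$layers))
  g <- dscores
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    gl <- list(conv = NULL, bn = NULL)
    if (l$spec$act == "lrelu") g <- lrelu_backward(g, caches[[i]]$neg)
    if (!is.null(l$bn)) {
      bb <- bn_backward(g, l$bn, caches[[i]]$bn)
      g <- bb$dx
      gl$bn <- list(gamma = bb$gamma, beta = bb$beta)
    }
    cb <- conv_backward(g, l$conv, caches[[i]]$conv,
                        want_dx = want_dx || i > 1)
    gl$conv <- list(W = cb$W, b = cb$b)
    grads[[i]] <- gl
    g <- cb$dx
  }
  list(grads = grads, dx = g)
}

#' Mean absolute error between two HU images
#'
#' The generator's L1 reconstruction term: `(1/n) * sum(|rct_i - sct_i|)`
#' over all voxels, in HU.
#'
#' @param rct,sct `image_volume`s or plain numeric arrays of identical shape.
#' @return Scalar MAE (HU).
#' @export
l1_loss <- function(rct, sct) {
  a <- if (is_image_volume(rct)) rct$data else rct
  b <- if (is_image_volume(sct)) sct$data else sct
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("invalid input: shape mismatch", call. = FALSE)
  mean(abs(a - b))
}

#' Adversarial (pix2pix) losses from discriminator score grids
#'
#' Binary cross-entropy on sigmoid scores: the discriminator targets
#' real -> 1 and fake -> 0; the generator targets fake -> 1.
#'
#' @param d_scores_real,d_scores_fake Logit grids (arrays) from the
#'   discriminator on real and generated pairs.
#' @return List with `disc_loss` (mean of the real and fake BCE terms),
#'   `gen_adv_loss`, and the components `bce_real`, `bce_fake`.
#' @export
adversarial_losses <- function(d_scores_real, d_scores_fake) {
  br <- bce_with_logits(d_scores_real, 1)
  bf <- bce_with_logits(d_scores_fake, 0)
  bg <- bce_with_logits(d_scores_fake, 1)
  list(disc_loss = 0.5 * (br$loss + bf$loss), gen_adv_loss = bg$loss,
       bce_real = br$loss, bce_fake = bf$loss)
}

#' Partition dataset IDs into cross-validation folds
#'
#' Randomly divides the IDs into `k` disjoint groups whose sizes differ by
#' at most one (15 IDs at k = 5 give five groups of exactly three).
#'
#' @param ids Vector of dataset identifiers.
#' @param k Number of folds (<= number of IDs).
#' @param seed Integer seed; the partition is deterministic per seed.
#' @return Object of class `fold_split`: list with `folds` (list of k ID
#'   vectors), `k`, `seed`.
#' @export
make_cv_folds <- function(ids, k = 5L, seed = 1L) {
  k <- as.integer(k)
  n <- length(ids)
  if (k > n) stop("invalid argument: k exceeds the number of IDs", call. = FALSE)
  if (k < 1L) stop("invalid argument: k must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  perm <- sample(ids, n)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  grp <- rep(seq_len(k), sizes)
  folds <- split(perm, grp)
  names(folds) <- paste0("fold", seq_len(k))
  structure(list(folds = folds, k = k, seed = as.integer(seed)),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d folds (seed %d):\n", x$k, x$seed))
  for (i in seq_len(x$k))
    cat(" ", names(x$folds)[i], ":", paste(x$folds[[i]], collapse = ", "), "\n")
  invisible(x)
}

hu_to_unit <- function(hu, rng) (hu - rng[1]) / (rng[2] - rng[1]) * 2 - 1
unit_to_hu <- function(u, rng) (u + 1) / 2 * (rng[2] - rng[1]) + rng[1]
mr_to_unit <- function(x) x / 2047.5 - 1

# assemble (H, W, N, C) training batches from patch pairs
patch_batch <- function(patches, idx, hu_rng) {
  side <- nrow(patches[[idx[1]]]$ct)
  nb <- length(idx)
  X <- array(0, c(side, side, nb, 3L))
  Y <- array(0, c(side, side, nb, 1L))
  for (j in seq_along(idx)) {
    X[, , j, ] <- mr_to_unit(patches[[idx[j]]]$mr)
    Y[, , j, 1L] <- hu_to_unit(patches[[idx[j]]]$ct, hu_rng)
  }
  list(X = X, Y = Y)
}

#' Fit the MR-to-CT conditional GAN
#'
#' Alternating optimisation of a PatchGAN discriminator and a U-Net
#' generator on aligned MR/CT patch pairs.  The generator objective is
#' `BCE(D(mr, G(mr)), 1) + lambda_l1 * MAE(ct, G(mr))`; the discriminator
#' sees real and generated pairs with binary cross-entropy targets.  Both
#' networks are He-initialised with zero biases and trained with Adam.
#' Patches are split 9:1 into training and validation at the slice level
#' (patches cut from the same slice stay on one side of the split), and the
#' per-epoch training/validation L1 (in HU) is recorded.
#'
#' @param patches List of `patch_pair`s from [sample_patches()] (MR in
#'   standardized intensities, CT in HU).
#' @param gen_cfg,disc_cfg,train_cfg Configurations; defaults are the desk
#'   profile from [cgan_profile()].
#' @param generator,discriminator Optional pre-built (or pre-trained)
#'   networks to continue from.
#' @param freeze_discriminator If TRUE, the discriminator is not updated.
#' @param verbose Print per-epoch losses.
#' @return Object of class `cgan`: list with `generator`, `discriminator`,
#'   `history` (data.frame epoch, d_loss, g_adv, g_l1_train, g_l1_val),
#'   and the three configs.  A NaN/Inf loss aborts with the epoch index.
#' @seealso [predict.cgan()], [predict_sct()]
#' @export
fit_cgan <- function(patches, gen_cfg = NULL, disc_cfg = NULL,
                     train_cfg = NULL, generator = NULL, discriminator = NULL,
                     freeze_discriminator = FALSE, verbose = FALSE) {
  if (length(patches) < 1) stop("invalid input: empty training set", call. = FALSE)
  prof <- cgan_profile("desk")
  if (is.null(gen_cfg)) gen_cfg <- prof$gen
  if (is.null(disc_cfg)) disc_cfg <- prof$disc
  if (is.null(train_cfg)) train_cfg <- prof$train
  set.seed(train_cfg$seed)
  if (is.null(generator)) generator <- build_generator(gen_cfg)
  if (is.null(discriminator)) discriminator <- build_discriminator(disc_cfg)
  hu_rng <- gen_cfg$hu_range

  # 9:1 slice-level split
  keys <- vapply(patches, function(p)
    paste0(if (is.null(p$subject)) "s" else p$subject, "_", p$slice), "")
  uk <- unique(keys)
  if (length(uk) > 1) {
    nval <- max(1L, round(train_cfg$val_fraction * length(uk)))
    val_keys <- sample(uk, nval)
    val_idx <- which(keys %in% val_keys)
    train_idx <- setdiff(seq_along(patches), val_idx)
    if (length(train_idx) == 0) { train_idx <- seq_along(patches); val_idx <- integer() }
  } else {
    train_idx <- seq_along(patches)
    val_idx <- integer()
  }

  opt_g <- NULL
  opt_d <- NULL
  tstep <- 0L
  tstep_d <- 0L
  hist <- vector("list", train_cfg$epochs)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr_ep <- if (is.finite(train_cfg$lr_decay_from) && epoch > train_cfg$lr_decay_from)
      train_cfg$lr * (train_cfg$epochs - epoch + 1) /
        (train_cfg$epochs - train_cfg$lr_decay_from + 1)
    else train_cfg$lr
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / train_cfg$batch_size)
    ep_d <- ep_adv <- ep_l1 <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * train_cfg$batch_size + 1):min(b * train_cfg$batch_size, length(ord))]
      batch <- patch_batch(patches, idx, hu_rng)

      gf <- gen_forward(generator, batch$X, train = TRUE)
      generator <- gf$model
      fake <- gf$out

      # one fake-pair pass drives the discriminator update and, through the
      # same (pre-update) discriminator, the generator's adversarial gradient
      df <- disc_forward(discriminator, concat_channels(batch$X, fake), train = TRUE)
      discriminator <- df$model
      bf <- bce_with_logits(df$scores, 0)
      bg <- bce_with_logits(df$scores, 1)
      g_adv <- bg$loss
      db <- disc_backward(discriminator, df$caches, bg$grad, want_dx = TRUE)
      if (!freeze_discriminator) {
        dr <- disc_forward(discriminator, concat_channels(batch$X, batch$Y), train = TRUE)
        discriminator <- dr$model
        br <- bce_with_logits(dr$scores, 1)
        d_loss <- 0.5 * (br$loss + bf$loss)
        gr_r <- disc_backward(discriminator, dr$caches, 0.5 * br$grad,
                              want_dx = FALSE)$grads
        gr_f <- disc_backward(discriminator, df$caches, 0.5 * bf$grad,
                              want_dx = FALSE)$grads
        gsum <- add_grad_trees(gr_r, gr_f)
        if (is.null(opt_d)) opt_d <- adam_state_init(gsum)
        tstep_d <- tstep_d + 1L
        res <- adam_step_tree(discriminator$layers, gsum, opt_d,
                              lr_ep, train_cfg$beta1, train_cfg$beta2,
                              1e-8, tstep_d)
        discriminator$layers <- res$p
        opt_d <- res$s
      } else {
        d_loss <- bf$loss
      }

      nmr <- dim(batch$X)[4]
      dfake_adv <- db$dx[, , , nmr + seq_len(dim(fake)[4]), drop = FALSE]
      resid <- fake - batch$Y
      g_l1 <- mean(abs(resid))
      dfake <- dfake_adv + train_cfg$lambda_l1 * sign(resid) / length(resid)
      ggr <- gen_backward(generator, gf$caches, dfake)
      if (is.null(opt_g)) opt_g <- adam_state_init(ggr)
      tstep <- tstep + 1L
      res <- adam_step_tree(generator[c("stem", "enc", "dec", "out")], ggr,
                            opt_g, lr_ep, train_cfg$beta1, train_cfg$beta2,
                            1e-8, tstep)
      generator$stem <- res$p$stem
      generator$enc <- res$p$enc
      generator$dec <- res$p$dec
      generator$out <- res$p$out
      opt_g <- res$s

      if (!is.finite(d_loss) || !is.finite(g_adv) || !is.finite(g_l1))
        stop(sprintf("divergence error: non-finite loss at epoch %d", epoch),
             call. = FALSE)
      ep_d <- ep_d + d_loss; ep_adv <- ep_adv + g_adv; ep_l1 <- ep_l1 + g_l1
    }

    g_l1_val <- NA_real_
    if (length(val_idx) > 0) {
      vb <- patch_batch(patches, val_idx, hu_rng)
      pv <- gen_forward(generator, vb$X, train = FALSE, keep_cache = FALSE)$out
      g_l1_val <- mean(abs(pv - vb$Y)) * (hu_rng[2] - hu_rng[1]) / 2
    }
    hist[[epoch]] <- data.frame(epoch = epoch, d_loss = ep_d / nb,
                                g_adv = ep_adv / nb,
                                g_l1_train = ep_l1 / nb * (hu_rng[2] - hu_rng[1]) / 2,
                                g_l1_val = g_l1_val)
    if (verbose)
      cat(sprintf("epoch %3d  d %.4f  g_adv %.4f  l1_train %.1f HU  l1_val %.1f HU\n",
                  epoch, ep_d / nb, ep_adv / nb,
                  ep_l1 / nb * (hu_rng[2] - hu_rng[1]) / 2, g_l1_val))
  }
  structure(list(generator = generator, discriminator = discriminator,
                 history = do.call(rbind, hist), gen_cfg = gen_cfg,
                 disc_cfg = disc_cfg, train_cfg = train_cfg),
            class = "cgan")
}

add_grad_trees <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  keys <- if (!is.null(names(a))) names(a) else seq_along(a)
  for (k in keys) {
    if (is.null(a[[k]])) next
    a[[k]] <- add_grad_trees(a[[k]], b[[k]])
  }
  a
}

#' Alias for [fit_cgan()]
#' @inheritParams fit_cgan
#' @param ... Passed to [fit_cgan()].
#' @export
train_cgan <- function(patches, ...) fit_cgan(patches, ...)

#' @export
print.cgan <- function(x, ...) {
  h <- x$history
  cat(sprintf("<cgan> U-Net generator (depth %d, width %d) + PatchGAN (rf %d px)\n",
              x$gen_cfg$depth, x$gen_cfg$base_width, x$disc_cfg$receptive_field))
  cat(sprintf("  trained %d epochs; final train L1 %.1f HU, val L1 %.1f HU\n",
              nrow(h), h$g_l1_train[nrow(h)], h$g_l1_val[nrow(h)]))
  invisible(x)
}

#' @export
summary.cgan <- function(object, ...) {
  print(object)
  cat("training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.cgan <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$g_l1_train, type = "l", xlab = "epoch",
                 ylab = "L1 (HU)", main = "cGAN training history", ...)
  if (any(is.finite(h$g_l1_val)))
    graphics::lines(h$epoch, h$g_l1_val, lty = 2)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(h)
}

#' Predict a synthetic CT volume from multi-sequence MR
#'
#' Slice-wise fully-convolutional inference with the trained generator:
#' training uses patches, but prediction runs on full-sized slices.  Sides
#' not divisible by `2^depth` are reflect-padded and cropped back, so the
#' output geometry equals the input geometry.  Output HU lie within the
#' configured range.
#'
#' @param model A fitted [fit_cgan()] object (an untrained
#'   [build_generator()] wrapped the same way also works).
#' @param mr A `multi_sequence_volume` with 3 channels, in the same
#'   intensity convention used for training.
#' @return An `image_volume` of predicted HU.
#' @export
predict_sct <- function(model, mr) {
  gen <- if (inherits(model, "cgan")) model$generator else model
  stopifnot(inherits(gen, "cgan_generator"))
  if (!inherits(mr, "multi_sequence_volume") || dim(mr$data)[4] != 3L)
    stop("invalid input: expected a 3-channel multi_sequence_volume", call. = FALSE)
  cfg <- gen$cfg
  m <- 2^cfg$depth
  d <- dim(mr$data)
  th <- ceiling(d[1] / m) * m
  tw <- ceiling(d[2] / m) * m
  out <- array(0, d[1:3])
  for (k in seq_len(d[3])) {
    x <- mr_to_unit(mr$data[, , k, , drop = FALSE][, , 1, ])
    if (th != d[1] || tw != d[2]) x <- reflect_pad_hw(x, th, tw)
    xb <- array(x, c(th, tw, 1L, 3L))   # (H, W, N=1, C) channel-last
    y <- gen_forward(gen, xb, train = FALSE, keep_cache = FALSE)$out
    out[, , k] <- unit_to_hu(y[seq_len(d[1]), seq_len(d[2]), 1L, 1L], cfg$hu_range)
  }
  image_volume(out, mr$spacing, mr$origin)
}

#' @rdname predict_sct
#' @param object A fitted `cgan` model.
#' @param newdata A `multi_sequence_volume`.
#' @param ... Unused.
#' @export
predict.cgan <- function(object, newdata, ...) predict_sct(object, newdata)
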