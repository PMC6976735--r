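test_that("the generator is fully convolutional: patch-trained shapes scale to full slices", {
  set.seed(1)
  cfg <- generator_config(depth = 5L, base_width = 16L)
  gen <- build_generator(cfg)
  x128 <- array(stats::rnorm(128 * 128 * 3), c(128, 128, 1, 3))
  y128 <- mr2sct:::gen_forward(gen, x128, train = FALSE, keep_cache = FALSE)$out
  expect_identical(dim(y128), c(128L, 128L, 1L, 1L))
  x512 <- array(stats::rnorm(512 * 512 * 3), c(512, 512, 1, 3))
  y512 <- mr2sct:::gen_forward(gen, x512, train = FALSE, keep_cache = FALSE)$out
  expect_identical(dim(y512), c(512L, 512L, 1L, 1L))
  expect_true(all(y512 >= -1 & y512 <= 1))
  expect_error(mr2sct:::gen_forward(gen, array(0, c(60, 60, 1, 3))),
               "divisible")
})

test_that("an untrained generator predicts finite HU within the configured range", {
  set.seed(2)
  gen <- build_generator(generator_config(depth = 3L, base_width = 8L))
  model <- structure(list(generator = gen), class = "cgan")
  mk <- function() image_volume(array(stats::runif(70 * 70 * 2, 0, 4095), c(70, 70, 2)))
  mr <- stack_sequences(mk(), mk(), mk())   # 70 not divisible by 8: exercises padding
  sct <- predict_sct(model, mr)
  expect_identical(dim(sct$data), c(70L, 70L, 2L))
  expect_true(all(is.finite(sct$data)))
  expect_true(all(sct$data >= -1024 & sct$data <= 3071))
  expect_error(predict_sct(model, mk()), "3-channel")
})

test_that("discriminator receptive field matches layer-stack arithmetic within 2 px of the request", {
  cfg <- discriminator_config(receptive_field = 32L, base_width = 8L)
  # independent oracle: r_in = k + (r_out - 1) * s, folded from the top
  r <- 1
  for (l in rev(cfg$layers)) r <- l$k + (r - 1) * l$s
  expect_equal(r, cfg$receptive_field)
  expect_lte(abs(cfg$receptive_field - 32), 2)

  set.seed(3)
  disc <- build_discriminator(cfg)
  x <- array(stats::rnorm(128 * 128 * 2 * 4), c(128, 128, 2, 4))
  s <- mr2sct:::disc_forward(disc, x, train = TRUE)$scores
  expect_gt(prod(dim(s)[1:2]), 1)   # patch-wise score grid, not a scalar
  expect_equal(dim(s)[4], 1L)
  # permuting the batch permutes the scores identically
  xp <- x[, , c(2, 1), , drop = FALSE]
  sp <- mr2sct:::disc_forward(disc, xp, train = TRUE)$scores
  expect_equal(sp[, , 1, 1], s[, , 2, 1], tolerance = 1e-12)
  expect_error(mr2sct:::disc_forward(disc, array(0, c(16, 16, 1, 4))),
               "receptive field")
})

test_that("the L1 term reproduces hand-computed mean absolute errors", {
  expect_identical(l1_loss(array(5, c(2, 2, 1)), array(5, c(2, 2, 1))), 0)
  expect_identical(l1_loss(c(0, 100), c(10, 90)), 10)
  set.seed(4)
  a <- array(stats::rnorm(60), c(5, 4, 3))
  expect_equal(l1_loss(a, a + 7.5), 7.5)
  expect_equal(l1_loss(image_volume(a), image_volume(a - 2)), 2)
  expect_error(l1_loss(a, a[, , 1:2]), "shape mismatch")
})

test_that("adversarial BCE losses have the right closed forms and limits", {
  z0 <- array(0, c(3, 3, 1, 2))
  al <- adversarial_losses(z0, z0)
  expect_equal(al$bce_real, log(2), tolerance = 1e-12)
  expect_equal(al$bce_fake, log(2), tolerance = 1e-12)
  expect_equal(al$disc_loss, log(2), tolerance = 1e-12)
  expect_equal(al$gen_adv_loss, log(2), tolerance = 1e-12)
  # confident correct discriminator drives its loss to zero
  conf <- adversarial_losses(z0 + 30, z0 - 30)
  expect_lt(conf$disc_loss, 1e-10)
  # generator loss decreases monotonically as fake logits increase
  gl <- vapply(seq(-4, 4, by = 1), function(v)
    adversarial_losses(z0, z0 + v)$gen_adv_loss, 0)
  expect_true(all(diff(gl) < 0))
  expect_error(adversarial_losses(z0 + Inf * 0 / 0, z0), "non-finite")
})

test_that("cross-validation folds partition IDs into near-equal groups", {
  f <- make_cv_folds(1:15, k = 5, seed = 3)
  expect_equal(unname(lengths(f$folds)), rep(3L, 5))
  expect_setequal(unlist(f$folds), 1:15)
  f10 <- make_cv_folds(1:10, k = 5, seed = 1)
  expect_equal(unname(lengths(f10$folds)), rep(2L, 5))
  for (seed in 1:8) {
    fs <- make_cv_folds(letters[1:13], k = 4, seed = seed)
    expect_setequal(unlist(fs$folds), letters[1:13])
    expect_lte(diff(range(lengths(fs$folds))), 1)
    expect_equal(sum(lengths(fs$folds)), 13L)
  }
  expect_identical(make_cv_folds(1:15, 5, seed = 9)$folds,
                   make_cv_folds(1:15, 5, seed = 9)$folds)
  expect_error(make_cv_folds(1:3, k = 5), "invalid argument")
})

test_that("analytic gradients match central differences on tiny networks", {
  set.seed(42)
  gen <- build_generator(generator_config(depth = 2L, base_width = 2L))
  x <- array(stats::rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  tgt <- array(stats::runif(8 * 8 * 2, -0.8, 0.8), c(8, 8, 2, 1))
  lossfun <- function(g)
    mean(abs(mr2sct:::gen_forward(g, x, train = TRUE)$out - tgt))
  fw <- mr2sct:::gen_forward(gen, x, train = TRUE)
  dout <- sign(fw$out - tgt) / length(fw$out)
  gr <- mr2sct:::gen_backward(gen, fw$caches, dout)
  getleaf <- function(tree, p) { for (k in p) tree <- tree[[k]]; tree }
  setleaf <- function(tree, p, val) {
    if (length(p) == 1) { tree[[p[[1]]]] <- val; return(tree) }
    tree[[p[[1]]]] <- setleaf(tree[[p[[1]]]], p[-1], val)
    tree
  }
  paths <- list(list("stem", "conv", "W"), list("enc", 1L, "conv", "W"),
                list("enc", 2L, "conv", "W"), list("enc", 2L, "bn", "gamma"),
                list("dec", 2L, "convt", "W"), list("dec", 2L, "bn", "beta"),
                list("dec", 1L, "convt", "W"), list("dec", 1L, "bn", "gamma"),
                list("out", "conv1", "W"), list("out", "conv2", "W"),
                list("enc", 1L, "conv", "b"))
  h <- 1e-6
  set.seed(7)
  for (p in paths) {
    leafp <- getleaf(gen, p)
    leafg <- getleaf(gr, p)
    expect_false(is.null(leafg))
    for (i in sample(length(leafp), min(3, length(leafp)))) {
      lp <- leafp; lp[i] <- lp[i] + h
      lm <- leafp; lm[i] <- lm[i] - h
      num <- (lossfun(setleaf(gen, p, lp)) - lossfun(setleaf(gen, p, lm))) / (2 * h)
      expect_lt(abs(num - leafg[i]) / max(1e-6, abs(num) + abs(leafg[i])), 1e-4)
    }
  }

  set.seed(5)
  disc <- build_discriminator(discriminator_config(16L, 2L))
  xd <- array(stats::rnorm(34 * 34 * 2 * 4), c(34, 34, 2, 4))
  dloss <- function(d) {
    s <- mr2sct:::disc_forward(d, xd, train = TRUE)$scores
    mr2sct:::bce_with_logits(s, 1)$loss
  }
  fwd <- mr2sct:::disc_forward(disc, xd, train = TRUE)
  bce <- mr2sct:::bce_with_logits(fwd$scores, 1)
  db <- mr2sct:::disc_backward(disc, fwd$caches, bce$grad)
  for (li in seq_along(disc$layers)) {
    leafg <- db$grads[[li]]$conv$W
    for (i in sample(length(disc$layers[[li]]$conv$W), 2)) {
      dp <- disc; dp$layers[[li]]$conv$W[i] <- dp$layers[[li]]$conv$W[i] + h
      dm <- disc; dm$layers[[li]]$conv$W[i] <- dm$layers[[li]]$conv$W[i] - h
      num <- (dloss(dp) - dloss(dm)) / (2 * h)
      expect_lt(abs(num - leafg[i]) / max(1e-6, abs(num) + abs(leafg[i])), 1e-4)
    }
  }
})

test_that("generator total loss decomposes into adversarial plus weighted L1 components", {
  set.seed(6)
  gen <- build_generator(generator_config(depth = 2L, base_width = 4L))
  disc <- build_discriminator(discriminator_config(16L, 4L))
  x <- array(stats::rnorm(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  y <- array(stats::runif(32 * 32 * 2, -1, 1), c(32, 32, 2, 1))
  fake <- mr2sct:::gen_forward(gen, x, train = TRUE)$out
  sc <- mr2sct:::disc_forward(disc, mr2sct:::concat_channels(x, fake),
                              train = TRUE)$scores
  lambda <- 100
  total <- adversarial_losses(sc, sc)$gen_adv_loss + lambda * l1_loss(y, fake)
  # independent recomputation from first principles
  bce <- mean(log(1 + exp(-sc)))
  expect_equal(total, bce + lambda * mean(abs(fake - y)), tolerance = 1e-10)
})

tiny_patches <- function(n = 16, side = 32, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    mr <- array(stats::runif(side * side * 3, 0, 4095), c(side, side, 3))
    structure(list(mr = mr, ct = 500 * round(mr[, , 1] / 4095) - 800,
                   slice = ((i - 1) %% 4) + 1L, row = 1L, col = 1L),
              class = "patch_pair")
  })
}

test_that("a frozen zero discriminator with zero L1 weight leaves the generator unchanged", {
  ps <- tiny_patches()
  prof <- cgan_profile("desk")
  gcfg <- generator_config(depth = 3L, base_width = 4L)
  dcfg <- discriminator_config(16L, 4L)
  tc <- train_config(epochs = 1L, batch_size = 8L, lambda_l1 = 0,
                     patch_side = 32L, seed = 5L)
  set.seed(5)
  gen0 <- build_generator(gcfg)
  disc0 <- build_discriminator(dcfg)
  for (i in seq_along(disc0$layers)) {
    disc0$layers[[i]]$conv$W[] <- 0
    disc0$layers[[i]]$conv$b[] <- 0
  }
  fit <- fit_cgan(ps, gcfg, dcfg, tc, generator = gen0, discriminator = disc0,
                  freeze_discriminator = TRUE)
  # adversarial loss stuck at ln 2 and no gradient reaches the generator
  expect_equal(fit$history$g_adv, log(2), tolerance = 1e-12)
  expect_equal(fit$generator$stem$conv$W, gen0$stem$conv$W, tolerance = 1e-14)
  expect_equal(fit$generator$enc[[2]]$conv$W, gen0$enc[[2]]$conv$W,
               tolerance = 1e-14)
  expect_equal(fit$generator$dec[[1]]$convt$W, gen0$dec[[1]]$convt$W,
               tolerance = 1e-14)
  expect_equal(fit$generator$out$conv2$W, gen0$out$conv2$W, tolerance = 1e-14)
})

test_that("training is deterministic for a fixed seed and rejects empty input", {
  ps <- tiny_patches()
  gcfg <- generator_config(depth = 2L, base_width = 4L)
  dcfg <- discriminator_config(16L, 4L)
  tc <- train_config(epochs = 2L, batch_size = 8L, patch_side = 32L, seed = 42L)
  f1 <- fit_cgan(ps, gcfg, dcfg, tc)
  f2 <- fit_cgan(ps, gcfg, dcfg, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generator$enc[[1]]$conv$W, f2$generator$enc[[1]]$conv$W)
  expect_error(fit_cgan(list(), gcfg, dcfg, tc), "empty")
})

test_that("a short fit on a deterministic MR-to-CT task reduces training L1", {
  ps <- tiny_patches(n = 32, seed = 2)
  gcfg <- generator_config(depth = 2L, base_width = 8L)
  dcfg <- discriminator_config(16L, 8L)
  tc <- train_config(epochs = 12L, batch_size = 8L, patch_side = 32L,
                     lr = 1e-3, seed = 7L)
  fit <- fit_cgan(ps, gcfg, dcfg, tc)
  h <- fit$history
  expect_lt(h$g_l1_train[12], 0.65 * h$g_l1_train[1])
  expect_true(all(is.finite(h$d_loss)))
  expect_s3_class(fit, "cgan")
  expect_output(print(fit), "U-Net")
})
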