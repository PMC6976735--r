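# Minimal convolutional network engine used by the conditional GAN.
# Tensors are numeric arrays with dims (H, W, N, C) -- channel-last, so a
# GEMM against an im2col unroll reshapes straight back into a tensor with no
# transposes.  Convolutions are im2col + GEMM (BLAS); transposed
# convolutions are the exact adjoint via col2im.

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

conv_init <- function(k, in_c, out_c) {
  list(W = he_init(k * k * in_c, out_c, k * k * in_c), b = rep(0, out_c),
       k = as.integer(k), in_c = as.integer(in_c), out_c = as.integer(out_c))
}

convt_init <- function(k, in_c, out_c) {
  # weight parameterised as the adjoint convolution (out_c -> in_c)
  list(W = he_init(k * k * out_c, in_c, k * k * in_c), b = rep(0, out_c),
       k = as.integer(k), in_c = as.integer(in_c), out_c = as.integer(out_c))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), rm = rep(0, c), rv = rep(1, c))
}

conv_forward <- function(x, p, s, pad, keep_cache = TRUE) {
  d <- dim(x)
  k <- p$k
  oh <- (d[1] + 2 * pad - k) %/% s + 1L
  ow <- (d[2] + 2 * pad - k) %/% s + 1L
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], k, k, s, s, pad, pad)
  y <- cols %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(oh, ow, d[3], p$out_c)
  list(y = y, cache = if (keep_cache) list(cols = cols, dims = d, s = s, pad = pad) else NULL)
}

conv_backward <- function(dy, p, cache, want_dx = TRUE) {
  do <- dim(dy)
  dym <- dy
  dim(dym) <- c(do[1] * do[2] * do[3], do[4])
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dx <- NULL
  if (want_dx) {
    dcols <- tcrossprod(dym, p$W)
    d <- cache$dims
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], p$k, p$k,
                     cache$s, cache$s, cache$pad, cache$pad)
  }
  list(dx = dx, W = dW, b = db)
}

convt_forward <- function(x, p, s, pad) {
  d <- dim(x)
  k <- p$k
  oh <- (d[1] - 1L) * s - 2L * pad + k
  ow <- (d[2] - 1L) * s - 2L * pad + k
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  cols <- tcrossprod(xm, p$W)
  y <- col2im_cpp(cols, oh, ow, d[3], p$out_c, k, k, s, s, pad, pad)
  y <- y + rep(p$b, each = oh * ow * d[3])
  list(y = y, cache = list(xm = xm, dims = d, odims = c(oh, ow, d[3], p$out_c),
                           s = s, pad = pad))
}

convt_backward <- function(dy, p, cache) {
  od <- cache$odims
  cols_dy <- im2col_cpp(dy, od[1], od[2], od[3], od[4], p$k, p$k,
                        cache$s, cache$s, cache$pad, cache$pad)
  dx <- cols_dy %*% p$W
  d <- cache$dims
  dim(dx) <- d
  dW <- crossprod(cols_dy, cache$xm)
  dym <- dy
  dim(dym) <- c(od[1] * od[2] * od[3], od[4])
  db <- colSums(dym)
  list(dx = dx, W = dW, b = db)
}

bn_forward <- function(x, p, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu, "-")
    va <- colMeans(xc * xc)
    invstd <- 1 / sqrt(va + eps)
    xhat <- sweep(xc, 2, invstd, "*")
    p$rm <- (1 - momentum) * p$rm + momentum * mu
    p$rv <- (1 - momentum) * p$rv + momentum * va
  } else {
    invstd <- 1 / sqrt(p$rv + eps)
    xhat <- sweep(sweep(xm, 2, p$rm, "-"), 2, invstd, "*")
  }
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d), p = p)
}

bn_backward <- function(dy, p, cache) {
  d <- cache$dims
  dym <- dy
  dim(dym) <- c(d[1] * d[2] * d[3], d[4])
  xhat <- cache$xhat
  m <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, p$gamma, "*")
  t1 <- sweep(dxhat * m, 2, colSums(dxhat), "-")
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$invstd / m, "*")
  dim(dx) <- d
  list(dx = dx, gamma = dgamma, beta = dbeta)
}

lrelu_forward <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, neg = neg)
}

lrelu_backward <- function(dy, neg, slope = 0.2) {
  dy[neg] <- dy[neg] * slope
  dy
}

relu_forward <- function(x) {
  neg <- x < 0
  x[neg] <- 0
  list(y = x, neg = neg)
}

relu_backward <- function(dy, neg) {
  dy[neg] <- 0
  dy
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# stable binary cross-entropy with logits; returns loss and d(loss)/d(logits)
bce_with_logits <- function(z, target) {
  if (any(!is.finite(z))) stop("numeric error: non-finite discriminator scores", call. = FALSE)
  loss <- mean(pmax(z, 0) - target * z + log1p(exp(-abs(z))))
  grad <- (1 / (1 + exp(-z)) - target) / length(z)
  list(loss = loss, grad = grad)
}

# ---- Adam over nested parameter/gradient trees -----------------------------

adam_state_init <- function(g) {
  if (is.numeric(g)) return(list(m = g * 0, v = g * 0))
  lapply(g, function(e) if (is.null(e)) NULL else adam_state_init(e))
}

adam_step_tree <- function(p, g, s, lr, b1, b2, eps, t) {
  if (is.numeric(g)) {
    s$m <- b1 * s$m + (1 - b1) * g
    s$v <- b2 * s$v + (1 - b2) * g * g
    mhat <- s$m / (1 - b1^t)
    vhat <- s$v / (1 - b2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    return(list(p = p, s = s))
  }
  keys <- if (!is.null(names(g))) names(g) else seq_along(g)
  for (k in keys) {
    if (is.null(g[[k]])) next
    res <- adam_step_tree(p[[k]], g[[k]], s[[k]], lr, b1, b2, eps, t)
    p[[k]] <- res$p
    s[[k]] <- res$s
  }
  list(p = p, s = s)
}

# reflect (mirror) a matrix/3D array to a larger H x W, padding bottom/right
reflect_pad_hw <- function(x, th, tw) {
  d <- dim(x)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1] - 1L)))[seq_len(th)]
  ci <- c(seq_len(d[2]), rev(seq_len(d[2] - 1L)))[seq_len(tw)]
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}
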