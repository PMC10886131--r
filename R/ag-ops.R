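# Differentiable tensor ops. Feature maps are (H, W, C, N) arrays; channel
# vectors per sample are (C, N) matrices.

dim4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) rds_shape_error("expected a 4-d (H, W, C, N) array")
  d
}

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xv <- x$value; wv <- w$value
  dx <- dim4(xv); dw <- dim4(wv)
  if (dx[3] != dw[3] * groups)
    rds_shape_error(sprintf("conv2d: input has %d channels but weights expect %d (groups = %d)",
                            dx[3], dw[3] * groups, groups))
  bv <- if (is.null(b)) numeric(0) else b$value
  y <- cpp_conv2d_fw(xv, wv, bv, as.integer(stride), as.integer(pad), as.integer(groups))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(g) {
    r <- cpp_conv2d_bw(xv, wv, g, as.integer(stride), as.integer(pad),
                       as.integer(groups), !is.null(b))
    if (is.null(b)) list(r$dx, r$dw) else list(r$dx, r$dw, r$db)
  })
}

ag_deform_conv <- function(x, w, b, off) {
  xv <- x$value; wv <- w$value; ov <- off$value
  dso <- dim(ov)
  if (is.null(dso) || length(dso) != 4L || dso[3] != 18L)
    rds_shape_error(sprintf("deformable_conv: offset field must carry 2N = 18 channels, got %s",
                            paste(dso[3], collapse = "x")))
  bv <- if (is.null(b)) numeric(0) else b$value
  y <- cpp_deform_fw(xv, wv, bv, ov)
  parents <- if (is.null(b)) list(x, w, off) else list(x, w, b, off)
  ag_node(y, parents, function(g) {
    r <- cpp_deform_bw(xv, wv, ov, g, !is.null(b))
    if (is.null(b)) list(r$dx, r$dw, r$doff) else list(r$dx, r$dw, r$db, r$doff)
  })
}

ag_relu <- function(x) {
  xv <- x$value
  ag_node(cpp_relu_fw(xv), list(x), function(g) list(cpp_relu_bw(xv, g)))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_concat_c <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim4(av); db4 <- dim4(bv)
  if (any(da[c(1, 2, 4)] != db4[c(1, 2, 4)]))
    rds_shape_error("concat: spatial/batch dims differ between skip and decoder features")
  y <- array(0, dim = c(da[1], da[2], da[3] + db4[3], da[4]))
  ia <- seq_len(da[3])
  y[, , ia, ] <- av
  y[, , da[3] + seq_len(db4[3]), ] <- bv
  ag_node(y, list(a, b), function(g) {
    list(g[, , ia, , drop = FALSE],
         g[, , da[3] + seq_len(db4[3]), , drop = FALSE])
  })
}

ag_maxpool <- function(x, k, stride, pad = 0L) {
  xv <- x$value
  d <- dim4(xv)
  r <- cpp_maxpool_fw(xv, as.integer(k), as.integer(stride), as.integer(pad))
  ag_node(r$y, list(x), function(g) list(cpp_maxpool_bw(r$idx, g, d[1], d[2])))
}

ag_upsample2x <- function(x) {
  d <- dim4(x$value)
  ag_node(cpp_upsample2x_fw(x$value), list(x),
          function(g) list(cpp_upsample2x_bw(g, d[1], d[2])))
}

# batch normalization over (H, W, N) per channel; state carries running
# moments for evaluation mode. Compiled kernels avoid R-level transposes.
ag_bn <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  r <- cpp_bn_fw(xv, gamma$value, beta$value, training, state$mean, state$var)
  if (training) {
    state$mean <- (1 - momentum) * state$mean + momentum * r$mu
    state$var <- (1 - momentum) * state$var + momentum * r$va
  }
  ag_node(r$y, list(x, gamma, beta), function(g) {
    b <- cpp_bn_bw(xv, g, gamma$value, r$mu, r$va, training)
    list(b$dx, b$dgamma, b$dbeta)
  })
}

# global average pool: (H, W, C, N) -> (C, N)
ag_gap <- function(x) {
  d <- dim4(x$value)
  hw <- d[1] * d[2]
  v <- matrix(colMeans(matrix(x$value, nrow = hw)), nrow = d[3])
  ag_node(v, list(x), function(g) {
    gx <- array(rep(as.vector(g) / hw, each = hw), dim = d)
    list(gx)
  })
}

# fully connected on (Cin, N) matrices: y = W x + b
ag_fc <- function(x, w, b = NULL) {
  y <- w$value %*% x$value
  if (!is.null(b)) y <- y + b$value
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(g) {
    dx <- crossprod(w$value, g)
    dw <- tcrossprod(g, x$value)
    if (is.null(b)) list(dx, dw) else list(dx, dw, rowSums(g))
  })
}

# multiply each channel c of sample n by gate (c, n)
ag_scale_channels <- function(x, gates) {
  d <- dim4(x$value)
  hw <- d[1] * d[2]
  ge <- rep(as.vector(gates$value), each = hw)
  ag_node(x$value * ge, list(x, gates), function(g) {
    dg <- matrix(colSums(matrix(g * x$value, nrow = hw)), nrow = d[3])
    list(g * ge, dg)
  })
}

# multiply every channel by a (H, W, 1, N) spatial gate
ag_scale_spatial <- function(x, gate) {
  d <- dim4(x$value)
  gv <- gate$value
  gexp <- array(gv[, , rep(1L, d[3]), , drop = FALSE], dim = d)
  ag_node(x$value * gexp, list(x, gate), function(g) {
    dgate <- rowSums(aperm(g * x$value, c(1, 2, 4, 3)), dims = 3)
    dim(dgate) <- c(d[1], d[2], 1L, d[4])
    list(g * gexp, dgate)
  })
}

# fused softmax + multiclass soft Dice loss; truth is (H, W, N) 0-based
ag_dice_loss <- function(logits, truth, eps = 1e-6, include_background = TRUE) {
  zv <- logits$value
  d <- dim4(zv)
  K <- d[3]
  tv <- as.integer(truth)
  if (any(tv < 0L) || any(tv >= K))
    rds_label_error(sprintf("dice_loss: truth contains class index outside 0..%d", K - 1L))
  M <- matrix(aperm(zv, c(1, 2, 4, 3)), ncol = K)
  M <- M - apply(M, 1, max)
  P <- exp(M)
  P <- P / rowSums(P)
  n_pix <- nrow(P)
  Tm <- matrix(0, n_pix, K)
  Tm[cbind(seq_len(n_pix), tv + 1L)] <- 1
  a <- 2 * colSums(P * Tm) + eps
  b <- colSums(P) + colSums(Tm) + eps
  dice <- a / b
  keep <- if (include_background) seq_len(K) else seq_len(K)[-1]
  loss <- 1 - mean(dice[keep])
  ag_node(loss, list(logits), function(g) {
    gp <- matrix(0, n_pix, K)
    kk <- length(keep)
    for (k in keep) {
      gp[, k] <- -(2 * Tm[, k] * b[k] - a[k]) / (kk * b[k]^2)
    }
    # backprop through the softmax
    dz <- P * (gp - rowSums(gp * P))
    dz <- aperm(array(dz, dim = c(d[1], d[2], d[4], K)), c(1, 2, 4, 3)) * g
    list(dz)
  })
}
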