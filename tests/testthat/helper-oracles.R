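# Brute-force reference implementations, kept deliberately independent of
# the package's compiled kernels: plain scalar loops over the defining sums.

# Eq.-style direct convolution: y(P0) = sum_n w(Pn) x(P0 + Pn), zero padding
oracle_conv <- function(x, w, b = NULL, stride = 1, pad = 0, groups = 1) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  wd <- dim(w)
  kh <- wd[1]; kw <- wd[2]; cing <- wd[3]; Cout <- wd[4]
  coutg <- Cout / groups
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (o in 1:Cout) {
    g <- (o - 1) %/% coutg
    for (ho in 1:Ho) for (wo in 1:Wo) {
      s <- if (is.null(b)) 0 else b[o]
      for (i in 1:kh) for (j in 1:kw) for (c in 1:cing) {
        hi <- (ho - 1) * stride - pad + i
        wi <- (wo - 1) * stride - pad + j
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          s <- s + w[i, j, c, o] * x[hi, wi, g * cing + c, n]
      }
      y[ho, wo, o, n] <- s
    }
  }
  y
}

# scalar bilinear lookup, 0-based coordinates, zero outside
oracle_bilinear <- function(x, py, px) {
  H <- nrow(x); W <- ncol(x)
  y0 <- floor(py); x0 <- floor(px)
  v <- 0
  for (a in 0:1) for (b in 0:1) {
    yy <- y0 + a; xx <- x0 + b
    if (yy < 0 || yy >= H || xx < 0 || xx >= W) next
    wy <- if (a == 1) py - y0 else 1 - (py - y0)
    wx <- if (b == 1) px - x0 else 1 - (px - x0)
    v <- v + x[yy + 1, xx + 1] * wy * wx
  }
  v
}

# deformable 3x3, stride 1, same padding; offsets (H, W, 18), taps row-major
oracle_deform <- function(x, w, off, b = NULL) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; Cin <- d[3]
  Cout <- dim(w)[4]
  y <- array(0, c(H, W, Cout))
  for (o in 1:Cout) for (ho in 1:H) for (wo in 1:W) {
    s <- if (is.null(b)) 0 else b[o]
    for (ik in 0:2) for (jk in 0:2) {
      tap <- ik * 3 + jk
      dy <- off[ho, wo, 2 * tap + 1]
      dx <- off[ho, wo, 2 * tap + 2]
      py <- (ho - 1) + (ik - 1) + dy
      px <- (wo - 1) + (jk - 1) + dx
      for (c in 1:Cin)
        s <- s + w[ik + 1, jk + 1, c, o] * oracle_bilinear(x[, , c], py, px)
    }
    y[ho, wo, o] <- s
  }
  y
}

# per-pixel metric oracles from raw label vectors
oracle_metrics <- function(pred, truth, k = 3) {
  pred <- as.vector(pred); truth <- as.vector(truth)
  ious <- c(); precs <- c(); recs <- c()
  for (cl in 0:(k - 1)) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp + fp + fn > 0) ious <- c(ious, tp / (tp + fp + fn))
    if (tp + fp > 0) precs <- c(precs, tp / (tp + fp))
    if (tp + fn > 0) recs <- c(recs, tp / (tp + fn))
  }
  list(miou = mean(ious), precision = mean(precs), recall = mean(recs))
}

# finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_scene_spec <- function(seed = 7, ...) {
  args <- list(image_size = 64, n_corn = c(1, 2), n_weeds = c(2, 6),
               corn_scale = c(10, 18), weed_scale = c(2, 5), seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(scene_spec, args)
}

make_tiny_dataset <- function(n, dir, seed = 7, ...) {
  generate_dataset(tiny_scene_spec(seed = seed, ...), n, dir)
}
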