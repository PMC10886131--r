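# Deformable 3x3 convolution: a convolution whose nine kernel taps sample the
# input at positions displaced by per-position fractional offsets, resolved by
# bilinear interpolation. Offset channel order is frozen (checkpoints depend
# on it): taps enumerate the receptive field {-1,0,1}^2 row-major, and each
# tap n contributes channels (2n, 2n+1) = (delta_y, delta_x), y = rows/down.

#' Kernel grid for a square convolution
#'
#' The receptive-field taps `P_n` of a `k x k` kernel, enumerated row-major,
#' plus the associated weight array.
#'
#' @param weights `(k, k, Cin, Cout)` weight array.
#' @return list with `taps` (an `N x 2` matrix of (row, col) displacements)
#'   and `weights`.
#' @export
kernel_grid <- function(weights) {
  d <- dim(weights)
  if (length(d) != 4L || d[1] != d[2])
    rds_shape_error("kernel_grid: weights must be (k, k, Cin, Cout)")
  k <- d[1]
  r <- (k - 1L) %/% 2L
  taps <- as.matrix(expand.grid(col = -r:r, row = -r:r))[, c("row", "col")]
  list(taps = taps, weights = weights, k = k)
}

#' Plain same-padded 2-d convolution (reference form)
#'
#' Direct translation of the standard convolution sum
#' `y(P0) = sum_{Pn in R} w(Pn) x(P0 + Pn)` with zero padding, written as an
#' im2col product. Serves as the degenerate (zero-offset) reference for
#' [deformable_conv()]; independent brute-force oracles live in the tests.
#'
#' @param x `(H, W, Cin)` or `(H, W, Cin, N)` input.
#' @param weights `(k, k, Cin, Cout)` weights (odd `k`).
#' @param bias optional length-`Cout` bias.
#' @return output array, same spatial size as the input.
#' @export
standard_conv_ref <- function(x, weights, bias = NULL) {
  x4 <- if (length(dim(x)) == 3L) array(x, dim = c(dim(x), 1L)) else x
  d <- dim(x4)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  wd <- dim(weights)
  k <- wd[1]
  pad <- (k - 1L) %/% 2L
  Cout <- wd[4]
  L <- H * W
  R <- k * k * Cin
  Wmat <- matrix(weights, nrow = R)
  out <- array(0, dim = c(H, W, Cout, N))
  # padded copy, then gather shifted planes into the (L x R) im2col matrix
  for (n in seq_len(N)) {
    xp <- array(0, dim = c(H + 2L * pad, W + 2L * pad, Cin))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x4[, , , n]
    colT <- matrix(0, L, R)
    r <- 0L
    for (c in seq_len(Cin)) {
      for (j in seq_len(k)) {
        for (i in seq_len(k)) {
          # r follows i + k*(j + k*c) ordering, matching the weight layout
          colT[, (c - 1L) * k * k + (j - 1L) * k + i] <-
            xp[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W), c]
          r <- r + 1L
        }
      }
    }
    y <- colT %*% Wmat
    if (!is.null(bias)) y <- sweep(y, 2, bias, "+")
    out[, , , n] <- array(y, dim = c(H, W, Cout))
  }
  if (length(dim(x)) == 3L) array(out, dim = dim(out)[1:3]) else out
}

#' Bilinear sampling at fractional coordinates
#'
#' Value at a fractional (row, col) position as the weighted mean of the up to
#' four integer neighbours; coordinates outside the grid contribute zero
#' (zero-padding convention). Coordinates are 0-based: `p = c(0, 0)` is the
#' first pixel.
#'
#' @param x numeric matrix.
#' @param p coordinates: length-2 vector `(row, col)` or an `n x 2` matrix.
#' @return sampled value(s).
#' @export
bilinear_sample <- function(x, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  if (any(!is.finite(p))) rds_numeric_error("bilinear_sample: non-finite coordinate")
  cpp_bilinear_points(x, p[, 1], p[, 2])
}

#' Deformable 3x3 convolution (functional form)
#'
#' Computes `y(P0) = sum_n w(P_n) x(P0 + P_n + dP_n)`: each of the nine taps
#' of a same-padded 3x3 convolution samples the input at a position displaced
#' by the learned fractional offset field, resolved by bilinear interpolation.
#' With an all-zero offset field this reduces exactly to [standard_conv_ref()].
#'
#' @param x `(H, W, Cin)` or `(H, W, Cin, N)` input.
#' @param weights `(3, 3, Cin, Cout)` kernel.
#' @param offsets `(H, W, 18)` or `(H, W, 18, N)` offset field; channel `2n`
#'   is the row displacement of tap `n`, channel `2n + 1` the column
#'   displacement (taps row-major over `{-1,0,1}^2`).
#' @param bias optional length-`Cout` bias.
#' @return output array `(H, W, Cout[, N])`.
#' @export
deformable_conv <- function(x, weights, offsets, bias = NULL) {
  three <- length(dim(x)) == 3L
  x4 <- if (three) array(x, dim = c(dim(x), 1L)) else x
  o4 <- if (length(dim(offsets)) == 3L) array(offsets, dim = c(dim(offsets), 1L)) else offsets
  if (dim(o4)[3] != 18L)
    rds_shape_error(sprintf("deformable_conv: offset field must carry 2N = 18 channels, got %d",
                            dim(o4)[3]))
  y <- cpp_deform_fw(x4, weights, if (is.null(bias)) numeric(0) else bias, o4)
  if (three) array(y, dim = dim(y)[1:3]) else y
}

#' Offset-prediction branch of a deformable convolution
#'
#' A same-padded 3x3 convolution from the input features to the 18 offset
#' channels (2N for N = 9 taps). Zero-initialized weights (see
#' [offset_branch_init()]) make training start at the standard-convolution
#' fixed point.
#'
#' @param x `(H, W, Cin)` or `(H, W, Cin, N)` input.
#' @param branch_weights list with `w` `(3, 3, Cin, 18)` and `b` length-18.
#' @return offset field `(H, W, 18[, N])`.
#' @export
offset_branch <- function(x, branch_weights) {
  three <- length(dim(x)) == 3L
  x4 <- if (three) array(x, dim = c(dim(x), 1L)) else x
  off <- cpp_conv2d_fw(x4, branch_weights$w, branch_weights$b, 1L, 1L, 1L)
  if (three) array(off, dim = dim(off)[1:3]) else off
}

#' @rdname offset_branch
#' @param in_channels input channel count of the branch.
#' @export
offset_branch_init <- function(in_channels) {
  list(w = array(0, dim = c(3L, 3L, in_channels, 18L)), b = numeric(18L))
}
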