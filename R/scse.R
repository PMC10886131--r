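# Concurrent spatial and channel squeeze-and-excitation (scSE): the sum of a
# channel-gated and a spatially gated recalibration of a feature map.

#' Parameters for an scSE attention module
#'
#' Channel branch: fully connected C -> C/2 with relu, then C/2 -> C with a
#' logistic gate (reduction ratio fixed at 2). Spatial branch: 1x1 convolution
#' to a single channel with a logistic gate. `init = "zero"` zeroes every
#' weight and bias, which makes [scse()] the exact identity (both gates are
#' sigmoid(0) = 1/2 and the two halves sum back to x); `init = "random"`
#' draws small He-scaled weights with zero biases.
#'
#' @param channels feature-map channel count C.
#' @param init `"random"` or `"zero"`.
#' @return named parameter list (`w1`, `b1`, `w2`, `b2`, `ws`, `bs`).
#' @export
scse_params <- function(channels, init = c("random", "zero")) {
  init <- match.arg(init)
  C <- as.integer(channels)
  Cr <- max(1L, C %/% 2L)
  if (init == "zero") {
    list(w1 = matrix(0, Cr, C), b1 = numeric(Cr),
         w2 = matrix(0, C, Cr), b2 = numeric(C),
         ws = array(0, dim = c(1L, 1L, C, 1L)), bs = numeric(1L))
  } else {
    list(w1 = matrix(stats::rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C),
         b1 = numeric(Cr),
         w2 = matrix(stats::rnorm(C * Cr, sd = sqrt(1 / Cr)), C, Cr),
         b2 = numeric(C),
         ws = array(0, dim = c(1L, 1L, C, 1L)), bs = numeric(1L))
  }
}

as_x4 <- function(x) {
  if (length(dim(x)) == 3L) list(x = array(x, dim = c(dim(x), 1L)), three = TRUE)
  else list(x = x, three = FALSE)
}

strip4 <- function(y, three) if (three) array(y, dim = dim(y)[1:3]) else y

#' Channel squeeze-and-excitation (csE)
#'
#' Global average pooling squeezes each channel to a scalar; two fully
#' connected layers (relu, then sigmoid) produce a per-channel gate in (0, 1)
#' which rescales the input channels.
#'
#' @param x `(H, W, C)` or `(H, W, C, N)` feature map.
#' @param params from [scse_params()].
#' @return recalibrated feature map, same shape as `x`.
#' @export
cse <- function(x, params) {
  a <- as_x4(x)
  if (dim(a$x)[3] != ncol(params$w1))
    rds_shape_error(sprintf("cse: params built for %d channels, input has %d",
                            ncol(params$w1), dim(a$x)[3]))
  xn <- ag_node(a$x)
  z <- ag_gap(xn)
  h <- ag_relu(ag_fc(z, ag_node(params$w1), ag_node(params$b1)))
  g <- ag_sigmoid(ag_fc(h, ag_node(params$w2), ag_node(params$b2)))
  strip4(ag_scale_channels(xn, g)$value, a$three)
}

#' Spatial squeeze-and-excitation (ssE)
#'
#' A 1x1 convolution to a single channel followed by a sigmoid yields an
#' `(H, W)` gate in (0, 1) which rescales every channel position-wise.
#'
#' @inheritParams cse
#' @return recalibrated feature map, same shape as `x`.
#' @export
sse <- function(x, params) {
  a <- as_x4(x)
  if (dim(a$x)[3] != dim(params$ws)[3])
    rds_shape_error(sprintf("sse: params built for %d channels, input has %d",
                            dim(params$ws)[3], dim(a$x)[3]))
  xn <- ag_node(a$x)
  g <- ag_sigmoid(ag_conv2d(xn, ag_node(params$ws), ag_node(params$bs), 1L, 0L))
  strip4(ag_scale_spatial(xn, g)$value, a$three)
}

#' Concurrent scSE recalibration
#'
#' Elementwise sum of the channel ([cse()]) and spatial ([sse()])
#' recalibrations.
#'
#' @inheritParams cse
#' @return recalibrated feature map, same shape as `x`.
#' @export
scse <- function(x, params) {
  cse(x, params) + sse(x, params)
}

#' Spatial gate map of an scSE module
#'
#' Exposes the `(H, W, 1[, N])` sigmoid gate of the spatial branch.
#'
#' @inheritParams cse
#' @return gate array with one channel.
#' @export
sse_gate <- function(x, params) {
  a <- as_x4(x)
  g <- ag_sigmoid(ag_conv2d(ag_node(a$x), ag_node(params$ws),
                            ag_node(params$bs), 1L, 0L))$value
  strip4(g, a$three)
}
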