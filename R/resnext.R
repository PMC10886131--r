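#' ResNeXt block configuration
#'
#' Describes one aggregated-residual bottleneck block: a 1x1 channel
#' compression, a grouped 3x3 convolution split into `cardinality` equal-width
#' groups, and a 1x1 expansion, wrapped by a residual shortcut. In the 32x4d
#' layout used here the stage-2 bottleneck is 128 channels wide, i.e. 32
#' groups of width 4, and the width doubles at every later stage.
#'
#' @param in_channels input channel count.
#' @param bottleneck_channels total width of the grouped 3x3 stage (across all
#'   groups, e.g. 128 at stage 2).
#' @param cardinality number of convolution groups (32 for 32x4d).
#' @param out_channels block output channels (twice the bottleneck width).
#' @param stride spatial stride of the grouped 3x3 stage, 1 or 2.
#' @return an object of class `resnext_block_config`.
#' @export
resnext_block_config <- function(in_channels, bottleneck_channels,
                                 cardinality = 32L, out_channels,
                                 stride = 1L) {
  if (bottleneck_channels %% cardinality != 0L)
    rds_spec_error("bottleneck_channels must be divisible by cardinality")
  if (!stride %in% c(1L, 2L))
    rds_spec_error("stride must be 1 or 2")
  structure(list(in_channels = as.integer(in_channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 cardinality = as.integer(cardinality),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride)),
            class = "resnext_block_config")
}

#' Initialize parameters for a single ResNeXt block
#'
#' He-initialized convolution weights and zero biases, for the
#' normalization-free functional form of [resnext_block()].
#'
#' @param config a [resnext_block_config()].
#' @return named list of weight arrays (`w1`, `b1`, `w2`, `b2`, `w3`, `b3`,
#'   and `wproj`/`bproj` when the shortcut needs a projection).
#' @export
resnext_block_init <- function(config) {
  cin <- config$in_channels
  width <- config$bottleneck_channels
  cout <- config$out_channels
  C <- config$cardinality
  p <- list(
    w1 = init_he(1L, 1L, cin, width), b1 = numeric(width),
    w2 = init_he(3L, 3L, width %/% C, width), b2 = numeric(width),
    w3 = init_he(1L, 1L, width, cout), b3 = numeric(cout)
  )
  if (cin != cout || config$stride != 1L) {
    p$wproj <- init_he(1L, 1L, cin, cout)
    p$bproj <- numeric(cout)
  }
  p
}

#' Aggregated-residual (ResNeXt) bottleneck block, functional form
#'
#' Computes `relu(shortcut(x) + expand(grouped3x3(reduce(x))))` without
#' normalization layers: the exact aggregated-transform arithmetic
#' `Y = X + sum_i T_i(X)` over `cardinality` parallel group transforms. The
#' network assembly uses the batch-normalized version of the same block; this
#' plain form is the reference surface for equivalence checks.
#'
#' @param x input feature map, `(H, W, C)` or `(H, W, C, N)` array.
#' @param config a [resnext_block_config()].
#' @param params parameter list as produced by [resnext_block_init()].
#' @return output feature map array with `config$out_channels` channels.
#' @export
resnext_block <- function(x, config, params) {
  x4 <- if (length(dim(x)) == 3L) array(x, dim = c(dim(x), 1L)) else x
  if (dim(x4)[3] != config$in_channels)
    rds_shape_error(sprintf("resnext_block: stage expects %d input channels, got %d",
                            config$in_channels, dim(x4)[3]))
  np <- function(v) ag_node(v)
  h <- ag_relu(ag_conv2d(np(x4), np(params$w1), np(params$b1), 1L, 0L))
  h <- ag_relu(ag_conv2d(h, np(params$w2), np(params$b2),
                         config$stride, 1L, config$cardinality))
  h <- ag_conv2d(h, np(params$w3), np(params$b3), 1L, 0L)
  sc <- if (!is.null(params$wproj)) {
    ag_conv2d(np(x4), np(params$wproj), np(params$bproj), config$stride, 0L)
  } else np(x4)
  out <- ag_relu(ag_add(sc, h))$value
  if (length(dim(x)) == 3L) array(out, dim = dim(out)[1:3]) else out
}

# internal: batch-normalized block used by the encoder assembly
mod_resnext_block <- function(reg, name, cin, width, cout, stride,
                              cardinality = 32L, norm = "batch") {
  c1 <- layer_cbr(reg, paste0(name, ".conv1"), 1L, cin, width, norm = norm)
  c2 <- layer_cbr(reg, paste0(name, ".conv2"), 3L, width, width, stride = stride,
                  groups = cardinality, norm = norm)
  c3 <- layer_cbr(reg, paste0(name, ".conv3"), 1L, width, cout, norm = norm,
                  relu = FALSE)
  proj <- if (cin != cout || stride != 1L) {
    layer_cbr(reg, paste0(name, ".proj"), 1L, cin, cout, stride = stride,
              pad = 0L, norm = norm, relu = FALSE)
  }
  function(x, training = FALSE) {
    h <- c3(c2(c1(x, training), training), training)
    sc <- if (is.null(proj)) x else proj(x, training)
    ag_relu(ag_add(sc, h))
  }
}

# table of the four stages: (bottleneck width, output channels, blocks, stride)
resnext50_stages <- function() {
  list(stage2 = list(width = 128L, out = 256L, blocks = 3L, stride = 1L),
       stage3 = list(width = 256L, out = 512L, blocks = 4L, stride = 2L),
       stage4 = list(width = 512L, out = 1024L, blocks = 6L, stride = 2L),
       stage5 = list(width = 1024L, out = 2048L, blocks = 3L, stride = 2L))
}

mod_resnext_encoder <- function(reg, in_channels = 3L, norm = "batch") {
  stem <- layer_cbr(reg, "encoder.stem", 7L, in_channels, 64L, stride = 2L,
                    pad = 3L, norm = norm)
  stages <- resnext50_stages()
  mods <- list()
  cin <- 64L
  for (s in names(stages)) {
    st <- stages[[s]]
    blocks <- list()
    for (bidx in seq_len(st$blocks)) {
      blocks[[bidx]] <- mod_resnext_block(
        reg, sprintf("encoder.%s.block%d", s, bidx),
        cin = if (bidx == 1L) cin else st$out,
        width = st$width, cout = st$out,
        stride = if (bidx == 1L) st$stride else 1L,
        norm = norm)
    }
    mods[[s]] <- blocks
    cin <- st$out
  }
  function(x, training = FALSE) {
    f1 <- stem(x, training)
    h <- ag_maxpool(f1, 3L, 2L, 1L)
    taps <- list(f1 = f1)
    for (s in names(stages)) {
      for (blk in mods[[s]]) h <- blk(h, training)
      taps[[c(stage2 = "f2", stage3 = "f3", stage4 = "f4", stage5 = "f5")[[s]]]] <- h
    }
    taps
  }
}

#' Build the ResNeXt-50 (32x4d) encoder backbone
#'
#' Stem (7x7 stride-2 convolution to 64 channels, then 3x3 stride-2 max-pool)
#' followed by four stages of aggregated-residual blocks repeated 3, 4, 6 and
#' 3 times, producing a five-level feature pyramid at strides 2/4/8/16/32 with
#' 64/256/512/1024/2048 channels. No classification head is built; the
#' backbone exists to feed decoder skip connections.
#'
#' @param in_channels input image channels (3 for RGB).
#' @param norm `"batch"` for batch-normalized blocks (training), `"none"` for
#'   the plain affine form used by arithmetic oracles.
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `rds_encoder`.
#' @export
build_encoder <- function(in_channels = 3L, norm = c("batch", "none"),
                          seed = NULL) {
  norm <- match.arg(norm)
  reg <- new_registry()
  build <- function() mod_resnext_encoder(reg, in_channels, norm)
  fwd <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(reg = reg, forward = fwd,
                 stage_blocks = c(3L, 4L, 6L, 3L),
                 cardinality = 32L,
                 bottleneck_widths = c(128L, 256L, 512L, 1024L),
                 out_channels = c(64L, 256L, 512L, 1024L, 2048L),
                 norm = norm),
            class = "rds_encoder")
}

#' Run the encoder on an image batch and return the feature pyramid
#'
#' @param encoder an `rds_encoder` from [build_encoder()].
#' @param x `(H, W, C)` or `(H, W, C, N)` array; `H`, `W` must be even
#'   multiples suitable for five halvings.
#' @return named list `f1`..`f5` of feature arrays at strides 2..32.
#' @export
encoder_forward <- function(encoder, x) {
  x4 <- if (length(dim(x)) == 3L) array(x, dim = c(dim(x), 1L)) else x
  taps <- encoder$forward(ag_node(x4), training = FALSE)
  lapply(taps, function(t) t$value)
}

#' @export
print.rds_encoder <- function(x, ...) {
  cat("ResNeXt-50 (32x4d) encoder\n")
  cat("  stage blocks:", paste(x$stage_blocks, collapse = "/"),
      " cardinality:", x$cardinality, "\n")
  cat("  pyramid channels:", paste(x$out_channels, collapse = "/"),
      " parameters:", format(n_params_reg(x$reg), big.mark = ","), "\n")
  invisible(x)
}
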