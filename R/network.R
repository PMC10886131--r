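# Model variants and assembly. Four named presets span the ablation ladder:
# plain U-net; U-net with the ResNeXt-50 encoder; plus a deformable 3x3
# convolution pair in the deepest decoder layer; plus scSE attention after the
# conv blocks of decoder layers 2-4.

#' Declarative model variant
#'
#' @param encoder `"plain_unet"` or `"resnext50"`.
#' @param deformable_layer1 replace both 3x3 convolutions of the deepest
#'   decoder layer with deformable 3x3 convolutions.
#' @param scse_layers234 append scSE attention after the conv block of decoder
#'   layers 2, 3 and 4.
#' @param n_classes number of output classes (3: background/corn/weed).
#' @param input_channels image channels (3).
#' @param norm `"batch"` (default) or `"none"`.
#' @return an object of class `model_variant`.
#' @export
model_variant <- function(encoder = c("plain_unet", "resnext50"),
                          deformable_layer1 = FALSE,
                          scse_layers234 = FALSE,
                          n_classes = 3L, input_channels = 3L,
                          norm = c("batch", "none")) {
  encoder <- match.arg(encoder)
  norm <- match.arg(norm)
  if (n_classes < 2L) rds_spec_error("n_classes must be at least 2")
  structure(list(encoder = encoder,
                 deformable_layer1 = isTRUE(deformable_layer1),
                 scse_layers234 = isTRUE(scse_layers234),
                 n_classes = as.integer(n_classes),
                 input_channels = as.integer(input_channels),
                 norm = norm),
            class = "model_variant")
}

#' Named ablation presets
#'
#' `unet` = plain U-net; `unet_1` adds the ResNeXt-50 encoder; `unet_12` adds
#' the deformable deepest decoder layer; `unet_123` (alias `rds_unet`) adds
#' scSE in decoder layers 2-4.
#'
#' @param name preset name.
#' @param n_classes number of output classes.
#' @return a [model_variant()].
#' @export
preset <- function(name, n_classes = 3L) {
  known <- c("unet", "unet_1", "unet_12", "unet_123", "rds_unet")
  if (!name %in% known)
    rds_spec_error(sprintf("unknown preset '%s'; valid presets: %s",
                           name, paste(known, collapse = ", ")))
  if (name == "rds_unet") name <- "unet_123"
  switch(name,
    unet = model_variant("plain_unet", FALSE, FALSE, n_classes),
    unet_1 = model_variant("resnext50", FALSE, FALSE, n_classes),
    unet_12 = model_variant("resnext50", TRUE, FALSE, n_classes),
    unet_123 = model_variant("resnext50", TRUE, TRUE, n_classes))
}

#' @export
preset_names <- function() c("unet", "unet_1", "unet_12", "unet_123")

# one decoder layer: 2x bilinear upsample, optional 1x1 channel reduction,
# concat with the skip tap, two 3x3 conv blocks (deformable when asked),
# optional scSE
mod_decoder_layer <- function(reg, name, cin_up, cin_skip, cout, norm,
                              reduce = NULL, deform = FALSE, scse = FALSE) {
  red <- if (!is.null(reduce))
    layer_cbr(reg, paste0(name, ".reduce"), 1L, cin_up, reduce, norm = norm)
  cin_cat <- (if (is.null(reduce)) cin_up else reduce) + cin_skip
  mk <- function(tag, ci, co) {
    if (deform) layer_deform_block(reg, paste0(name, tag), ci, co, norm)
    else layer_cbr(reg, paste0(name, tag), 3L, ci, co, norm = norm)
  }
  conv_a <- mk(".conv_a", cin_cat, cout)
  conv_b <- mk(".conv_b", cout, cout)
  att <- if (scse) layer_scse(reg, paste0(name, ".scse"), cout)
  function(x, skip, training = FALSE) {
    h <- ag_upsample2x(x)
    if (!is.null(red)) h <- red(h, training)
    h <- ag_concat_c(h, skip)
    h <- conv_b(conv_a(h, training), training)
    if (!is.null(att)) h <- att(h, training)
    h
  }
}

build_resnext_unet <- function(reg, variant) {
  norm <- variant$norm
  enc <- mod_resnext_encoder(reg, variant$input_channels, norm)
  d1 <- mod_decoder_layer(reg, "decoder.layer1", 2048L, 1024L, 1024L, norm,
                          deform = variant$deformable_layer1)
  d2 <- mod_decoder_layer(reg, "decoder.layer2", 1024L, 512L, 512L, norm,
                          scse = variant$scse_layers234)
  d3 <- mod_decoder_layer(reg, "decoder.layer3", 512L, 256L, 256L, norm,
                          scse = variant$scse_layers234)
  d4 <- mod_decoder_layer(reg, "decoder.layer4", 256L, 64L, 64L, norm,
                          scse = variant$scse_layers234)
  head <- layer_conv(reg, "head", 1L, 1L, 64L, variant$n_classes)
  function(x, training = FALSE) {
    f <- enc(x, training)
    h <- d1(f$f5, f$f4, training)
    h <- d2(h, f$f3, training)
    h <- d3(h, f$f2, training)
    h <- d4(h, f$f1, training)
    head(ag_upsample2x(h), training)
  }
}

build_plain_unet <- function(reg, variant) {
  norm <- variant$norm
  ch <- c(64L, 128L, 256L, 512L)
  encs <- list()
  cin <- variant$input_channels
  for (i in seq_along(ch)) {
    a <- layer_cbr(reg, sprintf("encoder.down%d.conv_a", i), 3L, cin, ch[i], norm = norm)
    b <- layer_cbr(reg, sprintf("encoder.down%d.conv_b", i), 3L, ch[i], ch[i], norm = norm)
    encs[[i]] <- list(a = a, b = b)
    cin <- ch[i]
  }
  bott_a <- layer_cbr(reg, "encoder.bottleneck.conv_a", 3L, 512L, 1024L, norm = norm)
  bott_b <- layer_cbr(reg, "encoder.bottleneck.conv_b", 3L, 1024L, 1024L, norm = norm)
  d1 <- mod_decoder_layer(reg, "decoder.layer1", 1024L, 512L, 512L, norm,
                          reduce = 512L, deform = variant$deformable_layer1)
  d2 <- mod_decoder_layer(reg, "decoder.layer2", 512L, 256L, 256L, norm,
                          reduce = 256L, scse = variant$scse_layers234)
  d3 <- mod_decoder_layer(reg, "decoder.layer3", 256L, 128L, 128L, norm,
                          reduce = 128L, scse = variant$scse_layers234)
  d4 <- mod_decoder_layer(reg, "decoder.layer4", 128L, 64L, 64L, norm,
                          reduce = 64L, scse = variant$scse_layers234)
  head <- layer_conv(reg, "head", 1L, 1L, 64L, variant$n_classes)
  function(x, training = FALSE) {
    taps <- list()
    h <- x
    for (i in seq_along(encs)) {
      h <- encs[[i]]$b(encs[[i]]$a(h, training), training)
      taps[[i]] <- h
      h <- ag_maxpool(h, 2L, 2L, 0L)
    }
    h <- bott_b(bott_a(h, training), training)
    h <- d1(h, taps[[4]], training)
    h <- d2(h, taps[[3]], training)
    h <- d3(h, taps[[2]], training)
    h <- d4(h, taps[[1]], training)
    head(h, training)
  }
}

#' Build a segmentation model from a variant
#'
#' @param variant a [model_variant()] or preset name string.
#' @param seed optional integer seed for weight initialization; with the same
#'   seed, variants sharing an encoder draw identical encoder weights (the
#'   encoder is initialized first).
#' @return an object of class `rds_model`.
#' @export
build_model <- function(variant, seed = NULL) {
  if (is.character(variant)) variant <- preset(variant)
  reg <- new_registry()
  build <- function() {
    if (variant$encoder == "resnext50") build_resnext_unet(reg, variant)
    else build_plain_unet(reg, variant)
  }
  fwd <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(variant = variant, reg = reg, forward_node = fwd,
                 norm_const = NULL, seed = seed),
            class = "rds_model")
}

check_input_batch <- function(model, images) {
  if (length(dim(images)) == 3L) images <- array(images, dim = c(dim(images), 1L))
  d <- dim(images)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    rds_shape_error(sprintf("input height/width must be multiples of 32, got %dx%d", d[1], d[2]))
  if (d[3] != model$variant$input_channels)
    rds_shape_error(sprintf("model expects %d input channels, got %d",
                            model$variant$input_channels, d[3]))
  images
}

#' Forward pass: images to class logits
#'
#' Deterministic in evaluation mode (running normalization statistics, no
#' sampling). Use [predict_mask()] for hard class maps.
#'
#' @param model an `rds_model`.
#' @param images `(H, W, C)` or `(H, W, C, N)` array of normalized images;
#'   `H`, `W` must be multiples of 32.
#' @param training propagate in training mode (batch statistics).
#' @return logits array `(H, W, n_classes, N)`.
#' @export
forward <- function(model, images, training = FALSE) {
  x <- check_input_batch(model, images)
  model$forward_node(ag_node(x), training = training)$value
}

#' Predict a class-index mask
#'
#' Argmax over the class axis; ties resolve to the lowest class index.
#'
#' @inheritParams forward
#' @return `(H, W, N)` integer array of class indices (0-based), or `(H, W)`
#'   for a single image.
#' @export
predict_mask <- function(model, images) {
  single <- length(dim(images)) == 3L
  lg <- forward(model, images, training = FALSE)
  d <- dim(lg)
  m <- matrix(aperm(lg, c(1, 2, 4, 3)), ncol = d[3])
  cls <- max.col(m, ties.method = "first") - 1L
  out <- array(cls, dim = c(d[1], d[2], d[4]))
  if (single) array(out, dim = d[1:2]) else out
}

#' Number of trainable parameters
#' @param model an `rds_model`.
#' @export
n_params <- function(model) n_params_reg(model$reg)

#' Extract / restore model weights
#'
#' `model_state()` captures all parameter values and normalization running
#' moments; `load_model_state()` writes them back into a (structurally
#' identical) model.
#'
#' @param model an `rds_model`.
#' @export
model_state <- function(model) {
  list(variant = model$variant,
       params = lapply(model$reg$params, function(p) p$value),
       states = lapply(model$reg$states, function(s) list(mean = s$mean, var = s$var)),
       norm_const = model$norm_const)
}

#' @rdname model_state
#' @param state a list from `model_state()`.
#' @export
load_model_state <- function(model, state) {
  if (!setequal(names(model$reg$params), names(state$params)))
    rds_shape_error("checkpoint parameter names do not match the model variant")
  # deep-copy: parameter storage is updated in place during training and must
  # not alias the checkpoint object
  for (nm in names(state$params)) model$reg$params[[nm]]$value <- state$params[[nm]] + 0
  for (nm in names(state$states)) {
    model$reg$states[[nm]]$mean <- state$states[[nm]]$mean
    model$reg$states[[nm]]$var <- state$states[[nm]]$var
  }
  model$norm_const <- state$norm_const
  model
}

#' @export
print.rds_model <- function(x, ...) {
  v <- x$variant
  cat(sprintf("segmentation model: encoder=%s deformable_layer1=%s scse_layers234=%s\n",
              v$encoder, v$deformable_layer1, v$scse_layers234))
  cat(sprintf("  classes: %d  parameters: %s\n", v$n_classes,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}
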