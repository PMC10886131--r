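# Paired image/mask augmentation. Four strategies, each applied independently
# with probability p_apply: additive Gaussian noise, random rotation,
# photometric adjustment (brightness, contrast, histogram equalization) and
# motion blur. Only rotation touches the mask, and it uses nearest-neighbour
# sampling so class labels are never interpolated.

#' Augmentation configuration
#'
#' @param p_apply per-strategy application probability (0.5 mirrors the
#'   source protocol).
#' @param noise_sigma Gaussian-noise standard deviation, 8-bit intensity
#'   units.
#' @param rotation_range rotation half-range in degrees; angles are drawn
#'   uniformly from `[-rotation_range, rotation_range]`.
#' @param brightness_range,contrast_range multiplicative factor ranges.
#' @param equalize_histogram include luminance histogram equalization in the
#'   photometric strategy.
#' @param motion_blur_len blur kernel length in pixels (forced odd).
#' @param target_count total images after [expand_dataset()].
#' @param seed integer seed for replicate generation.
#' @return an object of class `augmentation_config`.
#' @export
augmentation_config <- function(p_apply = 0.5, noise_sigma = 8,
                                rotation_range = 30,
                                brightness_range = c(0.8, 1.2),
                                contrast_range = c(0.8, 1.2),
                                equalize_histogram = TRUE,
                                motion_blur_len = 7L,
                                target_count = 4000L, seed = 1L) {
  if (p_apply < 0 || p_apply > 1)
    rds_spec_error("augmentation_config: p_apply must lie in [0, 1]")
  rng <- function(v, f) {
    if (length(v) == 1L) v <- c(v, v)
    if (v[1] > v[2] || any(v <= 0)) rds_spec_error(sprintf("augmentation_config: invalid range '%s'", f))
    v
  }
  if (noise_sigma < 0 || rotation_range < 0 || motion_blur_len < 1)
    rds_spec_error("augmentation_config: noise_sigma, rotation_range and motion_blur_len must be non-negative")
  structure(list(p_apply = p_apply, noise_sigma = noise_sigma,
                 rotation_range = rotation_range,
                 brightness_range = rng(brightness_range, "brightness_range"),
                 contrast_range = rng(contrast_range, "contrast_range"),
                 equalize_histogram = isTRUE(equalize_histogram),
                 motion_blur_len = as.integer(motion_blur_len),
                 target_count = as.integer(target_count),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Rotate a labeled scene about its center
#'
#' The image is resampled bilinearly with out-of-frame regions filled with
#' the scene's median background color; the mask uses nearest-neighbour
#' sampling with class-0 fill. Positive angles rotate the content
#' counter-clockwise in standard row/col coordinates.
#'
#' @param scene a [labeled_scene()].
#' @param angle degrees.
#' @return the rotated [labeled_scene()].
#' @export
rotate_scene <- function(scene, angle) {
  H <- nrow(scene$mask); W <- ncol(scene$mask)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- matrix(seq_len(H) - cy, H, W)
  cc <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  # inverse map: source = R(-theta) (dst - center) + center
  sy <- cy + rr * cos(th) - cc * sin(th)
  sx <- cx + rr * sin(th) + cc * cos(th)
  outside <- sy < 0.5 | sy > H + 0.5 | sx < 0.5 | sx > W + 0.5

  # mask: nearest neighbour, background fill
  ry <- pmin(pmax(round(sy), 1), H)
  rx <- pmin(pmax(round(sx), 1), W)
  mask <- matrix(scene$mask[cbind(as.vector(ry), as.vector(rx))], H, W)
  mask[outside] <- 0L

  bg <- scene$mask == 0
  fill <- vapply(1:3, function(ch) {
    pl <- scene$image[, , ch]
    stats::median(if (any(bg)) pl[bg] else pl)
  }, 0)
  img <- array(0, dim = c(H, W, 3L))
  pys <- pmin(pmax(as.vector(sy), 1), H) - 1 # clamp, then 0-based for sampling
  pxs <- pmin(pmax(as.vector(sx), 1), W) - 1
  for (ch in 1:3) {
    v <- cpp_bilinear_points(scene$image[, , ch], pys, pxs)
    v[as.vector(outside)] <- fill[ch]
    img[, , ch] <- matrix(v, H, W)
  }
  labeled_scene(round(clip255(img)), mask)
}

equalize_luminance <- function(img) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  q <- as.integer(pmin(pmax(round(lum), 0), 255))
  cdf <- cumsum(tabulate(q + 1L, 256L))
  cdf_min <- cdf[cdf > 0][1]
  denom <- max(1, length(q) - cdf_min)
  lut <- round((cdf - cdf_min) / denom * 255)
  eq <- matrix(lut[q + 1L], nrow(lum), ncol(lum))
  ratio <- ifelse(lum > 0, eq / pmax(lum, 1e-6), 1)
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch] * ratio
  clip255(out)
}

motion_blur_kernel <- function(len, angle) {
  k <- matrix(0, len, len)
  c0 <- (len + 1) / 2
  t <- seq(-(len - 1) / 2, (len - 1) / 2, length.out = 4L * len)
  rs <- pmin(pmax(round(c0 + t * sin(angle)), 1), len)
  cs <- pmin(pmax(round(c0 + t * cos(angle)), 1), len)
  k[cbind(rs, cs)] <- 1
  k / sum(k)
}

apply_motion_blur <- function(img, len, angle) {
  len <- as.integer(len)
  if (len %% 2L == 0L) len <- len + 1L
  if (len <= 1L) return(img)
  k <- motion_blur_kernel(len, angle)
  w <- array(0, dim = c(len, len, 1L, 3L))
  for (ch in 1:3) w[, , 1L, ch] <- k
  x4 <- array(img, dim = c(dim(img), 1L))
  y <- cpp_conv2d_fw(x4, w, numeric(0), 1L, (len - 1L) %/% 2L, 3L)
  clip255(array(y, dim = dim(img)))
}

#' Augment one labeled scene
#'
#' Each of the four strategies (Gaussian noise, rotation, photometric
#' adjustment, motion blur) is applied independently with probability
#' `config$p_apply`. Rotation is applied identically to image and mask;
#' photometric strategies touch the image only. Deterministic under a fixed
#' seed.
#'
#' @param scene a [labeled_scene()].
#' @param config an [augmentation_config()].
#' @param seed RNG seed for this draw.
#' @return the augmented [labeled_scene()].
#' @export
augment <- function(scene, config, seed = config$seed) {
  if (!inherits(config, "augmentation_config"))
    rds_spec_error("augment: config must be an augmentation_config")
  with_seed(seed, {
    apply_s <- stats::runif(4) < config$p_apply
    img <- scene$image
    mask <- scene$mask
    if (apply_s[1] && config$noise_sigma > 0) {
      img <- clip255(img + stats::rnorm(length(img), sd = config$noise_sigma))
    }
    if (apply_s[2] && config$rotation_range > 0) {
      ang <- stats::runif(1, -config$rotation_range, config$rotation_range)
      rot <- rotate_scene(labeled_scene(img, mask), ang)
      img <- rot$image
      mask <- rot$mask
    }
    if (apply_s[3]) {
      br <- stats::runif(1, config$brightness_range[1], config$brightness_range[2])
      ct <- stats::runif(1, config$contrast_range[1], config$contrast_range[2])
      mu <- mean(img)
      img <- clip255((img - mu) * ct + mu * br)
      if (config$equalize_histogram && stats::runif(1) < 0.5)
        img <- equalize_luminance(img)
    }
    if (apply_s[4] && config$motion_blur_len > 1) {
      img <- apply_motion_blur(img, config$motion_blur_len, stats::runif(1, 0, pi))
    }
    labeled_scene(round(img), mask)
  })
}

#' Grayscale + contrast-stretch preprocessing of a color annotation
#'
#' Converts a color annotation rendering to luminance (ITU-R 601 weights
#' 0.299/0.587/0.114) and linearly stretches the occupied intensity range to
#' the full 0-255 scale. Constant images are returned unchanged (the stretch
#' degenerates to the identity).
#'
#' @param mask_image `(H, W, 3)` color array (0-255), or an `H x W` matrix
#'   already holding luminance.
#' @return `H x W` numeric matrix in 0-255.
#' @export
preprocess_annotation <- function(mask_image) {
  lum <- if (length(dim(mask_image)) == 3L) {
    l <- 0.299 * mask_image[, , 1] + 0.587 * mask_image[, , 2] + 0.114 * mask_image[, , 3]
    matrix(l, dim(mask_image)[1], dim(mask_image)[2]) # keep shape for 1-row input
  } else mask_image
  lo <- min(lum); hi <- max(lum)
  if (hi > lo) lum <- (lum - lo) / (hi - lo) * 255
  lum
}
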