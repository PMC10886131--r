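# Synthetic corn/weed field scenes. Two green foreground classes with a
# deliberate scale disparity -- large multi-lobed "corn" rosettes vs small
# weed blobs and blades -- over a textured soil background, with occlusion by
# paint order, optional weed placement inside corn canopies, and a global
# illumination factor. The generator exists so the whole pipeline is testable
# without field imagery; it makes no attempt at photorealism.

#' Scene specification
#'
#' All two-sided arguments are `(low, high)` ranges sampled uniformly per
#' scene; scalars are fixed values.
#'
#' @param image_size pixels per side (>= 32).
#' @param n_corn corn plant count range.
#' @param n_weeds weed count range.
#' @param corn_scale characteristic corn radius range, pixels.
#' @param weed_scale characteristic weed radius range, pixels.
#' @param overlap_fraction probability a weed is planted inside a corn
#'   plant's bounding circle (occlusion pressure).
#' @param illumination multiplicative brightness factor range.
#' @param background_texture soil-noise amplitude on the 0-255 scale.
#' @param corn_shape `"lobed"` rosettes (default) or `"disc"` (a flat disc;
#'   used by geometric diagnostics because its painted area is known in
#'   closed form).
#' @param placement `"random"` or `"center"` (first corn at the image
#'   center).
#' @param seed integer seed used to derive per-scene seeds in
#'   [generate_dataset()].
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 224L, n_corn = c(1L, 3L), n_weeds = c(0L, 20L),
                       corn_scale = c(30, 60), weed_scale = c(3, 12),
                       overlap_fraction = 0.2, illumination = c(0.7, 1.3),
                       background_texture = 12, corn_shape = c("lobed", "disc"),
                       placement = c("random", "center"), seed = 1L) {
  corn_shape <- match.arg(corn_shape)
  placement <- match.arg(placement)
  rng <- function(v, field) {
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2])
      rds_spec_error(sprintf("scene_spec: invalid range for field '%s'", field))
    v
  }
  if (!is.finite(image_size) || image_size < 32L)
    rds_spec_error("scene_spec: invalid field 'image_size' (must be >= 32)")
  n_corn <- rng(n_corn, "n_corn"); n_weeds <- rng(n_weeds, "n_weeds")
  if (any(n_corn < 0) || any(n_weeds < 0))
    rds_spec_error("scene_spec: invalid field 'n_corn'/'n_weeds' (counts must be >= 0)")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    rds_spec_error("scene_spec: invalid field 'overlap_fraction' (must be in [0, 1])")
  if (background_texture < 0 || background_texture > 255)
    rds_spec_error("scene_spec: invalid field 'background_texture' (0-255 scale)")
  structure(list(image_size = as.integer(image_size),
                 n_corn = as.integer(n_corn), n_weeds = as.integer(n_weeds),
                 corn_scale = rng(corn_scale, "corn_scale"),
                 weed_scale = rng(weed_scale, "weed_scale"),
                 overlap_fraction = overlap_fraction,
                 illumination = rng(illumination, "illumination"),
                 background_texture = background_texture,
                 corn_shape = corn_shape, placement = placement,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Labeled scene constructor
#'
#' @param image `(H, W, 3)` array of 8-bit RGB intensities (0-255).
#' @param mask `H x W` integer matrix with 0 background, 1 corn, 2 weed.
#' @return an object of class `labeled_scene`.
#' @export
labeled_scene <- function(image, mask) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    rds_shape_error("labeled_scene: image and mask sizes differ")
  if (!all(mask %in% 0:2))
    rds_format_error("labeled_scene: mask values outside {0, 1, 2}")
  storage.mode(mask) <- "integer"
  structure(list(image = image, mask = mask), class = "labeled_scene")
}

# paint an axis-rotated ellipse; overwrites both image and mask (occlusion by
# paint order). env carries $img (H,W,3) and $mask.
paint_ellipse <- function(env, cy, cx, a, b, theta, cls, rgb_col) {
  H <- nrow(env$mask); W <- ncol(env$mask)
  rr <- max(a, b)
  r0 <- max(1L, floor(cy - rr)); r1 <- min(H, ceiling(cy + rr))
  c0 <- max(1L, floor(cx - rr)); c1 <- min(W, ceiling(cx + rr))
  if (r0 > r1 || c0 > c1) return(invisible(NULL))
  ri <- r0:r1; ci <- c0:c1
  dy <- matrix(ri - cy, length(ri), length(ci))
  dx <- matrix(ci - cx, length(ri), length(ci), byrow = TRUE)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(invisible(NULL))
  sub_m <- env$mask[ri, ci, drop = FALSE]
  sub_m[inside] <- cls
  env$mask[ri, ci] <- sub_m
  jitter <- stats::rnorm(sum(inside), sd = 6)
  for (ch in 1:3) {
    plane <- env$img[, , ch]
    sub <- plane[ri, ci, drop = FALSE]
    sub[inside] <- rgb_col[ch] + jitter
    plane[ri, ci] <- sub
    env$img[, , ch] <- plane
  }
  invisible(NULL)
}

runifr <- function(r) stats::runif(1, r[1], r[2])
sample_count <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

#' Generate one labeled scene
#'
#' Corn rosettes are unions of elongated ellipse lobes around a stem disc;
#' weeds are small discs or thin blades. Weeds are drawn after corn, so later
#' foreground overwrites earlier pixels and the mask stays paint-order
#' consistent with the image. Identical `(spec, seed)` pairs yield
#' bit-identical scenes.
#'
#' @param spec a [scene_spec()].
#' @param seed integer RNG seed for this scene.
#' @return a [labeled_scene()].
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "scene_spec")) rds_spec_error("generate_scene: spec must be a scene_spec")
  with_seed(seed, {
    S <- spec$image_size
    env <- new.env(parent = emptyenv())
    # soil: base tone + coarse patchiness + fine grain
    base <- c(126, 99, 72)
    coarse <- cpp_resize(array(stats::rnorm(8 * 8 * 3, sd = spec$background_texture),
                               dim = c(8L, 8L, 3L)), S, S, TRUE)
    fine <- array(stats::rnorm(S * S * 3, sd = spec$background_texture / 3), dim = c(S, S, 3))
    env$img <- sweep(coarse + fine, 3, base, "+")
    env$mask <- matrix(0L, S, S)

    nc <- sample_count(spec$n_corn)
    corn_centers <- NULL
    if (nc > 0) {
      for (i in seq_len(nc)) {
        r <- runifr(spec$corn_scale)
        if (spec$placement == "center" && i == 1L) {
          cy <- (S + 1) / 2; cx <- (S + 1) / 2
        } else {
          cy <- stats::runif(1, 1 + 0.2 * r, S - 0.2 * r)
          cx <- stats::runif(1, 1 + 0.2 * r, S - 0.2 * r)
        }
        corn_centers <- rbind(corn_centers, c(cy, cx, r))
        col <- c(45, 150, 45) + stats::rnorm(3, sd = c(12, 18, 12))
        if (spec$corn_shape == "disc") {
          paint_ellipse(env, cy, cx, r, r, 0, 1L, col)
        } else {
          nl <- sample(4:7, 1L)
          phase <- stats::runif(1, 0, 2 * pi)
          for (k in seq_len(nl)) {
            th <- phase + 2 * pi * k / nl + stats::rnorm(1, sd = 0.15)
            lc <- col + stats::rnorm(3, sd = 6)
            paint_ellipse(env, cy + 0.55 * r * sin(th), cx + 0.55 * r * cos(th),
                          0.72 * r, 0.22 * r, atan2(sin(th), cos(th)) , 1L, lc)
          }
          paint_ellipse(env, cy, cx, 0.2 * r, 0.2 * r, 0, 1L, col * 0.9)
        }
      }
    }

    nw <- sample_count(spec$n_weeds)
    if (nw > 0) {
      for (i in seq_len(nw)) {
        r <- runifr(spec$weed_scale)
        inside_corn <- !is.null(corn_centers) && stats::runif(1) < spec$overlap_fraction
        if (inside_corn) {
          j <- sample(nrow(corn_centers), 1L)
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, corn_centers[j, 3])
          cy <- corn_centers[j, 1] + rad * sin(ang)
          cx <- corn_centers[j, 2] + rad * cos(ang)
        } else {
          cy <- stats::runif(1, 1, S); cx <- stats::runif(1, 1, S)
        }
        col <- c(82, 132, 56) + stats::rnorm(3, sd = c(14, 16, 14))
        if (stats::runif(1) < 0.5) {
          paint_ellipse(env, cy, cx, r, r * stats::runif(1, 0.7, 1), stats::runif(1, 0, pi), 2L, col)
        } else { # blade: thin elongated ellipse
          paint_ellipse(env, cy, cx, 2 * r, max(0.8, 0.25 * r), stats::runif(1, 0, pi), 2L, col)
        }
      }
    }

    img <- env$img * runifr(spec$illumination)
    img <- round(pmin(pmax(img, 0), 255))
    labeled_scene(img, env$mask)
  })
}

#' Generate a dataset of scenes in Pascal-VOC segmentation layout
#'
#' Writes `JPEGImages/<id>.jpg`, `SegmentationClass/<id>.png`
#' (indexed-palette: black/green/red) and an
#' `ImageSets/Segmentation/train.txt` list with one zero-padded id per line.
#' Per-scene seeds are derived deterministically from `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param n number of scenes (>= 1).
#' @param out_dir dataset root directory (created if missing).
#' @return a `rds_dataset_index` of the written samples.
#' @export
generate_dataset <- function(spec, n, out_dir) {
  if (!is.numeric(n) || n < 1) rds_spec_error("generate_dataset: n must be >= 1")
  n <- as.integer(n)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) rds_io_error(sprintf("cannot create dataset directory %s", out_dir))
  for (d in c("JPEGImages", "SegmentationClass", "ImageSets/Segmentation"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("%05d", seq_len(n))
  for (i in seq_len(n)) {
    sc <- generate_scene(spec, seeds[i])
    jpeg::writeJPEG(sc$image / 255, file.path(out_dir, "JPEGImages", paste0(ids[i], ".jpg")),
                    quality = 0.95)
    write_palette_png(sc$mask, file.path(out_dir, "SegmentationClass", paste0(ids[i], ".png")))
  }
  idx <- new_dataset_index(out_dir, ids, stats::setNames(rep("train", n), ids))
  write_split_lists(idx)
  idx
}
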