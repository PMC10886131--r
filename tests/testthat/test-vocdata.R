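test_that("palette mask files round-trip exactly and reject bad indices", {
  m <- matrix(sample(0:2, 48 * 36, replace = TRUE), 48, 36)
  f <- tempfile(fileext = ".png")
  write_palette_png(m, f)
  expect_identical(read_mask_png(f), m)

  # a palette PNG carrying an out-of-range class index is a format error
  pal6 <- rbind(voc_palette <- matrix(c(0, 0, 0, 0, 255, 0, 255, 0, 0), 3, byrow = TRUE),
                c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  f5 <- tempfile(fileext = ".png")
  write_palette_png(matrix(5L, 8, 8), f5, palette = pal6)
  expect_error(read_mask_png(f5), class = "rds_format_error")
})

test_that("load_sample resizes to 224 with nearest-neighbour masks", {
  dir <- tempfile()
  idx <- make_tiny_dataset(2, dir, seed = 4)
  sc <- load_sample(idx, idx$ids[1]) # default size 224
  expect_identical(dim(sc$image), c(224L, 224L, 3L))
  expect_identical(dim(sc$mask), c(224L, 224L))
  expect_true(all(sc$mask %in% 0:2)) # no interpolated labels
  expect_error(load_sample(idx, "nope"), class = "rds_io_error")

  # native-size load round-trips the written mask exactly
  native <- load_sample(idx, idx$ids[1], size = NULL)
  stored <- read_mask_png(file.path(dir, "SegmentationClass",
                                    paste0(idx$ids[1], ".png")))
  expect_identical(native$mask, stored)
})

test_that("labelme polygons rasterize with exact pixel-center coverage", {
  j <- list(imageHeight = 32L, imageWidth = 32L,
            shapes = list(
              list(label = "corn",
                   points = list(list(10, 10), list(20, 10), list(20, 20), list(10, 20)))))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(j, f, auto_unbox = TRUE)
  sc <- labelme_to_voc(f)
  expect_identical(sum(sc$mask == 1L), 100L)
  # oracle: scanline fill at pixel centers
  centers_in <- outer(seq_len(32) - 0.5, seq_len(32) - 0.5,
                      function(y, x) y > 10 & y < 20 & x > 10 & x < 20)
  expect_identical(unname(sc$mask == 1L), unname(centers_in))

  # zero shapes -> all background; unknown label -> format error
  j0 <- list(imageHeight = 8L, imageWidth = 8L, shapes = list())
  f0 <- tempfile(fileext = ".json")
  jsonlite::write_json(j0, f0, auto_unbox = TRUE)
  expect_true(all(labelme_to_voc(f0)$mask == 0L))

  jbad <- list(imageHeight = 8L, imageWidth = 8L,
               shapes = list(list(label = "dandelion",
                                  points = list(list(1, 1), list(5, 1), list(5, 5)))))
  fbad <- tempfile(fileext = ".json")
  jsonlite::write_json(jbad, fbad, auto_unbox = TRUE)
  err <- expect_error(labelme_to_voc(fbad), class = "rds_format_error")
  expect_match(conditionMessage(err), "dandelion")

  # "grass" maps to class 2
  j2 <- list(imageHeight = 16L, imageWidth = 16L,
             shapes = list(list(label = "grass",
                                points = list(list(2, 2), list(9, 2), list(9, 9), list(2, 9)))))
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(j2, f2, auto_unbox = TRUE)
  expect_identical(sum(labelme_to_voc(f2)$mask == 2L), 49L)
})

test_that("augmentation separates photometric and geometric effects", {
  sc <- generate_scene(tiny_scene_spec(seed = 2), seed = 2)

  # p_apply = 0 is the identity
  cfg0 <- augmentation_config(p_apply = 0)
  expect_identical(augment(sc, cfg0, seed = 1), sc)

  # noise only: image changes, mask untouched
  cfgn <- augmentation_config(p_apply = 1, rotation_range = 0,
                              brightness_range = 1, contrast_range = 1,
                              equalize_histogram = FALSE, motion_blur_len = 1,
                              noise_sigma = 10)
  aug <- augment(sc, cfgn, seed = 5)
  expect_identical(aug$mask, sc$mask)
  expect_gt(mean(abs(aug$image - sc$image)), 0)

  # mask values never leave {0,1,2}, dimensions preserved
  cfg <- augmentation_config()
  for (s in 1:5) {
    a <- augment(sc, cfg, seed = s)
    expect_true(all(a$mask %in% 0:2))
    expect_identical(dim(a$mask), dim(sc$mask))
  }
  expect_identical(augment(sc, cfg, seed = 3), augment(sc, cfg, seed = 3))
})

test_that("rotation by exactly 90 degrees moves a pixel to its rotated place", {
  N <- 33
  mask <- matrix(0L, N, N)
  r0 <- 8L; c0 <- 21L
  mask[r0, c0] <- 1L
  img <- array(0, c(N, N, 3))
  img[r0, c0, ] <- 255
  rot <- rotate_scene(labeled_scene(img, mask), 90)
  # oracle: apply the inverse-map definition src = R(-theta)(dst - c) + c
  # directly over all destination pixels
  cy <- (N + 1) / 2
  hits <- which(rot$mask == 1L, arr.ind = TRUE)
  expect_identical(nrow(hits), 1L)
  expected <- c(c0, 2 * cy - r0) # solves the 90-degree inverse map
  expect_identical(as.integer(hits[1, ]), as.integer(expected))
})

test_that("expand_dataset hits the target count with round-robin provenance", {
  dir <- tempfile()
  idx <- make_tiny_dataset(3, dir, seed = 6)
  cfg <- augmentation_config(target_count = 7, seed = 1)
  out <- expand_dataset(idx, cfg)
  expect_length(out$ids, 7)
  extra <- out$provenance[!out$provenance$id %in% idx$ids, ]
  expect_identical(as.integer(table(extra$source)[idx$ids]), c(2L, 1L, 1L))
  expect_true(all(extra$source %in% idx$ids))

  # no-op expansion and invalid targets
  expect_identical(expand_dataset(idx, augmentation_config(target_count = 3))$ids, idx$ids)
  expect_error(expand_dataset(idx, augmentation_config(target_count = 2)),
               class = "rds_spec_error")
})

test_that("splits follow round(N f) arithmetic, are disjoint and seeded", {
  dir <- tempfile()
  idx <- make_tiny_dataset(10, dir, seed = 8)
  sp <- split_dataset(idx, 0.2, 0.2, seed = 3)
  sizes <- table(factor(sp$split_of, levels = c("train", "val", "test")))
  expect_identical(as.integer(sizes), c(6L, 2L, 2L))
  expect_setequal(unlist(lapply(c("train", "val", "test"), split_ids, index = sp)), idx$ids)

  sp2 <- split_dataset(idx, 0.2, 0.2, seed = 3)
  expect_identical(sp$split_of, sp2$split_of)
  sp3 <- split_dataset(idx, 0.2, 0.2, seed = 4)
  expect_false(identical(sp$split_of, sp3$split_of))

  # replicates stay with their source (no train/test leakage)
  ex <- expand_dataset(read_dataset_index(dir), augmentation_config(target_count = 30, seed = 2))
  spx <- split_dataset(ex, 0.2, 0.2, seed = 1)
  by_src <- split(spx$split_of[spx$provenance$id], spx$provenance$source)
  expect_true(all(vapply(by_src, function(v) length(unique(v)) == 1L, TRUE)))

  expect_error(split_dataset(idx, 0.0, 0.2), class = "rds_spec_error")
})

test_that("annotation preprocessing stretches luminance to the full range", {
  # constant image passes through unchanged
  flat <- array(77, c(6, 6, 3))
  expect_true(all(preprocess_annotation(flat) == 77))

  # green has higher ITU-R 601 luminance than red
  img <- array(0, c(1, 2, 3))
  img[1, 1, 1] <- 255 # red
  img[1, 2, 2] <- 255 # green
  lum <- preprocess_annotation(img)
  expect_equal(lum[1, 1] / 255, 0, tolerance = 1e-12) # after stretch red -> 0
  expect_equal(lum[1, 2], 255)

  # grayscale range [50, 150] stretches exactly to [0, 255]
  g <- matrix(seq(50, 150, length.out = 64), 8, 8)
  out <- preprocess_annotation(g)
  expect_equal(range(out), c(0, 255))
  expect_equal(out[1], (50 - 50) / 100 * 255)
  expect_equal(out[64], 255)
})
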