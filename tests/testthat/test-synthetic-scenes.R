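test_that("scene generation respects counts, classes and shapes", {
  spec <- scene_spec(image_size = 224, n_weeds = 0, seed = 3)
  sc <- generate_scene(spec, seed = 3)
  expect_identical(dim(sc$image), c(224L, 224L, 3L))
  expect_identical(dim(sc$mask), c(224L, 224L))
  expect_false(any(sc$mask == 2L)) # no weeds requested
  expect_true(all(sc$mask %in% 0:2))

  bare <- generate_scene(scene_spec(image_size = 64, n_corn = 0, n_weeds = 0), seed = 1)
  expect_true(all(bare$mask == 0L))
  expect_gt(stats::sd(bare$image), 0) # textured soil, not flat
})

test_that("invalid scene specifications name the offending field", {
  expect_error(scene_spec(image_size = 16), class = "rds_spec_error")
  expect_error(scene_spec(image_size = 16), "image_size")
  expect_error(scene_spec(n_corn = c(3, 1)), "n_corn")
  expect_error(scene_spec(overlap_fraction = 1.5), "overlap_fraction")
})

test_that("a centered disc corn paints close to pi r^2 pixels", {
  for (r in c(12, 20)) {
    spec <- scene_spec(image_size = 96, n_corn = 1, n_weeds = 0,
                       corn_scale = c(r, r), corn_shape = "disc",
                       placement = "center")
    sc <- generate_scene(spec, seed = 5)
    # oracle: rasterize the same disc directly at pixel centers
    cy <- (96 + 1) / 2
    grid <- expand.grid(rr = 1:96, cc = 1:96)
    expected <- sum((grid$rr - cy)^2 + (grid$cc - cy)^2 <= r^2)
    painted <- sum(sc$mask == 1L)
    expect_identical(painted, expected)
    expect_lt(abs(painted - pi * r^2) / (pi * r^2), 0.05)
  }
})

test_that("scene generation is bit-deterministic in (spec, seed)", {
  spec <- tiny_scene_spec(seed = 11)
  a <- generate_scene(spec, seed = 42)
  b <- generate_scene(spec, seed = 42)
  expect_identical(a, b)
  c <- generate_scene(spec, seed = 43)
  expect_false(identical(a$mask, c$mask) && identical(a$image, c$image))
})

test_that("expected foreground is monotone in plant counts", {
  frac <- function(nc) {
    mean(vapply(1:12, function(s) {
      spec <- scene_spec(image_size = 64, n_corn = nc, n_weeds = 0,
                         corn_scale = c(8, 14))
      mean(generate_scene(spec, seed = s)$mask == 1L)
    }, 0))
  }
  expect_gte(frac(3), frac(1))
})

test_that("generate_dataset writes a VOC layout that round-trips", {
  dir <- file.path(tempfile(), "voc")
  idx <- make_tiny_dataset(5, dir, seed = 9)
  expect_length(list.files(file.path(dir, "JPEGImages"), pattern = "\\.jpg$"), 5)
  expect_length(list.files(file.path(dir, "SegmentationClass"), pattern = "\\.png$"), 5)
  ids <- readLines(file.path(dir, "ImageSets", "Segmentation", "train.txt"))
  expect_length(ids, 5)

  # every stored mask decodes to legal class indices at native size
  for (id in idx$ids) {
    sc <- load_sample(idx, id, size = NULL)
    expect_true(all(sc$mask %in% 0:2))
    expect_identical(dim(sc$mask), c(64L, 64L))
  }

  # same seed twice -> byte-identical mask files
  dir2 <- file.path(tempfile(), "voc2")
  make_tiny_dataset(5, dir2, seed = 9)
  for (id in idx$ids) {
    f1 <- file.path(dir, "SegmentationClass", paste0(id, ".png"))
    f2 <- file.path(dir2, "SegmentationClass", paste0(id, ".png"))
    expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  }

  expect_error(generate_dataset(tiny_scene_spec(), 0, tempfile()), class = "rds_spec_error")
})
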