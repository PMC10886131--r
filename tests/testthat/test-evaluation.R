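test_that("confusion accumulation counts pixels exactly and is associative", {
  truth <- matrix(c(0L, 2L, 1L, 2L), 2, 2) # rows: (0,1), (2,2)
  pred <- matrix(c(0L, 2L, 2L, 1L), 2, 2)
  cm <- accumulate_confusion(pred, truth)
  expect_identical(sum(cm), 4)
  expect_identical(cm["0", "0"], 1)
  expect_identical(cm["1", "2"], 1)
  expect_identical(cm["2", "2"], 1)
  expect_identical(cm["2", "1"], 1)

  # perfect prediction -> diagonal with trace H*W
  p2 <- matrix(sample(0:2, 36, replace = TRUE), 6, 6)
  cmp <- accumulate_confusion(p2, p2)
  expect_identical(sum(diag(cmp)), 36)
  expect_identical(sum(cmp) - sum(diag(cmp)), 0)

  # two images == their concatenation
  a_p <- matrix(sample(0:2, 16, TRUE), 4, 4); a_t <- matrix(sample(0:2, 16, TRUE), 4, 4)
  b_p <- matrix(sample(0:2, 16, TRUE), 4, 4); b_t <- matrix(sample(0:2, 16, TRUE), 4, 4)
  two <- accumulate_confusion(b_p, b_t, accumulate_confusion(a_p, a_t))
  one <- accumulate_confusion(c(a_p, b_p), c(a_t, b_t))
  expect_identical(two, one)

  expect_error(accumulate_confusion(matrix(0L, 2, 2), matrix(0L, 2, 3)),
               class = "rds_shape_error")
  expect_error(accumulate_confusion(matrix(5L, 2, 2), matrix(0L, 2, 2)),
               class = "rds_label_error")
})

test_that("MIoU and precision/recall reproduce hand-computed toys", {
  # 2-class 4-pixel toy: truth (1,1,0,0), pred (1,0,0,0)
  truth <- c(1L, 1L, 0L, 0L)
  pred <- c(1L, 0L, 0L, 0L)
  cm <- accumulate_confusion(pred, truth, n_classes = 2L)
  expect_equal(miou(cm), 7 / 12)
  pr <- precision_recall(cm)
  expect_equal(pr$per_class$precision, c(2 / 3, 1))
  expect_equal(pr$per_class$recall, c(1, 1 / 2))
  expect_equal(pr$precision, 5 / 6)
  expect_equal(pr$recall, 3 / 4)

  # perfect prediction
  cmp <- accumulate_confusion(truth, truth, n_classes = 2L)
  expect_identical(miou(cmp), 1)
  expect_identical(precision_recall(cmp)$precision, 1)

  # swapping pred and truth swaps precision and recall
  cms <- accumulate_confusion(truth, pred, n_classes = 2L)
  prs <- precision_recall(cms)
  expect_equal(prs$precision, pr$recall)
  expect_equal(prs$recall, pr$precision)

  # invariance under simultaneous class relabeling
  relab <- c(1L, 0L) # swap labels 0 <-> 1
  cmr <- accumulate_confusion(relab[pred + 1L], relab[truth + 1L], n_classes = 2L)
  expect_equal(miou(cmr), miou(cm))

  expect_error(miou(empty_confusion(3)), class = "rds_metric_error")
})

test_that("metrics agree exactly with the per-pixel loop oracle", {
  set.seed(4)
  for (i in 1:25) {
    truth <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
    pred <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
    cm <- accumulate_confusion(pred, truth)
    ref <- oracle_metrics(pred, truth)
    expect_identical(miou(cm), ref$miou)
    pr <- precision_recall(cm)
    expect_identical(pr$precision, ref$precision)
    expect_identical(pr$recall, ref$recall)
    expect_gte(miou(cm), 0); expect_lte(miou(cm), 1)
  }
})

test_that("zero-denominator classes are excluded, not scored", {
  # class 2 absent from truth and prediction
  truth <- c(0L, 0L, 1L, 1L)
  pred <- c(0L, 1L, 1L, 0L)
  cm <- accumulate_confusion(pred, truth, n_classes = 3L)
  expect_equal(miou(cm), mean(c(1 / 3, 1 / 3)))
  pr <- precision_recall(cm, average = "foreground_only")
  expect_equal(pr$precision, 1 / 2) # only class 1 defined among foreground
})

test_that("fps measurement validates inputs and returns a positive rate", {
  m <- build_model("unet", seed = 1)
  expect_error(measure_fps(m, 64, n_frames = 0), class = "rds_spec_error")
  fps <- measure_fps(m, 64, n_frames = 2, warmup = 1)
  expect_true(is.finite(fps) && fps > 0)
})

test_that("overlays recolor exactly the labeled pixels and panels tile", {
  img <- array(100, c(8, 8, 3))
  mask <- matrix(0L, 8, 8)
  expect_identical(render_overlay(img, mask), img) # all background untouched

  mask[3, 5] <- 1L
  ov <- render_overlay(img, mask, alpha = 0.5)
  expect_equal(ov[3, 5, ], c(50, 177.5, 50)) # green-shifted pixel
  same <- ov; same[3, 5, ] <- 100
  expect_identical(same, img)

  pan <- render_panel(img, mask, mask, sep = 2)
  expect_identical(dim(pan), c(8L, 8L * 3L + 4L, 3L))
})
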