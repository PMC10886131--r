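test_that("dice loss has the right fixed points, range and hand value", {
  # near-perfect prediction drives the loss toward zero
  tr <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  lg <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) lg[i, j, tr[i, j] + 1L] <- 20
  expect_lt(dice_loss(lg, tr), 1e-3)

  # uniform logits on a 2-class 2x2 image, one pixel of class 1:
  # p_k = 1/2 everywhere; d_k = (2 * 0.5 * n_k + eps) / (0.5 * N + n_k + eps)
  tr2 <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  lg2 <- array(0, c(2, 2, 2))
  d0 <- (2 * 0.5 * 3 + 1e-6) / (0.5 * 4 + 3 + 1e-6)
  d1 <- (2 * 0.5 * 1 + 1e-6) / (0.5 * 4 + 1 + 1e-6)
  expect_equal(dice_loss(lg2, tr2), 1 - mean(c(d0, d1)), tolerance = 1e-12)

  # range [0, 1] for arbitrary logits
  set.seed(1)
  for (i in 1:10) {
    z <- array(rnorm(4 * 4 * 3, sd = 5), c(4, 4, 3))
    t3 <- matrix(sample(0:2, 16, replace = TRUE), 4, 4)
    l <- dice_loss(z, t3)
    expect_gte(l, 0)
    expect_lte(l, 1)
  }

  # out-of-range labels are rejected
  expect_error(dice_loss(array(0, c(2, 2, 2)), matrix(2L, 2, 2)),
               class = "rds_label_error")
})

test_that("dice loss gradient matches finite differences", {
  set.seed(2)
  z <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  tr <- array(sample(0:2, 18, replace = TRUE), c(3, 3, 2))
  n <- rdsunet:::ag_node(z)
  L <- rdsunet:::ag_dice_loss(n, tr)
  rdsunet:::ag_backward(L)
  fd <- fd_grad(function(zz) dice_loss(zz, tr), z)
  expect_lt(max(abs(n$grad - fd)), 1e-6)
})

test_that("training is seeded-deterministic and records one row per epoch", {
  dir <- tempfile()
  idx <- make_tiny_dataset(4, dir, seed = 21)
  # tiny plain U-net run keeps this affordable; determinism is a property of
  # the whole pipeline, not of one architecture
  cfg <- train_config(epochs = 2, batch_size = 2, seed = 9)
  r1 <- train("unet", idx, cfg)
  r2 <- train("unet", idx, cfg)
  expect_identical(nrow(r1$history), 2L)
  expect_equal(r1$history$train_loss[1], r2$history$train_loss[1], tolerance = 1e-6)
  expect_equal(r1$history$train_loss, r2$history$train_loss, tolerance = 1e-6)

  expect_error(train("unet", split_dataset(idx, 0.25, 0.25, seed = 1),
                     train_config(epochs = 1, batch_size = 64, seed = 1, loss = "dice"),
                     resume_from = tempfile()), class = "rds_io_error")
})

test_that("checkpoints round-trip to identical validation metrics and resume", {
  dir <- tempfile()
  idx <- split_dataset(make_tiny_dataset(6, dir, seed = 22), 1 / 6, 0.2, seed = 2)
  ck <- tempfile()
  cfg <- train_config(epochs = 2, batch_size = 2, seed = 5, checkpoint_dir = ck)
  res <- train("unet", idx, cfg)
  expect_true(file.exists(file.path(ck, "last.rds")))
  expect_true(file.exists(file.path(ck, "best.rds")))
  expect_true(file.exists(file.path(ck, "history.tsv")))

  val_scenes <- lapply(split_ids(idx, "val"), function(id) load_sample(idx, id, NULL))
  ev_direct <- evaluate_model(res$model, val_scenes)
  ev_loaded <- evaluate_model(load_checkpoint(file.path(ck, "last.rds")), val_scenes)
  expect_identical(ev_direct$miou, ev_loaded$miou)
  expect_identical(ev_direct$loss, ev_loaded$loss)
  expect_identical(ev_direct$cm, ev_loaded$cm)

  # resuming appends epochs to the same history
  cfg2 <- train_config(epochs = 3, batch_size = 2, seed = 5, checkpoint_dir = ck)
  res2 <- train(NULL, idx, cfg2, resume_from = file.path(ck, "last.rds"))
  expect_identical(res2$history$epoch, 1:3)
})

test_that("training configuration validates the protocol fields", {
  cfg <- train_config()
  expect_identical(cfg$epochs, 100L)
  expect_identical(cfg$batch_size, 4L)
  expect_identical(cfg$learning_rate, 0.001)
  expect_identical(cfg$beta1, 0.9)
  expect_identical(cfg$weight_decay, 1e-4)
  expect_identical(cfg$loss, "dice")
  expect_error(train_config(epochs = 0), class = "rds_spec_error")
  expect_error(train_config(loss = "focal"), class = "rds_spec_error")
})
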