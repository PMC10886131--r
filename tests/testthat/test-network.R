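test_that("presets map to the documented toggle combinations", {
  v <- preset("unet_123")
  expect_identical(v$encoder, "resnext50")
  expect_true(v$deformable_layer1)
  expect_true(v$scse_layers234)
  expect_identical(preset("rds_unet"), v) # alias

  v0 <- preset("unet")
  expect_identical(v0$encoder, "plain_unet")
  expect_false(v0$deformable_layer1 || v0$scse_layers234)

  expect_identical(preset("unet_1")$encoder, "resnext50")
  expect_false(preset("unet_1")$deformable_layer1)
  expect_true(preset("unet_12")$deformable_layer1)
  expect_false(preset("unet_12")$scse_layers234)

  err <- expect_error(preset("pspnet"), class = "rds_spec_error")
  expect_match(conditionMessage(err), "unet_123")
})

test_that("every preset maps 64x64 images to full-resolution 3-class logits", {
  set.seed(1)
  x <- array(rnorm(64 * 64 * 3 * 1), c(64, 64, 3, 1))
  counts <- numeric(0)
  for (p in preset_names()) {
    m <- build_model(p, seed = 2)
    lg <- forward(m, x)
    expect_identical(dim(lg), c(64L, 64L, 3L, 1L))
    expect_true(all(is.finite(lg)))
    counts[p] <- n_params(m)
  }
  # complexity ordering of the ablation ladder
  expect_gt(counts[["unet_123"]], counts[["unet"]])
  expect_gt(counts[["unet_123"]], counts[["unet_12"]])
  expect_gt(counts[["unet_12"]], counts[["unet_1"]])
})

test_that("non-multiples of 32 are rejected with a shape error", {
  m <- build_model("unet", seed = 1)
  err <- expect_error(forward(m, array(0, c(60, 60, 3, 1))), class = "rds_shape_error")
  expect_match(conditionMessage(err), "32")
  expect_error(forward(m, array(0, c(64, 64, 4, 1))), class = "rds_shape_error")
})

test_that("batch concatenation does not change per-sample outputs", {
  set.seed(3)
  m <- build_model("unet_1", seed = 4)
  a <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  b <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  ab <- array(c(a, b), c(64, 64, 3, 2))
  ya <- forward(m, a)
  yb <- forward(m, b)
  yab <- forward(m, ab)
  expect_equal(yab[, , , 1, drop = FALSE], ya, tolerance = 1e-10)
  expect_equal(unname(yab[, , , 2]), unname(yb[, , , 1]), tolerance = 1e-10)
})

test_that("a zero-weight head yields uniform logits and all-background argmax", {
  m <- build_model("unet", seed = 5)
  m$reg$params[["head.w"]]$value[] <- 0
  m$reg$params[["head.b"]]$value[] <- 0
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  lg <- forward(m, x)
  expect_true(all(lg == 0))
  expect_true(all(predict_mask(m, x) == 0L)) # first-index tie break
})

test_that("toggles are additive: shared seed gives identical encoder weights", {
  m12 <- build_model("unet_12", seed = 11)
  m123 <- build_model("unet_123", seed = 11)
  enc_names <- grep("^encoder\\.", names(m12$reg$params), value = TRUE)
  expect_gt(length(enc_names), 50)
  for (nm in enc_names) {
    expect_identical(m12$reg$params[[nm]]$value, m123$reg$params[[nm]]$value)
  }
})

test_that("one optimization step moves every parameter group (full preset)", {
  set.seed(6)
  m <- build_model("unet_123", seed = 7)
  cfg <- train_config(epochs = 1, batch_size = 2, seed = 1)
  opt <- rdsunet:::adam_new(m$reg$params)
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  tr <- array(sample(0:2, 64 * 64 * 2, replace = TRUE), c(64, 64, 2))
  before <- lapply(m$reg$params, function(p) p$value + 0) # deep copy: updates are in-place
  lg <- m$forward_node(rdsunet:::ag_node(x), training = TRUE)
  loss <- rdsunet:::ag_dice_loss(lg, tr)
  rdsunet:::ag_backward(loss)
  moved_grad <- vapply(m$reg$params, function(p) !is.null(p$grad) && any(p$grad != 0), TRUE)
  expect_true(all(moved_grad))
  rdsunet:::adam_step(m$reg, opt, cfg)
  moved <- vapply(names(m$reg$params),
                  function(nm) any(m$reg$params[[nm]]$value != before[[nm]]), TRUE)
  expect_true(all(moved))
  rm(m, opt, before, lg, loss)
  gc(FALSE)
})
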