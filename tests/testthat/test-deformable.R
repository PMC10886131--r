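test_that("reference convolution matches identity, impulse and brute force", {
  set.seed(1)
  x <- array(rnorm(5 * 5), c(5, 5, 1, 1))
  # identity kernel: center weight 1
  wid <- array(0, c(3, 3, 1, 1)); wid[2, 2, 1, 1] <- 1
  expect_equal(standard_conv_ref(x, wid), x)

  # all-ones kernel on an impulse -> 3x3 block of ones
  imp <- array(0, c(5, 5, 1, 1)); imp[3, 3, 1, 1] <- 1
  ones <- array(1, c(3, 3, 1, 1))
  y <- standard_conv_ref(imp, ones)
  expect_equal(sum(y), 9)
  expect_true(all(y[2:4, 2:4, 1, 1] == 1))
  expect_true(all(y[c(1, 5), , 1, 1] == 0))

  # random case against the scalar triple-loop oracle
  xr <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  wr <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  br <- rnorm(4)
  expect_lt(max(abs(standard_conv_ref(xr, wr, br) - oracle_conv(xr, wr, br, pad = 1))), 1e-6)
})

test_that("bilinear sampling is exact at integers, linear between, zero outside", {
  x <- matrix(1:12, 3, 4) * 1.0
  # integer coordinates return stored values (0-based coordinates)
  expect_identical(bilinear_sample(x, c(1, 2)), x[2, 3])
  # midpoint between two horizontal neighbours of values 2 and 4
  xm <- matrix(c(2, 4), 1, 2)
  expect_identical(bilinear_sample(xm, c(0, 0.5)), 3)
  # far outside the support
  expect_identical(bilinear_sample(x, c(-5.7, -5.7)), 0)
  expect_error(bilinear_sample(x, c(NaN, 0)), class = "rds_numeric_error")
  # random fractional points against the scalar oracle
  set.seed(2)
  for (i in 1:20) {
    p <- runif(2, -1.5, 4.5)
    expect_equal(bilinear_sample(x, p), oracle_bilinear(x, p[1], p[2]), tolerance = 1e-12)
  }
})

test_that("deformable convolution degenerates, shifts, and matches brute force", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)

  # zero offsets: exact reduction to the standard convolution
  off0 <- array(0, c(6, 6, 18))
  expect_identical(deformable_conv(x, w, off0, b), standard_conv_ref(x, w, b))

  # uniform (0, +1) offset on every tap == convolution of the column-shifted
  # input, away from the first column (the shifted copy has lost the original
  # leftmost column that the deformable taps can still reach)
  off1 <- array(0, c(6, 6, 18))
  off1[, , seq(2, 18, by = 2)] <- 1 # all delta_x = +1
  shifted <- array(0, dim(x))
  shifted[, 1:5, ] <- x[, 2:6, ] # content moved one column left, zero-padded
  dshift <- deformable_conv(x, w, off1, b) - standard_conv_ref(shifted, w, b)
  expect_lt(max(abs(dshift[, 2:6, ])), 1e-5)

  # random fractional offsets against the triple-loop oracle
  off <- array(rnorm(6 * 6 * 18, sd = 0.8), c(6, 6, 18))
  expect_lt(max(abs(deformable_conv(x, w, off, b) - oracle_deform(x, w, off, b))), 1e-5)

  # linearity in the input at fixed weights/offsets
  x2 <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  lhs <- deformable_conv(2 * x + 3 * x2, w, off)
  rhs <- 2 * deformable_conv(x, w, off) + 3 * deformable_conv(x2, w, off)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # wrong offset channel count is a shape error
  expect_error(deformable_conv(x, w, array(0, c(6, 6, 10))), class = "rds_shape_error")
})

test_that("offset branch starts at the standard-convolution fixed point", {
  set.seed(4)
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  bw <- offset_branch_init(3)
  off <- offset_branch(x, bw)
  expect_identical(dim(off), c(5L, 5L, 18L)) # 2N with N = 9
  expect_true(all(off == 0))

  # offsets are learnable: loss gradient w.r.t. branch weights is nonzero.
  # The finite-difference comparison is made at a point with fractional
  # offsets: at exactly integer sampling positions bilinear interpolation
  # has a kink, where central differences straddle the subgradient.
  wmain <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  bw$w[] <- rnorm(length(bw$w), sd = 0.03)
  f <- function(wb) {
    o <- offset_branch(x, list(w = wb, b = bw$b))
    sum(deformable_conv(x, wmain, o)^2)
  }
  # analytic gradient through the tape
  xn <- rdsunet:::ag_node(array(x, c(5, 5, 3, 1)))
  wbn <- rdsunet:::ag_param(bw$w)
  offn <- rdsunet:::ag_conv2d(xn, wbn, rdsunet:::ag_node(bw$b), 1L, 1L)
  yn <- rdsunet:::ag_deform_conv(xn, rdsunet:::ag_node(wmain), NULL, offn)
  loss <- rdsunet:::ag_node(sum(yn$value^2), list(yn), function(g) list(g * 2 * yn$value))
  rdsunet:::ag_backward(loss)
  expect_gt(max(abs(wbn$grad)), 0)
  # spot-check against finite differences on a few weight entries
  set.seed(5)
  pick <- sample(length(bw$w), 4)
  for (i in pick) {
    h <- 1e-5
    wp <- bw$w; wp[i] <- wp[i] + h
    wm <- bw$w; wm[i] <- wm[i] - h
    fd <- (f(wp) - f(wm)) / (2 * h)
    expect_equal(wbn$grad[i], fd, tolerance = 1e-3 * max(1, abs(fd)))
  }
})

test_that("deformable gradients agree with finite differences", {
  set.seed(6)
  x <- array(rnorm(4 * 4 * 2 * 1), c(4, 4, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  off <- array(rnorm(4 * 4 * 18, sd = 0.4), c(4, 4, 18, 1))
  dy <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  bwd <- rdsunet:::cpp_deform_bw(x, w, off, dy, FALSE)
  rel_ok <- function(a, b) max(abs(a - b)) / max(1, max(abs(b))) < 1e-3
  expect_true(rel_ok(bwd$dx, fd_grad(function(z) sum(rdsunet:::cpp_deform_fw(z, w, numeric(0), off) * dy), x)))
  expect_true(rel_ok(bwd$dw, fd_grad(function(z) sum(rdsunet:::cpp_deform_fw(x, z, numeric(0), off) * dy), w)))
  expect_true(rel_ok(bwd$doff, fd_grad(function(z) sum(rdsunet:::cpp_deform_fw(x, w, numeric(0), z) * dy), off)))
})
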