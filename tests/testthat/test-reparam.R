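# Structural re-parameterization: conv/BN fusion and rep-block collapse.

test_that("fuse_conv_bn: identity normalization leaves the conv unchanged", {
  set.seed(1)
  w <- glyolite:::he_init(3, 3, 4, 6)
  bn <- glyolite:::new_bn(6)
  bn$eps <- 0
  f <- fuse_conv_bn(w, bn, bias = rep(0.5, 6))
  expect_equal(f$w, w)
  expect_equal(f$bias, rep(0.5, 6))
})

test_that("fuse_conv_bn reproduces conv->BN on random inputs", {
  set.seed(2)
  w <- glyolite:::he_init(3, 3, 5, 7)
  bn <- randomize_bn(glyolite:::new_bn(7), seed = 2)
  x <- rand_fm(10, 10, 5, seed = 3)
  y0 <- glyolite:::bn_apply(glyolite:::conv2d(x, w), bn)
  f <- fuse_conv_bn(w, bn)
  y1 <- glyolite:::conv2d(x, f$w, f$bias)
  expect_lt(max(abs(y0 - y1)), 1e-5)
})

test_that("fuse_conv_bn: zero conv weights give the closed-form bias", {
  bn <- randomize_bn(glyolite:::new_bn(4), seed = 5)
  w <- array(0, c(3, 3, 2, 4))
  f <- fuse_conv_bn(w, bn)
  expect_equal(f$bias, bn$beta - bn$gamma * bn$mean / sqrt(bn$var + bn$eps))
  bn$var <- rep(-1, 4); bn$eps <- 0
  expect_error(fuse_conv_bn(w, bn), "variance")
})

test_that("identity-only collapse yields the centered unit kernel", {
  blk <- glyolite:::new_rep_block(4, 4, stride = 1)
  blk$w3[] <- 0; blk$w1[] <- 0
  blk$bn3$gamma[] <- 0; blk$bn1$gamma[] <- 0  # silence conv branches
  blk$bn3$beta[] <- 0; blk$bn1$beta[] <- 0
  blk$bnid$eps <- 0                           # identity BN
  fused <- collapse_rep_block(blk)
  expect_equal(fused$w, glyolite:::identity_kernel_3x3(4))
  x <- rand_fm(5, 5, 4, seed = 7)
  expect_equal(glyolite:::forward_rep(fused, x, pre_activation = TRUE), x,
               tolerance = 1e-12)
})

test_that("random three-branch rep block collapses within 1e-5", {
  for (seed in 1:3) {
    set.seed(seed)
    blk <- glyolite:::new_rep_block(8, 8, stride = 1)
    blk$bn3 <- randomize_bn(blk$bn3, seed)
    blk$bn1 <- randomize_bn(blk$bn1, seed + 10)
    blk$bnid <- randomize_bn(blk$bnid, seed + 20)
    x <- rand_fm(16, 16, 8, seed + 30)
    y0 <- glyolite:::forward_rep(blk, x, pre_activation = TRUE)
    y1 <- glyolite:::forward_rep(collapse_rep_block(blk), x, pre_activation = TRUE)
    expect_lt(max(abs(y0 - y1)), 1e-5)
    # post-activation outputs agree too (same monotone activation)
    expect_lt(max(abs(glyolite:::forward_rep(blk, x) -
                      glyolite:::forward_rep(collapse_rep_block(blk), x))), 1e-5)
  }
})

test_that("stride-2 rep blocks collapse without an identity branch", {
  set.seed(4)
  blk <- glyolite:::new_rep_block(4, 8, stride = 2)
  expect_null(blk$bnid)
  blk$bn3 <- randomize_bn(blk$bn3, 1); blk$bn1 <- randomize_bn(blk$bn1, 2)
  x <- rand_fm(12, 12, 4, seed = 8)
  y0 <- glyolite:::forward_rep(blk, x, pre_activation = TRUE)
  fused <- collapse_rep_block(blk)
  expect_lt(max(abs(y0 - glyolite:::forward_rep(fused, x, pre_activation = TRUE))), 1e-5)
  # shape-incompatible identity branch is rejected
  blk$bnid <- glyolite:::new_bn(8)
  expect_error(collapse_rep_block(blk), "identity branch")
})

test_that("fused parameter count follows the analytic conv calculus", {
  # c = 64, n = 128: 128 * (3*3*64 + 1) = 73,856
  set.seed(9)
  blk <- glyolite:::new_rep_block(64, 128, stride = 2)
  fused <- collapse_rep_block(blk)
  expect_equal(glyolite:::block_params(fused), 73856)
  expect_equal(count_parameters(conv_unit_spec(3, 3, 64, 128)), 73856)
})

test_that("convert_model_to_deploy is idempotent and a no-op without reps", {
  m <- build_model("gl_yolo_lite_tiny", seed = 2)
  d1 <- convert_model_to_deploy(m)
  d2 <- convert_model_to_deploy(d1)
  expect_identical(d1$layers, d2$layers)
  expect_lt(count_parameters(d1), count_parameters(m))  # strictly fewer params
  m2 <- build_model("yolov5s", nc = 20)
  d3 <- convert_model_to_deploy(m2)
  expect_identical(m2$layers, d3$layers)
  expect_equal(count_parameters(m2), count_parameters(d3))
})

test_that("whole tiny model agrees between training and deploy modes", {
  m <- build_model("gl_yolo_lite_tiny", seed = 5)
  x <- rand_fm(96, 96, 3, seed = 11)
  y0 <- model_forward(m, x)
  y1 <- model_forward(convert_model_to_deploy(m), x)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)), y0, y1)), 1e-4)
  # detection output shapes, strides and anchors unchanged
  expect_identical(lapply(y0, dim), lapply(y1, dim))
  expect_identical(m$detect$anchors, convert_model_to_deploy(m)$detect$anchors)
})
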