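# The bespoke building blocks: focus slicing, stem, CoT attention, SimAM,
# SPP, and their shape/parameter contracts.

test_that("focus_slice is a bijection with the documented lattice order", {
  # 2x2x1 grid [[a, b], [c, d]] (a = [0,0], b = [0,1], c = [1,0], d = [1,1])
  x <- feature_map(c(1, 3, 2, 4), 2, 2, 1)  # column-major: x[1,1]=1 x[2,1]=3 x[1,2]=2 x[2,2]=4
  s <- focus_slice(x)
  expect_equal(dim(s), c(1L, 1L, 4L))
  # even/even, odd/even, even/odd, odd/odd (0-based row/col parity)
  expect_equal(as.numeric(s[1, 1, ]), c(1, 3, 2, 4))
  # arbitrary input round-trips exactly
  for (seed in 1:3) {
    y <- rand_fm(8, 8, 3, seed)
    expect_identical(focus_inverse(focus_slice(y)), y)
  }
  expect_error(focus_slice(rand_fm(7, 8, 3)), "even")
})

test_that("focus shape contract: 640x640x3 -> 320x320x12 -> 320x320x32", {
  # asserted on the shape ledger (block_shape), not a full 640 forward
  set.seed(0)
  blk <- new_focus(3L, 32L, 3L)
  sh <- glyolite:::block_shape(blk, 640L, 640L, 3L)
  expect_equal(unlist(sh), c(h = 320, w = 320, c = 32))
  # slice alone: 4x channels at half resolution
  x <- rand_fm(16, 16, 3)
  expect_equal(dim(focus_slice(x)), c(8L, 8L, 12L))
  # small-scale forward through the conv
  y <- focus_forward(x, blk$conv)
  expect_equal(dim(y), c(8L, 8L, 32L))
  # channel mismatch is a shape error
  expect_error(focus_forward(x, new_conv_unit(8L, 16L, 3L)), "channels")
})

test_that("identity-like 1x1 focus conv reproduces the sliced input", {
  x <- rand_fm(6, 6, 2)
  conv <- new_conv_unit(8L, 8L, 1L, bn = FALSE, act = "none")
  conv$w[] <- 0
  for (i in 1:8) conv$w[1, 1, i, i] <- 1
  expect_equal(focus_forward(x, conv), focus_slice(x), tolerance = 1e-12)
})

test_that("stem has overall stride 4 and validates input dims", {
  set.seed(1)
  x <- rand_fm(16, 16, 3)
  y <- stem_forward(x, 8L)
  expect_equal(dim(y), c(4L, 4L, 8L))
  expect_error(stem_forward(rand_fm(10, 10, 3), 8L), "divisible by 4")
  # branch concat width = conv branch + pool branch channels
  st <- new_stem(3L, 8L)
  expect_equal(st$proj$c1, 16L)
})

test_that("CoT preserves shape, doubles channels at the concat, and matches
           the naive per-position aggregation oracle", {
  set.seed(5)
  ct <- new_cot(8L)
  x <- rand_fm(4, 4, 8, seed = 5)
  y <- cot_forward(x, ct)
  expect_equal(dim(y), dim(x))
  expect_equal(ct$att1$c1, 16L)   # concat carries 2C channels
  # brute-force positional oracle for the local matrix multiplication
  ks <- glyolite:::forward_conv_unit(ct$key, x)
  v <- glyolite:::forward_conv_unit(ct$value, x)
  a <- glyolite:::forward_conv_unit(ct$att2,
        glyolite:::forward_conv_unit(ct$att1, glyolite:::channel_concat(list(ks, x))))
  C <- 8L
  naive <- array(0, dim(v))
  for (i in 1:4) for (j in 1:4) for (ch in 1:C) {
    logits <- vapply(1:9, function(q) a[i, j, (q - 1L) * C + ch], 0)
    w <- exp(logits - max(logits)); w <- w / sum(w)
    acc <- 0; q <- 0L
    for (dj in 0:2) for (di in 0:2) {
      q <- q + 1L
      ii <- i + di - 1L; jj <- j + dj - 1L
      acc <- acc + w[q] * (if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 4) v[ii, jj, ch] else 0)
    }
    naive[i, j, ch] <- acc
  }
  expect_lt(max(abs(glyolite:::cot_aggregate(v, a, 3L) - naive)), 1e-5)
  expect_equal(y, ks + naive, tolerance = 1e-10)  # fusion is addition
  expect_error(new_cot(8L, k = 4L), "odd")
  expect_error(new_cot(6L, groups = 4L), "group")
})

test_that("cot3 keeps the C3 shape contract", {
  set.seed(2)
  x <- rand_fm(4, 4, 8)
  y1 <- cot3_forward(x, n_repeats = 1L)
  expect_equal(dim(y1), dim(x))
  set.seed(2)
  blk <- glyolite:::new_c3(8L, 8L, n = 2L, cot = TRUE)
  expect_equal(dim(cot3_forward(x, blk)), dim(x))
  expect_error(cot3_forward(x, n_repeats = 0L), "n_repeats")
})

test_that("SimAM gates match numerical minimization of the energy", {
  lam <- 1e-4
  x <- array(c(1, 3, 2, 4), c(2, 2, 1))   # channel values 1, 2, 3, 4
  gates <- simam_forward(x, lam) / x
  vals <- as.numeric(x)
  for (t in seq_along(vals)) {
    others <- vals[-t]
    energy <- function(p)
      (1 - (p[1] * vals[t] + p[2]))^2 +
      mean((-1 - (p[1] * others + p[2]))^2) + lam * p[1]^2
    opt <- stats::optim(c(0, 0), energy, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 1000))
    expect_equal(as.numeric(gates)[t], glyolite:::sigmoid(1 / opt$value),
                 tolerance = 1e-6)
  }
})

test_that("SimAM symmetry, range and error cases", {
  # constant channel: all energies equal -> uniform scaling
  xc <- array(2.5, c(3, 3, 1))
  g <- simam_forward(xc) / xc
  expect_equal(max(g) - min(g), 0)
  # gates strictly inside (0, 1)
  x <- rand_fm(5, 5, 4, seed = 9)
  g2 <- simam_forward(x) / x
  expect_true(all(g2 > 0 & g2 < 1))
  expect_equal(dim(simam_forward(x)), dim(x))
  expect_error(simam_forward(x, lambda = 0), "lambda")
  expect_error(simam_forward(array(1, c(1, 1, 2))), "neurons")
})

test_that("SPP preserves spatial dims and concatenates correctly", {
  set.seed(3)
  x <- rand_fm(6, 6, 8)
  y <- spp_forward(x)
  expect_equal(dim(y), c(6L, 6L, 16L))
  # all-equal input: pooled branches equal the projected input path
  xe <- array(1, c(4, 4, 4))
  set.seed(4)
  blk <- glyolite:::new_spp(4L, 8L, c(5L, 9L, 13L))
  y1 <- glyolite:::forward_conv_unit(blk$cv1, xe)
  for (k in blk$kernels)
    expect_equal(glyolite:::maxpool2d(y1, k), y1, tolerance = 1e-12)
  # degenerate single-kernel config: concat is 2x the branch width
  blk2 <- glyolite:::new_spp(4L, 8L, 5L)
  expect_equal(blk2$cv2$c1, 4L)
  expect_error(glyolite:::new_spp(4L, 8L, c(4L)), "odd")
})

test_that("table-driven layer shapes: CoT3 layer keeps its table channels", {
  m <- build_model("gl_yolo", nc = 20)
  # Layer 2 of the backbone table: CoT3, nominal 128 channels (width 0.5)
  expect_equal(m$layers[[3]]$name, "cot3")
  expect_equal(m$channels[3], 64L)
})
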