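# The composed detection loss.

tiny_two_cell_model <- function(nc = 1L) {
  # one detect scale would be enough conceptually, but the head always reads
  # three; use a 3-conv toy graph with strides 16/32/64 on a 32 px input so
  # the first scale is a 2x2 grid.
  cfg <- list(nc = nc, img_size = 32,
              anchors = list(c(8, 8, 12, 10, 10, 14),
                             c(16, 16, 20, 18, 18, 24),
                             c(26, 26, 30, 28, 28, 31)),
              layers = list(list(-1, 1, "Conv", c(8, 3, 16)),
                            list(-1, 1, "Conv", c(8, 3, 2)),
                            list(-1, 1, "Conv", c(8, 3, 2))),
              detect = c(0, 1, 2))
  build_model(cfg, seed = 0)
}

test_that("a 2x2-grid objectness term equals the hand-summed BCE over 12 anchor-cells", {
  m <- tiny_two_cell_model()
  no <- 5L + m$detect$nc
  preds <- list(array(0, c(2, 2, 3 * no)), array(0, c(1, 1, 3 * no)),
                array(0, c(1, 1, 3 * no)))
  set.seed(8)
  preds[[1]][, , (0:2) * no + 5L] <- rnorm(12)   # objectness logits only
  # one target in the cell (0, 0) of the first scale, matched to anchors by ratio
  tg <- data.frame(class = 0L, cx = 7, cy = 6, w = 10, h = 11)
  L <- detection_loss(preds, tg, m)
  # hand enumeration: Eq-style BCE at every anchor-cell of scale 1, target 1
  # where the ratio rule places the box, 0 elsewhere; balance weight 4.0
  anchors <- m$detect$anchors[[1]]
  ratio <- pmax(pmax(10 / anchors[, 1], anchors[, 1] / 10),
                pmax(11 / anchors[, 2], anchors[, 2] / 11))
  pos_anchors <- which(ratio < 4)
  # positive targets are the IoU of the zero-logit (prior) box with the
  # ground truth, floored at 0.05; negatives are 0
  iou_hand <- function(acx, acy, aw, ah, bcx, bcy, bw, bh) {
    iw <- max(0, min(acx + aw / 2, bcx + bw / 2) - max(acx - aw / 2, bcx - bw / 2))
    ih <- max(0, min(acy + ah / 2, bcy + bh / 2) - max(acy - ah / 2, bcy - bh / 2))
    iw * ih / (aw * ah + bw * bh - iw * ih)
  }
  hand <- 0
  for (a in 1:3) for (gj in 0:1) for (gi in 0:1) {
    y <- 0
    if (a %in% pos_anchors && gi == 0 && gj == 0)
      y <- max(0.05, iou_hand((0.5 + gi) * 16, (0.5 + gj) * 16,
                              anchors[a, 1], anchors[a, 2], 7, 6, 10, 11))
    p <- glyolite:::sigmoid(preds[[1]][gj + 1, gi + 1, (a - 1) * no + 5])
    hand <- hand + (-y * log(p) - (1 - y) * log(1 - p))
  }
  hand <- 4.0 * hand / 12
  # other scales hold all-zero logits and no positives (ratio rule excludes
  # them for this box): bce(0, sigmoid(0)) = log 2 each, balance 1.0 and 0.4
  expected_obj <- hand + 1.0 * log(2) + 0.4 * log(2)
  expect_equal(L$obj, expected_obj, tolerance = 1e-10)
})

test_that("predictions that encode the targets drive the loss to zero in the limit", {
  m <- tiny_two_cell_model()
  no <- 5L + m$detect$nc
  tg <- data.frame(class = 0L, cx = 8, cy = 8, w = 12, h = 10)
  grid_hw <- list(c(2L, 2L), c(1L, 1L), c(1L, 1L))
  asg <- glyolite:::build_targets(tg, m$detect$anchors, m$detect$strides, grid_hw)
  big <- 12
  preds <- list(array(-big, c(2, 2, 3 * no)), array(-big, c(1, 1, 3 * no)),
                array(-big, c(1, 1, 3 * no)))
  inv_sig <- function(p) log(p / (1 - p))
  for (r in seq_len(nrow(asg))) {
    s <- asg$scale[r]; a <- asg$anchor[r]; base <- (a - 1) * no
    anc <- m$detect$anchors[[s]][a, ]; st <- m$detect$strides[s]
    tx <- inv_sig(((tg$cx / st - asg$gi[r]) + 0.5) / 2)
    ty <- inv_sig(((tg$cy / st - asg$gj[r]) + 0.5) / 2)
    tw <- inv_sig(sqrt(tg$w / anc[1]) / 2)
    th <- inv_sig(sqrt(tg$h / anc[2]) / 2)
    preds[[s]][asg$gj[r] + 1, asg$gi[r] + 1, base + 1:5] <- c(tx, ty, tw, th, big)
  }
  L <- detection_loss(preds, tg, m)
  expect_lt(L$box, 1e-6)
  expect_lt(L$obj, 0.01)
  expect_equal(L$cls, 0)       # single class: classification term vanishes
  expect_lt(L$total, 0.02)
})

test_that("empty target set: classification and box terms are zero, objectness defined", {
  m <- tiny_two_cell_model(nc = 3L)
  no <- 5L + 3L
  preds <- list(array(-9, c(2, 2, 3 * no)), array(-9, c(1, 1, 3 * no)),
                array(-9, c(1, 1, 3 * no)))
  empty <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  L <- detection_loss(preds, empty, m)
  expect_equal(L$cls, 0)
  expect_equal(L$box, 0)
  expect_gt(L$obj, 0)
  expect_equal(L$n_positive, 0)
})

test_that("every target yields at least one positive assignment", {
  m <- tiny_two_cell_model()
  grid_hw <- list(c(2L, 2L), c(1L, 1L), c(1L, 1L))
  # extreme aspect ratio box fails the ratio rule everywhere
  tg <- data.frame(class = 0L, cx = 16, cy = 16, w = 31, h = 2)
  asg <- glyolite:::build_targets(tg, m$detect$anchors, m$detect$strides, grid_hw)
  expect_gte(nrow(asg), 1)
})
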