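# BCE, precision/recall/F1, mAP@0.5 and TOPSIS.

test_that("bce analytic points and convexity/monotonicity", {
  expect_equal(bce(1, 1), 0, tolerance = 1e-6)
  expect_equal(bce(0, 0), 0, tolerance = 1e-6)
  expect_equal(bce(1, exp(-1)), 1)
  # convex in p; decreasing for g = 1, increasing for g = 0
  p <- seq(0.05, 0.95, by = 0.05)
  l1 <- vapply(p, function(q) bce(1, q), 0)
  l0 <- vapply(p, function(q) bce(0, q), 0)
  expect_true(all(diff(l1) < 0))
  expect_true(all(diff(l0) > 0))
  expect_true(all(diff(diff(l1)) > 0))   # second difference positive
  expect_true(all(diff(diff(l0)) > 0))
  # mean reduction over a batch
  expect_equal(bce(c(1, 0), c(exp(-1), 1 - exp(-1))), 1)
})

test_that("F1 reproduces the published precision/recall worked examples", {
  expect_equal(round(f1_score(0.843, 0.859), 3), 0.851)
  expect_equal(round(f1_score(0.812, 0.838), 3), 0.825)
  # harmonic mean of equals is the value itself
  for (x in c(0.1, 0.5, 0.9, 1)) expect_equal(f1_score(x, x), x)
})

test_that("precision/recall/F1 guards and harmonic bound", {
  r <- precision_recall_f1(8, 2, 4)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
  z <- precision_recall_f1(0, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_true(z$degenerate)
  # F1 never exceeds the arithmetic mean; F1 = 0 iff P * R = 0
  set.seed(1)
  for (i in 1:50) {
    p <- runif(1); q <- runif(1)
    expect_lte(f1_score(p, q), (p + q) / 2 + 1e-12)
  }
  expect_equal(f1_score(0, 0.7), 0)
})

make_dets <- function(img, score, box) {
  data.frame(image = img, class = 0L, score = score,
             x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4])
}

test_that("mAP endpoints: perfect detections give 1, none give 0", {
  gt <- data.frame(image = c("a", "a", "b"), class = 0L,
                   x1 = c(0, 50, 10), y1 = c(0, 50, 10),
                   x2 = c(20, 80, 40), y2 = c(20, 80, 40))
  perfect <- cbind(gt[, c("image", "class")], score = 1,
                   gt[, c("x1", "y1", "x2", "y2")])
  expect_equal(map50(perfect, gt), 1)
  none <- perfect[0, ]
  expect_equal(map50(none, gt), 0)
})

test_that("mAP on a 3-image toy set matches the hand-integrated staircase", {
  gt <- data.frame(image = c("a", "b", "c"), class = 0L,
                   x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  dets <- rbind(
    make_dets("a", 0.9, c(0, 0, 10, 10)),    # TP
    make_dets("b", 0.8, c(50, 50, 60, 60)),  # FP (no overlap)
    make_dets("c", 0.7, c(0, 0, 10, 10)))    # TP
  # ranked: TP, FP, TP -> precision 1, 1/2, 2/3 at recall 1/3, 1/3, 2/3.
  # envelope: 1 for r <= 1/3, 2/3 for 1/3 < r <= 2/3, 0 beyond.
  # 101-point mean: (34 * 1 + 33 * 2/3 + 34 * 0) / 101
  expect_equal(map50(dets, gt), (34 + 33 * 2 / 3) / 101)
})

test_that("mAP is invariant to image permutation and harmless duplicates", {
  set.seed(4)
  gt <- data.frame(image = rep(c("a", "b"), each = 2), class = 0L,
                   x1 = runif(4, 0, 50), y1 = runif(4, 0, 50))
  gt$x2 <- gt$x1 + 30; gt$y2 <- gt$y1 + 30
  dets <- cbind(gt[, c("image", "class")], score = runif(4, 0.5, 1),
                gt[, c("x1", "y1", "x2", "y2")])
  base <- map50(dets, gt)
  perm <- map50(dets[sample(nrow(dets)), ], gt[sample(nrow(gt)), ])
  expect_equal(perm, base)
  # a duplicate detection below every ground truth's IoU threshold
  dup <- rbind(dets, make_dets("a", 0.01, c(900, 900, 910, 910)))
  expect_equal(map50(dup, gt), base)
})

test_that("topsis endpoints, hand oracle and scale invariance", {
  # two alternatives, one benefit criterion: closeness 0 and 1
  one <- topsis(matrix(c(3, 4), ncol = 1), weights = 1, benefit = TRUE)
  expect_equal(as.numeric(one$scores), c(0, 1))
  # 3x2 hand-computed oracle (vector norm, native cost orientation)
  M <- matrix(c(4, 3, 5,
                2, 6, 4), ncol = 2)
  w <- c(0.6, 0.4); ben <- c(TRUE, FALSE)
  N <- sweep(M, 2, sqrt(colSums(M^2)), `/`)
  V <- sweep(N, 2, w, `*`)
  ideal <- c(max(V[, 1]), min(V[, 2])); anti <- c(min(V[, 1]), max(V[, 2]))
  dp <- sqrt(rowSums(sweep(V, 2, ideal)^2)); dn <- sqrt(rowSums(sweep(V, 2, anti)^2))
  hand <- dn / (dp + dn)
  got <- topsis(M, weights = w, benefit = ben)
  expect_equal(as.numeric(got$scores), hand, tolerance = 1e-9)
  expect_true(all(got$scores >= 0 & got$scores <= 1))
  # multiplying one criterion by a positive constant changes nothing
  M2 <- M; M2[, 2] <- M2[, 2] * 37
  expect_equal(topsis(M2, weights = w, benefit = ben)$scores, got$scores)
  expect_error(topsis(matrix(c(1, -1, 2, 2), 2), weights = c(.5, .5),
                      benefit = c(TRUE, TRUE)), "positive")
})

test_that("ties in the ranking break by input order", {
  M <- matrix(c(2, 2, 1, 1), ncol = 2)
  r <- topsis(M, weights = c(.5, .5), benefit = c(TRUE, TRUE))
  expect_equal(as.integer(r$ranking), c(1L, 2L))
})

test_that("the shipped comparison tables rank the lite model first", {
  for (f in c("results_fpdd.csv", "results_voc.csv")) {
    path <- system.file("extdata", f, package = "glyolite")
    res <- rank_methods(path, fps_column = "gpu",
                        norm = "minmax", cost_transform = "reciprocal")
    expect_equal(res$method[res$ranking == 1], "GL-YOLO-Lite")
  }
})
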