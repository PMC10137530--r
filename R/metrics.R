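# Losses and evaluation metrics: binary cross-entropy, the confusion-count
# metrics (precision / recall / F1), mAP@0.5, and TOPSIS composite ranking.

#' Binary cross-entropy (natural log)
#'
#' `Loss(g, p) = -g log p - (1 - g) log(1 - p)`, reduced by the mean over
#' the inputs. Probabilities are clamped to `[eps, 1 - eps]` before the
#' logs, so `bce(1, 1) == 0` and `bce(0, 0) == 0` hold exactly up to the
#' clamp; `bce(1, exp(-1))` is exactly 1 nat.
#'
#' @param g true labels in `{0, 1}`.
#' @param p predicted probabilities.
#' @param eps probability clamp (default `1e-7`).
#' @export
bce <- function(g, p, eps = 1e-7) {
  stopifnot(length(g) == length(p), all(g %in% c(0, 1)))
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-g * log(p) - (1 - g) * log(1 - p))
}

# BCE on logits (numerically stable), mean reduction; used by the loss.
bce_logits <- function(target, logit) {
  mean(pmax(logit, 0) - logit * target + log1p(exp(-abs(logit))))
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, and the harmonic
#' F1 `2 P R / (P + R)`; all guarded to report 0 (with a flag) on empty
#' denominators.
#'
#' @param tp,fp,fn non-negative confusion counts at a fixed IoU-0.5 matching.
#' @return a `metrics_report` list with `precision`, `recall`, `f1` and a
#'   `degenerate` flag set when every count-derived term was 0/0.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall    <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 degenerate = (tp + fp + fn) == 0),
            class = "metrics_report")
}

#' F1 from a precision/recall pair
#' @param precision,recall values in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f%s\n",
              round(x$precision, 3), round(x$recall, 3), round(x$f1, 3),
              if (isTRUE(x$degenerate)) "  [degenerate: all counts zero]" else ""))
  invisible(x)
}

box_iou_xyxy <- function(a, b) {
  # a: n x 4, b: m x 4 (x1, y1, x2, y2 half-open); returns n x m IoU matrix
  a <- matrix(a, ncol = 4L); b <- matrix(b, ncol = 4L)
  n <- nrow(a); m <- nrow(b)
  iw <- pmax(0, pmin(outer(a[, 3], rep(1, m)), outer(rep(1, n), b[, 3])) -
                pmax(outer(a[, 1], rep(1, m)), outer(rep(1, n), b[, 1])))
  ih <- pmax(0, pmin(outer(a[, 4], rep(1, m)), outer(rep(1, n), b[, 4])) -
                pmax(outer(a[, 2], rep(1, m)), outer(rep(1, n), b[, 2])))
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(area_a, rep(1, m)) + outer(rep(1, n), area_b) - inter + 1e-12)
}

#' Mean average precision at IoU 0.5
#'
#' Detections are matched to ground truth greedily in order of descending
#' confidence, one match per ground-truth box, at IoU >= 0.5. AP per class
#' uses 101-point interpolation of the precision envelope; mAP is the mean
#' over classes present in the ground truth (a class with detections but no
#' ground truth contributes AP 0).
#'
#' @param detections data.frame with columns `image`, `class`, `score`,
#'   `x1`, `y1`, `x2`, `y2`.
#' @param ground_truth data.frame with columns `image`, `class`, `x1`,
#'   `y1`, `x2`, `y2`.
#' @param iou_threshold matching threshold (default 0.5).
#' @return scalar mAP in `[0, 1]`.
#' @export
map50 <- function(detections, ground_truth, iou_threshold = 0.5) {
  classes <- sort(unique(c(ground_truth$class, detections$class)))
  if (nrow(ground_truth) == 0L) return(0)
  aps <- vapply(classes, function(cl) {
    gt <- ground_truth[ground_truth$class == cl, , drop = FALSE]
    dt <- detections[detections$class == cl, , drop = FALSE]
    if (nrow(gt) == 0L) return(0)       # detections without any ground truth
    if (nrow(dt) == 0L) return(0)
    dt <- dt[order(-dt$score), , drop = FALSE]
    matched <- logical(nrow(gt))
    tp <- numeric(nrow(dt))
    for (i in seq_len(nrow(dt))) {
      cand <- which(gt$image == dt$image[i] & !matched)
      if (length(cand) == 0L) next
      ious <- box_iou_xyxy(as.numeric(dt[i, c("x1", "y1", "x2", "y2")]),
                           as.matrix(gt[cand, c("x1", "y1", "x2", "y2")]))
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) { tp[i] <- 1; matched[cand[j]] <- TRUE }
    }
    cum_tp <- cumsum(tp); cum_fp <- cumsum(1 - tp)
    recall <- cum_tp / nrow(gt)
    precision <- cum_tp / (cum_tp + cum_fp)
    ap101(recall, precision)
  }, 0)
  mean(aps)
}

ap101 <- function(recall, precision) {
  # precision envelope, integrated at 101 evenly spaced recall points
  grid <- seq(0, 1, by = 0.01)
  env <- vapply(grid, function(r) {
    ok <- recall >= r
    if (!any(ok)) 0 else max(precision[ok])
  }, 0)
  mean(env)
}

# ------------------------------------------------------------------------
# TOPSIS

#' TOPSIS composite ranking
#'
#' Ranks alternatives by relative closeness `d- / (d+ + d-)` to the weighted
#' ideal and anti-ideal points. Cost criteria can be handled natively
#' (ideal = column minimum) or first converted to benefit form by `1/x` or
#' `max - x`; normalization is vector (root-sum-square, the default) or
#' min-max. Ties in the ranking break by input order.
#'
#' @param matrix numeric matrix (alternatives x criteria), all entries
#'   positive; rownames name the alternatives.
#' @param weights criterion weights summing to 1
#'   (default `c(0.4, 0.2, 0.2, 0.2)`: mAP 40%, FPS 20%, parameters 20%,
#'   GFLOPs 20%).
#' @param benefit logical; `TRUE` for larger-is-better criteria
#'   (default `c(TRUE, TRUE, FALSE, FALSE)`).
#' @param norm `"vector"` or `"minmax"`.
#' @param cost_transform `"none"`, `"reciprocal"` or `"max-minus"`.
#' @return list with `scores` (closeness in `[0, 1]`), `ranking`
#'   (1 = best), and the `weighted` decision matrix.
#' @export
topsis <- function(matrix, weights = c(0.4, 0.2, 0.2, 0.2),
                   benefit = c(TRUE, TRUE, FALSE, FALSE),
                   norm = c("vector", "minmax"),
                   cost_transform = c("none", "reciprocal", "max-minus")) {
  norm <- match.arg(norm)
  cost_transform <- match.arg(cost_transform)
  X <- as.matrix(matrix)
  stopifnot(ncol(X) == length(weights), length(benefit) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) stop("topsis: weights must sum to 1", call. = FALSE)
  if (any(X <= 0)) stop("topsis: all criterion values must be positive", call. = FALSE)
  if (any(colSums(X^2) == 0)) stop("topsis: zero column cannot be normalized", call. = FALSE)
  b <- benefit
  if (cost_transform == "reciprocal") { for (j in which(!b)) X[, j] <- 1 / X[, j]; b[] <- TRUE }
  if (cost_transform == "max-minus")  { for (j in which(!b)) X[, j] <- max(X[, j]) - X[, j]; b[] <- TRUE }
  N <- switch(norm,
    vector = sweep(X, 2, sqrt(colSums(X^2)), `/`),
    minmax = vapply(seq_len(ncol(X)), function(j) {
      v <- X[, j]; rng <- max(v) - min(v)
      if (rng == 0) stop("topsis: constant column under min-max normalization", call. = FALSE)
      if (b[j]) (v - min(v)) / rng else (max(v) - v) / rng
    }, numeric(nrow(X))))
  if (norm == "minmax") b[] <- TRUE
  V <- sweep(N, 2, weights, `*`)
  ideal <- ifelse(b, apply(V, 2, max), apply(V, 2, min))
  anti  <- ifelse(b, apply(V, 2, min), apply(V, 2, max))
  dpos <- sqrt(rowSums(sweep(V, 2, ideal)^2))
  dneg <- sqrt(rowSums(sweep(V, 2, anti)^2))
  scores <- dneg / (dpos + dneg)
  names(scores) <- rownames(matrix)
  list(scores = scores,
       ranking = rank(-scores, ties.method = "first"),
       weighted = V)
}

#' TOPSIS over a results table read from CSV
#'
#' The CSV needs columns `method`, `map50`, `params`, `gflops` and an FPS
#' column (`fps`, or `fps_gpu` / `fps_cpu` selected by `fps_column`).
#'
#' @param path CSV file.
#' @param fps_column `"gpu"` or `"cpu"` when both are present.
#' @param ... passed to [topsis()].
#' @export
rank_methods <- function(path, fps_column = c("gpu", "cpu"), ...) {
  fps_column <- match.arg(fps_column)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fps <- if ("fps" %in% names(df)) df$fps else df[[paste0("fps_", fps_column)]]
  M <- cbind(map50 = df$map50, fps = fps, params = df$params, gflops = df$gflops)
  rownames(M) <- df$method
  res <- topsis(M, ...)
  data.frame(method = df$method, score = as.numeric(res$scores),
             ranking = as.integer(res$ranking))
}
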