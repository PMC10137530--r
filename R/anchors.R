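# K-means++ anchor generation from labeled box dimensions.
#
# Clustering runs in plain Euclidean (w, h) space at the network input
# scale: the method names K-means++ specifically, so the IoU-style distance
# some anchor tools use is deliberately not employed. Normalized YOLO-txt
# label dimensions are multiplied by the input size before clustering.

#' D-squared (K-means++) seeding
#'
#' The first center is drawn uniformly from the boxes; each subsequent
#' center is drawn with probability proportional to the squared Euclidean
#' distance to its nearest already-chosen center. Deterministic under a
#' fixed seed.
#'
#' @param boxes numeric matrix (n x 2) of box widths and heights (> 0).
#' @param k number of centers; must not exceed the number of distinct boxes.
#' @param seed RNG seed.
#' @return a k x 2 matrix of chosen centers.
#' @export
kmeanspp_seed <- function(boxes, k, seed = 0L) {
  boxes <- as.matrix(boxes)
  stopifnot(ncol(boxes) == 2L, all(boxes > 0))
  ndistinct <- nrow(unique(boxes))
  if (k > ndistinct)
    stop(sprintf("kmeanspp_seed: k = %d exceeds %d distinct boxes", k, ndistinct),
         call. = FALSE)
  set.seed(seed)
  n <- nrow(boxes)
  centers <- matrix(0, k, 2L)
  centers[1L, ] <- boxes[sample.int(n, 1L), ]
  d2 <- rowSums((boxes - matrix(centers[1L, ], n, 2L, byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) stop("kmeanspp_seed: degenerate boxes", call. = FALSE)
    pick <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- boxes[pick, ]
    d2 <- pmin(d2, rowSums((boxes - matrix(centers[j, ], n, 2L, byrow = TRUE))^2))
  }
  centers
}

cluster_inertia <- function(boxes, centers) {
  d2 <- outer(rowSums(boxes^2), rep(1, nrow(centers))) +
        outer(rep(1, nrow(boxes)), rowSums(centers^2)) -
        2 * boxes %*% t(centers)
  sum(apply(d2, 1L, min))
}

#' Cluster anchors with K-means++
#'
#' Lloyd iterations from the [kmeanspp_seed()] initialization until the
#' center shift drops below `tol` or `max_iter` is reached. The result is
#' sorted by ascending box area and grouped three per detection scale.
#'
#' @param boxes n x 2 matrix of (w, h) pairs at the network input scale.
#' @param k number of anchors (default 9).
#' @param seed RNG seed (default 0).
#' @param max_iter,tol Lloyd iteration controls.
#' @return an `anchor_set`: a k x 2 matrix sorted by area, with attributes
#'   `scales` (grouping index, 3 per scale), `inertia` and `seed`.
#' @export
cluster_anchors <- function(boxes, k = 9L, seed = 0L, max_iter = 300L, tol = 1e-6) {
  boxes <- as.matrix(boxes)
  stopifnot(ncol(boxes) == 2L)
  if (nrow(boxes) < k) stop("cluster_anchors: need at least k boxes", call. = FALSE)
  if (k > 1L && nrow(unique(boxes)) == 1L)
    stop("cluster_anchors: all boxes identical, cannot form k > 1 clusters", call. = FALSE)
  centers <- kmeanspp_seed(boxes, k, seed)
  inertia <- cluster_inertia(boxes, centers)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(boxes^2), rep(1, k)) + outer(rep(1, nrow(boxes)), rowSums(centers^2)) -
          2 * boxes %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    newc <- centers
    for (j in seq_len(k)) {
      idx <- assign == j
      if (any(idx)) newc[j, ] <- colMeans(boxes[idx, , drop = FALSE])
      else newc[j, ] <- boxes[which.max(apply(d2, 1L, min)), ]   # revive empty cluster
    }
    shift <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    new_inertia <- cluster_inertia(boxes, centers)
    stopifnot(new_inertia <= inertia + 1e-9)   # Lloyd is monotone
    inertia <- new_inertia
    if (shift < tol) break
  }
  ord <- order(centers[, 1] * centers[, 2])
  out <- centers[ord, , drop = FALSE]
  colnames(out) <- c("w", "h")
  structure(out, class = c("anchor_set", class(out)),
            scales = rep(seq_len(ceiling(k / 3)), each = 3L)[seq_len(k)],
            inertia = inertia, seed = seed)
}

#' Cluster anchors directly from a directory of YOLO-txt labels
#'
#' @param labels_dir directory of `.txt` label files (normalized YOLO format).
#' @param img_size network input size used to scale normalized dimensions.
#' @inheritParams cluster_anchors
#' @export
anchors_from_labels <- function(labels_dir, img_size = 640L, k = 9L, seed = 0L) {
  files <- list.files(labels_dir, pattern = "\\.txt$", full.names = TRUE)
  wh <- do.call(rbind, lapply(files, function(f) {
    b <- read_yolo_labels(f)
    if (nrow(b) == 0L) return(NULL)     # empty-label images are skipped
    cbind(b$w * img_size, b$h * img_size)
  }))
  if (is.null(wh)) stop("anchors_from_labels: no labeled boxes found", call. = FALSE)
  cluster_anchors(wh, k = k, seed = seed)
}
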