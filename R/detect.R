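# Inference: letterboxing, grid decode, confidence filtering and per-class
# non-maximum suppression. Pixel boxes are 0-based half-open (x1, y1, x2,
# y2) in the letterboxed frame, mapped back to the original frame on output.

#' Letterbox an image to a square network input
#'
#' Aspect-preserving nearest-neighbor resize with symmetric gray padding
#' (value 114/255, the baseline convention).
#'
#' @param img `(H, W, 3)` array with values in `[0, 1]`.
#' @param size target side length.
#' @return list with `img` (`size x size x 3`), `ratio`, and `pad = c(left,
#'   top)` used to map boxes back.
#' @export
letterbox <- function(img, size = 640L) {
  d <- dim(img)
  r <- min(size / d[1], size / d[2])
  nh <- max(1L, as.integer(round(d[1] * r))); nw <- max(1L, as.integer(round(d[2] * r)))
  ri <- pmin(d[1], pmax(1L, as.integer(ceiling(seq_len(nh) / r))))
  ci <- pmin(d[2], pmax(1L, as.integer(ceiling(seq_len(nw) / r))))
  resized <- img[ri, ci, , drop = FALSE]
  out <- array(114 / 255, c(size, size, d[3]))
  top <- (size - nh) %/% 2L; left <- (size - nw) %/% 2L
  out[top + seq_len(nh), left + seq_len(nw), ] <- resized
  list(img = out, ratio = r, pad = c(left = left, top = top))
}

# Decode one scale's raw output into candidate boxes (letterboxed pixels).
decode_scale <- function(p, anchors, stride, nc, conf_threshold) {
  d <- dim(p); no <- 5L + nc
  out <- vector("list", 3L)
  gx <- matrix(rep(0:(d[2] - 1L), each = d[1]), d[1], d[2])  # column index per cell
  gy <- matrix(rep(0:(d[1] - 1L), times = d[2]), d[1], d[2]) # row index per cell
  for (a in 1:3) {
    base <- (a - 1L) * no
    obj <- sigmoid(p[, , base + 5L])
    cls <- array(sigmoid(p[, , base + 5L + seq_len(nc)]), c(d[1], d[2], nc))
    if (nc == 1L) {
      best_cls <- matrix(1L, d[1], d[2])
      best_p <- cls[, , 1L]
    } else {
      best_cls <- apply(cls, c(1, 2), which.max)
      best_p <- apply(cls, c(1, 2), max)
    }
    conf <- obj * best_p
    keep <- which(conf > conf_threshold)
    if (length(keep) == 0L) next
    cx <- (2 * sigmoid(p[, , base + 1L]) - 0.5 + gx) * stride
    cy <- (2 * sigmoid(p[, , base + 2L]) - 0.5 + gy) * stride
    w <- (2 * sigmoid(p[, , base + 3L]))^2 * anchors[a, 1]
    h <- (2 * sigmoid(p[, , base + 4L]))^2 * anchors[a, 2]
    out[[a]] <- data.frame(
      class = best_cls[keep] - 1L, score = conf[keep],
      x1 = cx[keep] - w[keep] / 2, y1 = cy[keep] - h[keep] / 2,
      x2 = cx[keep] + w[keep] / 2, y2 = cy[keep] + h[keep] / 2)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Per-class non-maximum suppression
#'
#' @param boxes data.frame with `class`, `score`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_threshold suppression threshold (default 0.45).
#' @export
nms <- function(boxes, iou_threshold = 0.45) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(boxes)
  keep_rows <- list()
  for (cl in unique(boxes$class)) {
    b <- boxes[boxes$class == cl, , drop = FALSE]
    b <- b[order(-b$score), , drop = FALSE]
    taken <- logical(nrow(b))
    for (i in seq_len(nrow(b))) {
      if (taken[i]) next
      keep_rows[[length(keep_rows) + 1L]] <- b[i, , drop = FALSE]
      if (i < nrow(b)) {
        rest <- (i + 1L):nrow(b)
        ious <- box_iou_xyxy(as.numeric(b[i, c("x1", "y1", "x2", "y2")]),
                             as.matrix(b[rest, c("x1", "y1", "x2", "y2")]))
        taken[rest[ious >= iou_threshold]] <- TRUE
      }
    }
  }
  out <- do.call(rbind, keep_rows)
  out[order(-out$score), , drop = FALSE]
}

#' Run detection on an image
#'
#' Letterboxes the image to the model input size, runs the network, decodes
#' each scale's grid offsets and anchor-scaled sizes to pixel boxes, filters
#' by confidence and applies per-class NMS; boxes are mapped back to the
#' original image frame.
#'
#' @param model a `glyo_model`.
#' @param image `(H, W, 3)` array in `[0, 1]`, or a path to a PNG file.
#' @param conf_threshold confidence threshold (default 0.25).
#' @param iou_threshold NMS IoU threshold (default 0.45).
#' @return data.frame of detections: `class`, `score`, `x1`, `y1`, `x2`,
#'   `y2` (original-frame pixels, 0-based half-open).
#' @export
detect <- function(model, image, conf_threshold = 0.25, iou_threshold = 0.45) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 2L) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (dim(image)[3] > 3L) image <- image[, , 1:3, drop = FALSE]
  if (is.null(model$detect$anchors)) stop("detect: no anchors loaded", call. = FALSE)
  lb <- letterbox(image, model$img_size)
  preds <- model_forward(model, lb$img)
  dets <- decode_predictions(preds, model, conf_threshold, iou_threshold)
  if (nrow(dets) > 0L) {
    dets$x1 <- (dets$x1 - lb$pad["left"]) / lb$ratio
    dets$x2 <- (dets$x2 - lb$pad["left"]) / lb$ratio
    dets$y1 <- (dets$y1 - lb$pad["top"]) / lb$ratio
    dets$y2 <- (dets$y2 - lb$pad["top"]) / lb$ratio
  }
  rownames(dets) <- NULL
  dets
}

#' Decode raw head outputs into final detections (letterboxed frame)
#'
#' @param preds list of raw per-scale head outputs.
#' @param model the producing model.
#' @inheritParams detect
#' @export
decode_predictions <- function(preds, model, conf_threshold = 0.25, iou_threshold = 0.45) {
  nc <- model$detect$nc
  parts <- lapply(seq_along(preds), function(s)
    decode_scale(preds[[s]], model$detect$anchors[[s]], model$detect$strides[s],
                 nc, conf_threshold))
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0L)
    return(data.frame(class = integer(), score = numeric(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric()))
  nms(do.call(rbind, parts), iou_threshold)
}
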