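# Detection loss: BCE for objectness and classification, complete-IoU for
# the box term, composed with the baseline per-scale balance weights.
#
# Target assignment: each ground-truth box is assigned, on every scale, to
# the anchors passing the ratio test max(wh/anchor, anchor/wh) < 4 at the
# grid cell containing the box center; a box matching no anchor anywhere is
# assigned to its globally best-ratio anchor, so every target produces at
# least one positive. The objectness target is 1 at positives, 0 elsewhere.

# raw head output layout: (H, W, 3 * (5 + nc)); per anchor a the channel
# block a*(5+nc) + (tx, ty, tw, th, obj, cls...).

decode_box_at <- function(t, gi, gj, stride, anchor) {
  # t: 4 raw logits; (gi, gj) 0-based cell; returns (cx, cy, w, h) in pixels
  cx <- (2 * sigmoid(t[1]) - 0.5 + gi) * stride
  cy <- (2 * sigmoid(t[2]) - 0.5 + gj) * stride
  w <- (2 * sigmoid(t[3]))^2 * anchor[1]
  h <- (2 * sigmoid(t[4]))^2 * anchor[2]
  c(cx, cy, w, h)
}

iou_cxcywh <- function(p, g) {
  iw <- max(0, min(p[1] + p[3] / 2, g[1] + g[3] / 2) - max(p[1] - p[3] / 2, g[1] - g[3] / 2))
  ih <- max(0, min(p[2] + p[4] / 2, g[2] + g[4] / 2) - max(p[2] - p[4] / 2, g[2] - g[4] / 2))
  inter <- iw * ih
  inter / (p[3] * p[4] + g[3] * g[4] - inter + 1e-9)
}

ciou_cxcywh <- function(p, g) {
  # complete IoU between two (cx, cy, w, h) boxes
  pa <- c(p[1] - p[3] / 2, p[2] - p[4] / 2, p[1] + p[3] / 2, p[2] + p[4] / 2)
  ga <- c(g[1] - g[3] / 2, g[2] - g[4] / 2, g[1] + g[3] / 2, g[2] + g[4] / 2)
  iw <- max(0, min(pa[3], ga[3]) - max(pa[1], ga[1]))
  ih <- max(0, min(pa[4], ga[4]) - max(pa[2], ga[2]))
  inter <- iw * ih
  union <- p[3] * p[4] + g[3] * g[4] - inter + 1e-9
  iou <- inter / union
  cw <- max(pa[3], ga[3]) - min(pa[1], ga[1])
  chh <- max(pa[4], ga[4]) - min(pa[2], ga[2])
  c2 <- cw^2 + chh^2 + 1e-9
  rho2 <- (p[1] - g[1])^2 + (p[2] - g[2])^2
  v <- (4 / pi^2) * (atan(g[3] / (g[4] + 1e-9)) - atan(p[3] / (p[4] + 1e-9)))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - alpha * v
}

# Objectness ignore mask: anchor-cells whose cell center lies inside a
# ground-truth box but which are not positive assignments are excluded from
# the objectness loss (the classic ignore-region rule). Pushing them to
# zero would contradict the positives two cells away that share nearly the
# same receptive field.
objectness_ignore <- function(targets, stride, grid_hw) {
  ign <- matrix(FALSE, grid_hw[1], grid_hw[2])
  if (nrow(targets) == 0L) return(ign)
  cx <- (col(ign) - 0.5) * stride
  cy <- (row(ign) - 0.5) * stride
  for (r in seq_len(nrow(targets))) {
    tg <- targets[r, ]
    ign <- ign | (cx > tg$cx - tg$w / 2 & cx < tg$cx + tg$w / 2 &
                  cy > tg$cy - tg$h / 2 & cy < tg$cy + tg$h / 2)
  }
  ign
}

# Build the positive-assignment table for one image.
# targets: data.frame(class, cx, cy, w, h) in input pixels.
build_targets <- function(targets, anchors, strides, grid_hw, anchor_t = 4) {
  out <- list()
  if (nrow(targets) == 0L) return(out)
  anchor_flat <- do.call(rbind, anchors)
  for (ti in seq_len(nrow(targets))) {
    tg <- targets[ti, ]
    ratios <- pmax(pmax(tg$w / anchor_flat[, 1], anchor_flat[, 1] / tg$w),
                   pmax(tg$h / anchor_flat[, 2], anchor_flat[, 2] / tg$h))
    hit <- which(ratios < anchor_t)
    if (length(hit) == 0L) hit <- which.min(ratios)
    for (a in hit) {
      s <- (a - 1L) %/% 3L + 1L        # scale index
      ai <- (a - 1L) %% 3L + 1L        # anchor-in-scale index
      gx <- tg$cx / strides[s]; gy <- tg$cy / strides[s]
      gi <- min(max(floor(gx), 0), grid_hw[[s]][2] - 1L)
      gj <- min(max(floor(gy), 0), grid_hw[[s]][1] - 1L)
      # baseline 3-cell rule: the center cell plus the laterally nearest
      # x- and y-neighbors (decoded offsets span (-0.5, 1.5) cells, so the
      # neighbors can still regress onto the box center)
      cells <- list(c(gi, gj))
      fx <- gx - gi; fy <- gy - gj
      if (fx < 0.5 && gi >= 1L) cells <- c(cells, list(c(gi - 1L, gj)))
      if (fx > 0.5 && gi < grid_hw[[s]][2] - 1L) cells <- c(cells, list(c(gi + 1L, gj)))
      if (fy < 0.5 && gj >= 1L) cells <- c(cells, list(c(gi, gj - 1L)))
      if (fy > 0.5 && gj < grid_hw[[s]][1] - 1L) cells <- c(cells, list(c(gi, gj + 1L)))
      for (cl in cells)
        out[[length(out) + 1L]] <- data.frame(
          scale = s, anchor = ai, gi = cl[1], gj = cl[2], class = tg$class,
          cx = tg$cx, cy = tg$cy, w = tg$w, h = tg$h, target_idx = ti)
    }
  }
  if (length(out) == 0L) return(out)
  asg <- do.call(rbind, out)
  # one target per anchor-cell: keep the first claim
  asg[!duplicated(asg[, c("scale", "anchor", "gi", "gj")]), , drop = FALSE]
}

#' Detection loss
#'
#' Classification and objectness use binary cross-entropy; the box term is
#' `1 - CIoU` over positive assignments; the objectness target at a
#' positive is the current predicted box's IoU (clamped below at 0.05),
#' the baseline framework's score-by-localization convention. Per-scale
#' objectness balance
#' weights are `(4.0, 1.0, 0.4)` (ascending stride) and the component gains
#' default to `box 0.05, obj 1.0, cls 0.5`.
#'
#' @param preds list of raw head outputs, one `(H, W, 3(5+nc))` array per
#'   scale, ascending stride.
#' @param targets data.frame with columns `class`, `cx`, `cy`, `w`, `h`
#'   (input-scale pixels); zero rows means a background-only image.
#' @param model the `glyo_model` that produced `preds` (for anchors,
#'   strides and class count).
#' @param gains named list overriding `box`, `obj`, `cls`.
#' @return list with `total` and the `box`, `obj`, `cls` components.
#' @export
detection_loss <- function(preds, targets, model, gains = list()) {
  g <- utils::modifyList(list(box = 0.05, obj = 1.0, cls = 0.5), gains)
  nc <- model$detect$nc
  no <- 5L + nc
  anchors <- model$detect$anchors
  strides <- model$detect$strides
  balance <- c(4.0, 1.0, 0.4)
  grid_hw <- lapply(preds, function(p) dim(p)[1:2])
  asg <- build_targets(targets, anchors, strides, grid_hw)
  lbox <- 0; lcls <- 0; n_pos <- 0
  obj_loss <- 0
  for (s in seq_along(preds)) {
    p <- preds[[s]]
    d <- dim(p)
    obj_target <- array(0, c(d[1], d[2], 3L))
    if (is.data.frame(asg) && nrow(asg) > 0L) {
      rows <- asg[asg$scale == s, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        a <- rows$anchor[r]; gi <- rows$gi[r]; gj <- rows$gj[r]
        base <- (a - 1L) * no
        t4 <- p[gj + 1L, gi + 1L, base + 1:4]
        gtb <- c(rows$cx[r], rows$cy[r], rows$w[r], rows$h[r])
        pb <- decode_box_at(t4, gi, gj, strides[s], anchors[[s]][a, ])
        lbox <- lbox + (1 - ciou_cxcywh(pb, gtb))
        if (nc > 1L) {
          cls_logits <- p[gj + 1L, gi + 1L, base + 5L + 1:nc]
          cls_t <- numeric(nc); cls_t[rows$class[r] + 1L] <- 1
          lcls <- lcls + bce_logits(cls_t, cls_logits)
        }
        # baseline convention: the objectness target is the (detached)
        # IoU of the currently predicted box, so confidence learns to
        # rank detections by localization quality
        obj_target[gj + 1L, gi + 1L, a] <- max(0.05, iou_cxcywh(pb, gtb))
        n_pos <- n_pos + 1L
      }
    }
    obj_logits <- p[, , (0:2) * no + 5L, drop = FALSE]
    ign <- objectness_ignore(targets, strides[s], d[1:2])
    keep <- !(array(ign, c(d[1], d[2], 3L)) & obj_target == 0)
    obj_loss <- obj_loss + balance[s] *
      bce_logits(as.numeric(obj_target)[keep], as.numeric(obj_logits)[keep])
  }
  if (n_pos > 0L) { lbox <- lbox / n_pos; lcls <- lcls / n_pos }
  comps <- c(box = g$box * lbox, obj = g$obj * obj_loss, cls = g$cls * lcls)
  list(total = sum(comps), box = comps[["box"]], obj = comps[["obj"]], cls = comps[["cls"]],
       n_positive = n_pos)
}
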