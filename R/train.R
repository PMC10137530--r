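# Training loop.
#
# The backbone is frozen at its (deterministic) initialization and only the
# detection-head 1x1 convolutions are optimized -- a deliberate desk-scale
# regime: backbone features per image are computed once and cached, after
# which each epoch costs a handful of small matrix products per image. The
# objective is the full detection loss (BCE objectness/classification +
# CIoU box term); objectness/classification gradients are analytic, the box
# term's gradient is taken by central differences on the four box logits of
# each positive (the CIoU scalar is cheap). Optimizer defaults follow the
# published hyperparameters: Adam, initial learning rate 0.01, first-moment
# coefficient 0.937, weight decay 5e-4, 300 epochs.

head_matrices <- function(model) {
  lapply(model$detect$convs, function(cv) {
    W <- cv$w; dim(W) <- c(dim(cv$w)[3], dim(cv$w)[4])
    list(W = W, b = cv$bias)
  })
}

set_head_matrices <- function(model, hm) {
  for (s in seq_along(hm)) {
    d <- dim(model$detect$convs[[s]]$w)
    model$detect$convs[[s]]$w <- array(hm[[s]]$W, d)
    model$detect$convs[[s]]$bias <- hm[[s]]$b
  }
  model
}

head_forward <- function(feats, hm) {
  lapply(seq_along(feats), function(s) {
    d <- dim(feats[[s]])
    fm <- feats[[s]]; dim(fm) <- c(d[1] * d[2], d[3])
    out <- fm %*% hm[[s]]$W + rep(hm[[s]]$b, each = d[1] * d[2])
    dim(out) <- c(d[1], d[2], ncol(hm[[s]]$W))
    out
  })
}

# gradient of detection_loss w.r.t. the raw head outputs of one image
head_output_grad <- function(preds, asg, targets, model, gains, n_pos_total) {
  nc <- model$detect$nc; no <- 5L + nc
  balance <- c(4.0, 1.0, 0.4)
  grads <- vector("list", length(preds))
  for (s in seq_along(preds)) {
    p <- preds[[s]]; d <- dim(p)
    gmat <- array(0, d)
    # objectness: mean BCE over the whole scale tensor
    obj_idx <- (0:2) * no + 5L
    tgt <- array(0, c(d[1], d[2], 3L))
    if (is.data.frame(asg) && nrow(asg) > 0L) {
      rows <- asg[asg$scale == s, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        a0 <- rows$anchor[r]
        t4 <- p[rows$gj[r] + 1L, rows$gi[r] + 1L, (a0 - 1L) * no + 1:4]
        pb <- decode_box_at(t4, rows$gi[r], rows$gj[r], model$detect$strides[s],
                            model$detect$anchors[[s]][a0, ])
        tgt[rows$gj[r] + 1L, rows$gi[r] + 1L, a0] <-
          max(0.05, iou_cxcywh(pb, c(rows$cx[r], rows$cy[r], rows$w[r], rows$h[r])))
      }
    }
    ign <- objectness_ignore(targets, model$detect$strides[s], d[1:2])
    keep <- !(array(ign, c(d[1], d[2], 3L)) & tgt == 0)
    nel <- sum(keep)
    gobj <- gains$obj * balance[s] * (sigmoid(p[, , obj_idx]) - tgt) / nel
    gobj[!keep] <- 0
    gmat[, , obj_idx] <- gobj
    if (is.data.frame(asg) && nrow(asg) > 0L) {
      rows <- asg[asg$scale == s, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        a <- rows$anchor[r]; gi <- rows$gi[r]; gj <- rows$gj[r]
        base <- (a - 1L) * no
        # classification (analytic, only when more than one class)
        if (nc > 1L) {
          cls_ch <- base + 5L + seq_len(nc)
          y <- numeric(nc); y[rows$class[r] + 1L] <- 1
          gmat[gj + 1L, gi + 1L, cls_ch] <- gmat[gj + 1L, gi + 1L, cls_ch] +
            gains$cls * (sigmoid(p[gj + 1L, gi + 1L, cls_ch]) - y) / (nc * n_pos_total)
        }
        # box: central differences on the four logits
        t4 <- p[gj + 1L, gi + 1L, base + 1:4]
        gtb <- c(rows$cx[r], rows$cy[r], rows$w[r], rows$h[r])
        f <- function(tv) 1 - ciou_cxcywh(
          decode_box_at(tv, gi, gj, model$detect$strides[s], model$detect$anchors[[s]][a, ]), gtb)
        hstep <- 1e-3
        for (q in 1:4) {
          tp <- t4; tm <- t4
          tp[q] <- tp[q] + hstep; tm[q] <- tm[q] - hstep
          gmat[gj + 1L, gi + 1L, base + q] <- gmat[gj + 1L, gi + 1L, base + q] +
            gains$box * (f(tp) - f(tm)) / (2 * hstep) / n_pos_total
        }
      }
    }
    grads[[s]] <- gmat
  }
  grads
}

# Weighted ridge regression of each head output channel onto target logits
# over the cached training features: objectness fits +/- prior logits with
# the positive class up-weighted to parity and ignore-region cells given
# zero weight; box channels fit the exactly inverse-decoded offset logits
# at positive cells; class channels fit +/- logits at positives.
ridge_init_head <- function(hm, feats, targets, asgs, model) {
  clamp01 <- function(z) pmin(pmax(z, 0.02), 0.98)
  nc <- model$detect$nc; no <- 5L + nc
  n_img <- length(feats)
  for (s in seq_along(hm)) {
    d <- dim(feats[[1]][[s]])
    ncell <- d[1] * d[2]
    X <- do.call(rbind, lapply(feats, function(f) {
      fm <- f[[s]]; dim(fm) <- c(ncell, d[3]); fm
    }))
    X <- cbind(X, 1)   # bias column
    p <- ncol(X)
    ridge_solve <- function(wts, y) {
      sw <- sqrt(wts)
      Xw <- X * sw
      A <- crossprod(Xw) + diag(1e-2 * mean(colSums(Xw^2)), p)
      drop(solve(A, crossprod(Xw, y * sw)))
    }
    for (a in 1:3) {
      # row index of cell (gj, gi) within image i: i0 + gi * H + gj + 1
      pos <- integer(); obj_pos <- integer()
      tx <- ty <- tw <- th <- numeric(); cls_rows <- integer()
      cls_y <- integer()
      wobj <- rep(1, n_img * ncell); yobj <- rep(-log(99), n_img * ncell)
      for (i in seq_len(n_img)) {
        i0 <- (i - 1L) * ncell
        ign <- objectness_ignore(targets[[i]], model$detect$strides[s], d[1:2])
        wobj[i0 + which(as.logical(ign))] <- 0
        asg <- asgs[[i]]
        if (!is.data.frame(asg) || nrow(asg) == 0L) next
        rows <- asg[asg$scale == s & asg$anchor == a, , drop = FALSE]
        if (nrow(rows) == 0L) next
        ridx <- i0 + rows$gi * d[1] + rows$gj + 1L
        obj_pos <- c(obj_pos, ridx)
        st <- model$detect$strides[s]; anc <- model$detect$anchors[[s]][a, ]
        base0 <- (a - 1L) * no
        for (r in seq_len(nrow(rows))) {
          t4 <- as.numeric(X[ridx[r], -p] %*% hm[[s]]$W[, base0 + 1:4]) +
                hm[[s]]$b[base0 + 1:4]
          pb <- decode_box_at(t4, rows$gi[r], rows$gj[r], st, anc)
          iou <- iou_cxcywh(pb, c(rows$cx[r], rows$cy[r], rows$w[r], rows$h[r]))
          wobj[ridx[r]] <- 1
          yobj[ridx[r]] <- log(clamp01(max(iou, 0.05)) / (1 - clamp01(max(iou, 0.05))))
        }
        clamp <- function(z) pmin(pmax(z, 0.02), 0.98)
        inv_sig <- function(z) { z <- clamp(z); log(z / (1 - z)) }
        # box-regression rows: every cell whose decoded center range can
        # still reach the box center (offsets span (-0.5, 1.5) cells), not
        # only the assigned positives -- covered cells that score well at
        # inference then carry correct boxes instead of extrapolations
        tg_rows <- rows[!duplicated(rows$target_idx), , drop = FALSE]
        for (tr in seq_len(nrow(tg_rows))) {
          tb <- tg_rows[tr, ]
          gx <- tb$cx / st; gy <- tb$cy / st
          gis <- max(0L, ceiling(gx - 1.4)):min(d[2] - 1L, floor(gx + 0.4))
          gjs <- max(0L, ceiling(gy - 1.4)):min(d[1] - 1L, floor(gy + 0.4))
          for (gj2 in gjs) for (gi2 in gis) {
            ridx2 <- i0 + gi2 * d[1] + gj2 + 1L
            pos <- c(pos, ridx2)
            tx <- c(tx, inv_sig((gx - gi2 + 0.5) / 2))
            ty <- c(ty, inv_sig((gy - gj2 + 0.5) / 2))
            tw <- c(tw, inv_sig(sqrt(tb$w / anc[1]) / 2))
            th <- c(th, inv_sig(sqrt(tb$h / anc[2]) / 2))
            if (nc > 1L) { cls_rows <- c(cls_rows, ridx2); cls_y <- c(cls_y, tb$class) }
          }
        }
      }
      if (length(pos) == 0L) next
      # balance: total positive weight = total negative weight
      wobj[obj_pos] <- wobj[obj_pos] * max(1, sum(wobj > 0) / length(obj_pos) - 1)
      base <- (a - 1L) * no
      co <- ridge_solve(wobj, yobj)
      hm[[s]]$W[, base + 5L] <- co[-p]; hm[[s]]$b[base + 5L] <- co[p]
      Xp <- X[pos, , drop = FALSE]
      box_solve <- function(y) {
        A <- crossprod(Xp) + diag(1e-2 * mean(colSums(Xp^2)) + 1e-8, p)
        drop(solve(A, crossprod(Xp, y)))
      }
      for (q in 1:4) {
        co <- box_solve(list(tx, ty, tw, th)[[q]])
        hm[[s]]$W[, base + q] <- co[-p]; hm[[s]]$b[base + q] <- co[p]
      }
      if (nc > 1L && length(cls_rows) > 0L) {
        Xc <- X[cls_rows, , drop = FALSE]
        Ac <- crossprod(Xc) + diag(1e-2 * mean(colSums(Xc^2)) + 1e-8, p)
        for (k in seq_len(nc)) {
          yk <- ifelse(cls_y == k - 1L, 4, -4)
          co <- drop(solve(Ac, crossprod(Xc, yk)))
          hm[[s]]$W[, base + 5L + k] <- co[-p]; hm[[s]]$b[base + 5L + k] <- co[p]
        }
      }
    }
  }
  hm
}


# Identify the per-scale "head adapter": when a detect tap is a Concat of a
# base feature layer with a 3x3 conv computed from that same layer, the
# conv is treated as part of the trainable detection subnetwork (a
# two-layer head); otherwise the head is the bare 1x1 detect conv.
head_adapters <- function(model) {
  lapply(seq_along(model$detect_from), function(s) {
    tap <- model$detect_from[s]
    ly <- model$layers[[tap + 1L]]
    if (identical(ly$name, "concat") && length(ly$from) == 2L) {
      f1 <- ly$from[1]; f2 <- ly$from[2]
      ly2 <- model$layers[[f2 + 1L]]
      if (identical(ly2$name, "conv") && length(ly2$from) == 1L &&
          ly2$from[1] == f1 && ly2$block$k == 3L && ly2$block$stride == 1L)
        return(list(tap = tap, base = f1, adapter = f2))
    }
    list(tap = tap, base = tap, adapter = NA_integer_)
  })
}

silu_prime <- function(z) { sg <- sigmoid(z); sg * (1 + z * (1 - sg)) }

# forward one scale: base features -> (optional adapter conv) -> tap
tap_forward <- function(base, hs) {
  if (is.null(hs$E)) return(list(tap = base, z = NULL))
  z <- conv2d(base, hs$E, NULL, 1L, 1L)
  zb <- bn_apply(z, hs$bn)
  list(tap = channel_concat(list(base, silu(zb))), z = zb)
}

# backprop the adapter: dtap is the gradient w.r.t. the concatenated tap
adapter_grad <- function(base, z, dtap, hs) {
  d <- dim(base); cb <- d[3]
  cexp <- dim(hs$E)[4]
  dphi <- dtap[, cb + seq_len(cexp), drop = FALSE]
  zm <- z; dim(zm) <- c(d[1] * d[2], cexp)
  scale <- hs$bn$gamma / sqrt(hs$bn$var + hs$bn$eps)
  dz <- dphi * silu_prime(zm) * rep(scale, each = d[1] * d[2])
  bp <- pad_hw(base, 1L)
  dE <- array(0, dim(hs$E))
  for (di in 1:3) for (dj in 1:3) {
    sl <- bp[seq_len(d[1]) + di - 1L, seq_len(d[2]) + dj - 1L, , drop = FALSE]
    dim(sl) <- c(d[1] * d[2], cb)
    dE[di, dj, , ] <- crossprod(sl, dz)
  }
  dE
}

letterboxed_targets <- function(label_path, orig_hw, img_size) {
  b <- read_yolo_labels(label_path)
  if (nrow(b) == 0L)
    return(data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  r <- min(img_size / orig_hw[1], img_size / orig_hw[2])
  nh <- round(orig_hw[1] * r); nw <- round(orig_hw[2] * r)
  top <- (img_size - nh) %/% 2; left <- (img_size - nw) %/% 2
  data.frame(class = b$class,
             cx = b$cx * orig_hw[2] * r + left, cy = b$cy * orig_hw[1] * r + top,
             w = b$w * orig_hw[2] * r, h = b$h * orig_hw[1] * r)
}

#' Train the detection head on a dataset split
#'
#' Builds the model from `config` with K-means++ anchors clustered from the
#' training labels, freezes the randomly initialized backbone, caches its
#' features for every training image and optimizes the detection head with
#' Adam on the detection loss. Logs one JSON line per epoch.
#'
#' @param config model config (name, path or list).
#' @param split a `dataset_split` from [generate_dataset()] /
#'   [split_dataset()].
#' @param epochs training epochs (default 300, the published setting;
#'   smoke tests use far fewer).
#' @param img_size input size; defaults to the config value.
#' @param lr initial learning rate (default 0.01).
#' @param momentum Adam first-moment coefficient (default 0.937).
#' @param weight_decay L2 weight decay (default 5e-4).
#' @param seed seed for model init and shuffling.
#' @param out_dir where the checkpoint and log are written.
#' @param calibrate_bn run [calibrate_model()] on a few training images
#'   before caching features (off by default; see the methods vignette).
#' @param anchor_t anchor-ratio matching threshold; the default 2.5 is
#'   tighter than the baseline 4 so that scales specialize even when the
#'   label size distribution is narrow.
#' @param cluster_anchors_first recluster anchors from the train labels
#'   (default TRUE; requires at least 9 boxes).
#' @param refit_every closed-form refit period: every this many epochs the
#'   detection-head linear layer is re-solved exactly (weighted ridge) on
#'   the current adapter basis -- an alternating-minimization step that
#'   removes the stochastic-gradient residual from the final layer.
#' @param verbose print per-epoch summaries.
#' @return list with `model` (head-trained), `history` (per-epoch loss
#'   data.frame), `train_map50`, `checkpoint` and `log` paths.
#' @export
train <- function(config, split, epochs = 300L, img_size = NULL, lr = 0.01,
                  momentum = 0.937, weight_decay = 5e-4, seed = 0L,
                  out_dir = tempfile("glyo_run_"), cluster_anchors_first = TRUE,
                  calibrate_bn = FALSE, anchor_t = 2.5, refit_every = 5L,
                  verbose = FALSE) {
  if (is.character(config)) config <- read_model_config(config)
  if (nrow(split$train) == 0L) stop("train: empty train split", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(img_size)) img_size <- if (is.null(config$img_size)) 640L else config$img_size

  if (cluster_anchors_first) {
    wh <- do.call(rbind, lapply(split$train$label, function(f) {
      b <- read_yolo_labels(f)
      if (nrow(b) == 0L) return(NULL)
      cbind(b$w, b$h)
    }))
    if (!is.null(wh) && nrow(wh) >= 9L) {
      anc <- cluster_anchors(wh * img_size, k = 9L, seed = seed)
      config$anchors <- lapply(1:3, function(s) as.numeric(t(anc[(s - 1) * 3 + 1:3, ])))
    }
  }
  model <- build_model(config, img_size = img_size, seed = seed)
  gains <- list(box = 0.05, obj = 1.0, cls = 0.5)

  # optionally calibrate BN statistics on a few training images, then
  # cache features and assignments per training image
  n_img <- nrow(split$train)
  load_img <- function(path) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    img
  }
  if (calibrate_bn) {
    calib <- lapply(split$train$image[seq_len(min(4L, n_img))],
                    function(p) letterbox(load_img(p), img_size)$img)
    calibrate_model(model, calib)
  }
  ads <- head_adapters(model)
  base_idx <- vapply(ads, function(a) a$base, 0L)
  feats <- vector("list", n_img); targets <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    img <- load_img(split$train$image[i])
    lb <- letterbox(img, img_size)
    feats[[i]] <- model_forward(model, lb$img, capture = base_idx)
    targets[[i]] <- letterboxed_targets(split$train$label[i], dim(img)[1:2], img_size)
  }
  grid_hw <- lapply(seq_along(ads), function(s) {
    if (is.na(ads[[s]]$adapter)) dim(feats[[1]][[s]])[1:2]
    else dim(feats[[1]][[s]])[1:2]
  })
  asgs <- lapply(targets, build_targets, anchors = model$detect$anchors,
                 strides = model$detect$strides, grid_hw = grid_hw,
                 anchor_t = anchor_t)

  # head init: closed-form weighted ridge fit of every output channel to
  # its target logits (a data-dependent initialization); the subsequent
  # Adam epochs then refine under the exact detection loss instead of
  # spending their step budget crawling out of a cold start.
  hm <- head_matrices(model)
  nc <- model$detect$nc; no <- 5L + nc
  for (s in seq_along(hm)) {
    hm[[s]]$W[] <- 0
    hm[[s]]$b[] <- 0
    hm[[s]]$b[(0:2) * no + 5L] <- -log(99)
    if (nc == 1L) hm[[s]]$b[(0:2) * no + 6L] <- log(99)  # single class: certain
    if (!is.na(ads[[s]]$adapter)) {
      blk <- model$layers[[ads[[s]]$adapter + 1L]]$block
      hm[[s]]$E <- blk$w
      hm[[s]]$bn <- blk$bn
    }
  }
  tap_feats <- lapply(feats, function(fb)
    lapply(seq_along(fb), function(s) tap_forward(fb[[s]], hm[[s]])$tap))
  hm <- ridge_init_head(hm, tap_feats, targets, asgs, model)
  adam <- lapply(hm, function(h) {
    st <- list(mW = h$W * 0, vW = h$W * 0, mb = h$b * 0, vb = h$b * 0)
    if (!is.null(h$E)) { st$mE <- h$E * 0; st$vE <- h$E * 0 }
    st
  })
  beta1 <- momentum; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  log_path <- file.path(out_dir, "train_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  history <- data.frame()
  set.seed(seed + 1000L)
  for (ep in seq_len(epochs)) {
    # cosine decay of the learning rate to 5% of its initial value
    lr_ep <- lr * (0.05 + 0.95 * 0.5 * (1 + cos(pi * (ep - 1) / max(1, epochs - 1))))
    ep_loss <- c(total = 0, box = 0, obj = 0, cls = 0)
    for (i in sample.int(n_img)) {
      tf <- lapply(seq_along(hm), function(s) tap_forward(feats[[i]][[s]], hm[[s]]))
      taps <- lapply(tf, `[[`, "tap")
      preds <- head_forward(taps, hm)
      L <- detection_loss(preds, targets[[i]], model, gains)
      ep_loss <- ep_loss + c(L$total, L$box, L$obj, L$cls)
      gr <- head_output_grad(preds, asgs[[i]], targets[[i]], model, gains,
                             max(1L, L$n_positive))
      step <- step + 1L
      for (s in seq_along(hm)) {
        d <- dim(taps[[s]])
        fm <- taps[[s]]; dim(fm) <- c(d[1] * d[2], d[3])
        gmat <- gr[[s]]; dim(gmat) <- c(d[1] * d[2], dim(gr[[s]])[3])
        W_pre <- hm[[s]]$W
        dW <- crossprod(fm, gmat) + weight_decay * hm[[s]]$W
        db <- colSums(gmat)
        a <- adam[[s]]
        a$mW <- beta1 * a$mW + (1 - beta1) * dW
        a$vW <- beta2 * a$vW + (1 - beta2) * dW^2
        a$mb <- beta1 * a$mb + (1 - beta1) * db
        a$vb <- beta2 * a$vb + (1 - beta2) * db^2
        mhatW <- a$mW / (1 - beta1^step); vhatW <- a$vW / (1 - beta2^step)
        mhatb <- a$mb / (1 - beta1^step); vhatb <- a$vb / (1 - beta2^step)
        hm[[s]]$W <- hm[[s]]$W - lr_ep * mhatW / (sqrt(vhatW) + eps)
        hm[[s]]$b <- hm[[s]]$b - lr_ep * mhatb / (sqrt(vhatb) + eps)
        if (!is.null(hm[[s]]$E)) {
          dtap <- gmat %*% t(W_pre)
          dE <- adapter_grad(feats[[i]][[s]], tf[[s]]$z, dtap, hm[[s]]) +
                weight_decay * hm[[s]]$E
          a$mE <- beta1 * a$mE + (1 - beta1) * dE
          a$vE <- beta2 * a$vE + (1 - beta2) * dE^2
          hm[[s]]$E <- hm[[s]]$E - lr_ep * (a$mE / (1 - beta1^step)) /
            (sqrt(a$vE / (1 - beta2^step)) + eps)
        }
        adam[[s]] <- a
      }
    }
    if (refit_every > 0L && ep %% refit_every == 0L) {
      tap_feats <- lapply(feats, function(fb)
        lapply(seq_along(fb), function(s) tap_forward(fb[[s]], hm[[s]])$tap))
      hm <- ridge_init_head(hm, tap_feats, targets, asgs, model)
    }
    ep_loss <- ep_loss / n_img
    rec <- data.frame(epoch = ep, loss = ep_loss[1], box = ep_loss[2],
                      obj = ep_loss[3], cls = ep_loss[4])
    history <- rbind(history, rec)
    cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
    if (verbose) cat(sprintf("epoch %3d  loss %.4f (box %.4f obj %.4f cls %.4f)\n",
                             ep, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4]))
  }
  model <- set_head_matrices(model, hm)
  for (s in seq_along(hm))
    if (!is.null(hm[[s]]$E))
      model$layers[[ads[[s]]$adapter + 1L]]$block$w <- hm[[s]]$E

  # train-split mAP@0.5 from the cached features
  dets <- list(); gts <- list()
  for (i in seq_len(n_img)) {
    taps <- lapply(seq_along(hm), function(s) tap_forward(feats[[i]][[s]], hm[[s]])$tap)
    preds <- head_forward(taps, hm)
    dd <- decode_predictions(preds, model, conf_threshold = 0.001)
    if (nrow(dd) > 0L) { dd$image <- split$train$image[i]; dets[[length(dets) + 1L]] <- dd }
    tg <- targets[[i]]
    if (nrow(tg) > 0L)
      gts[[length(gts) + 1L]] <- data.frame(image = split$train$image[i], class = tg$class,
                                            x1 = tg$cx - tg$w / 2, y1 = tg$cy - tg$h / 2,
                                            x2 = tg$cx + tg$w / 2, y2 = tg$cy + tg$h / 2)
  }
  det_df <- if (length(dets)) do.call(rbind, dets) else
    data.frame(image = character(), class = integer(), score = numeric(),
               x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
  gt_df <- do.call(rbind, gts)
  tmap <- map50(det_df, gt_df)

  ckpt <- file.path(out_dir, "model.rds")
  saveRDS(model, ckpt)
  list(model = model, history = history, train_map50 = tmap,
       checkpoint = ckpt, log = log_path)
}

#' Evaluate a model on an image/label split
#'
#' Runs full inference on every image and scores mAP@0.5 against the YOLO
#' labels.
#'
#' @param model a trained `glyo_model`.
#' @param split_df data.frame with `image`, `label` columns.
#' @param conf_threshold decode confidence threshold (low by default so the
#'   PR curve is well populated).
#' @export
evaluate_dataset <- function(model, split_df, conf_threshold = 0.001) {
  dets <- list(); gts <- list()
  for (i in seq_len(nrow(split_df))) {
    dd <- detect(model, split_df$image[i], conf_threshold = conf_threshold)
    if (nrow(dd) > 0L) { dd$image <- split_df$image[i]; dets[[length(dets) + 1L]] <- dd }
    img <- png::readPNG(split_df$image[i])
    hw <- dim(img)[1:2]
    b <- read_yolo_labels(split_df$label[i])
    if (nrow(b) > 0L) {
      xy <- yolo_to_xyxy(b, hw[1])   # square generator images
      xy$image <- split_df$image[i]
      gts[[length(gts) + 1L]] <- xy
    }
  }
  det_df <- if (length(dets)) do.call(rbind, dets) else
    data.frame(image = character(), class = integer(), score = numeric(),
               x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
  gt_df <- if (length(gts)) do.call(rbind, gts) else
    data.frame(image = character(), class = integer(),
               x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
  list(map50 = map50(det_df, gt_df), detections = det_df, ground_truth = gt_df)
}
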