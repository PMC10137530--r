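# Network building blocks.
#
# Every block is a list with a $type tag plus its weights; the forward
# helpers dispatch on the tag. Constructors draw their weights from the current
# RNG stream (He-scaled normal), so a model built under set.seed() is fully
# deterministic. Batch norms run in inference form (running statistics);
# gamma/beta are the learnable parameters, the running mean/var are buffers.

new_bn <- function(c2, eps = 1e-3, momentum = 0.03) {
  # environments, not lists: batch-norm statistics can be calibrated in
  # place by a data pass (see calibrate_model) without rebuilding the model
  e <- new.env(parent = emptyenv())
  e$gamma <- rep(1, c2); e$beta <- rep(0, c2)
  e$mean <- rep(0, c2); e$var <- rep(1, c2)
  e$eps <- eps; e$momentum <- momentum; e$calib_n <- 0L
  e
}

# package-internal state: BN calibration switch
.glyo_state <- new.env(parent = emptyenv())
.glyo_state$calibrating <- FALSE

# apply BN; in calibration mode first fold the batch statistics of x into
# the running mean/var (simple cumulative average over calibration passes)
bn_forward <- function(x, bn) {
  if (isTRUE(.glyo_state$calibrating)) {
    d <- dim(x)
    xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
    m <- colMeans(xm)
    v <- colMeans(xm^2) - m^2
    n <- bn$calib_n
    bn$mean <- (bn$mean * n + m) / (n + 1)
    bn$var <- pmax((bn$var * n + v) / (n + 1), 1e-8)
    bn$calib_n <- n + 1L
  }
  bn_apply(x, bn)
}

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Conv-BN-activation unit
#'
#' The standard convolutional unit: `k x k` convolution (no bias) followed by
#' batch normalization and SiLU, matching the baseline convention. Detection
#' convs use `bn = FALSE, bias = TRUE, act = "none"`.
#'
#' @param c1,c2 input/output channels.
#' @param k kernel size.
#' @param stride stride.
#' @param act `"silu"`, `"relu"` or `"none"`.
#' @param bn apply batch normalization.
#' @param bias carry a bias vector (conventionally only when `bn = FALSE`).
#' @param groups group count for grouped convolution.
#' @param pad zero padding; defaults to `k %/% 2`.
#' @return a conv block (list with weights and batch-norm state).
#' @export
new_conv_unit <- function(c1, c2, k = 1L, stride = 1L, act = "silu",
                          bn = TRUE, bias = FALSE, groups = 1L, pad = NULL) {
  stopifnot(c1 >= 1, c2 >= 1, k >= 1, stride >= 1)
  if (c1 %% groups != 0) stop("input channels not divisible by groups", call. = FALSE)
  list(type = "conv",
       w = he_init(k, k, c1 %/% groups, c2),
       bias = if (bias) rep(0, c2) else NULL,
       bn = if (bn) new_bn(c2) else NULL,
       stride = as.integer(stride), pad = if (is.null(pad)) k %/% 2L else as.integer(pad),
       groups = as.integer(groups), act = act, c1 = as.integer(c1), c2 = as.integer(c2),
       k = as.integer(k))
}

forward_conv_unit <- function(blk, x) {
  y <- conv2d(x, blk$w, blk$bias, blk$stride, blk$pad, blk$groups)
  if (!is.null(blk$bn)) y <- bn_forward(y, blk$bn)
  apply_activation(y, blk$act)
}

# ---------------------------------------------------------------- focus ----

#' Space-to-depth slicing of the focus module
#'
#' Takes every other pixel of the input, producing the four half-resolution
#' sub-lattices stacked along channels in the fixed order even/even,
#' odd/even, even/odd, odd/odd (0-based row/column parity). The operation is
#' a bijection; [focus_inverse()] reassembles the input exactly.
#'
#' @param x feature map with even H and W.
#' @return feature map of shape `(H/2, W/2, 4C)`.
#' @export
#' @examples
#' x <- feature_map(1:4, 2, 2, 1)
#' focus_slice(x)[1, 1, ]
focus_slice <- function(x) {
  assert_feature_map(x)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("focus_slice: H and W must be even, got ", d[1], "x", d[2], call. = FALSE)
  ev <- function(n) seq.int(1L, n, 2L)  # 0-based even indices
  od <- function(n) seq.int(2L, n, 2L)
  channel_concat(list(
    x[ev(d[1]), ev(d[2]), , drop = FALSE],
    x[od(d[1]), ev(d[2]), , drop = FALSE],
    x[ev(d[1]), od(d[2]), , drop = FALSE],
    x[od(d[1]), od(d[2]), , drop = FALSE]))
}

#' @rdname focus_slice
#' @param y a sliced map of shape `(H/2, W/2, 4C)`.
#' @export
focus_inverse <- function(y) {
  d <- dim(y)
  if (d[3] %% 4L != 0L) stop("focus_inverse: channels not divisible by 4", call. = FALSE)
  C <- d[3] %/% 4L
  out <- array(0, c(2L * d[1], 2L * d[2], C))
  ev <- function(n) seq.int(1L, n, 2L); od <- function(n) seq.int(2L, n, 2L)
  out[ev(2 * d[1]), ev(2 * d[2]), ] <- y[, , seq_len(C)]
  out[od(2 * d[1]), ev(2 * d[2]), ] <- y[, , C + seq_len(C)]
  out[ev(2 * d[1]), od(2 * d[2]), ] <- y[, , 2L * C + seq_len(C)]
  out[od(2 * d[1]), od(2 * d[2]), ] <- y[, , 3L * C + seq_len(C)]
  out
}

new_focus <- function(c1, c2, k = 3L) {
  list(type = "focus", conv = new_conv_unit(4L * c1, c2, k), c1 = c1, c2 = c2)
}

#' Focus module forward pass
#'
#' [focus_slice()] followed by a conv unit whose input channels must equal
#' four times the map's channels (a 640x640x3 image with a 3x3, n = 32 conv
#' yields 320x320x32).
#'
#' @param x feature map with even spatial dims.
#' @param conv a conv unit from [new_conv_unit()] with `c1 = 4 * C`.
#' @export
focus_forward <- function(x, conv) {
  s <- focus_slice(x)
  if (conv$c1 != dim(s)[3])
    stop(sprintf("focus_forward: conv expects %d channels, sliced map has %d",
                 conv$c1, dim(s)[3]), call. = FALSE)
  forward_conv_unit(conv, s)
}

# ----------------------------------------------------------------- stem ----

new_stem <- function(c1, c2) {
  # 3x3/s2 entry conv, then a squeezed conv branch (1x1 c->c/2, 3x3/s2
  # c/2->c) beside a 2x2/s2 max-pool branch, concatenated and projected by a
  # 1x1 conv. Overall spatial stride 4.
  if (c2 %% 2L != 0L) stop("stem: out_channels must be even", call. = FALSE)
  list(type = "stem",
       conv1 = new_conv_unit(c1, c2, 3L, stride = 2L),
       br1   = new_conv_unit(c2, c2 %/% 2L, 1L),
       br2   = new_conv_unit(c2 %/% 2L, c2, 3L, stride = 2L),
       proj  = new_conv_unit(2L * c2, c2, 1L),
       c1 = c1, c2 = c2)
}

#' Stem block forward pass
#'
#' A stride-4 convolutional entry stage replacing the focus module: a 3x3
#' stride-2 convolution for rapid spatial reduction, then a dual-branch
#' stage (squeezed 3x3 stride-2 conv branch and a 2x2 max-pool branch)
#' concatenated and projected back to `out_channels` by a 1x1 convolution.
#'
#' @param x feature map with H, W divisible by 4.
#' @param stem a stem block (from the internal constructor) or an integer
#'   `out_channels`, in which case a freshly initialized stem is drawn from
#'   the current RNG stream.
#' @export
stem_forward <- function(x, stem) {
  assert_feature_map(x)
  d <- dim(x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("stem_forward: H and W must be divisible by 4", call. = FALSE)
  if (is.numeric(stem)) stem <- new_stem(d[3], as.integer(stem))
  x1 <- forward_conv_unit(stem$conv1, x)
  a  <- forward_conv_unit(stem$br2, forward_conv_unit(stem$br1, x1))
  b  <- maxpool2d(x1, 2L, stride = 2L, pad = 0L)
  forward_conv_unit(stem$proj, channel_concat(list(a, b)))
}

# ------------------------------------------------------------------ CoT ----

#' Contextual transformer (CoT) attention block
#'
#' Keys pass a `k x k` group convolution so the attention matrix is
#' conditioned on neighborhood ("static") context; the concatenation of the
#' static context and the queries (2C channels) is mapped by two consecutive
#' 1x1 convolutions (the first with ReLU, the second without activation) to
#' per-channel attention logits over each `k x k` neighborhood; values are
#' aggregated under the softmax of those logits ("dynamic" context), and the
#' output is the elementwise sum of static and dynamic context. Output shape
#' equals input shape.
#'
#' @param c channels; must be divisible by `2 * groups`.
#' @param k contextual kernel size (odd, default 3).
#' @param groups group count of the key convolution (default 4).
#' @param reduction bottleneck factor of the attention embedding (default 4).
#' @return a CoT block.
#' @export
new_cot <- function(c, k = 3L, groups = 4L, reduction = 4L) {
  if (k %% 2L == 0L) stop("CoT: contextual kernel k must be odd", call. = FALSE)
  if (c %% groups != 0L) stop("CoT: channels not divisible by group count", call. = FALSE)
  cm <- max(1L, (2L * c) %/% reduction)  # attention embedding width
  list(type = "cot",
       key   = new_conv_unit(c, c, k, groups = groups, bn = FALSE, act = "none"),
       value = new_conv_unit(c, c, 1L, act = "none"),
       att1  = new_conv_unit(2L * c, cm, 1L, act = "relu"),
       att2  = new_conv_unit(cm, k * k * c, 1L, bn = FALSE, act = "none"),
       c = as.integer(c), k = as.integer(k), groups = as.integer(groups))
}

#' @rdname new_cot
#' @param x feature map with `C = c`.
#' @param cot a CoT block; if missing, one is drawn from the current RNG.
#' @export
cot_forward <- function(x, cot = NULL) {
  assert_feature_map(x)
  d <- dim(x)
  if (is.null(cot)) cot <- new_cot(d[3])
  if (d[3] != cot$c)
    stop(sprintf("cot_forward: block built for %d channels, input has %d", cot$c, d[3]),
         call. = FALSE)
  k <- cot$k
  kstatic <- forward_conv_unit(cot$key, x)
  v <- forward_conv_unit(cot$value, x)
  qk <- channel_concat(list(kstatic, x))          # H x W x 2C
  a <- forward_conv_unit(cot$att2, forward_conv_unit(cot$att1, qk))  # H x W x k*k*C
  kdyn <- cot_aggregate(v, a, k)
  kstatic + kdyn
}

# Softmax-normalized aggregation of V over each k x k neighborhood.
# Attention logits are laid out neighbor-major: channel block j (size C)
# holds the logit of neighbor offset j, offsets enumerated row-fastest
# (di = -r..r fast, dj = -r..r slow). Values outside the frame contribute 0.
cot_aggregate <- function(v, a, k) {
  d <- dim(v); C <- d[3]; n <- k * k; r <- k %/% 2L
  # softmax over the n neighbor logits, per position and channel
  e <- vector("list", n); m <- NULL
  for (j in seq_len(n)) {
    aj <- a[, , (j - 1L) * C + seq_len(C), drop = FALSE]
    m <- if (is.null(m)) aj else pmax(m, aj)
  }
  z <- NULL
  for (j in seq_len(n)) {
    e[[j]] <- exp(a[, , (j - 1L) * C + seq_len(C), drop = FALSE] - m)
    z <- if (is.null(z)) e[[j]] else z + e[[j]]
  }
  vp <- pad_hw(v, r)
  out <- array(0, d)
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    j <- dj * k + di + 1L
    sl <- vp[seq_len(d[1]) + di, seq_len(d[2]) + dj, , drop = FALSE]
    out <- out + (e[[j]] / z) * sl
  }
  out
}

new_cot_bottleneck <- function(c1, c2, shortcut = TRUE) {
  list(type = "cot_bottleneck",
       cv1 = new_conv_unit(c1, c2, 1L),
       cot = new_cot(c2),
       add = shortcut && c1 == c2)
}

forward_cot_bottleneck <- function(blk, x) {
  y <- cot_forward(forward_conv_unit(blk$cv1, x), blk$cot)
  if (blk$add) y + x else y
}

# ----------------------------------------------------------- C3 / CoT3 -----

new_bottleneck <- function(c1, c2, shortcut = TRUE) {
  list(type = "bottleneck",
       cv1 = new_conv_unit(c1, c2, 1L),
       cv2 = new_conv_unit(c2, c2, 3L),
       add = shortcut && c1 == c2)
}

forward_bottleneck <- function(blk, x) {
  y <- forward_conv_unit(blk$cv2, forward_conv_unit(blk$cv1, x))
  if (blk$add) y + x else y
}

new_c3 <- function(c1, c2, n = 1L, shortcut = TRUE, cot = FALSE) {
  ch <- c2 %/% 2L
  mk <- if (cot) function() new_cot_bottleneck(ch, ch, shortcut)
        else     function() new_bottleneck(ch, ch, shortcut)
  list(type = if (cot) "cot3" else "c3",
       cv1 = new_conv_unit(c1, ch, 1L),
       cv2 = new_conv_unit(c1, ch, 1L),
       m = lapply(seq_len(n), function(i) mk()),
       cv3 = new_conv_unit(2L * ch, c2, 1L),
       n = as.integer(n), c1 = c1, c2 = c2)
}

forward_c3 <- function(blk, x) {
  y <- forward_conv_unit(blk$cv1, x)
  for (b in blk$m)
    y <- if (b$type == "cot_bottleneck") forward_cot_bottleneck(b, y) else forward_bottleneck(b, y)
  forward_conv_unit(blk$cv3, channel_concat(list(y, forward_conv_unit(blk$cv2, x))))
}

#' CoT3 forward pass
#'
#' A C3-style split/merge module whose bottleneck 3x3 convolutions are
#' replaced by CoT blocks; the shape contract is identical to the C3 it
#' replaces.
#'
#' @param x feature map.
#' @param block an existing CoT3 block, or `NULL` to draw one with
#'   `out_channels = C` from the current RNG.
#' @param n_repeats number of stacked CoT bottlenecks when building fresh.
#' @export
cot3_forward <- function(x, block = NULL, n_repeats = 1L) {
  assert_feature_map(x)
  if (n_repeats < 1L) stop("cot3_forward: n_repeats must be >= 1", call. = FALSE)
  if (is.null(block)) block <- new_c3(dim(x)[3], dim(x)[3], n = n_repeats, cot = TRUE)
  forward_c3(block, x)
}

# ---------------------------------------------------------------- SimAM ----

#' SimAM: parameter-free energy-based attention
#'
#' Gates every neuron by the closed-form minimum of its energy function. For
#' a neuron with value `t` in a channel of `M = H * W` neurons, with
#' leave-one-out mean `mu` and variance `sigma2` of the remaining `M - 1`
#' neurons, the minimal energy under the binary targets (+1 for the neuron,
#' -1 for the rest) and an L2 regularizer `lambda` is
#' `e* = 4 (sigma2 + lambda) / ((t - mu)^2 + 2 sigma2 + 2 lambda)`; the gate
#' is `sigmoid(1 / e*)` and the output is the elementwise product with the
#' input. The layer has exactly zero learnable parameters.
#'
#' @param x feature map; every channel needs `H * W >= 2`.
#' @param lambda positive variance regularizer (default `1e-4`).
#' @return gated feature map, same shape as the input.
#' @export
simam_forward <- function(x, lambda = 1e-4) {
  assert_feature_map(x)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("simam_forward: lambda must be a positive scalar", call. = FALSE)
  d <- dim(x)
  M <- d[1] * d[2]
  if (M < 2L) stop("simam_forward: each channel needs at least 2 neurons", call. = FALSE)
  xm <- x; dim(xm) <- c(M, d[3])
  g <- simam_gates(xm, lambda)
  out <- xm * g
  dim(out) <- d
  out
}

# Gates for a (M x C) matrix of channel columns; exact leave-one-out form.
simam_gates <- function(xm, lambda) {
  M <- nrow(xm)
  s1 <- colSums(xm); s2 <- colSums(xm^2)
  mu_t <- (rep(s1, each = M) - xm) / (M - 1)                 # mean of the others
  ss <- rep(s2, each = M) - xm^2 - (M - 1) * mu_t^2          # centered SS of the others
  ss <- pmax(ss, 0)                                          # guard fp negatives
  var_t <- ss / (M - 1)
  dev2 <- (xm - mu_t)^2
  e_min <- 4 * (var_t + lambda) / (dev2 + 2 * var_t + 2 * lambda)
  sigmoid(1 / e_min)
}

# ------------------------------------------------------------------ SPP ----

new_spp <- function(c1, c2, kernels = c(5L, 9L, 13L)) {
  if (any(kernels %% 2L == 0L)) stop("SPP: pooling kernels must be odd", call. = FALSE)
  ch <- c1 %/% 2L
  list(type = "spp",
       cv1 = new_conv_unit(c1, ch, 1L),
       cv2 = new_conv_unit(ch * (length(kernels) + 1L), c2, 1L),
       kernels = as.integer(kernels), c1 = c1, c2 = c2)
}

#' Spatial pyramid pooling forward pass
#'
#' Parallel same-padded max-pools at the configured kernel sizes are
#' concatenated with the identity path and projected by a 1x1 convolution;
#' spatial dims are preserved.
#'
#' @param x feature map.
#' @param block an SPP block, or `NULL` to draw one (`c2 = 2 * C`) from the
#'   current RNG.
#' @param kernels odd pooling kernel sizes used when building fresh.
#' @export
spp_forward <- function(x, block = NULL, kernels = c(5L, 9L, 13L)) {
  assert_feature_map(x)
  if (is.null(block)) block <- new_spp(dim(x)[3], 2L * dim(x)[3], kernels)
  y <- forward_conv_unit(block$cv1, x)
  pooled <- lapply(block$kernels, function(k) maxpool2d(y, k))
  forward_conv_unit(block$cv2, channel_concat(c(list(y), pooled)))
}

# ------------------------------------------------------------------ rep ----

new_rep_block <- function(c1, c2, stride = 2L, act = "silu") {
  # Multi-branch training form: dense 3x3 + 1x1, each conv+BN; an identity
  # BN branch exists only when shapes permit (c1 == c2 and stride 1).
  list(type = "rep", deploy = FALSE,
       w3 = he_init(3L, 3L, c1, c2), bn3 = new_bn(c2),
       w1 = he_init(1L, 1L, c1, c2), bn1 = new_bn(c2),
       bnid = if (c1 == c2 && stride == 1L) new_bn(c2) else NULL,
       stride = as.integer(stride), act = act, c1 = as.integer(c1), c2 = as.integer(c2))
}

forward_rep <- function(blk, x, pre_activation = FALSE) {
  if (isTRUE(blk$deploy)) {
    y <- conv2d(x, blk$w, blk$bias, blk$stride, 1L)
  } else {
    y <- bn_forward(conv2d(x, blk$w3, NULL, blk$stride, 1L), blk$bn3) +
         bn_forward(conv2d(x, blk$w1, NULL, blk$stride, 0L), blk$bn1)
    if (!is.null(blk$bnid)) y <- y + bn_forward(x, blk$bnid)
  }
  if (pre_activation) y else apply_activation(y, blk$act)
}

# --------------------------------------------------------------- detect ----

new_detect <- function(cins, nc, anchors, strides) {
  no <- 3L * (5L + nc)
  list(type = "detect",
       convs = lapply(cins, function(ci) new_conv_unit(ci, no, 1L, bn = FALSE, bias = TRUE, act = "none")),
       nc = as.integer(nc), anchors = anchors, strides = as.integer(strides))
}

forward_detect <- function(blk, xs) {
  lapply(seq_along(xs), function(i) forward_conv_unit(blk$convs[[i]], xs[[i]]))
}
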