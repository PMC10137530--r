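# Low-level dense tensor ops on (H, W, C) numeric arrays.
#
# Feature maps are plain R arrays in H-fastest (column-major) order; all
# convolutions are expressed as a small number of BLAS matrix products
# (one per kernel offset) rather than an explicit im2col buffer, which keeps
# peak memory proportional to a single feature map.

#' Create a feature map
#'
#' A feature map is a numeric array of dimension `H x W x C` with finite
#' values. This is the common currency of every block in the package.
#'
#' @param values numeric vector (recycled in column-major order) or array.
#' @param H,W,C spatial height, width and channel count (all >= 1).
#' @return a numeric array of dimension `c(H, W, C)`.
#' @export
#' @examples
#' x <- feature_map(rnorm(2 * 2 * 3), 2, 2, 3)
#' dim(x)
feature_map <- function(values, H, W, C) {
  stopifnot(H >= 1, W >= 1, C >= 1)
  x <- array(as.numeric(values), dim = c(H, W, C))
  assert_feature_map(x)
  x
}

assert_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be a 3-d array (H, W, C)", call. = FALSE)
  if (any(dim(x) < 1L)) stop("feature map dims must be >= 1", call. = FALSE)
  if (!all(is.finite(x))) stop("feature map values must be finite", call. = FALSE)
  invisible(x)
}

pad_hw <- function(x, ph, pw = ph, value = 0) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2 * ph, d[2] + 2 * pw, d[3]))
  out[(ph + 1):(ph + d[1]), (pw + 1):(pw + d[2]), ] <- x
  out
}

#' 2-d convolution (cross-correlation) on an (H, W, C) array
#'
#' @param x input array `(H, W, C)`.
#' @param w kernel array `(kh, kw, C/groups, Cout)`.
#' @param bias optional length-`Cout` bias vector.
#' @param stride integer stride (same in both spatial dims).
#' @param pad zero padding; default `kh %/% 2` ("same" for odd kernels).
#' @param groups group count; `C` must be `groups * dim(w)[3]`.
#' @return array `(Hout, Wout, Cout)`.
#' @keywords internal
conv2d <- function(x, w, bias = NULL, stride = 1L, pad = NULL, groups = 1L) {
  d <- dim(x)
  kh <- dim(w)[1]; kw <- dim(w)[2]; cing <- dim(w)[3]; cout <- dim(w)[4]
  if (is.null(pad)) pad <- kh %/% 2L
  if (d[3] != cing * groups)
    stop(sprintf("conv2d: input has %d channels but kernel expects %d (groups=%d)",
                 d[3], cing * groups, groups), call. = FALSE)
  if (cout %% groups != 0) stop("conv2d: output channels not divisible by groups", call. = FALSE)
  xp <- pad_hw(x, pad)
  ho <- (d[1] + 2 * pad - kh) %/% stride + 1L
  wo <- (d[2] + 2 * pad - kw) %/% stride + 1L
  rows <- seq.int(1L, by = stride, length.out = ho)
  cols <- seq.int(1L, by = stride, length.out = wo)
  coutg <- cout %/% groups
  out <- matrix(0, ho * wo, cout)
  gin <- split(seq_len(d[3]), rep(seq_len(groups), each = cing))
  gout <- split(seq_len(cout), rep(seq_len(groups), each = coutg))
  for (di in seq_len(kh)) {
    ri <- rows + di - 1L
    for (dj in seq_len(kw)) {
      sl <- xp[ri, cols + dj - 1L, , drop = FALSE]
      dim(sl) <- c(ho * wo, d[3])
      if (groups == 1L) {
        wm <- w[di, dj, , ]
        dim(wm) <- c(cing, cout)
        out <- out + sl %*% wm
      } else {
        for (g in seq_len(groups)) {
          wm <- w[di, dj, , gout[[g]]]
          dim(wm) <- c(cing, coutg)
          out[, gout[[g]]] <- out[, gout[[g]]] + sl[, gin[[g]], drop = FALSE] %*% wm
        }
      }
    }
  }
  if (!is.null(bias)) out <- out + rep(bias, each = ho * wo)
  dim(out) <- c(ho, wo, cout)
  out
}

#' Max pooling with "same"-style padding
#' @keywords internal
maxpool2d <- function(x, k, stride = 1L, pad = k %/% 2L) {
  d <- dim(x)
  xp <- pad_hw(x, pad, value = -Inf)
  ho <- (d[1] + 2 * pad - k) %/% stride + 1L
  wo <- (d[2] + 2 * pad - k) %/% stride + 1L
  rows <- seq.int(1L, by = stride, length.out = ho)
  cols <- seq.int(1L, by = stride, length.out = wo)
  out <- NULL
  for (di in seq_len(k)) {
    ri <- rows + di - 1L
    for (dj in seq_len(k)) {
      sl <- xp[ri, cols + dj - 1L, , drop = FALSE]
      out <- if (is.null(out)) sl else pmax(out, sl)
    }
  }
  out
}

upsample_nearest2x <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)

apply_activation <- function(x, act) {
  switch(act,
    silu = silu(x),
    relu = pmax(x, 0),
    none = x,
    stop("unknown activation: ", act, call. = FALSE))
}

# Batch normalization in inference form, per channel.
bn_apply <- function(x, bn) {
  scale <- bn$gamma / sqrt(bn$var + bn$eps)
  shift <- bn$beta - bn$mean * scale
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3])
  xm <- xm * rep(scale, each = d[1] * d[2]) + rep(shift, each = d[1] * d[2])
  dim(xm) <- d
  xm
}

channel_concat <- function(xs) {
  d1 <- dim(xs[[1]])
  for (x in xs[-1])
    if (!identical(dim(x)[1:2], d1[1:2]))
      stop("channel_concat: spatial dims disagree", call. = FALSE)
  array(unlist(xs, use.names = FALSE),
        c(d1[1], d1[2], sum(vapply(xs, function(x) dim(x)[3], 1L))))
}
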