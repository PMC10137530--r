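# Structural re-parameterization: collapse the multi-branch rep blocks used
# at training time into single 3x3 convolutions for inference. Equivalence
# is algebraic (conv and BN are both affine), so fused and multi-branch
# paths agree up to floating-point rounding; tests assert 1e-5 per block and
# 1e-4 for a whole model.

#' Fuse a convolution with its batch normalization
#'
#' Returns weights and bias of the single convolution equivalent to
#' conv -> BN on all inputs: with `s = gamma / sqrt(var + eps)`, the fused
#' kernel is the original scaled by `s` per output channel and the fused
#' bias is `(bias - mean) * s + beta`.
#'
#' @param w conv kernel array `(kh, kw, cin, cout)`.
#' @param bn batch-norm statistics (`gamma`, `beta`, `mean`, `var`, `eps`).
#' @param bias optional original conv bias (default zero).
#' @return list with elements `w` and `bias`.
#' @export
fuse_conv_bn <- function(w, bn, bias = NULL) {
  if (any(bn$var + bn$eps <= 0))
    stop("fuse_conv_bn: non-positive variance + epsilon", call. = FALSE)
  cout <- dim(w)[4]
  if (is.null(bias)) bias <- rep(0, cout)
  s <- bn$gamma / sqrt(bn$var + bn$eps)
  wf <- sweep(w, 4, s, `*`)
  list(w = wf, bias = (bias - bn$mean) * s + bn$beta)
}

pad_1x1_to_3x3 <- function(w1) {
  d <- dim(w1)
  w <- array(0, c(3L, 3L, d[3], d[4]))
  w[2L, 2L, , ] <- w1[1L, 1L, , ]
  w
}

identity_kernel_3x3 <- function(c) {
  w <- array(0, c(3L, 3L, c, c))
  for (i in seq_len(c)) w[2L, 2L, i, i] <- 1
  w
}

#' Collapse a rep block into a single 3x3 convolution
#'
#' BN-fuses each branch, pads the 1x1 kernel to 3x3, renders the identity
#' branch (when present) as a centered unit kernel, and sums kernels and
#' biases. The fused convolution reproduces the pre-activation sum of the
#' branch outputs on all inputs.
#'
#' @param blk a rep block in training form.
#' @return the same block with `deploy = TRUE`, carrying the fused `w` and
#'   `bias` (a `FusedConv`); branch weights are dropped.
#' @export
collapse_rep_block <- function(blk) {
  if (!identical(blk$type, "rep")) stop("collapse_rep_block: not a rep block", call. = FALSE)
  if (isTRUE(blk$deploy)) return(blk)
  if (!is.null(blk$bnid) && (blk$c1 != blk$c2 || blk$stride != 1L))
    stop("collapse_rep_block: identity branch present despite channel/stride mismatch",
         call. = FALSE)
  f3 <- fuse_conv_bn(blk$w3, blk$bn3)
  f1 <- fuse_conv_bn(pad_1x1_to_3x3(blk$w1), blk$bn1)
  w <- f3$w + f1$w
  b <- f3$bias + f1$bias
  if (!is.null(blk$bnid)) {
    fid <- fuse_conv_bn(identity_kernel_3x3(blk$c1), blk$bnid)
    w <- w + fid$w
    b <- b + fid$bias
  }
  list(type = "rep", deploy = TRUE, w = w, bias = b,
       stride = blk$stride, act = blk$act, c1 = blk$c1, c2 = blk$c2)
}

#' Convert a model to its deployment form
#'
#' Replaces every rep block by its fused single 3x3 convolution (see
#' [collapse_rep_block()]); all other layers are untouched, so models
#' without rep blocks are returned unchanged. The conversion is idempotent.
#' Whole-model outputs agree with the training form within float tolerance,
#' and the deployment parameter count is strictly lower whenever at least
#' one rep block exists.
#'
#' @param model a model from [build_model()].
#' @return the converted model.
#' @export
convert_model_to_deploy <- function(model) {
  stopifnot(inherits(model, "glyo_model"))
  for (i in seq_along(model$layers)) {
    blk <- model$layers[[i]]$block
    if (identical(blk$type, "rep") && !isTRUE(blk$deploy))
      model$layers[[i]]$block <- collapse_rep_block(blk)
  }
  model$mode <- "deploy"
  model
}
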