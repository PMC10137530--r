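# Parameter and FLOP accounting.
#
# Two conventions coexist (the literature mixes them) and both are exposed:
#   A  analytic conv-unit calculus: Parameters = n (h w c + 1),
#      FLOPs = H W n (h w c + 1) -- one op per multiply-accumulate, +1 for
#      the bias, H/W the *output* map dims.
#   B  profiler convention used for the whole-model table numbers: 2 ops per
#      multiply-accumulate over MAC-bearing operations (convolutions and the
#      CoT neighborhood aggregation); BN, activations, pooling, upsampling
#      and concatenation count zero.
# Model parameter counts sum learnable elements only: conv kernels, biases
# and BN gamma/beta (running statistics are buffers, not parameters).

#' Analytic conv-unit spec for the parameter/FLOP calculus
#'
#' @param h,w kernel height and width.
#' @param c input channels.
#' @param n output channels.
#' @return an object of class `conv_unit_spec`.
#' @export
#' @examples
#' count_parameters(conv_unit_spec(3, 3, 3, 32))      # 896
#' count_flops(conv_unit_spec(3, 3, 3, 32), 320, 320) # 91,750,400
conv_unit_spec <- function(h, w, c, n) {
  stopifnot(h >= 1, w >= 1, c >= 1, n >= 1)
  structure(list(h = h, w = w, c = c, n = n), class = "conv_unit_spec")
}

#' Count parameters
#'
#' For a [conv_unit_spec()], the analytic count `n * (h * w * c + 1)`; for a
#' model, the sum of all learnable elements (BN affine terms included).
#'
#' @param x a `conv_unit_spec` or `glyo_model`.
#' @param ... unused.
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.conv_unit_spec <- function(x, ...) x$n * (x$h * x$w * x$c + 1)

#' @export
count_parameters.glyo_model <- function(x, ...) {
  sum(vapply(x$layers, function(ly) block_params(ly$block), 0)) +
    block_params(x$detect)
}

#' Analytic FLOP count of a conv unit (convention A)
#'
#' `FLOPs = H * W * n * (h * w * c + 1)` with `H`, `W` the output map dims.
#'
#' @param spec a [conv_unit_spec()].
#' @param out_h,out_w output feature-map height and width.
#' @export
count_flops <- function(spec, out_h, out_w) {
  stopifnot(inherits(spec, "conv_unit_spec"), out_h >= 1, out_w >= 1)
  out_h * out_w * spec$n * (spec$h * spec$w * spec$c + 1)
}

# ------------------------------------------------------------------------
# learnable parameter count per block

bn_params <- function(bn) if (is.null(bn)) 0 else 2 * length(bn$gamma)

conv_params <- function(b) length(b$w) + length(b$bias) + bn_params(b$bn)

block_params <- function(blk) {
  switch(blk$type,
    conv = conv_params(blk),
    focus = conv_params(blk$conv),
    stem = conv_params(blk$conv1) + conv_params(blk$br1) +
           conv_params(blk$br2) + conv_params(blk$proj),
    bottleneck = conv_params(blk$cv1) + conv_params(blk$cv2),
    cot_bottleneck = conv_params(blk$cv1) + block_params(blk$cot),
    cot = conv_params(blk$key) + conv_params(blk$value) +
          conv_params(blk$att1) + conv_params(blk$att2),
    c3 = ,
    cot3 = conv_params(blk$cv1) + conv_params(blk$cv2) + conv_params(blk$cv3) +
           sum(vapply(blk$m, block_params, 0)),
    spp = conv_params(blk$cv1) + conv_params(blk$cv2),
    rep = if (isTRUE(blk$deploy)) length(blk$w) + length(blk$bias)
          else length(blk$w3) + bn_params(blk$bn3) +
               length(blk$w1) + bn_params(blk$bn1) + bn_params(blk$bnid),
    simam = 0,
    concat = 0,
    upsample = 0,
    detect = sum(vapply(blk$convs, conv_params, 0)),
    stop("block_params: unknown type ", blk$type, call. = FALSE))
}

# ------------------------------------------------------------------------
# MACs (convention B counts 2 * macs) and convention-A FLOPs per block,
# given the block's *input* spatial dims. Returns out dims as well.

conv_cost <- function(b, h, w) {
  ho <- (h + 2L * b$pad - b$k) %/% b$stride + 1L
  wo <- (w + 2L * b$pad - b$k) %/% b$stride + 1L
  cing <- b$c1 %/% b$groups
  list(macs = as.numeric(ho) * wo * b$k * b$k * cing * b$c2,
       flops_a = as.numeric(ho) * wo * b$c2 * (b$k * b$k * cing + 1),
       h = ho, w = wo)
}

add_cost <- function(a, b) list(macs = a$macs + b$macs, flops_a = a$flops_a + b$flops_a,
                                h = b$h, w = b$w)

block_cost <- function(blk, h, w, c) {
  zero <- function(h, w) list(macs = 0, flops_a = 0, h = h, w = w)
  switch(blk$type,
    conv = conv_cost(blk, h, w),
    focus = {
      cc <- conv_cost(blk$conv, h %/% 2L, w %/% 2L)
      cc
    },
    stem = {
      c1 <- conv_cost(blk$conv1, h, w)
      b1 <- conv_cost(blk$br1, c1$h, c1$w)
      b2 <- conv_cost(blk$br2, b1$h, b1$w)
      pj <- conv_cost(blk$proj, b2$h, b2$w)
      add_cost(add_cost(add_cost(c1, b1), b2), pj)
    },
    bottleneck = add_cost(conv_cost(blk$cv1, h, w), conv_cost(blk$cv2, h, w)),
    cot_bottleneck = add_cost(conv_cost(blk$cv1, h, w), block_cost(blk$cot, h, w, NULL)),
    cot = {
      agg <- blk$k * blk$k * as.numeric(h) * w * blk$c    # neighborhood aggregation MACs
      base <- Reduce(add_cost, list(conv_cost(blk$key, h, w), conv_cost(blk$value, h, w),
                                    conv_cost(blk$att1, h, w), conv_cost(blk$att2, h, w)))
      list(macs = base$macs + agg, flops_a = base$flops_a + agg, h = h, w = w)
    },
    c3 = ,
    cot3 = {
      parts <- c(list(conv_cost(blk$cv1, h, w), conv_cost(blk$cv2, h, w)),
                 lapply(blk$m, block_cost, h = h, w = w, c = NULL),
                 list(conv_cost(blk$cv3, h, w)))
      Reduce(add_cost, parts)
    },
    spp = add_cost(conv_cost(blk$cv1, h, w), conv_cost(blk$cv2, h, w)),
    rep = {
      if (isTRUE(blk$deploy)) {
        ho <- (h + 2L - 3L) %/% blk$stride + 1L; wo <- (w + 2L - 3L) %/% blk$stride + 1L
        list(macs = as.numeric(ho) * wo * 9 * blk$c1 * blk$c2,
             flops_a = as.numeric(ho) * wo * blk$c2 * (9 * blk$c1 + 1), h = ho, w = wo)
      } else {
        ho <- (h + 2L - 3L) %/% blk$stride + 1L; wo <- (w + 2L - 3L) %/% blk$stride + 1L
        list(macs = as.numeric(ho) * wo * (9 + 1) * blk$c1 * blk$c2,
             flops_a = as.numeric(ho) * wo * blk$c2 * (10 * blk$c1 + 2), h = ho, w = wo)
      }
    },
    simam = zero(h, w),
    concat = zero(h, w),
    upsample = zero(2L * h, 2L * w),
    stop("block_cost: unknown type ", blk$type, call. = FALSE))
}

#' Profile a model: parameters and FLOPs under both conventions
#'
#' Walks the graph with symbolic shapes (no data pass). Reports the total
#' learnable parameter count, the convention-B profiler FLOPs (2 ops per
#' multiply-accumulate at the given input size) and the convention-A
#' analytic total, plus a per-layer table.
#'
#' @param model a `glyo_model`.
#' @param img_size input size; defaults to the model's build size.
#' @return a list of class `glyo_profile` with `params`, `params_m`
#'   (millions, 2 d.p.), `macs`, `gflops` (convention B, 1 d.p.),
#'   `flops_a`, and `per_layer`.
#' @export
profile_model <- function(model, img_size = NULL) {
  stopifnot(inherits(model, "glyo_model"))
  if (is.null(img_size)) img_size <- model$img_size
  n <- length(model$layers)
  hh <- integer(n); ww <- integer(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ly <- model$layers[[i]]
    h1 <- if (ly$idx == 0L) img_size else hh[ly$from[1] + 1L]
    w1 <- if (ly$idx == 0L) img_size else ww[ly$from[1] + 1L]
    cost <- block_cost(ly$block, h1, w1, NULL)
    hh[i] <- cost$h; ww[i] <- cost$w
    rows[[i]] <- data.frame(layer = ly$idx, module = ly$name,
                            params = block_params(ly$block),
                            macs = cost$macs, flops_a = cost$flops_a)
  }
  det_macs <- 0; det_fa <- 0
  for (s in seq_along(model$detect_from)) {
    f <- model$detect_from[s] + 1L
    cc <- conv_cost(model$detect$convs[[s]], hh[f], ww[f])
    det_macs <- det_macs + cc$macs; det_fa <- det_fa + cc$flops_a
  }
  rows[[n + 1L]] <- data.frame(layer = NA_integer_, module = "detect",
                               params = block_params(model$detect),
                               macs = det_macs, flops_a = det_fa)
  per <- do.call(rbind, rows)
  params <- sum(per$params); macs <- sum(per$macs)
  structure(list(params = params, params_m = round(params / 1e6, 2),
                 macs = macs, gflops = round(2 * macs / 1e9, 1),
                 flops_a = sum(per$flops_a), img_size = img_size,
                 per_layer = per),
            class = "glyo_profile")
}

#' @export
print.glyo_profile <- function(x, ...) {
  cat(sprintf("parameters: %d (%.2f M)\n", x$params, x$params_m))
  cat(sprintf("FLOPs @%d: %.1f G (profiler, 2 ops/MAC)  |  %.3f G (analytic calculus)\n",
              x$img_size, x$gflops, x$flops_a / 1e9))
  invisible(x)
}
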