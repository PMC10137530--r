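# Model assembly from declarative layer tables.
#
# An architecture config is data, not code: a list of rows
# [from, number, module, args] mirroring the published layer tables, plus
# nc, width/depth multiples, anchors and the detect taps. Shipped configs
# live under inst/configs (yolov5s, gl_yolo, gl_yolo_stem, gl_yolo_lite and
# a reduced gl_yolo_lite_tiny for CPU-scale experiments).

MODULE_REGISTRY <- c("focus", "stem", "conv", "rep", "c3", "cot3", "spp",
                     "simam", "concat", "upsample")

normalize_module_name <- function(name) {
  n <- tolower(gsub("[ _.-]|block|nn\\.", "", name))
  n <- switch(n, upsample = "upsample", up = "upsample", n)
  if (!n %in% MODULE_REGISTRY)
    stop("unknown module name: ", name, call. = FALSE)
  n
}

make_divisible <- function(x, divisor = 8L) as.integer(ceiling(x / divisor) * divisor)

#' Read an architecture config
#'
#' @param path a YAML file or a named config of the installed package (e.g.
#'   `"gl_yolo_lite"`, resolved under `inst/configs`).
#' @return the config list (`nc`, `depth_multiple`, `width_multiple`,
#'   `anchors`, `layers`, `detect`).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("configs", paste0(path, ".yaml"), package = "glyolite")
    if (nzchar(shipped)) path <- shipped
    else stop("config not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$layers) || length(cfg$layers) == 0L)
    stop("config error: empty layer table", call. = FALSE)
  for (i in seq_along(cfg$layers)) {
    row <- cfg$layers[[i]]
    if (length(row) < 4L)
      stop("config error at layer ", i - 1L, ": row needs [from, number, module, args]",
           call. = FALSE)
    from <- unlist(row[[1]])
    idx <- i - 1L
    abs_from <- ifelse(from < 0, idx + from, from)
    if (any(abs_from >= idx) || any(abs_from < if (idx == 0L) -1L else 0L))
      stop("config error at layer ", idx, ": dangling input ref", call. = FALSE)
    normalize_module_name(row[[3]])   # errors on unknown modules
  }
  invisible(cfg)
}

resolve_from <- function(from, idx) {
  from <- unlist(from)
  as.integer(ifelse(from < 0, idx + from, from))
}

#' Build a runnable detection model from a layer table
#'
#' Instantiates every row of the config into a block (weights drawn
#' deterministically under `seed`), tracks channels, spatial shapes and
#' strides, and attaches the detection head to the configured taps, with the
#' nine anchors sorted by ascending area and grouped three per scale in
#' ascending-stride order.
#'
#' @param cfg a config list or a name/path accepted by [read_model_config()].
#' @param nc number of classes; overrides the config value when given.
#' @param img_size network input size (square), default from config or 640.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `glyo_model`.
#' @export
build_model <- function(cfg, nc = NULL, img_size = NULL, seed = 0L) {
  if (is.character(cfg)) cfg <- read_model_config(cfg)
  validate_config(cfg)
  nc <- as.integer(if (is.null(nc)) cfg$nc else nc)
  img_size <- as.integer(if (is.null(img_size)) { if (is.null(cfg$img_size)) 640L else cfg$img_size } else img_size)
  gd <- if (is.null(cfg$depth_multiple)) 1 else cfg$depth_multiple
  gw <- if (is.null(cfg$width_multiple)) 1 else cfg$width_multiple
  cw <- function(x) make_divisible(x * gw, 8L)

  set.seed(seed)
  layers <- vector("list", length(cfg$layers))
  ch <- integer(length(cfg$layers))       # output channels per layer
  hh <- integer(length(cfg$layers)); ww <- integer(length(cfg$layers))
  in_ch <- 3L
  for (i in seq_along(cfg$layers)) {
    row <- cfg$layers[[i]]
    idx <- i - 1L
    from <- resolve_from(row[[1]], idx)
    n_nominal <- as.integer(row[[2]])
    mod <- normalize_module_name(row[[3]])
    args <- row[[4]]
    c1 <- if (idx == 0L) in_ch else ch[from[1] + 1L]
    h1 <- if (idx == 0L) img_size else hh[from[1] + 1L]
    w1 <- if (idx == 0L) img_size else ww[from[1] + 1L]
    n <- if (mod %in% c("c3", "cot3")) max(1L, as.integer(round(n_nominal * gd))) else 1L
    blk <- switch(mod,
      focus = new_focus(c1, cw(args[[1]]), as.integer(args[[2]])),
      stem  = new_stem(c1, cw(args[[1]])),
      conv  = new_conv_unit(c1, cw(args[[1]]), as.integer(args[[2]]),
                            stride = if (length(args) >= 3L) as.integer(args[[3]]) else 1L),
      rep   = new_rep_block(c1, cw(args[[1]]),
                            stride = if (length(args) >= 3L) as.integer(args[[3]]) else 2L),
      c3    = new_c3(c1, cw(args[[1]]), n,
                     shortcut = !(length(args) >= 2L && identical(args[[2]], FALSE))),
      cot3  = new_c3(c1, cw(args[[1]]), n,
                     shortcut = !(length(args) >= 2L && identical(args[[2]], FALSE)), cot = TRUE),
      spp   = new_spp(c1, cw(args[[1]]), as.integer(unlist(args[[2]]))),
      simam = list(type = "simam", lambda = if (length(args) >= 2L) args[[2]] else 1e-4),
      concat = {
        cc <- sum(ch[from + 1L])
        list(type = "concat", c2 = cc)
      },
      upsample = list(type = "upsample"))
    pr <- block_shape(blk, h1, w1, c1)
    ch[i] <- pr$c; hh[i] <- pr$h; ww[i] <- pr$w
    layers[[i]] <- list(idx = idx, from = from, name = mod, n = n, block = blk)
  }
  detect_from <- as.integer(unlist(cfg$detect))
  if (is.null(detect_from) || length(detect_from) != 3L)
    stop("config error: detect must list three source layers", call. = FALSE)
  strides <- img_size %/% hh[detect_from + 1L]
  anc <- matrix(unlist(cfg$anchors), ncol = 2L, byrow = TRUE)
  if (nrow(anc) != 9L) stop("config error: nine anchors required", call. = FALSE)
  anc <- anc[order(anc[, 1] * anc[, 2]), , drop = FALSE]
  ord <- order(strides)
  anchors <- vector("list", 3L)
  for (s in 1:3) anchors[[ord[s]]] <- anc[(s - 1L) * 3L + 1:3, , drop = FALSE]
  det <- new_detect(ch[detect_from + 1L], nc, anchors, strides)
  structure(list(layers = layers, detect = det, detect_from = detect_from,
                 nc = nc, img_size = img_size, seed = seed, mode = "train",
                 name = if (is.null(cfg$name)) "model" else cfg$name,
                 channels = ch, heights = hh, widths = ww),
            class = "glyo_model")
}

# Output shape of a block given input (h, w, c); mirrors each forward.
block_shape <- function(blk, h, w, c) {
  switch(blk$type,
    conv = {
      s <- blk$stride
      list(h = (h + 2L * blk$pad - blk$k) %/% s + 1L,
           w = (w + 2L * blk$pad - blk$k) %/% s + 1L, c = blk$c2)
    },
    focus = list(h = h %/% 2L, w = w %/% 2L, c = blk$conv$c2),
    stem = list(h = h %/% 4L, w = w %/% 4L, c = blk$c2),
    rep = list(h = (h + 2L - 3L) %/% blk$stride + 1L,
               w = (w + 2L - 3L) %/% blk$stride + 1L, c = blk$c2),
    c3 = ,
    cot3 = list(h = h, w = w, c = blk$c2),
    spp = list(h = h, w = w, c = blk$c2),
    simam = list(h = h, w = w, c = c),
    concat = list(h = h, w = w, c = blk$c2),
    upsample = list(h = 2L * h, w = 2L * w, c = c),
    stop("block_shape: unknown type ", blk$type, call. = FALSE))
}

forward_layer <- function(blk, inputs) {
  switch(blk$type,
    conv = forward_conv_unit(blk, inputs[[1]]),
    focus = focus_forward(inputs[[1]], blk$conv),
    stem = stem_forward(inputs[[1]], blk),
    rep = forward_rep(blk, inputs[[1]]),
    c3 = ,
    cot3 = forward_c3(blk, inputs[[1]]),
    spp = spp_forward(inputs[[1]], blk),
    simam = simam_forward(inputs[[1]], blk$lambda),
    concat = channel_concat(inputs),
    upsample = upsample_nearest2x(inputs[[1]]),
    stop("forward_layer: unknown type ", blk$type, call. = FALSE))
}

#' Run a model forward
#'
#' @param model a `glyo_model`.
#' @param x input feature map `(H, W, 3)`, typically letterboxed to the
#'   model input size.
#' @param features if `TRUE`, return the feature maps feeding the detection
#'   head instead of applying the head convolutions.
#' @param capture optional vector of layer indices whose outputs are
#'   returned instead (internal caching aid for training).
#' @return a list of three raw head outputs (or feature maps), one per
#'   detection scale, ascending stride.
#' @export
model_forward <- function(model, x, features = FALSE, capture = NULL) {
  assert_feature_map(x)
  cache <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    inputs <- if (ly$idx == 0L) list(x) else lapply(ly$from, function(f) cache[[f + 1L]])
    cache[[i]] <- forward_layer(ly$block, inputs)
  }
  if (!is.null(capture)) return(lapply(capture, function(f) cache[[f + 1L]]))
  feats <- lapply(model$detect_from, function(f) cache[[f + 1L]])
  if (features) feats else forward_detect(model$detect, feats)
}

#' @export
print.glyo_model <- function(x, ...) {
  p <- profile_model(x)
  cat(sprintf("<glyo_model '%s'> %d layers + detect, %d classes, input %d, mode=%s\n",
              x$name, length(x$layers), x$nc, x$img_size, x$mode))
  cat(sprintf("  parameters: %.2f M   GFLOPs (2 ops/MAC @%d): %.1f\n",
              p$params_m, x$img_size, p$gflops))
  invisible(x)
}

#' Calibrate batch-norm statistics on sample inputs
#'
#' Runs the given inputs through the network while replacing every batch
#' norm's running mean/variance with the observed activation statistics (a
#' data-dependent initialization in the LSUV spirit). Without this, a
#' randomly initialized deep stack under identity BN statistics lets
#' activation variance collapse with depth, which starves the SiLU
#' nonlinearities and impoverishes the features; after calibration every
#' stage sees approximately standardized inputs. Statistics are updated in
#' place; the model is also returned invisibly.
#'
#' @param model a `glyo_model`.
#' @param inputs list of input arrays (or a single array).
#' @export
calibrate_model <- function(model, inputs) {
  if (!is.list(inputs)) inputs <- list(inputs)
  .glyo_state$calibrating <- TRUE
  on.exit(.glyo_state$calibrating <- FALSE)
  for (x in inputs) model_forward(model, x, features = TRUE)
  invisible(model)
}
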