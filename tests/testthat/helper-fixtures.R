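# Shared fixtures: deterministic random feature maps and small label sets.

rand_fm <- function(H, W, C, seed = 1L) {
  set.seed(seed)
  feature_map(stats::rnorm(H * W * C), H, W, C)
}

# randomize BN statistics so conv/BN fusion tests are non-trivial
randomize_bn <- function(bn, seed = 1L) {
  set.seed(seed)
  n <- length(bn$gamma)
  bn$gamma <- stats::runif(n, 0.5, 1.5)
  bn$beta <- stats::rnorm(n)
  bn$mean <- stats::rnorm(n)
  bn$var <- stats::runif(n, 0.5, 2)
  bn
}

tiny_split <- function(n = 12L, size = 96L, seed = 3L, boxes = c(1L, 2L)) {
  generate_dataset(n, size, boxes, seed = seed,
                   out_dir = file.path(tempdir(), paste0("ds_", n, "_", size, "_", seed)))
}
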