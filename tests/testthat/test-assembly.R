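# Graph assembly from layer tables and the parameter/FLOP calculus.

test_that("analytic conv calculus reproduces the worked examples", {
  expect_equal(count_parameters(conv_unit_spec(3, 3, 3, 32)), 896)
  expect_equal(count_flops(conv_unit_spec(3, 3, 3, 32), 320, 320), 91750400)
  expect_equal(count_parameters(conv_unit_spec(3, 3, 12, 32)), 3488)
  expect_equal(count_flops(conv_unit_spec(3, 3, 12, 32), 320, 320), 357171200)
  expect_equal(count_parameters(conv_unit_spec(1, 1, 1, 1)), 2)
  expect_equal(count_flops(conv_unit_spec(1, 1, 1, 1), 1, 1), 2)
})

test_that("focus module costs about 3.9x the single stride-2 conv", {
  expect_equal(3488 / 896, 357171200 / 91750400)
  expect_equal(round(3488 / 896, 1), 3.9)
})

test_that("convention-A total of a pure-conv toy net is the hand sum", {
  cfg <- list(nc = 1, anchors = list(c(10, 13, 16, 30, 33, 23),
                                     c(30, 61, 62, 45, 59, 119),
                                     c(116, 90, 156, 198, 373, 326)),
              layers = list(list(-1, 1, "Conv", c(8, 3, 2)),
                            list(-1, 1, "Conv", c(16, 3, 2)),
                            list(-1, 1, "Conv", c(32, 3, 2))),
              detect = c(0, 1, 2), img_size = 64)
  m <- build_model(cfg, seed = 0)
  p <- profile_model(m, img_size = 64)
  hand <- count_flops(conv_unit_spec(3, 3, 3, 8), 32, 32) +
          count_flops(conv_unit_spec(3, 3, 8, 16), 16, 16) +
          count_flops(conv_unit_spec(3, 3, 16, 32), 8, 8)
  conv_rows <- p$per_layer$module == "conv"
  expect_equal(sum(p$per_layer$flops_a[conv_rows]), hand)
})

test_that("profiler convention B is about twice convention A on conv graphs", {
  p <- profile_model(build_model("yolov5s", nc = 20))
  expect_equal(2 * p$macs / p$flops_a, 2, tolerance = 0.05)
})

test_that("the lite table builds 25 graph nodes with the expected modules", {
  m <- build_model("gl_yolo_lite", nc = 20)
  expect_length(m$layers, 25L)
  expect_equal(m$layers[[1]]$name, "stem")
  expect_equal(m$layers[[25]]$name, "simam")
  expect_equal(vapply(m$layers[2 + c(0, 2, 4, 6)], `[[`, "", "name"),
               rep("rep", 4))
  # head channels follow the 128-nominal-width table at width multiple 0.5
  expect_equal(m$channels[14], 64L)
  expect_equal(m$channels[24], 64L)
})

test_that("config validation rejects malformed tables", {
  expect_error(build_model(list(layers = list()), seed = 0), "empty")
  bad <- list(nc = 1, layers = list(list(-1, 1, "Warp", c(8, 3))), detect = c(0, 0, 0))
  expect_error(build_model(bad, seed = 0), "unknown module")
  dangling <- list(nc = 1, layers = list(list(-1, 1, "Conv", c(8, 3, 2)),
                                         list(5, 1, "Conv", c(8, 3, 2))),
                   detect = c(0, 1, 1))
  expect_error(build_model(dangling, seed = 0), "dangling")
})

test_that("stride ledger: stem entry is stride 4 and lite strides double the baseline", {
  base <- build_model("yolov5s", nc = 20)
  lite <- build_model("gl_yolo_lite", nc = 20)
  expect_equal(base$detect$strides, c(8L, 16L, 32L))
  expect_equal(lite$detect$strides, c(16L, 32L, 64L))
  expect_equal(lite$heights[1], 160L)   # stem output at 640 input
})

test_that("anchors are grouped ascending by area across ascending strides", {
  m <- build_model("gl_yolo_lite_tiny", seed = 1)
  areas <- unlist(lapply(m$detect$anchors, function(a) a[, 1] * a[, 2]))
  expect_equal(areas, sort(areas))
})

test_that("profiled table cells match the published architecture numbers", {
  # deployment-mode profile (rep blocks fused), the tables' convention
  profile_cells <- function(name, nc) {
    m <- convert_model_to_deploy(build_model(name, nc = nc))
    p <- profile_model(m)
    c(p$params_m, p$gflops)
  }
  expect_equal(profile_cells("yolov5s", 20), c(7.11, 16.4))
  expect_equal(profile_cells("gl_yolo", 20), c(7.08, 16.4))
  expect_equal(profile_cells("gl_yolo_stem", 20)[2], 4.5)
  expect_equal(profile_cells("gl_yolo_lite", 20), c(4.42, 3.4))
  expect_equal(profile_cells("gl_yolo_lite", 1), c(4.41, 3.3))
})

test_that("SimAM layers contribute zero parameters in the profiler", {
  m <- build_model("gl_yolo_lite", nc = 20)
  per <- profile_model(m)$per_layer
  expect_equal(per$params[per$module == "simam"], 0)
  # removing the SimAM row (and re-pointing the detect tap) changes nothing
  cfg <- read_model_config("gl_yolo")
  cfg_nosim <- cfg
  cfg_nosim$layers <- cfg$layers[1:24]
  cfg_nosim$detect <- c(17, 20, 23)
  expect_equal(count_parameters(build_model(cfg, nc = 20)),
               count_parameters(build_model(cfg_nosim, nc = 20)))
})
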