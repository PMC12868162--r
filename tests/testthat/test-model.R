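# Detector assembly: stride contracts, ablation switches, determinism,
# parameter counting, checkpoints.

eng <- asNamespace("ivyolo")

test_that("configuration validates input size", {
  expect_error(ivyolo_config(input_size = 100), "divisible by 32")
  cfg <- ivyolo_config(input_size = 320, width = 0.25)
  expect_equal(cfg$channels, c(4, 8, 16, 32, 64))
  expect_equal(cfg$strides, c(8L, 16L, 32L))
})

test_that("backbone and neck obey the stride contract", {
  det <- build_model(tiny_model_config(), seed = 1)
  for (size in c(96, 160)) {
    img <- array(runif(size * size * 3), c(size, size, 3))
    pyr <- backbone_forward(img, det)
    expect_equal(dim(pyr$low)[1:2], c(size / 8, size / 8))
    expect_equal(dim(pyr$mid)[1:2], c(size / 16, size / 16))
    expect_equal(dim(pyr$high)[1:2], c(size / 32, size / 32))
    neck <- gfen_forward(pyr, det)
    for (s in 1:3)
      expect_equal(dim(neck[[s]])[1:2], rep(size / c(8, 16, 32)[s], 2))
    raw <- head_forward(neck, det)
    # single class: 4 box channels + 1 logit per cell
    for (s in 1:3) expect_equal(dim(raw[[s]])[3], 5L)
    expect_equal(prod(dim(raw[[1]])[1:2]), (size / 8)^2)
  }
  expect_error(backbone_forward(array(0, c(100, 100, 3)), det),
               "divisible")
})

test_that("model construction is deterministic in the seed", {
  d1 <- build_model(tiny_model_config(), seed = 5)
  d2 <- build_model(tiny_model_config(), seed = 5)
  d3 <- build_model(tiny_model_config(), seed = 6)
  f1 <- eng$flatten_params(eng$detector_modules(d1))
  f2 <- eng$flatten_params(eng$detector_modules(d2))
  f3 <- eng$flatten_params(eng$detector_modules(d3))
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  expect_identical(forward_detector(img, d1), forward_detector(img, d2))
})

test_that("ablation switches change the topology as intended", {
  cfg_full <- tiny_model_config()
  cfg_nomsiv <- tiny_model_config(use_msiv = FALSE)
  cfg_nogfen <- tiny_model_config(use_gfen = FALSE)
  det_full <- build_model(cfg_full, seed = 0)
  det_nomsiv <- build_model(cfg_nomsiv, seed = 0)
  det_nogfen <- build_model(cfg_nogfen, seed = 0)
  count_msiv_blocks <- function(det) {
    n <- sum(vapply(det$backbone$layers,
                    function(l) l$type == "msiv", logical(1)))
    if (det$neck$type == "gfen")
      n <- n + sum(vapply(c("ms_low", "ms_mid", "ms_f1", "ms_high"),
                          function(nm) det$neck[[nm]]$type == "msiv",
                          logical(1)))
    n
  }
  expect_gt(count_msiv_blocks(det_full), 0)
  expect_equal(count_msiv_blocks(det_nomsiv), 0)
  # removing MSIV strictly reduces the parameter count
  expect_lt(count_parameters(det_nomsiv), count_parameters(det_full))
  # the plain neck still honours strides
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  raw <- forward_detector(img, det_nogfen)
  expect_equal(sapply(raw, function(r) dim(r)[1]), c(12, 6, 3))
})

test_that("count_parameters agrees with hand counts on small modules", {
  set.seed(1)
  conv_nobias <- eng$mod_conv(1, 1, 3, act = FALSE, bias = FALSE)
  expect_equal(count_parameters(conv_nobias), 9L)
  conv_bias <- eng$mod_conv(2, 3, 3)
  expect_equal(count_parameters(conv_bias), 9L * 2L * 3L + 3L)
  # one MSIV block: attention projection (K*C + K) + DyT (2C + 1)
  C <- 6L; K <- 3L
  msiv <- eng$mod_msiv(C, K)
  expect_equal(count_parameters(msiv), K * C + K + 2L * C + 1L)
})

test_that("checkpoints round-trip parameters and configuration", {
  det <- build_model(tiny_model_config(num_classes = 2), seed = 3)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(det, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  det2 <- load_checkpoint(path)
  expect_identical(eng$flatten_params(eng$detector_modules(det)),
                   eng$flatten_params(eng$detector_modules(det2)))
  expect_equal(det2$config$num_classes, 2L)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  expect_identical(forward_detector(img, det),
                   forward_detector(img, det2))
  unlink(c(path, paste0(path, ".json")))
})

test_that("gradients from a scalar loss reach every pyramid level and all parameters", {
  det <- build_model(tiny_model_config(), seed = 2)
  mods <- eng$detector_modules(det)
  eng$zero_all_grads(mods)
  scenes <- tiny_scenes(1)
  raw <- forward_detector(scenes[[1]]$pixels, det)
  ls <- detection_loss(raw, scenes[[1]]$boxes)
  expect_gte(ls$total, 0)
  dimg <- eng$backward_detector(det, ls$draws)
  # gradient flowed all the way back to the image plane
  expect_true(any(dimg != 0))
  for (m in mods) for (nm in m$par_names) {
    g <- m[[paste0("g_", nm)]]
    expect_true(all(is.finite(g)))
    expect_true(any(g != 0))
  }
})
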