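# Detector assembly: backbone ("Conv k3 + C3K2 + MSIVConv" hierarchy),
# progressive-fusion neck (GFEN) or plain top-down neck, and an anchor-free
# three-scale head.

round4 <- function(x) max(4L, as.integer(round(x / 4) * 4))

#' Detector configuration
#'
#' The default configuration is the published scale of the detector: a
#' nano-class width (base channels 16/32/64/128/256, one bottleneck per C3K2
#' block, head hidden width 120), a single "panicle" class and 640-pixel
#' input. At this scale the full model (MSIV + GFEN enabled) carries
#' approximately 2.52 million trainable parameters; see [count_parameters()].
#'
#' @param input_size input resolution in pixels, divisible by 32.
#' @param num_classes number of object classes.
#' @param width width multiplier on the base channels (rounded to multiples
#'   of 4, minimum 4).
#' @param depth bottlenecks per C3K2 block.
#' @param use_msiv include MSIV blocks (`FALSE` removes every MSIV
#'   block, leaving the plain Conv + C3K2 topology with a concat-only
#'   neck — the "- MSIV" ablation).
#' @param use_gfen use the progressive-fusion neck (`FALSE` substitutes a
#'   plain top-down concat neck — the "- GFEN" ablation).
#' @param base_channels backbone stage widths before the multiplier.
#' @param head_hidden hidden width of the head stems before the multiplier.
#' @param msiv list of MSIV settings: `K`, `kernel_sizes`, `alpha_angle`,
#'   `beta_offset`, `mode`, `alpha_random`.
#' @return an object of class `ivyolo_config`.
#' @export
ivyolo_config <- function(input_size = 640L, num_classes = 1L, width = 1.0,
                          depth = 1L, use_msiv = TRUE, use_gfen = TRUE,
                          base_channels = c(16L, 32L, 64L, 128L, 256L),
                          head_hidden = 120L,
                          msiv = list()) {
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  msiv_defaults <- list(K = 3L, kernel_sizes = c(3L, 5L, 7L),
                        alpha_angle = 1.0, beta_offset = 2.0,
                        mode = "cyclic_shift", alpha_random = FALSE)
  msiv <- utils::modifyList(msiv_defaults, msiv)
  structure(list(input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 width = width, depth = as.integer(depth),
                 use_msiv = isTRUE(use_msiv), use_gfen = isTRUE(use_gfen),
                 base_channels = as.integer(base_channels),
                 head_hidden_base = as.integer(head_hidden),
                 channels = vapply(base_channels * width, round4, integer(1)),
                 head_hidden = round4(head_hidden * width),
                 strides = c(8L, 16L, 32L),
                 msiv = msiv),
            class = "ivyolo_config")
}

mod_identity <- function() mod_new("identity")

# An MSIV block when enabled; the identity otherwise, so the "- MSIV"
# ablation is the plain Conv + C3K2 topology with strictly fewer parameters.
msiv_or <- function(cfg, C) {
  if (cfg$use_msiv) {
    mod_msiv(C, K = cfg$msiv$K, kernel_sizes = cfg$msiv$kernel_sizes,
             alpha_angle = cfg$msiv$alpha_angle,
             beta_offset = cfg$msiv$beta_offset, mode = cfg$msiv$mode,
             alpha_random = cfg$msiv$alpha_random,
             seed = sample.int(.Machine$integer.max, 1L))
  } else {
    mod_identity()
  }
}

#' Build the detector
#'
#' Constructs the full detector from a configuration: a five-stage strided
#' backbone whose three deepest stages end in MSIV blocks, either the
#' two-stage progressive-fusion neck or a plain top-down neck, and the
#' three-scale anchor-free head. Construction is fully deterministic given
#' the seed.
#'
#' @param config an [ivyolo_config()].
#' @param seed integer seed for parameter initialization.
#' @return a detector object (class `ivyolo_model`).
#' @export
build_model <- function(config = ivyolo_config(), seed = 0L) {
  stopifnot(inherits(config, "ivyolo_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ch <- config$channels
  n <- config$depth
  bb <- mod_new("backbone",
                layers = list(
                  mod_conv(3L, ch[1], 3L, 2L),            # /2
                  mod_conv(ch[1], ch[2], 3L, 2L),         # /4
                  mod_c3k2(ch[2], ch[2], n),
                  mod_conv(ch[2], ch[3], 3L, 2L),         # /8
                  mod_c3k2(ch[3], ch[3], n),
                  msiv_or(config, ch[3]),                 # -> low tap
                  mod_conv(ch[3], ch[4], 3L, 2L),         # /16
                  mod_c3k2(ch[4], ch[4], n),
                  msiv_or(config, ch[4]),                 # -> mid tap
                  mod_conv(ch[4], ch[5], 3L, 2L),         # /32
                  mod_c3k2(ch[5], ch[5], n),
                  msiv_or(config, ch[5])),                # -> high tap
                taps = c(6L, 9L, 12L))
  if (config$use_gfen) {
    neck <- mod_new("gfen",
                    ms_low = msiv_or(config, ch[3]),
                    ms_mid = msiv_or(config, ch[4]),
                    down1 = mod_conv(ch[3], ch[4], 3L, 2L),
                    fuse1 = mod_c3k2(2L * ch[4], ch[4], n),
                    ms_f1 = msiv_or(config, ch[4]),
                    ms_high = msiv_or(config, ch[5]),
                    down2 = mod_conv(ch[4], ch[5], 3L, 2L),
                    fuse2 = mod_c3k2(2L * ch[5], ch[5], n),
                    c3 = ch[3], c4 = ch[4], c5 = ch[5])
  } else {
    neck <- mod_new("plain_neck",
                    up1 = mod_upsample(),
                    fuse4 = mod_c3k2(ch[5] + ch[4], ch[4], n),
                    up2 = mod_upsample(),
                    fuse3 = mod_c3k2(ch[4] + ch[3], ch[3], n),
                    c3 = ch[3], c4 = ch[4], c5 = ch[5])
  }
  no <- 4L + config$num_classes
  hh <- config$head_hidden
  head <- lapply(ch[3:5], function(ci) {
    hd <- list(stem = mod_conv(ci, hh, 3L),
               pred = mod_conv(hh, no, 1L, act = FALSE))
    # low-probability prior on the class logits: most cells are background
    hd$pred$b[4L + seq_len(config$num_classes)] <- -3
    hd
  })
  det <- mod_new("detector", config = config, backbone = bb, neck = neck,
                 head = head, seed = as.integer(seed))
  class(det) <- c("ivyolo_model", "environment")
  det
}

# --- forward / backward ----------------------------------------------------

#' Backbone forward pass
#'
#' @param image numeric array (H, W, 3) with H, W divisible by 32; pixel
#'   values are expected in `[0, 1]`.
#' @param detector a built detector.
#' @return list with feature maps `low` (stride 8), `mid` (16), `high` (32).
#' @export
backbone_forward <- function(image, detector) {
  d <- dim(image)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("image dimensions must be divisible by 32")
  bb <- detector$backbone
  # standardize [0,1] pixels to roughly zero mean, unit scale
  x <- (image - 0.5) / 0.25
  outs <- vector("list", 3L)
  for (i in seq_along(bb$layers)) {
    x <- f_forward(bb$layers[[i]], x)
    hit <- which(bb$taps == i)
    if (length(hit)) outs[[hit]] <- x
  }
  list(low = outs[[1]], mid = outs[[2]], high = outs[[3]])
}

backbone_backward <- function(detector, dlow, dmid, dhigh) {
  bb <- detector$backbone
  dy <- dhigh
  for (i in rev(seq_along(bb$layers))) {
    if (i == bb$taps[2]) dy <- dy + dmid
    if (i == bb$taps[1]) dy <- dy + dlow
    dy <- f_backward(bb$layers[[i]], dy)
  }
  invisible(dy)
}

cat_ch <- function(a, b) {
  da <- dim(a)
  out <- array(0, dim = c(da[1], da[2], da[3] + dim(b)[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(dim(b)[3])] <- b
  out
}

#' Neck forward pass
#'
#' With GFEN: stage 1 vortex-enhances the low and mid features, matches
#' resolutions (stride-2 conv on the low path), concatenates and fuses them
#' into `Ffusion1`; stage 2 repeats the pattern with `Ffusion1` and the high
#' features, yielding `Ffusion2`. The three head inputs are the enhanced
#' low-level map (stride 8), `Ffusion1` (stride 16) and `Ffusion2`
#' (stride 32). Without GFEN a plain top-down upsample-concat-fuse neck is
#' used instead.
#'
#' @param pyr list with `low`, `mid`, `high` from [backbone_forward()].
#' @param detector a built detector.
#' @return list of three feature maps at strides 8, 16, 32.
#' @export
gfen_forward <- function(pyr, detector) {
  nk <- detector$neck
  if (nk$type == "gfen") {
    el <- f_forward(nk$ms_low, pyr$low)
    em <- f_forward(nk$ms_mid, pyr$mid)
    F1 <- f_forward(nk$fuse1, cat_ch(f_forward(nk$down1, el), em))
    e1 <- f_forward(nk$ms_f1, F1)
    eh <- f_forward(nk$ms_high, pyr$high)
    F2 <- f_forward(nk$fuse2, cat_ch(f_forward(nk$down2, e1), eh))
    list(el, F1, F2)
  } else {
    n4 <- f_forward(nk$fuse4, cat_ch(f_forward(nk$up1, pyr$high), pyr$mid))
    n3 <- f_forward(nk$fuse3, cat_ch(f_forward(nk$up2, n4), pyr$low))
    list(n3, n4, pyr$high)
  }
}

neck_backward <- function(detector, douts) {
  nk <- detector$neck
  if (nk$type == "gfen") {
    del <- douts[[1]]; dF1 <- douts[[2]]; dF2 <- douts[[3]]
    dcat2 <- bwd_c3k2(nk$fuse2, dF2)
    dd2 <- dcat2[, , seq_len(nk$c5), drop = FALSE]
    deh <- dcat2[, , nk$c5 + seq_len(nk$c5), drop = FALSE]
    dhigh <- f_backward(nk$ms_high, deh)
    dF1 <- dF1 + f_backward(nk$ms_f1, f_backward(nk$down2, dd2))
    dcat1 <- bwd_c3k2(nk$fuse1, dF1)
    dd1 <- dcat1[, , seq_len(nk$c4), drop = FALSE]
    dem <- dcat1[, , nk$c4 + seq_len(nk$c4), drop = FALSE]
    dmid <- f_backward(nk$ms_mid, dem)
    del <- del + f_backward(nk$down1, dd1)
    dlow <- f_backward(nk$ms_low, del)
    list(dlow = dlow, dmid = dmid, dhigh = dhigh)
  } else {
    dn3 <- douts[[1]]; dn4 <- douts[[2]]; dhigh <- douts[[3]]
    dcat3 <- bwd_c3k2(nk$fuse3, dn3)
    du2 <- dcat3[, , seq_len(nk$c4), drop = FALSE]
    dlow <- dcat3[, , nk$c4 + seq_len(nk$c3), drop = FALSE]
    dn4 <- dn4 + f_backward(nk$up2, du2)
    dcat4 <- bwd_c3k2(nk$fuse4, dn4)
    du1 <- dcat4[, , seq_len(nk$c5), drop = FALSE]
    dmid <- dcat4[, , nk$c5 + seq_len(nk$c4), drop = FALSE]
    dhigh <- dhigh + f_backward(nk$up1, du1)
    list(dlow = dlow, dmid = dmid, dhigh = dhigh)
  }
}

#' Head forward pass
#'
#' Per scale, a 3x3 stem conv followed by a 1x1 prediction conv emitting
#' `4 + num_classes` channels per grid cell: box parameters (tx, ty, tw, th)
#' then class logits.
#'
#' @param neck_out list of three feature maps from [gfen_forward()].
#' @param detector a built detector.
#' @return list of three raw prediction arrays, one per stride.
#' @export
head_forward <- function(neck_out, detector) {
  lapply(seq_along(detector$head), function(s) {
    hd <- detector$head[[s]]
    fwd_conv(hd$pred, fwd_conv(hd$stem, neck_out[[s]]))
  })
}

head_backward <- function(detector, draws) {
  lapply(seq_along(detector$head), function(s) {
    hd <- detector$head[[s]]
    bwd_conv(hd$stem, bwd_conv(hd$pred, draws[[s]]))
  })
}

#' Full detector forward pass
#' @param image array (H, W, 3), values in `[0, 1]`, H and W divisible by 32.
#' @param detector a built detector.
#' @return list of three raw prediction arrays (strides 8, 16, 32).
#' @export
forward_detector <- function(image, detector) {
  pyr <- backbone_forward(image, detector)
  head_forward(gfen_forward(pyr, detector), detector)
}

backward_detector <- function(detector, draws) {
  dneck <- head_backward(detector, draws)
  dpyr <- neck_backward(detector, dneck)
  backbone_backward(detector, dpyr$dlow, dpyr$dmid, dpyr$dhigh)
}

# --- parameters and checkpoints -------------------------------------------

detector_modules <- function(detector) {
  if (is.null(detector$mod_cache))
    detector$mod_cache <- c(collect_modules(detector$backbone),
                            collect_modules(detector$neck),
                            collect_modules(detector$head))
  detector$mod_cache
}

#' Count trainable parameters
#'
#' Sums the lengths of every trainable tensor in the detector (conv weights
#' and biases, attention projections, DyT scalars and vectors). Fixed
#' buffers — the vortex kernel banks and sampling geometry — are not counted.
#'
#' @param detector a built detector (or any module environment).
#' @return integer parameter count.
#' @examples
#' \donttest{
#' m <- build_model(ivyolo_config())  # published scale
#' count_parameters(m) / 1e6          # ~2.52
#' }
#' @export
count_parameters <- function(detector) {
  mods <- if (inherits(detector, "ivyolo_model")) detector_modules(detector)
          else collect_modules(detector)
  as.integer(n_params_of(mods))
}

#' Save / load detector checkpoints
#'
#' A checkpoint is a flat named list of parameter tensors written with
#' `saveRDS()`, plus the model configuration serialized as JSON alongside
#' (`<path>.json`). Loading rebuilds the model from the JSON config and
#' validates that every parameter name and shape agrees.
#'
#' @param detector a built detector.
#' @param path checkpoint file path (the JSON sidecar adds `.json`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored detector.
#' @export
save_checkpoint <- function(detector, path) {
  mods <- detector_modules(detector)
  saveRDS(flatten_params(mods), path)
  cfg <- detector$config
  jsonlite::write_json(
    list(config = unclass(cfg), seed = detector$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- meta$config
  config <- ivyolo_config(input_size = cfg$input_size,
                          num_classes = cfg$num_classes,
                          width = cfg$width, depth = cfg$depth,
                          use_msiv = cfg$use_msiv, use_gfen = cfg$use_gfen,
                          base_channels = cfg$base_channels,
                          head_hidden = cfg$head_hidden_base,
                          msiv = as.list(cfg$msiv))
  det <- build_model(config, seed = meta$seed)
  assign_params(detector_modules(det), readRDS(path))
  det
}

#' @export
print.ivyolo_model <- function(x, ...) {
  cfg <- x$config
  cat("<ivyolo detector>\n")
  cat(sprintf("  input %dpx, %d class(es), width %.2f, depth %d\n",
              cfg$input_size, cfg$num_classes, cfg$width, cfg$depth))
  cat(sprintf("  MSIV: %s | GFEN: %s\n",
              if (cfg$use_msiv) "on" else "off",
              if (cfg$use_gfen) "on" else "off"))
  np <- count_parameters(x)
  cat(sprintf("  trainable parameters: %d (%.2fM)\n", np, np / 1e6))
  invisible(x)
}
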