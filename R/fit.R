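# Training loop and the user-facing fitting interface.

#' Fit the detector to a dataset
#'
#' The single entry point for training: builds the detector from `config`,
#' runs `steps` Adam updates of the composite detection loss over the
#' dataset and returns a fitted-model object with the usual methods
#' (`print`, `summary`, `coef`, `predict`, `plot`). Deterministic given
#' `seed`: identical calls produce identical loss curves and weights.
#'
#' @param data a dataset directory in YOLO layout (`images/`, `labels/`), or
#'   a list of image samples as returned by [generate_scene()] /
#'   [load_yolo_dataset()].
#' @param config an [ivyolo_config()]; image sizes in `data` must be
#'   divisible by 32 (they need not equal `config$input_size`).
#' @param steps number of optimizer steps.
#' @param lr Adam learning rate.
#' @param lr_schedule `"cosine"` (default) decays the learning rate from
#'   `lr` to `lr/10` over `steps` with a half-cosine; `"constant"` keeps it
#'   fixed.
#' @param batch_size images per step; defaults to the full dataset.
#' @param seed seed controlling initialization and batch sampling.
#' @param verbose print the loss every 25 steps.
#' @param eval_every if set, evaluate training-set AP50 every this many
#'   steps (recorded in the returned object).
#' @param target_ap50 if set (with `eval_every`), stop as soon as the
#'   training-set AP50 reaches this value.
#' @return an object of class `ivyolo`.
#' @examples
#' \donttest{
#' cfg <- scene_config(image_size = 96, n_plants = 4, seed = 1)
#' scenes <- lapply(1:2, function(i) generate_scene(cfg, seed = i))
#' fit <- ivyolo(scenes, ivyolo_config(input_size = 96, width = 0.25),
#'               steps = 5, verbose = FALSE)
#' print(fit)
#' }
#' @export
ivyolo <- function(data, config = ivyolo_config(), steps = 300L, lr = 1e-2,
                   lr_schedule = c("cosine", "constant"),
                   batch_size = NULL, seed = 0L, verbose = TRUE,
                   eval_every = NULL, target_ap50 = NULL) {
  lr_schedule <- match.arg(lr_schedule)
  samples <- if (is.character(data)) load_yolo_dataset(data) else data
  if (!length(samples)) stop("empty dataset: nothing to train on")
  for (s in samples) {
    d <- dim(s$pixels)
    if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
      stop("image sizes must be divisible by 32")
  }
  det <- build_model(config, seed = seed)
  mods <- detector_modules(det)
  nb <- if (is.null(batch_size)) length(samples)
        else min(batch_size, length(samples))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  history <- data.frame(step = integer(0), loss = numeric(0),
                        box = numeric(0), cls = numeric(0))
  ap50_trace <- list()
  for (step in seq_len(steps)) {
    idx <- if (nb == length(samples)) seq_along(samples)
           else sample.int(length(samples), nb)
    zero_all_grads(mods)
    tot <- box <- cls <- 0
    for (k in idx) {
      sm <- samples[[k]]
      raw <- forward_detector(sm$pixels, det)
      ls <- detection_loss(raw, sm$boxes)
      backward_detector(det, ls$draws)
      tot <- tot + ls$total; box <- box + ls$box; cls <- cls + ls$cls
    }
    lr_t <- if (lr_schedule == "cosine")
      lr * (0.1 + 0.9 * (1 + cos(pi * (step - 1) / steps)) / 2)
    else lr
    adam_step(mods, lr_t, step, scale = 1 / nb)
    history[step, ] <- list(step, tot / nb, box / nb, cls / nb)
    if (verbose && (step %% 25L == 0L || step == 1L))
      message(sprintf("step %4d  loss %.4f (box %.4f, cls %.4f)",
                      step, tot / nb, box / nb, cls / nb))
    if (!is.null(eval_every) && step %% eval_every == 0L) {
      rep <- evaluate_model(structure(list(model = det), class = "ivyolo"),
                            samples)
      ap50_trace[[length(ap50_trace) + 1L]] <- c(step = step,
                                                 ap50 = rep$ap50)
      if (verbose) message(sprintf("step %4d  train AP50 %.3f", step,
                                   rep$ap50))
      if (!is.null(target_ap50) && rep$ap50 >= target_ap50) break
    }
  }
  structure(list(model = det, config = config, history = history,
                 ap50_trace = if (length(ap50_trace))
                   as.data.frame(do.call(rbind, ap50_trace)) else NULL,
                 n_images = length(samples), seed = seed, lr = lr,
                 steps = nrow(history)),
            class = "ivyolo")
}

#' @export
print.ivyolo <- function(x, ...) {
  cat("<fitted ivyolo detector>\n")
  cat(sprintf("  trained %d steps on %d image(s), lr %g, seed %d\n",
              x$steps, x$n_images, x$lr, x$seed))
  if (nrow(x$history))
    cat(sprintf("  final loss %.4f (first %.4f)\n",
                tail(x$history$loss, 1), x$history$loss[1]))
  print(x$model)
  invisible(x)
}

#' @export
summary.ivyolo <- function(object, ...) {
  h <- object$history
  cat("Training summary\n")
  cat(sprintf("  steps: %d   images: %d   lr: %g\n",
              object$steps, object$n_images, object$lr))
  if (nrow(h)) {
    cat(sprintf("  loss: first %.4f  min %.4f  final %.4f\n",
                h$loss[1], min(h$loss), tail(h$loss, 1)))
    cat(sprintf("  final box %.4f  cls %.4f\n",
                tail(h$box, 1), tail(h$cls, 1)))
  }
  cat(sprintf("  parameters: %.2fM\n",
              count_parameters(object$model) / 1e6))
  invisible(object)
}

#' @export
coef.ivyolo <- function(object, ...) {
  flatten_params(detector_modules(object$model))
}

#' Predict detections on new images
#'
#' @param object a fitted `ivyolo` model.
#' @param newdata a single (H, W, 3) array, an `ivy_image_sample`, a list of
#'   either, or a path to a PNG file or dataset directory.
#' @param conf_threshold,nms_iou decoding thresholds.
#' @param ... unused.
#' @return a detection data frame (rows from all images, identified by
#'   `image_id`).
#' @export
predict.ivyolo <- function(object, newdata, conf_threshold = 0.25,
                           nms_iou = 0.5, ...) {
  samples <- normalize_image_input(newdata)
  out <- lapply(samples, function(s) {
    raw <- forward_detector(s$pixels, object$model)
    decode_predictions(raw, conf_threshold, nms_iou,
                       strides = object$config$strides,
                       image_id = s$image_id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

normalize_image_input <- function(newdata) {
  as_sample <- function(x, id) {
    if (inherits(x, "ivy_image_sample")) return(x)
    if (is.array(x) && length(dim(x)) == 3L)
      return(structure(list(pixels = x, boxes = NULL, image_id = id),
                       class = "ivy_image_sample"))
    stop("cannot interpret input image")
  }
  if (is.character(newdata)) {
    if (dir.exists(newdata)) return(load_yolo_dataset(newdata))
    px <- png::readPNG(newdata)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
    return(list(as_sample(px[, , 1:3, drop = FALSE],
                          tools::file_path_sans_ext(basename(newdata)))))
  }
  if (inherits(newdata, "ivy_image_sample")) return(list(newdata))
  if (is.array(newdata)) return(list(as_sample(newdata, "img")))
  lapply(seq_along(newdata), function(i)
    as_sample(newdata[[i]], sprintf("img_%d", i)))
}

#' Plot the training loss curve
#'
#' @param x a fitted `ivyolo` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ivyolo <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$loss, type = "l", xlab = "step", ylab = "loss",
                 main = "training loss", ...)
  graphics::lines(h$step, h$box, col = "steelblue")
  graphics::lines(h$step, h$cls, col = "tomato")
  graphics::legend("topright", legend = c("total", "box", "cls"),
                   col = c("black", "steelblue", "tomato"), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Evaluate a fitted model on a dataset
#'
#' Convenience wrapper: runs prediction over labelled samples and computes
#' the full evaluation report against their ground truth.
#'
#' @param fit a fitted `ivyolo` model (or a bare detector).
#' @param samples list of `ivy_image_sample` objects with `boxes`.
#' @param conf_threshold score threshold of the precision/recall operating
#'   point. Decoding for the AP curves uses `decode_threshold`, a much lower
#'   cutoff, so average precision sees the full ranked detection list.
#' @param nms_iou suppression threshold.
#' @param decode_threshold minimum score kept when decoding.
#' @return an `ivy_eval_report`.
#' @export
evaluate_model <- function(fit, samples, conf_threshold = 0.25,
                           nms_iou = 0.5, decode_threshold = 0.01) {
  det <- if (inherits(fit, "ivyolo")) fit$model else fit
  strides <- det$config$strides
  dets <- list(); gts <- list()
  for (s in samples) {
    d <- dim(s$pixels)
    raw <- forward_detector(s$pixels, det)
    dets[[length(dets) + 1L]] <-
      decode_predictions(raw, decode_threshold, nms_iou, strides,
                         image_id = s$image_id)
    gts[[length(gts) + 1L]] <-
      yolo_to_xyxy(s$boxes, d[2], d[1], image_id = s$image_id)
  }
  evaluate(do.call(rbind, dets), do.call(rbind, gts), conf_threshold)
}
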