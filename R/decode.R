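# Anchor-free decoding of raw head outputs into pixel-space detections.

# Per-cell box parametrization at stride s, cell (i, j) (0-based):
#   cx = (j + 2*sigmoid(tx) - 0.5) * s     w = exp(tw) * s
#   cy = (i + 2*sigmoid(ty) - 0.5) * s     h = exp(th) * s
# The 2*sigmoid - 0.5 range lets neighbouring cells of a target center also
# regress onto it (the loss assigns up to three cells per target).
# Class channels are independent logits.

#' Decode raw predictions into detections
#'
#' Converts the per-scale raw prediction arrays into pixel-space boxes
#' (xyxy, 0-based, half-open), keeps cells whose best class score reaches
#' `conf_threshold`, and applies class-wise greedy non-maximum suppression.
#'
#' @param raw list of raw prediction arrays from [forward_detector()].
#' @param conf_threshold confidence threshold in (0, 1).
#' @param nms_iou IoU threshold for suppression, in (0, 1).
#' @param strides stride of each prediction scale.
#' @param image_id identifier attached to the returned detections.
#' @param max_dets keep at most this many detections after suppression
#'   (COCO-style per-image cap).
#' @return data frame with columns `image_id`, `class_id` (0-based), `x1`,
#'   `y1`, `x2`, `y2`, `score`, sorted by decreasing score.
#' @export
decode_predictions <- function(raw, conf_threshold = 0.25, nms_iou = 0.5,
                               strides = c(8L, 16L, 32L), image_id = "img",
                               max_dets = 300L) {
  stopifnot(conf_threshold > 0, conf_threshold < 1,
            nms_iou > 0, nms_iou < 1)
  rows <- list()
  for (s in seq_along(raw)) {
    r <- raw[[s]]
    d <- dim(r)
    stride <- strides[s]
    nc <- d[3] - 4L
    ii <- matrix(0:(d[1] - 1), d[1], d[2])
    jj <- matrix(rep(0:(d[2] - 1), each = d[1]), d[1], d[2])
    cx <- (jj + 2 * stats::plogis(r[, , 1]) - 0.5) * stride
    cy <- (ii + 2 * stats::plogis(r[, , 2]) - 0.5) * stride
    w <- exp(pmin(r[, , 3], 8)) * stride
    h <- exp(pmin(r[, , 4], 8)) * stride
    cls <- array(r[, , 4 + seq_len(nc)], dim = c(d[1], d[2], nc))
    probs <- stats::plogis(cls)
    best <- if (nc == 1L) {
      list(score = probs[, , 1], id = matrix(0L, d[1], d[2]))
    } else {
      sc <- apply(probs, c(1, 2), max)
      id <- apply(probs, c(1, 2), which.max) - 1L
      list(score = sc, id = id)
    }
    keep <- which(best$score >= conf_threshold)
    if (length(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = image_id,
        class_id = as.integer(best$id[keep]),
        x1 = cx[keep] - w[keep] / 2, y1 = cy[keep] - h[keep] / 2,
        x2 = cx[keep] + w[keep] / 2, y2 = cy[keep] + h[keep] / 2,
        score = best$score[keep])
    }
  }
  dets <- if (length(rows)) do.call(rbind, rows) else empty_detections()
  dets <- dets[order(-dets$score), , drop = FALSE]
  rownames(dets) <- NULL
  out <- nms_filter(dets, nms_iou)
  head(out, max_dets)
}

empty_detections <- function() {
  data.frame(image_id = character(0), class_id = integer(0),
             x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
             y2 = numeric(0), score = numeric(0))
}

# Class-wise greedy NMS on a score-sorted detection frame.
nms_filter <- function(dets, nms_iou) {
  if (nrow(dets) <= 1L) return(dets)
  keep <- logical(nrow(dets))
  bx <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  area <- (bx[, 3] - bx[, 1]) * (bx[, 4] - bx[, 2])
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    alive <- rep(TRUE, length(idx))
    for (a in seq_along(idx)) {
      if (!alive[a]) next
      keep[idx[a]] <- TRUE
      if (a < length(idx)) {
        rest <- idx[(a + 1L):length(idx)]
        me <- idx[a]
        iw <- pmax(0, pmin(bx[me, 3], bx[rest, 3]) -
                     pmax(bx[me, 1], bx[rest, 1]))
        ih <- pmax(0, pmin(bx[me, 4], bx[rest, 4]) -
                     pmax(bx[me, 2], bx[rest, 2]))
        inter <- iw * ih
        ious <- inter / (area[me] + area[rest] - inter)
        kill <- ((a + 1L):length(idx))[ious > nms_iou]
        alive[kill] <- FALSE
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
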