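# COCO-style detection metrics: Precision, Recall, AP (IoU 0.50:0.95),
# AP50, AP75, plus the feature-purity diagnostic.

#' Intersection over union of two boxes
#'
#' Boxes are pixel-space `(x1, y1, x2, y2)`, 0-based, half-open, with
#' `x2 > x1` and `y2 > y1`.
#'
#' @param a,b numeric length-4 boxes.
#' @return IoU in `[0, 1]`; symmetric in its arguments.
#' @examples
#' iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1))  # 1/3
#' @export
iou <- function(a, b) {
  check_box(a); check_box(b)
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

check_box <- function(b) {
  if (length(b) != 4L || !all(is.finite(b)))
    stop("box must be four finite numbers (x1, y1, x2, y2)")
  if (b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box: need x2 > x1 and y2 > y1")
  invisible(b)
}

# Canonical ground-truth frame: image_id, class_id, x1, y1, x2, y2.
check_gt <- function(gts) {
  need <- c("image_id", "class_id", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(gts))) stop("ground truth needs columns: ",
                                       paste(need, collapse = ", "))
  gts
}

#' Greedy matching of detections to ground truth
#'
#' Detections are processed in decreasing score order; each is matched to
#' the not-yet-matched same-class, same-image ground-truth box of highest
#' IoU, provided that IoU reaches the threshold. Matching is one-to-one;
#' IoU ties are broken toward the lower ground-truth row index.
#'
#' @param dets detection frame (`image_id`, `class_id`, `x1`..`y2`, `score`).
#' @param gts ground-truth frame (`image_id`, `class_id`, `x1`..`y2`).
#' @param iou_threshold minimum IoU for a match.
#' @return `dets` sorted by decreasing score with columns `tp` (logical) and
#'   `gt_row` (matched row index in `gts`, NA for false positives);
#'   attribute `n_gt` carries the ground-truth count.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  check_gt(gts)
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  n <- nrow(dets)
  tp <- logical(n)
  gt_row <- rep(NA_integer_, n)
  taken <- logical(nrow(gts))
  if (n > 0) {
    dkey <- paste(dets$image_id, dets$class_id)
    gkey <- paste(gts$image_id, gts$class_id)
    gb <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
    garea <- (gb[, 3] - gb[, 1]) * (gb[, 4] - gb[, 2])
    for (key in unique(dkey)) {
      drows <- which(dkey == key)
      grows <- which(gkey == key)
      if (!length(grows)) next
      for (d in drows) {
        cand <- grows[!taken[grows]]
        if (!length(cand)) next
        x1 <- dets$x1[d]; y1 <- dets$y1[d]
        x2 <- dets$x2[d]; y2 <- dets$y2[d]
        iw <- pmax(0, pmin(x2, gb[cand, 3]) - pmax(x1, gb[cand, 1]))
        ih <- pmax(0, pmin(y2, gb[cand, 4]) - pmax(y1, gb[cand, 2]))
        inter <- iw * ih
        ious <- inter / ((x2 - x1) * (y2 - y1) + garea[cand] - inter)
        ok <- which(ious >= iou_threshold)
        if (!length(ok)) next
        # max IoU, ties toward lower gt index (cand is ascending)
        pick <- cand[ok[which.max(ious[ok])]]
        tp[d] <- TRUE
        gt_row[d] <- pick
        taken[pick] <- TRUE
      }
    }
  }
  out <- dets
  out$tp <- tp
  out$gt_row <- gt_row
  rownames(out) <- NULL
  attr(out, "n_gt") <- nrow(gts)
  out
}

#' Average precision at one IoU threshold
#'
#' 101-point interpolated AP: the precision envelope
#' `p(r) = max{precision at recall >= r}` is sampled at recalls
#' 0.00, 0.01, ..., 1.00 and averaged, computed from the full score-ranked
#' precision-recall curve.
#'
#' @inheritParams match_detections
#' @return AP in `[0, 1]`; 0 when there are no detections or no ground truth.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  if (nrow(gts) == 0L || nrow(dets) == 0L) return(0)
  m <- match_detections(dets, gts, iou_threshold)
  ctp <- cumsum(m$tp)
  prec <- ctp / seq_len(nrow(m))
  rec <- ctp / nrow(gts)
  rs <- seq(0, 1, by = 0.01)
  penv <- vapply(rs, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(penv)
}

#' Full detection evaluation report
#'
#' Precision and recall are computed at `conf_threshold` with IoU-0.5
#' matching (precision is defined as 0 when there are no detections above
#' threshold); `ap` is the mean of [average_precision()] over IoU
#' 0.50:0.95 in steps of 0.05; `ap50`/`ap75` are the fixed-threshold values.
#' The report also records the maximum-F1 operating point of the IoU-0.5
#' PR curve and the per-threshold curves themselves.
#'
#' @inheritParams match_detections
#' @param conf_threshold score threshold for the precision/recall
#'   operating point.
#' @return object of class `ivy_eval_report`: list with `precision`,
#'   `recall`, `ap`, `ap50`, `ap75`, `max_f1` (list: f1, score_threshold,
#'   precision, recall) and `curves` (per-IoU PR curves).
#' @export
evaluate <- function(dets, gts, conf_threshold = 0.25) {
  check_gt(gts)
  thrs <- seq(0.50, 0.95, by = 0.05)
  aps <- vapply(thrs, function(t) average_precision(dets, gts, t), numeric(1))
  keep <- dets[dets$score >= conf_threshold, , drop = FALSE]
  n_gt <- nrow(gts)
  if (nrow(keep) == 0L) {
    precision <- 0; recall <- 0
  } else {
    m <- match_detections(keep, gts, 0.5)
    precision <- sum(m$tp) / nrow(m)
    recall <- if (n_gt > 0) sum(m$tp) / n_gt else 0
  }
  # PR curve at IoU 0.5 and its max-F1 point
  curves <- list()
  max_f1 <- list(f1 = 0, score_threshold = NA_real_,
                 precision = 0, recall = 0)
  if (nrow(dets) > 0L && n_gt > 0L) {
    m <- match_detections(dets, gts, 0.5)
    ctp <- cumsum(m$tp)
    prec <- ctp / seq_len(nrow(m))
    rec <- ctp / n_gt
    curves[["iou50"]] <- data.frame(score = m$score, precision = prec,
                                    recall = rec)
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    b <- which.max(f1)
    max_f1 <- list(f1 = f1[b], score_threshold = m$score[b],
                   precision = prec[b], recall = rec[b])
  }
  structure(list(precision = precision, recall = recall,
                 ap = mean(aps), ap50 = aps[1], ap75 = aps[6],
                 ap_per_iou = setNames(aps, sprintf("iou%.2f", thrs)),
                 max_f1 = max_f1, curves = curves,
                 conf_threshold = conf_threshold),
            class = "ivy_eval_report")
}

#' @export
print.ivy_eval_report <- function(x, ...) {
  cat("<detection evaluation>\n")
  cat(sprintf("  precision %.4f  recall %.4f  (conf >= %.2f, IoU 0.5)\n",
              x$precision, x$recall, x$conf_threshold))
  cat(sprintf("  AP %.4f  AP50 %.4f  AP75 %.4f\n", x$ap, x$ap50, x$ap75))
  if (!is.na(x$max_f1$score_threshold))
    cat(sprintf("  max F1 %.4f at score %.3f\n",
                x$max_f1$f1, x$max_f1$score_threshold))
  invisible(x)
}

#' Feature-purity diagnostic
#'
#' Ratio of mean per-pixel channel-L2 activation magnitude inside a target
#' mask to that outside it. Values above 1 indicate the map responds more
#' strongly in target regions than in background.
#'
#' @param F feature map (H, W, C).
#' @param target_mask logical or 0/1 matrix (H, W); both classes must be
#'   present.
#' @return the purity ratio; `+Inf` with attribute
#'   `degenerate_background = TRUE` when the background response is exactly
#'   zero.
#' @export
feature_purity <- function(F, target_mask) {
  check_feature_map(F)
  mask <- target_mask > 0
  if (!any(mask) || all(mask))
    stop("target mask must contain both target and background pixels")
  resp <- sqrt(apply(F^2, c(1, 2), sum))
  inside <- mean(resp[mask])
  outside <- mean(resp[!mask])
  if (outside == 0) {
    out <- Inf
    attr(out, "degenerate_background") <- TRUE
    return(out)
  }
  inside / outside
}

#' Convert normalized YOLO boxes to a pixel ground-truth frame
#'
#' @param boxes matrix with columns `class`, `cx`, `cy`, `w`, `h` in
#'   normalized coordinates.
#' @param width,height image size in pixels.
#' @param image_id identifier for the frame.
#' @return ground-truth data frame (`image_id`, `class_id`, `x1`..`y2`).
#' @export
yolo_to_xyxy <- function(boxes, width, height, image_id = "img") {
  boxes <- as.matrix(boxes)
  if (nrow(boxes) == 0L)
    return(data.frame(image_id = character(0), class_id = integer(0),
                      x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  data.frame(image_id = image_id,
             class_id = as.integer(boxes[, 1]),
             x1 = (boxes[, 2] - boxes[, 4] / 2) * width,
             y1 = (boxes[, 3] - boxes[, 5] / 2) * height,
             x2 = (boxes[, 2] + boxes[, 4] / 2) * width,
             y2 = (boxes[, 3] + boxes[, 5] / 2) * height)
}
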