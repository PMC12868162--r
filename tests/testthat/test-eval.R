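# Detection metrics: IoU, greedy matching, interpolated AP, the evaluation
# report and the feature-purity diagnostic.

gt_frame <- function(boxes, image_id = "a", class_id = 0L) {
  data.frame(image_id = image_id, class_id = class_id,
             x1 = boxes[, 1], y1 = boxes[, 2],
             x2 = boxes[, 3], y2 = boxes[, 4])
}

det_frame <- function(boxes, scores, image_id = "a", class_id = 0L) {
  cbind(gt_frame(boxes, image_id, class_id), score = scores)
}

test_that("iou handles identity, disjoint and partial overlap", {
  expect_equal(iou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1)), 1 / 3)
  expect_equal(iou(c(0.5, 0, 1.5, 1), c(0, 0, 1, 1)), 1 / 3)  # symmetric
  expect_error(iou(c(0, 0, 0, 1), c(0, 0, 1, 1)), "degenerate")
})

test_that("greedy matching is one-to-one with documented tie-breaks", {
  gts <- gt_frame(rbind(c(0, 0, 10, 10), c(20, 0, 30, 10)))
  # one detection exactly on one gt
  m <- match_detections(det_frame(rbind(c(0, 0, 10, 10)), 0.9), gts)
  expect_equal(sum(m$tp), 1)
  # two detections on one gt: second becomes a false positive
  m2 <- match_detections(
    det_frame(rbind(c(0, 0, 10, 10), c(0.5, 0, 10.5, 10)), c(0.9, 0.8)),
    gts)
  expect_equal(m2$tp, c(TRUE, FALSE))
  # greedy by score: best-scoring detection claims the gt it overlaps most
  dets3 <- det_frame(rbind(c(0, 0, 10, 10),      # overlaps gt1 fully
                           c(2, 0, 12, 10),      # overlaps gt1 partially
                           c(19, 0, 29, 10)),    # overlaps gt2
                     c(0.8, 0.95, 0.7))
  m3 <- match_detections(dets3, gts)
  # verify against a scalar enumeration of the greedy rule
  oracle_greedy <- function(dets, gts, thr) {
    ord <- order(-dets$score)
    taken <- logical(nrow(gts)); tp <- logical(nrow(dets))
    for (d in ord) {
      best_iou <- -1; best_g <- NA
      for (g in seq_len(nrow(gts))) {
        if (taken[g]) next
        v <- iou(as.numeric(dets[d, c("x1", "y1", "x2", "y2")]),
                 as.numeric(gts[g, c("x1", "y1", "x2", "y2")]))
        if (v >= thr && v > best_iou) { best_iou <- v; best_g <- g }
      }
      if (!is.na(best_g)) { taken[best_g] <- TRUE; tp[d] <- TRUE }
    }
    tp[ord]
  }
  expect_equal(m3$tp, oracle_greedy(dets3, gts, 0.5))
  # class and image separation
  mx <- match_detections(det_frame(rbind(c(0, 0, 10, 10)), 0.9,
                                   class_id = 1L), gts)
  expect_equal(sum(mx$tp), 0)
})

test_that("average precision reproduces the hand-evaluated ranked list", {
  # ranked TP, FP, TP over two ground truths
  gts <- gt_frame(rbind(c(0, 0, 10, 10), c(100, 100, 110, 110)))
  dets <- det_frame(rbind(c(0, 0, 10, 10),
                          c(50, 50, 60, 60),
                          c(100, 100, 110, 110)),
                    c(0.9, 0.8, 0.7))
  # independent scalar evaluation of the 101-point interpolation:
  # PR points (1, 0.5), (0.5, 0.5), (2/3, 1)
  prec <- c(1, 1 / 2, 2 / 3); rec <- c(0.5, 0.5, 1)
  ap_ref <- mean(sapply(seq(0, 1, 0.01), function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }))
  expect_equal(ap_ref, (51 * 1 + 50 * 2 / 3) / 101)   # = 0.8349835...
  expect_equal(average_precision(dets, gts, 0.5), ap_ref, tolerance = 1e-12)
  # trivial extremes
  perfect <- det_frame(rbind(c(0, 0, 10, 10), c(100, 100, 110, 110)),
                       c(0.9, 0.8))
  expect_equal(average_precision(perfect, gts, 0.5), 1)
  expect_equal(average_precision(perfect[0, ], gts, 0.5), 0)
})

test_that("average precision is stable under equal-score permutations", {
  gts <- gt_frame(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)))
  dets <- det_frame(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)),
                    c(0.5, 0.5))
  expect_equal(average_precision(dets, gts, 0.5),
               average_precision(dets[2:1, ], gts, 0.5))
})

test_that("evaluate returns exact metrics in the perfect and planted cases", {
  gts <- gt_frame(rbind(c(0, 0, 10, 10), c(20, 20, 35, 35),
                        c(50, 50, 70, 70)))
  perfect <- det_frame(as.matrix(gts[, c("x1", "y1", "x2", "y2")]),
                       c(0.9, 0.8, 0.7))
  rep <- evaluate(perfect, gts)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$ap, 1)
  expect_equal(rep$ap50, 1)
  expect_equal(rep$ap75, 1)
  # empty detections: both operating-point metrics defined as 0
  rep0 <- evaluate(perfect[0, ], gts)
  expect_equal(rep0$precision, 0)
  expect_equal(rep0$recall, 0)
  expect_equal(rep0$ap50, 0)
  # planted 4 TP + 1 FP + 1 FN across three images
  gts3 <- rbind(gt_frame(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)), "i1"),
                gt_frame(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)), "i2"),
                gt_frame(rbind(c(0, 0, 10, 10)), "i3"))
  dets3 <- rbind(
    det_frame(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)), c(0.9, 0.9), "i1"),
    det_frame(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)), c(0.9, 0.9), "i2"),
    det_frame(rbind(c(60, 60, 70, 70)), 0.9, "i3"))   # FP; gt on i3 missed
  rep3 <- evaluate(dets3, gts3)
  expect_equal(rep3$precision, 0.8)
  expect_equal(rep3$recall, 0.8)
})

test_that("AP orderings hold across IoU thresholds on noisy detections", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    base <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    gts <- gt_frame(cbind(base, base[, 1] + runif(n, 8, 20),
                          base[, 2] + runif(n, 8, 20)))
    jit <- as.matrix(gts[, c("x1", "y1", "x2", "y2")]) +
      matrix(rnorm(4 * n, sd = 2), n, 4)
    jit[, 3] <- pmax(jit[, 3], jit[, 1] + 1)
    jit[, 4] <- pmax(jit[, 4], jit[, 2] + 1)
    dets <- det_frame(jit, runif(n, 0.3, 1))
    r <- evaluate(dets, gts)
    expect_lte(r$ap, r$ap50 + 1e-12)
    expect_lte(r$ap75, r$ap50 + 1e-12)
    expect_true(all(diff(r$ap_per_iou) <= 1e-12))  # monotone in IoU
  }
})

test_that("feature purity matches direct arithmetic and guards degeneracy", {
  Fc <- make_feature_fixture(6, 6, 3, "constant", value = 2)
  mask <- matrix(FALSE, 6, 6); mask[1:3, 1:3] <- TRUE
  expect_equal(feature_purity(Fc, mask), 1)
  # two-blobs fixture: compare with scalar computation
  Fb <- make_feature_fixture(12, 12, 4, "two_blobs", seed = 8)
  mask2 <- matrix(FALSE, 12, 12); mask2[1:6, 1:6] <- TRUE
  resp <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) resp[i, j] <- sqrt(sum(Fb[i, j, ]^2))
  expect_equal(feature_purity(Fb, mask2),
               mean(resp[mask2]) / mean(resp[!mask2]))
  # zero background: +Inf sentinel with flag
  Fz <- array(0, c(4, 4, 2)); Fz[1, 1, ] <- 1
  mz <- matrix(FALSE, 4, 4); mz[1, 1] <- TRUE
  pz <- feature_purity(Fz, mz)
  expect_true(is.infinite(pz))
  expect_true(attr(pz, "degenerate_background"))
  expect_error(feature_purity(Fc, matrix(TRUE, 6, 6)), "both")
})
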