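# Composite detection loss: IoU box regression + binary cross-entropy
# classification, with center-in-cell positive assignment. Gradients with
# respect to the raw prediction maps are returned alongside the loss so the
# engine can run its backward pass.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Detection loss
#'
#' Assigns each ground-truth box to the grid cell containing its center at
#' the scale matched to its size, then scores an IoU loss (plus a small L1
#' pull on the raw box parameters, which keeps gradients alive when a
#' prediction does not yet overlap its target) on positive cells and
#' binary cross-entropy on every class logit. Degenerate (zero-area) targets
#' are skipped with a warning. The box component is exactly zero when every
#' assigned prediction reproduces its target box.
#'
#' @param raw list of raw prediction arrays (strides 8/16/32).
#' @param targets matrix or data frame of ground-truth boxes, columns
#'   `class`, `cx`, `cy`, `w`, `h`, normalized to `[0, 1]`.
#' @param strides stride of each scale.
#' @param lambda_l1 weight of the L1 stabilizer on raw box parameters.
#' @param pos_weight weight on positive cells in the classification BCE
#'   (positives are rare relative to background cells).
#' @param neighbor_cells also assign each target to its two nearest
#'   neighbour cells (denser supervision at the cost of noisier ranking).
#' @return list with `total`, `box`, `cls`, `n_pos` and `draws` (the
#'   gradient of `total` with respect to each raw array).
#' @export
detection_loss <- function(raw, targets, strides = c(8L, 16L, 32L),
                           lambda_l1 = 0.4, pos_weight = 3,
                           neighbor_cells = FALSE) {
  d1 <- dim(raw[[1]])
  H_img <- d1[1] * strides[1]
  W_img <- d1[2] * strides[1]
  nc <- d1[3] - 4L
  draws <- lapply(raw, function(r) array(0, dim(r)))
  # size thresholds routing targets to scales, proportional to image size
  thr <- c(H_img / 8, H_img / 4)

  targets <- as.matrix(targets)
  n_t <- if (is.null(targets) || nrow(targets) == 0L) 0L else nrow(targets)
  pos <- list()   # assignment records
  occupied <- new.env(parent = emptyenv())
  if (n_t > 0) for (t in seq_len(n_t)) {
    cls <- as.integer(targets[t, 1])
    cx <- targets[t, 2] * W_img; cy <- targets[t, 3] * H_img
    wpx <- targets[t, 4] * W_img; hpx <- targets[t, 5] * H_img
    if (wpx <= 0 || hpx <= 0) {
      warning("skipping degenerate (zero-area) target box")
      next
    }
    lvl <- findInterval(max(wpx, hpx), thr) + 1L
    s <- strides[lvl]
    dL <- dim(raw[[lvl]])
    j <- clamp(floor(cx / s), 0, dL[2] - 1L)
    i <- clamp(floor(cy / s), 0, dL[1] - 1L)
    # center cell; optionally also the horizontally and vertically nearest
    # neighbour cells (reachable because the center offset spans (-0.5, 1.5)).
    # Single-cell assignment keeps the score ranking clean: every target has
    # exactly one confident cell, so suppression has nothing to miss.
    fx <- cx / s - j; fy <- cy / s - i
    cells <- list(c(i, j))
    if (neighbor_cells) {
      cells <- c(cells, list(c(i, j + if (fx < 0.5) -1L else 1L),
                             c(i + if (fy < 0.5) -1L else 1L, j)))
    }
    for (ce in cells) {
      ii <- ce[1]; jj <- ce[2]
      if (ii < 0 || jj < 0 || ii >= dL[1] || jj >= dL[2]) next
      key <- paste(lvl, ii, jj)
      if (!is.null(occupied[[key]])) next   # one target per cell
      occupied[[key]] <- TRUE
      pos[[length(pos) + 1L]] <- list(lvl = lvl, i = ii, j = jj, cls = cls,
                                      cx = cx, cy = cy, w = wpx, h = hpx)
    }
  }
  n_pos <- length(pos)
  norm <- max(1L, n_pos)

  # --- box loss over positive cells ---------------------------------------
  box_loss <- 0
  for (p in pos) {
    r <- raw[[p$lvl]]
    s <- strides[p$lvl]
    i1 <- p$i + 1L; j1 <- p$j + 1L
    tx <- r[i1, j1, 1]; ty <- r[i1, j1, 2]
    tw <- clamp(r[i1, j1, 3], -8, 8); th <- clamp(r[i1, j1, 4], -8, 8)
    sx <- stats::plogis(tx); sy <- stats::plogis(ty)
    cxp <- (p$j + 2 * sx - 0.5) * s; cyp <- (p$i + 2 * sy - 0.5) * s
    wp <- exp(tw) * s; hp <- exp(th) * s
    g <- iou_loss_grad(c(cxp, cyp, wp, hp), c(p$cx, p$cy, p$w, p$h))
    # L1 stabilizer on raw-parameter residuals
    sxs <- (p$cx / s - p$j + 0.5) / 2; sys <- (p$cy / s - p$i + 0.5) / 2
    tws <- log(p$w / s); ths <- log(p$h / s)
    res <- c(sx - sxs, sy - sys, tw - tws, th - ths)
    box_loss <- box_loss + g$loss + lambda_l1 * sum(abs(res))
    # chain to raw parameters
    dsx <- g$grad[1] * 2 * s + lambda_l1 * sign(res[1])
    dsy <- g$grad[2] * 2 * s + lambda_l1 * sign(res[2])
    dtw <- g$grad[3] * wp + lambda_l1 * sign(res[3])
    dth <- g$grad[4] * hp + lambda_l1 * sign(res[4])
    dr <- draws[[p$lvl]]
    dr[i1, j1, 1] <- dr[i1, j1, 1] + dsx * sx * (1 - sx) / norm
    dr[i1, j1, 2] <- dr[i1, j1, 2] + dsy * sy * (1 - sy) / norm
    dr[i1, j1, 3] <- dr[i1, j1, 3] + dtw / norm
    dr[i1, j1, 4] <- dr[i1, j1, 4] + dth / norm
    draws[[p$lvl]] <- dr
  }
  box_loss <- box_loss / norm

  # --- classification BCE over all cells ----------------------------------
  cls_loss <- 0
  for (s in seq_along(raw)) {
    r <- raw[[s]]
    dL <- dim(r)
    z <- array(r[, , 4 + seq_len(nc)], dim = c(dL[1], dL[2], nc))
    y <- array(0, dim(z))
    for (p in pos) if (p$lvl == s) y[p$i + 1L, p$j + 1L, p$cls + 1L] <- 1
    pr <- stats::plogis(z)
    w <- 1 + (pos_weight - 1) * y
    # numerically stable BCE with logits
    bce <- w * (pmax(z, 0) - z * y + log1p(exp(-abs(z))))
    cls_loss <- cls_loss + sum(bce) / norm
    draws[[s]][, , 4 + seq_len(nc)] <- w * (pr - y) / norm
  }

  list(total = box_loss + cls_loss, box = box_loss, cls = cls_loss,
       n_pos = n_pos, draws = draws)
}

# IoU loss (1 - IoU) of a predicted box given as (cx, cy, w, h) against a
# ground-truth (cx, cy, w, h), with the analytic gradient with respect to
# the four prediction parameters. Zero-overlap pairs return loss 1 with a
# zero gradient (the L1 stabilizer takes over there).
iou_loss_grad <- function(p, g) {
  px1 <- p[1] - p[3] / 2; px2 <- p[1] + p[3] / 2
  py1 <- p[2] - p[4] / 2; py2 <- p[2] + p[4] / 2
  gx1 <- g[1] - g[3] / 2; gx2 <- g[1] + g[3] / 2
  gy1 <- g[2] - g[4] / 2; gy2 <- g[2] + g[4] / 2
  iw <- min(px2, gx2) - max(px1, gx1)
  ih <- min(py2, gy2) - max(py1, gy1)
  if (iw <= 0 || ih <= 0)
    return(list(loss = 1, iou = 0, grad = c(0, 0, 0, 0)))
  I <- iw * ih
  U <- p[3] * p[4] + g[3] * g[4] - I
  iou <- I / U
  dI_dpx1 <- if (px1 > gx1) -ih else 0
  dI_dpx2 <- if (px2 < gx2)  ih else 0
  dI_dpy1 <- if (py1 > gy1) -iw else 0
  dI_dpy2 <- if (py2 < gy2)  iw else 0
  dI <- c(cx = dI_dpx1 + dI_dpx2,
          cy = dI_dpy1 + dI_dpy2,
          w = 0.5 * (dI_dpx2 - dI_dpx1),
          h = 0.5 * (dI_dpy2 - dI_dpy1))
  dA <- c(0, 0, p[4], p[3])
  diou <- (dI * U - I * (dA - dI)) / U^2
  list(loss = 1 - iou, iou = iou, grad = -diou)
}
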