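# Lightweight CPU training engine: layers are environments carrying
# parameters, accumulated gradients and a forward cache; backward passes are
# hand-derived reverse-mode chains. Conv kernels run through the compiled
# im2col GEMM path; everything else is vectorized R.

silu <- function(x) x * stats::plogis(x)
dsilu <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

mod_new <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par_names <- character(0)
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

# Standard conv: k x k, given stride, "same" padding (k %/% 2), optional SiLU.
# Weight init uses gain 2 (sd = 2/sqrt(fan_in)) rather than He's sqrt(2):
# the network has no normalization layers, and SiLU's small-signal gain of
# ~0.5 would otherwise halve the activation scale at every layer.
mod_conv <- function(cin, cout, k = 3L, stride = 1L, act = TRUE,
                     bias = TRUE) {
  W <- matrix(rnorm(k * k * cin * cout, sd = 2 / sqrt(k * k * cin)),
              k * k * cin, cout)
  m <- mod_new("conv", k = as.integer(k), stride = as.integer(stride),
               pad = as.integer(k %/% 2), act = act, has_bias = bias,
               cin = as.integer(cin), cout = as.integer(cout),
               W = W, b = rep(0, cout))
  m$par_names <- if (bias) c("W", "b") else "W"
  zero_grads(m)
  m
}

fwd_conv <- function(m, x) {
  pre <- conv2d_fw(x, m$W, m$b, m$k, m$stride, m$pad)
  m$cache <- list(x = x, pre = if (m$act) pre else NULL)
  if (m$act) silu(pre) else pre
}

bwd_conv <- function(m, dy) {
  if (m$act) dy <- dy * dsilu(m$cache$pre)
  r <- conv2d_bw(m$cache$x, m$W, dy, m$k, m$stride, m$pad)
  m$g_W <- m$g_W + r$dW
  if (m$has_bias) m$g_b <- m$g_b + as.numeric(r$db)
  r$dx
}

# Nearest-neighbour 2x upsampling (stateless).
mod_upsample <- function() mod_new("upsample")

fwd_upsample <- function(m, x) {
  d <- dim(x)
  m$cache <- list(d = d)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

bwd_upsample <- function(m, dy) {
  d <- m$cache$d
  o1 <- seq(1, 2 * d[1], by = 2)
  o2 <- seq(1, 2 * d[2], by = 2)
  dy[o1, o2, , drop = FALSE] + dy[o1 + 1, o2, , drop = FALSE] +
    dy[o1, o2 + 1, , drop = FALSE] + dy[o1 + 1, o2 + 1, , drop = FALSE]
}

# CSP-style residual fusion block ("C3K2"): a 1x1 conv splits into two
# halves; n bottlenecks (two 3x3 convs + residual) refine one half; all
# intermediate halves are concatenated and fused by a final 1x1 conv.
mod_c3k2 <- function(cin, cout, n = 1L) {
  h <- max(4L, as.integer(cout) %/% 2L)
  bts <- vector("list", n)
  for (i in seq_len(n))
    bts[[i]] <- list(cv1 = mod_conv(h, h, 3L), cv2 = mod_conv(h, h, 3L))
  mod_new("c3k2", h = h, n = as.integer(n),
          cv_in = mod_conv(cin, 2L * h, 1L),
          bts = bts,
          cv_out = mod_conv((2L + n) * h, cout, 1L))
}

fwd_c3k2 <- function(m, x) {
  y1 <- fwd_conv(m$cv_in, x)
  h <- m$h
  # parts: [a, c0 = b, c1, ..., cn] with c_i = c_{i-1} + f_i(c_{i-1})
  parts <- list(y1[, , seq_len(h), drop = FALSE],
                y1[, , h + seq_len(h), drop = FALSE])
  cur <- parts[[2]]
  for (i in seq_len(m$n)) {
    cur <- cur + fwd_conv(m$bts[[i]]$cv2, fwd_conv(m$bts[[i]]$cv1, cur))
    parts[[2 + i]] <- cur
  }
  d1 <- dim(y1)
  cat3 <- array(unlist(parts, use.names = FALSE),
                dim = c(d1[1], d1[2], (2L + m$n) * h))
  fwd_conv(m$cv_out, cat3)
}

bwd_c3k2 <- function(m, dy) {
  h <- m$h
  dcat <- bwd_conv(m$cv_out, dy)
  slot <- function(i) dcat[, , (i - 1L) * h + seq_len(h), drop = FALSE]
  # reverse the bottleneck chain: c_{i-1} receives its own concat slot plus
  # the residual and conv paths out of c_i
  dcur <- slot(2L + m$n)
  if (m$n > 0) for (i in m$n:1) {
    dthrough <- bwd_conv(m$bts[[i]]$cv1, bwd_conv(m$bts[[i]]$cv2, dcur))
    dcur <- slot(i + 1L) + dcur + dthrough
  }
  db <- if (m$n > 0) dcur else slot(2L)
  da <- slot(1L)
  dy1 <- array(0, dim = c(dim(da)[1], dim(da)[2], 2L * h))
  dy1[, , seq_len(h)] <- da
  dy1[, , h + seq_len(h)] <- db
  bwd_conv(m$cv_in, dy1)
}

# MSIV block (trainable: attention projection + DyT; kernels fixed buffers).
mod_msiv <- function(C, K = 3L, kernel_sizes = c(3L, 5L, 7L),
                     alpha_angle = 1.0, beta_offset = 2.0,
                     mode = "cyclic_shift", alpha_random = FALSE,
                     seed = NULL) {
  if (isTRUE(alpha_random)) {
    bank <- make_vortex_kernels(C, K, kernel_sizes = kernel_sizes,
                                seed = seed, alpha_random = TRUE)
  } else {
    bank <- make_vortex_kernels(C, K, alpha_angle, kernel_sizes)
  }
  flipped <- lapply(bank$groups, function(g) {
    k <- dim(g$kernel)[1]
    g$kernel[k:1, k:1, , drop = FALSE]
  })
  m <- mod_new("msiv", C = as.integer(C), K = as.integer(K),
               bank = bank, flipped = flipped, beta_offset = beta_offset,
               mode = mode, geom = list(),
               att_W = matrix(rnorm(K * C, sd = 1 / sqrt(C)), K, C),
               att_b = rep(0, K),
               dyt_alpha = 0.5, dyt_gamma = rep(1, C), dyt_beta = rep(0, C))
  m$par_names <- c("att_W", "att_b", "dyt_alpha", "dyt_gamma", "dyt_beta")
  zero_grads(m)
  m
}

# Per-resolution fixed geometry (shift matrices + warp coordinates), cached.
msiv_geometry <- function(m, H, W) {
  key <- paste0(H, "x", W)
  if (!is.null(m$geom[[key]])) return(m$geom[[key]])
  g <- lapply(m$bank$groups, function(gr) {
    co <- spatial_offset_coords(H, W, gr$theta, m$beta_offset)
    list(shift = spiral_shift_matrix(H, W, m$C, gr$theta),
         si = co$si, sj = co$sj)
  })
  m$geom[[key]] <- g
  g
}

fwd_msiv <- function(m, x) {
  d <- dim(x)
  geo <- msiv_geometry(m, d[1], d[2])
  branches <- vector("list", m$K)
  for (k in seq_len(m$K)) {
    fk <- dwconv_fw(x, m$bank$groups[[k]]$kernel) + x
    fch <- if (m$mode == "cyclic_shift") channel_shift_fw(fk, geo[[k]]$shift)
           else channel_broadcast_fw(fk, geo[[k]]$shift)
    branches[[k]] <- bilinear_warp_fw(fch, geo[[k]]$si, geo[[k]]$sj)
  }
  total <- Reduce(`+`, branches)
  pool <- apply(total, 3, mean)
  logits <- drop(m$att_W %*% pool) + m$att_b
  A <- stats::plogis(logits)
  fused <- branches[[1]] * A[1]
  if (m$K > 1) for (k in 2:m$K) fused <- fused + branches[[k]] * A[k]
  th <- tanh(m$dyt_alpha * fused)
  out <- sweep(sweep(th, 3, m$dyt_gamma, `*`), 3, m$dyt_beta, `+`)
  m$cache <- list(d = d, branches = branches, pool = pool, A = A,
                  fused = fused, th = th)
  out
}

bwd_msiv <- function(m, dy) {
  cc <- m$cache
  d <- cc$d
  geo <- msiv_geometry(m, d[1], d[2])
  # DyT backward
  m$g_dyt_beta <- m$g_dyt_beta + apply(dy, 3, sum)
  m$g_dyt_gamma <- m$g_dyt_gamma + apply(dy * cc$th, 3, sum)
  dth <- sweep(dy, 3, m$dyt_gamma, `*`)
  dpre <- dth * (1 - cc$th^2)
  m$g_dyt_alpha <- m$g_dyt_alpha + sum(dpre * cc$fused)
  dfused <- dpre * m$dyt_alpha
  # attention backward
  dA <- vapply(seq_len(m$K),
               function(k) sum(dfused * cc$branches[[k]]), numeric(1))
  dlogits <- dA * cc$A * (1 - cc$A)
  m$g_att_W <- m$g_att_W + dlogits %*% t(cc$pool)
  m$g_att_b <- m$g_att_b + dlogits
  dpool <- drop(t(m$att_W) %*% dlogits)
  dsum_per_px <- dpool / (d[1] * d[2])
  dshared <- array(rep(dsum_per_px, each = d[1] * d[2]), dim = d)
  dx <- array(0, dim = d)
  for (k in seq_len(m$K)) {
    dbranch <- dfused * cc$A[k] + dshared
    dfch <- bilinear_warp_bw(dbranch, geo[[k]]$si, geo[[k]]$sj, d[1], d[2])
    dfk <- if (m$mode == "cyclic_shift") channel_shift_bw(dfch, geo[[k]]$shift)
           else stop("literal_broadcast mode is not trainable")
    dx <- dx + dwconv_fw(dfk, m$flipped[[k]]) + dfk
  }
  dx
}

# --- generic dispatch ------------------------------------------------------

f_forward <- function(m, x) {
  switch(m$type,
         conv = fwd_conv(m, x),
         upsample = fwd_upsample(m, x),
         c3k2 = fwd_c3k2(m, x),
         msiv = fwd_msiv(m, x),
         identity = x,
         seq = {
           for (ch in m$children) x <- f_forward(ch, x)
           x
         },
         stop("unknown module type: ", m$type))
}

f_backward <- function(m, dy) {
  switch(m$type,
         conv = bwd_conv(m, dy),
         upsample = bwd_upsample(m, dy),
         c3k2 = bwd_c3k2(m, dy),
         msiv = bwd_msiv(m, dy),
         identity = dy,
         seq = {
           for (ch in rev(m$children)) dy <- f_backward(ch, dy)
           dy
         },
         stop("unknown module type: ", m$type))
}

mod_seq <- function(...) mod_new("seq", children = list(...))

# --- parameter walking -----------------------------------------------------

# All environments (with non-empty par_names) reachable from a module tree.
collect_modules <- function(m, acc = list()) {
  if (is.environment(m)) {
    if (length(m$par_names) > 0) acc[[length(acc) + 1L]] <- m
    for (nm in ls(m)) {
      v <- m[[nm]]
      if (is.environment(v) || is.list(v)) acc <- collect_modules(v, acc)
    }
  } else if (is.list(m) && !is.null(names(m)) || is.list(m)) {
    for (v in m) if (is.environment(v) || is.list(v))
      acc <- collect_modules(v, acc)
  }
  acc
}

zero_grads <- function(m) {
  for (nm in m$par_names) {
    p <- m[[nm]]
    m[[paste0("g_", nm)]] <- if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
                             else p * 0
  }
  invisible(m)
}

zero_all_grads <- function(mods) {
  for (m in mods) zero_grads(m)
  invisible(NULL)
}

n_params_of <- function(mods) {
  sum(vapply(mods, function(m)
    sum(vapply(m$par_names, function(nm) length(m[[nm]]), numeric(1))),
    numeric(1)))
}

# Flat named parameter list (for checkpoints and coef()).
flatten_params <- function(mods, prefix = "p") {
  out <- list()
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    for (nm in m$par_names)
      out[[sprintf("%s%03d.%s", prefix, i, nm)]] <- m[[nm]]
  }
  out
}

assign_params <- function(mods, flat, prefix = "p") {
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    for (nm in m$par_names) {
      key <- sprintf("%s%03d.%s", prefix, i, nm)
      v <- flat[[key]]
      if (is.null(v)) stop("checkpoint is missing parameter ", key)
      cur <- m[[nm]]
      if (length(v) != length(cur))
        stop("checkpoint shape mismatch for ", key)
      if (is.matrix(cur)) v <- matrix(v, nrow(cur), ncol(cur))
      else if (is.array(cur)) v <- array(v, dim(cur))
      m[[nm]] <- v
    }
  }
  invisible(NULL)
}

# --- Adam ------------------------------------------------------------------

adam_step <- function(mods, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      scale = 1, clip_norm = 5) {
  if (is.finite(clip_norm)) {
    gsq <- 0
    for (m in mods) for (nm in m$par_names)
      gsq <- gsq + sum((m[[paste0("g_", nm)]] * scale)^2)
    gn <- sqrt(gsq)
    if (gn > clip_norm) scale <- scale * clip_norm / gn
  }
  for (m in mods) {
    for (nm in m$par_names) {
      g <- m[[paste0("g_", nm)]] * scale
      mk <- paste0("am_", nm); vk <- paste0("av_", nm)
      if (is.null(m[[mk]])) { m[[mk]] <- g * 0; m[[vk]] <- g * 0 }
      m[[mk]] <- beta1 * m[[mk]] + (1 - beta1) * g
      m[[vk]] <- beta2 * m[[vk]] + (1 - beta2) * g^2
      mhat <- m[[mk]] / (1 - beta1^t)
      vhat <- m[[vk]] / (1 - beta2^t)
      m[[nm]] <- m[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}
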