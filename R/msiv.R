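# Multi-scale Spiral Information Vortex (MSIV) operator.
#
# A feature map is a plain numeric array indexed (row i, column j, channel c),
# i.e. dim = c(H, W, C). All MSIV stages preserve that shape. Row/column
# indices in the spiral formulas are 0-based.

DEG <- pi / 180

#' Validate a feature map array
#'
#' @param x numeric array with dim (H, W, C), all entries finite.
#' @return `x`, invisibly.
#' @keywords internal
check_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be a 3-d array (H, W, C)")
  if (!all(is.finite(x))) stop("feature map contains non-finite entries")
  invisible(x)
}

#' Generate a bank of rotated multi-scale vortex kernels
#'
#' Builds `K` groups of fixed (non-trainable) depthwise convolution kernels.
#' Group `k` carries an anisotropic 2-D Gaussian of size `s_k x s_k` whose
#' major axis is rotated by the vortex angle
#' `theta_k = clamp(alpha * k * pi / (2K), 15deg, 60deg)`,
#' normalized to sum to one and replicated over all `C` channels. The three
#' default sizes 3/5/7 target small, medium and large canopy structure.
#'
#' @param C channel count the kernels will be applied to.
#' @param K number of kernel groups (scales).
#' @param alpha_angle angle adjustment coefficient in `[0.5, 1.5]`. With
#'   `alpha_random = TRUE` a single coefficient is drawn uniformly from that
#'   interval at construction time (seeded); it is never redrawn per forward
#'   pass.
#' @param kernel_sizes odd kernel sizes, one per group.
#' @param seed integer seed used only when `alpha_random = TRUE`.
#' @param alpha_random draw `alpha_angle` from `[0.5, 1.5]` instead of using
#'   the supplied value.
#' @return An object of class `ivy_kernel_bank`: a list with `groups` (each
#'   holding `kernel` — an `s_k x s_k x C` array, `theta` in radians and
#'   `size`), the realized `alpha` and `K`.
#' @examples
#' bank <- make_vortex_kernels(C = 4, K = 3, alpha_angle = 0.5)
#' sapply(bank$groups, function(g) g$theta) / pi * 180  # 15 30 45
#' @export
make_vortex_kernels <- function(C, K = 3L, alpha_angle = 1.0,
                                kernel_sizes = c(3L, 5L, 7L),
                                seed = NULL, alpha_random = FALSE) {
  if (isTRUE(alpha_random)) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    alpha_angle <- runif(1L, 0.5, 1.5)
  }
  if (!is.numeric(alpha_angle) || alpha_angle < 0.5 || alpha_angle > 1.5)
    stop("alpha_angle must lie in [0.5, 1.5]")
  if (length(kernel_sizes) != K)
    stop("K must equal length(kernel_sizes)")
  if (any(kernel_sizes %% 2L != 1L))
    stop("kernel sizes must be odd so that padding s %/% 2 preserves shape")
  groups <- vector("list", K)
  for (k in seq_len(K)) {
    theta <- vortex_angle(k, K, alpha_angle)
    s <- as.integer(kernel_sizes[k])
    g <- gaussian_vortex_kernel(s, theta)
    groups[[k]] <- list(kernel = array(g, dim = c(s, s, C)),
                        theta = theta, size = s)
  }
  structure(list(groups = groups, alpha = alpha_angle, K = K,
                 channels = as.integer(C)),
            class = "ivy_kernel_bank")
}

#' Vortex rotation angle for one kernel group
#'
#' `theta_k = alpha * k * pi / (2K)`, clamped to `[15, 60]` degrees.
#'
#' @param k group index (1-based), `K` group count, `alpha` coefficient.
#' @return angle in radians.
#' @export
vortex_angle <- function(k, K, alpha) {
  theta <- alpha * k * pi / (2 * K)
  min(max(theta, 15 * DEG), 60 * DEG)
}

# Anisotropic 2-D Gaussian rotated so its major axis lies at angle theta.
# sigma_major = s/3, sigma_minor = s/6: anisotropy makes the rotation
# observable; normalized to sum 1 so the kernel is averaging, not amplifying.
gaussian_vortex_kernel <- function(s, theta) {
  half <- (s - 1) / 2
  u <- matrix(rep(-half:half, s), s, s)          # row offset
  v <- t(u)                                      # column offset
  ct <- cos(theta); st <- sin(theta)
  a <- u * ct + v * st                           # major-axis coordinate
  b <- -u * st + v * ct                          # minor-axis coordinate
  sM <- s / 3; sm <- s / 6
  g <- exp(-0.5 * ((a / sM)^2 + (b / sm)^2))
  g / sum(g)
}

#' Rotational residual convolution
#'
#' Depthwise-convolves a feature map with one vortex kernel group (stride 1,
#' zero padding `s %/% 2` so the spatial size is unchanged) and adds the input
#' back as a residual, so rotational perturbation cannot destroy the original
#' signal.
#'
#' @param F feature map array (H, W, C).
#' @param group one element of `make_vortex_kernels()$groups`.
#' @return feature map of identical shape.
#' @export
rotate_conv_residual <- function(F, group) {
  check_feature_map(F)
  if (dim(group$kernel)[3] != dim(F)[3])
    stop("kernel channel count does not match feature map channels")
  dwconv_fw(F, group$kernel) + F
}

# Per-pixel integer spiral shift matrix: floor(i sin(theta) + j cos(theta))
# mod C with a non-negative result; i, j are 0-based.
spiral_shift_matrix <- function(H, W, C, theta) {
  ii <- matrix(0:(H - 1), H, W)
  jj <- matrix(rep(0:(W - 1), each = H), H, W)
  s <- floor(ii * sin(theta) + jj * cos(theta)) %% C
  storage.mode(s) <- "integer"
  s
}

#' Spiral channel reorganization
#'
#' Re-indexes channels by a spatial-coordinate-driven spiral:
#' `shift(i,j) = floor(i*sin(theta) + j*cos(theta)) mod C` (non-negative).
#' In the default `cyclic_shift` mode every pixel's channel vector is rotated
#' by its shift, preserving all C values:
#' `out(i,j,c) = F(i,j, (c + shift(i,j)) mod C)`.
#' The `literal_broadcast` mode instead copies the single selected channel
#' into every output channel, `out(i,j,c) = F(i,j, shift(i,j))` — this
#' collapses channel diversity and is kept only for fidelity to the original
#' formulation.
#'
#' @param F feature map (H, W, C).
#' @param theta_k spiral angle in radians.
#' @param mode `"cyclic_shift"` (default) or `"literal_broadcast"`.
#' @return feature map of identical shape.
#' @export
channel_reorganize <- function(F, theta_k,
                               mode = c("cyclic_shift", "literal_broadcast")) {
  check_feature_map(F)
  mode <- match.arg(mode)
  d <- dim(F)
  s <- spiral_shift_matrix(d[1], d[2], d[3], theta_k)
  if (mode == "cyclic_shift") channel_shift_fw(F, s)
  else channel_broadcast_fw(F, s)
}

# Sample coordinate fields for the rotational offset, 0-based pixel units.
spatial_offset_coords <- function(H, W, theta, beta_offset) {
  beta_eff <- beta_offset / (H * W / 4)
  ii <- matrix(0:(H - 1), H, W)
  jj <- matrix(rep(0:(W - 1), each = H), H, W)
  raw <- beta_eff * (ii - H / 2) * (jj - W / 2)
  list(si = ii + raw * sin(theta), sj = jj + raw * cos(theta))
}

#' Rotational spatial reorganization
#'
#' Applies a position-dependent rotational offset and resamples the map by
#' bilinear interpolation. The raw offset magnitude
#' `beta * (i - H/2) * (j - W/2)` grows with the map area, so it is
#' normalized by `H*W/4`: the effective corner displacement is then about
#' `beta_offset` pixels regardless of resolution. The offset is split into
#' `delta_i = raw * sin(theta)` and `delta_j = raw * cos(theta)`;
#' out-of-bounds sample coordinates are clamped to the border.
#'
#' @param Fch feature map (H, W, C), typically channel-reorganized.
#' @param theta_k vortex angle in radians.
#' @param beta_offset non-negative offset strength in pixels (at the corner).
#' @return feature map of identical shape. `beta_offset = 0` is the exact
#'   identity.
#' @export
spatial_reorganize <- function(Fch, theta_k, beta_offset) {
  check_feature_map(Fch)
  if (!is.numeric(beta_offset) || beta_offset < 0)
    stop("beta_offset must be >= 0")
  d <- dim(Fch)
  co <- spatial_offset_coords(d[1], d[2], theta_k, beta_offset)
  bilinear_warp_fw(Fch, co$si, co$sj)
}

#' Attention-weighted fusion of multi-scale branches
#'
#' Pools the element-wise sum of the branches by global average pooling (a
#' C-vector of channel statistics), maps it through a learnable linear
#' projection `C -> K` and a sigmoid to obtain one weight per scale in
#' `(0, 1)`, and returns the weighted sum of the branches.
#'
#' @param branches list of K feature maps of identical shape.
#' @param projection list with `W` (`K x C` matrix) and `b` (length-K vector).
#' @return list with `output` (fused feature map) and `weights` (length-K
#'   vector of attention weights, each strictly in (0, 1)).
#' @export
attention_fuse <- function(branches, projection) {
  if (length(branches) == 0L) stop("need at least one branch")
  d <- dim(branches[[1]])
  for (b in branches)
    if (!identical(dim(b), d)) stop("branch shapes differ")
  K <- length(branches)
  if (nrow(projection$W) != K || ncol(projection$W) != d[3])
    stop("projection must map C channels to K logits")
  total <- Reduce(`+`, branches)
  pool <- apply(total, 3, mean)
  logits <- drop(projection$W %*% pool) + projection$b
  A <- stats::plogis(logits)
  out <- branches[[1]] * A[1]
  if (K > 1) for (k in 2:K) out <- out + branches[[k]] * A[k]
  list(output = out, weights = A)
}

#' Dynamic Tanh (DyT) layer
#'
#' Normalization-free elementwise transform `gamma_c * tanh(alpha * x) +
#' beta_c`, with a learnable scalar `alpha` and learnable per-channel vectors
#' `gamma`, `beta`. Output is bounded per channel in
#' `[beta_c - |gamma_c|, beta_c + |gamma_c|]`, which compresses extreme
#' activations the way a normalization layer would, without computing batch
#' statistics.
#'
#' @param x feature map (H, W, C), or any array whose last dimension is the
#'   channel axis.
#' @param params list with scalar `alpha` (> 0) and numeric vectors `gamma`,
#'   `beta` of length C.
#' @return array of the same shape as `x`.
#' @export
dyt <- function(x, params) {
  d <- dim(x)
  C <- if (is.null(d)) length(params$gamma) else d[length(d)]
  if (length(params$gamma) != C || length(params$beta) != C)
    stop("DyT gamma/beta length must match the channel dimension")
  t <- tanh(params$alpha * x)
  if (is.null(d)) return(params$gamma * t + params$beta)
  nd <- length(d)
  sweep(sweep(t, nd, params$gamma, `*`), nd, params$beta, `+`)
}

#' Default DyT parameter initialization
#' @param C channel count.
#' @param alpha initial scalar gain.
#' @return a DyT parameter list.
#' @export
dyt_params <- function(C, alpha = 0.5) {
  list(alpha = alpha, gamma = rep(1, C), beta = rep(0, C))
}

#' MSIV hyperparameter bundle
#'
#' Collects every knob of one MSIV block and materializes its fixed kernel
#' bank and (seeded) learnable parameters.
#'
#' @param C channel count of the maps this block will process.
#' @param K number of vortex scales.
#' @param kernel_sizes odd sizes, one per scale.
#' @param alpha_angle vortex angle coefficient in `[0.5, 1.5]`.
#' @param beta_offset spatial offset strength (pixels at the map corner).
#' @param channel_reorg_mode `"cyclic_shift"` or `"literal_broadcast"`.
#' @param alpha_random draw `alpha_angle` uniformly from `[0.5, 1.5]` at
#'   construction (seeded), instead of the fixed value.
#' @param seed seed for the attention projection initialization (and the
#'   alpha draw if requested).
#' @return list of class `ivy_msiv_params` with the kernel `bank`, attention
#'   `projection`, `dyt` parameters and all settings.
#' @export
msiv_params <- function(C, K = 3L, kernel_sizes = c(3L, 5L, 7L),
                        alpha_angle = 1.0, beta_offset = 2.0,
                        channel_reorg_mode = c("cyclic_shift",
                                               "literal_broadcast"),
                        alpha_random = FALSE, seed = 0L) {
  channel_reorg_mode <- match.arg(channel_reorg_mode)
  bank <- make_vortex_kernels(C, K, alpha_angle, kernel_sizes,
                              seed = seed, alpha_random = alpha_random)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  projection <- list(W = matrix(rnorm(K * C, sd = 1 / sqrt(C)), K, C),
                     b = rep(0, K))
  structure(list(C = as.integer(C), K = as.integer(K),
                 kernel_sizes = as.integer(kernel_sizes),
                 alpha_angle = bank$alpha, beta_offset = beta_offset,
                 channel_reorg_mode = channel_reorg_mode,
                 bank = bank, projection = projection,
                 dyt = dyt_params(C), seed = as.integer(seed)),
            class = "ivy_msiv_params")
}

#' MSIV forward pass (functional form)
#'
#' Runs the full vortex pipeline: for each scale k, rotational residual
#' convolution, spiral channel reorganization and rotational spatial
#' reorganization; then attention-weighted fusion of the K reorganized
#' branches, followed by one DyT layer. Exactly equivalent to chaining
#' [rotate_conv_residual()], [channel_reorganize()], [spatial_reorganize()],
#' [attention_fuse()] and [dyt()] by hand with the same parameters.
#'
#' @param F feature map (H, W, C).
#' @param params an `ivy_msiv_params` bundle for C channels.
#' @param return_weights also return the attention weights.
#' @return the transformed (H, W, C) feature map; if `return_weights = TRUE`,
#'   a list with `output` and `weights`.
#' @export
msiv_forward <- function(F, params, return_weights = FALSE) {
  check_feature_map(F)
  if (dim(F)[3] != params$C) stop("channel count does not match params")
  branches <- vector("list", params$K)
  for (k in seq_len(params$K)) {
    g <- params$bank$groups[[k]]
    Fk <- rotate_conv_residual(F, g)
    Fch <- channel_reorganize(Fk, g$theta, params$channel_reorg_mode)
    branches[[k]] <- spatial_reorganize(Fch, g$theta, params$beta_offset)
  }
  fused <- attention_fuse(branches, params$projection)
  out <- dyt(fused$output, params$dyt)
  if (return_weights) list(output = out, weights = fused$weights) else out
}

# --- RNG bracketing helpers: seed locally without disturbing the caller ---
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
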