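# Brute-force scalar oracles for the reorganization stages. These share no
# code with the vectorized/C++ implementations: every quantity is recomputed
# per pixel with plain scalar arithmetic, so they can serve as independent
# references on small inputs (intended for H, W, C <= 32).

#' Scalar reference for spiral channel reorganization
#'
#' Pure per-pixel loop implementation of the spiral channel reindexing,
#' written independently of [channel_reorganize()] for verification.
#'
#' @inheritParams channel_reorganize
#' @return feature map of identical shape.
#' @export
oracle_channel_reorganize <- function(F, theta_k,
                                      mode = c("cyclic_shift",
                                               "literal_broadcast")) {
  mode <- match.arg(mode)
  d <- dim(F)
  H <- d[1]; W <- d[2]; C <- d[3]
  out <- array(0, d)
  for (i in 0:(H - 1)) {
    for (j in 0:(W - 1)) {
      raw <- i * sin(theta_k) + j * cos(theta_k)
      sh <- floor(raw) %% C
      if (sh < 0) sh <- sh + C
      for (c in 0:(C - 1)) {
        src <- if (mode == "cyclic_shift") (c + sh) %% C else sh
        out[i + 1, j + 1, c + 1] <- F[i + 1, j + 1, src + 1]
      }
    }
  }
  out
}

#' Scalar reference for rotational spatial reorganization
#'
#' Pure per-pixel loop implementation of the offset-and-bilinear-sample
#' stage, with its own scalar bilinear interpolation and border clamping,
#' written independently of [spatial_reorganize()] for verification.
#'
#' @inheritParams spatial_reorganize
#' @return feature map of identical shape.
#' @export
oracle_spatial_reorganize <- function(Fch, theta_k, beta_offset) {
  d <- dim(Fch)
  H <- d[1]; W <- d[2]; C <- d[3]
  out <- array(0, d)
  for (i in 0:(H - 1)) {
    for (j in 0:(W - 1)) {
      raw <- (beta_offset / (H * W / 4)) * (i - H / 2) * (j - W / 2)
      u <- i + raw * sin(theta_k)
      v <- j + raw * cos(theta_k)
      if (u < 0) u <- 0
      if (u > H - 1) u <- H - 1
      if (v < 0) v <- 0
      if (v > W - 1) v <- W - 1
      i0 <- floor(u); j0 <- floor(v)
      i1 <- min(i0 + 1, H - 1); j1 <- min(j0 + 1, W - 1)
      fu <- u - i0; fv <- v - j0
      for (c in seq_len(C)) {
        out[i + 1, j + 1, c] <-
          (1 - fu) * (1 - fv) * Fch[i0 + 1, j0 + 1, c] +
          (1 - fu) * fv       * Fch[i0 + 1, j1 + 1, c] +
          fu       * (1 - fv) * Fch[i1 + 1, j0 + 1, c] +
          fu       * fv       * Fch[i1 + 1, j1 + 1, c]
      }
    }
  }
  out
}
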