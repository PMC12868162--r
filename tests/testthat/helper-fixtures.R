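# Shared helpers: numerical differentiation and small fixtures.

# central-difference directional gradient of sum(fwd(x) * dy) w.r.t. x
num_grad <- function(fwd, x, dy, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- sum((fwd(xp) - fwd(xm)) * dy) / (2 * eps)
  }
  g
}

tiny_model_config <- function(...)
  ivyolo_config(input_size = 96L, width = 0.25, ...)

tiny_scenes <- function(n = 2, size = 96, plants = 3, seed = 7) {
  cfg <- scene_config(image_size = size, n_plants = plants,
                      length_range = c(14, 24), width_range = c(5, 8),
                      seed = seed)
  lapply(seq_len(n), function(i) generate_scene(cfg, seed = seed + i - 1))
}

deg <- function(x) x * pi / 180
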