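# Multi-scale spiral vortex operator: kernels, reorganizations, attention,
# DyT, and the composed forward pass.

test_that("vortex angles follow the clamped angle law", {
  b <- make_vortex_kernels(C = 4, K = 3, alpha_angle = 1.0)
  expect_equal(sapply(b$groups, `[[`, "theta"),
               deg(c(30, 60, 60)))   # third clamped down from 90 degrees
  b2 <- make_vortex_kernels(C = 4, K = 3, alpha_angle = 0.5)
  expect_equal(sapply(b2$groups, `[[`, "theta"), deg(c(15, 30, 45)))
  # law holds over the full coefficient range and K values
  for (alpha in seq(0.5, 1.5, by = 0.25)) {
    for (K in 1:8) {
      th <- sapply(seq_len(K), vortex_angle, K = K, alpha = alpha)
      expect_true(all(th >= deg(15) - 1e-12 & th <= deg(60) + 1e-12))
      expect_true(!is.unsorted(th))   # non-decreasing in k
    }
  }
})

test_that("vortex kernels are normalized, non-negative, depthwise", {
  b <- make_vortex_kernels(C = 5, K = 3, alpha_angle = 1.2,
                           kernel_sizes = c(3, 5, 7))
  for (g in b$groups) {
    expect_equal(dim(g$kernel), c(g$size, g$size, 5))
    expect_true(all(g$kernel >= 0))
    for (c in 1:5) expect_equal(sum(g$kernel[, , c]), 1)
    # all channel slices identical (depthwise replication)
    expect_equal(g$kernel[, , 1], g$kernel[, , 3])
  }
})

test_that("kernel construction validates its configuration", {
  expect_error(make_vortex_kernels(4, 3, 1.0, kernel_sizes = c(3, 4, 7)),
               "odd")
  expect_error(make_vortex_kernels(4, 3, 2.0), "alpha")
  expect_error(make_vortex_kernels(4, 2, 1.0, kernel_sizes = c(3, 5, 7)),
               "K")
})

test_that("randomized angle coefficient is seeded and in range", {
  b1 <- make_vortex_kernels(4, 3, seed = 11, alpha_random = TRUE)
  b2 <- make_vortex_kernels(4, 3, seed = 11, alpha_random = TRUE)
  b3 <- make_vortex_kernels(4, 3, seed = 12, alpha_random = TRUE)
  expect_identical(b1$alpha, b2$alpha)
  expect_false(identical(b1$alpha, b3$alpha))
  expect_gte(b1$alpha, 0.5)
  expect_lte(b1$alpha, 1.5)
})

test_that("rotational residual convolution preserves shape and limits", {
  F <- make_feature_fixture(8, 8, 4, "random", seed = 1)
  b <- make_vortex_kernels(4, 3, 1.0)
  out <- rotate_conv_residual(F, b$groups[[2]])
  expect_equal(dim(out), c(8, 8, 4))
  expect_true(all(is.finite(out)))
  # zero kernel: residual only
  g0 <- b$groups[[1]]; g0$kernel[] <- 0
  expect_equal(rotate_conv_residual(F, g0), F)
  # centered delta: identity convolution + residual = 2F
  gd <- b$groups[[1]]; gd$kernel[] <- 0; gd$kernel[2, 2, ] <- 1
  expect_equal(rotate_conv_residual(F, gd), 2 * F)
  # channel mismatch rejected
  expect_error(rotate_conv_residual(make_feature_fixture(4, 4, 3, "random"),
                                    b$groups[[1]]), "channel")
})

test_that("channel reorganization matches its scalar oracle exactly", {
  set.seed(42)
  for (rep in 1:10) {
    H <- sample(2:16, 1); W <- sample(2:16, 1); C <- sample(2:16, 1)
    th <- runif(1, deg(15), deg(60))
    F <- make_feature_fixture(H, W, C, "random", seed = rep)
    for (mode in c("cyclic_shift", "literal_broadcast")) {
      expect_equal(channel_reorganize(F, th, mode),
                   oracle_channel_reorganize(F, th, mode))
    }
  }
})

test_that("channel reorganization fixed points and pixel (0,0)", {
  Fc <- make_feature_fixture(6, 7, 4, "constant", value = 3.5)
  for (mode in c("cyclic_shift", "literal_broadcast"))
    expect_equal(channel_reorganize(Fc, deg(30), mode), Fc)
  # shift at (0,0) is zero for any angle in (0, 90)
  F <- make_feature_fixture(4, 4, 3, "random", seed = 5)
  for (th in deg(c(15, 30, 60)))
    expect_equal(channel_reorganize(F, th)[1, 1, ], F[1, 1, ])
  # the ramp fixture agrees with the oracle entry by entry
  Fr <- make_feature_fixture(2, 2, 4, "ramp")
  expect_equal(channel_reorganize(Fr, deg(30)),
               oracle_channel_reorganize(Fr, deg(30)))
})

test_that("spatial reorganization matches its scalar oracle", {
  set.seed(17)
  for (rep in 1:10) {
    H <- sample(2:16, 1); W <- sample(2:16, 1); C <- sample(1:16, 1)
    th <- runif(1, deg(15), deg(60))
    beta <- runif(1, 0, 4)
    F <- make_feature_fixture(H, W, C, "random", seed = 100 + rep)
    expect_lt(max(abs(spatial_reorganize(F, th, beta) -
                        oracle_spatial_reorganize(F, th, beta))), 1e-5)
  }
})

test_that("spatial reorganization identities", {
  F <- make_feature_fixture(8, 8, 2, "random", seed = 3)
  # zero offset strength: exact identity
  expect_identical(spatial_reorganize(F, deg(30), 0), F)
  # the central row/column offsets vanish: values unchanged there
  out <- spatial_reorganize(F, deg(30), 2)
  expect_equal(out[5, , ], F[5, , ])   # i = H/2 (0-based row 4)
  expect_equal(out[, 5, ], F[, 5, ])   # j = W/2
  expect_error(spatial_reorganize(F, deg(30), -1), "beta")
})

test_that("attention fusion weights are sigmoid-bounded and linear", {
  F <- make_feature_fixture(5, 6, 4, "random", seed = 9)
  proj <- list(W = matrix(rnorm(3 * 4), 3, 4), b = rep(0, 3))
  branches <- lapply(1:3, function(k) F * k)
  fu <- attention_fuse(branches, proj)
  expect_true(all(fu$weights > 0 & fu$weights < 1))
  expect_equal(dim(fu$output), dim(F))
  # identical branches: output is (sum of weights) * F
  same <- attention_fuse(list(F, F, F), proj)
  expect_equal(same$output, sum(same$weights) * F)
  # single branch degenerate case
  p1 <- list(W = matrix(rnorm(4), 1, 4), b = 0)
  one <- attention_fuse(list(F), p1)
  expect_equal(one$output, one$weights[1] * F)
  # linearity at frozen weights: scaling branches scales the weighted sum
  sc <- lapply(branches, function(b) 2 * b)
  fu2 <- attention_fuse(sc, proj)
  manual <- Reduce(`+`, Map(`*`, sc, as.list(fu2$weights)))
  expect_equal(fu2$output, manual)
  expect_error(attention_fuse(list(), proj), "branch")
  expect_error(attention_fuse(list(F, F[1:4, , ]), proj), "shapes")
})

test_that("DyT matches its closed form and bounds", {
  p <- dyt_params(3); p$alpha <- 1
  x0 <- array(0, c(2, 2, 3))
  expect_equal(dyt(x0, p), array(0, c(2, 2, 3)))   # beta = 0 initially
  p$beta <- c(1, 2, 3)
  out0 <- dyt(x0, p)
  expect_equal(out0[1, 1, ], c(1, 2, 3))           # DyT(0) = beta
  expect_equal(dyt(array(0.5, c(1, 1, 3)),
                   list(alpha = 1, gamma = rep(1, 3), beta = rep(0, 3)))[1],
               tanh(0.5))
  # saturation toward gamma for large inputs
  expect_equal(dyt(array(1e6, c(1, 1, 3)),
                   list(alpha = 1, gamma = rep(1, 3), beta = rep(0, 3)))[1],
               1)
  # bounds beta +/- |gamma| and monotonicity for gamma > 0
  p2 <- list(alpha = 0.7, gamma = c(2, -1, 0.5), beta = c(0, 1, -1))
  x <- make_feature_fixture(6, 6, 3, "random", seed = 2) * 10
  y <- dyt(x, p2)
  for (c in 1:3) {
    expect_true(all(y[, , c] >= p2$beta[c] - abs(p2$gamma[c]) - 1e-12))
    expect_true(all(y[, , c] <= p2$beta[c] + abs(p2$gamma[c]) + 1e-12))
  }
  xs <- sort(rnorm(50))
  ys <- dyt(array(xs, c(50, 1, 1)),
            list(alpha = 0.5, gamma = 2, beta = 0))
  expect_true(!is.unsorted(as.numeric(ys)))
  expect_error(dyt(x, dyt_params(5)), "length")
})

test_that("msiv_forward equals the chained component operations", {
  F <- make_feature_fixture(10, 12, 6, "random", seed = 4)
  mp <- msiv_params(6, seed = 3)
  got <- msiv_forward(F, mp, return_weights = TRUE)
  branches <- lapply(seq_len(mp$K), function(k) {
    g <- mp$bank$groups[[k]]
    spatial_reorganize(
      channel_reorganize(rotate_conv_residual(F, g), g$theta,
                         mp$channel_reorg_mode),
      g$theta, mp$beta_offset)
  })
  fu <- attention_fuse(branches, mp$projection)
  expect_identical(got$output, dyt(fu$output, mp$dyt))
  expect_identical(got$weights, fu$weights)
  expect_equal(dim(got$output), dim(F))
  expect_true(all(got$weights > 0 & got$weights < 1))
})

test_that("msiv_forward is deterministic and channel-checked", {
  F <- make_feature_fixture(16, 16, 8, "random", seed = 21)
  mp <- msiv_params(8, seed = 5)
  expect_identical(msiv_forward(F, mp), msiv_forward(F, mp))
  mp2 <- msiv_params(8, seed = 5)
  expect_identical(msiv_forward(F, mp), msiv_forward(F, mp2))
  expect_error(msiv_forward(make_feature_fixture(4, 4, 3, "random"), mp),
               "channel")
})
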