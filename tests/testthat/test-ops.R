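# The loop-based reference implementations live in helper-oracles.R.

test_that("spatial_graph_conv matches the dense loop oracle", {
  g <- chain3_graph()
  for (norm in c(TRUE, FALSE)) {
    adj <- spatial_partition(g, normalize = norm)
    for (seed in 1:3) {
      set.seed(seed)
      f_in <- array(rnorm(2 * 1 * 3), c(2, 1, 3))
      params <- make_sgc_params(2, 2, 3, seed = seed + 20)
      got <- spatial_graph_conv(f_in, adj, params)
      expect_equal(got, oracle_graph_conv(f_in, adj, params),
                   tolerance = 1e-10)
    }
  }
  # larger fixture: V=4 star graph, T=3
  g4 <- skeleton_graph(4, rbind(c(1, 2), c(2, 3), c(2, 4)), 1)
  adj4 <- spatial_partition(g4)
  set.seed(9)
  f_in <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  params <- make_sgc_params(3, 5, 4, seed = 31)
  expect_equal(spatial_graph_conv(f_in, adj4, params),
               oracle_graph_conv(f_in, adj4, params), tolerance = 1e-10)
})

test_that("all-zero adjacency gives an all-zero graph convolution", {
  g <- chain3_graph()
  adj <- spatial_partition(g)
  adj$subsets <- lapply(adj$subsets, function(S) S * 0)
  set.seed(2)
  f_in <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  params <- make_sgc_params(2, 4, 3, seed = 3)
  expect_equal(spatial_graph_conv(f_in, adj, params),
               array(0, c(4, 2, 3)))
})

test_that("an all-ones mask equals the un-masked graph convolution", {
  g <- chain3_graph()
  adj <- spatial_partition(g)
  set.seed(5)
  f_in <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  p1 <- make_sgc_params(2, 3, 3, seed = 6, ones_mask = TRUE)
  # oracle with masks dropped entirely (M == 1 element-wise)
  p_ref <- p1; p_ref$M <- array(1, c(3, 3, 3))
  expect_equal(spatial_graph_conv(f_in, adj, p1),
               oracle_graph_conv(f_in, adj, p_ref), tolerance = 1e-10)
})

test_that("multi-head attention matches the explicit-loop oracle", {
  # V=3, H=1, d_k=d_v=2, fixed small weights
  set.seed(13)
  f_in <- array(rnorm(2 * 1 * 3), c(2, 1, 3))
  p <- small_attention_params(C_in = 2, dk = 2, dv = 2, H = 1, C_out = 2)
  expect_equal(multi_head_spatial_attention(f_in, p),
               oracle_attention(f_in, p), tolerance = 1e-10)
  # multi-head, multi-frame, rectangular projection
  set.seed(14)
  f2 <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  p2 <- small_attention_params(C_in = 3, dk = 2, dv = 3, H = 2,
                               C_out = 5, seed = 15)
  expect_equal(multi_head_spatial_attention(f2, p2),
               oracle_attention(f2, p2), tolerance = 1e-10)
})

test_that("attention rows sum to one for every head, frame and node", {
  set.seed(21)
  p <- small_attention_params(C_in = 3, dk = 2, dv = 2, H = 3, C_out = 4,
                              seed = 22)
  frame <- matrix(rnorm(3 * 6), 3, 6)
  alpha <- attention_coefficients(frame, p)
  expect_equal(apply(alpha, c(2, 3), sum), matrix(1, 6, 3),
               tolerance = 1e-12)
  expect_true(all(alpha > 0))
})

test_that("identical joint features give uniform attention 1/V", {
  p <- small_attention_params(C_in = 2, dk = 2, dv = 2, H = 2, C_out = 2,
                              seed = 23)
  frame <- matrix(rep(c(0.3, -1.2), 5), 2, 5)   # V=5 identical joints
  alpha <- attention_coefficients(frame, p)
  expect_equal(alpha, array(1 / 5, c(5, 5, 2)), tolerance = 1e-12)
})

test_that("attention is equivariant under joint permutation", {
  set.seed(31)
  p <- small_attention_params(C_in = 3, dk = 2, dv = 2, H = 2, C_out = 4,
                              seed = 32)
  f_in <- array(rnorm(3 * 2 * 6), c(3, 2, 6))
  perm <- c(4, 1, 6, 2, 5, 3)
  out <- multi_head_spatial_attention(f_in, p)
  out_perm <- multi_head_spatial_attention(f_in[, , perm, drop = FALSE], p)
  expect_equal(out_perm, out[, , perm, drop = FALSE], tolerance = 1e-10)
})

test_that("attention output at frame t depends only on frame t", {
  set.seed(41)
  p <- small_attention_params(C_in = 2, dk = 2, dv = 2, H = 1, C_out = 2,
                              seed = 42)
  f_in <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  f_mod <- f_in
  f_mod[, 2, ] <- f_mod[, 2, ] + 5   # perturb frame 2 only
  out <- multi_head_spatial_attention(f_in, p)
  out_mod <- multi_head_spatial_attention(f_mod, p)
  expect_equal(out_mod[, -2, ], out[, -2, ], tolerance = 1e-12)
  expect_gt(max(abs(out_mod[, 2, ] - out[, 2, ])), 1e-4)
})

test_that("attention residual: identity branch and projection branch", {
  set.seed(51)
  f_in <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  # C_in = C_out, f_o = 0 -> f_a = f_in
  expect_equal(attention_residual(array(0, dim(f_in)), f_in), f_in)
  # C_in != C_out, f_in = 0 -> f_a = f_o
  f_o <- array(rnorm(3 * 2 * 3), c(3, 2, 3))
  Wr <- matrix(rnorm(2 * 3), 2, 3)
  expect_equal(attention_residual(f_o, array(0, c(2, 2, 3)), Wr), f_o)
  # projection equals the loop-evaluated matrix product
  got <- attention_residual(f_o, f_in, Wr)
  want <- f_o
  for (t in 1:2) for (v in 1:3) {
    want[, t, v] <- f_o[, t, v] + as.vector(t(Wr) %*% f_in[, t, v])
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(attention_residual(f_o, f_in), "Wr")
})

test_that("gated combination semantics", {
  set.seed(61)
  f_g <- array(rnorm(12), c(2, 2, 3))
  f_a <- array(rnorm(12), c(2, 2, 3))
  # r = 1: the plain average, the gate-ablation form
  expect_equal(gated_combine(f_g, f_a, 1), (f_g + f_a) / 2)
  # r = 0: attention branch fully suppressed
  expect_equal(gated_combine(f_g, f_a, 0), f_g / 2)
  # identical branches and r = 1 pass through
  expect_equal(gated_combine(f_g, f_g, 1), f_g)
  expect_error(gated_combine(f_g, array(0, c(2, 3, 2))), "shape")
})

test_that("temporal convolution: unit kernel, stride arithmetic, oracle", {
  set.seed(71)
  f <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
  # K_t = 1 identity kernel
  Wid <- array(0, c(2, 2, 1)); Wid[, , 1] <- diag(2)
  expect_equal(temporal_conv(f, Wid), f)
  # stride-2 output length
  f128 <- array(rnorm(1 * 128 * 2), c(1, 128, 2))
  W1 <- array(1, c(1, 1, 1))
  expect_equal(dim(temporal_conv(f128, W1, stride = 2))[2], 64L)
  # K_t = 3 moving average on a ramp: interior equals the sliding mean
  ramp <- array(0, c(1, 10, 1)); ramp[1, , 1] <- 1:10
  Wma <- array(1 / 3, c(1, 1, 3))
  out <- temporal_conv(ramp, Wma)
  expect_equal(out[1, 2:9, 1], sapply(2:9, function(t) mean((t - 1):(t + 1))))
  # zero-padded edges
  expect_equal(out[1, 1, 1], mean(c(0, 1, 2)))
  expect_equal(out[1, 10, 1], mean(c(9, 10, 0)))
})

test_that("odd temporal kernels are enforced", {
  f <- array(0, c(1, 4, 1))
  expect_error(temporal_conv(f, array(1, c(1, 1, 2))), "odd")
})
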