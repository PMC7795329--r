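test_that("model output rows are probabilities and shapes are correct", {
  m <- tiny_model()
  set.seed(1)
  x <- array(rnorm(2 * 3 * 5 * 3), c(2, 3, 5, 3))   # N x C x T x V
  probs <- model_forward(m, x)
  expect_equal(dim(probs), c(2L, 3L))
  expect_equal(rowSums(probs), rep(1, 2), tolerance = 1e-12)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("default channel plan is the 10-block 32/64/128 stack", {
  cfg <- model_config()
  expect_equal(cfg$channels,
               c(32L, 32L, 32L, 32L, 64L, 64L, 64L, 128L, 128L, 128L))
  expect_length(cfg$channels, 10)
  # stride 2 exactly at the channel-doubling blocks
  expect_equal(which(cfg$strides == 2L), c(5L, 8L))
})

test_that("evaluation-mode forward is deterministic and per-sample", {
  m <- tiny_model()
  set.seed(2)
  x <- array(rnorm(4 * 3 * 5 * 3), c(4, 3, 5, 3))
  p1 <- model_forward(m, x)
  p2 <- model_forward(m, x)
  expect_identical(p1, p2)
  # permuting samples permutes rows identically
  perm <- c(3, 1, 4, 2)
  expect_equal(model_forward(m, x[perm, , , , drop = FALSE]),
               p1[perm, ], tolerance = 1e-12)
})

test_that("basic block forward is bit-identical across calls in eval mode", {
  m <- tiny_model()
  set.seed(3)
  f_in <- array(rnorm(3 * 5 * 3), c(3, 5, 3))
  o1 <- basic_block_forward(f_in, m$adj, m$params$blocks[[1]],
                            stride = 1, config = m$config)
  o2 <- basic_block_forward(f_in, m$adj, m$params$blocks[[1]],
                            stride = 1, config = m$config)
  expect_identical(o1, o2)
  expect_equal(dim(o1), c(4L, 5L, 3L))
  # stride-2 block halves the frame count (ceiling)
  o3 <- basic_block_forward(o1, m$adj, m$params$blocks[[2]],
                            stride = 2, config = m$config)
  expect_equal(dim(o3), c(6L, 3L, 3L))
})

test_that("parameter count matches the closed-form sum", {
  closed_form <- function(cfg) {
    V <- cfg$num_joints
    K <- 3
    nb <- length(cfg$channels)
    in_c <- c(cfg$in_channels, cfg$channels[-nb])
    total <- 2 * cfg$in_channels * V                     # data_bn
    for (i in seq_len(nb)) {
      ci <- in_c[i]; co <- cfg$channels[i]
      dk <- max(1, co %/% cfg$heads); dv <- dk
      total <- total + K * co * ci + K * co + K * V * V  # sgc W, b, M
      total <- total + 2 * ci * dk * cfg$heads +         # Wq, Wk
        ci * dv * cfg$heads + cfg$heads * dv * co        # Wv, Wo
      if (ci != co) total <- total + ci * co             # Wr
      total <- total + 1                                 # gate r
      total <- total + 2 * co                            # bn1
      total <- total + co * co * cfg$temporal_kernel + co  # tconv
      total <- total + 2 * co                            # bn2
      if (ci != co || cfg$strides[i] != 1) {
        total <- total + co * ci + co + 2 * co           # res conv + bn
      }
    }
    total + cfg$num_classes * cfg$channels[nb] + cfg$num_classes
  }
  m_small <- tiny_model()
  expect_equal(count_parameters(m_small), closed_form(m_small$config))
  cfg_full <- model_config()
  m_full <- sstgcn(cfg_full, seed = 1)
  expect_equal(count_parameters(m_full), closed_form(cfg_full))
})

test_that("with the gate at zero the output ignores attention parameters", {
  m <- tiny_model(seed = 11)
  for (i in seq_along(m$params$blocks)) m$params$blocks[[i]]$r <- 0
  set.seed(12)
  x <- array(rnorm(2 * 3 * 5 * 3), c(2, 3, 5, 3))
  base <- model_forward(m, x)
  m2 <- m
  set.seed(13)
  for (i in seq_along(m2$params$blocks)) {
    att <- m2$params$blocks[[i]]$att
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      att[[nm]] <- array(rnorm(length(att[[nm]])), dim(att[[nm]]))
    }
    m2$params$blocks[[i]]$att <- att
  }
  expect_equal(model_forward(m2, x), base, tolerance = 1e-12)
})

test_that("disabling the gate freezes r at 1 in the forward pass", {
  m <- tiny_model(seed = 21, gated = FALSE)
  set.seed(22)
  x <- array(rnorm(1 * 3 * 5 * 3), c(1, 3, 5, 3))
  base <- model_forward(m, x)
  # the stored r value is ignored when gating is disabled
  m2 <- m
  for (i in seq_along(m2$params$blocks)) m2$params$blocks[[i]]$r <- 99
  expect_equal(model_forward(m2, x), base, tolerance = 1e-12)
  # with gating enabled and r = 1 the layer equals the ablation form
  m3 <- m
  m3$config$gated <- TRUE
  for (i in seq_along(m3$params$blocks)) m3$params$blocks[[i]]$r <- 1
  expect_equal(model_forward(m3, x), base, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny model", {
  m <- tiny_model(seed = 31)
  set.seed(32)
  x <- array(rnorm(3 * 5 * 3 * 2), c(3, 5, 3, 2))
  y <- c(1, 3)
  loss_of <- function(model) {
    fwd <- net_fwd(model, x, training = TRUE)
    softmax_ce(fwd$logits, y)$loss
  }
  fwd <- net_fwd(m, x, training = TRUE)
  grads <- net_bwd(m, fwd$caches, softmax_ce(fwd$logits, y)$dlogits)
  eps <- 1e-5
  probe <- function(get, set, gval) {
    v <- get(m)
    n <- length(v)
    for (i in unique(c(1L, n %/% 2 + 1L, n))) {
      mp <- set(m, i, eps); mm <- set(m, i, -eps)
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(gval[i], num, tolerance = 1e-4)
    }
  }
  probe(function(m) m$params$blocks[[1]]$att$Wq,
        function(m, i, d) {
          m$params$blocks[[1]]$att$Wq[i] <-
            m$params$blocks[[1]]$att$Wq[i] + d; m
        },
        grads$blocks[[1]]$att$Wq)
  probe(function(m) m$params$blocks[[1]]$sgc$M,
        function(m, i, d) {
          m$params$blocks[[1]]$sgc$M[i] <-
            m$params$blocks[[1]]$sgc$M[i] + d; m
        },
        grads$blocks[[1]]$sgc$M)
  probe(function(m) m$params$blocks[[2]]$tconv$W,
        function(m, i, d) {
          m$params$blocks[[2]]$tconv$W[i] <-
            m$params$blocks[[2]]$tconv$W[i] + d; m
        },
        grads$blocks[[2]]$tconv$W)
  probe(function(m) m$params$fc$W,
        function(m, i, d) { m$params$fc$W[i] <- m$params$fc$W[i] + d; m },
        grads$fc$W)
  # gate gradients, both blocks
  for (b in 1:2) {
    mp <- m; mp$params$blocks[[b]]$r <- mp$params$blocks[[b]]$r + eps
    mm <- m; mm$params$blocks[[b]]$r <- mm$params$blocks[[b]]$r - eps
    expect_equal(grads$blocks[[b]]$r,
                 (loss_of(mp) - loss_of(mm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("checkpoints restore an identical model", {
  m <- tiny_model(seed = 41)
  m$classes <- c("a", "b", "c")
  set.seed(42)
  x <- array(rnorm(2 * 3 * 5 * 3), c(2, 3, 5, 3))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(model_forward(m2, x), model_forward(m, x))
  expect_equal(m2$classes, m$classes)
  expect_equal(m2$config, m$config)
  unlink(path)
})

test_that("mismatched input dimensions are rejected", {
  m <- tiny_model()
  expect_error(model_forward(m, array(0, c(1, 3, 5, 4))), "V=3")
  expect_error(model_forward(m, array(0, c(1, 2, 5, 3))), "channels")
})
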