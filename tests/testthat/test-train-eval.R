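test_that("UAR and WAR match hand-computed values on toy confusions", {
  r1 <- eval_report(rbind(c(5, 0), c(0, 5)))
  expect_equal(r1$uar, 1)
  expect_equal(r1$war, 1)
  # [[9,1],[4,1]]: recalls 0.9 and 0.2, accuracy 10/15
  r2 <- eval_report(rbind(c(9, 1), c(4, 1)))
  expect_equal(r2$uar, (0.9 + 0.2) / 2)
  expect_equal(r2$war, 10 / 15)
  expect_equal(r2$per_class_recall, c(0.9, 0.2))
  # all-one-class predictor on balanced 4-class data
  conf <- matrix(0, 4, 4); conf[, 1] <- 10
  expect_equal(eval_report(conf)$uar, 0.25)
})

test_that("absent class triggers a warning and UAR over present classes", {
  conf <- rbind(c(3, 1, 0), c(1, 3, 0), c(0, 0, 0))
  expect_warning(r <- eval_report(conf), "absent")
  expect_equal(r$uar, 0.75)
  expect_true(is.nan(r$per_class_recall[3]))
})

test_that("UAR is invariant to class-prevalence changes at fixed recalls", {
  conf <- rbind(c(8, 2), c(3, 7))
  # duplicate every sample of class 1: recalls unchanged
  conf2 <- conf; conf2[1, ] <- conf2[1, ] * 3
  expect_equal(eval_report(conf)$uar, eval_report(conf2)$uar)
  expect_false(isTRUE(all.equal(eval_report(conf)$war,
                                eval_report(conf2)$war)))
})

test_that("split realizes the 8 : 0.5 : 1.5 ratio", {
  samples <- lapply(seq_len(1000), function(i) {
    random_sequence(Tn = 2, V = 2, seed = i,
                    label = c("a", "b", "c", "d")[(i - 1) %% 4 + 1])
  })
  sp <- split_dataset(samples, split_spec(seed = 5))
  expect_length(sp$train, 800)
  expect_length(sp$dev, 50)
  expect_length(sp$test, 150)
  # stratification: each class near its overall share in every split
  for (part in sp) {
    tab <- table(sapply(part, function(s) s$label))
    expect_true(max(tab) - min(tab) <= 2)
  }
})

test_that("splits are deterministic, disjoint and exhaustive", {
  samples <- lapply(seq_len(97), function(i) {
    random_sequence(Tn = 2, V = 2, seed = i, label = (i - 1) %% 4 + 1)
  })
  sp1 <- split_dataset(samples, split_spec(seed = 3))
  sp2 <- split_dataset(samples, split_spec(seed = 3))
  ids <- function(part) sort(sapply(part, function(s) s$sample_id))
  expect_identical(lapply(sp1, ids), lapply(sp2, ids))
  all_ids <- c(ids(sp1$train), ids(sp1$dev), ids(sp1$test))
  expect_equal(sort(all_ids), ids(samples))
  expect_equal(anyDuplicated(all_ids), 0L)
  # a different seed gives a different partition
  sp3 <- split_dataset(samples, split_spec(seed = 4))
  expect_false(identical(ids(sp1$train), ids(sp3$train)))
})

test_that("cross-entropy of a uniform 4-class model is log(4)", {
  g <- build_upper_body_graph()
  cfg <- model_config(channels = c(4, 4), strides = c(1, 1),
                      temporal_kernel = 3, t_fix = 4, dropout = 0)
  m <- sstgcn(cfg, g, seed = 1)
  # zero output layer -> equal logits -> uniform probabilities
  m$params$fc$W[] <- 0
  m$params$fc$b[] <- 0
  set.seed(2)
  x <- array(rnorm(3 * 4 * 10 * 8), c(3, 4, 10, 8))
  fwd <- net_fwd(m, x, training = FALSE)
  ce <- softmax_ce(fwd$logits, rep(1:4, 2))
  expect_equal(ce$loss, log(4), tolerance = 1e-10)
  expect_equal(as.vector(ce$probs), rep(0.25, 32), tolerance = 1e-12)
})

test_that("training is deterministic: same seed, same losses", {
  fx <- make_tiny_fixture()
  samples <- lapply(fx$samples, standardize_length,
                    policy = length_policy(5))
  cfg <- tiny_model_config(num_classes = 2)
  run <- function() {
    m <- sstgcn(cfg, fx$graph, seed = 9)
    train_model(m, samples, epochs = 3, batch_size = 4, seed = 17)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$final_loss, f2$final_loss)
})

test_that("WAR equals accuracy computed independently from predictions", {
  fx <- make_tiny_fixture()
  samples <- lapply(fx$samples, standardize_length,
                    policy = length_policy(5))
  m <- sstgcn(tiny_model_config(num_classes = 2), fx$graph, seed = 5)
  m$classes <- c("1", "2")
  rep <- suppressWarnings(evaluate(m, samples))
  probs <- predict_scores(m, samples)
  pred <- max.col(probs, ties.method = "first")
  truth <- match(sapply(samples, function(s) as.character(s$label)),
                 m$classes)
  expect_equal(rep$war, mean(pred == truth))
  expect_equal(sum(rep$confusion), length(samples))
})

test_that("a tiny model overfits a tiny separable set", {
  # two classes distinguished by a large constant offset; a handful of
  # gradient steps must reach perfect training accuracy
  set.seed(33)
  samples <- lapply(1:12, function(i) {
    cls <- (i - 1) %% 2 + 1
    coords <- array(rnorm(5 * 3 * 3, sd = 0.05), c(5, 3, 3))
    coords[, , 1] <- coords[, , 1] + ifelse(cls == 1, -1, 1)
    skeleton_sequence(coords, label = cls, sample_id = paste0("s", i))
  })
  m <- sstgcn(tiny_model_config(num_classes = 2), chain3_graph(), seed = 2)
  fit <- train_model(m, samples, epochs = 40, lr = 0.05, batch_size = 4,
                     seed = 3, stop_at_train_acc = 1.0)
  rep <- suppressWarnings(evaluate(fit$model, samples))
  expect_gte(rep$war, 0.95)
  expect_lt(fit$epochs_run, 41)
})

test_that("a non-finite loss aborts training with a diagnostic", {
  fx <- make_tiny_fixture()
  samples <- lapply(fx$samples, standardize_length,
                    policy = length_policy(5))
  m <- sstgcn(tiny_model_config(num_classes = 2), fx$graph, seed = 1)
  m$params$fc$W[1] <- NaN    # corrupted state must be caught, not trained on
  expect_error(
    train_model(m, samples, epochs = 2, batch_size = 4, seed = 1),
    "diverged")
})
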