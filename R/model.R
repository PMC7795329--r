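#' Network architecture configuration
#'
#' The classifier stacks basic blocks, each combining a self-attention
#' enhanced spatial graph convolution (S-SGC) with a temporal convolution
#' of receptive field `(K_t, 1)`, followed by global average pooling and a
#' linear output layer with softmax. The default plan is the 10-block stack
#' with output channels 32, 32, 32, 32, 64, 64, 64, 128, 128, 128;
#' temporal stride 2 is applied at the channel-doubling blocks (5 and 8).
#' Shorter stacks (e.g. `blocks = 4`) are supported for fast experiments.
#'
#' @param num_classes Number of emotion classes.
#' @param num_joints Joints V in the skeleton graph.
#' @param in_channels Input feature channels (3 for xyz coordinates).
#' @param channels Integer vector of per-block output channels.
#' @param strides Integer vector of per-block temporal strides (1 or 2);
#'   default puts stride 2 wherever the channel count doubles.
#' @param temporal_kernel Odd temporal kernel size K_t.
#' @param heads Attention heads H per S-SGC layer.
#' @param d_k,d_v Per-head query/key and value dimensions; default
#'   `max(1, out_channels / heads)` per layer.
#' @param dropout Dropout rate after the temporal convolution.
#' @param t_fix Fixed input length the model expects (see
#'   [standardize_length()]).
#' @param gated If `TRUE` the attention branch is weighted by a trainable
#'   per-layer scalar r (initialized at 1); if `FALSE` r is frozen at 1,
#'   the ablation variant.
#' @return An object of class `model_config`.
#' @export
model_config <- function(num_classes = 4, num_joints = 10, in_channels = 3,
                         channels = c(32, 32, 32, 32, 64, 64, 64,
                                      128, 128, 128),
                         strides = NULL, temporal_kernel = 9, heads = 4,
                         d_k = NULL, d_v = NULL, dropout = 0.5,
                         t_fix = 128, gated = TRUE) {
  channels <- as.integer(channels)
  if (is.null(strides)) {
    prev <- c(channels[1], channels[-length(channels)])
    strides <- ifelse(channels > prev, 2L, 1L)
  }
  strides <- as.integer(strides)
  if (length(strides) != length(channels)) {
    stop("strides and channels must have the same length")
  }
  if (temporal_kernel %% 2 != 1) stop("temporal_kernel must be odd")
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (!all(strides %in% c(1L, 2L))) stop("strides must be 1 or 2")
  structure(list(num_classes = as.integer(num_classes),
                 num_joints = as.integer(num_joints),
                 in_channels = as.integer(in_channels),
                 channels = channels, strides = strides,
                 temporal_kernel = as.integer(temporal_kernel),
                 heads = as.integer(heads), d_k = d_k, d_v = d_v,
                 dropout = dropout, t_fix = as.integer(t_fix),
                 gated = isTRUE(gated)),
            class = "model_config")
}

#' Read / write a model configuration as YAML
#' @param path File path.
#' @return `read_model_config` returns a [model_config()].
#' @export
read_model_config <- function(path) {
  do.call(model_config, yaml::read_yaml(path))
}

#' @rdname read_model_config
#' @param config A [model_config()].
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

layer_dims <- function(cfg, c_out) {
  dk <- if (is.null(cfg$d_k)) max(1L, c_out %/% cfg$heads) else cfg$d_k
  dv <- if (is.null(cfg$d_v)) max(1L, c_out %/% cfg$heads) else cfg$d_v
  list(dk = as.integer(dk), dv = as.integer(dv))
}

init_block_params <- function(c_in, c_out, V, cfg, K = 3L) {
  ld <- layer_dims(cfg, c_out)
  Kt <- cfg$temporal_kernel
  p <- list(
    sgc = list(W = glorot(c(K * c_out, c_in), c_in, c_out),
               b = numeric(K * c_out),
               M = array(1, c(V, V, K))),
    att = list(Wq = glorot(c(c_in, ld$dk, cfg$heads), c_in, ld$dk),
               Wk = glorot(c(c_in, ld$dk, cfg$heads), c_in, ld$dk),
               Wv = glorot(c(c_in, ld$dv, cfg$heads), c_in, ld$dv),
               Wo = glorot(c(cfg$heads * ld$dv, c_out),
                           cfg$heads * ld$dv, c_out)),
    r = 1,
    bn1 = list(g = rep(1, c_out), b = numeric(c_out)),
    tconv = list(W = glorot(c(c_out, c_out, Kt), c_out * Kt, c_out),
                 b = numeric(c_out)),
    bn2 = list(g = rep(1, c_out), b = numeric(c_out))
  )
  if (c_in != c_out) {
    p$att$Wr <- glorot(c(c_in, c_out), c_in, c_out)
  }
  p
}

init_block_state <- function(c_out, has_res) {
  s <- list(bn1 = list(rm = numeric(c_out), rv = rep(1, c_out)),
            bn2 = list(rm = numeric(c_out), rv = rep(1, c_out)))
  if (has_res) s$resbn <- list(rm = numeric(c_out), rv = rep(1, c_out))
  s
}

#' Construct a two-branch spatial-temporal graph convolutional classifier
#'
#' Initializes all trainable parameters of the network described by
#' `config` on the given skeleton graph: for every block the graph
#' convolution weights W_k with per-subset masks M_k (initialized to
#' all-ones), the per-head attention projections W_Q, W_K, W_V with output
#' projection W_O (plus the channel-matching residual projection W_R where
#' needed), the gate scalar r (initialized to 1), temporal convolution
#' weights, and batch-normalization parameters; then global pooling and
#' the linear output layer.
#'
#' @param config A [model_config()].
#' @param graph A [skeleton_graph()] with `config$num_joints` joints.
#' @param seed Optional integer seed controlling weight initialization.
#' @return An object of class `sstgcn_model`.
#' @export
sstgcn <- function(config = model_config(), graph = build_upper_body_graph(),
                   seed = NULL) {
  if (graph$num_joints != config$num_joints) {
    stop("graph joint count does not match config$num_joints")
  }
  if (!is.null(seed)) set.seed(seed)
  adj <- spatial_partition(graph)
  V <- config$num_joints
  nb <- length(config$channels)
  in_c <- c(config$in_channels,
            config$channels[-nb])
  blocks <- vector("list", nb)
  bstate <- vector("list", nb)
  for (i in seq_len(nb)) {
    blocks[[i]] <- init_block_params(in_c[i], config$channels[i], V, config)
    has_res <- in_c[i] != config$channels[i] || config$strides[i] != 1L
    if (has_res) {
      blocks[[i]]$res <- list(
        W = array(glorot(c(config$channels[i], in_c[i]),
                         in_c[i], config$channels[i]),
                  c(config$channels[i], in_c[i], 1)),
        b = numeric(config$channels[i]),
        bn = list(g = rep(1, config$channels[i]),
                  b = numeric(config$channels[i])))
    }
    bstate[[i]] <- init_block_state(config$channels[i], has_res)
  }
  cf <- config$channels[nb]
  params <- list(
    data_bn = list(g = rep(1, config$in_channels * V),
                   b = numeric(config$in_channels * V)),
    blocks = blocks,
    fc = list(W = glorot(c(config$num_classes, cf), cf, config$num_classes),
              b = numeric(config$num_classes)))
  state <- list(
    data_bn = list(rm = numeric(config$in_channels * V),
                   rv = rep(1, config$in_channels * V)),
    blocks = bstate)
  structure(list(config = config, graph = graph, adj = adj,
                 params = params, state = state, classes = NULL),
            class = "sstgcn_model")
}

#' @export
print.sstgcn_model <- function(x, ...) {
  cat(sprintf(
    "sstgcn_model: %d blocks (channels %s), V=%d, %d classes, %s parameters\n",
    length(x$config$channels),
    paste(x$config$channels, collapse = ","),
    x$config$num_joints, x$config$num_classes,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- block forward / backward ----------------------------------------------

block_fwd <- function(x, p, s, adj, stride, cfg, training) {
  cache <- list()
  c1 <- conv1x1_fwd(x, p$sgc$W, p$sgc$b)
  ga <- graph_aggregate_fwd(c1$out, adj$subsets, p$sgc$M)
  at <- attention_fwd(x, p$att)
  rs <- residual_fwd(x, p$att$Wr)
  fa <- at$out + rs$out
  r_eff <- if (cfg$gated) p$r else 1
  gt <- gate_fwd(ga$out, fa, r_eff)
  bn1 <- bn_fwd(gt$out, p$bn1, s$bn1, training)
  rl1 <- relu_fwd(bn1$out)
  tc <- tconv_fwd(rl1$out, p$tconv$W, p$tconv$b, stride)
  bn2 <- bn_fwd(tc$out, p$bn2, s$bn2, training)
  dp <- dropout_fwd(bn2$out, cfg$dropout, training)
  if (is.null(p$res)) {
    resid <- x
    rc <- NULL; rbn <- NULL
  } else {
    rc <- tconv_fwd(x, p$res$W, p$res$b, stride)
    rbn <- bn_fwd(rc$out, p$res$bn, s$resbn, training)
    resid <- rbn$out
  }
  pre <- dp$out + resid
  out <- relu_fwd(pre)
  new_s <- list(bn1 = bn1$state, bn2 = bn2$state)
  if (!is.null(rbn)) new_s$resbn <- rbn$state
  list(out = out$out,
       cache = list(c1 = c1$cache, ga = ga$cache, at = at$cache,
                    rs = rs$cache, gt = gt$cache, bn1 = bn1$cache,
                    rl1 = rl1$cache, tc = tc$cache, bn2 = bn2$cache,
                    dp = dp$cache, rc = if (is.null(rc)) NULL else rc$cache,
                    rbn = if (is.null(rbn)) NULL else rbn$cache,
                    out = out$cache, identity_res = is.null(p$res)),
       state = new_s)
}

block_bwd <- function(dout, cache, p, cfg) {
  g <- list()
  dpre <- relu_bwd(dout, cache$out)
  # main path
  ddp <- dropout_bwd(dpre, cache$dp)
  bn2 <- bn_bwd(ddp, cache$bn2)
  g$bn2 <- list(g = bn2$dg, b = bn2$db)
  tc <- tconv_bwd(bn2$dx, cache$tc)
  g$tconv <- list(W = tc$dW, b = tc$db)
  drl <- relu_bwd(tc$dx, cache$rl1)
  bn1 <- bn_bwd(drl, cache$bn1)
  g$bn1 <- list(g = bn1$dg, b = bn1$db)
  gt <- gate_bwd(bn1$dx, cache$gt)
  # graph-conv branch
  ga <- graph_aggregate_bwd(gt$dfg, cache$ga)
  c1 <- conv1x1_bwd(ga$dx, cache$c1)
  g$sgc <- list(W = c1$dW, b = c1$db, M = ga$dM)
  # attention branch
  at <- attention_bwd(gt$dfa, cache$at)
  rs <- residual_bwd(gt$dfa, cache$rs)
  g$att <- list(Wq = at$dWq, Wk = at$dWk, Wv = at$dWv, Wo = at$dWo)
  if (!is.null(rs$dWr)) g$att$Wr <- rs$dWr
  g$r <- if (cfg$gated) gt$dr else 0
  dx <- c1$dx + at$dx + rs$dx
  # block residual path
  if (cache$identity_res) {
    dx <- dx + dpre
  } else {
    rbn <- bn_bwd(dpre, cache$rbn)
    rc <- tconv_bwd(rbn$dx, cache$rc)
    g$res <- list(W = rc$dW, b = rc$db, bn = list(g = rbn$dg, b = rbn$db))
    dx <- dx + rc$dx
  }
  list(dx = dx, grads = g)
}

# ---- whole-network forward / backward ---------------------------------------

# x: (C, T, V, N) batch; returns logits (classes x N), caches, new bn state
net_fwd <- function(model, x, training) {
  cfg <- model$config
  p <- model$params
  s <- model$state
  d <- dims4(x)
  # input normalization over (channel, joint) features
  xp <- aperm(x, c(1, 3, 2, 4))                      # (C, V, T, N)
  bn0 <- bn_mat_fwd(matrix(xp, d[1] * d[3], d[2] * d[4]),
                    p$data_bn$g, p$data_bn$b,
                    s$data_bn$rm, s$data_bn$rv, training)
  h <- aperm(array(bn0$out, c(d[1], d[3], d[2], d[4])), c(1, 3, 2, 4))
  bcaches <- vector("list", length(p$blocks))
  bstates <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bf <- block_fwd(h, p$blocks[[i]], s$blocks[[i]], model$adj,
                    cfg$strides[i], cfg, training)
    h <- bf$out
    bcaches[[i]] <- bf$cache
    bstates[[i]] <- bf$state
  }
  pl <- pool_fwd(h)
  fc <- linear_fwd(pl$out, p$fc$W, p$fc$b)
  list(logits = fc$out,
       caches = list(bn0 = c(bn0$cache, list(d = d)), blocks = bcaches,
                     pool = pl$cache, fc = fc$cache),
       state = list(data_bn = list(rm = bn0$rm, rv = bn0$rv),
                    blocks = bstates))
}

net_bwd <- function(model, caches, dlogits) {
  cfg <- model$config
  p <- model$params
  fc <- linear_bwd(dlogits, caches$fc)
  dh <- pool_bwd(fc$dx, caches$pool)
  bgrads <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bb <- block_bwd(dh, caches$blocks[[i]], p$blocks[[i]], cfg)
    dh <- bb$dx
    bgrads[[i]] <- bb$grads
  }
  d <- caches$bn0$d
  dxp <- matrix(aperm(dh, c(1, 3, 2, 4)), d[1] * d[3], d[2] * d[4])
  bn0 <- bn_mat_bwd(dxp, caches$bn0)
  list(data_bn = list(g = bn0$dg, b = bn0$db),
       blocks = bgrads,
       fc = list(W = fc$dW, b = fc$db))
}

# ---- public forward ---------------------------------------------------------

# convert a list of equal-length sequences into a (C, T, V, N) batch
batch_from_samples <- function(samples) {
  Tn <- n_frames(samples[[1]])
  V <- n_joints_seq(samples[[1]])
  N <- length(samples)
  x <- array(0, c(3, Tn, V, N))
  for (n in seq_len(N)) {
    if (n_frames(samples[[n]]) != Tn || n_joints_seq(samples[[n]]) != V) {
      stop("all samples in a batch must share T and V; ",
           "use standardize_length() first")
    }
    x[, , , n] <- aperm(samples[[n]]$coords, c(3, 1, 2))
  }
  x
}

#' Forward pass: class probabilities for a batch
#'
#' Runs input normalization, the block stack, global average pooling over
#' time and joints, and the linear output layer; returns softmax
#' probabilities.
#'
#' @param model An [sstgcn()] model.
#' @param x Either a numeric array in batch-first order `N x C x T x V`,
#'   a single-sample `C x T x V` array, or a list of
#'   [skeleton_sequence()] objects with equal frame counts.
#' @param training If `TRUE`, batch statistics and dropout are active
#'   (used by the training loop); default `FALSE` for inference.
#' @return An `N x num_classes` matrix of class probabilities, rows
#'   summing to 1.
#' @export
model_forward <- function(model, x, training = FALSE) {
  if (is.list(x) && !is.array(x)) x <- batch_from_samples(x)
  else if (length(dim(x)) == 3) x <- aperm(array(x, c(dim(x), 1)),
                                           c(1, 2, 3, 4))
  else if (length(dim(x)) == 4) x <- aperm(x, c(2, 3, 4, 1))  # N-first in
  d <- dims4(x)
  if (d[1] != model$config$in_channels) {
    stop(sprintf("expected %d input channels, got %d",
                 model$config$in_channels, d[1]))
  }
  if (d[3] != model$config$num_joints) {
    stop(sprintf("expected V=%d joints, got %d",
                 model$config$num_joints, d[3]))
  }
  fwd <- net_fwd(model, x, training)
  t(softmax_cols(fwd$logits))
}

#' Pooled feature embeddings for a batch of sequences
#'
#' The global-average-pooled feature vector feeding the output layer; used
#' as the skeleton modality embedding in multimodal fusion.
#'
#' @inheritParams model_forward
#' @param samples List of [skeleton_sequence()] objects.
#' @return An `N x C_final` matrix.
#' @export
skeleton_embedding <- function(model, samples) {
  x <- batch_from_samples(samples)
  cfg <- model$config
  fwd <- net_fwd(model, x, training = FALSE)
  emb <- t(fwd$caches$fc$x)
  rownames(emb) <- vapply(samples, function(s) s$sample_id, "")
  emb
}

#' Number of trainable parameters
#'
#' Counts every entry of every trainable array (the gate scalars are
#' excluded when gating is disabled, since they are frozen).
#'
#' @param model An [sstgcn()] model.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  n <- length(unlist(model$params))
  if (!model$config$gated) {
    n <- n - length(model$params$blocks)    # frozen gate scalars
  }
  n
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it stores the full configuration,
#' graph, parameters, normalization statistics and class labels, so it can
#' be reloaded without the original config file.
#'
#' @param model An [sstgcn()] model.
#' @param path File path (`.rds`).
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = unclass(model$config),
              graph = unclass(model$graph),
              params = model$params, state = model$state,
              classes = model$classes)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "model_config")
  graph <- skeleton_graph(obj$graph$num_joints, obj$graph$edges,
                          obj$graph$center_joint, obj$graph$joint_names)
  model <- structure(list(config = cfg, graph = graph,
                          adj = spatial_partition(graph),
                          params = obj$params, state = obj$state,
                          classes = obj$classes),
                     class = "sstgcn_model")
  model
}
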