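# Two-stream (joint + bone) fusion and the generic multimodal late-fusion
# head. Score matrices are N x num_classes with sample ids as row names.

check_matched_scores <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("score matrices must have identical dimensions")
  }
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("sample ids of the two streams do not match")
  }
}

#' Two-stream fusion by score summation
#'
#' Adds the per-sample softmax scores of the joint-stream and bone-stream
#' models element-wise and predicts the argmax; ties resolve to the
#' lowest class index.
#'
#' @param scores_joint,scores_bone `N x num_classes` softmax score
#'   matrices with matching sample ids.
#' @return List with `scores` (summed), `predictions` (1-based class
#'   indices).
#' @export
two_stream_fuse_sum <- function(scores_joint, scores_bone) {
  check_matched_scores(scores_joint, scores_bone)
  fused <- scores_joint + scores_bone
  list(scores = fused,
       predictions = max.col(fused, ties.method = "first"))
}

# full-batch gradient-descent training of a linear softmax head
# X: N x d design matrix; labels: 1-based; W: k x d, b: k
train_linear_head <- function(X, labels, k, W0, b0, epochs, lr, momentum) {
  W <- W0; b <- b0
  vW <- W * 0; vb <- b * 0
  n <- nrow(X)
  Y <- matrix(0, k, n); Y[cbind(labels, seq_len(n))] <- 1
  for (ep in seq_len(epochs)) {
    logits <- W %*% t(X) + b
    probs <- softmax_cols(logits)
    dlog <- (probs - Y) / n
    gW <- dlog %*% X
    gb <- rowSums(dlog)
    vW <- momentum * vW - lr * gW; vb <- momentum * vb - lr * gb
    W <- W + vW; b <- b + vb
  }
  list(W = W, b = b)
}

#' Two-stream fusion through a trained fully connected layer
#'
#' Concatenates the two streams' score vectors into a length
#' `2 * num_classes` input and trains a single linear layer with softmax
#' output by full-batch gradient descent on cross-entropy. The layer is
#' initialized with paired identity weights, which reproduces summation
#' fusion exactly before training, so the trained head can only move away
#' from summation where the data supports it.
#'
#' @param scores_joint,scores_bone Training-set score matrices
#'   (`N x num_classes`) with matching sample ids.
#' @param labels_train Integer (1-based) class labels, or labels matching
#'   `classes`.
#' @param classes Optional class label vector used to convert
#'   `labels_train`.
#' @param epochs,lr,momentum Gradient-descent settings for the head.
#' @param seed Integer seed (the head is deterministic; the seed guards
#'   any future stochastic extension and is recorded in the result).
#' @return An object of class `fusion_head`: list with `W`, `b`,
#'   `classes`, and `predictions`/`probs` on the training inputs. Apply
#'   it to new score pairs with [predict_fusion_fc()].
#' @export
two_stream_fuse_fc <- function(scores_joint, scores_bone, labels_train,
                               classes = NULL, epochs = 300, lr = 0.5,
                               momentum = 0.9, seed = 1) {
  check_matched_scores(scores_joint, scores_bone)
  k <- ncol(scores_joint)
  if (!is.numeric(labels_train)) {
    if (is.null(classes)) classes <- sort(unique(as.character(labels_train)))
    labels_train <- match(as.character(labels_train), classes)
  }
  if (anyNA(labels_train) || any(labels_train < 1 | labels_train > k)) {
    stop("labels_train must map to 1..num_classes")
  }
  set.seed(seed)
  X <- cbind(scores_joint, scores_bone)
  W0 <- cbind(diag(k), diag(k))      # paired identity = summation fusion
  fit <- train_linear_head(X, labels_train, k, W0, numeric(k),
                           epochs, lr, momentum)
  head <- structure(list(W = fit$W, b = fit$b, classes = classes),
                    class = "fusion_head")
  pr <- predict_fusion_fc(head, scores_joint, scores_bone)
  head$predictions <- pr$predictions
  head$probs <- pr$probs
  head
}

#' Apply a trained two-stream fusion head to new score pairs
#'
#' @param head A `fusion_head` from [two_stream_fuse_fc()].
#' @param scores_joint,scores_bone Score matrices for the new samples.
#' @return List with `probs` (softmax output, rows sum to 1) and
#'   `predictions`.
#' @export
predict_fusion_fc <- function(head, scores_joint, scores_bone) {
  check_matched_scores(scores_joint, scores_bone)
  X <- cbind(scores_joint, scores_bone)
  probs <- t(softmax_cols(head$W %*% t(X) + head$b))
  rownames(probs) <- rownames(scores_joint)
  list(probs = probs, predictions = max.col(probs, ties.method = "first"))
}

#' Late-fusion head over per-modality embedding vectors
#'
#' The generic multimodal head: each modality's fixed-length embedding is
#' passed through its own fully connected layer, the outputs are
#' concatenated, and a linear output layer with softmax predicts the
#' class. The skeleton modality's embedding is the pooled feature vector
#' from [skeleton_embedding()]; other modalities supply externally
#' computed vectors. With a single modality this reduces to a linear
#' probe on that embedding. Trained by full-batch gradient descent on
#' cross-entropy.
#'
#' @param embeddings List (one element per modality) of `N x d_m`
#'   matrices with matching sample ids / row order.
#' @param labels_train Integer (1-based) labels or labels matching
#'   `classes`.
#' @param num_classes Number of classes.
#' @param classes Optional class label vector.
#' @param proj_dim Output width of each per-modality layer.
#' @param epochs,lr,momentum Gradient-descent settings.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `multimodal_head` with fields `proj`
#'   (per-modality weights), `W`, `b`, and a `predict` closure mapping a
#'   list of embedding matrices to probabilities and predictions.
#' @export
multimodal_fusion_head <- function(embeddings, labels_train,
                                   num_classes = 4, classes = NULL,
                                   proj_dim = 16, epochs = 400, lr = 0.2,
                                   momentum = 0.9, seed = 1) {
  if (!length(embeddings)) stop("at least one modality is required")
  ns <- vapply(embeddings, nrow, 1L)
  if (length(unique(ns)) != 1) stop("modalities disagree on sample count")
  rn <- lapply(embeddings, rownames)
  rn <- rn[!vapply(rn, is.null, TRUE)]
  if (length(rn) > 1 &&
      !all(vapply(rn[-1], identical, TRUE, rn[[1]]))) {
    stop("sample ids of the modalities do not match")
  }
  if (!is.numeric(labels_train)) {
    if (is.null(classes)) classes <- sort(unique(as.character(labels_train)))
    labels_train <- match(as.character(labels_train), classes)
  }
  set.seed(seed)
  M <- length(embeddings)
  proj <- lapply(embeddings, function(E) {
    d <- ncol(E)
    list(W = glorot(c(proj_dim, d), d, proj_dim), b = numeric(proj_dim))
  })
  concat <- function(proj, embeddings) {
    do.call(cbind, lapply(seq_along(embeddings), function(m) {
      t(proj[[m]]$W %*% t(embeddings[[m]]) + proj[[m]]$b)
    }))
  }
  k <- num_classes
  n <- ns[1]
  W <- glorot(c(k, M * proj_dim), M * proj_dim, k)
  b <- numeric(k)
  vel <- list(proj = tree_map(function(x) x * 0, proj), W = W * 0, b = b * 0)
  Y <- matrix(0, k, n); Y[cbind(labels_train, seq_len(n))] <- 1
  for (ep in seq_len(epochs)) {
    Z <- concat(proj, embeddings)                 # N x (M * proj_dim)
    logits <- W %*% t(Z) + b
    probs <- softmax_cols(logits)
    dlog <- (probs - Y) / n                       # k x N
    gW <- dlog %*% Z
    gb <- rowSums(dlog)
    dZ <- t(crossprod(dlog, W))                   # (M*proj_dim) x N
    gproj <- vector("list", M)
    for (m in seq_len(M)) {
      rows <- (m - 1L) * proj_dim + seq_len(proj_dim)
      dzm <- dZ[rows, , drop = FALSE]
      gproj[[m]] <- list(W = dzm %*% embeddings[[m]], b = rowSums(dzm))
    }
    vel$proj <- tree_map2(function(v, g) momentum * v - lr * g,
                          vel$proj, gproj)
    proj <- tree_map2(`+`, proj, vel$proj)
    vel$W <- momentum * vel$W - lr * gW; W <- W + vel$W
    vel$b <- momentum * vel$b - lr * gb; b <- b + vel$b
  }
  head <- structure(list(proj = proj, W = W, b = b, classes = classes,
                         proj_dim = proj_dim),
                    class = "multimodal_head")
  head$predict <- function(new_embeddings) {
    Z <- concat(head$proj, new_embeddings)
    probs <- t(softmax_cols(head$W %*% t(Z) + head$b))
    rownames(probs) <- rownames(new_embeddings[[1]])
    list(probs = probs,
         predictions = max.col(probs, ties.method = "first"))
  }
  head
}
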