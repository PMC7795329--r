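# ---- parameter-tree utilities ----------------------------------------------
# Parameters, gradients and optimizer velocities share one nested-list
# shape; these helpers map over matching leaves (matching by name where
# names exist, by position otherwise).

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(el) tree_map(f, el))
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    out <- lapply(keys, function(k) tree_map2(f, a[[k]], b[[k]]))
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

# ---- label handling ---------------------------------------------------------

sample_labels <- function(samples) {
  vapply(samples, function(s) as.character(s$label), "")
}

resolve_classes <- function(samples, num_classes) {
  labs <- sample_labels(samples)
  if (all(!is.na(suppressWarnings(as.integer(labs))))) {
    cl <- as.character(seq_len(num_classes))
  } else {
    cl <- sort(unique(labs))
  }
  if (length(unique(labs)) > num_classes) {
    stop("more label values than config$num_classes")
  }
  cl
}

label_indices <- function(samples, classes) {
  idx <- match(sample_labels(samples), classes)
  if (anyNA(idx)) stop("labels not covered by the model's class set")
  idx
}

#' Return a copy of the dataset with labels randomly permuted
#'
#' Destroys any association between movement and label while preserving
#' the label marginal; a classifier trained on the result should score at
#' chance, the standard negative control.
#'
#' @param samples List of [skeleton_sequence()] objects.
#' @param seed Integer seed for the permutation.
#' @return List of sequences with permuted labels.
#' @export
shuffle_labels <- function(samples, seed = 1) {
  set.seed(seed)
  perm <- sample(length(samples))
  mapply(function(s, i) {
    s$label <- samples[[i]]$label
    s
  }, samples, perm, SIMPLIFY = FALSE)
}

# ---- dataset splitting ------------------------------------------------------

#' Train / development / test split specification
#'
#' The default ratios 8 : 0.5 : 1.5 correspond to 80% training, 5%
#' development and 15% test.
#'
#' @param ratios Positive weights for (train, dev, test); stored
#'   normalized.
#' @param seed Integer seed making the split deterministic.
#' @param stratified If `TRUE`, splits are balanced within each label.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(8, 0.5, 1.5), seed = 1, stratified = TRUE) {
  if (length(ratios) != 3 || any(ratios <= 0)) {
    stop("ratios must be three positive numbers")
  }
  structure(list(ratios = ratios / sum(ratios), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

# largest-remainder apportionment of n into quotas proportional to ratios
apportion <- function(n, ratios) {
  ideal <- n * ratios
  base <- floor(ideal)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a dataset into train / development / test sets
#'
#' Deterministic given the seed. Overall split sizes follow the ratios by
#' largest-remainder apportionment; under stratification each class is
#' spread across the three sets as evenly as the counts allow while the
#' overall sizes are met exactly.
#'
#' @param samples List of [skeleton_sequence()] objects.
#' @param spec A [split_spec()].
#' @return A list with elements `train`, `dev`, `test` (lists of samples).
#' @export
split_dataset <- function(samples, spec = split_spec()) {
  n <- length(samples)
  quota <- apportion(n, spec$ratios)
  set.seed(spec$seed)
  if (!spec$stratified) {
    perm <- sample(n)
    parts <- split(perm, factor(rep(1:3, times = quota), levels = 1:3))
  } else {
    labs <- sample_labels(samples)
    if (any(table(labs) < 1)) stop("every class needs at least one sample")
    assigned <- integer(n)
    left <- quota
    for (cl in unique(labs)) {
      idx <- sample(which(labs == cl))
      want <- apportion(length(idx), spec$ratios)
      # cap by what each split still needs so overall quotas hold exactly
      for (s in 1:3) want[s] <- min(want[s], left[s])
      overflow <- length(idx) - sum(want)
      while (overflow > 0) {
        room <- left - want
        s <- which.max(room)
        take <- min(overflow, room[s])
        want[s] <- want[s] + take
        overflow <- overflow - take
      }
      pos <- rep(1:3, times = want)
      assigned[idx] <- pos
      left <- left - want
    }
    parts <- split(seq_len(n), factor(assigned, levels = 1:3))
  }
  list(train = samples[parts[[1]]],
       dev = samples[parts[[2]]],
       test = samples[parts[[3]]])
}

# ---- evaluation -------------------------------------------------------------

#' Evaluation report: confusion matrix, UAR, WAR
#'
#' The unweighted average recall (UAR) is the mean of per-class recalls
#' and treats every class equally regardless of prevalence; the weighted
#' average recall (WAR) weights recalls by class frequency and equals
#' plain accuracy. If a class is absent from the reference labels its
#' recall is undefined and UAR averages over the present classes, with a
#' warning.
#'
#' @param confusion Square integer matrix, rows = true class, columns =
#'   predicted class.
#' @param classes Optional class labels for the dimnames.
#' @return An object of class `eval_report` with fields `confusion`,
#'   `uar`, `war`, `per_class_recall`.
#' @export
eval_report <- function(confusion, classes = NULL) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("confusion matrix must be square")
  }
  if (!is.null(classes)) dimnames(confusion) <- list(classes, classes)
  n_per_class <- rowSums(confusion)
  recall <- diag(confusion) / n_per_class
  present <- n_per_class > 0
  if (!all(present)) {
    warning("classes absent from the reference labels: ",
            paste(which(!present), collapse = ", "),
            "; UAR computed over present classes")
  }
  structure(list(confusion = confusion,
                 uar = mean(recall[present]),
                 war = sum(diag(confusion)) / sum(confusion),
                 per_class_recall = recall),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: UAR %.3f, WAR %.3f\n", x$uar, x$war))
  print(x$confusion)
  invisible(x)
}

#' Class-probability scores for a list of sequences
#'
#' @param model A trained [sstgcn()] model.
#' @param samples List of [skeleton_sequence()] objects (equal lengths).
#' @param batch_size Samples per forward chunk.
#' @return `N x num_classes` probability matrix with sample ids as row
#'   names.
#' @export
predict_scores <- function(model, samples, batch_size = 32) {
  n <- length(samples)
  probs <- matrix(0, n, model$config$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    probs[idx, ] <- model_forward(model, samples[idx])
  }
  rownames(probs) <- vapply(samples, function(s) s$sample_id, "")
  colnames(probs) <- model$classes
  probs
}

#' Evaluate a trained model on a labeled test set
#'
#' @inheritParams predict_scores
#' @param test List of labeled [skeleton_sequence()] objects.
#' @return An [eval_report()].
#' @export
evaluate <- function(model, test, batch_size = 32) {
  if (!length(test)) stop("test set is empty")
  probs <- predict_scores(model, test, batch_size)
  pred <- max.col(probs, ties.method = "first")
  truth <- label_indices(test, model$classes)
  k <- model$config$num_classes
  confusion <- matrix(0L, k, k)
  for (i in seq_along(pred)) {
    confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  }
  eval_report(confusion, classes = model$classes)
}

# ---- training loop ----------------------------------------------------------

#' Train a model by stochastic gradient descent on cross-entropy loss
#'
#' Mini-batch SGD with momentum and step learning-rate decay. When a
#' development set is supplied, the parameters with the best development
#' UAR are restored at the end (checkpoint selection); otherwise the final
#' parameters are kept. Fully deterministic given `seed`.
#'
#' @param model An [sstgcn()] model (untrained or warm).
#' @param train List of labeled [skeleton_sequence()] objects, all with
#'   `config$t_fix` frames.
#' @param dev Optional development set for checkpoint selection.
#' @param epochs Number of passes over the training set.
#' @param lr Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param batch_size Mini-batch size.
#' @param lr_decay_at Fractions of `epochs` after which the learning rate
#'   is multiplied by `lr_decay_factor`.
#' @param lr_decay_factor Multiplicative step-decay factor.
#' @param seed Integer seed covering shuffling, dropout and any
#'   initialization drawn inside the loop.
#' @param stop_at_train_acc Optional early-stop target: when the running
#'   training accuracy reaches this value the loop verifies it with an
#'   evaluation-mode pass over the training set and stops if confirmed.
#' @param verbose Print per-epoch progress.
#' @return A list with `model` (trained), `history` (data frame with
#'   epoch, loss, train_acc, dev_uar), `best_dev_uar`, `final_loss`,
#'   `epochs_run`.
#' @export
train_model <- function(model, train, dev = NULL, epochs = 50, lr = 0.01,
                        momentum = 0.9, batch_size = 16,
                        lr_decay_at = c(0.6, 0.85), lr_decay_factor = 0.1,
                        seed = 1, stop_at_train_acc = NULL,
                        verbose = FALSE) {
  if (!length(train)) stop("training set is empty")
  if (is.null(model$classes)) {
    model$classes <- resolve_classes(train, model$config$num_classes)
  }
  labels <- label_indices(train, model$classes)
  x_all <- batch_from_samples(train)
  n <- length(train)
  set.seed(seed)
  vel <- tree_map(function(x) x * 0, model$params)
  decay_epochs <- ceiling(lr_decay_at * epochs)
  best <- list(uar = -Inf, params = NULL, state = NULL)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     train_acc = numeric(), dev_uar = numeric())
  cur_lr <- lr
  final_loss <- NA_real_
  epochs_run <- 0L
  for (ep in seq_len(epochs)) {
    if (ep %in% (decay_epochs + 1L)) cur_lr <- cur_lr * lr_decay_factor
    ord <- sample(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- labels[idx]
      fwd <- net_fwd(model, xb, training = TRUE)
      model$state <- fwd$state
      ce <- softmax_ce(fwd$logits, yb)
      if (!is.finite(ce$loss) || !all(is.finite(fwd$logits))) {
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d (lr=%g)",
          ep, cur_lr))
      }
      ep_loss <- ep_loss + ce$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(t(ce$probs), ties.method = "first") == yb)
      grads <- net_bwd(model, fwd$caches, ce$dlogits)
      vel <- tree_map2(function(v, g) momentum * v - cur_lr * g,
                       vel, grads)
      model$params <- tree_map2(`+`, model$params, vel)
    }
    ep_loss <- ep_loss / n
    ep_acc <- ep_correct / n
    dev_uar <- NA_real_
    if (!is.null(dev) && length(dev)) {
      dev_uar <- suppressWarnings(evaluate(model, dev)$uar)
      if (dev_uar > best$uar) {
        best <- list(uar = dev_uar, params = model$params,
                     state = model$state)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss,
                                   train_acc = ep_acc, dev_uar = dev_uar))
    final_loss <- ep_loss
    epochs_run <- ep
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  dev UAR %s",
                      ep, ep_loss, ep_acc,
                      ifelse(is.na(dev_uar), "-", sprintf("%.3f", dev_uar))))
    }
    if (!is.null(stop_at_train_acc) && ep_acc >= stop_at_train_acc) {
      eval_acc <- suppressWarnings(evaluate(model, train)$war)
      if (eval_acc >= stop_at_train_acc) break
    }
  }
  if (!is.null(best$params)) {
    model$params <- best$params
    model$state <- best$state
  }
  list(model = model, history = hist,
       best_dev_uar = if (is.finite(best$uar)) best$uar else NA_real_,
       final_loss = final_loss, epochs_run = epochs_run)
}
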