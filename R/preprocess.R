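#' Low-pass filter configuration
#'
#' Pose estimators introduce high-frequency jitter into joint trajectories;
#' voluntary human movement occupies the low end of the spectrum, so a
#' low-pass filter separates signal from estimation noise. The default is a
#' 4th-order Butterworth at 6 Hz for 30 fps recordings, applied forward and
#' backward for zero phase.
#'
#' @param cutoff_hz Cutoff frequency in Hz; must satisfy
#'   `0 < cutoff_hz < frame_rate / 2`.
#' @param order Filter order (positive integer).
#' @param frame_rate Sampling rate in Hz.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(cutoff_hz = 6, order = 4, frame_rate = 30) {
  if (!(cutoff_hz > 0 && cutoff_hz < frame_rate / 2)) {
    stop("cutoff_hz must lie in (0, frame_rate/2)")
  }
  if (order < 1) stop("order must be a positive integer")
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 frame_rate = frame_rate),
            class = "filter_config")
}

butter_coefficients <- function(cfg) {
  signal::butter(cfg$order, cfg$cutoff_hz / (cfg$frame_rate / 2),
                 type = "low")
}

# Zero-phase filtering with odd reflection padding at both ends; plain
# forward-backward filtering leaves large transients at the sequence
# edges. The pad of 10 * (taps - 1) samples lets the startup transient
# decay below 1e-8 for the default 4th-order filter.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- 10L * (max(length(bf$b), length(bf$a)) - 1L)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(x)
  head_ext <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ext <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(bf, c(head_ext, x, tail_ext))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase low-pass filtering of a skeleton sequence
#'
#' Filters every scalar trajectory (each joint, each axis) with a
#' Butterworth low-pass filter applied forward and backward, so the output
#' has no temporal lag. The sequence edges are extended by odd reflection
#' before filtering to suppress boundary transients.
#'
#' @param seq A [skeleton_sequence()].
#' @param cfg A [filter_config()]; its `frame_rate` should match the
#'   sequence.
#' @return The filtered [skeleton_sequence()], same shape and label.
#' @export
lowpass_filter_sequence <- function(seq, cfg = filter_config()) {
  Tn <- n_frames(seq)
  min_len <- cfg$order + 1L
  if (Tn < min_len) {
    stop(sprintf(
      "sequence too short to filter: %d frames, need at least %d (order + 1)",
      Tn, min_len))
  }
  bf <- butter_coefficients(cfg)
  out <- seq$coords
  for (v in seq_len(dim(out)[2])) {
    for (a in 1:3) {
      out[, v, a] <- filtfilt_padded(bf, seq$coords[, v, a])
    }
  }
  skeleton_sequence(out, label = seq$label, sample_id = seq$sample_id,
                    frame_rate = seq$frame_rate)
}

#' Restrict a sequence to a subset of joints
#'
#' Used to drop unreliable keypoints (e.g. the lower body in seated video)
#' before graph construction: the model sees only the kept joints, in the
#' given order.
#'
#' @param seq A [skeleton_sequence()].
#' @param keep Integer vector of unique 1-based joint indices.
#' @return A [skeleton_sequence()] with `length(keep)` joints.
#' @export
select_joints <- function(seq, keep) {
  keep <- as.integer(keep)
  V <- n_joints_seq(seq)
  if (any(keep < 1L | keep > V)) {
    stop(sprintf("joint indices out of range [1, %d]", V))
  }
  if (anyDuplicated(keep)) stop("joint indices must be unique")
  skeleton_sequence(seq$coords[, keep, , drop = FALSE], label = seq$label,
                    sample_id = seq$sample_id, frame_rate = seq$frame_rate)
}

#' Length standardization policy
#'
#' Video clips have variable duration; batched training needs a fixed
#' number of frames T. Three deterministic modes: `resample` (default)
#' linearly interpolates the trajectories onto `target_length` equally
#' spaced time points, `pad_repeat` tiles the sequence cyclically, and
#' `pad_zero` appends all-zero frames. Sequences longer than the target
#' are truncated under the pad modes.
#'
#' @param target_length Desired frame count T_fix.
#' @param mode One of `"resample"`, `"pad_repeat"`, `"pad_zero"`.
#' @return An object of class `length_policy`.
#' @export
length_policy <- function(target_length = 128,
                          mode = c("resample", "pad_repeat", "pad_zero")) {
  if (target_length < 1) stop("target_length must be >= 1")
  structure(list(target_length = as.integer(target_length),
                 mode = match.arg(mode)),
            class = "length_policy")
}

#' Standardize a sequence to a fixed number of frames
#'
#' @param seq A [skeleton_sequence()].
#' @param policy A [length_policy()].
#' @return A [skeleton_sequence()] with exactly `policy$target_length`
#'   frames.
#' @export
standardize_length <- function(seq, policy = length_policy()) {
  Tn <- n_frames(seq)
  Tfix <- policy$target_length
  if (Tn == Tfix) return(seq)
  V <- n_joints_seq(seq)
  out <- array(0, c(Tfix, V, 3))
  if (policy$mode == "pad_repeat") {
    idx <- ((seq_len(Tfix) - 1L) %% Tn) + 1L
    out <- seq$coords[idx, , , drop = FALSE]
  } else if (policy$mode == "pad_zero") {
    keep <- min(Tn, Tfix)
    out[seq_len(keep), , ] <- seq$coords[seq_len(keep), , , drop = FALSE]
  } else {  # resample
    if (Tn == 1L) {
      out <- seq$coords[rep(1L, Tfix), , , drop = FALSE]
    } else {
      t_new <- seq(1, Tn, length.out = Tfix)
      lo <- pmin(floor(t_new), Tn - 1L)
      w <- t_new - lo
      for (v in seq_len(V)) {
        for (a in 1:3) {
          tr <- seq$coords[, v, a]
          out[, v, a] <- (1 - w) * tr[lo] + w * tr[lo + 1L]
        }
      }
    }
  }
  skeleton_sequence(out, label = seq$label, sample_id = seq$sample_id,
                    frame_rate = seq$frame_rate)
}

#' Apply the standard preprocessing chain to a dataset
#'
#' Low-pass filtering followed by length standardization (and optional
#' joint subsetting), in that order, for every sample.
#'
#' @param samples List of [skeleton_sequence()] objects.
#' @param cfg A [filter_config()], or `NULL` to skip filtering.
#' @param policy A [length_policy()], or `NULL` to keep native lengths.
#' @param keep Optional joint indices passed to [select_joints()].
#' @return List of preprocessed sequences.
#' @export
preprocess_dataset <- function(samples, cfg = filter_config(),
                               policy = length_policy(), keep = NULL) {
  lapply(samples, function(s) {
    if (!is.null(keep)) s <- select_joints(s, keep)
    if (!is.null(cfg)) s <- lowpass_filter_sequence(s, cfg)
    if (!is.null(policy)) s <- standardize_length(s, policy)
    s
  })
}
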