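#' Labeled skeleton sequence
#'
#' One sample: a T x V x 3 array of 3D joint coordinates over T frames,
#' with an emotion label and metadata. Coordinates are in consistent
#' length units (the synthetic generator uses meters).
#'
#' @param coords Numeric T x V x 3 array.
#' @param label Class label: integer index (1-based) or factor level name;
#'   may be `NA` for unlabeled data.
#' @param sample_id Character identifier.
#' @param frame_rate Frames per second.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(coords, label = NA, sample_id = "sample",
                              frame_rate = 30) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be a T x V x 3 array")
  }
  if (dim(coords)[1] < 1) stop("sequence must have at least one frame")
  if (!all(is.finite(coords))) stop("coords must be finite")
  structure(list(coords = coords, label = label,
                 sample_id = as.character(sample_id),
                 frame_rate = frame_rate),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("%s '%s': T=%d frames, V=%d joints, label=%s, %g fps\n",
              class(x)[1], x$sample_id, d[1], d[2], as.character(x$label),
              x$frame_rate))
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1]
n_joints_seq <- function(seq) dim(seq$coords)[2]

#' Derive bone features from joint coordinates
#'
#' Bones are second-order features: for every non-center joint j the bone
#' vector is `v_j - v_parent(j)`, where the parent is the unique neighbor
#' one hop closer to the body center (child minus parent, i.e. the vector
#' from the source node near the center to the target node away from it).
#' The center joint has no inbound bone; its entry is the zero vector so
#' both streams share the T x V x 3 tensor shape and one network
#' definition serves both.
#'
#' @param seq A [skeleton_sequence()] with V joints matching `graph`.
#' @param graph A [skeleton_graph()].
#' @return A `bone_sequence` (also a `skeleton_sequence`) with the same
#'   label and metadata.
#' @export
joints_to_bones <- function(seq, graph) {
  if (n_joints_seq(seq) != graph$num_joints) {
    stop(sprintf("sequence has %d joints but graph has %d",
                 n_joints_seq(seq), graph$num_joints))
  }
  parents <- joint_parents(graph)
  bones <- array(0, dim(seq$coords))
  for (j in seq_len(graph$num_joints)) {
    if (j == graph$center_joint) next
    bones[, j, ] <- seq$coords[, j, ] - seq$coords[, parents[j], ]
  }
  out <- skeleton_sequence(bones, label = seq$label,
                           sample_id = seq$sample_id,
                           frame_rate = seq$frame_rate)
  class(out) <- c("bone_sequence", class(out))
  out
}

#' Reconstruct joint coordinates from bones
#'
#' Inverse of [joints_to_bones()] given the center joint's trajectory:
#' summing bone vectors along the tree path from the center to joint j
#' yields `v_j - v_center`.
#'
#' @param bones A `bone_sequence`.
#' @param graph The [skeleton_graph()] used to derive the bones.
#' @param center_trajectory T x 3 matrix of center-joint positions
#'   (defaults to the origin).
#' @return A [skeleton_sequence()].
#' @export
bones_to_joints <- function(bones, graph, center_trajectory = NULL) {
  parents <- joint_parents(graph)
  Tn <- n_frames(bones)
  if (is.null(center_trajectory)) center_trajectory <- matrix(0, Tn, 3)
  coords <- array(0, dim(bones$coords))
  coords[, graph$center_joint, ] <- center_trajectory
  # resolve joints in order of increasing distance so parents come first
  ord <- order(graph_center_distances(graph))
  for (j in ord) {
    if (j == graph$center_joint) next
    coords[, j, ] <- coords[, parents[j], ] + bones$coords[, j, ]
  }
  skeleton_sequence(coords, label = bones$label, sample_id = bones$sample_id,
                    frame_rate = bones$frame_rate)
}

#' Read and write skeleton datasets as JSON Lines
#'
#' One JSON object per line:
#' `{"sample_id": ..., "label": ..., "frame_rate": ..., "coords": [[[x,y,z], ...V], ...T]}`.
#'
#' @param samples List of [skeleton_sequence()] objects.
#' @param path File path.
#' @return `read_skeleton_jsonl` returns a list of `skeleton_sequence`;
#'   `write_skeleton_jsonl` returns `path` invisibly.
#' @export
write_skeleton_jsonl <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in samples) {
    obj <- list(sample_id = s$sample_id, label = s$label,
                frame_rate = s$frame_rate,
                coords = unclass(s$coords))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_skeleton_jsonl
#' @export
read_skeleton_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    skeleton_sequence(obj$coords, label = obj$label,
                      sample_id = obj$sample_id,
                      frame_rate = obj$frame_rate)
  })
}

#' Read one sample from long-format CSV
#'
#' Columns `frame`, `joint`, `x`, `y`, `z` with 1-based frame and joint
#' indices.
#'
#' @param path CSV file path.
#' @inheritParams skeleton_sequence
#' @return A [skeleton_sequence()].
#' @export
read_skeleton_csv <- function(path, label = NA, sample_id = NULL,
                              frame_rate = 30) {
  df <- utils::read.csv(path)
  need <- c("frame", "joint", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  }
  Tn <- max(df$frame); V <- max(df$joint)
  coords <- array(NA_real_, c(Tn, V, 3))
  idx <- cbind(df$frame, df$joint)
  coords[cbind(idx, 1)] <- df$x
  coords[cbind(idx, 2)] <- df$y
  coords[cbind(idx, 3)] <- df$z
  if (anyNA(coords)) stop("CSV is missing (frame, joint) combinations")
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  skeleton_sequence(coords, label = label, sample_id = sample_id,
                    frame_rate = frame_rate)
}
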