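#' Spatial-configuration partitioning of the skeleton adjacency
#'
#' Splits the neighborhood of every joint into K = 3 subsets by graph
#' distance to the body center: the root joint itself (subset 1), neighbors
#' closer to the center than the root (centripetal, subset 2), and
#' neighbors farther from the center (centrifugal, subset 3). Neighbors at
#' equal distance are assigned to the centripetal subset, a deterministic
#' tie-break. Each subset gets its own weights in the graph convolution, so
#' the layer can treat inward, outward and self connections differently.
#'
#' Entry (i, j) of a subset is nonzero when joint j is a neighbor (or self)
#' of root joint i falling in that subset; the un-normalized subsets sum
#' exactly to A + I.
#'
#' @param graph A [skeleton_graph()].
#' @param normalize If `TRUE` (default), each subset is degree-normalized
#'   as `A_k / rowdeg` computed per subset, with empty rows left at zero
#'   (a small constant guards the division). If `FALSE`, raw 0/1 subsets
#'   are returned.
#' @return An object of class `partitioned_adjacency`: a list with
#'   `subsets` (list of three V x V matrices, ordered root / centripetal /
#'   centrifugal), `num_joints`, and `normalized`.
#' @export
spatial_partition <- function(graph, normalize = TRUE) {
  V <- graph$num_joints
  d <- graph_center_distances(graph)
  if (any(!is.finite(d))) {
    stop("graph is disconnected: unreachable joints ",
         paste(graph$joint_names[!is.finite(d)], collapse = ", "))
  }
  A <- matrix(0, V, V)
  A[graph$edges] <- 1
  A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  hood <- A + diag(V)  # adjacency plus self-connections

  subsets <- list(root = matrix(0, V, V),
                  centripetal = matrix(0, V, V),
                  centrifugal = matrix(0, V, V))
  for (i in seq_len(V)) {
    for (j in which(hood[i, ] > 0)) {
      k <- if (j == i) 1L else if (d[j] <= d[i]) 2L else 3L
      subsets[[k]][i, j] <- 1
    }
  }
  if (normalize) {
    subsets <- lapply(subsets, function(S) {
      deg <- rowSums(S)
      S / pmax(deg, 1e-6)
    })
  }
  structure(list(subsets = subsets, num_joints = V, normalized = normalize),
            class = "partitioned_adjacency")
}

#' @export
print.partitioned_adjacency <- function(x, ...) {
  cat(sprintf(
    "partitioned_adjacency: V=%d, K=%d subsets (%s), normalized=%s\n",
    x$num_joints, length(x$subsets),
    paste(names(x$subsets), collapse = "/"), x$normalized))
  invisible(x)
}
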