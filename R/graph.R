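#' Skeleton graph
#'
#' A `skeleton_graph` describes the static body graph: joints as vertices,
#' natural bone connections as undirected edges, and a designated body-center
#' joint (the spine-base surrogate) used by the spatial-configuration
#' partitioning strategy and by the bone-feature derivation.
#'
#' @param num_joints Number of joints V.
#' @param edges Two-column integer matrix of 1-based joint index pairs, one
#'   row per undirected edge.
#' @param center_joint 1-based index of the body-center joint.
#' @param joint_names Optional character vector of length `num_joints`.
#' @return An object of class `skeleton_graph` with fields `num_joints`,
#'   `edges`, `center_joint` and `joint_names`.
#' @export
skeleton_graph <- function(num_joints, edges, center_joint,
                           joint_names = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (num_joints < 1) stop("num_joints must be positive")
  if (any(edges < 1L) || any(edges > num_joints)) {
    stop("edge indices must lie in [1, num_joints]")
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  if (center_joint < 1 || center_joint > num_joints) {
    stop("center_joint out of range")
  }
  if (is.null(joint_names)) {
    joint_names <- paste0("joint_", seq_len(num_joints))
  }
  stopifnot(length(joint_names) == num_joints)
  g <- structure(
    list(num_joints = as.integer(num_joints), edges = edges,
         center_joint = as.integer(center_joint),
         joint_names = as.character(joint_names)),
    class = "skeleton_graph")
  d <- graph_center_distances(g)
  if (any(!is.finite(d))) {
    stop("graph is disconnected: unreachable joints ",
         paste(joint_names[!is.finite(d)], collapse = ", "))
  }
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d joints, %d edges, center = %s\n",
              x$num_joints, nrow(x$edges), x$joint_names[x$center_joint]))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_edgelist(graph$edges, directed = FALSE)
}

#' Graph distance of every joint from the body center
#'
#' @param graph A [skeleton_graph()].
#' @return Integer vector of hop counts from `center_joint`; `Inf` for
#'   unreachable joints.
#' @export
graph_center_distances <- function(graph) {
  ig <- igraph::add_vertices(
    as_igraph(graph),
    max(0L, graph$num_joints - max(graph$edges)))
  as.vector(igraph::distances(ig, v = graph$center_joint))
}

#' Parent of each joint on the path toward the body center
#'
#' On the (tree) skeleton graph every non-center joint has a unique
#' neighbor one hop closer to the center: its parent. Bones are the
#' child-minus-parent coordinate differences along these links.
#'
#' @param graph A [skeleton_graph()].
#' @return Integer vector of length V; the center joint's entry is `NA`.
#' @export
joint_parents <- function(graph) {
  d <- graph_center_distances(graph)
  parents <- rep(NA_integer_, graph$num_joints)
  for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges[r, 1]; b <- graph$edges[r, 2]
    if (d[a] == d[b] + 1) parents[a] <- b
    if (d[b] == d[a] + 1) parents[b] <- a
  }
  orphan <- is.na(parents) & seq_len(graph$num_joints) != graph$center_joint
  if (any(orphan)) {
    stop("no unique parent toward center for joints ",
         paste(graph$joint_names[orphan], collapse = ", "),
         " (graph is not a tree rooted at the center)")
  }
  parents
}

#' Default 10-joint upper-body skeleton
#'
#' Lower-body joints are unreliable in seated conversational video, so only
#' the upper body is modeled. The roster keeps one pelvis-level keypoint
#' (`spine_base`) as the graph's center for partitioning and bone
#' derivation, a neck/head/nose chain, and both arms down to the wrists.
#' The graph is a tree: 10 joints, 9 edges.
#'
#' @return A [skeleton_graph()] with V = 10 and `center_joint` at
#'   `spine_base`.
#' @export
build_upper_body_graph <- function() {
  joint_names <- c("spine_base", "neck", "head", "nose",
                   "shoulder_l", "elbow_l", "wrist_l",
                   "shoulder_r", "elbow_r", "wrist_r")
  edges <- rbind(
    c(1, 2),   # spine_base - neck
    c(2, 3),   # neck - head
    c(3, 4),   # head - nose
    c(2, 5),   # neck - shoulder_l
    c(5, 6),   # shoulder_l - elbow_l
    c(6, 7),   # elbow_l - wrist_l
    c(2, 8),   # neck - shoulder_r
    c(8, 9),   # shoulder_r - elbow_r
    c(9, 10))  # elbow_r - wrist_r
  skeleton_graph(10, edges, center_joint = 1, joint_names = joint_names)
}

#' Read / write a skeleton graph definition (YAML)
#'
#' The file stores `joint_names`, `edges` (list of 1-based index pairs) and
#' `center_joint`. A definition for the default upper-body skeleton ships
#' in `inst/extdata/upper_body_graph.yaml`.
#'
#' @param path File path.
#' @return `read_graph_yaml` returns a [skeleton_graph()];
#'   `write_graph_yaml` returns `path` invisibly.
#' @export
read_graph_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  edges <- do.call(rbind, lapply(spec$edges, as.integer))
  skeleton_graph(length(spec$joint_names), edges,
                 center_joint = spec$center_joint,
                 joint_names = spec$joint_names)
}

#' @rdname read_graph_yaml
#' @param graph A [skeleton_graph()].
#' @export
write_graph_yaml <- function(graph, path) {
  yaml::write_yaml(
    list(joint_names = graph$joint_names,
         center_joint = graph$center_joint,
         edges = lapply(seq_len(nrow(graph$edges)),
                        function(i) as.integer(graph$edges[i, ]))),
    path)
  invisible(path)
}
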