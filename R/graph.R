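#' Spatial partitioned skeleton graph
#'
#' Builds the normalized adjacency stack used by the graph-convolution
#' kernel. Neighbors within `max_hop` of each joint are partitioned by
#' the spatial-configuration strategy relative to the pelvis-rooted
#' skeleton: subset 1 holds the joint itself and neighbors at equal
#' distance from the root, subset 2 the centripetal neighbors (closer
#' to the root), subset 3 the centrifugal ones (farther). Each
#' neighborhood is degree-normalized so the incoming weights of every
#' joint sum to one across subsets, balancing the contribution of
#' differently sized neighborhoods.
#'
#' @param joints a `joint_set` with a connected bone graph.
#' @param strategy partition strategy (only `"spatial"` implemented).
#' @param gamma temporal kernel size carried in the graph metadata.
#' @param max_hop spatial neighborhood radius D.
#' @return a `joint_graph`: list with `A` (V x V x K normalized
#'   adjacency stack), `K`, `gamma`, `max_hop`, `strategy`.
#' @export
build_joint_graph <- function(joints, strategy = "spatial", gamma = 9,
                              max_hop = 1) {
  stopifnot(inherits(joints, "joint_set"))
  strategy <- match.arg(strategy, "spatial")
  V <- n_joints(joints)
  adj <- matrix(0, V, V)
  bi <- cbind(match(joints$bones[, 1], joints$names),
              match(joints$bones[, 2], joints$names))
  adj[bi] <- 1
  adj[bi[, 2:1]] <- 1

  # all-pairs hop distance by BFS (small V)
  hop <- matrix(Inf, V, V)
  diag(hop) <- 0
  for (s in seq_len(V)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0L) {
      dist <- dist + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[hop[s, nxt] > dist]
      hop[s, nxt] <- dist
      frontier <- nxt
    }
  }
  if (any(!is.finite(hop))) {
    comp <- integer(V)
    cid <- 0L
    for (s in seq_len(V)) {
      if (comp[s] == 0L) {
        cid <- cid + 1L
        comp[is.finite(hop[s, ])] <- cid
      }
    }
    members <- split(joints$names, comp)
    stop("bone graph is disconnected; components: ",
         paste(vapply(members, paste, "", collapse = "+"), collapse = " | "))
  }

  root <- joint_index(joints, "PELVIS")
  r <- hop[root, ]
  K <- 3L
  A <- array(0, dim = c(V, V, K))
  support <- hop <= max_hop
  for (v in seq_len(V)) {
    for (u in which(support[, v])) {
      k <- if (r[u] == r[v]) 1L else if (r[u] < r[v]) 2L else 3L
      A[u, v, k] <- 1
    }
  }
  deg <- colSums(support)            # neighborhood cardinality per joint
  for (k in seq_len(K)) A[, , k] <- sweep(A[, , k], 2, deg, "/")
  structure(list(A = A, K = K, gamma = gamma, max_hop = max_hop,
                 strategy = strategy, joints = joints),
            class = "joint_graph")
}

#' Apply one graph-convolution subset stack
#'
#' Low-level primitive: computes, for every frame and example,
#' `Y = sum_k W_k' X A_k` over the partition subsets. Exposed so the
#' operation can be validated against a dense matrix-product oracle.
#'
#' @param x numeric array (C_in, T, V, B).
#' @param A adjacency stack (V, V, K).
#' @param W weight stack (C_in, C_out, K).
#' @return numeric array (C_out, T, V, B).
#' @export
graph_conv_apply <- function(x, A, W) {
  gconv_forward(x, A, W)
}
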