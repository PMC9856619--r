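#' Embedding hyperparameters for one variable block
#'
#' The published per-block settings are: ordinal block — 44 neighbours,
#' learning rate 5e-4, minimal distance 0.2, spread 1.5, Canberra metric;
#' binary block — 38 neighbours, learning rate 0.5, minimal distance
#' 0.99, spread 3, correlation metric.
#'
#' @param n_neighbors Number of nearest neighbours for graph construction
#'   (at least 2, below the number of patients).
#' @param learning_rate Initial step size of the layout optimiser.
#' @param min_dist Minimal distance packing parameter of the
#'   low-dimensional similarity curve.
#' @param spread Scale of the low-dimensional similarity curve
#'   (`min_dist <= spread`).
#' @param metric `"canberra"` or `"correlation"`.
#' @param seed Seed for the layout.
#' @return An `embedding_params` list.
#' @export
embedding_params <- function(n_neighbors, learning_rate, min_dist, spread,
                             metric = c("canberra", "correlation"), seed = 42L) {
  metric <- match.arg(metric)
  if (n_neighbors < 2) abort("`n_neighbors` must be at least 2.")
  if (min_dist > spread) abort("`min_dist` must not exceed `spread`.")
  if (learning_rate <= 0 || min_dist <= 0 || spread <= 0) {
    abort("`learning_rate`, `min_dist` and `spread` must be positive.")
  }
  structure(list(n_neighbors = as.integer(n_neighbors),
                 learning_rate = learning_rate, min_dist = min_dist,
                 spread = spread, metric = metric, seed = as.integer(seed)),
            class = "embedding_params")
}

#' @rdname embedding_params
#' @export
ordinal_embedding_params <- function(seed = 42L) {
  embedding_params(44L, 5e-4, 0.2, 1.5, "canberra", seed)
}

#' @rdname embedding_params
#' @export
binary_embedding_params <- function(seed = 42L) {
  embedding_params(38L, 0.5, 0.99, 3, "correlation", seed)
}

new_fuzzy_graph <- function(w) {
  structure(list(n = nrow(w), w = w), class = "fuzzy_graph")
}

#' @export
print.fuzzy_graph <- function(x, ...) {
  ne <- sum(x$w > 0) / 2
  cat(sprintf("<fuzzy_graph: %d nodes, %d undirected edges, max weight %.3f>\n",
              x$n, as.integer(ne), max(x$w)))
  invisible(x)
}

# Per-point adaptive kernel: for each row of the k-NN distance matrix find
# the bandwidth sigma such that the neighbour memberships sum to log2(k),
# after subtracting rho (distance to the nearest neighbour, local
# connectivity 1).
smooth_knn_weights <- function(dists, target, n_iter = 64L, tol = 1e-5) {
  rho <- dists[1]
  adj <- pmax(dists - rho, 0)
  if (all(adj == 0)) return(rep(1, length(dists)))
  lo <- 0; hi <- Inf; sigma <- 1
  for (iter in seq_len(n_iter)) {
    val <- sum(exp(-adj / sigma))
    if (abs(val - target) < tol) break
    if (val > target) {
      hi <- sigma; sigma <- (lo + hi) / 2
    } else {
      lo <- sigma
      sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2
    }
  }
  exp(-adj / sigma)
}

#' Build the fuzzy neighbourhood graph of a variable block
#'
#' Constructs the k-nearest-neighbour graph under the block's metric,
#' converts distances to memberships with a per-point adaptive
#' exponential kernel (local connectivity 1, bandwidth calibrated so each
#' point's memberships sum to `log2(k)`), and symmetrizes with the
#' probabilistic t-conorm `a + b - a*b`. Edge weights lie in `(0, 1]`.
#'
#' @param block Data frame or matrix (patients x variables) of integer
#'   codes.
#' @param params An [embedding_params()] object; its `metric` and
#'   `n_neighbors` are used here.
#' @return A `fuzzy_graph` (node count `n`, symmetric weight matrix `w`
#'   with zero diagonal).
#' @export
build_fuzzy_graph <- function(block, params) {
  d <- block_distance_matrix(as.matrix(block), params$metric)
  knn_graph_from_dist(d, params$n_neighbors)
}

#' Fuse two fuzzy graphs by intersection
#'
#' Fuzzy-set intersection takes the elementwise product of membership
#' weights over the union of the two edge sets. A pure product would
#' annihilate every edge supported by only one block, so an absent edge's
#' membership is floored at `eps_ratio` times the partner's weight before
#' multiplying; the floor is documented and configurable. Weights stay in
#' `(0, 1]`.
#'
#' @param g1,g2 `fuzzy_graph` objects over the same nodes in the same
#'   order.
#' @param eps_ratio Floor for an edge absent from one graph, as a
#'   fraction of the weight in the graph that has it.
#' @param reset_local_connectivity Renormalise each node's memberships
#'   after the product so its strongest edge has weight 1, then
#'   re-symmetrise (the local-connectivity reset of the reference fuzzy
#'   set operations). Keeps every patient attached to the fused manifold
#'   when the two blocks' neighbourhoods disagree; disable to study the
#'   raw t-norm algebra.
#' @return A fused `fuzzy_graph` with weights in `(0, 1]`.
#' @export
intersect_graphs <- function(g1, g2, eps_ratio = 1e-3,
                             reset_local_connectivity = TRUE) {
  if (g1$n != g2$n) abort("Graphs must have the same number of nodes.")
  w1 <- g1$w; w2 <- g2$w
  both <- (w1 > 0) & (w2 > 0)
  only1 <- (w1 > 0) & (w2 == 0)
  only2 <- (w2 > 0) & (w1 == 0)
  w <- matrix(0, g1$n, g1$n)
  w[both] <- w1[both] * w2[both]
  w[only1] <- eps_ratio * w1[only1] * w1[only1]
  w[only2] <- eps_ratio * w2[only2] * w2[only2]
  diag(w) <- 0
  if (reset_local_connectivity) {
    rmax <- apply(w, 1, max)
    rmax[rmax == 0] <- 1
    p <- w / rmax
    w <- p + t(p) - p * t(p)
    diag(w) <- 0
  }
  new_fuzzy_graph(pmin(w, 1))
}

#' Export a fuzzy graph as an edge list
#'
#' @param g A `fuzzy_graph`.
#' @return Tibble with columns `i`, `j` (1-based, `i < j`) and `weight`.
#' @export
graph_edges <- function(g) {
  idx <- which(upper.tri(g$w) & g$w > 0, arr.ind = TRUE)
  tibble(i = idx[, 1], j = idx[, 2], weight = g$w[idx]) |>
    dplyr::arrange(dplyr::desc(.data$weight))
}
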