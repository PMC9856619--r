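#' Embed one variable block
#'
#' Builds the fuzzy neighbourhood graph of the block under its metric and
#' lays it out in two dimensions. Convenience wrapper around
#' [build_fuzzy_graph()] and [layout_graph()].
#'
#' @inheritParams build_fuzzy_graph
#' @inheritParams layout_graph
#' @return A `bcrl_embedding` tibble (`x`, `y`).
#' @export
embed_block <- function(block, params, n_epochs = 200L) {
  g <- build_fuzzy_graph(block, params)
  layout_graph(g, params, n_epochs = n_epochs)
}

#' Build the fused prognostic embedding of a cohort
#'
#' The ordinal and binary blocks are modelled as two separate fuzzy
#' graphs with type-appropriate metrics; the graphs are fused by
#' fuzzy-set intersection and the fused graph is laid out from scratch in
#' two dimensions. The layout inherits the ordinal block's geometry
#' parameters (`min_dist`, `spread`) by default.
#'
#' @param blocks A `bcrl_blocks` object (see [partition_blocks()]), or a
#'   `bcrl_cohort` (partitioned automatically).
#' @param ordinal_params,binary_params Per-block [embedding_params()].
#' @param layout_params Parameters used to lay out the fused graph
#'   (default: the ordinal block's geometry).
#' @param layout_learning_rate Initial step size for the fused layout
#'   optimiser (the per-block learning rates belong to the block models;
#'   the fused graph is re-optimised from scratch).
#' @inheritParams intersect_graphs
#' @inheritParams layout_graph
#' @return A `bcrl_embedding` tibble with the fused graph stored in the
#'   `"graph"` attribute.
#' @export
fused_embedding <- function(blocks,
                            ordinal_params = ordinal_embedding_params(),
                            binary_params = binary_embedding_params(),
                            layout_params = ordinal_params,
                            layout_learning_rate = 0.1,
                            eps_ratio = 1e-3,
                            n_epochs = 200L) {
  if (inherits(blocks, "bcrl_cohort")) blocks <- partition_blocks(blocks)
  g_ord <- build_fuzzy_graph(blocks$ordinal, ordinal_params)
  g_bin <- build_fuzzy_graph(blocks$binary, binary_params)
  g <- intersect_graphs(g_ord, g_bin, eps_ratio = eps_ratio)
  emb <- layout_graph(g, layout_params, n_epochs = n_epochs,
                      learning_rate = layout_learning_rate)
  attr(emb, "graph") <- g
  emb
}

#' Default hyperparameter ranges for the random search
#'
#' @return A list with `ordinal` and `binary` elements, each holding
#'   `(low, high)` ranges for `n_neighbors`, `learning_rate` (log scale),
#'   `min_dist` and `spread`.
#' @export
default_search_ranges <- function() {
  rng <- list(n_neighbors = c(10, 60), learning_rate = c(1e-4, 1),
              min_dist = c(0.05, 1), spread = c(1, 3))
  list(ordinal = rng, binary = rng)
}

sample_params <- function(ranges, metric, seed) {
  set.seed(seed)
  nn <- sample(seq(ranges$n_neighbors[1], ranges$n_neighbors[2]), 1)
  lr <- exp(runif(1, log(ranges$learning_rate[1]), log(ranges$learning_rate[2])))
  sp <- runif(1, ranges$spread[1], ranges$spread[2])
  md <- runif(1, ranges$min_dist[1], min(ranges$min_dist[2], sp))
  embedding_params(nn, lr, md, sp, metric, seed)
}

#' Random hyperparameter search over fused embeddings
#'
#' Samples `n_models` parameter sets per block, prepares the block
#' graphs, fuses `n_combinations` randomly drawn ordinal/binary pairs,
#' lays out and clusters each fused map, and ranks the candidates that
#' pass the silhouette gate by their silhouette score. The published
#' search used 15,000 models per block and 100,000 combinations; the
#' defaults here are desk-scale (50 models, 100 combinations) with the
#' full scale reachable through the arguments.
#'
#' @inheritParams fused_embedding
#' @param ranges Search ranges, as from [default_search_ranges()].
#' @param n_models Parameter sets sampled per block.
#' @param n_combinations Ordinal/binary model pairs evaluated.
#' @param ks Candidate cluster counts for the gate.
#' @param gate Minimum acceptable silhouette score.
#' @param seed Master seed for the whole search.
#' @return A tibble of gate-passing candidates ranked by silhouette
#'   (columns `ordinal_model`, `binary_model`, `k`, `silhouette`, and a
#'   `map` list-column of [select_clustering()] results). Empty, with a
#'   warning, when no candidate passes the gate.
#' @export
random_search <- function(blocks, ranges = default_search_ranges(),
                          n_models = 50L, n_combinations = 100L,
                          ks = 2:4, gate = 0.6, seed = 1L,
                          n_epochs = 200L, eps_ratio = 1e-3) {
  if (inherits(blocks, "bcrl_cohort")) blocks <- partition_blocks(blocks)
  if (n_models < 1 || n_combinations < 1) {
    abort("`n_models` and `n_combinations` must be at least 1.")
  }
  p_ord <- purrr::map(seq_len(n_models),
                      ~ sample_params(ranges$ordinal, "canberra", derive_seed(seed, .x)))
  p_bin <- purrr::map(seq_len(n_models),
                      ~ sample_params(ranges$binary, "correlation", derive_seed(seed, 10000L + .x)))
  # Graphs depend only on (metric, n_neighbors): cache per unique k.
  d_ord <- block_distance_matrix(blocks$ordinal, "canberra")
  d_bin <- block_distance_matrix(blocks$binary, "correlation")
  graph_cache <- new.env(parent = emptyenv())
  get_graph <- function(d, k, tag) {
    key <- paste0(tag, k)
    if (is.null(graph_cache[[key]])) {
      graph_cache[[key]] <- knn_graph_from_dist(d, k)
    }
    graph_cache[[key]]
  }
  set.seed(derive_seed(seed, 20000L))
  pairs <- tibble(
    ordinal_model = sample.int(n_models, n_combinations, replace = TRUE),
    binary_model = sample.int(n_models, n_combinations, replace = TRUE)
  )
  res <- purrr::pmap(pairs, function(ordinal_model, binary_model) {
    po <- p_ord[[ordinal_model]]; pb <- p_bin[[binary_model]]
    g <- intersect_graphs(get_graph(d_ord, po$n_neighbors, "o"),
                          get_graph(d_bin, pb$n_neighbors, "b"),
                          eps_ratio = eps_ratio)
    emb <- layout_graph(g, po, n_epochs = n_epochs, learning_rate = 0.1)
    map <- select_clustering(emb, ks = ks, gate = gate,
                             seed = derive_seed(seed, 30000L + ordinal_model))
    list(map = map, silhouette = map$silhouette %||% NA_real_,
         k = map$k %||% NA_integer_, accepted = isTRUE(map$accepted))
  })
  out <- dplyr::mutate(pairs,
    k = purrr::map_int(res, ~ as.integer(.x$k %||% NA_integer_)),
    silhouette = purrr::map_dbl(res, "silhouette"),
    accepted = purrr::map_lgl(res, "accepted"),
    map = purrr::map(res, "map")
  )
  out <- dplyr::arrange(dplyr::filter(out, .data$accepted),
                        dplyr::desc(.data$silhouette))
  if (nrow(out) == 0) {
    warn("No candidate passed the silhouette gate; returning an empty ranking.")
  }
  out
}

# Build a symmetrized fuzzy k-NN graph from a precomputed distance matrix.
knn_graph_from_dist <- function(d, k) {
  n <- nrow(d)
  if (k >= n) abort("`n_neighbors` must be smaller than the number of rows.")
  target <- log2(k)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    nbr <- seq_len(n)[-i][ord][seq_len(k)]
    p[i, nbr] <- smooth_knn_weights(d[i, nbr], target)
  }
  w <- p + t(p) - p * t(p)
  diag(w) <- 0
  new_fuzzy_graph(w)
}
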