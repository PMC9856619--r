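# 2-D layout of a fuzzy graph by minimising fuzzy cross-entropy between
# graph memberships and the low-dimensional similarity curve
# q(r) = 1 / (1 + a r^(2b)), with (a, b) fitted from (min_dist, spread).
#
# The optimiser is a deterministic full-gradient descent over all point
# pairs (the graphs here are a few hundred nodes, so the O(n^2) epoch is
# cheap) with per-pair gradient clipping and a linearly annealed step, and
# a spectral initialisation from the symmetric normalised graph Laplacian.
# Determinism given the seed is exact: no negative sampling is involved.

# Fit the (a, b) parameters of the low-dimensional curve so that it
# approximates: 1 for r <= min_dist, exp(-(r - min_dist)/spread) beyond.
fit_ab_params <- function(min_dist, spread) {
  xv <- seq(0, spread * 3, length.out = 300)
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  fit <- tryCatch(
    nls(yv ~ 1 / (1 + a * xv^(2 * b)), start = list(a = 1.6, b = 0.9),
        algorithm = "port", lower = c(a = 1e-3, b = 0.05),
        control = list(warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- coef(fit)
    return(list(a = unname(cf["a"]), b = unname(cf["b"])))
  }
  obj <- function(p) sum((yv - 1 / (1 + exp(p[1]) * xv^(2 * exp(p[2]))))^2)
  op <- stats::optim(c(log(1.6), log(0.9)), obj)
  list(a = exp(op$par[1]), b = exp(op$par[2]))
}

spectral_init <- function(w) {
  n <- nrow(w)
  deg <- rowSums(w)
  dinv <- 1 / sqrt(deg)
  lsym <- diag(n) - (dinv * w) * rep(dinv, each = n)
  ev <- eigen(lsym, symmetric = TRUE)
  coords <- ev$vectors[, c(n - 1, n - 2), drop = FALSE]
  # Winsorize before scaling: localized eigenvector spikes on loosely
  # connected nodes would otherwise eject a handful of points far from
  # the bulk and fake cluster structure.
  for (j in 1:2) {
    q <- quantile(coords[, j], c(0.01, 0.99))
    coords[, j] <- pmin(pmax(coords[, j], q[1]), q[2])
  }
  scale <- max(abs(coords))
  if (scale == 0) scale <- 1
  coords * (10 / scale)
}

#' Lay out a fuzzy graph in two dimensions
#'
#' Minimises the fuzzy cross-entropy between the graph's edge memberships
#' and the pairwise low-dimensional similarities by stochastic gradient
#' descent: edges are sampled proportionally to their membership weight,
#' each positive sample attracts its endpoints and repels the head from
#' `neg_rate` uniformly sampled nodes, per-component gradients are
#' clipped and the step size decays linearly. Initialisation is spectral
#' (graph Laplacian) by default. The sampling RNG is internal and seeded
#' from `params$seed`, so identical inputs give identical coordinates.
#'
#' @param g A `fuzzy_graph`; every node must have at least one edge.
#' @param params An [embedding_params()]; `min_dist` and `spread` shape
#'   the low-dimensional similarity curve and `learning_rate` sets the
#'   initial step size unless overridden.
#' @param n_epochs Optimisation epochs.
#' @param neg_rate Negative (repulsive) samples per positive sample.
#' @param learning_rate Initial step size; defaults to
#'   `params$learning_rate`.
#' @param init `"spectral"` (default) or `"random"`.
#' @return A `bcrl_embedding` tibble with columns `x` and `y`, one row
#'   per node, in graph node order.
#' @export
layout_graph <- function(g, params, n_epochs = 200L, neg_rate = 5L,
                         learning_rate = NULL,
                         init = c("spectral", "random")) {
  init <- match.arg(init)
  w <- g$w
  n <- g$n
  isolated <- which(rowSums(w) == 0)
  if (length(isolated)) {
    abort(sprintf("Graph has isolated node(s): %s.",
                  paste(head(isolated, 5), collapse = ", ")))
  }
  ab <- fit_ab_params(params$min_dist, params$spread)
  set.seed(params$seed)
  y0 <- if (init == "spectral") {
    spectral_init(w) + matrix(rnorm(2 * n, sd = 1e-4), n, 2)
  } else {
    matrix(runif(2 * n, -10, 10), n, 2)
  }
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  y <- .layout_sgd(y0, idx[, 1], idx[, 2], w[idx],
                   as.integer(n_epochs), ab$a, ab$b,
                   learning_rate %||% params$learning_rate,
                   as.integer(neg_rate), as.double(params$seed))
  structure(tibble(x = y[, 1], y = y[, 2]),
            params = params, class = c("bcrl_embedding", class(tibble())))
}
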