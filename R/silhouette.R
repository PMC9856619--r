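#' Silhouette score of a clustering on the 2-D map
#'
#' Mean over points of `(b - a) / max(a, b)`, where `a` is the mean
#' Euclidean distance to the point's own cluster and `b` the smallest
#' mean distance to any other cluster. Singleton clusters contribute 0
#' for their lone member (the usual convention).
#'
#' @param coords Data frame with `x`, `y` columns or a two-column matrix.
#' @param labels Cluster labels, one per row; at least two distinct
#'   clusters each with at least one member.
#' @return A single number in `[-1, 1]`.
#' @export
silhouette_score <- function(coords, labels) {
  y <- as.matrix(coords[, c("x", "y")])
  n <- nrow(y)
  labels <- as.vector(labels)
  if (length(labels) != n) abort("`labels` must have one entry per point.")
  cl <- unique(labels)
  if (length(cl) < 2) abort("Silhouette needs at least two clusters.")
  d <- as.matrix(stats::dist(y))
  sizes <- table(factor(labels, levels = cl))
  # Mean distance from every point to each cluster.
  mean_to <- vapply(cl, function(g) {
    rowSums(d[, labels == g, drop = FALSE]) / sum(labels == g)
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- match(labels[i], cl)
    ni <- sizes[[g]]
    if (ni == 1) { s[i] <- 0; next }
    a <- mean_to[i, g] * ni / (ni - 1)  # exclude self from own-cluster mean
    b <- min(mean_to[i, -g])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
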