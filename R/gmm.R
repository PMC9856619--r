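#' Fit a Gaussian mixture model to 2-D map coordinates
#'
#' Full-covariance mixture fitted by expectation-maximisation from a
#' k-means initialisation (component means, covariances and weights taken
#' from the k-means partition), run to convergence of the log-likelihood.
#' Hard labels are the argmax responsibilities. Covariances carry a small
#' diagonal regularisation; a collapsing component triggers a regularised
#' retry before failing.
#'
#' @param coords Data frame with columns `x` and `y` (a
#'   `bcrl_embedding`), or a two-column matrix.
#' @param k Number of mixture components (at least 2).
#' @param seed Seed for the k-means initialisation.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   increase falls below `tol` or after `max_iter` iterations.
#' @param reg Diagonal covariance regularisation.
#' @return A `bcrl_gmm` object: `weights`, `means` (k x 2), `covs`
#'   (2 x 2 x k), `responsibilities` (n x k), `labels`, `loglik`,
#'   and the per-iteration `loglik_trace`.
#' @export
fit_gmm <- function(coords, k, seed = 42L, max_iter = 500L, tol = 1e-8,
                    reg = 1e-6) {
  y <- as.matrix(coords[, c("x", "y")])
  n <- nrow(y)
  if (k < 2) abort("`k` must be at least 2.")
  if (n <= k) abort("Need more points than components.")
  fit <- try_em(y, k, seed, max_iter, tol, reg)
  if (is.null(fit)) fit <- try_em(y, k, seed, max_iter, tol, reg * 1000)
  if (is.null(fit)) abort("EM failed: a component covariance collapsed even after regularised retry.")
  structure(c(fit, list(k = k, n = n, seed = seed)), class = "bcrl_gmm")
}

try_em <- function(y, k, seed, max_iter, tol, reg) {
  n <- nrow(y)
  set.seed(seed)
  km <- kmeans(y, centers = k, nstart = 10L)
  means <- km$centers
  weights <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  covs <- array(0, c(2, 2, k))
  for (j in seq_len(k)) {
    pts <- y[km$cluster == j, , drop = FALSE]
    cv <- if (nrow(pts) > 2) stats::cov(pts) else diag(2) * stats::var(as.vector(y))
    covs[, , j] <- cv + diag(2) * reg
  }
  loglik_trace <- numeric(0)
  prev <- -Inf
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    # E step: responsibilities from current parameters.
    logdens <- vapply(seq_len(k), function(j) {
      mvnorm_logpdf(y, means[j, ], covs[, , j])
    }, numeric(n))
    logw <- sweep(logdens, 2, log(pmax(weights, 1e-300)), "+")
    m <- apply(logw, 1, max)
    lse <- m + log(rowSums(exp(logw - m)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(logw - lse)
    if (is.finite(prev) && ll - prev < tol) break
    prev <- ll
    # M step.
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    weights <- nk / n
    means <- (t(resp) %*% y) / nk
    for (j in seq_len(k)) {
      d <- sweep(y, 2, means[j, ])
      cv <- t(d * resp[, j]) %*% d / nk[j]
      # regularise only near singularity, so the usual path is exact EM
      # (unconditional ridging breaks per-iteration monotonicity)
      if (det(cv) < 1e-8) cv <- cv + diag(2) * reg
      if (det(cv) < 1e-12) return(NULL)
      covs[, , j] <- cv
    }
  }
  list(weights = weights, means = means, covs = covs,
       responsibilities = resp, labels = max.col(resp),
       loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace)
}

mvnorm_logpdf <- function(y, mu, sigma) {
  d <- sweep(y, 2, mu)
  ch <- chol(sigma)
  z <- d %*% chol2inv(ch)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * rowSums(z * d)
}

#' @export
print.bcrl_gmm <- function(x, ...) {
  cat(sprintf("<bcrl_gmm: k = %d, n = %d, loglik = %.3f (%d EM iterations)>\n",
              x$k, x$n, x$loglik, length(x$loglik_trace)))
  invisible(x)
}

#' @rdname fit_gmm
#' @param x A `bcrl_gmm`.
#' @param ... Unused.
#' @method tidy bcrl_gmm
#' @export
tidy.bcrl_gmm <- function(x, ...) {
  tibble(
    component = seq_len(x$k),
    weight = x$weights,
    mean_x = x$means[, 1],
    mean_y = x$means[, 2],
    size = as.integer(tabulate(x$labels, nbins = x$k))
  )
}

#' @rdname fit_gmm
#' @method glance bcrl_gmm
#' @export
glance.bcrl_gmm <- function(x, ...) {
  tibble(k = x$k, n = x$n, loglik = x$loglik,
         iterations = length(x$loglik_trace))
}
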