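#' Distances for mixed-type variable blocks
#'
#' The ordinal block uses the Canberra distance, sensitive to differences
#' near zero (appropriate for count-like codes); the binary block uses the
#' correlation distance `1 - r`, which compares co-occurrence patterns
#' rather than raw mismatches.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single non-negative distance. `canberra_distance()` treats
#'   coordinates with `x == y == 0` as contributing zero;
#'   `correlation_distance()` returns values in `[0, 2]` and falls back to
#'   1 (with a warning) when either vector is constant.
#' @export
canberra_distance <- function(x, y) {
  check_lengths_equal(x, y)
  num <- abs(x - y)
  den <- abs(x) + abs(y)
  sum(ifelse(den == 0, 0, num / den))
}

#' @rdname canberra_distance
#' @export
correlation_distance <- function(x, y) {
  check_lengths_equal(x, y)
  if (length(x) < 2) abort("Vectors must have length >= 2.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant vector in correlation distance; returning fallback distance 1.")
    return(1)
  }
  1 - cor(x, y)
}

# Full pairwise distance matrix for a block under the given metric.
block_distance_matrix <- function(block, metric = c("canberra", "correlation")) {
  metric <- match.arg(metric)
  m <- as.matrix(block)
  n <- nrow(m)
  if (metric == "canberra") {
    d <- matrix(0, n, n)
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      num <- abs(outer(col, col, "-"))
      den <- outer(abs(col), abs(col), "+")
      term <- num / den
      term[den == 0] <- 0
      d <- d + term
    }
    d
  } else {
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      warn("Constant patient row(s) in correlation distance; using fallback distance 1.")
    }
    cc <- suppressWarnings(cor(t(m)))
    cc[!is.finite(cc)] <- 0
    d <- 1 - cc
    diag(d) <- 0
    d
  }
}
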