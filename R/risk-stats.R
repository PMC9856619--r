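# Contingency-table statistics implemented by formula. Base R's
# chisq.test / fisher.test / prop.trend.test serve as independent
# cross-checks in the test suite, not as the implementation.

#' Pearson chi-square test of independence
#'
#' Statistic `sum((O - E)^2 / E)` with `E` the products of margins over
#' the grand total; the optional Yates continuity correction (2 x 2
#' tables only) subtracts 0.5 from each `|O - E|` before squaring.
#' Degrees of freedom are `(r - 1)(c - 1)`.
#'
#' @param tab Counts as a matrix, table or data frame.
#' @param correct Apply the Yates correction (2 x 2 only).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  m <- as_count_matrix(tab, "tab")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Chi-square requires non-zero row and column margins.")
  }
  if (correct && !all(dim(m) == c(2, 2))) {
    abort("The Yates correction applies to 2 x 2 tables only.")
  }
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  dev <- abs(m - e)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  tibble(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         method = if (correct) "chi-square (Yates)" else "chi-square")
}

#' Cramer's V effect size
#'
#' `sqrt(chi2 / (N * min(r - 1, c - 1)))` with the uncorrected Pearson
#' statistic; equals the phi coefficient on 2 x 2 tables.
#'
#' @inheritParams chi_square_test
#' @return A number in `[0, 1]`.
#' @export
cramers_v <- function(tab) {
  m <- as_count_matrix(tab, "tab")
  stat <- chi_square_test(m, correct = FALSE)$statistic
  sqrt(stat / (sum(m) * min(dim(m) - 1)))
}

# log-probability of a table under the multivariate hypergeometric model
# given its margins: (prod Ri! prod Cj!) / (N! prod nij!).
log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

#' Fisher-Freeman-Halton exact test for r x c tables
#'
#' Exact two-sided test of independence: enumerates every table with the
#' observed margins and sums the multivariate hypergeometric
#' probabilities of all tables no more probable than the observed one.
#' On 2 x 2 tables this reduces to the classical two-sided Fisher exact
#' test. Enumeration is margin-constrained and aborts beyond
#' `max_tables` candidate tables (use the chi-square test for large
#' tables).
#'
#' @inheritParams chi_square_test
#' @param max_tables Enumeration cap.
#' @return One-row tibble: `p_value`, `n_tables` enumerated, `method`.
#' @export
freeman_halton_test <- function(tab, max_tables = 2e6) {
  m <- as_count_matrix(tab, "tab")
  if (any(m != round(m))) abort("Exact test requires integer counts.")
  rs <- rowSums(m); cs <- colSums(m)
  lp_obs <- log_table_prob(m)
  tol <- 1e-7
  acc <- new.env(parent = emptyenv())
  acc$p <- 0; acc$count <- 0
  r <- nrow(m); cc <- ncol(m)
  # Recursive enumeration, row-major; the last cell of each row and the
  # whole last row are forced by the margins.
  fill <- function(cur, i, j, col_left) {
    if (acc$count > max_tables) {
      abort("Enumeration cap exceeded; use chi_square_test() for this table.")
    }
    if (i == r) {
      if (any(col_left < 0)) return(invisible())
      cur[r, ] <- col_left
      acc$count <- acc$count + 1
      lp <- log_table_prob(cur)
      if (lp <= lp_obs + tol) acc$p <- acc$p + exp(lp)
      return(invisible())
    }
    row_left <- rs[i] - sum(cur[i, seq_len(j - 1)])
    if (j == cc) {
      if (row_left < 0 || row_left > col_left[j]) return(invisible())
      cur[i, j] <- row_left
      fill(cur, i + 1, 1, col_left - cur[i, ])
      return(invisible())
    }
    hi <- min(row_left, col_left[j])
    if (hi < 0) return(invisible())
    for (v in 0:hi) {
      cur[i, j] <- v
      fill(cur, i, j + 1, col_left)
    }
  }
  fill(matrix(0, r, cc), 1, 1, cs)
  tibble(p_value = min(acc$p, 1), n_tables = acc$count,
         method = "Fisher-Freeman-Halton exact")
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in proportions across ordered groups.
#' For a 2 x k table with events in the first row and monotone scores
#' `s`, the statistic is
#' `Z = sum n_j (p_j - p)(s_j - s_bar) / sqrt(p(1 - p) sum n_j (s_j - s_bar)^2)`
#' with `s_bar` the count-weighted mean score and `p` the pooled event
#' proportion; the p-value is two-sided normal.
#'
#' @param tab A 2 x k table with events in the first row; a trend needs
#'   k >= 3 ordered groups (with k = 2 the statistic reduces to the
#'   two-proportion z-test, whose square is the Pearson chi-square).
#' @param scores Monotone column scores (default `0:(k-1)`).
#' @return One-row tibble: `z`, `p_value`, `method`.
#' @export
cochran_armitage_test <- function(tab, scores = NULL) {
  m <- as_count_matrix(tab, "tab")
  if (nrow(m) != 2) abort("Trend test requires a 2 x k table.")
  k <- ncol(m)
  if (k < 2) abort("Trend test requires at least 2 ordered columns.")
  scores <- scores %||% (seq_len(k) - 1)
  if (length(scores) != k) abort("`scores` must have one value per column.")
  ds <- diff(scores)
  if (!(all(ds >= 0) || all(ds <= 0))) abort("`scores` must be monotone.")
  n_j <- colSums(m)
  p_j <- m[1, ] / n_j
  p_bar <- sum(m[1, ]) / sum(n_j)
  s_bar <- sum(n_j * scores) / sum(n_j)
  num <- sum(n_j * (p_j - p_bar) * (scores - s_bar))
  den <- sqrt(p_bar * (1 - p_bar) * sum(n_j * (scores - s_bar)^2))
  z <- num / den
  tibble(z = z, p_value = 2 * pnorm(-abs(z)), method = "Cochran-Armitage trend")
}

#' Joint and conditional probability table
#'
#' For a 2 x K outcome-by-cluster table (events in the first row),
#' expresses per cluster the joint probability of being an event case in
#' that cluster, the probability of the event conditional on cluster
#' membership (the cluster's point prevalence), and the probability of
#' the cluster conditional on being an event case. All values in
#' percent.
#'
#' @inheritParams cochran_armitage_test
#' @return Tibble with columns `cluster`, `joint_pct`,
#'   `cond_on_cluster_pct`, `cond_on_outcome_pct`.
#' @export
probability_table <- function(tab) {
  m <- as_count_matrix(tab, "tab")
  if (nrow(m) != 2) abort("Probability table expects a 2 x K outcome-by-cluster table.")
  n <- sum(m)
  if (n <= 0) abort("Grand total must be positive.")
  cl <- colnames(m) %||% paste0("cluster_", seq_len(ncol(m)))
  tibble(
    cluster = cl,
    joint_pct = 100 * m[1, ] / n,
    cond_on_cluster_pct = 100 * m[1, ] / colSums(m),
    cond_on_outcome_pct = 100 * m[1, ] / sum(m[1, ])
  )
}

#' Prevalence measures on a two-group table
#'
#' For a 2 x 2 outcome-by-group table (events in the first row): each
#' group's point prevalence (events over group total), the prevalence
#' ratio (higher over lower), each group's positive:negative odds, and
#' the excess odds (difference of the two positive:negative ratios) --
#' the "excess probability" figure reported alongside two-cluster
#' gradings.
#'
#' @inheritParams cochran_armitage_test
#' @return One-row tibble: `prevalence_1`, `prevalence_2` (table column
#'   order), `prevalence_ratio`, `odds_1`, `odds_2`, `excess_odds`.
#' @export
prevalence_measures <- function(tab) {
  m <- as_count_matrix(tab, "tab")
  if (!all(dim(m) == c(2, 2))) abort("Prevalence measures expect a 2 x 2 table.")
  tot <- colSums(m)
  if (any(tot == 0)) abort("Both groups must be non-empty.")
  prev <- unname(m[1, ] / tot)
  odds <- unname(ifelse(m[2, ] > 0, m[1, ] / m[2, ], Inf))
  tibble(
    prevalence_1 = prev[1], prevalence_2 = prev[2],
    prevalence_ratio = max(prev) / min(prev),
    odds_1 = odds[1], odds_2 = odds[2],
    excess_odds = abs(odds[1] - odds[2])
  )
}
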