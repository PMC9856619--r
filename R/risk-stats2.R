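#' Mann-Whitney U test for ordinal samples
#'
#' Rank-sum test with midrank ties. Small samples (both sizes at most
#' `exact_max`) are handled by exact permutation enumeration of the
#' pooled values; larger samples use the normal approximation with
#' tie-corrected variance and a continuity correction.
#'
#' @param x,y Non-empty numeric (ordinal-coded) samples.
#' @param exact_max Size threshold below which both samples trigger
#'   exact enumeration.
#' @return One-row tibble: `u` (statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) abort("Both samples must be non-empty.")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sets <- utils::combn(n, n1)
    us <- colSums(matrix(rk[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(tibble(u = u, p_value = p, method = "Mann-Whitney exact"))
  }
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(tibble(u = u, p_value = 1, method = "Mann-Whitney normal"))
  z <- max(abs(u - mu) - 0.5, 0) / sqrt(v)
  tibble(u = u, p_value = min(2 * pnorm(-z), 1), method = "Mann-Whitney normal")
}

#' Modal values per cluster and outcome
#'
#' Most common code of each categorical variable within every
#' cluster-by-outcome cell. Ties report the smallest tied code and raise
#' the `tie` flag.
#'
#' @param data Data frame holding the variables (a prepared cohort).
#' @param labels Cluster label per row.
#' @param outcome Binary outcome per row.
#' @param variables Names of the categorical variables to summarise.
#' @return Tibble: `variable`, `cluster`, `outcome`, `mode`, `tie`.
#' @export
modal_table <- function(data, labels, outcome, variables) {
  df <- as_tibble(data)[, variables, drop = FALSE]
  df$.cluster <- labels
  df$.outcome <- as.integer(outcome)
  tidyr::pivot_longer(df, dplyr::all_of(variables),
                      names_to = "variable", values_to = "code") |>
    dplyr::group_by(.data$variable, cluster = .data$.cluster,
                    outcome = .data$.outcome) |>
    dplyr::summarise(
      mode = {
        tb <- table(.data$code)
        as.integer(names(tb)[which.max(tb)])
      },
      tie = {
        tb <- table(.data$code)
        sum(tb == max(tb)) > 1
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$variable, .data$cluster, .data$outcome)
}

#' Absolute risk difference between two clusters for a binary exposure
#'
#' Within each cluster, risk is the count of exposed patients with the
#' outcome divided by the count of exposed patients (cumulative
#' incidence among the exposed); the result is the absolute difference
#' of the two risks. A cluster with no exposed patients contributes risk
#' 0 and raises `zero_exposed` (the measure stays defined on tables with
#' empty cells, which is why it is used).
#'
#' @param data Data frame holding the binary variable.
#' @param labels Two-group cluster label per row.
#' @param outcome Binary outcome per row.
#' @param variable Name of the binary exposure variable.
#' @param exposed_code Code meaning "exposed" (default 1).
#' @return One-row tibble: `variable`, `risk_<group1>`, `risk_<group2>`
#'   (column order = descending group prevalence), `abs_risk_diff`,
#'   `zero_exposed`.
#' @export
risk_difference <- function(data, labels, outcome, variable, exposed_code = 1L) {
  df <- as_tibble(data)
  if (!variable %in% names(df)) abort(sprintf("Unknown variable '%s'.", variable))
  groups <- sort(unique(labels))
  if (length(groups) != 2) abort("Risk difference needs exactly two clusters.")
  outcome <- as.integer(outcome)
  prev <- vapply(groups, function(g) mean(outcome[labels == g]), numeric(1))
  groups <- groups[order(-prev)]  # high-risk cluster first, as in reports
  risks <- unname(vapply(groups, function(g) {
    in_g <- labels == g
    exposed <- in_g & df[[variable]] == exposed_code
    if (!sum(exposed)) return(0)
    sum(outcome[exposed]) / sum(exposed)
  }, numeric(1)))
  flags <- unname(vapply(groups, function(g) {
    sum(labels == g & df[[variable]] == exposed_code) == 0
  }, logical(1)))
  out <- tibble(variable = variable, r1 = risks[1], r2 = risks[2],
                abs_risk_diff = abs(risks[1] - risks[2]),
                zero_exposed = any(flags))
  names(out)[2:3] <- paste0("risk_", groups)
  out
}

#' @rdname risk_difference
#' @param variables Names of the binary variables to tabulate (one row
#'   each, mirroring a published risk-difference table).
#' @export
binary_risk_table <- function(data, labels, outcome, variables,
                              exposed_code = 1L) {
  purrr::map_dfr(variables, function(v) {
    risk_difference(data, labels, outcome, v, exposed_code = exposed_code)
  })
}

#' Per-cluster association between a binary variable and the outcome
#'
#' Within each cluster, builds the 2 x 2 exposure-by-outcome table and
#' tests independence: Fisher's exact test when any expected cell count
#' is below 5 (small-sample rule), otherwise the chi-square test.
#'
#' @inheritParams risk_difference
#' @return Tibble: `variable`, `cluster`, `p_value`, `test`.
#' @export
per_cluster_association <- function(data, labels, outcome, variable,
                                    exposed_code = 1L) {
  df <- as_tibble(data)
  outcome <- as.integer(outcome)
  purrr::map_dfr(sort(unique(labels)), function(g) {
    in_g <- labels == g
    exposed <- as.integer(df[[variable]][in_g] == exposed_code)
    out <- outcome[in_g]
    m <- rbind(events = c(sum(out[exposed == 1]), sum(out[exposed == 0])),
               none = c(sum(exposed == 1) - sum(out[exposed == 1]),
                        sum(exposed == 0) - sum(out[exposed == 0])))
    colnames(m) <- c("exposed", "unexposed")
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(tibble(variable = variable, cluster = g,
                    p_value = 1, test = "degenerate"))
    }
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(e < 5)) {
      tibble(variable = variable, cluster = g,
             p_value = freeman_halton_test(m)$p_value, test = "fisher")
    } else {
      tibble(variable = variable, cluster = g,
             p_value = chi_square_test(m)$p_value, test = "chi-square")
    }
  })
}

#' Full risk report for a graded clustering
#'
#' Runs the whole statistics battery for a graded prognostic map: the
#' outcome-by-cluster contingency analysis (chi-square, Cramer's V,
#' Fisher-Freeman-Halton exact test, Cochran-Armitage trend on the
#' risk-ordered table), the joint/conditional probability table, the
#' two-cluster merge analysis (Yates chi-square, prevalence measures),
#' per-variable Mann-Whitney comparisons of ordinal variables between
#' the merged risk groups stratified by outcome, modal values of the
#' categorical variables, absolute risk differences and per-cluster
#' association tests for the binary variables.
#'
#' @param cohort A prepared `bcrl_cohort` aligned with the map rows.
#' @param map A graded `prognostic_map` with three (or two) clusters.
#' @param merge_low_risk Merge all but the highest-risk cluster into an
#'   "others" group for the two-group analyses (done when the map has
#'   more than two clusters).
#' @return A `bcrl_risk_report` list; see the components above. Use
#'   [write_risk_report()] for JSON serialisation.
#' @export
risk_report <- function(cohort, map, merge_low_risk = TRUE) {
  cohort <- prepare_cohort(cohort)
  if (is.null(map$grading)) abort("Grade the map with grade_clusters() first.")
  tab <- cluster_outcome_table(map)
  outcome <- map$data$outcome
  three <- list(
    table = tab,
    chi_square = chi_square_test(tab),
    cramers_v = cramers_v(tab),
    freeman_halton = freeman_halton_test(tab),
    trend = if (ncol(tab) >= 3) cochran_armitage_test(tab) else NULL,
    probabilities = probability_table(tab)
  )
  merged_map <- map
  if (merge_low_risk && map$k > 2) {
    low_ids <- map$grading$cluster[-map$k]
    merged_map <- merge_clusters(map, low_ids)
  }
  tab2 <- cluster_outcome_table(merged_map)
  labels2 <- merged_map$data$cluster
  two <- list(
    table = tab2,
    chi_square_yates = chi_square_test(tab2, correct = TRUE),
    cramers_v = cramers_v(tab2),
    prevalence = prevalence_measures(tab2)
  )
  df <- as_tibble(cohort)
  ord_vars <- c(ORDINAL_VARS, GROUP_VARS)
  groups <- merged_map$grading$cluster
  high <- groups[length(groups)]
  ordinal_tests <- purrr::map_dfr(ord_vars, function(v) {
    purrr::map_dfr(c(0L, 1L), function(st) {
      sel <- outcome == st
      xs <- df[[v]][sel & labels2 == high]
      ys <- df[[v]][sel & labels2 != high]
      res <- mann_whitney_test(xs, ys)
      tibble(variable = v, outcome = st, u = res$u, p_value = res$p_value)
    })
  })
  cat_vars <- schema_of(cohort)$name[schema_of(cohort)$vtype == "categorical"]
  structure(
    list(
      three_cluster = three,
      two_cluster = two,
      ordinal_tests = ordinal_tests,
      modal_values = modal_table(df, labels2, outcome, cat_vars),
      risk_differences = binary_risk_table(df, labels2, outcome, BINARY_VARS),
      associations = purrr::map_dfr(
        BINARY_VARS, ~ per_cluster_association(df, labels2, outcome, .x)
      ),
      grading = map$grading,
      merged_grading = merged_map$grading
    ),
    class = "bcrl_risk_report"
  )
}

#' @rdname risk_report
#' @param report A `bcrl_risk_report`.
#' @param path Output JSON path.
#' @export
write_risk_report <- function(report, path) {
  ser <- purrr::map(unclass(report), function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.bcrl_risk_report <- function(x, ...) {
  cat("== Risk report ==\n\nOutcome by cluster (ascending risk):\n")
  print(x$three_cluster$table)
  cat(sprintf("\nchi-square: %.3f (p = %.4g); Cramer's V: %.4f\n",
              x$three_cluster$chi_square$statistic,
              x$three_cluster$chi_square$p_value, x$three_cluster$cramers_v))
  cat(sprintf("Freeman-Halton exact p: %.4g\n",
              x$three_cluster$freeman_halton$p_value))
  if (!is.null(x$three_cluster$trend)) {
    cat(sprintf("Cochran-Armitage trend: Z = %.3f (p = %.4g)\n",
                x$three_cluster$trend$z, x$three_cluster$trend$p_value))
  }
  cat("\nProbability table (%):\n")
  print(as.data.frame(x$three_cluster$probabilities), digits = 4)
  cat("\nTwo-group analysis:\n")
  print(x$two_cluster$table)
  cat(sprintf("Yates chi-square: %.3f (p = %.4g); prevalence ratio: %.2f; excess odds: %.3f\n",
              x$two_cluster$chi_square_yates$statistic,
              x$two_cluster$chi_square_yates$p_value,
              x$two_cluster$prevalence$prevalence_ratio,
              x$two_cluster$prevalence$excess_odds))
  cat("\nTop absolute risk differences:\n")
  print(as.data.frame(head(dplyr::arrange(x$risk_differences,
                                          dplyr::desc(.data$abs_risk_diff)), 5)),
        digits = 3)
  invisible(x)
}
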