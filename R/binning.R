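#' Bin a continuous variable to ordinal levels
#'
#' Continuous AGE and BMI are converted to ten-level ordinal variables
#' before embedding. The default rule uses equal-width bins over the
#' observed range `[min(x), max(x)]`, which is parameter-free and exactly
#' reproducible from `(min, max, n_bins)`; quantile bins are available as
#' an alternative. The maximum is assigned to the top bin and the mapping
#' is monotone.
#'
#' @param x Finite numeric vector.
#' @param n_bins Number of ordinal levels (default 10).
#' @param method `"width"` for equal-width bins (default) or
#'   `"quantile"` for equal-frequency bins.
#' @return Integer vector of bin indices in `0:(n_bins - 1)`. A constant
#'   input yields all zeros with a warning.
#' @export
bin_to_ordinal <- function(x, n_bins = 10L, method = c("width", "quantile")) {
  method <- match.arg(method)
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn("Constant vector: all values assigned to bin 0.")
    return(integer(length(x)))
  }
  if (method == "width") {
    idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins)
  } else {
    breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    idx <- findInterval(x, breaks, rightmost.closed = TRUE) - 1L
  }
  as.integer(pmin(pmax(idx, 0L), n_bins - 1L))
}

#' Prepare a cohort for embedding
#'
#' Bins continuous AGE and BMI into ten-level AGE GROUP and BMI GROUP
#' ordinal variables, drops the raw continuous columns, and updates the
#' attached schema accordingly. After preparation the cohort holds
#' exactly 23 coded variables: 11 in the ordinal block (9
#' ordinal/categorical plus the two derived groups) and 12 binary.
#'
#' @param cohort A `bcrl_cohort` (see [read_cohort()]).
#' @inheritParams bin_to_ordinal
#' @return A prepared `bcrl_cohort`.
#' @export
prepare_cohort <- function(cohort, n_bins = 10L, method = c("width", "quantile")) {
  method <- match.arg(method)
  sch <- schema_of(cohort)
  df <- as_tibble(cohort)
  if (all(GROUP_VARS %in% names(df))) return(cohort)
  for (v in c("AGE", "BMI")) {
    if (!v %in% names(df)) abort(sprintf("Cohort lacks continuous variable '%s'.", v))
    df[[paste(v, "GROUP")]] <- bin_to_ordinal(df[[v]], n_bins = n_bins, method = method)
    df[[v]] <- NULL
  }
  keep <- sch$vtype != "continuous"
  grp <- bcrl_schema(
    name = GROUP_VARS, vtype = c("ordinal", "ordinal"),
    levels = c(n_bins, n_bins),
    codes = list(0:(n_bins - 1L), 0:(n_bins - 1L))
  )
  sch2 <- dplyr::bind_rows(sch[keep, ], grp)
  class(sch2) <- class(sch)
  new_bcrl_cohort(df, sch2)
}

#' Partition a prepared cohort into ordinal and binary variable blocks
#'
#' The ordinal block gathers the 9 ordinal/categorical variables plus
#' AGE GROUP and BMI GROUP (11 columns); the binary block the 12 binary
#' variables. The outcome travels alongside, in neither block. Rows keep
#' the cohort order in both blocks.
#'
#' @param cohort A prepared `bcrl_cohort` (see [prepare_cohort()]).
#' @return A `bcrl_blocks` list with elements `ordinal` (tibble, 11
#'   columns), `binary` (tibble, 12 columns), `outcome` (integer vector)
#'   and `patient_id`.
#' @export
partition_blocks <- function(cohort) {
  cohort <- prepare_cohort(cohort)
  df <- as_tibble(cohort)
  ord_names <- c(ORDINAL_VARS, GROUP_VARS)
  missing_ord <- setdiff(ord_names, names(df))
  missing_bin <- setdiff(BINARY_VARS, names(df))
  if (length(missing_ord) || length(missing_bin)) {
    abort(sprintf("Cohort lacks block variable(s): %s.",
                  paste(c(missing_ord, missing_bin), collapse = ", ")))
  }
  structure(
    list(
      ordinal = df[, ord_names],
      binary = df[, BINARY_VARS],
      outcome = df[[OUTCOME_VAR]],
      patient_id = df$patient_id
    ),
    class = "bcrl_blocks"
  )
}
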