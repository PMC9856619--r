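#' Configuration for the end-to-end pipeline
#'
#' @param ordinal_params,binary_params Per-block [embedding_params()].
#' @param eps_ratio Intersection floor (see [intersect_graphs()]).
#' @param n_epochs Layout epochs.
#' @param ks Candidate cluster counts.
#' @param gate Silhouette acceptance threshold.
#' @param merge_low_risk Merge all but the highest-risk cluster for the
#'   two-group analyses.
#' @param cv_folds,cv_repeats Cross-validation design for the label
#'   reproduction check (set `cv_repeats = 0` to skip it).
#' @param seed Master seed.
#' @return A `bcrl_pipeline_config` list.
#' @export
pipeline_config <- function(ordinal_params = ordinal_embedding_params(),
                            binary_params = binary_embedding_params(),
                            eps_ratio = 1e-3, n_epochs = 200L, ks = 2:4,
                            gate = 0.6, merge_low_risk = TRUE,
                            cv_folds = 5L, cv_repeats = 10L, seed = 42L) {
  structure(list(ordinal_params = ordinal_params,
                 binary_params = binary_params, eps_ratio = eps_ratio,
                 n_epochs = as.integer(n_epochs), ks = ks, gate = gate,
                 merge_low_risk = merge_low_risk,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 seed = as.integer(seed)),
            class = "bcrl_pipeline_config")
}

#' Run the full risk stratification pipeline
#'
#' Stages, in order: bin continuous variables and partition blocks,
#' embed each block as a fuzzy graph, fuse by intersection, lay out the
#' fused graph, cluster under the silhouette gate, grade clusters by
#' outcome prevalence, run the risk statistics battery (including the
#' two-group merge), and check label reproducibility with the classifier
#' panel. When no clustering passes the gate the run stops there and
#' returns the no-accept map with `accepted = FALSE`.
#'
#' @param cohort A `bcrl_cohort` (see [read_cohort()] or
#'   [simulate_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: writes the map CSV, the
#'   map figure (PNG), the risk report JSON, the CV report JSON and a
#'   run log.
#' @return A `bcrl_run` list: `embedding`, `map` (graded), `report`
#'   (`bcrl_risk_report`), `cv_three`, `cv_two`, `config`, plus
#'   `accepted`.
#' @export
run_bcrl_pipeline <- function(cohort, config = pipeline_config(),
                              out_dir = NULL) {
  t0 <- Sys.time()
  cohort <- prepare_cohort(cohort)
  blocks <- partition_blocks(cohort)
  op <- config$ordinal_params; op$seed <- derive_seed(config$seed, 11L)
  bp <- config$binary_params
  emb <- fused_embedding(blocks, ordinal_params = op, binary_params = bp,
                         eps_ratio = config$eps_ratio,
                         n_epochs = config$n_epochs)
  map <- select_clustering(emb, ks = config$ks, gate = config$gate,
                           seed = derive_seed(config$seed, 12L))
  if (!map$accepted) {
    res <- structure(list(embedding = emb, map = map, report = NULL,
                          cv_three = NULL, cv_two = NULL, config = config,
                          accepted = FALSE),
                     class = "bcrl_run")
    return(res)
  }
  map <- grade_clusters(map, blocks$outcome)
  report <- risk_report(cohort, map, merge_low_risk = config$merge_low_risk)
  features <- dplyr::bind_cols(blocks$ordinal, blocks$binary)
  cv_three <- cv_two <- NULL
  if (config$cv_repeats > 0) {
    cv_three <- run_cv_panel(features, map$data$cluster,
                             folds = config$cv_folds,
                             repeats = config$cv_repeats,
                             seed = derive_seed(config$seed, 13L))
    if (config$merge_low_risk && map$k > 2) {
      merged <- merge_clusters(map, map$grading$cluster[-map$k])
      cv_two <- run_cv_panel(features, merged$data$cluster,
                             folds = config$cv_folds,
                             repeats = config$cv_repeats,
                             seed = derive_seed(config$seed, 14L))
    }
  }
  res <- structure(list(embedding = emb, map = map, report = report,
                        cv_three = cv_three, cv_two = cv_two,
                        config = config, accepted = TRUE),
                   class = "bcrl_run")
  if (!is.null(out_dir)) write_run(res, blocks, out_dir, t0)
  res
}

write_run <- function(res, blocks, out_dir, t0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  map_df <- dplyr::mutate(res$map$data, patient_id = blocks$patient_id,
                          .before = 1)
  utils::write.csv(map_df, file.path(out_dir, "map.csv"), row.names = FALSE)
  plot_map(res$map, file.path(out_dir, "map.png"))
  write_risk_report(res$report, file.path(out_dir, "risk_report.json"))
  if (!is.null(res$cv_three)) {
    jsonlite::write_json(
      list(three_cluster = tidy(res$cv_three),
           two_cluster = if (is.null(res$cv_two)) NULL else tidy(res$cv_two)),
      file.path(out_dir, "cv_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  }
  log <- c(sprintf("seed: %d", res$config$seed),
           sprintf("k: %d  silhouette: %.4f", res$map$k, res$map$silhouette),
           sprintf("elapsed_sec: %.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.bcrl_run <- function(x, ...) {
  cat("== BCRL stratification run ==\n")
  print(x$map)
  if (x$accepted) {
    cat("\n")
    print(x$report)
    if (!is.null(x$cv_three)) {
      cat("\nLabel reproduction (three clusters):\n")
      print(as.data.frame(tidy(x$cv_three)), digits = 3)
    }
  }
  invisible(x)
}

#' Published outcome-by-cluster tables
#'
#' The printed patient-distribution tables shipped as plain-text
#' fixtures: the three-cluster table in ascending risk order (low, mid,
#' high; events row first) and the merged two-group table (others vs
#' high risk). These are the inputs for the reproducible contingency
#' statistics.
#'
#' @param which `"three"` or `"two"`.
#' @return A 2 x K integer matrix with `presence`/`absence` rows.
#' @export
published_cluster_table <- function(which = c("three", "two")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("published_", which, "_cluster_table.csv"),
                      package = "bcrlmap", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
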