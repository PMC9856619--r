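new_prognostic_map <- function(data, k, silhouette, accepted, candidates,
                               gmm = NULL, grading = NULL) {
  structure(
    list(data = data, k = k, silhouette = silhouette, accepted = accepted,
         candidates = candidates, gmm = gmm, grading = grading),
    class = "prognostic_map"
  )
}

#' Cluster a 2-D map under a silhouette gate
#'
#' Fits a Gaussian mixture for each candidate number of clusters
#' (2, 3 and 4 by default), scores each hard clustering by silhouette,
#' retains only clusterings with silhouette at least `gate`, and returns
#' the highest-silhouette survivor. When no candidate passes, an explicit
#' no-accept map is returned (`accepted = FALSE`, no labels) rather than
#' an error.
#'
#' @param coords A `bcrl_embedding` (or any data frame with `x`, `y`).
#' @param ks Candidate cluster counts.
#' @param gate Minimum acceptable silhouette score; set to `-1` to
#'   disable the gate.
#' @param seed Seed for the mixture initialisations.
#' @return A `prognostic_map`: coordinates plus `cluster` labels, the
#'   chosen `k`, the map `silhouette`, the acceptance flag, and a
#'   `candidates` tibble with every `(k, silhouette, passed)` evaluated.
#' @export
select_clustering <- function(coords, ks = 2:4, gate = 0.6, seed = 42L) {
  coords <- as_tibble(coords)
  fits <- purrr::map(ks, function(k) fit_gmm(coords, k, seed = derive_seed(seed, k)))
  sils <- purrr::map_dbl(fits, ~ silhouette_score(coords, .x$labels))
  candidates <- tibble(k = as.integer(ks), silhouette = sils,
                       passed = sils >= gate)
  if (!any(candidates$passed)) {
    return(new_prognostic_map(
      data = dplyr::mutate(coords, cluster = NA_integer_),
      k = NA_integer_, silhouette = max(sils), accepted = FALSE,
      candidates = candidates
    ))
  }
  best <- which(sils == max(sils[candidates$passed]) & candidates$passed)[1]
  new_prognostic_map(
    data = dplyr::mutate(coords, cluster = fits[[best]]$labels),
    k = as.integer(ks[best]), silhouette = sils[best], accepted = TRUE,
    candidates = candidates, gmm = fits[[best]]
  )
}

#' @export
print.prognostic_map <- function(x, ...) {
  if (!x$accepted) {
    cat(sprintf("<prognostic_map: no clustering passed the gate (best silhouette %.3f)>\n",
                x$silhouette))
    return(invisible(x))
  }
  cat(sprintf("<prognostic_map: %d patients, k = %d, silhouette = %.3f%s>\n",
              nrow(x$data), x$k, x$silhouette,
              if (is.null(x$grading)) "" else ", graded"))
  if (!is.null(x$grading)) {
    g <- x$grading
    cat(sprintf("  risk order (ascending prevalence): %s\n",
                paste(g$cluster, collapse = " < ")))
  }
  invisible(x)
}

#' Grade clusters by outcome prevalence
#'
#' Orders the clusters of an accepted map by ascending within-cluster
#' outcome prevalence, so the clustering reads as an ordinal risk scale
#' (last = highest risk). Ties are broken by cluster size, then label.
#' The outcome is stored on the map for downstream statistics.
#'
#' @param map An accepted `prognostic_map`.
#' @param outcome Binary outcome vector (1 = BCRL present), aligned with
#'   the map's rows.
#' @return The map with a `grading` tibble (`cluster`, `size`, `events`,
#'   `prevalence`, `risk_rank`) and per-patient `outcome` and
#'   `risk_rank` columns in its data.
#' @export
grade_clusters <- function(map, outcome) {
  if (!inherits(map, "prognostic_map")) abort("`map` must be a prognostic_map.")
  if (!map$accepted) abort("Cannot grade a map with no accepted clustering.")
  if (length(outcome) != nrow(map$data)) {
    abort("`outcome` must align with the map's rows.")
  }
  df <- dplyr::mutate(map$data, outcome = as.integer(outcome))
  grading <- df |>
    dplyr::count(.data$cluster, wt = NULL, name = "size") |>
    dplyr::left_join(
      df |> dplyr::group_by(.data$cluster) |>
        dplyr::summarise(events = sum(.data$outcome), .groups = "drop"),
      by = "cluster"
    ) |>
    dplyr::mutate(prevalence = .data$events / .data$size) |>
    dplyr::arrange(.data$prevalence, .data$size, .data$cluster) |>
    dplyr::mutate(risk_rank = dplyr::row_number())
  map$data <- dplyr::left_join(
    df, grading[, c("cluster", "risk_rank")], by = "cluster"
  )
  map$grading <- grading
  map
}

#' Merge clusters on a graded map
#'
#' Joins the named clusters into one (such as pooling the two lower-risk
#' clusters into an "Others" group), relabels the merged patients with
#' `new_label`, and recomputes the grading. Counts are additive.
#'
#' @param map A graded `prognostic_map` (see [grade_clusters()]).
#' @param ids Cluster labels to merge.
#' @param new_label Label given to the merged cluster (default: smallest
#'   of `ids`).
#' @return The merged, re-graded `prognostic_map`.
#' @export
merge_clusters <- function(map, ids, new_label = min(ids)) {
  if (!inherits(map, "prognostic_map")) abort("`map` must be a prognostic_map.")
  if (is.null(map$grading)) abort("Grade the map with grade_clusters() before merging.")
  present <- unique(map$data$cluster)
  if (!all(ids %in% present)) {
    abort(sprintf("Unknown cluster id(s): %s.",
                  paste(setdiff(ids, present), collapse = ", ")))
  }
  df <- map$data
  df$cluster[df$cluster %in% ids] <- new_label
  map$data <- df[, setdiff(names(df), "risk_rank")]
  map$k <- length(unique(df$cluster))
  map$silhouette <- if (map$k >= 2) silhouette_score(df, df$cluster) else NA_real_
  grade_clusters(map, df$outcome)
}

#' Outcome-by-cluster contingency table of a graded map
#'
#' @param map A graded `prognostic_map`.
#' @return A 2 x K integer matrix (rows `presence`/`absence` of the
#'   outcome) with columns in ascending risk order.
#' @export
cluster_outcome_table <- function(map) {
  if (is.null(map$grading)) abort("Grade the map with grade_clusters() first.")
  g <- map$grading
  m <- rbind(presence = g$events, absence = g$size - g$events)
  colnames(m) <- paste0("cluster_", g$cluster)
  m
}

#' @rdname select_clustering
#' @param x A `prognostic_map`.
#' @param ... Unused.
#' @method tidy prognostic_map
#' @export
tidy.prognostic_map <- function(x, ...) {
  if (!is.null(x$grading)) return(as_tibble(x$grading))
  as_tibble(x$candidates)
}

#' @rdname select_clustering
#' @method glance prognostic_map
#' @export
glance.prognostic_map <- function(x, ...) {
  tibble(n = nrow(x$data), k = x$k, silhouette = x$silhouette,
         accepted = x$accepted, graded = !is.null(x$grading))
}

#' Plot a prognostic map
#'
#' Scatter of the fused 2-D embedding with cluster colour and outcome
#' marker shape: dots are patients without the outcome, crosses patients
#' with it. Axes are unitless embedding coordinates.
#'
#' @param object A `prognostic_map`.
#' @param outcome Optional binary outcome when the map is not graded yet.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prognostic_map
#' @export
autoplot.prognostic_map <- function(object, outcome = NULL, ...) {
  df <- object$data
  if (!"outcome" %in% names(df)) {
    if (is.null(outcome)) abort("Supply `outcome` or grade the map first.")
    df$outcome <- as.integer(outcome)
  }
  df$cluster_f <- factor(df$cluster)
  df$status <- factor(ifelse(df$outcome == 1, "BCRL", "no BCRL"),
                      levels = c("no BCRL", "BCRL"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster_f,
                                   shape = .data$status)) +
    ggplot2::geom_point(size = 2, stroke = 1) +
    ggplot2::scale_shape_manual(values = c("no BCRL" = 16, "BCRL" = 4),
                                drop = TRUE) +
    ggplot2::labs(x = "map dimension 1", y = "map dimension 2",
                  colour = "cluster", shape = "outcome",
                  title = sprintf("Prognostic map (k = %s, silhouette = %.3f)",
                                  object$k, object$silhouette)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.prognostic_map
#' @param map A `prognostic_map`.
#' @param file Output path (device chosen from the extension by
#'   [ggplot2::ggsave()]; PNG and PDF are always available).
#' @param width,height Figure size in inches.
#' @export
plot_map <- function(map, file, outcome = NULL, width = 7, height = 5) {
  p <- autoplot(map, outcome = outcome)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  invisible(file)
}
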