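test_that("three well-separated blobs select k = 3 above the gate", {
  blobs <- three_blobs(n_per = 60, dist = 12, sd = 0.8, seed = 5)
  map <- select_clustering(blobs[, c("x", "y")], seed = 1)
  expect_true(map$accepted)
  expect_equal(map$k, 3)
  expect_gte(map$silhouette, 0.6)
  expect_equal(mclust::adjustedRandIndex(map$data$cluster, blobs$label), 1)
})

test_that("an isotropic cloud is rejected by the gate in most seeds", {
  rejected <- vapply(1:5, function(s) {
    set.seed(s)
    cloud <- tibble::tibble(x = rnorm(150), y = rnorm(150))
    !select_clustering(cloud, seed = s)$accepted
  }, logical(1))
  expect_gte(sum(rejected), 3)
})

test_that("disabling the gate always returns the best clustering", {
  set.seed(30)
  cloud <- tibble::tibble(x = rnorm(100), y = rnorm(100))
  map <- select_clustering(cloud, gate = -1, seed = 2)
  expect_true(map$accepted)
  expect_equal(map$silhouette, max(map$candidates$silhouette))
})

test_that("grading orders clusters by ascending outcome prevalence", {
  # counts mirroring the published 4/45, 16/93, 50/156 pattern
  blobs <- three_blobs(n_per = 60, seed = 7)
  map <- select_clustering(blobs[, c("x", "y")], seed = 1)
  sizes <- table(map$data$cluster)
  prev_by <- c(0.3, 0.05, 0.15)  # by raw label 1, 2, 3
  set.seed(41)
  outcome <- rbinom(nrow(blobs), 1, prev_by[map$data$cluster])
  graded <- grade_clusters(map, outcome)
  expect_equal(graded$grading$cluster, order(prev_by))
  expect_true(all(diff(graded$grading$prevalence) >= 0))
  # permutation equivariance: relabel clusters, grading follows
  relabel <- c(3L, 1L, 2L)
  map2 <- map
  map2$data$cluster <- relabel[map$data$cluster]
  graded2 <- grade_clusters(map2, outcome)
  expect_equal(relabel[graded$grading$cluster], graded2$grading$cluster)
  expect_equal(graded$grading$events, graded2$grading$events)
})

test_that("equal prevalences fall back to ordering by cluster size", {
  coords <- tibble::tibble(x = c(rnorm(20), rnorm(30, 10)),
                           y = c(rnorm(20), rnorm(30, 10)))
  map <- select_clustering(coords, ks = 2, seed = 1)
  graded <- grade_clusters(map, rep(0L, 50))
  expect_equal(graded$grading$size, c(20L, 30L))
})

test_that("merging pools counts additively and regrades", {
  blobs <- three_blobs(n_per = 50, seed = 9)
  map <- select_clustering(blobs[, c("x", "y")], seed = 1)
  set.seed(10)
  outcome <- rbinom(nrow(blobs), 1, c(0.08, 0.33, 0.17)[map$data$cluster])
  graded <- grade_clusters(map, outcome)
  low_ids <- graded$grading$cluster[1:2]
  merged <- merge_clusters(graded, low_ids)
  expect_equal(merged$k, 2)
  expect_equal(sum(merged$grading$size), sum(graded$grading$size))
  expect_equal(sum(merged$grading$events), sum(graded$grading$events))
  m_low <- merged$grading[merged$grading$cluster == min(low_ids), ]
  g_low <- graded$grading[graded$grading$cluster %in% low_ids, ]
  expect_equal(m_low$size, sum(g_low$size))
  expect_equal(m_low$events, sum(g_low$events))
  # merging a single cluster with itself is a no-op on counts
  same <- merge_clusters(graded, graded$grading$cluster[1])
  expect_equal(sort(same$grading$size), sort(graded$grading$size))
  expect_error(merge_clusters(graded, 99), "Unknown cluster")
})

test_that("the published three-cluster counts grade as low < mid < high", {
  # 4/45 (A) < 16/93 (C) < 50/156 (B): build per-patient labels and outcome
  lab <- rep(c("A", "B", "C"), times = c(45, 156, 93))
  out <- c(rep(1, 4), rep(0, 41), rep(1, 50), rep(0, 106), rep(1, 16), rep(0, 77))
  set.seed(1)
  coords <- tibble::tibble(x = rnorm(294), y = rnorm(294))
  map <- bcrlmap:::new_prognostic_map(
    data = dplyr::mutate(coords, cluster = lab), k = 3L, silhouette = 0.8,
    accepted = TRUE, candidates = NULL
  )
  graded <- grade_clusters(map, out)
  expect_equal(graded$grading$cluster, c("A", "C", "B"))
  tab <- cluster_outcome_table(graded)
  expect_equal(unname(tab["presence", ]), c(4, 16, 50))
})
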