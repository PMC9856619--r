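test_that("chi-square matches the published values and the base-R oracle", {
  res <- chi_square_test(table_three())
  expect_equal(res$statistic, 13.601, tolerance = 0.01 / 13.601)
  expect_equal(res$p_value, 0.001113, tolerance = 1e-3)
  expect_equal(res$df, 2)
  ref <- suppressWarnings(chisq.test(table_three(), correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)

  yates <- chi_square_test(table_two(), correct = TRUE)
  expect_equal(yates$statistic, 11.496, tolerance = 0.01 / 11.496)
  ref2 <- chisq.test(table_two(), correct = TRUE)
  expect_equal(yates$statistic, unname(ref2$statistic), tolerance = 1e-12)

  prop <- matrix(c(10, 20, 30, 60), nrow = 2, byrow = TRUE)
  expect_equal(chi_square_test(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "margins")
  expect_error(chi_square_test(table_three(), correct = TRUE), "2 x 2")
})

test_that("Cramer's V reproduces the published effect sizes", {
  expect_equal(cramers_v(table_three()), 0.2151, tolerance = 0.001 / 0.2151)
  expect_equal(round(cramers_v(table_two()), 2), 0.21)
  perfect <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(cramers_v(perfect), 1)
})

test_that("Freeman-Halton enumeration reproduces the published exact p", {
  res <- freeman_halton_test(table_three())
  expect_equal(res$p_value, 0.0009473, tolerance = 0.05)
  expect_gt(res$n_tables, 1000)
  expect_equal(freeman_halton_test(matrix(1, 2, 2))$p_value, 1)
  # diagonal 2 x 2: both extreme tables, p = 2 / choose(20, 10)
  diag_p <- freeman_halton_test(matrix(c(10, 0, 0, 10), 2))$p_value
  expect_equal(diag_p, 2 / choose(20, 10), tolerance = 1e-9)
})

test_that("Freeman-Halton agrees with fisher.test on r x c tables", {
  set.seed(17)
  for (rep in 1:8) {
    m <- matrix(rpois(6, 8), nrow = 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(freeman_halton_test(m)$p_value, fisher.test(m)$p.value,
                 tolerance = 1e-6, label = paste(m, collapse = ","))
  }
  m22 <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(freeman_halton_test(m22)$p_value, fisher.test(m22)$p.value,
               tolerance = 1e-9)
  expect_error(freeman_halton_test(table_three(), max_tables = 10), "cap")
})

test_that("trend test reproduces the published Z on the risk-ordered table", {
  res <- cochran_armitage_test(table_three(), scores = 0:2)
  expect_equal(res$z, 3.643, tolerance = 0.01 / 3.643)
  expect_equal(res$p_value, 3e-4, tolerance = 0.15)
  # antisymmetry under score reversal
  rev_ <- cochran_armitage_test(table_three(), scores = 2:0)
  expect_equal(rev_$z, -res$z)
  # no trend in proportional columns
  flat <- matrix(c(10, 20, 30, 30, 60, 90), nrow = 2, byrow = TRUE)
  expect_equal(cochran_armitage_test(flat)$z, 0, tolerance = 1e-12)
  # chi-square identity on 2 x 2 with scores (0, 1)
  m22 <- matrix(c(12, 30, 40, 28), 2)
  expect_equal(cochran_armitage_test(m22, scores = 0:1)$z^2,
               chi_square_test(m22)$statistic, tolerance = 1e-10)
  # agreement with the base-R trend test
  ref <- prop.trend.test(table_three()[1, ], colSums(table_three()), 0:2)
  expect_equal(res$z^2, unname(ref$statistic), tolerance = 1e-10)
  expect_error(cochran_armitage_test(table_three(), scores = c(0, 2, 1)),
               "monotone")
})

test_that("probability tables reproduce the published conditional rows", {
  pt <- probability_table(table_three())
  expect_lt(max(abs(pt$cond_on_outcome_pct - c(5.71, 22.86, 71.42))), 0.011)
  expect_lt(max(abs(pt$cond_on_cluster_pct - c(8.88, 17.2, 32.05))), 0.011)
  expect_lt(max(abs(pt$joint_pct - c(1.36, 5.44, 17.0))), 0.011)
  expect_equal(sum(pt$cond_on_outcome_pct), 100, tolerance = 1e-9)
  expect_equal(sum(pt$joint_pct) + 100 * 224 / 294, 100, tolerance = 1e-9)
})

test_that("prevalence measures reproduce the published two-group figures", {
  pm <- prevalence_measures(table_two())
  expect_equal(pm$prevalence_1, 20 / 138, tolerance = 1e-9)   # 14.5%
  expect_equal(pm$prevalence_2, 50 / 156, tolerance = 1e-9)   # 32.05%
  expect_equal(pm$prevalence_ratio, 2.2, tolerance = 0.05 / 2.2)
  expect_equal(pm$odds_1, 20 / 118, tolerance = 1e-9)          # 0.17
  expect_equal(pm$odds_2, 50 / 106, tolerance = 1e-9)          # 0.47
  expect_equal(pm$excess_odds, 0.30, tolerance = 0.01)
  eq <- prevalence_measures(matrix(c(5, 5, 15, 15), 2, byrow = TRUE))
  expect_equal(eq$prevalence_ratio, 1)
  expect_equal(eq$excess_odds, 0)
})

test_that("statistics are invariant under column permutation", {
  m <- table_three()
  perm <- m[, c(3, 1, 2)]
  expect_equal(chi_square_test(perm)$statistic,
               chi_square_test(m)$statistic, tolerance = 1e-12)
  expect_equal(cramers_v(perm), cramers_v(m), tolerance = 1e-12)
  expect_equal(freeman_halton_test(perm)$p_value,
               freeman_halton_test(m)$p_value, tolerance = 1e-9)
})

test_that("Mann-Whitney handles exact, tied and approximate regimes", {
  same <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  shift <- mann_whitney_test(1:3, 4:6)
  expect_equal(shift$p_value, 0.1, tolerance = 1e-9)
  expect_equal(shift$u, 0)
  # approximation close to exact enumeration at n = 8
  set.seed(23)
  for (rep in 1:5) {
    x <- sample(0:5, 8, replace = TRUE)
    y <- sample(0:6, 8, replace = TRUE)
    exact <- mann_whitney_test(x, y)$p_value
    approx <- mann_whitney_test(x, y, exact_max = 0)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
  # agreement with wilcox.test in the tie-corrected normal regime
  set.seed(29)
  x <- sample(0:9, 40, replace = TRUE)
  y <- sample(0:9, 55, replace = TRUE) + 1
  mine <- mann_whitney_test(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(mine$u, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("modal values report the most common code with tie flags", {
  df <- tibble::tibble(v1 = rep(1L, 5), v2 = c(0L, 0L, 6L, 6L, 6L))
  mt <- modal_table(df, labels = rep("B", 5), outcome = rep(1L, 5),
                    variables = c("v1", "v2"))
  expect_equal(mt$mode[mt$variable == "v1"], 1L)
  expect_equal(mt$mode[mt$variable == "v2"], 6L)
  expect_false(any(mt$tie))
  tied <- modal_table(tibble::tibble(v = c(2L, 2L, 5L, 5L)),
                      labels = rep("B", 4), outcome = rep(0L, 4), "v")
  expect_equal(tied$mode, 2L)  # smallest tied code
  expect_true(tied$tie)
})

test_that("risk differences match a hand-computed oracle and flag zero exposure", {
  # cluster B: 40 exposed of whom 12 events; cluster O: 30 exposed, 3 events
  df <- tibble::tibble(
    TTZ = c(rep(1L, 40), rep(0L, 20), rep(1L, 30), rep(0L, 30))
  )
  labels <- rep(c("B", "O"), each = 60)
  outcome <- c(rep(1L, 12), rep(0L, 28), rep(0L, 20),
               rep(1L, 3), rep(0L, 27), rep(0L, 30))
  rd <- risk_difference(df, labels, outcome, "TTZ")
  expect_equal(rd$risk_B, 12 / 40)
  expect_equal(rd$risk_O, 3 / 30)
  expect_equal(rd$abs_risk_diff, abs(12 / 40 - 3 / 30))
  expect_false(rd$zero_exposed)
  # no exposed patients in one cluster: risk 0 with the flag raised
  df0 <- tibble::tibble(TTZ = c(rep(1L, 40), rep(0L, 20), rep(0L, 60)))
  rd0 <- risk_difference(df0, labels, outcome, "TTZ")
  expect_equal(rd0$risk_O, 0)
  expect_true(rd0$zero_exposed)
  # identical clusters give zero difference
  df_same <- tibble::tibble(v = rep(c(1L, 0L), 60))
  out_same <- rep(c(1L, 0L, 0L, 0L), 30)
  rds <- risk_difference(df_same, labels, out_same, "v")
  expect_equal(rds$abs_risk_diff, 0)
})

test_that("per-cluster association picks Fisher for sparse tables", {
  # balanced 2x2 with large expected counts: chi-square path, p near 1
  df <- tibble::tibble(v = rep(c(1L, 0L), each = 100))
  out <- rep(c(1L, 0L), 100)
  res <- per_cluster_association(df, rep("B", 200), out, "v")
  expect_equal(res$test, "chi-square")
  expect_gt(res$p_value, 0.9)
  # perfectly associated sparse table: Fisher path with tiny p
  df2 <- tibble::tibble(v = rep(c(1L, 0L), each = 9))
  out2 <- c(rep(1L, 9), rep(0L, 9))
  res2 <- per_cluster_association(df2, rep("B", 18), out2, "v")
  expect_equal(res2$test, "fisher")
  expect_equal(res2$p_value, fisher.test(matrix(c(9, 0, 0, 9), 2))$p.value,
               tolerance = 1e-9)
  # expected count 2.3 in a cell forces the Fisher branch
  df3 <- tibble::tibble(v = c(rep(1L, 9), rep(0L, 31)))
  out3 <- c(rep(1L, 2), rep(0L, 7), rep(1L, 8), rep(0L, 23))
  res3 <- per_cluster_association(df3, rep("B", 40), out3, "v")
  expect_equal(res3$test, "fisher")
})

test_that("the full risk report assembles every battery component", {
  cohort <- prepare_cohort(simulate_cohort(cohort_sim_config(seed = 11)))
  blocks <- partition_blocks(cohort)
  emb <- suppressWarnings(fused_embedding(blocks))
  map <- select_clustering(emb, seed = 1)
  expect_true(map$accepted)
  map <- grade_clusters(map, blocks$outcome)
  rep_ <- risk_report(cohort, map)
  expect_s3_class(rep_, "bcrl_risk_report")
  expect_equal(sum(rep_$three_cluster$table), 294)
  expect_equal(nrow(rep_$risk_differences), 12)
  expect_equal(nrow(rep_$ordinal_tests), 22)  # 11 variables x 2 outcome strata
  expect_true(all(rep_$ordinal_tests$p_value >= 0 &
                    rep_$ordinal_tests$p_value <= 1))
  expect_true(all(rep_$associations$p_value >= 0 &
                    rep_$associations$p_value <= 1))
  expect_equal(ncol(rep_$two_cluster$table), 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_risk_report(rep_, f)
  parsed <- jsonlite::read_json(f)
  expect_true(all(c("three_cluster", "two_cluster", "risk_differences")
                  %in% names(parsed)))
  expect_output(print(rep_), "Risk report")
})
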