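test_that("cohort CSV round-trips exactly through read and write", {
  df <- toy_cohort_df(3)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  cohort <- read_cohort(f)
  expect_s3_class(cohort, "bcrl_cohort")
  expect_equal(nrow(cohort), 3)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, f2)
  cohort2 <- read_cohort(f2)
  expect_equal(as.data.frame(cohort2), as.data.frame(cohort))
})

test_that("schema violations are reported with variable and row", {
  df <- toy_cohort_df(3)
  df$SIDE[2] <- 3L
  expect_error(validate_cohort(df), "SIDE.*row 2")
  df <- toy_cohort_df(3)
  df$G <- NULL
  expect_error(validate_cohort(df), "missing column.*G")
  df <- toy_cohort_df(3)
  df$BCRL[1] <- 2L
  expect_error(validate_cohort(df), "BCRL")
})

test_that("a generated 294-patient cohort loads back unchanged", {
  cohort <- simulate_cohort(cohort_sim_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), 294)
  expect_equal(back$`NR METASTATIC LN`, cohort$`NR METASTATIC LN`)
  expect_equal(back$BCRL, cohort$BCRL)
})

test_that("schema JSON round-trips and ships a valid default", {
  sch <- default_bcrl_schema()
  expect_equal(nrow(sch), 23)
  expect_equal(sum(sch$vtype == "binary"), 12)
  f <- withr::local_tempfile(fileext = ".json")
  write_schema(sch, f)
  back <- read_schema(f)
  expect_equal(back$name, sch$name)
  expect_equal(back$levels, sch$levels)
  packaged <- read_schema(system.file("extdata", "bcrl_schema.json",
                                      package = "bcrlmap"))
  expect_equal(packaged$name, sch$name)
  expect_error(
    bcrl_schema("HT", "binary", 3, list(0:2)),
    "exactly 2 levels"
  )
})

test_that("equal-width binning maps extremes and singletons correctly", {
  expect_equal(bin_to_ordinal(0:9, 10), 0:9)
  expect_equal(bin_to_ordinal(c(0, 10), 10), c(0L, 9L))
  expect_warning(z <- bin_to_ordinal(rep(5, 4)), "Constant")
  expect_equal(z, rep(0L, 4))
  expect_error(bin_to_ordinal(c(1, NA, 3)), "finite")
})

test_that("binning matches an independent histogram oracle and is monotone", {
  set.seed(42)
  x <- runif(200, 20, 90)
  bins <- bin_to_ordinal(x, 10)
  edges <- seq(min(x), max(x), length.out = 11)
  oracle <- hist(x, breaks = edges, plot = FALSE, right = FALSE,
                 include.lowest = TRUE)$counts
  # top edge: the maximum belongs to the top bin in both schemes
  expect_equal(as.integer(table(factor(bins, levels = 0:9))), oracle)
  ord <- order(x)
  expect_true(all(diff(bins[ord]) >= 0))
})

test_that("block partition yields the published 11 + 12 variable split", {
  cohort <- prepare_cohort(simulate_cohort(cohort_sim_config(seed = 5)))
  blocks <- partition_blocks(cohort)
  expect_equal(ncol(blocks$ordinal), 11)
  expect_equal(ncol(blocks$binary), 12)
  expect_setequal(names(blocks$ordinal),
                  c("NR METASTATIC LN", "TOTAL NR DISSECTED LN", "RT TYPE",
                    "HR DRUG", "HISTOTYPE", "G", "T", "N",
                    "MOLECULAR SUBTYPE", "AGE GROUP", "BMI GROUP"))
  expect_setequal(names(blocks$binary),
                  c("BREAST SURGERY", "SIDE", "Ki67", "TAXANE BASED CT",
                    "HT", "TTZ", "LVI", "ECE", "ER", "HER2", "NCD", "PR"))
  # union of blocks plus outcome covers every prepared variable
  expect_setequal(
    c(names(blocks$ordinal), names(blocks$binary), "BCRL"),
    setdiff(names(tibble::as_tibble(cohort)), c("patient_id", ".stratum"))
  )
  expect_equal(nrow(blocks$ordinal), length(blocks$outcome))
})

test_that("partition fails informatively when a block variable is absent", {
  cohort <- prepare_cohort(simulate_cohort(cohort_sim_config(seed = 5)))
  broken <- tibble::as_tibble(cohort)
  broken$G <- NULL
  attr(broken, "schema") <- attr(cohort, "schema")
  class(broken) <- class(cohort)
  expect_error(partition_blocks(broken), "G")
})
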