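test_that("neoantigen density matches hand values", {
  expect_equal(neoantigen_density(40, 0.2, 0.5), 100)       # 40 / 0.4
  expect_equal(neoantigen_density(0, 0.2, 0.5), 0)
  expect_equal(neoantigen_density(42, 0.591, 1), 42 / 0.591, tolerance = 1e-9)
  expect_equal(round(neoantigen_density(42, 0.591, 1), 3), 71.066)
  expect_error(neoantigen_density(10, 0, 0.5), "dispersion")
})

test_that("cohort standard: medians by default, constants passed through", {
  std <- cohort_standard(c(10, 20, 30), c(0.2, 0.4, 0.6), c(1, 1, 1))
  expect_equal(std$s_nal, 20)
  expect_equal(std$s_mad_over_median, 0.4)
  fx <- cohort_standard(c(1, 2), c(0.1, 0.2), c(1, 1), method = "fixed",
                        fixed = c(100, 0.5))
  expect_equal(fx, list(s_nal = 100, s_mad_over_median = 0.5))
  expect_error(cohort_standard(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("escape index identities: standard difference, sign, self-reference", {
  expect_equal(escape_index(100, 100), 0)
  expect_equal(escape_index(100, 200), 100)
  expect_lt(escape_index(300, 200), 0)

  # a single-patient cohort is its own standard
  math_df <- data.frame(patient_id = "P1", median_vaf = 0.4, scaled_mad = 0.16,
                        math = 40)
  neo_df <- data.frame(patient_id = "P1", nal = 25)
  esc <- compute_escape(math_df, neo_df)
  expect_equal(esc$escape_index, 0)
  expect_equal(esc$patient_density, esc$standard_density)
})

test_that("escape index is monotone: decreasing in NAL, increasing in MATH", {
  set.seed(41)
  for (i in 1:1000) {
    nal <- sample(0:300, 1); math <- runif(1, 5, 120)
    d0 <- escape_index(neoantigen_density(nal, math / 100, 1), 150)
    expect_lt(escape_index(neoantigen_density(nal + 1, math / 100, 1), 150), d0)
    expect_gt(escape_index(neoantigen_density(nal + 1, (math + 5) / 100, 1),
                           150) -
                escape_index(neoantigen_density(nal + 1, math / 100, 1), 150), 0)
  }
})

test_that("fixed-standard indices translate; cohort-median ranks are shift-stable", {
  set.seed(43)
  math_df <- data.frame(patient_id = paste0("P", 1:20),
                        median_vaf = runif(20, 0.2, 0.5),
                        scaled_mad = runif(20, 0.05, 0.3))
  math_df$math <- 100 * math_df$scaled_mad / math_df$median_vaf
  neo_df <- data.frame(patient_id = math_df$patient_id, nal = rpois(20, 40))
  e1 <- compute_escape(math_df, neo_df, method = "fixed", fixed = c(50, 0.5))
  e2 <- compute_escape(math_df, neo_df, method = "fixed", fixed = c(100, 0.5))
  expect_equal(e2$escape_index - e1$escape_index, rep(100, 20))
  e3 <- compute_escape(math_df, neo_df)
  expect_identical(order(e3$escape_index), order(e1$escape_index))
})

test_that("escape stratification splits at the median with ties low", {
  df <- data.frame(patient_id = paste0("P", 1:4),
                   escape_index = c(-5, 0, 10, 20))
  df$nal <- 1; df$mad_over_median <- 1; df$patient_density <- 1
  df$s_nal <- 1; df$s_mad_over_median <- 1; df$standard_density <- 1
  out <- stratify_by_escape(df)
  expect_equal(as.character(out$escape_group), c("low", "low", "high", "high"))

  df$escape_index <- rep(3, 4)
  expect_warning(out2 <- stratify_by_escape(df), "equal")
  expect_true(all(out2$escape_group == "low"))

  # 43 distinct values -> 22 low / 21 high, mirroring a median split of an
  # odd-sized cohort
  df43 <- df[rep(1, 43), ]; df43$patient_id <- paste0("P", 1:43)
  set.seed(9); df43$escape_index <- rnorm(43)
  out3 <- stratify_by_escape(df43)
  expect_equal(as.integer(table(out3$escape_group)), c(22L, 21L))
})
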