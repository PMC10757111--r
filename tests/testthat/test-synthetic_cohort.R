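test_that("simulated VAF spectra behave like binomial read sampling", {
  # one clone at high depth: dispersion shrinks toward zero
  v <- simulate_vafs(1, 1, purity = 1, mean_depth = 10000, n_mutations = 2000,
                     seed = 1)
  expect_lt(math_score(v$vaf)$math, 5)

  # two well-separated clones: wide spectrum
  v2 <- simulate_vafs(c(1, 0.2), c(0.5, 0.5), purity = 1, mean_depth = 200,
                      n_mutations = 500, seed = 2)
  expect_gt(math_score(v2$vaf)$math, 40)

  # pure function of the seed
  expect_identical(simulate_vafs(c(1, .4), c(.5, .5), .8, 100, 50, seed = 3),
                   simulate_vafs(c(1, .4), c(.5, .5), .8, 100, 50, seed = 3))
  expect_error(simulate_vafs(c(1, .4), c(.9, .3), .8, 100, 10, seed = 1),
               "sum to 1")
})

test_that("synthetic peptidome is reproducible and tiles to the closed form", {
  p1 <- synthetic_peptidome(5, seed = 4)
  expect_identical(p1, synthetic_peptidome(5, seed = 4))
  expect_equal(length(p1$proteins), 5)
  for (i in 1:5) {
    eff <- p1$effects[i, ]
    wt <- p1$proteins[[eff$protein_id]]
    m <- mutant_protein(wt, eff$effect, eff$protein_pos,
                        alt_residue = eff$alt_residue)
    expect_equal(nrow(tile_mutant_peptides(wt, m$mutant, m$interval)), 27)
  }
})

test_that("per-patient simulation honors the outcome model switches", {
  sp0 <- cohort_spec(n_patients = 10, censor_rate = 0, seed = 5)
  co0 <- simulate_cohort(sp0, peptidome = FALSE)
  expect_true(all(co0$clinical$pfs_event))

  sp <- cohort_spec(n_patients = 30, seed = 6)
  co <- simulate_cohort(sp)
  expect_equal(nrow(co$clinical), 30)
  expect_equal(sort(unique(co$variants$patient_id)), sort(co$clinical$patient_id))
  expect_true(all(lengths(co$hla) == 6))
  expect_true(all(grepl("^HLA-[ABC]\\*\\d{2}:\\d{2}$", unlist(co$hla))))
  # truth table aligns with the annotation floor
  expect_true(all(co$truth$n_annotated <= co$truth$n_variants))
  expect_identical(simulate_cohort(sp)$truth, co$truth)  # seed-pure
})

test_that("single-clone cohorts fall below the high-ITH cutoff", {
  sp <- cohort_spec(n_patients = 15, subclones_per_patient = c(1L, 1L),
                    seed = 7)
  co <- simulate_cohort(sp, peptidome = FALSE)
  m <- compute_math(co$variants)
  expect_lt(median(m$math, na.rm = TRUE), 40)
})

test_that("different seeds change the draws but not the cohort-level structure", {
  m1 <- simulate_cohort(cohort_spec(n_patients = 40, seed = 21), peptidome = FALSE)
  m2 <- simulate_cohort(cohort_spec(n_patients = 40, seed = 22), peptidome = FALSE)
  expect_false(identical(m1$variants$vaf, m2$variants$vaf))
  expect_lt(abs(median(m1$truth$nal) - median(m2$truth$nal)), 25)
})

test_that("end-to-end pipeline recovers the generative structure", {
  co <- simulate_cohort(cohort_spec(n_patients = 120, seed = 31))
  res <- suppressMessages(run_pipeline(co))

  # surrogate-scored NAL tracks the latent NAL
  nn <- merge(res$neo$summary, co$truth, by = "patient_id")
  expect_gt(cor(nn$nal.x, nn$nal.y), 0.9)

  # the MATH-NAL anticorrelation survives the full pipeline
  expect_lt(res$stats$kendall_math_nal$effect, -0.1)

  # protective NAL + harmful MATH: high-escape group progresses earlier
  expect_lt(res$stats$logrank_escape$p_value, 0.05)

  # Cox recovers a positive MATH log-hazard
  expect_gt(res$stats$cox_pfs$table$hazard_ratio[
    res$stats$cox_pfs$table$covariate == "math"], 1)
})
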