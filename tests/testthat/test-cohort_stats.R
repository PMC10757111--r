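test_that("median split sends ties and the median element low", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(sort(s$low), c(1, 2)); expect_equal(sort(s$high), c(3, 4))
  s <- median_split(c(1, 2, 3))
  expect_equal(sort(s$low), c(1, 2)); expect_equal(s$high, 3)
  set.seed(2); s43 <- median_split(rnorm(43))
  expect_equal(length(s43$low), 22); expect_equal(length(s43$high), 21)
})

test_that("Kendall tau-b reproduces hand counts and handles ties", {
  expect_equal(kendall_tau_b(1:10, 1:10)$effect, 1)
  expect_equal(kendall_tau_b(1:10, 10:1)$effect, -1)
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4))$effect, 2 / 3,
               tolerance = 1e-9)                       # (5 - 1) / 6
  expect_equal(kendall_tau_b(c(1, 1, 2), c(1, 2, 3))$effect, 2 / sqrt(6),
               tolerance = 1e-9)                       # tie-corrected
  expect_error(kendall_tau_b(rep(1, 5), 1:5), "constant")
})

test_that("Spearman rho is monotone-invariant and midranks ties", {
  x <- c(0.3, 1.2, 2.5, 4.1, 7.7)
  expect_equal(spearman_rho(x, exp(x))$effect, 1)
  expect_equal(spearman_rho(c(1, 1, 2), c(1, 2, 3))$effect, sqrt(3) / 2,
               tolerance = 1e-9)                       # 0.866 by midranks
})

test_that("rank-test p-values are uniform under the null", {
  set.seed(71)
  p_k <- replicate(300, { x <- rnorm(25); kendall_tau_b(x, rnorm(25))$p_value })
  p_w <- replicate(300, wilcoxon_rank_sum(rnorm(15), rnorm(15))$p_value)
  expect_lt(suppressWarnings(ks.test(p_k, "punif"))$statistic, 0.1)
  expect_lt(suppressWarnings(ks.test(p_w, "punif"))$statistic, 0.1)
})

test_that("Wilcoxon rank-sum: exact small-sample p and identical-sample limit", {
  t <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(t$statistic, 0)             # U = 0
  expect_equal(t$p_value, 0.1)             # exact two-sided, 2/20
  expect_gt(wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.95)
})

test_that("uncorrected chi-square reproduces the remission-table arithmetic", {
  tab <- matrix(c(8, 14, 14, 7), 2, byrow = TRUE)
  t <- chi_square_2x2(tab)
  # hand value: n (ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(t$statistic, 43 * (8 * 7 - 14 * 14)^2 / (22 * 21 * 22 * 21),
               tolerance = 1e-12)
  expect_equal(round(t$p_value, 3), 0.047)
  expect_equal(round(100 * t$proportions, 1), c(36.4, 66.7))

  t0 <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(t0$statistic, 0); expect_equal(t0$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("log-rank matches the hypergeometric hand table and degenerate cases", {
  time <- c(1, 2, 3, 10, 20, 30); event <- rep(1, 6)
  grp <- rep(c("A", "B"), each = 3)
  t <- km_logrank(time, event, grp)
  expect_equal(t$statistic, brute_logrank(time, event, grp), tolerance = 1e-6)

  t_same <- km_logrank(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("A", "B"), 3))
  expect_equal(t_same$statistic, 0, tolerance = 1e-9)
  expect_equal(t_same$p_value, 1)

  # all censored: flat curves at 1
  fit <- km_logrank(c(5, 6, 7, 8), c(0, 0, 0, 0), c("A", "A", "B", "B"))$fit
  expect_true(all(summary(fit)$surv == 1) || length(summary(fit)$surv) == 0)

  expect_error(km_logrank(1:3, c(1, 1, 1), rep("A", 3)), "2 non-empty groups")
})

test_that("Cox PH: null covariate gives HR ~ 1; Efron fit recovers a true HR of 2", {
  dat <- data.frame(x = rep(0:1, each = 5))
  fit <- cox_ph(dat, time = rep(c(3, 5, 8, 13, 21), 2), event = rep(1, 10))
  expect_true(fit$converged)
  expect_equal(fit$table$hazard_ratio, 1, tolerance = 0.25)
  expect_gt(fit$table$p_value, 0.9)

  set.seed(19)
  hr <- replicate(10, {
    x <- rep(0:1, each = 150)
    t <- rexp(300, 0.05 * 2^x)
    cens <- rexp(300, 0.01)
    cox_ph(data.frame(x = x), pmin(t, cens), t <= cens)$table$hazard_ratio
  })
  expect_equal(median(hr), 2, tolerance = 0.15)

  expect_error(cox_ph(data.frame(x = rep(1, 10)), 1:10, rep(1, 10)), "constant")
})

test_that("Cox model on a synthetic cohort emits one row per clinical covariate", {
  co <- simulate_cohort(cohort_spec(n_patients = 60, seed = 8), peptidome = FALSE)
  m <- compute_math(co$variants)
  cd <- merge(m, co$clinical, by = "patient_id")
  covs <- data.frame(
    math = cd$math, fish = as.integer(cd$fish_high_risk),
    iss = match(cd$iss_stage, c("I", "II", "III")),
    gender = as.integer(cd$gender == "male"), age = cd$age, ecog = cd$ecog,
    hyperdiploid = as.integer(cd$hyperdiploid),
    light_chain = as.integer(cd$light_chain == "lambda"))
  fit <- cox_ph(covs, cd$pfs_months, cd$pfs_event)
  expect_equal(nrow(fit$table), 8)
  expect_true(all(fit$table$ci95_low <= fit$table$hazard_ratio + 1e-9))
  expect_true(all(fit$table$hazard_ratio <= fit$table$ci95_high + 1e-9))
  expect_lte(fit$n_events, fit$n)
})

test_that("one-way ANOVA: degenerate equality, and F = t^2 for two groups", {
  vals <- rep(c(1, 2, 3), 3); grp <- rep(c("a", "b", "c"), each = 3)
  t_id <- one_way_anova(rep(5, 9), grp)
  expect_equal(t_id$statistic, 0); expect_equal(t_id$p_value, 1)

  set.seed(5)
  a <- rnorm(12); b <- rnorm(12, 1)
  f <- one_way_anova(c(a, b), rep(c("a", "b"), each = 12))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(f$p_value, tt$p.value, tolerance = 1e-9)

  # power: three groups with one shifted mean
  set.seed(6)
  rej <- mean(replicate(100, one_way_anova(
    c(rnorm(30), rnorm(30), rnorm(30, 2)),
    rep(c("a", "b", "c"), each = 30))$p_value < 0.01))
  expect_gte(rej, 0.95)
})
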