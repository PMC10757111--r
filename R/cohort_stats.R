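#' Cohort-level statistical tests
#'
#' @description Conventions shared by the hypothesis-test wrappers.
#' @section Test result container:
#' All hypothesis-test wrappers return an `ith_test` list with fields
#' `method`, `statistic`, `p_value`, `effect` (tau, rho, F, or a proportion
#' difference; `NA` when not applicable) and `n`. Tests are two-sided; the
#' conventional threshold in the analyses this package supports is 0.05.
#' @name cohort-stats
NULL

.ith_test <- function(method, statistic, p_value, effect = NA_real_, n = NA_integer_,
                      extra = NULL) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value), effect = unname(effect),
                   n = n), extra),
            class = "ith_test")
}

#' @exportS3Method base::print
print.ith_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3),
      if (!is.na(x$effect)) paste0(", effect = ", format(x$effect, digits = 3)),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Median split of per-patient values
#'
#' Values at or below the median go to the `"low"` group, values strictly
#' above to `"high"`. With an odd number of patients the median element itself
#' is therefore low, and for 43 patients the split is 22 low / 21 high.
#'
#' @param values Named (by patient) or unnamed numeric vector, length >= 2.
#' @return List with `group` (character vector aligned with `values`),
#'   `low`, `high` (the values), and `median`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("median_split: need at least 2 values", call. = FALSE)
  med <- stats::median(values)
  group <- ifelse(values <= med, "low", "high")
  list(group = group, low = values[group == "low"], high = values[group == "high"],
       median = med)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation with a two-sided p-value (exact for small
#' untied samples, normal approximation otherwise, per `stats::cor.test`).
#'
#' @param x,y Equal-length paired numeric vectors, n >= 3.
#' @return An `ith_test` with `effect` = tau-b.
#' @export
kendall_tau_b <- function(x, y) {
  .check_pair(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  .ith_test("Kendall tau-b", ct$statistic, ct$p.value, ct$estimate, length(x))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, two-sided p-value (per `stats::cor.test`).
#'
#' @inheritParams kendall_tau_b
#' @return An `ith_test` with `effect` = rho.
#' @export
spearman_rho <- function(x, y) {
  .check_pair(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  .ith_test("Spearman rho", ct$statistic, ct$p.value, ct$estimate, length(x))
}

.check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples of unequal length", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant input: correlation undefined", call. = FALSE)
  invisible(TRUE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided; exact distribution for small untied samples, normal
#' approximation with tie correction otherwise (per `stats::wilcox.test`).
#'
#' @param a,b Non-empty numeric samples.
#' @return An `ith_test`; `effect` is the difference in medians.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  .ith_test("Wilcoxon rank-sum", wt$statistic, wt$p.value,
            stats::median(a) - stats::median(b), length(a) + length(b))
}

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' The uncorrected statistic is used deliberately: on remission 2x2 tables of
#' the size this package targets, the Yates-corrected p can differ at the
#' second decimal, and the uncorrected Pearson form is the one that matches
#' hand computation `n(ad-bc)^2 / (r1 r2 c1 c2)`. Also returns the per-row
#' proportions of the first column (e.g. response rates per group).
#'
#' @param tab 2x2 matrix of non-negative counts, all margins > 0. Rows are
#'   groups, columns outcomes.
#' @return An `ith_test` with `proportions` (row-wise first-column rates) and
#'   `effect` = their difference.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("chi_square_2x2: need a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("chi_square_2x2: negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi_square_2x2: zero margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  props <- tab[, 1] / rowSums(tab)
  .ith_test("Pearson chi-square (uncorrected)", ct$statistic, ct$p.value,
            props[1] - props[2], sum(tab),
            extra = list(proportions = unname(props)))
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit survival estimates per group and the log-rank chi-square for
#' the group difference.
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicators (1/TRUE = progression observed).
#' @param group Group labels (>= 2 non-empty groups).
#' @return An `ith_test` with the log-rank chi-square and p; the
#'   `survfit` object is attached as `$fit`.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("km_logrank: need at least 2 non-empty groups", call. = FALSE)
  if (any(time < 0)) stop("km_logrank: negative times", call. = FALSE)
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (sum(event) == 0)  # no events anywhere: the contrast is undefined
    return(.ith_test("log-rank", NA_real_, NA_real_, n = length(time),
                     extra = list(fit = fit, df = nlevels(group) - 1)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  .ith_test("log-rank", sd$chisq, p, n = length(time),
            extra = list(fit = fit, df = df))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie approximation. Each
#' covariate's hazard ratio, Wald 95% CI and p-value are returned in a tidy
#' data frame; non-convergence or infinite coefficients (separation) set the
#' `converged` flag rather than raising an error.
#'
#' @param covariates Data frame or matrix of covariates (no constant column).
#' @param time,event Survival outcome.
#' @return A `survival_fit` list: `table` (covariate, hazard_ratio, ci95_low,
#'   ci95_high, p_value), `n`, `n_events`, `converged`, and the underlying
#'   `coxph` fit.
#' @export
cox_ph <- function(covariates, time, event) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time)) stop("dimension mismatch", call. = FALSE)
  if (nrow(covariates) <= ncol(covariates))
    stop("cox_ph: need more observations than covariates", call. = FALSE)
  constant <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) < 2,
                     logical(1))
  if (any(constant))
    stop("cox_ph: constant covariate(s): ",
         paste(names(covariates)[constant], collapse = ", "), call. = FALSE)
  dat <- cbind(covariates, .time = time, .event = as.integer(event))
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  if (any(!is.finite(coef(fit)))) converged <- FALSE
  tabl <- data.frame(
    covariate = rownames(s$coefficients),
    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
    ci95_low = unname(s$conf.int[, "lower .95"]),
    ci95_high = unname(s$conf.int[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  structure(list(table = tabl, n = s$n, n_events = fit$nevent,
                 converged = converged, fit = fit),
            class = "survival_fit")
}

#' @exportS3Method base::print
print.survival_fit <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties): n =", x$n,
      ", events =", x$n_events,
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classic equal-variance one-way ANOVA F test across >= 2 groups.
#'
#' @param values Numeric vector of observations.
#' @param group Group labels (each group needs >= 2 observations).
#' @return An `ith_test` with the F statistic.
#' @export
one_way_anova <- function(values, group) {
  group <- as.factor(group)
  sizes <- table(droplevels(group))
  if (length(sizes) < 2 || any(sizes < 2))
    stop("one_way_anova: need >= 2 groups with >= 2 observations each", call. = FALSE)
  if (all(vapply(split(values, group), function(g) stats::sd(g) == 0, logical(1))) &&
      length(unique(values)) == 1)
    return(.ith_test("one-way ANOVA", 0, 1, 0, length(values)))
  ow <- stats::oneway.test(values ~ group, var.equal = TRUE)
  .ith_test("one-way ANOVA", ow$statistic, ow$p.value, ow$statistic, length(values))
}
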