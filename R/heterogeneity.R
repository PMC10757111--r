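#' Scaled median absolute deviation
#'
#' `constant * median(|x - median(x)|)`. With the default constant 1.4826 the
#' expected value for a normal sample equals the standard deviation, which is
#' what puts the MATH score on an interpretable percent-of-median scale.
#'
#' @param values Numeric vector, non-empty and finite.
#' @param constant Consistency constant; default 1.4826.
#' @return Non-negative scalar.
#' @export
scaled_mad <- function(values, constant = 1.4826) {
  if (length(values) == 0) stop("scaled_mad: empty input", call. = FALSE)
  if (!all(is.finite(values))) stop("scaled_mad: non-finite values", call. = FALSE)
  constant * stats::median(abs(values - stats::median(values)))
}

#' MATH score of a VAF distribution
#'
#' MATH (mutant-allele tumor heterogeneity) is the percentage ratio of the
#' scaled median absolute deviation to the median of a tumor's somatic variant
#' allele fractions: `MATH = 100 * scaled_mad(vafs) / median(vafs)`. Wider VAF
#' spectra -- more subclonal structure -- give higher scores.
#'
#' @param vafs Numeric vector of variant allele fractions in (0, 1].
#' @param min_variants Minimum number of VAFs required (default 5); below this
#'   the score is dominated by sampling noise and an error of class
#'   `ithmm_insufficient_data` is raised carrying the observed count.
#' @param cutoff High-ITH classification cutoff (default 40, strict `>`).
#' @param constant MAD scaling constant (default 1.4826).
#' @param patient_id Optional id carried into the result.
#' @return A `math_result` list: `patient_id`, `n_variants_used`, `median_vaf`,
#'   `scaled_mad`, `math`, `ith_class`.
#' @examples
#' math_score(c(0.4, 0.5, 0.6), min_variants = 3)$math  # 29.652
#' @export
math_score <- function(vafs, min_variants = 5, cutoff = 40, constant = 1.4826,
                       patient_id = NA_character_) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < min_variants) {
    cond <- structure(
      class = c("ithmm_insufficient_data", "error", "condition"),
      list(message = sprintf(
        "math_score: %d VAF(s), need at least %d", length(vafs), min_variants),
        call = sys.call(-1), n = length(vafs)))
    stop(cond)
  }
  if (any(vafs <= 0 | vafs > 1))
    stop("math_score: VAFs must lie in (0, 1]", call. = FALSE)
  med <- stats::median(vafs)
  if (med <= 0) stop("math_score: median VAF is zero", call. = FALSE)
  smad <- scaled_mad(vafs, constant)
  math <- 100 * smad / med
  structure(list(patient_id = patient_id, n_variants_used = length(vafs),
                 median_vaf = med, scaled_mad = smad, math = math,
                 ith_class = classify_ith(math, cutoff)),
            class = "math_result")
}

#' Classify intratumor heterogeneity from a MATH score
#'
#' `"high"` strictly above the cutoff, `"low"` otherwise (a score exactly at
#' the cutoff is low). The default cutoff of 40 is the cross-tumor median used
#' to define high-ITH myeloma; it is exposed because the appropriate value is
#' cohort-dependent.
#'
#' @param math Numeric vector of MATH scores (>= 0).
#' @param cutoff Classification cutoff, default 40.
#' @return Character vector, `"high"` or `"low"`.
#' @export
classify_ith <- function(math, cutoff = 40) {
  stopifnot(all(math >= 0, na.rm = TRUE), cutoff > 0)
  ifelse(math > cutoff, "high", "low")
}

#' Mixture-based VAF outlier filter
#'
#' Optional pre-filter mirroring the clustering step some MATH implementations
#' apply before scoring: fits a one-dimensional Gaussian mixture (components
#' chosen by BIC, up to `max_components`), drops components holding fewer than
#' `min_cluster_fraction` of the variants, and returns the surviving VAFs.
#' Disabled by default -- the plain formula is the reproducible baseline.
#' Never returns an empty set (falls back to the input).
#'
#' @param vafs Numeric vector of VAFs, non-empty.
#' @param enabled Apply the filter? Default `FALSE` (identity).
#' @param min_cluster_fraction Minimum fraction of variants a mixture component
#'   must hold to survive; default 0.05.
#' @param max_components Upper bound for BIC model selection; default 6.
#' @return Filtered numeric vector.
#' @export
vaf_cluster_filter <- function(vafs, enabled = FALSE, min_cluster_fraction = 0.05,
                               max_components = 6) {
  if (length(vafs) == 0) stop("vaf_cluster_filter: empty input", call. = FALSE)
  if (!enabled || length(unique(vafs)) < 3) return(vafs)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller scope
  fit <- tryCatch(
    mclust::Mclust(vafs, G = seq_len(max_components), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$classification)) return(vafs)
  tab <- table(fit$classification) / length(vafs)
  keep <- names(tab)[tab >= min_cluster_fraction]
  out <- vafs[fit$classification %in% as.integer(keep)]
  if (length(out) == 0) vafs else out
}

#' Per-patient MATH scores for a variant table
#'
#' Applies the default somatic-call filters (non-silent functional class,
#' `depth >= min_depth`, `vaf >= min_vaf`), optionally the mixture outlier
#' filter, and computes one MATH score per patient. Patients with fewer than
#' `min_variants` passing calls get `NA` scores rather than an error so a
#' cohort run never aborts on one sparse sample.
#'
#' @param variants A `somatic_variants` data frame.
#' @param min_variants,cutoff,constant See [math_score()].
#' @param min_depth Minimum read depth for a call to enter the score
#'   (default 14).
#' @param min_vaf Minimum VAF (default 0.05).
#' @param classes Functional classes used (default: all non-silent).
#' @param cluster_filter,min_cluster_fraction See [vaf_cluster_filter()].
#' @return Data frame with one row per patient: `patient_id`, `n_variants_used`,
#'   `median_vaf`, `scaled_mad`, `math`, `ith_class`.
#' @export
compute_math <- function(variants, min_variants = 5, cutoff = 40,
                         constant = 1.4826, min_depth = 14, min_vaf = 0.05,
                         classes = setdiff(.variant_classes, "silent"),
                         cluster_filter = FALSE, min_cluster_fraction = 0.05) {
  keep <- variants$variant_class %in% classes &
    variants$depth >= min_depth & variants$vaf >= min_vaf
  v <- variants[keep, , drop = FALSE]
  ids <- unique(variants$patient_id)
  rows <- lapply(ids, function(id) {
    vafs <- v$vaf[v$patient_id == id]
    vafs <- vaf_cluster_filter(vafs, enabled = cluster_filter,
                               min_cluster_fraction = min_cluster_fraction)
    res <- tryCatch(
      math_score(vafs, min_variants = min_variants, cutoff = cutoff,
                 constant = constant, patient_id = id),
      ithmm_insufficient_data = function(e)
        list(patient_id = id, n_variants_used = e$n, median_vaf = NA_real_,
             scaled_mad = NA_real_, math = NA_real_, ith_class = NA_character_))
    as.data.frame(unclass(res), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tumor mutation burden
#'
#' Counts variants in the selected functional classes and divides by the
#' captured exome size. The 38 Mb default reflects a standard whole-exome
#' capture; both the denominator and the counted classes are parameters
#' because conventions differ between pipelines.
#'
#' @param variants A `somatic_variants` data frame for one patient, or a
#'   pre-computed count.
#' @param exome_megabases Captured exome size in Mb (default 38).
#' @param counted_classes Functional classes counted (default: non-silent).
#' @return A `tmb_result` list: `patient_id`, `n_counted_variants`,
#'   `exome_megabases`, `tmb_per_mb`.
#' @export
tmb <- function(variants, exome_megabases = 38,
                counted_classes = setdiff(.variant_classes, "silent")) {
  stopifnot(exome_megabases > 0)
  if (is.numeric(variants) && length(variants) == 1) {
    n <- as.integer(variants)
    pid <- NA_character_
  } else {
    n <- sum(variants$variant_class %in% counted_classes)
    pid <- if (nrow(variants)) variants$patient_id[1] else NA_character_
  }
  structure(list(patient_id = pid, n_counted_variants = n,
                 exome_megabases = exome_megabases,
                 tmb_per_mb = n / exome_megabases),
            class = "tmb_result")
}

#' @exportS3Method base::print
print.math_result <- function(x, ...) {
  cat(sprintf("MATH %.3f (%s ITH): n=%d, median VAF %.4f, scaled MAD %.4f\n",
              x$math, x$ith_class, x$n_variants_used, x$median_vaf, x$scaled_mad))
  invisible(x)
}
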