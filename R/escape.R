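#' Strong-binding neoantigen density per unit of VAF dispersion
#'
#' A patient's strong-binding neoantigen load divided by the width of their
#' VAF distribution in MATH units: `NAL / (MAD/median) = NAL / (MATH/100)`.
#' Tumors that retain many strong binders per unit of heterogeneity have high
#' density; immune escape manifests as a shortfall.
#'
#' @param nal Strong-binding neoantigen load (count, >= 0).
#' @param scaled_mad Scaled MAD of the patient's VAFs (> 0).
#' @param median_vaf Median VAF (> 0).
#' @return `nal / (scaled_mad / median_vaf)`.
#' @export
neoantigen_density <- function(nal, scaled_mad, median_vaf) {
  if (any(scaled_mad <= 0))
    stop("neoantigen_density: zero VAF dispersion, density undefined", call. = FALSE)
  if (any(median_vaf <= 0))
    stop("neoantigen_density: non-positive median VAF", call. = FALSE)
  nal / (scaled_mad / median_vaf)
}

#' Cohort standard for the escape index
#'
#' The reference (sNAL, sMAD/sMedian) pair against which each patient's
#' density is compared. The default takes cohort medians of the per-patient
#' NAL and MAD/median ratios -- an absolute standard would require much larger
#' studies, so only relative values are meaningful. `method = "fixed"` passes
#' user-supplied constants through unchanged.
#'
#' @param nal Vector of per-patient NAL counts.
#' @param scaled_mad,median_vaf Vectors of per-patient dispersion components.
#' @param method `"cohort_median"` (default) or `"fixed"`.
#' @param fixed For `method = "fixed"`: `c(s_nal, s_mad_over_median)`.
#' @return List with `s_nal` and `s_mad_over_median`.
#' @export
cohort_standard <- function(nal, scaled_mad, median_vaf,
                            method = c("cohort_median", "fixed"), fixed = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(length(fixed) == 2, all(is.finite(fixed)), fixed[2] > 0)
    return(list(s_nal = fixed[1], s_mad_over_median = fixed[2]))
  }
  if (!length(nal)) stop("cohort_standard: empty cohort", call. = FALSE)
  list(s_nal = stats::median(nal),
       s_mad_over_median = stats::median(scaled_mad / median_vaf))
}

#' Immune-escape index
#'
#' Difference between the cohort-standard strong-binder density and the
#' patient's own: `sNAL/(sMAD/sMedian) - NAL/(MAD/Median)`. Larger values mean
#' more neoantigen loss per unit of heterogeneity, i.e. stronger immune
#' escape; a patient exactly at the standard scores 0 and denser-than-standard
#' patients score negative.
#'
#' @param patient_density,standard_density Finite densities (see
#'   [neoantigen_density()]).
#' @return `standard_density - patient_density`.
#' @export
escape_index <- function(patient_density, standard_density) {
  stopifnot(all(is.finite(patient_density)), all(is.finite(standard_density)))
  standard_density - patient_density
}

#' Per-patient escape indices for a cohort
#'
#' Joins MATH results and neoantigen summaries on `patient_id`, derives each
#' patient's density, the cohort standard, and the escape index. Patients with
#' missing MATH or zero dispersion are dropped with a message (their density
#' is undefined).
#'
#' @param math_df Output of [compute_math()].
#' @param neo_summary Summary component of [compute_neoantigens()], or any
#'   data frame with `patient_id` and `nal`.
#' @param method,fixed See [cohort_standard()].
#' @return Data frame: `patient_id, nal, mad_over_median, patient_density,
#'   s_nal, s_mad_over_median, standard_density, escape_index`.
#' @export
compute_escape <- function(math_df, neo_summary,
                           method = c("cohort_median", "fixed"), fixed = NULL) {
  method <- match.arg(method)
  m <- merge(math_df[, c("patient_id", "median_vaf", "scaled_mad", "math")],
             neo_summary[, c("patient_id", "nal")], by = "patient_id")
  ok <- is.finite(m$math) & m$scaled_mad > 0 & m$median_vaf > 0
  if (any(!ok))
    message(sum(!ok), " patient(s) dropped from escape index: ",
            "missing MATH or zero VAF dispersion")
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) stop("compute_escape: no patients with defined density", call. = FALSE)
  std <- cohort_standard(m$nal, m$scaled_mad, m$median_vaf, method, fixed)
  out <- data.frame(
    patient_id = m$patient_id, nal = m$nal,
    mad_over_median = m$scaled_mad / m$median_vaf,
    patient_density = neoantigen_density(m$nal, m$scaled_mad, m$median_vaf),
    s_nal = std$s_nal, s_mad_over_median = std$s_mad_over_median,
    stringsAsFactors = FALSE)
  out$standard_density <- std$s_nal / std$s_mad_over_median
  out$escape_index <- escape_index(out$patient_density, out$standard_density)
  out
}

#' Split a cohort at the median escape index
#'
#' Patients at or below the median index form the low-escape group, those
#' strictly above form the high-escape group (ties go low; the rule is
#' arbitrary but fixed). If every index is equal the high group is empty and a
#' warning is emitted.
#'
#' @param escape_df Output of [compute_escape()] (>= 2 patients).
#' @return `escape_df` with an added `escape_group` factor
#'   (`"low"`/`"high"`).
#' @export
stratify_by_escape <- function(escape_df) {
  if (nrow(escape_df) < 2)
    stop("stratify_by_escape: need at least 2 patients", call. = FALSE)
  grp <- median_split(setNames(escape_df$escape_index, escape_df$patient_id))
  if (all(grp$group == "low"))
    warning("all escape indices equal: high-escape group is empty")
  escape_df$escape_group <- factor(grp$group, levels = c("low", "high"))
  escape_df
}
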