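#' Analysis configuration
#'
#' Every fixed constant of the analysis is a configuration key with its
#' conventional default, so sensitivity analyses need no code edits: the MAD
#' scaling constant (1.4826), the high-ITH MATH cutoff (40), the strong/weak
#' percentile-rank thresholds (0.5 / 2), the peptide window lengths (8-10),
#' the NAL definition, and the escape-standard method.
#'
#' @param ith_cutoff High-ITH MATH cutoff (strict `>`), default 40.
#' @param mad_constant MAD scaling constant, default 1.4826.
#' @param min_variants Minimum VAFs per patient for MATH, default 5.
#' @param min_depth,min_vaf Somatic-call filters for MATH, defaults 14 and
#'   0.05.
#' @param strong_rank,weak_rank Binder thresholds, defaults 0.5 and 2.
#' @param peptide_lengths Tiling window lengths, subset of 8..11, default
#'   8:10.
#' @param nal_definition `"strong_snv"` (default) or `"strong_all"`.
#' @param standard_method `"cohort_median"` (default) or `"fixed"`.
#' @param standard_fixed For `standard_method = "fixed"`:
#'   `c(s_nal, s_mad_over_median)`.
#' @param cluster_filter Apply the mixture VAF filter before MATH? Default
#'   `FALSE`.
#' @param seed Seed for the surrogate predictor, default 1.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(ith_cutoff = 40, mad_constant = 1.4826,
                            min_variants = 5L, min_depth = 14L, min_vaf = 0.05,
                            strong_rank = 0.5, weak_rank = 2.0,
                            peptide_lengths = c(8L, 9L, 10L),
                            nal_definition = c("strong_snv", "strong_all"),
                            standard_method = c("cohort_median", "fixed"),
                            standard_fixed = NULL, cluster_filter = FALSE,
                            seed = 1L) {
  nal_definition <- match.arg(nal_definition)
  standard_method <- match.arg(standard_method)
  stopifnot(ith_cutoff > 0, mad_constant > 0, min_variants >= 1,
            strong_rank < weak_rank, strong_rank > 0,
            all(peptide_lengths %in% 8:11))
  structure(as.list(environment()), class = "analysis_config")
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values are parsed as numeric where possible, comma-separated values as
#' vectors, `true`/`false` as logicals. Unknown keys raise an error so typos
#' do not silently fall back to defaults.
#'
#' @param path Path to the config file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2
  if (any(bad)) stop("config: malformed line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], "\\s*,\\s*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num
    else if (all(tolower(v) %in% c("true", "false"))) as.logical(toupper(v))
    else v
  })
  names(vals) <- keys
  known <- names(formals(analysis_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(analysis_config, vals)
}

#' Read/write protein FASTA
#'
#' Thin wrappers over Biostrings returning/accepting a named character vector.
#'
#' @param path FASTA path.
#' @return `read_protein_fasta`: named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' @rdname read_protein_fasta
#' @param proteins Named character vector of protein sequences.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(proteins), path, width = 60)
  invisible(path)
}

#' Read a per-patient HLA haplotype table
#'
#' TSV with columns `patient_id` and `allele`; returns a named list of
#' normalized allele vectors.
#'
#' @param path Path to the TSV.
#' @return Named list, one character vector per patient.
#' @export
read_hla_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_cols(df, c("patient_id", "allele"), "HLA table")
  split(normalize_hla_allele(df$allele), df$patient_id)
}

#' Run the full heterogeneity -> neoantigen -> escape -> statistics pipeline
#'
#' Executes the analysis end to end on an assembled or simulated cohort:
#' per-patient MATH scores and ITH classes; neoantigen enumeration and binder
#' counts (when proteins/effects/HLA are available); escape indices and the
#' median-split escape groups; and the cohort statistics (MATH-NAL Kendall and
#' Spearman correlations, the response 2x2 chi-square over the escape split,
#' log-rank between escape groups, and a multivariate Cox model of PFS on
#' MATH and the standard clinical covariates). Stages whose inputs are absent
#' are skipped with a message, never an error.
#'
#' When `out_dir` is given, each stage writes a tab-delimited table plus a
#' `manifest.txt` (configuration echo, package version, seed, input checksums)
#' sufficient to reproduce the run bit-exactly.
#'
#' @param cohort An `ith_cohort` (see [assemble_cohort()],
#'   [simulate_cohort()]).
#' @param config An [analysis_config()].
#' @param predictor Binding predictor for [assign_ranks()]; default the
#'   surrogate seeded from `config$seed`.
#' @param out_dir Optional output directory.
#' @return A `pipeline_result` list: `math`, `neo` (or `NULL`), `escape`,
#'   `stats` (list of `ith_test`/`survival_fit` objects), `config`.
#' @export
run_pipeline <- function(cohort, config = analysis_config(),
                         predictor = list(type = "surrogate", seed = config$seed),
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "ith_cohort"), inherits(config, "analysis_config"))
  if (identical(predictor$type, "table") && is.null(cohort$hla))
    stop("run_pipeline: a binding table predictor needs per-patient HLA input",
         call. = FALSE)

  math_df <- compute_math(
    cohort$variants, min_variants = config$min_variants,
    cutoff = config$ith_cutoff, constant = config$mad_constant,
    min_depth = config$min_depth, min_vaf = config$min_vaf,
    cluster_filter = config$cluster_filter)
  message("math: ", nrow(math_df), " patients, ",
          sum(is.finite(math_df$math)), " scored, ",
          sum(math_df$ith_class == "high", na.rm = TRUE), " high-ITH")

  neo <- NULL
  if (!is.null(cohort$proteins) && !is.null(cohort$effects) &&
      !is.null(cohort$hla)) {
    neo <- compute_neoantigens(
      cohort$variants, cohort$proteins, cohort$effects, cohort$hla,
      predictor = predictor, strong_cut = config$strong_rank,
      weak_cut = config$weak_rank, nal_definition = config$nal_definition,
      peptide_lengths = config$peptide_lengths)
    message("neo: ", nrow(neo$candidates), " candidate peptides, median NAL ",
            stats::median(neo$summary$nal))
  } else message("neo: skipped (no proteins/effects/HLA)")

  escape <- NULL
  if (!is.null(neo)) {
    escape <- tryCatch(
      stratify_by_escape(compute_escape(
        math_df, neo$summary, method = config$standard_method,
        fixed = config$standard_fixed)),
      error = function(e) { message("escape: skipped (", conditionMessage(e), ")"); NULL })
    if (!is.null(escape))
      message("escape: ", nrow(escape), " patients, ",
              sum(escape$escape_group == "high"), " high-escape")
  }

  stats_out <- list()
  clin <- cohort$clinical
  if (!is.null(neo)) {
    m <- merge(math_df, neo$summary[, c("patient_id", "nal")], by = "patient_id")
    m <- m[is.finite(m$math), , drop = FALSE]
    if (nrow(m) >= 3 && length(unique(m$nal)) > 1) {
      stats_out$kendall_math_nal <- kendall_tau_b(m$math, m$nal)
      stats_out$spearman_math_nal <- spearman_rho(m$math, m$nal)
    }
  }
  if (!is.null(escape) && all(c("pfs_months", "pfs_event") %in% names(clin))) {
    e <- merge(escape, clin, by = "patient_id")
    if (nlevels(droplevels(e$escape_group)) == 2)
      stats_out$logrank_escape <- km_logrank(e$pfs_months, e$pfs_event,
                                             e$escape_group)
    if ("best_response" %in% names(clin)) {
      tab <- table(factor(e$escape_group, levels = c("high", "low")),
                   factor(e$best_response, levels = c(">=VGPR", "<VGPR")))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        stats_out$chisq_response <- chi_square_2x2(tab)
    }
  }
  cox_cols <- c("fish_high_risk", "iss_stage", "gender", "age", "ecog",
                "hyperdiploid", "light_chain")
  if (all(c("pfs_months", "pfs_event") %in% names(clin)) &&
      all(cox_cols %in% names(clin))) {
    cd <- merge(math_df[is.finite(math_df$math),
                        c("patient_id", "math")], clin, by = "patient_id")
    covs <- data.frame(
      math = cd$math,
      fish_high_risk = as.integer(cd$fish_high_risk),
      iss_stage = match(cd$iss_stage, c("I", "II", "III")),
      gender = as.integer(cd$gender == "male"),
      age = cd$age, ecog = cd$ecog,
      hyperdiploid = as.integer(cd$hyperdiploid),
      light_chain = as.integer(cd$light_chain == "lambda"))
    ok <- stats::complete.cases(covs)
    if (sum(ok) > ncol(covs) + 1)
      stats_out$cox_pfs <- tryCatch(
        cox_ph(covs[ok, ], cd$pfs_months[ok], cd$pfs_event[ok]),
        error = function(e) { message("cox: skipped (", conditionMessage(e), ")"); NULL })
  }
  message("stats: ", length(stats_out), " analyses run")

  result <- structure(list(math = math_df, neo = neo, escape = escape,
                           stats = stats_out, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(result, cohort, out_dir)
  result
}

.write_pipeline_outputs <- function(result, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(result$math, "math.tsv")
  if (!is.null(result$neo)) {
    wt(result$neo$summary, "neoantigen_summary.tsv")
    wt(result$neo$candidates, "neoantigen_candidates.tsv")
  }
  if (!is.null(result$escape)) wt(result$escape, "escape.tsv")
  if (length(result$stats)) {
    srows <- lapply(names(result$stats), function(nm) {
      s <- result$stats[[nm]]
      if (inherits(s, "ith_test"))
        data.frame(analysis = nm, method = s$method, statistic = s$statistic,
                   p_value = s$p_value, effect = s$effect, n = s$n)
      else NULL
    })
    wt(do.call(rbind, srows), "stats.tsv")
    if (!is.null(result$stats$cox_pfs)) wt(result$stats$cox_pfs$table, "cox.tsv")
  }
  cfg <- result$config
  manifest <- c(
    sprintf("ithmm_version = %s", as.character(utils::packageVersion("ithmm"))),
    vapply(names(cfg), function(k)
      sprintf("%s = %s", k, paste(format(cfg[[k]]), collapse = ",")), ""),
    sprintf("n_patients = %d", nrow(cohort$clinical)),
    sprintf("n_variants = %d", nrow(cohort$variants)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("ithmm pipeline result\n")
  cat("  MATH: ", sum(is.finite(x$math$math)), " patients scored, ",
      sum(x$math$ith_class == "high", na.rm = TRUE), " high-ITH (cutoff ",
      x$config$ith_cutoff, ")\n", sep = "")
  if (!is.null(x$neo))
    cat("  NAL: median", stats::median(x$neo$summary$nal), "strong binders\n")
  if (!is.null(x$escape))
    cat("  escape: ", sum(x$escape$escape_group == "high"), "high /",
        sum(x$escape$escape_group == "low"), "low\n")
  for (nm in names(x$stats))
    if (inherits(x$stats[[nm]], "ith_test"))
      cat("  ", nm, ": p = ", format(x$stats[[nm]]$p_value, digits = 3),
          "\n", sep = "")
  invisible(x)
}
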