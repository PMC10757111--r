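#' Specification of a synthetic myeloma-like cohort
#'
#' Collects the generative parameters for [simulate_cohort()]. The defaults
#' describe the data structure the analysis pipeline assumes: multi-subclone
#' VAF spectra read-sampled at exome depth from CD138-sorted (high purity)
#' tumor samples, a per-sample mutation count centered near the study scale,
#' a strong-binding neoantigen load negatively rank-correlated with true
#' heterogeneity, immune-cell fractions positively coupled to that load, and
#' exponential proportional-hazards progression-free survival with independent
#' censoring.
#'
#' @param n_patients Cohort size (default 200, the size used for the
#'   package's end-to-end recovery checks).
#' @param subclones_per_patient Inclusive range for the number of clones,
#'   counting the clonal trunk (default 3-6).
#' @param ccf_range Cancer-cell-fraction range for the subclones below the
#'   trunk (which is always at CCF 1); default 0.05-0.5. Deep subclones with
#'   non-trivial mutation share are what give the wide VAF spectra of
#'   high-burden myeloma.
#' @param purity_range Tumor purity range (default 0.6-0.95).
#' @param mean_depth Mean sequencing depth, Poisson with floor 10 (default
#'   120).
#' @param mutations_per_patient Inclusive range for somatic calls per patient
#'   (default 20-120, median near 42 when combined with the annotation floor).
#' @param target_tau Kendall tau imposed between true MATH and NAL (default
#'   -0.25).
#' @param mu_nal,nal_dispersion Negative-binomial mean and size for the
#'   strong-binding neoantigen load (defaults 42 and 1.8).
#' @param beta_math Log-hazard per MATH unit (default `log(1.022)`).
#' @param beta_nal Log-hazard per strong binder (default -0.015, protective).
#' @param censor_rate Expected fraction of censored patients in `[0, 1)`
#'   (default 0.3).
#' @param immune_coupling Strength of the NAL -> CD8/NK coupling (default
#'   0.35; 0 decouples them).
#' @param baseline_median_pfs Median PFS in months for a patient at the
#'   cohort-center covariates (default 24).
#' @param strong_cut Strong-binder percentile-rank threshold assumed when
#'   sizing the annotated-variant load (default 0.5).
#' @param seed Integer seed; every draw is a pure function of (spec, seed).
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 200, subclones_per_patient = c(3L, 6L),
                        ccf_range = c(0.05, 0.5), purity_range = c(0.6, 0.95),
                        mean_depth = 120, mutations_per_patient = c(20L, 120L),
                        target_tau = -0.25, mu_nal = 42, nal_dispersion = 1.8,
                        beta_math = log(1.022), beta_nal = -0.015,
                        censor_rate = 0.3, immune_coupling = 0.35,
                        baseline_median_pfs = 24, strong_cut = 0.5, seed = 1L) {
  stopifnot(n_patients >= 2,
            length(subclones_per_patient) == 2,
            subclones_per_patient[1] >= 1,
            diff(subclones_per_patient) >= 0,
            length(ccf_range) == 2, ccf_range[1] > 0, ccf_range[2] <= 1,
            diff(ccf_range) > 0,
            length(purity_range) == 2, purity_range[1] > 0,
            purity_range[2] <= 1, diff(purity_range) > 0,
            mean_depth >= 10,
            length(mutations_per_patient) == 2, mutations_per_patient[1] >= 1,
            diff(mutations_per_patient) > 0,
            abs(target_tau) < 1, mu_nal > 0, nal_dispersion > 0,
            censor_rate >= 0, censor_rate < 1,
            baseline_median_pfs > 0, strong_cut > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# Class I allele pool the generator samples haplotypes from (2 per gene).
.hla_pool <- list(
  A = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*24:02"),
  B = c("HLA-B*07:02", "HLA-B*08:01", "HLA-B*15:01", "HLA-B*35:01"),
  C = c("HLA-C*03:04", "HLA-C*04:01", "HLA-C*07:01", "HLA-C*07:02"))

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Probability that a peptide's best rank over n_alleles i.i.d. Uniform(0,100)
# draws falls at or below `cut` -- the surrogate's per-peptide strong rate.
.p_strong_surrogate <- function(n_alleles, cut = 0.5) {
  1 - (1 - cut / 100)^n_alleles
}

#' Simulate somatic variants of one tumor by binomial read sampling
#'
#' Each mutation is assigned to a subclone by weight; its expected VAF under
#' the diploid heterozygous model (no copy-number change) is
#' `purity * ccf / 2`. Read depth is Poisson(`mean_depth`) floored at 10 and
#' the alt count binomial, so the realized VAF spectrum carries both the
#' inter-subclone spread and the binomial sampling noise that MATH sees in
#' real data.
#'
#' @param subclone_ccfs Cancer-cell fractions in (0, 1], one per subclone.
#' @param subclone_weights Mutation-assignment weights (must sum to 1).
#' @param purity Tumor purity in (0, 1].
#' @param mean_depth Mean read depth (Poisson, floored at 10).
#' @param n_mutations Number of somatic calls to draw.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param patient_id Id stamped on the rows.
#' @param variant_class Functional classes, recycled (default "missense").
#' @return A `somatic_variants` data frame with a `subclone` column and an
#'   `expected_vaf` column (the latent per-mutation mean VAF).
#' @export
simulate_vafs <- function(subclone_ccfs, subclone_weights, purity, mean_depth,
                          n_mutations, seed = 1L, patient_id = "P1",
                          variant_class = "missense") {
  stopifnot(all(subclone_ccfs > 0), all(subclone_ccfs <= 1),
            length(subclone_weights) == length(subclone_ccfs),
            all(subclone_weights >= 0), purity > 0, purity <= 1,
            mean_depth >= 1, n_mutations >= 1)
  if (abs(sum(subclone_weights) - 1) > 1e-8)
    stop("simulate_vafs: subclone weights must sum to 1", call. = FALSE)
  with_seed(seed, {
    sub <- sample.int(length(subclone_ccfs), n_mutations, replace = TRUE,
                      prob = subclone_weights)
    exp_vaf <- purity * subclone_ccfs[sub] / 2
    depth <- pmax(10L, stats::rpois(n_mutations, mean_depth))
    alt <- stats::rbinom(n_mutations, depth, exp_vaf)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_mutations, replace = TRUE)
    alt_allele <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    v <- data.frame(
      patient_id = patient_id,
      chrom = as.character(sample(1:22, n_mutations, replace = TRUE)),
      pos = sample.int(2e8, n_mutations),
      ref = ref, alt = unname(alt_allele),
      gene = sprintf("G%s_%04d", patient_id, seq_len(n_mutations)),
      variant_class = rep_len(variant_class, n_mutations),
      variant_type = "SNV",
      alt_count = alt, depth = depth, vaf = alt / depth,
      subclone = sub, expected_vaf = exp_vaf,
      stringsAsFactors = FALSE)
    class(v) <- c("somatic_variants", "data.frame")
    v
  })
}

#' Random proteins and protein-effect annotations for tiling tests
#'
#' Generates `n_variants` random wild-type proteins over the 20-residue
#' alphabet and one somatic protein effect per protein: interior missense
#' substitutions by default, with an optional share of frameshifts carrying a
#' novel translated tail. Positions keep at least 9 wild-type residues on each
#' side of a missense site, so the closed-form tiled-window count (8+9+10 = 27
#' per missense) holds for every record -- which is what makes these fixtures
#' useful as oracles.
#'
#' @param n_variants Number of protein/effect pairs.
#' @param protein_length_range Inclusive length range, min >= 28 (default
#'   30-60).
#' @param seed Integer seed.
#' @param patient_id Id stamped on the effect rows.
#' @param frameshift_prob Share of frameshift effects (default 0).
#' @return List with `proteins` (named character vector) and `effects` (data
#'   frame with `patient_id, chrom, pos, protein_id, protein_pos, effect,
#'   alt_residue, novel_tail`).
#' @export
synthetic_peptidome <- function(n_variants, protein_length_range = c(30L, 60L),
                                seed = 1L, patient_id = "P1",
                                frameshift_prob = 0) {
  stopifnot(n_variants >= 1, protein_length_range[1] >= 28,
            frameshift_prob >= 0, frameshift_prob <= 1)
  with_seed(seed, {
    lens <- sample(protein_length_range[1]:protein_length_range[2],
                   n_variants, replace = TRUE)
    proteins <- vapply(lens, function(L)
      paste(sample(.aa_alphabet, L, replace = TRUE), collapse = ""), "")
    names(proteins) <- sprintf("PROT_%s_%04d", patient_id, seq_len(n_variants))
    is_fs <- stats::runif(n_variants) < frameshift_prob
    pos <- vapply(lens, function(L) sample(10:(L - 9), 1), 1L)
    wt_res <- substr(proteins, pos, pos)
    alt_res <- vapply(wt_res, function(r) sample(setdiff(.aa_alphabet, r), 1), "")
    tails <- vapply(seq_len(n_variants), function(i)
      paste(sample(.aa_alphabet, sample(10:20, 1), replace = TRUE), collapse = ""), "")
    effects <- data.frame(
      patient_id = patient_id, chrom = "0", pos = seq_len(n_variants),
      protein_id = names(proteins), protein_pos = pos,
      effect = ifelse(is_fs, "frameshift", "missense"),
      alt_residue = ifelse(is_fs, NA_character_, unname(alt_res)),
      novel_tail = ifelse(is_fs, unname(tails), NA_character_),
      stringsAsFactors = FALSE)
    list(proteins = proteins, effects = effects)
  })
}

# Clonal trunk (ccf = 1) plus subclones drawn from ccf_range; mutation shares
# Dirichlet(2). The deep-subclone default is what makes most synthetic
# spectra as wide as the high-burden myeloma samples the analysis targets.
.architecture <- function(spec) {
  n_sub <- if (spec$subclones_per_patient[1] == spec$subclones_per_patient[2])
    spec$subclones_per_patient[1]
  else sample(spec$subclones_per_patient[1]:spec$subclones_per_patient[2], 1)
  ccfs <- c(1, sort(stats::runif(n_sub - 1, spec$ccf_range[1], spec$ccf_range[2]),
                    decreasing = TRUE))
  w <- stats::rgamma(n_sub, shape = 2)
  list(n_sub = n_sub, ccfs = ccfs, weights = w / sum(w),
       purity = stats::runif(1, spec$purity_range[1], spec$purity_range[2]))
}

# One patient's realized VAF spectrum: subclone assignment, Poisson depth
# (floored at 10), binomial alt counts. The tumor's "true" MATH is the score
# of this spectrum after the standard low-VAF filter -- the generator's
# ground-truth heterogeneity that NAL is coupled to and that the pipeline
# re-estimates after its own filters.
.draw_spectrum <- function(arch, n_mut, spec) {
  sub <- sample.int(arch$n_sub, n_mut, replace = TRUE, prob = arch$weights)
  exp_vaf <- arch$purity * arch$ccfs[sub] / 2
  depth <- pmax(10L, stats::rpois(n_mut, spec$mean_depth))
  alt <- stats::rbinom(n_mut, depth, exp_vaf)
  list(sub = sub, exp_vaf = exp_vaf, depth = depth, alt = alt,
       vaf = alt / depth)
}

.spectrum_math <- function(vaf, min_vaf = 0.05) {
  v <- vaf[vaf >= min_vaf]
  if (length(v) < 5) v <- vaf[vaf > 0]
  if (length(v) < 2 || stats::median(v) <= 0) return(0)
  100 * scaled_mad(v) / stats::median(v)
}

.math_ref_cache <- new.env(parent = emptyenv())

# Reference sample of true MATH under `spec` (the marginal CDF the Gaussian
# copula is anchored to); cached per spec fingerprint.
.math_reference <- function(spec, n_ref = 512L) {
  key <- paste(vapply(spec[setdiff(names(spec), "n_patients")],
                      function(x) paste(format(x, digits = 12), collapse = ","), ""),
               collapse = ";")
  if (!is.null(.math_ref_cache[[key]])) return(.math_ref_cache[[key]])
  ref <- with_seed(spec$seed + 7L, vapply(seq_len(n_ref), function(i) {
    arch <- .architecture(spec)
    n_mut <- sample(spec$mutations_per_patient[1]:spec$mutations_per_patient[2], 1)
    .spectrum_math(.draw_spectrum(arch, n_mut, spec)$vaf)
  }, 0))
  .math_ref_cache[[key]] <- ref
  ref
}

#' Simulate one patient of a synthetic cohort
#'
#' Draws the patient's subclonal architecture, somatic variants (binomial read
#' sampling via [simulate_vafs()]), latent strong-binding neoantigen load,
#' protein annotations, immune-cell fractions, clinical covariates and
#' proportional-hazards PFS outcome.
#'
#' The MATH-NAL coupling is imposed through a Gaussian copula: the patient's
#' architecture MATH is converted to a normal score against the spec's
#' reference distribution, correlated noise with
#' `rho = sin(pi * target_tau / 2)` is added, and the result is mapped through
#' the negative-binomial quantile function -- so the population Kendall tau of
#' (true MATH, NAL) equals `target_tau` (up to discreteness). The number of
#' protein-annotated variants is sized so that the surrogate-scored pipeline
#' recovers NAL in expectation: `round(NAL / (27 * p_strong))`, where
#' `p_strong` is the chance that a peptide's best rank across the patient's
#' alleles clears the strong threshold.
#'
#' @param spec A [cohort_spec()].
#' @param patient_index 1-based patient index (determines the per-patient
#'   seed).
#' @param peptidome Generate the per-patient proteins/effects? (default
#'   `TRUE`). Skipping it leaves every other draw unchanged -- the peptidome
#'   has its own nested seed -- and is useful when only MATH/survival
#'   structure is needed.
#' @return List with `variants`, `clinical` (one-row data frame), `hla`,
#'   `proteins`, `effects`, and `truth` (one-row data frame of latent values:
#'   architecture MATH, NAL, purity, subclone count).
#' @export
simulate_patient <- function(spec, patient_index, peptidome = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), patient_index >= 1)
  pid <- sprintf("SYN%03d", patient_index)
  seed_i <- (spec$seed + 104729 * patient_index) %% 2147483647
  ref <- .math_reference(spec)

  with_seed(seed_i, {
    arch <- .architecture(spec)
    n_mut_draw <- sample(spec$mutations_per_patient[1]:spec$mutations_per_patient[2], 1)

    # realized VAF spectrum -> true MATH -> copula-coupled NAL
    sp0 <- .draw_spectrum(arch, n_mut_draw, spec)
    true_math <- .spectrum_math(sp0$vaf)
    u <- (sum(ref <= true_math) + 0.5) / (length(ref) + 1)
    z1 <- stats::qnorm(u)
    rho <- sin(pi * spec$target_tau / 2)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
    nal <- stats::qnbinom(stats::pnorm(z2), mu = spec$mu_nal,
                          size = spec$nal_dispersion)

    hla <- unlist(lapply(.hla_pool, sample, size = 2), use.names = FALSE)
    p_strong <- .p_strong_surrogate(length(hla), spec$strong_cut)
    n_annot <- max(1L, as.integer(round(nal / (27 * p_strong))))
    n_mut <- max(n_mut_draw, n_annot)

    # annotated (protein-bearing) variants come first; if the annotation floor
    # exceeds the mutation draw, extra calls from the same architecture are
    # appended, so observed MATH stays the true score + filter jitter
    spx <- sp0
    if (n_mut > n_mut_draw) {
      extra <- .draw_spectrum(arch, n_mut - n_mut_draw, spec)
      spx <- lapply(setNames(names(sp0), names(sp0)),
                    function(f) c(sp0[[f]], extra[[f]]))
    }
    classes <- c(rep("missense", n_annot),
                 sample(c("missense", "silent", "other"), n_mut - n_annot,
                        replace = TRUE, prob = c(0.7, 0.15, 0.15)))
    bases <- c("A", "C", "G", "T")
    refb <- sample(bases, n_mut, replace = TRUE)
    altb <- vapply(refb, function(r) sample(setdiff(bases, r), 1), "")
    variants <- data.frame(
      patient_id = pid,
      chrom = as.character(sample(1:22, n_mut, replace = TRUE)),
      pos = sample.int(2e8, n_mut),
      ref = refb, alt = unname(altb),
      gene = sprintf("G%s_%04d", pid, seq_len(n_mut)),
      variant_class = classes, variant_type = "SNV",
      alt_count = spx$alt, depth = spx$depth, vaf = spx$vaf,
      subclone = spx$sub, expected_vaf = spx$exp_vaf,
      stringsAsFactors = FALSE)
    class(variants) <- c("somatic_variants", "data.frame")

    pep <- if (peptidome) {
      p <- synthetic_peptidome(n_annot, seed = seed_i + 2L, patient_id = pid)
      p$effects$chrom <- variants$chrom[seq_len(n_annot)]
      p$effects$pos <- variants$pos[seq_len(n_annot)]
      p
    } else list(proteins = NULL, effects = NULL)

    # immune fractions: affine in the NAL normal score + noise
    cd8 <- max(1, 24 + 10 * spec$immune_coupling * z2 + stats::rnorm(1, 0, 4))
    nk <- max(0.5, 12 + 6 * spec$immune_coupling * z2 + stats::rnorm(1, 0, 2.5))
    cd4 <- max(1, 35 + stats::rnorm(1, 0, 5))
    cd3 <- min(95, max(20, cd4 + cd8 + stats::rnorm(1, 8, 4)))
    cd19 <- max(0.2, 8 + stats::rnorm(1, 0, 3))

    # exponential PH outcome, centered so the reference patient has the
    # baseline median PFS; independent exponential censoring at censor_rate
    lp <- spec$beta_math * (true_math - stats::median(ref)) +
      spec$beta_nal * (nal - spec$mu_nal)
    h <- log(2) / spec$baseline_median_pfs * exp(lp)
    t_event <- stats::rexp(1, h)
    if (spec$censor_rate > 0) {
      t_cens <- stats::rexp(1, h * spec$censor_rate / (1 - spec$censor_rate))
      pfs <- min(t_event, t_cens); ev <- t_event <= t_cens
    } else {
      pfs <- t_event; ev <- TRUE
    }
    response <- stats::runif(1) < stats::plogis((nal - spec$mu_nal) / 20)

    clinical <- data.frame(
      patient_id = pid, disease_stage = "NDMM",
      iss_stage = sample(c("I", "II", "III"), 1, prob = c(0.3, 0.4, 0.3)),
      age = round(min(85, max(35, stats::rnorm(1, 60, 8)))),
      gender = sample(c("male", "female"), 1),
      ecog = sample(0:2, 1, prob = c(0.5, 0.4, 0.1)),
      fish_high_risk = stats::runif(1) < 0.3,
      hyperdiploid = stats::runif(1) < 0.5,
      light_chain = sample(c("kappa", "lambda"), 1, prob = c(0.6, 0.4)),
      pfs_months = pfs, pfs_event = ev,
      best_response = if (response) ">=VGPR" else "<VGPR",
      cd3 = cd3, cd4 = cd4, cd8 = cd8, cd19 = cd19, nk = nk,
      hla_loh = FALSE, stringsAsFactors = FALSE)

    truth <- data.frame(
      patient_id = pid, true_math = true_math, nal = nal,
      n_subclones = arch$n_sub, purity = arch$purity,
      n_variants = n_mut, n_annotated = n_annot,
      z_math = z1, z_nal = z2, stringsAsFactors = FALSE)

    list(variants = variants, clinical = clinical, hla = hla,
         proteins = pep$proteins, effects = pep$effects, truth = truth)
  })
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Applies [simulate_patient()] across the cohort and stacks the results into
#' an `ith_cohort` (variants, clinical table, HLA haplotypes, proteins,
#' protein effects) plus a ground-truth table of the latent values each
#' patient was generated from. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param peptidome See [simulate_patient()].
#' @return An `ith_cohort` with an extra `truth` data frame and the generating
#'   `spec` attached.
#' @export
simulate_cohort <- function(spec = cohort_spec(), peptidome = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  pts <- lapply(seq_len(spec$n_patients),
                function(i) simulate_patient(spec, i, peptidome = peptidome))
  variants <- do.call(rbind, lapply(pts, `[[`, "variants"))
  class(variants) <- c("somatic_variants", "data.frame")
  clinical <- do.call(rbind, lapply(pts, `[[`, "clinical"))
  class(clinical) <- c("clinical_table", "data.frame")
  cohort <- assemble_cohort(
    variants, clinical,
    hla = setNames(lapply(pts, `[[`, "hla"), clinical$patient_id),
    proteins = do.call(c, lapply(pts, `[[`, "proteins")),
    effects = do.call(rbind, lapply(pts, `[[`, "effects")))
  cohort$truth <- do.call(rbind, lapply(pts, `[[`, "truth"))
  cohort$spec <- spec
  cohort
}

#' Write a simulated cohort to plain-text files
#'
#' Writes the variant table (simple_tsv), clinical table (CSV), HLA list
#' (TSV), protein FASTA, effect table (TSV) and ground-truth table (CSV) under
#' `dir`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(cohort$variants,
                      file.path(dir, "variants.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  hla_df <- data.frame(
    patient_id = rep(names(cohort$hla), lengths(cohort$hla)),
    allele = unlist(cohort$hla, use.names = FALSE))
  utils::write.table(hla_df, file.path(dir, "hla.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_protein_fasta(cohort$proteins, file.path(dir, "proteins.fasta"))
  utils::write.table(cohort$effects, file.path(dir, "effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.table(cohort$truth, file.path(dir, "truth.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
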