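#' Apply a protein-level somatic effect to a wild-type protein
#'
#' Builds the mutant protein sequence from an annotated effect. Supported
#' effects: `missense` (single residue substitution), `nonsense` (truncation
#' before the stop), `frameshift` (wild-type prefix plus the novel translated
#' tail up to the first stop, `*` stripped), `inframe_ins` (whole residues
#' inserted after `protein_pos`), `inframe_del` (`del_length` residues deleted
#' starting at `protein_pos`). The package does not re-annotate genomes: the
#' effect table is an input, typically produced by the upstream annotator.
#'
#' @param wt_protein Wild-type amino-acid string.
#' @param effect One of `"missense"`, `"nonsense"`, `"frameshift"`,
#'   `"inframe_ins"`, `"inframe_del"`.
#' @param protein_pos 1-based residue position of the change.
#' @param alt_residue Replacement residue (missense).
#' @param novel_tail Novel translated tail (frameshift); may end in `"*"`.
#' @param ins_seq Inserted residues (inframe_ins).
#' @param del_length Number of deleted residues (inframe_del).
#' @return List with `mutant` (the mutant protein) and `interval`
#'   (`c(start, end)` of changed/novel residues in mutant coordinates;
#'   `integer(0)` for a pure truncation, which creates no novel sequence).
#' @export
mutant_protein <- function(wt_protein, effect, protein_pos,
                           alt_residue = NULL, novel_tail = NULL,
                           ins_seq = NULL, del_length = NULL) {
  n <- nchar(wt_protein)
  if (n < 1) stop("empty wild-type protein", call. = FALSE)
  if (protein_pos < 1 || protein_pos > n)
    stop("annotation inconsistency: protein position ", protein_pos,
         " outside protein of length ", n, call. = FALSE)
  pre <- function(k) substr(wt_protein, 1, k)
  switch(effect,
    missense = {
      if (is.null(alt_residue)) stop("missense effect needs alt_residue", call. = FALSE)
      mut <- paste0(pre(protein_pos - 1), alt_residue,
                    substr(wt_protein, protein_pos + 1, n))
      list(mutant = mut, interval = c(protein_pos, protein_pos))
    },
    nonsense = list(mutant = pre(protein_pos - 1), interval = integer(0)),
    frameshift = {
      if (is.null(novel_tail)) stop("frameshift effect needs novel_tail", call. = FALSE)
      tail <- sub("\\*.*$", "", novel_tail)
      mut <- paste0(pre(protein_pos - 1), tail)
      iv <- if (nchar(tail)) c(protein_pos, protein_pos - 1 + nchar(tail))
            else integer(0)
      list(mutant = mut, interval = iv)
    },
    inframe_ins = {
      if (is.null(ins_seq)) stop("inframe_ins effect needs ins_seq", call. = FALSE)
      mut <- paste0(pre(protein_pos), ins_seq,
                    substr(wt_protein, protein_pos + 1, n))
      list(mutant = mut,
           interval = c(protein_pos + 1, protein_pos + nchar(ins_seq)))
    },
    inframe_del = {
      if (is.null(del_length)) stop("inframe_del effect needs del_length", call. = FALSE)
      if (protein_pos + del_length - 1 > n)
        stop("annotation inconsistency: deletion runs past protein end", call. = FALSE)
      mut <- paste0(pre(protein_pos - 1),
                    substr(wt_protein, protein_pos + del_length, n))
      # the junction residue(s) flanking the deletion are the changed site
      iv <- c(max(1, protein_pos - 1), min(nchar(mut), protein_pos))
      if (nchar(mut) == 0) iv <- integer(0)
      list(mutant = mut, interval = iv)
    },
    stop("unknown effect: ", effect, call. = FALSE)
  )
}

#' Tile mutation-spanning peptides from a mutant protein
#'
#' Enumerates every window of the requested lengths (default 8, 9 and 10
#' residues) that overlaps the changed interval and differs from the
#' corresponding wild-type window. For substitutions each window is paired
#' with its wild-type counterpart; for frameshift/indel-derived windows
#' (coordinates not preserved) the wild-type peptide is `NA`. Duplicate mutant
#' peptide strings are collapsed. Proteins shorter than the smallest window
#' length yield no candidates.
#'
#' @param wt_protein,mut_protein Wild-type and mutant amino-acid strings.
#' @param changed_interval `c(start, end)` in mutant coordinates, or
#'   `integer(0)` (returns no candidates).
#' @param lengths Window lengths; default `c(8, 9, 10)`.
#' @param coords_preserved Are mutant coordinates aligned with wild-type
#'   (substitutions)? Default: `TRUE` when the two proteins have equal length.
#' @return Data frame with columns `mutant_peptide`, `wt_peptide` (`NA` when
#'   absent), `start`, `length`.
#' @export
tile_mutant_peptides <- function(wt_protein, mut_protein, changed_interval,
                                 lengths = c(8L, 9L, 10L),
                                 coords_preserved = nchar(wt_protein) == nchar(mut_protein)) {
  empty <- data.frame(mutant_peptide = character(), wt_peptide = character(),
                      start = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (length(changed_interval) == 0) return(empty)
  lm <- nchar(mut_protein)
  out <- list()
  for (L in sort(as.integer(lengths))) {
    if (lm < L) next
    starts <- seq_len(lm - L + 1L)
    starts <- starts[starts <= changed_interval[2] &
                     (starts + L - 1L) >= changed_interval[1]]
    if (!length(starts)) next
    mp <- substring(mut_protein, starts, starts + L - 1L)
    wp <- if (coords_preserved) substring(wt_protein, starts, starts + L - 1L)
          else rep(NA_character_, length(starts))
    differs <- is.na(wp) | wp != mp
    out[[length(out) + 1L]] <- data.frame(
      mutant_peptide = mp[differs], wt_peptide = wp[differs],
      start = starts[differs], length = L, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[!duplicated(res$mutant_peptide), , drop = FALSE]
}

#' Classify MHC binders by percentile rank
#'
#' Strong binder at `rank_percent <= strong_cut` (default 0.5), weak binder in
#' `(strong_cut, weak_cut]` (default 2), otherwise non-binder. Equality goes
#' to the stronger class, matching the behavior of the standard percentile-rank
#' predictors.
#'
#' @param rank_percent Numeric vector of percentile ranks (lower = stronger).
#' @param strong_cut,weak_cut Thresholds; `strong_cut < weak_cut`.
#' @return Character vector in `{"strong", "weak", "non"}`.
#' @export
classify_binder <- function(rank_percent, strong_cut = 0.5, weak_cut = 2.0) {
  stopifnot(strong_cut < weak_cut, all(rank_percent >= 0, na.rm = TRUE))
  ifelse(rank_percent <= strong_cut, "strong",
         ifelse(rank_percent <= weak_cut, "weak", "non"))
}

#' Deterministic surrogate binding predictor
#'
#' Maps each (peptide, allele) pair to a pseudo-random percentile rank in
#' \[0, 100) via an FNV-1a hash of `"peptide|allele|seed"`. The stream is a
#' pure function of its arguments -- bit-identical across runs and platforms --
#' so the full counting/classification pipeline can be exercised and tested
#' without the external binding neural network. Ranks are uniform by
#' construction, so with thresholds (0.5, 2) about 0.5% / 1.5% of pairs are
#' strong / weak binders per allele.
#'
#' @param peptide,allele Character vectors (allele recycled if length 1).
#' @param seed Integer salt.
#' @return Numeric vector of percentile ranks in \[0, 100).
#' @export
surrogate_rank <- function(peptide, allele, seed = 1L) {
  if (length(allele) == 1L) allele <- rep(allele, length(peptide))
  surrogate_rank_cpp(as.character(peptide), as.character(allele),
                     as.integer(seed))
}

#' Assign each candidate its best percentile rank across a patient's alleles
#'
#' For every candidate peptide and every HLA allele, obtains a percentile rank
#' from the predictor and keeps the best (lowest) rank, recording the allele
#' that achieves it. The predictor is either a netMHCpan-style table (list
#' `list(type = "table", records = <data frame from [read_binding_table()]>)`;
#' pairs absent from the table are reported in `attr(, "unresolved")`, never
#' silently dropped) or the built-in surrogate
#' (`list(type = "surrogate", seed = <int>)`).
#'
#' @param candidates Data frame with at least `mutant_peptide` (and optionally
#'   `wt_peptide`).
#' @param alleles Character vector of the patient's class I alleles
#'   (normalized).
#' @param predictor Predictor specification, see above.
#' @return `candidates` with `rank_percent`, `allele`, and (table predictor,
#'   when affinities are present) `kd_mut_nm`/`kd_wt_nm` columns added.
#' @export
assign_ranks <- function(candidates, alleles, predictor) {
  stopifnot(is.list(predictor), predictor$type %in% c("table", "surrogate"))
  n <- nrow(candidates)
  if (n == 0) {
    candidates$rank_percent <- numeric(0)
    candidates$allele <- character(0)
    return(candidates)
  }
  alleles <- unique(alleles[!is.na(alleles)])
  if (!length(alleles)) stop("assign_ranks: no HLA alleles supplied", call. = FALSE)
  peps <- candidates$mutant_peptide
  grid_pep <- rep(peps, times = length(alleles))
  grid_all <- rep(alleles, each = n)

  if (predictor$type == "surrogate") {
    ranks <- surrogate_rank(grid_pep, grid_all, seed = predictor$seed %||% 1L)
    unresolved <- NULL
  } else {
    tab <- predictor$records
    key <- paste(tab$peptide, tab$allele, sep = "|")
    hit <- match(paste(grid_pep, grid_all, sep = "|"), key)
    ranks <- tab$rank_percent[hit]
    unresolved <- unique(data.frame(peptide = grid_pep[is.na(hit)],
                                    allele = grid_all[is.na(hit)],
                                    stringsAsFactors = FALSE))
    if (nrow(unresolved) == 0) unresolved <- NULL
  }
  rank_mat <- matrix(ranks, nrow = n)
  best <- apply(rank_mat, 1L, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))
  candidates$rank_percent <- rank_mat[cbind(seq_len(n), best)]
  candidates$allele <- alleles[best]

  if (predictor$type == "table" && !is.null(predictor$records$kd_nm)) {
    tab <- predictor$records
    key <- paste(tab$peptide, tab$allele, sep = "|")
    candidates$kd_mut_nm <- tab$kd_nm[match(
      paste(candidates$mutant_peptide, candidates$allele, sep = "|"), key)]
    if ("wt_peptide" %in% names(candidates))
      candidates$kd_wt_nm <- tab$kd_nm[match(
        paste(candidates$wt_peptide, candidates$allele, sep = "|"), key)]
  }
  attr(candidates, "unresolved") <- unresolved
  candidates
}

#' Summarize per-patient neoantigen counts
#'
#' Counts unique mutant peptides per binder class, split by mutation type
#' (SNV vs indel). The neoantigen unit is the unique mutant peptide for the
#' patient -- a peptide reachable from several alleles or variants counts
#' once, at its best rank. The strong-binding neoantigen load (NAL) defaults
#' to the SNV-derived strong-binder count; set `nal_definition = "strong_all"`
#' to include indel-derived strong binders.
#'
#' @param candidates Data frame with `mutant_peptide`, `rank_percent`,
#'   `mutation_type` (`"SNV"`/`"indel"`), for one patient.
#' @param strong_cut,weak_cut See [classify_binder()].
#' @param nal_definition `"strong_snv"` (default) or `"strong_all"`.
#' @param patient_id Optional id carried into the result.
#' @return A `neoantigen_summary` list: `total_snv`, `strong_snv`, `weak_snv`,
#'   `total_indel`, `strong_indel`, `weak_indel`, `nal`.
#' @export
summarize_neoantigens <- function(candidates, strong_cut = 0.5, weak_cut = 2.0,
                                  nal_definition = c("strong_snv", "strong_all"),
                                  patient_id = NA_character_) {
  nal_definition <- match.arg(nal_definition)
  if (nrow(candidates)) {
    # dedup across variants/alleles: keep best rank per unique mutant peptide
    ord <- order(candidates$mutant_peptide, candidates$rank_percent)
    cand <- candidates[ord, , drop = FALSE]
    cand <- cand[!duplicated(cand$mutant_peptide), , drop = FALSE]
    cls <- classify_binder(cand$rank_percent, strong_cut, weak_cut)
    cls[is.na(cls)] <- "non"
    is_snv <- cand$mutation_type == "SNV"
  } else {
    cls <- character(0); is_snv <- logical(0)
  }
  cnt <- function(type, class = NULL) {
    sel <- if (type == "SNV") is_snv else !is_snv
    if (!is.null(class)) sel <- sel & cls == class
    sum(sel)
  }
  s <- list(patient_id = patient_id,
            total_snv = cnt("SNV"), strong_snv = cnt("SNV", "strong"),
            weak_snv = cnt("SNV", "weak"),
            total_indel = cnt("indel"), strong_indel = cnt("indel", "strong"),
            weak_indel = cnt("indel", "weak"))
  s$nal <- if (nal_definition == "strong_snv") s$strong_snv
           else s$strong_snv + s$strong_indel
  structure(s, class = "neoantigen_summary")
}

#' Amplitude component of the recognition potential
#'
#' Ratio of wild-type to mutant predicted dissociation constants,
#' `A = Kd_wt / Kd_mut`: values above 1 mean the mutant peptide binds MHC more
#' tightly than its wild-type counterpart. For frameshift-novel peptides,
#' which have no wild-type partner, callers substitute a configured constant
#' (1 by default in [compute_neoantigens()]).
#'
#' @param kd_wt_nm,kd_mut_nm Predicted affinities in nM, both > 0.
#' @return `kd_wt_nm / kd_mut_nm`.
#' @export
amplitude_a <- function(kd_wt_nm, kd_mut_nm) {
  if (any(kd_wt_nm <= 0) || any(kd_mut_nm <= 0))
    stop("amplitude_a: affinities must be positive", call. = FALSE)
  kd_wt_nm / kd_mut_nm
}

#' Similarity of a peptide to a reference epitope set
#'
#' Scores the peptide against every reference epitope by the best gapless
#' local alignment under a substitution matrix (BLOSUM62 by default), takes
#' the maximum score s*, and maps it through a logistic curve:
#' `R = 1 / (1 + exp(-slope_k * (s* - midpoint_a)))`. R rises from 0 toward 1
#' as the peptide approaches a known immunogenic epitope; the defaults
#' (midpoint 26, slope 4.87) are the standard calibration of the
#' recognition-potential model.
#'
#' @param mut_peptide Amino-acid string.
#' @param epitope_reference_set Character vector of reference epitopes
#'   (non-empty).
#' @param midpoint_a Logistic midpoint on the alignment-score scale.
#' @param slope_k Logistic steepness.
#' @param substitution_matrix Square scoring matrix with residue dimnames;
#'   default BLOSUM62 (from Biostrings).
#' @return List with `r` (in \[0,1\]), `best_score` (s*), and `best_ref`.
#' @export
similarity_r <- function(mut_peptide, epitope_reference_set,
                         midpoint_a = 26, slope_k = 4.87,
                         substitution_matrix = NULL) {
  if (!length(epitope_reference_set))
    stop("similarity_r: empty epitope reference set", call. = FALSE)
  sub <- substitution_matrix %||% .blosum62()
  scores <- gapless_local_scores_cpp(mut_peptide,
                                     as.character(epitope_reference_set),
                                     sub, rownames(sub))
  best <- which.max(scores)
  s_star <- scores[best]
  list(r = stats::plogis(slope_k * (s_star - midpoint_a)),
       best_score = s_star,
       best_ref = epitope_reference_set[best])
}

.blosum_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62
  }
  .blosum_cache$m
}

#' Recognition potential of a neoantigen
#'
#' Product of the MHC-binding amplitude A and the TCR-recognition similarity
#' R: candidates need both tight (differential) MHC binding and resemblance to
#' known immunogenic epitopes to score highly.
#'
#' @param a Amplitude, >= 0 (see [amplitude_a()]).
#' @param r Similarity in \[0, 1\] (see [similarity_r()]).
#' @return A `recognition_score` list: `amplitude_a`, `similarity_r`,
#'   `potential`.
#' @export
recognition_potential <- function(a, r) {
  stopifnot(all(a >= 0), all(r >= 0 & r <= 1))
  structure(list(amplitude_a = a, similarity_r = r, potential = a * r),
            class = "recognition_score")
}

#' Enumerate and classify neoantigens for a cohort
#'
#' Runs the full neoepitope stage: joins variants to their protein effects,
#' builds mutant proteins, tiles mutation-spanning 8-10mers, assigns each
#' unique candidate its best percentile rank across the patient's HLA class I
#' alleles, classifies binders, and summarizes per-patient counts. Variants
#' without a protein-effect annotation (non-coding, or genes without product)
#' are skipped. Frameshift-novel candidates carry `amplitude_a =
#' default_amplitude` since no wild-type affinity exists; they are flagged by
#' `wt_peptide = NA`.
#'
#' @param variants `somatic_variants` data frame.
#' @param proteins Named character vector of wild-type protein sequences.
#' @param effects Data frame linking variants to proteins: columns
#'   `patient_id, chrom, pos, protein_id, protein_pos, effect` plus
#'   effect-specific `alt_residue`, `novel_tail`, `ins_seq`, `del_length`.
#' @param hla Named list (patient_id -> character vector of alleles).
#' @param predictor See [assign_ranks()].
#' @param strong_cut,weak_cut,nal_definition See [summarize_neoantigens()].
#' @param peptide_lengths Window lengths, default `c(8, 9, 10)`.
#' @param default_amplitude Amplitude for candidates without a wild-type
#'   partner; default 1.
#' @return List with `candidates` (cohort-wide data frame) and `summary`
#'   (one row per patient: counts and `nal`).
#' @export
compute_neoantigens <- function(variants, proteins, effects, hla, predictor,
                                strong_cut = 0.5, weak_cut = 2.0,
                                nal_definition = "strong_snv",
                                peptide_lengths = c(8L, 9L, 10L),
                                default_amplitude = 1) {
  key_v <- paste(variants$patient_id, variants$chrom, variants$pos)
  key_e <- paste(effects$patient_id, effects$chrom, effects$pos)
  hit <- match(key_v, key_e)
  ids <- unique(variants$patient_id)
  all_cand <- list()
  summaries <- list()
  for (id in ids) {
    rows <- which(variants$patient_id == id & !is.na(hit))
    cand_list <- list()
    for (i in rows) {
      eff <- effects[hit[i], ]
      wt <- proteins[[eff$protein_id]]
      if (is.null(wt)) next
      mp <- tryCatch(mutant_protein(
        wt, eff$effect, eff$protein_pos,
        alt_residue = eff$alt_residue %||% NULL,
        novel_tail = eff$novel_tail %||% NULL,
        ins_seq = eff$ins_seq %||% NULL,
        del_length = eff$del_length %||% NULL), error = function(e) NULL)
      if (is.null(mp)) next
      tiles <- tile_mutant_peptides(wt, mp$mutant, mp$interval,
                                    lengths = peptide_lengths)
      if (!nrow(tiles)) next
      tiles$patient_id <- id
      tiles$chrom <- variants$chrom[i]
      tiles$pos <- variants$pos[i]
      tiles$mutation_type <- if (variants$variant_type[i] == "SNV") "SNV" else "indel"
      cand_list[[length(cand_list) + 1L]] <- tiles
    }
    cand <- if (length(cand_list)) do.call(rbind, cand_list) else
      data.frame(mutant_peptide = character(), wt_peptide = character(),
                 start = integer(), length = integer(), patient_id = character(),
                 chrom = character(), pos = integer(), mutation_type = character(),
                 stringsAsFactors = FALSE)
    alleles <- hla[[id]]
    if (nrow(cand) && length(alleles)) {
      cand <- assign_ranks(cand, alleles, predictor)
      cand$binder_class <- classify_binder(cand$rank_percent, strong_cut, weak_cut)
      if (!"kd_wt_nm" %in% names(cand)) cand$kd_wt_nm <- NA_real_
      if (!"kd_mut_nm" %in% names(cand)) cand$kd_mut_nm <- NA_real_
      cand$amplitude_a <- ifelse(
        !is.na(cand$kd_wt_nm) & !is.na(cand$kd_mut_nm),
        cand$kd_wt_nm / cand$kd_mut_nm, default_amplitude)
    } else {
      cand$rank_percent <- rep(NA_real_, nrow(cand))
      cand$allele <- rep(NA_character_, nrow(cand))
      cand$binder_class <- rep("non", nrow(cand))
    }
    summaries[[id]] <- as.data.frame(unclass(
      summarize_neoantigens(cand, strong_cut, weak_cut, nal_definition,
                            patient_id = id)), stringsAsFactors = FALSE)
    all_cand[[id]] <- cand
  }
  list(candidates = do.call(rbind, c(all_cand, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))))
}
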