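#' Variant table input and output
#'
#' @description Conventions shared by the variant readers and writers.
#' @section Variant table dialects:
#' Coordinates are 1-based inclusive (MAF convention); VCF positions already
#' are. `simple_tsv` is the canonical tab-delimited format with columns
#' `patient_id, chrom, pos, ref, alt, gene, variant_class, alt_count, depth`
#' and optionally `vaf`. `maf` uses the standard MAF column names
#' (`Hugo_Symbol`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Classification`, `t_alt_count`, `t_depth`,
#' `Tumor_Sample_Barcode`). `vcf` reads a VCF 4.x file and takes allele counts
#' from the `AD`/`DP` FORMAT fields of the tumor sample.
#' @name variant-io
NULL

.variant_classes <- c("missense", "nonsense", "frameshift_ins", "frameshift_del",
                      "inframe_ins", "inframe_del", "silent", "splice", "other")
.nonsilent_classes <- setdiff(.variant_classes, "silent")

.maf_class_map <- c(
  Missense_Mutation = "missense", Nonsense_Mutation = "nonsense",
  Nonstop_Mutation = "other", Frame_Shift_Ins = "frameshift_ins",
  Frame_Shift_Del = "frameshift_del", In_Frame_Ins = "inframe_ins",
  In_Frame_Del = "inframe_del", Silent = "silent", Splice_Site = "splice",
  Translation_Start_Site = "other", RNA = "other", Intron = "other",
  `3'UTR` = "other", `5'UTR` = "other", `3'Flank` = "other", `5'Flank` = "other"
)

.norm_variant_class <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% .variant_classes, x,
                unname(.maf_class_map[match(x, names(.maf_class_map))]))
  out[is.na(out)] <- "other"
  as.character(out)
}

# Shared validation/assembly for all dialects. `raw` has standardized columns.
# Rows with depth <= 0 or alleles outside the {SNV, INS, DEL} length rules are
# skipped and tallied in attr(result, "skipped").
.build_variants <- function(raw) {
  raw$ref <- toupper(as.character(raw$ref))
  raw$alt <- toupper(as.character(raw$alt))
  ref1 <- gsub("-", "", raw$ref, fixed = TRUE)
  alt1 <- gsub("-", "", raw$alt, fixed = TRUE)
  allele_ok <- grepl("^[ACGTN]*$", ref1) & grepl("^[ACGTN]*$", alt1) &
    (nchar(ref1) > 0 | nchar(alt1) > 0) & ref1 != alt1
  type <- rep(NA_character_, nrow(raw))
  type[nchar(ref1) == 1 & nchar(alt1) == 1] <- "SNV"
  type[nchar(alt1) > nchar(ref1)] <- "INS"
  type[nchar(alt1) < nchar(ref1)] <- "DEL"
  allele_ok <- allele_ok & !is.na(type)   # equal-length MNVs are unsupported

  depth <- suppressWarnings(as.numeric(raw$depth))
  alt_count <- suppressWarnings(as.numeric(raw$alt_count))
  depth_ok <- !is.na(depth) & depth > 0 & !is.na(alt_count) &
    alt_count >= 0 & alt_count <= depth

  keep <- allele_ok & depth_ok
  skipped <- c(bad_alleles = sum(!allele_ok), bad_depth = sum(allele_ok & !depth_ok))

  v <- data.frame(
    patient_id = as.character(raw$patient_id)[keep],
    chrom = as.character(raw$chrom)[keep],
    pos = as.integer(raw$pos)[keep],
    ref = raw$ref[keep], alt = raw$alt[keep],
    gene = as.character(raw$gene)[keep],
    variant_class = .norm_variant_class(raw$variant_class)[keep],
    variant_type = type[keep],
    alt_count = as.integer(alt_count[keep]),
    depth = as.integer(depth[keep]),
    stringsAsFactors = FALSE
  )
  vaf_counts <- v$alt_count / v$depth
  if (!is.null(raw$vaf) && any(!is.na(raw$vaf))) {
    vaf <- suppressWarnings(as.numeric(raw$vaf))[keep]
    inconsistent <- !is.na(vaf) & abs(vaf - vaf_counts) > 1e-6
    if (any(inconsistent))
      warning(sum(inconsistent), " row(s) have a VAF column inconsistent with ",
              "alt_count/depth (> 1e-6); the explicit VAF column is kept.")
    v$vaf <- ifelse(is.na(vaf), vaf_counts, vaf)
  } else {
    v$vaf <- vaf_counts
  }
  class(v) <- c("somatic_variants", "data.frame")
  attr(v, "skipped") <- skipped
  v
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("malformed ", what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Read a somatic variant table
#'
#' Parses per-patient somatic variant calls from one of three dialects and
#' returns a `somatic_variants` data frame (one row per call) with columns
#' `patient_id, chrom, pos, ref, alt, gene, variant_class, variant_type,
#' alt_count, depth, vaf`. The reader is lossless with respect to functional
#' class: silent and splice calls are retained and filtered downstream.
#'
#' VAF is taken from an explicit `vaf` column when present (a discrepancy
#' > 1e-6 against `alt_count/depth` triggers a warning, not an error, to
#' tolerate upstream rounding); otherwise it is computed from the counts.
#' Rows with zero/invalid depth or unparseable alleles (including equal-length
#' multi-nucleotide substitutions, which fall outside the SNV/INS/DEL typing)
#' are skipped and tallied in `attr(x, "skipped")`.
#'
#' @param path Path to the variant file.
#' @param dialect One of `"simple_tsv"`, `"maf"`, `"vcf"`.
#' @param tumor_sample For `dialect = "vcf"`: name or index of the tumor sample
#'   column; defaults to the last sample in the file.
#' @return A `somatic_variants` data frame; `attr(, "skipped")` counts the
#'   dropped rows. An empty table yields a zero-row frame, not an error.
#' @seealso [write_variant_table()], [variant-io]
#' @export
read_variant_table <- function(path, dialect = c("simple_tsv", "maf", "vcf"),
                               tumor_sample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "vcf") return(.read_vcf_variants(path, tumor_sample))

  # read everything as character: allele columns like "T" must never be
  # coerced to logicals; numeric conversion happens during validation
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (dialect == "simple_tsv") {
    .require_cols(df, c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                        "variant_class", "alt_count", "depth"), "simple_tsv table")
    raw <- df
  } else {
    .require_cols(df, c("Hugo_Symbol", "Chromosome", "Start_Position",
                        "Reference_Allele", "Tumor_Seq_Allele2",
                        "Variant_Classification", "t_alt_count", "t_depth"),
                  "MAF table")
    raw <- data.frame(
      patient_id = if ("Tumor_Sample_Barcode" %in% names(df))
        df$Tumor_Sample_Barcode else "sample",
      chrom = df$Chromosome, pos = df$Start_Position,
      ref = df$Reference_Allele, alt = df$Tumor_Seq_Allele2,
      gene = df$Hugo_Symbol, variant_class = df$Variant_Classification,
      alt_count = df$t_alt_count, depth = df$t_depth,
      stringsAsFactors = FALSE
    )
    if ("vaf" %in% names(df)) raw$vaf <- df$vaf
  }
  .build_variants(raw)
}

.read_vcf_variants <- function(path, tumor_sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) == 0) stop("VCF has no sample columns", call. = FALSE)
  tumor <- tumor_sample %||% samples[length(samples)]
  if (is.numeric(tumor)) tumor <- samples[tumor]
  if (!tumor %in% samples) stop("tumor sample not in VCF: ", tumor, call. = FALSE)

  ad <- vcfR::extract.gt(vcf, element = "AD")[, tumor]
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "DP")[, tumor]))
  alt_count <- suppressWarnings(as.numeric(vapply(
    strsplit(ad, ","), function(x) if (length(x) >= 2) x[2] else NA_character_,
    character(1))))
  raw <- data.frame(
    patient_id = tumor, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, gene = NA_character_,
    variant_class = "other", alt_count = alt_count, depth = dp,
    stringsAsFactors = FALSE
  )
  .build_variants(raw)
}

#' Write a somatic variant table in the canonical simple_tsv dialect
#'
#' Numeric VAFs are written with full precision so that write/read round-trips
#' reproduce every field exactly.
#'
#' @param variants A `somatic_variants` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants[, c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                      "variant_class", "alt_count", "depth", "vaf")]
  out$vaf <- vapply(out$vaf, function(x) format(x, digits = 17, scientific = FALSE),
                    character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize HLA class I allele names
#'
#' Accepts the dialects found in binding-predictor output and typing reports
#' (`"HLA-A*02:01"`, `"HLA-A02:01"`, `"A*02:01"`, `"A0201"`) and returns the
#' canonical 4-digit form `"HLA-A*02:01"`.
#'
#' @param x Character vector of allele names.
#' @return Character vector of normalized names; unparseable entries are `NA`
#'   with a warning.
#' @export
normalize_hla_allele <- function(x) {
  x0 <- toupper(trimws(as.character(x)))
  y <- sub("^HLA-?", "", x0)
  y <- gsub("[*:]", "", y)
  ok <- grepl("^[ABC][0-9]{4,5}$", y)
  gene <- substr(y, 1, 1)
  digits <- substring(y, 2)
  # 4 digits -> 2+2; 5 digits -> 3+2 (e.g. A*101:01 does not occur in class I,
  # but B*15:xxx style 2+3 does; keep the common 2+2 split for 4, 2+3 for 5)
  grp <- ifelse(nchar(digits) == 4, substr(digits, 1, 2), substr(digits, 1, 2))
  prot <- ifelse(nchar(digits) == 4, substr(digits, 3, 4), substr(digits, 3, 5))
  out <- ifelse(ok, paste0("HLA-", gene, "*", grp, ":", prot), NA_character_)
  if (any(!ok & !is.na(x0)))
    warning("unparseable HLA allele name(s): ",
            paste(unique(x0[!ok]), collapse = ", "))
  out
}

#' Read a netMHCpan-style binding prediction table
#'
#' Accepts whitespace- or tab-delimited tables with at least a peptide column,
#' an allele column (`MHC`/`allele`/`HLA`) and a percentile-rank column
#' (`%Rank_EL`, `%Rank`, `EL_Rank`, or `Rank`). Comment lines (`#`) and
#' netMHCpan separator lines are tolerated. Allele names are normalized via
#' [normalize_hla_allele()]. An affinity column (`Aff(nM)`/`kd_nm`) is carried
#' through when present.
#'
#' @param path Path to the table.
#' @return A data frame with columns `peptide`, `allele`, `rank_percent` and
#'   optionally `kd_nm`.
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|-{3,})", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("binding table is empty: ", path, call. = FALSE)
  tokens <- strsplit(trimws(lines), "[\t ]+")
  header <- tokens[[1]]
  rank_col <- which(header %in% c("%Rank_EL", "%Rank", "EL_Rank", "Rank",
                                  "rank_percent", "%Rank_BA"))[1]
  if (is.na(rank_col))
    stop("binding table has no recognizable percentile-rank column ",
         "(%Rank_EL / %Rank / EL_Rank / Rank)", call. = FALSE)
  pep_col <- which(tolower(header) %in% c("peptide", "pep"))[1]
  allele_col <- which(tolower(header) %in% c("mhc", "allele", "hla"))[1]
  if (is.na(pep_col) || is.na(allele_col))
    stop("binding table needs peptide and MHC/allele columns", call. = FALSE)
  aff_col <- which(header %in% c("Aff(nM)", "kd_nm", "Affinity"))[1]

  body <- tokens[-1]
  body <- body[vapply(body, length, 1L) >= max(rank_col, pep_col, allele_col)]
  get <- function(i) vapply(body, `[`, character(1), i)
  out <- data.frame(
    peptide = toupper(get(pep_col)),
    allele = normalize_hla_allele(get(allele_col)),
    rank_percent = as.numeric(get(rank_col)),
    stringsAsFactors = FALSE
  )
  if (!is.na(aff_col)) out$kd_nm <- as.numeric(get(aff_col))
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", out$peptide) |
    !is.finite(out$rank_percent)
  if (any(bad)) {
    warning(sum(bad), " binding row(s) with invalid peptide or rank skipped")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

.clin_enum <- function(x, col, levels, aliases = NULL) {
  x0 <- trimws(as.character(x))
  if (!is.null(aliases)) {
    hit <- match(toupper(x0), toupper(names(aliases)))
    x0 <- ifelse(is.na(hit), x0, unname(aliases[hit]))
  }
  bad <- !is.na(x0) & nzchar(x0) & !x0 %in% levels
  if (any(bad))
    stop("clinical table: invalid value(s) for '", col, "': ",
         paste(unique(x0[bad]), collapse = ", "),
         " (expected ", paste(levels, collapse = "/"), ")", call. = FALSE)
  ifelse(nzchar(x0), x0, NA_character_)
}

.clin_bool <- function(x, col) {
  x0 <- toupper(trimws(as.character(x)))
  map <- c(`1` = TRUE, `0` = FALSE, `TRUE` = TRUE, `FALSE` = FALSE,
           YES = TRUE, NO = FALSE, T = TRUE, F = FALSE)
  out <- unname(map[match(x0, names(map))])
  bad <- is.na(out) & !is.na(x0) & nzchar(x0)
  if (any(bad))
    stop("clinical table: invalid boolean value(s) for '", col, "': ",
         paste(unique(x0[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Read a clinical covariate table
#'
#' CSV with one row per patient. Required: `patient_id` (unique). Recognized
#' optional columns: `disease_stage` (MGUS/NDMM/RRMM), `iss_stage` (or `iss`;
#' I/II/III or 1/2/3), `age`, `gender` (male/female), `ecog` (0-4),
#' `fish_high_risk`, `hyperdiploid`, `light_chain` (kappa/lambda/none),
#' `pfs_months` (or `pfs`), `pfs_event` (or `event`), `best_response`
#' (`>=VGPR` / `<VGPR`), `hla_loh`, and lymphocyte-subset percentages
#' `cd3, cd4, cd8, cd19, nk`. Unknown category labels raise an error naming
#' the column and the offending values; missing optional columns are left out.
#'
#' @param path Path to the CSV file.
#' @return A `clinical_table` data frame keyed by `patient_id`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_cols(df, "patient_id", "clinical table")
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("clinical table: duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "),
         call. = FALSE)
  nm <- names(df)
  if ("iss" %in% nm && !"iss_stage" %in% nm) names(df)[nm == "iss"] <- "iss_stage"
  if ("pfs" %in% nm && !"pfs_months" %in% nm) names(df)[names(df) == "pfs"] <- "pfs_months"
  if ("event" %in% nm && !"pfs_event" %in% nm) names(df)[names(df) == "event"] <- "pfs_event"

  if ("disease_stage" %in% names(df))
    df$disease_stage <- .clin_enum(df$disease_stage, "disease_stage",
                                   c("MGUS", "NDMM", "RRMM"))
  if ("iss_stage" %in% names(df))
    df$iss_stage <- .clin_enum(df$iss_stage, "iss_stage", c("I", "II", "III"),
                               aliases = c(`1` = "I", `2` = "II", `3` = "III"))
  if ("gender" %in% names(df))
    df$gender <- .clin_enum(df$gender, "gender", c("male", "female"),
                            aliases = c(M = "male", F = "female",
                                        MALE = "male", FEMALE = "female"))
  if ("light_chain" %in% names(df))
    df$light_chain <- .clin_enum(df$light_chain, "light_chain",
                                 c("kappa", "lambda", "none"))
  if ("best_response" %in% names(df))
    df$best_response <- .clin_enum(df$best_response, "best_response",
                                   c(">=VGPR", "<VGPR"),
                                   aliases = c(`≥VGPR` = ">=VGPR"))
  for (col in intersect(c("fish_high_risk", "hyperdiploid", "pfs_event", "hla_loh"),
                        names(df)))
    df[[col]] <- .clin_bool(df[[col]], col)
  for (col in intersect(c("age", "ecog", "pfs_months", "cd3", "cd4", "cd8",
                          "cd19", "nk"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if ("ecog" %in% names(df) && any(!is.na(df$ecog) & !df$ecog %in% 0:4))
    stop("clinical table: invalid value(s) for 'ecog' (expected 0-4)", call. = FALSE)
  if ("pfs_months" %in% names(df) && any(!is.na(df$pfs_months) & df$pfs_months < 0))
    stop("clinical table: negative pfs_months", call. = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Assemble a cohort object from its component tables
#'
#' Bundles variants, clinical covariates and per-patient HLA class I haplotypes
#' into an `ith_cohort` list used by [run_pipeline()]. HLA alleles are
#' normalized; each patient's variants must carry that patient's id.
#'
#' @param variants A `somatic_variants` data frame (all patients stacked).
#' @param clinical A `clinical_table` data frame.
#' @param hla Named list (by patient_id) of character vectors of class I
#'   alleles, or `NULL` when the neoepitope stage is not run.
#' @param proteins Named character vector of protein sequences (names are
#'   protein ids), or `NULL`.
#' @param effects Protein-effect table linking variants to proteins (see
#'   [mutant_protein()]), or `NULL`.
#' @return An object of class `ith_cohort`.
#' @export
assemble_cohort <- function(variants, clinical, hla = NULL,
                            proteins = NULL, effects = NULL) {
  if (!is.null(hla)) {
    hla <- lapply(hla, normalize_hla_allele)
    unknown <- setdiff(names(hla), clinical$patient_id)
    if (length(unknown))
      warning("HLA entries for patients absent from the clinical table: ",
              paste(unknown, collapse = ", "))
  }
  structure(list(variants = variants, clinical = clinical, hla = hla,
                 proteins = proteins, effects = effects),
            class = "ith_cohort")
}

#' @exportS3Method base::print
print.ith_cohort <- function(x, ...) {
  cat("ith_cohort:", nrow(x$clinical), "patients,",
      nrow(x$variants), "somatic variants\n")
  if (!is.null(x$hla)) cat("  HLA haplotypes for", length(x$hla), "patients\n")
  if (!is.null(x$proteins)) cat("  ", length(x$proteins), "annotated proteins\n")
  invisible(x)
}
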