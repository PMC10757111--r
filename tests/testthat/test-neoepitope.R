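test_that("protein effects build the documented mutant sequences", {
  m <- mutant_protein("ACDEFGHIK", "missense", 5, alt_residue = "Y")
  expect_equal(m$mutant, "ACDEYGHIK")
  expect_equal(m$interval, c(5, 5))

  m <- mutant_protein("ACDEFGHIK", "nonsense", 5)
  expect_equal(m$mutant, "ACDE")
  expect_length(m$interval, 0)

  m <- mutant_protein("ACDEFGHIK", "frameshift", 5, novel_tail = "RSTW*")
  expect_equal(m$mutant, "ACDERSTW")
  expect_equal(m$interval, c(5, 8))

  m <- mutant_protein("ACDEFGHIK", "inframe_ins", 3, ins_seq = "WW")
  expect_equal(m$mutant, "ACDWWEFGHIK")
  expect_equal(m$interval, c(4, 5))

  expect_error(mutant_protein("ACDE", "missense", 9, alt_residue = "Y"),
               "inconsistency")
})

test_that("tiling yields the closed-form window counts", {
  set.seed(3)
  wt <- random_peptide(100)
  mut <- mutant_protein(wt, "missense", 50,
                        alt_residue = setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                              substr(wt, 50, 50))[1])
  tiles <- tile_mutant_peptides(wt, mut$mutant, mut$interval)
  expect_equal(nrow(tiles), 27)           # 8 + 9 + 10 interior windows

  # mutation at position 1: one window per length
  mut1 <- mutant_protein(wt, "missense", 1,
                         alt_residue = setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                               substr(wt, 1, 1))[1])
  expect_equal(nrow(tile_mutant_peptides(wt, mut1$mutant, mut1$interval)), 3)

  # protein shorter than the smallest window
  short <- "ACDEFGH"
  ms <- mutant_protein(short, "missense", 4, alt_residue = "W")
  expect_equal(nrow(tile_mutant_peptides(short, ms$mutant, ms$interval)), 0)
})

test_that("tiling equals brute-force window enumeration on random fixtures", {
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:100) {
    L <- sample(8:60, 1)
    wt <- random_peptide(L)
    pos <- sample(seq_len(L), 1)
    if (runif(1) < 0.5) {
      eff <- mutant_protein(wt, "missense", pos,
                            alt_residue = setdiff(aa, substr(wt, pos, pos))[1])
    } else {
      eff <- mutant_protein(wt, "frameshift", pos,
                            novel_tail = random_peptide(sample(1:15, 1)))
    }
    got <- tile_mutant_peptides(wt, eff$mutant, eff$interval)
    expect_setequal(got$mutant_peptide, brute_tiles(wt, eff$mutant, eff$interval))
  }
})

test_that("binder classification respects thresholds with ties to the stronger class", {
  expect_equal(classify_binder(0.12), "strong")
  expect_equal(classify_binder(1.0), "weak")
  expect_equal(classify_binder(5.0), "non")
  expect_equal(classify_binder(c(0.5, 2.0)), c("strong", "weak"))  # boundary
  # threshold monotonicity: lowering strong_cut never increases strong count
  set.seed(2)
  ranks <- runif(500, 0, 5)
  n_strong <- vapply(c(1, 0.5, 0.25, 0.1),
                     function(s) sum(classify_binder(ranks, s) == "strong"), 0)
  expect_true(all(diff(n_strong) <= 0))
})

test_that("surrogate ranks are deterministic, uniform-ish, and golden-stable", {
  p <- c("KLDETFFYV", "SLYNTVATL", "AAAAAAAA")
  a <- c("HLA-A*02:01", "HLA-A*02:01", "HLA-B*07:02")
  expect_identical(surrogate_rank(p, a, 7L), surrogate_rank(p, a, 7L))
  expect_equal(surrogate_rank(p, a, 7L),
               c(44.5783255425, 56.4591714694, 57.7819746788), tolerance = 1e-9)
  expect_false(any(surrogate_rank(p, a, 7L) == surrogate_rank(p, a, 8L)))
  set.seed(1)
  r <- surrogate_rank(replicate(2000, random_peptide(9)), "HLA-A*02:01", 1L)
  expect_gt(ks.test(r / 100, "punif")$p.value, 0.01)
})

test_that("candidates keep their best rank across alleles; missing pairs reported", {
  cand <- data.frame(mutant_peptide = c("KLDETFFYV", "SLYNTVATL"),
                     stringsAsFactors = FALSE)
  tab <- data.frame(
    peptide = c("KLDETFFYV", "KLDETFFYV", "SLYNTVATL"),
    allele = c("HLA-A*02:01", "HLA-B*07:02", "HLA-A*02:01"),
    rank_percent = c(0.3, 4.0, 1.2), stringsAsFactors = FALSE)
  out <- assign_ranks(cand, c("HLA-A*02:01", "HLA-B*07:02"),
                      list(type = "table", records = tab))
  expect_equal(out$rank_percent[1], 0.3)
  expect_equal(out$allele[1], "HLA-A*02:01")
  unresolved <- attr(out, "unresolved")
  expect_equal(nrow(unresolved), 1)      # SLYNTVATL x B*07:02 absent
  expect_equal(unresolved$allele, "HLA-B*07:02")

  out2 <- assign_ranks(cand, c("HLA-A*02:01", "HLA-B*07:02"),
                       list(type = "surrogate", seed = 3))
  expect_identical(out2$rank_percent,
                   pmin(surrogate_rank(cand$mutant_peptide, "HLA-A*02:01", 3),
                        surrogate_rank(cand$mutant_peptide, "HLA-B*07:02", 3)))
})

test_that("neoantigen summaries count unique peptides per class and type", {
  expect_equal(summarize_neoantigens(
    data.frame(mutant_peptide = character(), rank_percent = numeric(),
               mutation_type = character()))$nal, 0)

  cand <- data.frame(
    mutant_peptide = c(paste0("PEP", 1:5), "WK1", "WK2", "IND1", "PEP1"),
    rank_percent = c(rep(0.2, 5), 1.5, 1.9, 0.1, 0.4),
    mutation_type = c(rep("SNV", 7), "indel", "SNV"),
    stringsAsFactors = FALSE)
  s <- summarize_neoantigens(cand)
  expect_equal(s$strong_snv, 5)   # PEP1 duplicated across alleles counts once
  expect_equal(s$weak_snv, 2)
  expect_equal(s$strong_indel, 1)
  expect_equal(s$nal, 5)
  expect_equal(summarize_neoantigens(cand, nal_definition = "strong_all")$nal, 6)
  # order invariance
  s2 <- summarize_neoantigens(cand[sample(nrow(cand)), ])
  expect_identical(unclass(s)[-1], unclass(s2)[-1])
})

test_that("amplitude is the wild-type/mutant affinity ratio", {
  expect_equal(amplitude_a(50, 50), 1)
  expect_equal(amplitude_a(5000, 50), 100)
  expect_equal(amplitude_a(50, 5000), 0.01)
  expect_error(amplitude_a(-1, 50), "positive")
})

test_that("similarity R matches a brute-force gapless alignment oracle", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  blosum <- e$BLOSUM62
  refs <- c("LMYDPTQRV", "KVFERATSL", "GQWNHTIDLK")

  # identical peptide with midpoint at its self-score -> logistic midpoint 0.5
  self_score <- brute_gapless_score("LMYDPTQRV", "LMYDPTQRV", blosum)
  r <- similarity_r("LMYDPTQRV", refs, midpoint_a = self_score)
  expect_equal(r$r, 0.5)
  expect_equal(r$best_score, self_score)

  set.seed(23)
  for (i in 1:25) {
    pep <- random_peptide(sample(8:10, 1))
    got <- similarity_r(pep, refs)
    s_star <- max(vapply(refs, function(b) brute_gapless_score(pep, b, blosum), 0))
    expect_equal(got$best_score, s_star)
    expect_equal(got$r, plogis(4.87 * (s_star - 26)), tolerance = 1e-9)
  }

  # logistic limits
  expect_lt(similarity_r("AAAAAAAA", refs, midpoint_a = 1e3)$r, 1e-6)
  expect_gt(similarity_r("LMYDPTQRV", refs, midpoint_a = -1e3)$r, 1 - 1e-6)
  expect_error(similarity_r("AAAA", character(0)), "empty")
})

test_that("gapless alignment agrees with Biostrings under prohibitive gap costs", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(31)
  for (i in 1:15) {
    a <- random_peptide(9); b <- random_peptide(sample(9:12, 1))
    got <- similarity_r(a, b)$best_score
    ora <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = e$BLOSUM62,
                                         gapOpening = 1e4, gapExtension = 1e4,
                                         scoreOnly = TRUE)
    expect_equal(got, max(0, ora))
  }
})

test_that("recognition potential is the A x R product", {
  expect_equal(recognition_potential(1, 0.5)$potential, 0.5)
  expect_equal(recognition_potential(0, 0.9)$potential, 0)
  expect_equal(recognition_potential(100, 0.25)$potential, 25)
  expect_error(recognition_potential(-1, 0.5))
  expect_error(recognition_potential(1, 1.5))
})

test_that("cohort neoantigen enumeration joins variants, effects, and HLA", {
  pep <- synthetic_peptidome(4, seed = 5, patient_id = "P1")
  v <- simulate_vafs(1, 1, 0.9, 100, 4, seed = 6, patient_id = "P1")
  pep$effects$chrom <- v$chrom; pep$effects$pos <- v$pos
  hla <- list(P1 = c("HLA-A*02:01", "HLA-B*07:02"))
  neo <- compute_neoantigens(v, pep$proteins, pep$effects, hla,
                             predictor = list(type = "surrogate", seed = 2))
  expect_equal(nrow(neo$candidates), 4 * 27)  # interior missense everywhere
  expect_equal(neo$summary$total_snv, length(unique(neo$candidates$mutant_peptide)))
  expect_equal(neo$summary$nal,
               sum(classify_binder(neo$candidates$rank_percent) == "strong"))
})
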