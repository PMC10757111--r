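---
title: "Quantifying intratumor heterogeneity and neoantigen escape in myeloma cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumor heterogeneity and neoantigen escape in myeloma cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithmm)
```

## The problem

Multiple myeloma cannot be profiled by multi-region sampling the way solid
tumors can, so its intratumor heterogeneity (ITH) has to be read off a single
sample. The quantity this package is built around is the **MATH score**
(mutant-allele tumor heterogeneity): the width of the somatic variant allele
fraction (VAF) distribution, expressed as a percentage of its center,

$$\mathrm{MATH} = 100 \cdot \frac{1.4826 \cdot \mathrm{MAD}(\mathrm{VAF})}{\mathrm{median}(\mathrm{VAF})}.$$

The 1.4826 factor makes the median absolute deviation estimate the standard
deviation under normality, so a tumor whose VAFs have a 10% coefficient of
variation scores MATH = 10. Subclonal structure widens the VAF spectrum and
drives the score up.

Around this center sit three further analyses:

* **Neoantigen enumeration.** Somatic mutations in protein-coding genes are
  translated to mutant peptides; every 8-, 9- and 10-residue window that
  covers the changed residues is a candidate epitope, scored against the
  patient's HLA class I alleles by percentile rank and classified as a strong
  (rank below 0.5) or weak (below 2) binder. The per-patient count of unique
  strong-binding, SNV-derived peptides is the neoantigen load (NAL).
* **The immune-escape index.** A patient's strong-binder *density* is
  NAL / (MAD/median) — strong binders per unit of VAF-dispersion. The escape
  index is the shortfall of that density against a cohort standard:
  `sNAL/(sMAD/sMedian) − NAL/(MAD/Median)`. High values mean the tumor has
  shed more strong binders per unit of heterogeneity than its peers: a
  signature of immunoediting rather than of a quiet genome.
* **Cohort statistics.** Rank correlations between MATH and NAL, median
  splits, the remission-rate 2×2 chi-square, Kaplan–Meier/log-rank contrasts
  and multivariate Cox models of progression-free survival (PFS).

## Key parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| `mad_constant` | 1.4826 | normal-consistency factor of the scaled MAD |
| `ith_cutoff` | 40 | MATH above which a tumor is called high-ITH (strict `>`; a score of exactly 40 is low). 40 is a cross-tumor median; it is configurable because it is cohort-dependent |
| `min_variants` | 5 | minimum VAFs per patient; below this the score is sampling noise |
| `min_depth`, `min_vaf` | 14, 0.05 | per-call filters before scoring, matching common somatic-caller practice |
| `strong_rank`, `weak_rank` | 0.5, 2.0 | percentile-rank binder thresholds; equality classifies into the stronger class |
| `peptide_lengths` | 8–10 | tiling window lengths |
| `nal_definition` | `strong_snv` | NAL counts unique strong SNV-derived peptides; `strong_all` adds indel-derived ones |
| `standard_method` | `cohort_median` | the escape standard; an absolute standard would need far larger cohorts, so only relative indices are interpreted |

Two conventions are deliberate and worth calling out. The chi-square on 2×2
remission tables is **uncorrected** Pearson: on tables of this size the Yates
correction changes the second decimal of p, and the uncorrected statistic is
the one that matches the hand formula $n(ad-bc)^2/(r_1 r_2 c_1 c_2)$. Median
splits send ties (and the median element) to the *low* group — the rule is
arbitrary but fixed and documented, so group sizes like 22/21 for 43 patients
are reproducible.

The neoantigen unit is the **unique mutant peptide per patient**, kept at its
best (lowest) rank across the patient's alleles: counting peptide×allele
pairs would double-count promiscuous binders and does not match per-patient
load reporting.

## The recognition-potential model

For candidates with both mutant and wild-type affinity predictions, the
package computes the recognition potential as the product $A \times R$:
$A = K_d^{wt} / K_d^{mut}$ (differential MHC binding; $A>1$ means the
mutation improved binding) and $R$, the probability of TCR recognition,
modeled as a logistic function of the best **gapless local alignment** score
of the peptide against a reference set of immunogenic epitopes
($R = \sigma(k(s^\ast - a))$ with $a = 26$, $k = 4.87$, the standard
calibration of this model family). The alignment is genuinely gapless — the
best contiguous diagonal run under BLOSUM62 — implemented directly (and
cross-checked in the tests against `Biostrings::pairwiseAlignment` under
prohibitive gap costs). Frameshift-novel peptides have no wild-type partner;
their amplitude defaults to a configured constant (1) and they are flagged by
a missing `wt_peptide`.

The built-in surrogate predictor replaces the external binding neural
network when none is available: it hashes (peptide, allele, seed) to a
percentile rank uniform on [0, 100). It has no immunological content — it
exists so that every counting, classification, deduplication and
threshold-monotonicity behavior of the pipeline can be exercised and tested
deterministically. Real analyses should feed netMHCpan-style tables through
`read_binding_table()`.

## What the synthetic cohort emulates

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, with known ground truth:

* **VAF spectra.** Each tumor has a clonal trunk (CCF 1) plus 2–5 subclones
  with CCFs in 0.05–0.5 and Dirichlet(2) mutation shares; expected VAF is
  `purity · CCF / 2` (diploid heterozygous, no copy number); reads are
  Poisson(120, floored at 10) deep with binomial alt counts. These defaults
  give cohort MATH medians in the 40s with ranges of roughly 10–110 and a
  majority of high-ITH patients — the regime of a high-burden, CD138-sorted
  myeloma cohort. Mutation counts per patient (20–120) bracket the median
  somatic-call count a myeloma exome typically yields (~40).
* **The MATH–NAL coupling** is imposed, not mechanistically simulated: the
  realized spectrum's MATH is converted to a normal score against the
  generator specification's reference distribution and a Gaussian copula with
  $\rho = \sin(\pi\tau/2)$ links it to the negative-binomial NAL
  (mean 42, size 1.8, a scale typical of strong-binder loads in exome cohorts, with a wide
  right tail). The population Kendall τ between true MATH and NAL therefore
  equals `target_tau` (default −0.25) up to NB discreteness.
* **The pipeline-recoverable load.** The number of protein-annotated coding
  variants is `round(NAL / (27 · p_strong))`, where 27 is the tiled-window
  count of an interior missense and `p_strong` the chance that a peptide's
  best surrogate rank over the patient's six alleles clears the strong
  threshold. The surrogate-scored pipeline then recovers the latent NAL in
  expectation, so the imposed τ survives end to end.
* **Outcomes.** PFS is exponential proportional-hazards with log-hazard
  `beta_math·(MATH − ref) + beta_nal·(NAL − 42)`; `beta_math = log(1.022)`
  per MATH unit (a per-unit effect at the scale such cohorts report) and
  `beta_nal = −0.015` per strong binder — chosen once so that a median NAL
  split carries a hazard ratio near 2, the effect size a 43-patient cohort
  could detect. Censoring is independent exponential at an expected 30%.
  CD8⁺ T-cell and NK percentages are affine in the NAL normal score
  (`immune_coupling`, default 0.35) plus noise; a ≥VGPR response indicator
  is logistic in NAL.

What the generator does **not** emulate: copy-number variation and
CCF-cancer-cell-fraction corrections, mechanistic immunoediting, expression
filtering of candidates, real binding chemistry (the surrogate is uniform),
shared/recurrent neoantigens, or informative censoring. Passing recovery
tests therefore show that the *statistical machinery* is correct and
well-calibrated under the assumed structure — not that the biological claims
hold in any particular patient cohort.

## Numerical choices and degenerate inputs

* `scaled_mad` and `math_score` are exact double-median computations; the
  tests hold them to bit-identity against an independent oracle.
* MATH needs a positive median VAF; zero-dispersion patients are legal for
  MATH (score 0) but have undefined neoantigen *density* — they are dropped
  from the escape index with a message.
* Patients below `min_variants` yield `NA` scores in cohort runs instead of
  aborting the cohort; the direct `math_score()` call raises a typed error
  carrying the observed count.
* The optional mixture VAF filter (off by default) fits 1-D Gaussian
  mixtures by BIC (up to 6 components) and drops components holding < 5% of
  variants; it never empties the input. It is an opt-in approximation of the
  clustering some MATH implementations apply; the plain formula is the
  reproducible baseline.
* Cox fits use the Efron tie approximation (the modern default; tie handling
  only moves third decimals at these cohort sizes). Non-convergence and
  separation set a flag rather than erroring.
* Variant readers are lossless (silent/splice calls are kept and filtered
  downstream), skip-and-count rows with zero depth or unparseable alleles,
  and prefer an explicit VAF column over counts (warning past 1e-6
  disagreement) to tolerate upstream rounding. Equal-length multi-nucleotide
  substitutions fall outside the SNV/INS/DEL typing and are counted as
  skipped.

## Problem sizes used by the checks

The package's own validation uses: 500 random VAF sets for the MAD oracle;
n = 2000 gaussian VAF sets over 20 replicates for the normal limit
(MATH = 10 ± 1); 200 random proteins for the tiling oracle; a 200-patient
synthetic cohort for τ recovery (tolerance ±0.08 — the Kendall sampling
s.d. at n = 200 is ≈ 0.04); 50 simulated cohorts of n = 500 for Cox
recovery of a true hazard ratio of 2; and 20 cohorts of n = 120 for the
escape-index log-rank power check (≥ 80% at α = 0.05). These sizes were
chosen so each check has comfortable statistical resolution at interactive
runtimes.

## Worked example

```{r example, eval = FALSE}
co  <- simulate_cohort(cohort_spec(n_patients = 49, seed = 1))
res <- run_pipeline(co)
res
res$stats$kendall_math_nal     # MATH-NAL rank correlation
res$stats$cox_pfs              # multivariate Cox of PFS
```

## Known limitations

MATH conflates subclonal structure with purity and copy-number effects; no
CCF correction is attempted. The escape index inherits the cohort-median
standard, so it is only interpretable *within* a cohort. Indel-derived
neoantigens are counted but the default NAL excludes them. The similarity
reference set shipped with the package is a synthetic stand-in; real use
requires a curated immunogenic-epitope set.
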