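# ithmm — intratumor heterogeneity and neoantigen escape analysis for myeloma cohorts

`ithmm` is an R package for cancer-genomics groups analyzing single-sample
tumor cohorts — multiple myeloma in particular, where multi-region sampling
is impossible and heterogeneity must be read off one variant allele fraction
(VAF) spectrum. It implements, end to end and with tested parameter-recovery
guarantees:

1. **MATH scoring** of intratumor heterogeneity (ITH):
   `MATH = 100 · 1.4826 · MAD(VAF) / median(VAF)`, with configurable call
   filters, an optional mixture outlier filter, high-ITH classification
   (strict `MATH > 40` by default) and tumor mutation burden.
2. **Neoantigen enumeration**: mutant proteins from annotated somatic
   effects, tiling of all mutation-spanning 8/9/10-mers, percentile-rank
   binder classification (strong ≤ 0.5, weak ≤ 2) against the patient's HLA
   class I alleles via netMHCpan-style tables or a deterministic surrogate
   scorer, the A×R recognition potential (affinity amplitude × gapless
   BLOSUM62 similarity to reference epitopes), and the per-patient
   strong-binding neoantigen load (NAL).
3. **The immune-escape index**:
   `sNAL/(sMAD/sMedian) − NAL/(MAD/Median)` — the shortfall of a patient's
   strong-binder density per unit of VAF-dispersion against a cohort
   standard (cohort medians by default).
4. **Cohort statistics**: Kendall/Spearman rank correlations, Wilcoxon
   rank-sum, uncorrected 2×2 chi-square with group response rates,
   Kaplan–Meier/log-rank, and multivariate Cox proportional hazards (Efron
   ties) for progression-free survival.
5. **A synthetic cohort generator** with known ground truth — subclonal VAF
   spectra by binomial read sampling, a Gaussian-copula MATH↔NAL coupling at
   a target Kendall τ, immune-cell fractions coupled to NAL, and
   proportional-hazards outcomes — so every stage can be validated without
   patient data.

## Worked example

```r
library(ithmm)

co  <- simulate_cohort(cohort_spec(n_patients = 49, seed = 1))
res <- run_pipeline(co)
res
#> ithmm pipeline result
#>   MATH: 49 patients scored, 36 high-ITH (cutoff 40)
#>   NAL: median 31 strong binders
#>   escape:  24 high / 25 low
#>   kendall_math_nal: p = 0.0168
#>   spearman_math_nal: p = 0.0215
#>   logrank_escape: p = 0.00224
#>   chisq_response: p = 0.0133

res$stats$kendall_math_nal
#> Kendall tau-b: statistic = -2.39, p = 0.0168, effect = -0.238, n = 49

head(res$math, 3)
#>   patient_id n_variants_used median_vaf scaled_mad     math ith_class
#> 1     SYN001              98  0.2038938 0.10103087 49.55074      high
#> 2     SYN002               9  0.1307692 0.10048634 76.84249      high
#> 3     SYN003              82  0.1138439 0.05006813 43.97964      high
```

Reading this: of 49 simulated newly diagnosed patients, 36 are high-ITH;
MATH and the surrogate-scored strong-binder count are negatively rank
correlated (τb = −0.238, the generator's imposed coupling); the high
escape-index half of the cohort progresses earlier (log-rank p = 0.002),
and the low-loss group has the higher ≥VGPR response rate (χ² p = 0.013) —
the qualitative structure the analysis is designed to detect.

Real data enter through `read_variant_table()` (simple TSV, MAF, or VCF with
tumor AD/DP), `read_clinical_table()`, `read_hla_table()` and
`read_binding_table()` (netMHCpan output), assembled with
`assemble_cohort()`. A thin command-line front end with subcommands
`math | neo | escape | stats | simulate | run` is in `inst/cli/ith.R`.

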