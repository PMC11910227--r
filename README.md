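# epireprog

Correlative multi-omic biomarker analysis for paired baseline /
on-treatment tumor biopsies under low-dose hypomethylating therapy
(5-azacytidine with immune checkpoint blockade), built for the small
paired-biopsy cohorts typical of Phase 1 trials. It is aimed at
computational biologists reproducing or extending trial-style
epigenetic-reprogramming analyses: EPIC-style methylome matrices and
RNA-seq count matrices go in, molecular endpoints come out.

## What it computes

* **Paired differential methylation.** Probe QC (detection p > 0.01 or
  bead count < 3 in over 5% of samples; SNP-overlapping, multi-mapping and
  X/Y probes removed), β → M conversion (`M = log2(β/(1−β))`), an
  empirical-Bayes moderated paired t-test on M values with
  Benjamini–Hochberg control, a sign-flip bump-hunting region finder with
  an exactly enumerated permutation null for ≤ 10 pairs, per-gene promoter
  Δβ, and Stouffer-combined gene-level statistics
  `Z_gene = Σ z_i / √n` over the promoter CpGs of each gene.
* **Expression scoring.** RPKM (`count · 10⁹ / (length · library)`),
  geometric-mean signature scores (the 6-gene IFN-γ signature
  IDO1/CXCL10/CXCL9/HLA-DRA/STAT1/IFNG, a 44-gene STING signature, M1/M2
  macrophage polarization ratios), and per-participant paired fold
  changes.
* **Methylome deconvolution.** Ten cell-type fractions per sample by
  constrained least squares on a signature-CpG reference
  (`min ‖Rf − b‖₂` s.t. `f ≥ 0, Σf = 1`), with a ν-SVR alternative.
* **Directional gene-set enrichment.** Logistic regression of set
  membership on the signed significance score `direction · (−ln p)`, for
  both expression and methylation statistics; joint
  "hypomethylated-and-upregulated" set calls.
* **Molecular endpoints.** Molecular responders (> 2-fold increase in
  both the IFN-γ signature score and CD274/PD-L1 expression), the
  biologically effective dose rule (≥ 10% marker decrease in ≥ 50% of
  participants at a dose level), tumor-suppressor-gene reversal (> 25%
  promoter demethylation with > 2-fold re-expression of
  tumor-hypermethylated TSGs), neutrophil-to-lymphocyte ratios, H-scores
  (`1·%₁ + 2·%₂ + 3·%₃`, range 0–300), exact Wilcoxon rank-sum tests and
  Kaplan–Meier summaries.
* **A synthetic cohort generator.** `simulate_cohort()` produces a fully
  specified paired cohort (methylome + QC, counts, reference and true
  fractions, gene sets, clinical, IHC) with planted responder effects, so
  every stage is testable without access to patient-level data.

## Worked example

```r
library(epireprog)

cohort <- simulate_cohort(sim_config(seed = 1))
report <- run_pipeline(cohort)
report
#> Pipeline report; stages run: methylation, expression, deconvolution, enrichment, endpoints
#> Molecular responders: P2, P5, P8
#> BED met at dose level(s): 5day

report$endpoints$responders
#> # A tibble: 8 x 5
#>   participant_id ifng_fc cd274_fc sting_fc responder
#> 1 P1               0.998    0.952    1.00  FALSE
#> 2 P2               2.82     2.81     1.76  TRUE
#> 3 P3               0.951    0.994    0.991 FALSE
#> ...
#> 8 P8               2.88     2.64     1.74  TRUE

report$endpoints$responder_vs_rest_p
#> [1] 0.03571429
```

The three planted responders (P2, P5, P8) show ~2.6–2.9-fold increases in
the IFN-γ signature and CD274 while the other five participants sit near
fold change 1, so the responder rule (> 2-fold on both, strict) recovers
exactly the planted truth; with the responders ranking strictly highest,
the exact 3-vs-5 rank-sum comparison attains its minimal two-sided value
2/56 ≈ 0.036. The report also carries the per-dose BED table (met at the
5-day level: 3 of 5 participants with ≥ 10% promoter-methylation
decrease), per-participant TSG reversal counts (20 of 20 planted reversals
found in each responder), cell-fraction changes (planted −35% Treg shift),
the recovered demethylated regions (exact permutation p = 2/256 each) and
the jointly hypomethylated-and-upregulated gene set.

Individual stages are ordinary data-frame-in / tibble-out functions that
compose with the pipe — e.g.
`rpkm(counts, lengths) |> signature_score(genes)`, `deconvolve(beta, ref)`
(with `tidy()`, `glance()` and `autoplot()` methods on the results).

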