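---
title: "Methods: paired methylome/transcriptome biomarkers of epigenetic immune reprogramming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired methylome/transcriptome biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epireprog)
```

## Scope and model of the data

epireprog analyzes *paired* tumor biopsies — one baseline and one
on-treatment sample per participant — profiled on a genome-scale CpG
methylation array (beta values, the methylated fraction of signal at each
CpG, in [0, 1]) and by RNA-seq (gene-level counts). The package starts
from normalized matrices: array preprocessing, normalization and batch
correction, read alignment and counting are upstream of its interface and
are assumed done. All user-facing functions take a data frame first and
return tibbles, so stages compose with the pipe.

The scientific question the pipeline serves is whether low-dose
demethylating therapy reprograms the tumor microenvironment: does the
IFN-γ signature rise, does PD-L1 (CD274) re-express, do regulatory T cells
recede and CD8 T cells infiltrate, are silenced tumor-suppressor genes
(TSGs) demethylated and re-expressed — and at which dose level do enough
participants show a molecular change for that dose to count as
biologically effective.

## Differential methylation

Beta values are heteroscedastic near their boundaries, so all testing is
done on M values, `M = log2(β/(1−β))`, with betas clipped to
`[ε, 1−ε]` (ε = 1e−6) to keep the logit finite; the reported effect size
stays on the interpretable β scale. `paired_dmp()` forms within-pair
M-value differences and, by default, moderates the per-probe variance with
empirical Bayes shrinkage (limma) — with 8 pairs the moderated test holds
its nominal size while gaining power; `moderated = FALSE` gives the
ordinary paired t-test, which the test suite checks against the direct
formula. Probes whose within-pair differences are constant carry no
information about variance and are flagged with p = 1 rather than being
allowed an arbitrarily confident call. BH adjustment runs across all
tested probes.

`find_dmrs()` is a deliberately simplified bump hunter: probes are
clustered at a maximum gap of 500 bp, candidate regions are maximal
same-sign runs of at least 3 probes with |mean Δβ| ≥ 0.1, the region
statistic is the area Σ|Δβ|, and the null is built by flipping the sign of
each participant's difference vector — the exact paired permutation group.
With ≤ 10 pairs all 2^n assignments are enumerated, so p-values live on a
1/2^n grid and the smallest attainable value is 1/2^n (1/256 at n = 8); no
loess smoothing is applied. Coordinates are 1-based closed (the array
manifest convention; strand is ignored since CpG methylation is
strand-symmetric on these arrays); the BED writer converts to 0-based
half-open at the boundary.

Gene-level methylation statistics use the Stouffer construction: for each
participant the promoter-CpG (TSS200/5′UTR) β differences are standardized
to Z-scores — the reference population is all promoter CpGs of that
participant's comparison, a choice the interface exposes by splitting the
computation into `promoter_probe_z()` and `gene_level_z()` — and each
gene's statistic is `Z = Σ z_i / √n` with a two-sided normal p. Under
independent standard-normal probe scores this is exactly standard normal,
which the suite verifies empirically at 10,000 genes.

## Expression scoring

RPKM is computed from its definition (`count · 10⁹ / (length_bp ·
library_size)`) and cross-checked in the tests against the edgeR
implementation. Signature scores are geometric means of `RPKM + offset`
over the signature genes; the offset (default 0.1 RPKM) keeps the log
defined at zero counts while barely perturbing expressed genes, and at
offset 0 the score is exactly multiplicative-scale equivariant. Paired
fold changes are linear-scale ratios, `(on + offset)/(base + offset)` per
gene and ratios of signature scores at signature level. For enrichment,
cohort-level per-gene statistics come from a paired t-test on log2 RPKM
fold changes — a lighter model than a count-based quasi-likelihood fit,
chosen so the enrichment input derives from the same paired fold changes
the endpoints use; it is a documented deviation and the statistics table
is a plain input, so any ranking can be substituted.

## Deconvolution

`deconvolve()` estimates the fractions of 10 cell types (fibroblasts,
neutrophils, CD4 T, CD8 T, Treg, CD14 monocyte/macrophage, CD19 B, CD56
NK, eosinophils, cancer) from bulk betas at signature CpGs. The default
solver minimizes `‖Rf − b‖₂` subject to `f ≥ 0` and `Σf = 1` as a
quadratic program — the simplex constraint is imposed exactly rather than
by post-hoc renormalization, so noiseless mixtures invert to machine
precision and the optimum is deterministic and testable. A linear ν-SVR
route (ν ∈ {0.25, 0.5, 0.75}, lowest-RMSE fit kept, negative coefficients
clipped and renormalized) is provided for fidelity to the
CIBERSORT-family tradition; the result records which solver produced it.
The reference is an input; `intersect_reference()` restricts it to
measured probes and refuses to proceed with fewer than 10 probes per cell
type. No cross-platform harmonization is attempted — reference and data
must share the β scale.

## Enrichment

`directional_enrichment()` regresses set membership on the signed score
`s_g = direction_g · (−ln p_g)` and tests the slope (Wald, by default).
The natural log is a convention choice: the base rescales the slope but
not its test. Set-size bounds of 10–500 after intersection stabilize the
fits. One caveat the package documents rather than hides: with a small,
uniformly extreme set against a clean null background the logistic fit can
reach quasi-complete separation, where Wald p-values degenerate
(Hauck–Donner); a likelihood-ratio option (`test = "lrt"`) is available
for such collections. Because the test is background-based, results
depend on the gene universe supplied — enrichment is invariant to gene
relabeling but not to padding the universe with extra genes.

## Molecular endpoints

Every endpoint rule is implemented as the literal predicate, with strict
or inclusive comparisons chosen to match the stated definitions:
responders need *strictly* more than 2-fold increases in both the IFN-γ
signature and CD274 (a conjunction; configurable to a disjunction);
the biologically-effective-dose rule is inclusive on both thresholds
("at least" 10% decrease in "at least" 50% of participants, so a dose
level with exactly half its participants qualifying is met); TSG reversal
requires promoter Δβ strictly below −0.25 and expression fold change
strictly above 2, restricted to TSGs with at least one
tumor-hypermethylated promoter probe (Δβ ≥ +0.10 at FDR < 0.05 in a
tumor-versus-normal compendium). Which molecular marker feeds the BED rule
is not uniquely determined by the endpoint's definition; the pipeline
defaults to the per-participant relative decrease in mean promoter
methylation and records the choice in its parameters.

The exact Wilcoxon rank-sum test enumerates rank assignments (midranks for
ties) whenever `choose(n, n_a)` is tractable and otherwise falls back to
the exact Mann–Whitney distribution (tie-free, combined n ≤ 30) or a
tie-corrected normal approximation, always flagging which route produced
the p-value. The permutation distribution of the rank sum is symmetric, so
the two-sided p is the probability of a rank sum at least as far from its
null mean as observed; with groups of 3 and 5 and complete separation this
floor is 2/56 ≈ 0.036. Kaplan–Meier summaries use the product-limit
estimator with Greenwood variance and log-log confidence limits; the
median is the first time survival reaches 0.5 or below and is reported as
missing when the curve never gets there.

## The synthetic cohort

`simulate_cohort()` emulates the study conditions end to end: 8
participants, paired biopsies, five at a 5-day and three at a 10-day dose
level, and 3 planted molecular responders. Defaults mirror the magnitudes
the analysis is meant to detect: responder on-treatment effects of 3.0× on
the IFN-γ genes, 2.8× on CD274 and 1.8× on the STING set; −0.30 promoter
Δβ with 3× re-expression on 20 reversed TSGs (the planted shift sits past
the strict −0.25 rule so the planted reversals are actually detectable);
−35% Treg and +50% CD8 fraction shifts with a −10% cancer-fraction change;
treatment-wide 5-probe demethylated regions at Δβ −0.30; a 15% relative
promoter-methylation decrease in 3 of 5 five-day and 1 of 3 ten-day
participants (so the 5-day level, and only it, meets the BED rule); and a
small global drift giving 6 of 8 participants a net methylation decrease.

Methylation noise is beta-distributed, parameterized by mean and
concentration (default 50, i.e. per-probe SD ≈ 0.07 at β = 0.5) because
mean-level effects are what the design manipulates. Counts follow a
hierarchical model: gene base weights are log-normal, each
participant-gene pair carries a shared gamma biological effect sized so
the *marginal* dispersion across participants is the negative-binomial
0.1, and the two samples of a pair draw Poisson counts around that shared
effect — the standard view of a paired RNA-seq design in which participant
is a covariate. Within-pair fold changes are therefore limited by counting
noise, as they are in a real paired analysis. Deconvolution truth comes
from an explicit forward model (`mix_methylomes()`): signature-probe betas
are fraction-weighted averages of a near-binary, full-rank 10-column
reference (1,197 CpGs, of which 933 are measured in the cohort), so
noiseless mixtures invert uniquely. Survival times are exponential with a
0.4 rate ratio for responders — enough to produce the qualitative
responder–survival association without claiming any particular survival
figure. Clinical blood counts drift so the cohort neutrophil-to-lymphocyte
ratio falls on treatment.

What the generator does *not* emulate: array preprocessing artifacts and
batch structure, probe cross-reactivity, tumor purity confounding of the
non-signature probes, HPV status, mutations, raw IDAT/FASTQ data, and any
correlation structure between genes beyond the planted sets. Passing
tests therefore demonstrate that the statistics and rules behave as
specified under a faithful generative model of the design — not that the
pipeline is robust to every artifact of real array and sequencing data.

Problem sizes used throughout the suite are the generator defaults
(20,000 probes, 5,000 genes, 8 pairs) for single runs, with a scaled-down
configuration (2,200 probes, 600 genes) for loops over many seeds; both
are choices of the package's own test design and can be raised freely in
the configuration.

## Numerical and degenerate-input choices

* M-value clipping ε = 1e−6; β↔M round-trips to < 1e−12 inside the clip
  range.
* Zero within-pair variance probes: flagged, p = 1.
* Zero lymphocyte counts: ratio reported missing, with a warning, rather
  than infinite.
* Zero baseline cell fraction: relative change missing, absolute change
  kept.
* Beta-noise means are clipped to [0.001, 0.999] before drawing so both
  beta shape parameters stay positive; draws are clipped to
  [1e−6, 1 − 1e−6].
* Ties in BH use the standard step-up procedure; ties in rank tests use
  midranks.
* The constrained least-squares Gram matrix receives a 1e−10 ridge only if
  numerically singular (rcond < 1e−12); in practice the full-rank
  reference never triggers it.

## Known limitations

The region finder omits smoothing, so very long, weak regions are less
detectable than in a full bump-hunting implementation with loess
pre-smoothing. The enrichment model inherits the logistic regression's
sensitivity to separation (see above). The deconvolution reference is
taken as given — no feature selection from purified profiles is performed
— and accuracy degrades if data and reference are on different scales.
Survival summaries are univariate (no proportional-hazards modeling), and
the molecular endpoints are deterministic rules, not estimators with
uncertainty.
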