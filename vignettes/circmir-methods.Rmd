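---
title: "Models and methods behind circmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`circmir` implements a serum small-RNA biomarker workflow for
neoadjuvant-chemotherapy (NCT) breast-cancer cohorts: read annotation and
counting, filtering and quantile normalization, negative-binomial
differential-abundance testing, and a cross-validated two-gene logistic
relapse signature. This vignette explains the models, the tunable
parameters with their defaults, the numerical conventions, and what the
synthetic-data generator does and does not emulate. It states no empirical
result beyond what the package's tests and acceptance script themselves
compute.

## The generative model of the synthetic cohort

Real serum sequencing data for this design (42 pre-treatment sera, 7–12
million aligned reads each) are not shipped with the package; a seeded
generator (`make_reference()`, `simulate_reads()`, `simulate_cohort()`,
`simulate_pcr()`) stands in for them so every downstream stage can be
exercised against known truth.

**Reference and reads.** `make_reference()` draws random sequences per
small-RNA class (mature miRNAs 18–25 nt; compact desk-scale surrogates for
tRNA/rRNA/scRNA/snRNA/snoRNA), regenerating on collision so all sequences
are pairwise distinct, and always includes `hsa-miR-375`, `hsa-miR-122`
and `hsa-miR-16`. `simulate_reads()` draws each read's class from a
mixture whose default reflects serum composition — 50% miRNA, 28% tRNA,
8.8% scRNA, 4.4% rRNA, 0.6% snRNA, 0.4% snoRNA, with the 7.8% remainder
labelled "other" — and emits an exact contiguous substring of a uniformly
chosen entry with length in 15–52 nt. Reads carry no sequencing errors or
adapters by design: the annotation stage is specified as exact matching,
and error-tolerant alignment is out of scope.

**Counts.** For gene $i$ in sample $j$ the count is drawn
$y_{ij} \sim \mathrm{NB}(\mu_{ij},\ \phi)$ with variance
$\mu + \phi\mu^2$ and

$$\mu_{ij} = L_j \, a_i \, 2^{\sum_k \beta_k x_{kj}},$$

where $L_j$ is a log-normal library size (default mean $5\times10^5$,
$\sigma = 0.3$ on the log scale, forcing non-trivial depth normalization),
$a_i$ a log-normal baseline relative abundance ($\sigma = 1.5$, so a few
genes dominate as in real circulating profiles), and the planted effects
$\beta_k$ multiply the mean by $2^{\beta}$ in samples where clinical
covariate $x_k$ is positive. Defaults plant the two relapse markers at the
reported magnitudes: miR-375 at $-1.90$ and miR-122 at $+1.35$ log2 units
on relapse. miR-122, miR-16 and miR-375 are pinned to high baseline
abundance quantiles (0.95/0.85/0.80) mirroring their high circulating
levels, and miR-16 — the qPCR reference gene — may never carry an effect.
The common dispersion defaults to $\phi = 0.1$, a moderate
between-patient biological variability typical of bulk count data; the
per-gene count distribution of the real sera is not published, so the
log-normal baseline and this $\phi$ are modelling choices, fixed once.

**Metadata.** Cohort structure follows the study design: 11/42 relapses,
23/42 HER2+ patients all on the trastuzumab-containing regimen C, the
HER2− patients split 7:12 over regimens A and B, pCR in 12/23 HER2+ and
2/19 HER2− patients, 21/42 ER+, PR+ drawn within ER+ (14/42), 10/42
inflammatory cases. Counts scale proportionally for other cohort sizes.

**qPCR.** `simulate_pcr()` generates threshold cycles
$Ct = a - b\,\log_2(\text{normalized count}) + \varepsilon$ with $b>0$
(defaults $a = 36$, $b = 1$, $\varepsilon \sim N(0, 0.5^2)$), so $-Ct$
correlates with sequencing abundance as observed when both assays are run
on the same extracts.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: sequencing error and adapter content,
isomiR length/end heterogeneity, multi-mapping against a full genome,
correlated gene-gene structure beyond the planted effects, batch and
extraction effects, and hemolysis-driven artefacts in serum miRNA levels.

## Annotation

A read is assigned when its U→T-normalized sequence is an exact substring
of at least one reference entry. Reads outside 15–52 nt are
`size_excluded`; reads with characters outside A/C/G/T/U/N, or matching
nothing, are `unassigned` (never an error). When a read matches entries of
several classes, the class is chosen by the fixed priority
miRNA > tRNA > rRNA > scRNA > snRNA > snoRNA > other, and within the
winning class the lexicographically smallest id wins with an `ambiguous`
flag — multi-mapping policy is not documented for such studies, and a
deterministic rule is required for testability. Each ambiguous read
contributes a single count to exactly one entry, keeping the count matrix
integral for the exact test. Composition fractions are computed over
assigned reads only.

## Filtering, normalization, clustering

The stage order is: detectability filter (count ≥ 1 in ≥ 2 samples) →
abundance filter (count **strictly** > 50 in ≥ ⌈10% of samples⌉) →
quantile normalization → $\log_2(x+1)$. The order mirrors how such
analyses describe detection first, then the analysis set, then normalized
values; it is fixed here because results depend on it.

Quantile normalization maps each column rank-wise onto the across-column
mean of order statistics; within-column ties receive the **mean of their
tied reference quantiles**. Count data are tie-heavy and the tie rule must
be exact for reproducibility; note that with ties the column multisets are
identical only up to tie-averaging, and the transform is idempotent
exactly on tie-free data. The log offset of 1 maps zero counts to zero and
is strictly monotone.

Sample clustering uses distance $1 - r$ (Pearson, between sample columns)
with average linkage; the display of such heatmaps rarely states either
choice, so both are package decisions. Columns are sorted by sample id
before clustering so equal-distance merges resolve deterministically, and
a zero-variance column (undefined correlation) is placed at maximal
distance 2 with a warning rather than failing.

## Differential abundance

**Model.** Counts for one gene follow an NB law with common dispersion
$\phi$ shared across genes (variance $\mu + \phi\mu^2$). No tagwise or
trended shrinkage is attempted: the single-$\phi$ model matches the
generator exactly, making parameter recovery well-posed, and is the
simplest faithful NB exact-test implementation.

**Dispersion.** `estimate_common_dispersion()` maximizes the summed
conditional NB log-likelihood over genes given each group's total, after
scaling all samples to the common geometric-mean library size. The
estimate is clamped to $[10^{-6}, 10]$; identical replicate columns hit
the lower clamp.

**Exact test.** For the two-group comparison the counts are first
equalized to geometric-mean depth with half-up rounding (the exact test
needs integer pseudo-counts and the rounding rule must be fixed). Writing
$s_1, s_2$ for the group sums of $n_1, n_2$ samples, the conditional law
of $s_1$ given $T = s_1 + s_2$ under equal means is
Beta-Binomial$(T,\ n_1/\phi,\ n_2/\phi)$. Two-sidedness doubles the
smaller tail (observation included), capped at 1. Totals up to $10^5$ are
enumerated exactly; above that the large-count limit of the beta-binomial
proportion is used, $s_1/T \to \mathrm{Beta}(n_1/\phi, n_2/\phi)$, with a
symmetric continuity convention — the upper tail is computed as the lower
tail of the group-swapped problem — so relabelling the groups preserves
the p-value exactly in both paths. As $\phi \to 0$ the test reduces to the
conditional binomial split of the total.

**Adjusted comparison.** With an adjustment covariate (the three-arm NCT
regimen, as an unordered factor), each gene is fitted by a log-linear NB
GLM at fixed $\phi$ (iteratively reweighted least squares via
`stats::glm` with the `MASS` negative-binomial family), log library sizes
as offsets, and the two-level group term is tested by a 1-df chi-squared
likelihood-ratio test against the adjustment-only null. Perfect
confounding of group with the adjustment (rank-deficient design) and
non-convergence are flagged with `p = NaN`, never an error.

**Reporting.** Group means and log2 folds are computed on
quantile-normalized (pre-log) counts; a zero mean yields a signed
infinity with a flag rather than a pseudo-count fold. FDR is
Benjamini–Hochberg (via `p.adjust`; the test suite checks it against the
definitional step-up). Published tables of this kind can print fold
differences that are *not* the log2 ratio of the printed group means
(covariate-adjusted estimates); `circmir` reports the arithmetic
group-mean fold and leaves adjusted estimation to the GLM path.

## The two-gene signature

"Univariate logistic regression using the two-gene signature" is read as
one logistic model with the two miRNA levels as two covariates; the
single-gene classifiers use one covariate each, so both readings of the
phrase are covered. Features are the normalized log2 counts (sequencing
input) or miR-16-normalized log2 qPCR levels (`pcr_features()`).

The fit is maximum likelihood by IRLS (score tolerance $10^{-8}$, 50
iterations) on internally z-scored features — which makes every
prediction invariant to positive affine rescaling of a feature — with
coefficients reported back on the input scale. Under complete separation
the likelihood has no maximum; a tiny L2 ridge ($10^{-4}$ on the
standardized scale) caps the coefficients and the fit is flagged
`converged = FALSE`. Zero-variance features get coefficient 0, leaving
the intercept at the logit of prevalence.

The probability cutoff minimizes the training misclassification count
over the midpoints between consecutive distinct predicted probabilities
plus one boundary candidate on each side; ties prefer the largest margin
to the nearest probability, then the smallest cutoff. A sample is called
"relapsed" when its probability is **strictly greater** than the cutoff.
LOOCV refits both the model and the cutoff on every fold of $n-1$
samples, so no fold ever sees the held-out label; a fold whose training
labels degenerate to one class predicts the training majority and is
flagged. External validation (`train_full_predict_external()`) fits once
on the full training cohort and applies model and cutoff unchanged.

## Performance statistics

Sensitivity and specificity are exact ratios, also reported as half-up
integer percentages to match the usual display. The odds ratio of a
binary predictor is the cross-product $(tp\cdot tn)/(fn\cdot fp)$ —
identical to the exponentiated slope of an unconditional logistic
regression, which the tests verify by exhaustive enumeration of small
tables — with a Woolf 95% CI ($\log \mathrm{OR} \pm 1.96\sqrt{\sum
1/\text{cell}}$) and Wald p-value; a zero cell triggers the
Haldane–Anscombe +0.5 correction with a flag. ΔCt relative levels are
$2^{Ct_{ref} - Ct_{gene}}$ against miR-16. Group comparisons of PCR
levels use Welch's unequal-variance t-test on the log2 scale (the display
scale of such figures is rarely stated; both choices are defensible and
Welch is the safer default). Sequencing–PCR agreement is Pearson's $r$
with the $t$-transform p-value on $n-2$ df.

## Problem sizes and numerical settings in the test suite

The suite runs at desk scale, chosen so that every stochastic claim is a
property of many seeds rather than one: 100-seed null calibrations for
the NB exact test and Welch t-test, 50-seed recovery runs for the planted
markers (42-sample cohorts) and for the two-gene-vs-miR-122 Youden
comparison (32-sample cohorts), a 100,000-read composition check, and
exhaustive small-total enumeration oracles for the exact test
(totals ≤ 30), the BH step-up, the logistic likelihood grid, and the
OR–logistic equivalence (all 2×2 tables with small cells). Exact-path
enumeration in the NB test covers totals to $10^5$; the acceptance script
reports the simulated serum composition at 100,000 reads.

## Known limitations

* Exact-match annotation cannot tolerate sequencing errors, isomiRs or
  novel miRNAs; it presumes a curated reference.
* The common-dispersion NB model ignores gene-specific dispersion; genes
  far from the common $\phi$ will be mis-calibrated.
* Quantile normalization assumes comparable global distributions across
  samples; a genuinely global shift in circulating RNA content would be
  normalized away.
* The cutoff rule optimizes raw training error, which is optimistic in
  small cohorts; LOOCV mitigates but does not remove this.
* Sensitivity/specificity of the signature on real sera cannot be
  reproduced here because the original cohort data are not public; the
  package demonstrates recovery of *planted* effects instead.
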