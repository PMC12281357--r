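---
title: "Multilayered methylation analysis of a tail-dichotomized trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayered methylation analysis of a tail-dichotomized trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Psychological resilience, measured by the 25-item Connor-Davidson Resilience
Scale (CD-RISC; items scored 0-4, total 0-100, up to 6 missing items
mean-imputed), is a weak, continuous trait. When a cohort is dichotomized
into its high- and low-scoring tails and whole-blood EPIC-array methylation
is compared between the groups, per-CpG signals are small: raw p values
below .05 abound, nothing survives genome-wide correction, and the biology
is easily drowned by confounders (age, menstrual status, cancer detection
mode, ER status, batch, leukocyte composition).

`epires` implements a multilayered strategy for exactly this regime:

1. **Percentile-subset stratification.** The tail groups are progressively
   thinned toward their extremes (retained fractions 100%, 90%, ..., 10%,
   5% per group). A probe genuinely coupled to the trait should be called
   more often, and with a growing effect size, as the compared groups move
   apart - a *dose-response* signature that pure false positives lack.
2. **Region-level evidence.** Bump hunting aggregates per-CpG coefficients
   over genomic clusters into candidate differentially methylated regions
   (DMRs) scored by the *area statistic* (absolute sum of member
   coefficients), with presence and area growth tracked across the subsets.
3. **Predictive confirmation.** A matched-triplet resampling random-forest
   classifier checks that the prioritized CpGs actually discriminate the
   groups in held-out samples, and an independent cohort validates the
   final model.

All modeling is on the M scale, `M = log2(beta/(1-beta))`, with beta values
clipped into `[1e-3, 1 - 1e-3]` before the logit (EPIC betas rarely touch
the boundaries after normalization; the clip is configurable). The sign
convention everywhere: a positive group coefficient ("log2FC") means
hypermethylated in the **low**-resilience group.

## The per-CpG model

For every probe, M values are regressed on the group indicator plus
covariates (defaults: age, menstrual status, detection mode, ER status).
Residual variances are shrunk toward a common prior by empirical Bayes:
with residual df $d$, the per-probe variances $s_g^2$ are modeled as scaled
inverse-chi-squared around a prior $(d_0, s_0^2)$ estimated by method of
moments on $\log s_g^2$ (using digamma/trigamma moments of the
log-chi-squared distribution; the trigamma inverse is solved by Newton
iteration). The moderated variance is the convex combination
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and the moderated t has
$d + d_0$ df. The test suite verifies this agrees with `limma::eBayes` to
numerical precision on simulated data, and that $d_0 \to \infty$ collapses
to the common-variance statistic.

A probe is a DMP iff raw $p < .05$ **and** $|\mathrm{log2FC}| > 0.5$
(roughly a 10-15% beta difference at intermediate methylation). BH
q values are reported everywhere but deliberately do not gate the call -
the consistency layers, not a multiplicity correction, control false
positives in this design. Covariates constant within a (small) subset are
dropped with a warning rather than failing the fit.

Per-probe consistency across the ordered subset sequence records the hit
count, the longest consecutive run, and a dose-response statistic: the
Spearman correlation between per-subset log2FC and the per-subset gap in
group mean CD-RISC scores. Spearman, not Pearson, because the claim being
scored is monotone growth, not linearity. The statistic is signed: hyper
probes trend to +1, hypo probes to -1.

## Bump hunting and the area statistic

Probes are clustered per chromosome with a maximum intra-cluster gap of
500 bp. Within clusters of at least 3 probes the coefficients are smoothed
by a centered running mean (window 3, shrinking at cluster edges); smaller
clusters stay raw. Candidate regions are maximal same-sign runs where the
absolute smoothed coefficient exceeds the 99th percentile of all absolute
smoothed coefficients. The area is computed from the **unsmoothed**
coefficients (the area is defined on estimated model coefficients, not on
the smoother's output), and equals the brute-force absolute sum exactly -
a test asserts this for every emitted region. The three tuning constants
(gap, window, cutoff quantile) are config keys recorded in every output.

The permutation null permutes group labels only (covariates stay attached
to their samples), refits, and re-runs bump finding at the *observed*
cutoff. Each permutation contributes its maximum null area, and a region's
p value is $(1 + \#\{\max\text{-null} \ge \text{area}\})/(1 + B)$. Because
observed regions other than the maximum are compared against a maximum-area
null, their p values are conservative; only the top region's p is uniform
under the null, and that is what the calibration tests check.

Regions are matched across subsets by shared gene label when available,
otherwise by 1-bp coordinate overlap, and each matched key gets a presence
run length and an area-trend statistic (Spearman of area against subset
distality).

## The classifier

The classifier set pairs every low-scoring sample (CD-RISC <= 50) with two
high-scoring samples (>= 80) agreeing exactly on ER, PR and HER2, with
never-smokers matched only to never-smokers (ever-smokers prefer
ever-smoker partners) and minimal age distance; matching is greedy in
ascending score order with id tie-breaks, so it is deterministic and the
reported distances make it auditable. Triplets are the atomic unit of every
split: train (50%) / confirmation (20%) / test (30%) partitions allocate
whole triplets (largest-remainder rounding), so no sample leaks across
partitions and every partition keeps the 1:2 class ratio.

Per iteration: bump hunting on the training samples proposes DMRs; CpGs in
regions spanning at least 5 probes survive; the confirmation set then
removes CpGs whose fold-change direction disagrees with training. A random
forest (ranger) on the selected CpGs' M values is tuned by grid search with
m = 3 repeats of k = 5 triplet-level cross-validation, scoring each
configuration by its mean out-of-fold Youden J (J = SN + SP - 1, the
imbalance-robust criterion; no class resampling is done). The operating
threshold is the Youden-optimal point of the pooled out-of-fold
predictions, reported at the midpoint of the gap below the optimal observed
probability: on the tuning data this classifies identically to the optimal
observed cut, but the centered boundary transfers much better to
independent samples, whose predicted probabilities are systematically less
extreme. AUC uses the rank-sum (trapezoidal) estimator.

Across iterations (seed of iteration i is `base_seed + i`, so a run is
fully reproducible from one integer) CpGs are ranked by selection
frequency. The final model scans panel sizes over the top-ranked CpGs plus
age (the one clinical covariate retained, given the strong age-methylation
link), tunes each on the whole classifier set, picks the size maximizing CV
AUC - ties break toward the **larger** panel, since near-separable training
data tie many sizes at AUC 1 and the larger panel is the more robust
operating choice - and is evaluated once on the independent validation set.

The documented default hyperparameter grid (`rf_grid()`) spans mtry
{sqrt(p), p/3, p}, 250/500/1000 trees, node sizes 1/5/10, depths
unlimited/4/8, and gini/hellinger split rules. Tuning that grid inside
hundreds of resampling iterations is wasteful; `run_iterations()` defaults
to the reduced `rf_grid_small()` (mtry {sqrt(p), p/3}, 250 trees, node
1/5, unlimited depth, gini), which in our simulations loses nothing at
these sample sizes.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions so every layer is
testable with known ground truth:

- **Scores.** Truncated-normal tail mixture: low group ~ N(56, 8) on
  [32, 65], high group ~ N(84, 5) on [77, 100], half the cohort each -
  the selection profile of a tail-dichotomized discovery set. The full
  cohort's score distribution is not identifiable from group summaries, so
  these mixture parameters are conventions, not estimates.
- **Spikes.** Each spiked region shifts its probes' M values by
  `direction * max_effect * (|s - midpoint|/half_range)^dose_exponent`,
  antisymmetrically about the score midpoint (default 71, the boundary
  between the two selection ranges; half-range is the distance from the
  midpoint to the near end of the 0-100 scale). A sample exactly at the
  midpoint is unshifted; extreme scorers reach the full effect. Spiked
  runs get compressed inter-probe gaps so they form genomic clusters, and
  intermediate baseline methylation so shifts do not saturate the beta
  scale.
- **Background.** Per-probe baseline M from a three-component Gaussian
  mixture (unmethylated/methylated/intermediate), giving the familiar
  bimodal beta distribution after the inverse logit; M-scale noise SD 0.35.
- **Structure.** Optional covariate loadings (a configurable fraction of
  probes pick up an age/menstrual/smoking/ER/detection effect), per-batch
  location/scale shifts, and per-sample leukocyte fractions (Dirichlet)
  mixed through a synthetic reference panel on designated reference probes.
- **QC failure modes.** Independent per-class flag rates (detection p,
  bead counts, non-CpG ids, SNP, multihit, X/Y) totalling ~16%, so the
  six-rule filter cascade retains ~84% - the filter, not the generator, is
  what is being exercised.

Per-probe baselines are redrawn for every seed, so two independently
seeded simulations are different "arrays" and are not comparable at the
level of absolute M values. An independent validation cohort is therefore
emulated by simulating one larger population and splitting its samples
into classifier and validation portions — exactly as real cohorts share
the array's per-probe biology while contributing disjoint samples.

What the generator does **not** emulate: probe-type (I/II) chemistry and
normalization artifacts, long-range correlation between distant probes,
genuine cell-type-coupled trait effects, and missing covariate values.
Passing tests therefore demonstrate the pipeline's statistical behavior
under its own assumptions, not performance on raw cohort data.

## Numerical and design choices

- Batch adjustment is per-probe, per-batch location/scale standardization
  to the probe's grand mean/SD, followed by an exact rescale so each
  probe's overall mean and SD are preserved to machine precision. It is
  shrinkage-free and exact (a single batch passes through unchanged;
  singleton batches are refused). The config keeps a `method` key should an
  empirical-Bayes variant be added.
- Cell-type deconvolution is Houseman-style constrained projection: per
  sample, non-negative least squares (Lawson-Hanson active set) on the
  reference profiles with a heavily weighted sum-to-one row; exactly
  representable mixtures are recovered to < 1e-6.
- Percentile subsets take `ceiling(q * n)` per group with id tie-breaks,
  which makes the subsets nested and reproducible; subsets leaving fewer
  than 3 samples in a group are dropped with a warning.
- Coordinates are 1-based inclusive throughout; BED export converts to
  0-based half-open.
- All randomness flows through named seeds; package functions restore the
  caller's RNG state.

## Problem sizes in the test suite

The suite exercises the pipeline at desk scale, chosen so the whole run
stays in a few minutes while keeping every statistical check adequately
powered: null calibration uses a 10,000-probe x 200-sample cohort;
parameter recovery uses ten 2,000-probe x 160-sample cohorts with three
spiked DMRs (6-8 probes, max effects 1.0-1.5 M units) and 50 classifier
iterations each; end-to-end determinism reruns a 5,000-probe pipeline
byte-for-byte. `scripts/acceptance.R` recomputes the same quantities from
scratch under a caller-supplied seed.

## Known limitations

- The subset analyses reuse overlapping samples; consistency across
  subsets is evidence of internal robustness, not of generalization - the
  held-out classifier layers exist precisely to address that.
- DMP calling follows the raw-p + fold-change convention; q values are
  reported but unused by design, so single-subset DMP lists are
  exploratory by construction.
- Greedy matching need not be globally optimal; with scarce
  covariate-compatible highs, some lows go unmatched (reported).
- Permutation p values for non-maximal regions are conservative (see
  above); they rank regions sensibly but are not uniform nulls.
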