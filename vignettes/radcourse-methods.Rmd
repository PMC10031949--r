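---
title: "Methods: micronucleus kinetics and multi-endpoint radiation time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micronucleus kinetics and multi-endpoint radiation time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcourse)
```

## Scope

`radcourse` analyzes longitudinal blood endpoints measured in non-human
primates after an acute whole-body radiation exposure: cytogenetic damage
scored by the cytokinesis-block micronucleus (CBMN) assay, complete blood
counts through the hematopoietic acute radiation syndrome and recovery, and
per-timepoint lists of differentially expressed transcripts and proteins.
Every analysis stage has a matching seeded generator, so the statistical
behavior of the whole pipeline can be verified on data with known ground
truth without any external files.

## The micronucleus kinetic model

The damage readout is MN/BN, micronuclei per binucleated lymphocyte. After
an acute exposure the population of micronucleated cells is fed by
production (damaged lymphocytes entering the assayable pool) and drained by
decay (repair, apoptosis, dilution by repopulating undamaged cells). The
working model family expresses the expected MN/BN at day $d$ as a baseline
plus a production term shaped by competing decay channels:

$$\mathrm{MN/BN}(d) = C + K_\mathrm{prod}\, d \,\bigl(P e^{-K_\mathrm{dec1} d}
  + (1-P) e^{-K_\mathrm{dec2} d^2}\bigr)$$

* $C$ — pre-irradiation baseline MN/BN (dimensionless, $\ge 0$). Baseline
  samples taken before exposure are assigned day 0 for fitting.
* $K_\mathrm{prod}$ — production rate (per day, $\ge 0$).
* $K_\mathrm{dec1}$ — linear exponential decay rate (per day).
* $K_\mathrm{dec2}$ — quadratic exponential decay rate (per day$^2$), a
  channel that shuts off sharply after the first days.
* $P \in [0,1]$ — fraction of decay through the linear channel.

Four candidate formalisms with different power dependences on time are
implemented (`mn_model_names()`): the linear-decay curve
$C + K_\mathrm{prod} d e^{-K_\mathrm{dec1} d}$ (M1), the quadratic-decay
curve $C + K_\mathrm{prod} d e^{-K_\mathrm{dec2} d^2}$ (M2), the
five-parameter mixture above (M3), and a quadratic-production variant
$C + K_\mathrm{prod} d^2 e^{-K_\mathrm{dec1} d}$ (M4). Only the mixture is
singled out by the data we emulate; the other three are plausible
alternatives used for AIC comparison, and their exact forms are a design
choice of this package.

### Weighting

Individual animal-by-day observations are fitted, not day means. Each
observation is weighted by the inverse squared standard error of the mean
of MN/BN across animals at its day, and weights are normalized so that
their mean over all fitted observations is exactly 1. The normalization
makes the weighted residual sum of squares — and hence the reported AIC —
invariant to any overall rescaling of the raw $1/\mathrm{SEM}^2$ values.
Days with fewer than two animals or zero spread cannot supply a finite
weight and fall back to the median SEM across the remaining days (with a
warning); a single-day table degenerates to unit weights.

### Fitting, likelihood and AIC

`fit_mn()` minimizes the weighted residual sum of squares under box
constraints with Levenberg–Marquardt iterations and an analytic Jacobian,
restarted from 16 Latin-hypercube starting points drawn deterministically
from the fit seed (cost tolerance $10^{-10}$). The weighted residual
standard error is $\sqrt{\mathrm{RSS}_w / (n - k)}$. The log-likelihood
follows the weighted Gaussian convention with the residual variance
profiled out,

$$\ell = \tfrac12 \sum_i \log w_i - \tfrac{n}{2}\bigl(\log 2\pi + 1 -
  \log n + \log \mathrm{RSS}_w\bigr),$$

and $\mathrm{AIC} = 2(k+1) - 2\ell$, counting the residual scale as an
estimated parameter. This is the convention of `stats::nls`, so rankings
are comparable with fits from that function. `compare_models()` sorts by
AIC, breaking ties toward fewer parameters and then by name, which makes
the ranking a deterministic, permutation-invariant function of the data.

### Mixed-effects variant

`fit_mn_mixed()` adds a per-animal Gaussian random intercept on $C$,
representing donor-to-donor baseline variability. The prescribed estimator
is a Laplace approximation of the marginal likelihood; because the
intercept enters the model additively, the Laplace approximation is exact —
each animal's observations are marginally normal with covariance
$\sigma^2 \mathrm{diag}(1/w) + \sigma_C^2 \mathbf{1}\mathbf{1}^\top$ — so
the implementation maximizes this closed-form marginal likelihood directly
(L-BFGS-B over the fixed effects, $\log\sigma$ and $\log\sigma_C$, with
$\sigma_C$ floored at $10^{-10}$ and three starting values for the variance
component). Nested profiling of $\sigma_C$ is unnecessary when the integral
is available in closed form.

One boundary property deserves note: when the true $\sigma_C$ is zero, the
maximum-likelihood estimate has a point mass at the boundary plus an
occasional small positive tail — a finite-sample draw can exhibit chance
per-animal clustering that genuinely raises the likelihood. Typical
simulations at scoring depth 2000 and 12 animals return estimates at the
floor with fixed effects identical to the fixed-effects fit; sporadic
estimates of order $10^{-3}$ are expected estimator behavior, not a defect.

## Proportion tests on MN data

Per-animal comparisons (late day vs baseline, heparin vs EDTA) pool
replicate well counts per animal-day and apply the chi-square test on the
2×2 micronucleus table — the squared two-proportions Z-test — with the
Yates continuity correction on by default (it never decreases the
p-value). Bonferroni correction uses the number of animals actually
tested. Animals missing a required time point or label are skipped with a
warning rather than failing the whole analysis. All-zero tables take the
$p = 1$ path explicitly to avoid 0/0 in the pooled statistic.

## Hematology time courses

Baseline is the per-animal unweighted mean over all pre-irradiation
occasions (days < 0). Each post-irradiation day is compared to baseline
with a two-sided paired t-test across animals (at least 3 complete pairs;
zero-variance differences are reported non-significant with a warning).
Percent change is computed on across-animal means. The nadir is the
post-irradiation day with the minimum mean count, ties broken to the
earliest day — a definition invariant under monotone transforms of the
counts. Recovery has no universally printed formula in this literature, so
the package adopts a dual criterion: the first day after the nadir whose
paired test is non-significant at `alpha` *and* whose mean has returned to
at least 80% of baseline. Both thresholds are arguments; reported recovery
days from descriptive studies should be expected to match approximately,
not exactly.

## Differential calling, overlap and the time-correlation filter

`call_differential()` applies per-feature two-sided Welch t-tests to a
two-group log2 matrix and adjusts either by Benjamini–Hochberg (default
threshold 0.005, the convention for the transcript lists we emulate) or by
pooled permutation FDR (default 0.05 with a 0.58 log2 fold-change floor,
i.e. 1.5-fold, the proteomics convention). Zero-variance features are
flagged and excluded from the adjustment family rather than given
degenerate p-values. The permutation scheme compares each observed |t|
against the permuted statistics pooled across features; when the label
space has fewer than 100 distinct assignments it is enumerated
exhaustively, otherwise at least 100 random relabelings are required.

Overlap bookkeeping (`intersect_lists()`) is exact set algebra on molecule
IDs. Cross-modality matching defaults to case-folded symbol equality with
an optional explicit two-column map; many-to-one entries collapse to their
target and each molecule counts once. Overlap is direction-agnostic by
default with a `concordant` switch. The time-correlation filter computes
per-molecule Pearson correlations of log2 fold change against day within
the first week (days ≤ 7) and keeps molecules below the threshold (default
−0.5) in *both* modalities; constant series have undefined correlation and
are excluded with a note rather than passed.

## Overrepresentation

`overrepresentation()` is the one-sided hypergeometric (Fisher enrichment)
test against a GMT collection with Bonferroni correction over the number of
sets and a corrected cutoff of 0.05 by default. The universe defaults to
the union of the collection's members and can be overridden with a
reference gene list — results are sensitive to this choice, which is why it
is an explicit argument.

## What the generators emulate — and what they do not

* `simulate_mn()` draws binucleate counts uniformly within a scoring-depth
  range (default 200–1000 cells, a typical CBMN scoring depth; the true
  depth per sample is rarely reported) and micronucleus counts from
  binomial, beta-binomial (overdispersion `rho`, reducing exactly to
  binomial at 0) or per-cell Poisson noise around the kinetic curve. The
  binomial family enforces MN/BN ≤ 1 and rejects parameter/day
  combinations whose expected ratio exceeds 1; per-cell Poisson permits
  multiple micronuclei per cell as in real scoring.
  `default_mn_params()` fixes a study-like truth (C = 0.01,
  K~prod~ = 0.37, K~dec1~ = 0.07, K~dec2~ = 0.12, P = 0.21) whose curve
  peaks near 0.5 at day 3, drops to ≈0.34 by day 6 and declines to ≈0.1 by
  day 56.
* `simulate_hematology()` uses a piecewise log-linear trajectory through
  (day 0, baseline), (nadir day, nadir fraction) and (recovery day,
  baseline), with unit-mean lognormal noise (the $e^{-s^2/2}$ mean
  correction is applied so expected counts equal the noiseless
  trajectory). Real granulocyte rebounds overshoot baseline and real
  counts are serially correlated within animal; neither is modeled.
* `simulate_molecule_lists()` plants an exact common core across days plus
  day-specific extras, drawn either disjointly (every pairwise overlap
  equals the core) or uniformly (pairwise extra overlap has hypergeometric
  expectation). Real differential lists share correlated biology far above
  chance; the generator only controls intersection sizes.
* `simulate_expression_matrix()` plants additive log2-scale shifts in
  independent Gaussian noise. Real arrays/proteomes have correlated
  features, heteroscedasticity and batch structure; passing tests on these
  fixtures demonstrate correctness of the calling machinery, not
  robustness to those real-data pathologies.

All generators consume a single integer seed and restore the caller's RNG
state, so they are pure functions of their arguments.

## Numerical choices and degenerate inputs

* Optimizer bounds are wide data-driven boxes (e.g. $C \le 2\max y$); the
  Latin-hypercube start box is narrower to concentrate starts in the
  plausible region. Non-convergence across all starts is an error for the
  single-model fit and a warning-with-exclusion in model comparison.
* The parameter covariance is $\mathrm{RSE}^2 (J^\top W J)^{-1}$ and falls
  back to `NA` when the Jacobian cross-product is singular.
* Weighted-RSS surfaces for these curves have a strongly correlated,
  shallow valley in $(C, K_\mathrm{prod})$; different optima along the
  valley can differ noticeably in parameters while differing little in
  objective. Tests therefore compare against grid-search oracles through
  the objective as well as the parameters.
* `mn > bn` rows are legal by default (per-cell scoring) and rejected
  under strict binomial semantics (`allow_mn_gt_bn = FALSE`).
* Problem sizes in the test-suite and acceptance simulations — 8 animals,
  scoring depth 500, the 8-day sampling grid, 50–100 replicates, 2000 null
  replicates for type-I checks — were chosen to mirror a realistic
  single-cohort study while keeping each check well-resolved statistically.

## Known limitations

* No dose–response calibration or dose inversion: the model describes one
  exposure level's time course.
* Recovery-day reproduction is approximate by construction (see above).
* Exact reproduction of published cross-modality overlap counts depends on
  the unstated probe-to-protein ID mapping of the source datasets; the
  package exposes the mapping as an input rather than guessing one.
* The enrichment module ships no pathway content; users supply GMT files.
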