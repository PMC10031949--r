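# radcourse

Longitudinal multi-endpoint analysis of blood from primates after acute
total-body irradiation.

After a single whole-body radiation exposure, peripheral blood carries
several time-resolved signatures of the dose and the hematopoietic acute
radiation syndrome that follows: chromosome damage scored as micronuclei
per binucleated lymphocyte (MN/BN) in the cytokinesis-block micronucleus
assay, depletion and recovery of the blood cell lineages, and waves of
transcriptional and proteomic change. `radcourse` implements the
statistical machinery for analyzing all of these endpoints from one cohort
sampled repeatedly over weeks, together with seeded generators that
simulate each data type with known ground truth, so the whole pipeline is
testable end to end without any external data.

## The core model

The MN/BN time course is modeled as baseline plus production shaped by two
competing decay channels:

```
MN/BN(d) = C + Kprod · d · ( P·exp(−Kdec1·d) + (1−P)·exp(−Kdec2·d²) )
```

with baseline `C`, production rate `Kprod` (per day), linear and quadratic
exponential decay rates `Kdec1` (per day) and `Kdec2` (per day²), and
mixture fraction `P ∈ [0,1]`. Individual animal×day observations are fitted
by weighted nonlinear least squares, each observation weighted by the
inverse squared day-level SEM of MN/BN (normalized to mean weight 1), with
bound-constrained Levenberg–Marquardt, analytic Jacobians and a
deterministic 16-point Latin-hypercube multistart. Four candidate curve
shapes are compared by AIC, and a mixed-effects variant puts a Gaussian
random intercept on `C` (exact marginal likelihood — the Laplace
approximation is exact for an additive intercept).

Around the kinetic core the package provides per-animal two-proportion
tests with Bonferroni correction (late-day persistence, anticoagulant
comparisons), hematology time-course characterization (baseline, paired
tests, percent change, nadir and recovery days), differential-molecule
calling with BH or pooled-permutation FDR, multi-timepoint and
cross-modality list overlap with a time-correlation filter, and
hypergeometric gene-set overrepresentation against GMT collections.

## Worked example

Simulate a study-like cohort (8 animals, sampling days 0–56, 400–800
binucleate cells scored per sample), pick the best curve by AIC, and
summarize a lymphocyte time course:

```r
library(radcourse)

params <- default_mn_params()   # study-like truth: peak ~0.5 at day 3
design <- mn_design(sprintf("NHP%d", 1:8), c(0, 1, 3, 6, 9, 15, 28, 56),
                    bn_range = c(400, 800))
mn <- simulate_mn(params, design, dispersion_spec("binomial"), seed = 101)

fits <- compare_models(mn, seed = 101)
attr(fits, "ranking")
#>           model k        aic        rse converged
#> 1    M3_mixture 5 -341.04950 0.01062312      TRUE
#> 2  M1_lin_decay 3 -133.27076 0.05464654      TRUE
#> 3 M2_quad_decay 3 -105.68905 0.06778684      TRUE
#> 4  M4_quad_prod 3  -92.93748 0.07488770      TRUE

print(fits[[1]])
#> Micronucleus time-course fit: M3_mixture
#>   n = 64, converged = TRUE (16 starts)
#>        C    Kprod    Kdec1    Kdec2        P
#> 0.009211 0.360546 0.070573 0.116487 0.215295
#>   weighted RSE = 0.01062  logLik = 176.5  AIC = -341
```

The mixture model wins the AIC ranking by a wide margin and recovers the
generating parameters (C = 0.01, Kprod = 0.37, Kdec1 = 0.07, Kdec2 = 0.12,
P = 0.21) closely; the weighted residual standard error (0.011) is the
standard deviation of the weighted residuals. Predictions trace the
characteristic curve — near-zero baseline, peak at day 3, slow plateau,
decline by day 56:

```r
predict_curve(fits[[1]], c(0, 3, 6, 28, 56))
#>   day        pred
#> 1   0 0.009210793
#> 2   3 0.495144923
#> 3   6 0.339795703
#> 4  28 0.310489600
#> 5  56 0.092735535

fit_mn_mixed(mn, "M3_mixture", seed = 101)$sigma_C
#> [1] 1e-08      # no donor baseline variability was simulated; the random
                 # intercept collapses to the boundary
```

Hematology: simulate lymphopenia reaching 15% of baseline at day 15 with
recovery by day 27, then recover those features from the noisy counts:

```r
prof <- hema_profile("lymphocyte", baseline_mean = 4.1, nadir_day = 15,
                     nadir_fraction = 0.15, recovery_day = 27, cv = 0.15)
cbc <- simulate_hematology(list(prof), sprintf("NHP%d", 1:8),
                           c(-12, -8, -3, 1, 3, 6, 9, 12, 15, 18, 21, 24, 27, 30),
                           seed = 101)
nadir_recovery(cbc, "lymphocyte")[c("nadir_day", "recovery_day")]
#> $nadir_day
#> [1] 15
#> $recovery_day
#> [1] 27
percent_change(cbc, "lymphocyte", 15)
#> [1] -83.8      # percent decline from pre-irradiation baseline at the nadir
```

See the methods vignette (`vignettes/radcourse-methods.Rmd`) for the model
conventions (weighting, likelihood/AIC, mixed-effects estimator), the
differential-calling and overlap rules, and what the generators do and do
not emulate.

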