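# qpcrBayes

Bayesian two-class classification from small-panel qRT-PCR
cycle-threshold (Ct) triplicates.

qPCR classifiers in the clinic often rest on just a handful of assays
measured in triplicate on a few dozen samples. This package implements
a complete, statistically explicit pipeline for that setting, built
around the tumor-typing use case of separating two carcinoma classes
("target" vs "versus", e.g. adenocarcinoma vs squamous-cell carcinoma)
from a three-assay panel: a discriminating marker (e.g. miR-205), a
helper marker (e.g. miR-21) and a reference gene (e.g. U6).

## The science

**Replicate-variance quality control.** For a triplicate with true
replicate scale σ, the sample variance s² follows a scaled χ²(2) law
with CDF `F(s²) = 1 − exp(−s²/(2σ²))`. The per-assay scale σ is fitted
by minimizing the Kolmogorov–Smirnov distance between this CDF and the
empirical CDF of the observed triplicate variances (robust to the very
outliers being screened for), and triplicates with
`s > σ_max = sqrt(−2 ln α)·σ ≈ 2.448·σ` (α = 0.05) are flagged as
variability outliers — each flag has false-positive probability α under
the fitted law.

**Normalization.** Raw measures are triplicate means `x`; normalized
measures are delta-Ct values `dx = x_marker − x_reference`. A
cross-session audit (`session_bias_audit()`) checks, per class, whether
session mean differences exceed twice their quadrature-combined
standard errors — raw Ct values typically fail this, delta-Ct values
pass, which is the empirical justification for normalizing.

**Gaussian Bayes classifier.** Each class is modeled as a Gaussian
`N(μ, σ²)` in the chosen measure. The optimal decision threshold χ
solves the quadratic
`η·χ² − 2β·χ + γ − 2·ln(p_T/p_V) = 0` with
`η = 1/σ_T² − 1/σ_V²`, `β = μ_T/σ_T² − μ_V/σ_V²`,
`γ = μ_T²/σ_T² − μ_V²/σ_V² + 2·ln(σ_T/σ_V)`;
the root between the class means is selected. Sensitivity
`H = Φ((μ_T−χ)/σ_T)`, specificity `C = Φ((χ−μ_V)/σ_V)` and predicted
accuracy `p_c = p_T·H + p_V·C` follow in closed form; χ maximizes
`p_c`. Threshold uncertainty is propagated from the standard errors of
the four Gaussian parameters (finite differences for χ, Monte-Carlo
for p_c).

**Posterior-odds reliability bands.** Every sample gets the posterior
odds ρ = P(target|y)/P(versus|y); calls are reported in four bands
(ρ>9, 9>ρ>1, 1>ρ>1/9, ρ<1/9) so that "reliable" calls (odds ≥ 9:1)
are distinguished from marginal ones. Bias outliers — samples far from
both class models — are screened with a Student-t tail probability.

**Noise reduction.** When the helper marker is correlated with the
discriminating marker *within* classes but separates the classes
poorly itself, the combination `y = dx_marker + c·dx_helper` with
`c = −r·σ_a/σ_b` cancels shared (histological-admixture) noise: the
within-class SD shrinks by `sqrt(1 − r²)` while the class separation
is preserved, yielding a better classifier. The coefficient can also
be optimized directly against the Welch t statistic or training
accuracy of the combined measure.

**Synthetic cohorts.** `synthetic_config()` / `generate_cohort()`
implement the full generative model (bivariate-normal class measures,
reference gene, session offsets, exact χ²(2) replicate noise,
injectable variability and bias outliers), with
`analytic_combination_gaussians()` giving the exact population
Gaussians implied by any configuration — the ground truth used by the
parameter-recovery tests.

## Worked example

```r
library(qpcrBayes)

cfg <- paper_like_config()          # study-condition generative model
cohort <- generate_cohort(cfg, seed = 42)

qc <- apply_qc(cohort, alpha = 0.05)
qc
#> miR-205    sigma=0.274 sigma_max=0.671 D=0.084 p=0.974 n=33 outliers=1
#> miR-21     sigma=0.175 sigma_max=0.430 D=0.129 p=0.646 n=33 outliers=3
#> U6         sigma=0.207 sigma_max=0.506 D=0.100 p=0.895 n=33 outliers=2

measures <- normalize_cohort(qc$cohort, "U6")
class_stats_table(measures, c("dx_miR-205", "dx_miR-21"))
#>      measure  class  n  mean   sd shapiro_p  welch_p
#> 1 dx_miR-205 target 17  2.41 2.61     0.353 1.32e-06
#> 2 dx_miR-205 versus 13 -4.61 3.17     0.674 1.32e-06
#> 3  dx_miR-21 target 17 -6.28 1.15     0.284 6.71e-01
#> 4  dx_miR-21 versus 13 -5.87 3.26     0.377 6.71e-01
```

The marker delta separates the classes (Welch p ≈ 1e−06) while the
helper alone does not (p ≈ 0.67) — exactly the situation in which the
noise-reduction admixture pays off. Fit the single-measure classifier:

```r
m <- fit_bayes_classifier(
  measures[["dx_miR-205"]][measures$class_label == "target"],
  measures[["dx_miR-205"]][measures$class_label == "versus"],
  measure = "dx_miR-205")
m
#> Gaussian Bayes classifier [dx_miR-205]
#>   target N(2.412, 2.607^2) n=17 | versus N(-4.609, 3.175^2) n=13
#>   eta=0.04788 beta=0.81198 gamma=-1.64513 prior_ratio=1.000
#>   threshold chi = -0.9845 +/- 0.5448 (working scale)

odds_thresholds(m)
#>             odds     chi     se
#> chi_10_90 0.1111 -3.3819 0.9279
#> chi       1.0000 -0.9845 0.5448
#> chi_90_10 9.0000  1.7871 1.1786

predicted_accuracy(m, n_draws = 2e4)
#>        p_c     p_c_se
#> 0.88840499 0.04565539
```

Or run everything — QC, normalization, class statistics, base
classifier, coefficient optimization, improved classifier, banded
confusion matrices and AUCs — in one call:

```r
res <- run_pipeline(cohort)
res
#> ...
#> == Improvement ==
#> admixture coefficient: c* = -0.914 (welch_t = 10.2); closed form c = -0.707 (r = 0.366)
#> Gaussian Bayes classifier [dx_miR-205 -0.91*dx_miR-21]
#>   target N(8.159, 2.629^2) n=16 | versus N(0.755, 1.109^2) n=13
#>   eta=-0.66805 beta=0.56752 gamma=10.89677 prior_ratio=1.000
#>   threshold chi = 3.2776 +/- 0.4500 (working scale)
#>         band
#> truth    rho>9 9>rho>1 1>rho>1/9 rho<1/9
#>   target    15       0         1       0
#>   versus     0       0         2      11
#> accuracy: 96.6 %; high-reliability accuracy: 89.7 % (n = 29)
#> AUC: base 0.9683 -> improved 0.9904
```

The admixture lifts the AUC from 0.968 to 0.990 and nearly all calls
into the reliable (odds > 9:1) bands. A command-line interface with
subcommands `simulate`, `qc`, `fit`, `improve`, `classify` and
`evaluate` is installed at `inst/cli/qpcrbayes` (exit codes: 0 ok,
2 invalid input, 3 degenerate data).

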