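---
title: "Methods: multilevel meta-analysis and piecewise SEM for decomposer biodiversity and litter decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel meta-analysis and piecewise SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(befmeta)
```

## The inference problem

Chemical stressors (metals, pesticides) and nutrient enrichment alter the
diversity and abundance of animal and microbial decomposers, and may thereby
alter litter decomposition — a core ecosystem function. `befmeta` implements
the full chain needed to synthesise such evidence across heterogeneous
studies:

1. convert raw study summaries into a common effect size;
2. standardise incommensurable stressor/nutrient concentrations into a single
   driver-intensity axis;
3. pool effects with a weighted multilevel meta-analysis;
4. ask whether biodiversity change *mediates* the decomposition response,
   with a piecewise structural equation model (SEM) fitted under stratified
   resampling;
5. probe robustness: publication-bias diagnostics and sensitivity reruns.

Every stage is exercised end-to-end on a synthetic-data generator with known
ground truth, so the package's statistical behaviour (bias, coverage, power,
size, calibration) is itself under test.

## Effect sizes

The common effect size is the Fisher z-transformed correlation coefficient,
chosen because it accommodates both study designs found in this literature:

* **Control–treatment studies** report group means, SDs and sample sizes.
  The chain is Hedges' d (small-sample correction
  $J = 1 - 3/(4(n_t+n_c-2)-1)$), converted to a correlation by
  $r = d/\sqrt{d^2 + a}$ with $a = (n_t+n_c)^2/(n_t n_c)$, then
  $z = \operatorname{atanh}(r)$.
* **Gradient studies** (four or more treatment levels) use the Pearson
  correlation between level-wise outcome means and concentrations.

The sampling variance is $1/(n_{\mathrm{eff}}-3)$ throughout, with
$n_{\mathrm{eff}}$ the total sample size for control–treatment chains and the
number of gradient levels for gradient correlations. Using the z-scale
variance uniformly (rather than propagating $\mathrm{var}(d)$ through the
conversion) keeps the weighting scheme identical across designs; the
alternative would give slightly different weights for control–treatment
studies but the same point estimates.

Numerical conventions:

* correlations with $|r| \ge 0.999$ (e.g. four perfectly collinear gradient
  points) are clipped to $\pm 0.999$ with a warning, so no effect is infinite;
* decomposition reported as *mass remaining* is sign-flipped so that a
  positive z always means "the response increases with the driver level";
  mass loss and decay rates $k = -\log(\text{fraction remaining})/t$ need no
  flip;
* when SDs are missing they are approximated by an ordinary least-squares
  regression of SD on mean, fitted separately within each driver-by-response
  dataset, floored at $10^{-6}$ and flagged `sd_approximated` (these records
  can be excluded wholesale in a sensitivity rerun);
* with several time points, only the last is retained (long-term response);
* the alternative log-response-ratio metric (`effect_metric = "lnRR"`) exists
  for sensitivity analyses; it requires positive means and a control group,
  so gradient records are excluded under it.

## Driver intensity

Concentrations of different compounds in water, soil or sediment are not
comparable. Each is standardised against its environmental quality criterion
(ECHA, USEPA, WFD, …):
$$\mathrm{intensity} = \log_{10}\!\frac{[\mathrm{compound}]_{\mathrm{treatment}}}{[\mathrm{compound}]_{\mathrm{criteria}}},$$
so 0 means exactly at the criterion and one unit is one order of magnitude.
Base 10 is the package default because criteria and field concentrations span
orders of magnitude; the base is configurable (`log_base`) and recorded in
outputs, since slope magnitudes scale with it. With several compounds per
observation, the compound with the highest standardised intensity is used;
ties break deterministically by input order and are reported.

## The multilevel meta-analytic engine

All pooling, meta-regression and SEM sub-models share one engine,
`fit_meta()`, the marginal model
$$y_i = x_i'\beta + u_{study(i)} + (u_{obs(i)}) + e_i, \qquad
  \mathrm{Var}(e_i) = v_i \text{ known},$$
with $u_{study} \sim N(0, \tau^2)$ and optionally a nested observation-level
component $N(0, \omega^2)$. Weights are the inverse sampling variances; the
between-level components are estimated by REML (default) or ML.

Implementation notes, for the numerically curious:

* the marginal covariance is block-diagonal by study and each block is
  diagonal-plus-rank-one, so the profiled (restricted) likelihood is
  evaluated in $O(np^2)$ via the Sherman–Morrison identity; no $n \times n$
  matrix is formed. The per-evaluation kernel is compiled (RcppArmadillo)
  because the resampled SEM evaluates it hundreds of thousands of times;
* components are constrained nonnegative by optimising on the SD scale with
  derivative-free methods: golden-section search for one component,
  Nelder–Mead for two (relative tolerance $10^{-10}$ for standalone fits,
  $10^{-8}$ inside resampling loops; at most 500 iterations; non-convergence
  is an error, never a silent result);
* categorical moderators use treatment contrasts with alphabetical first
  level; per-group grand means are linear combinations of coefficients, not
  refits;
* confidence intervals are Wald normal-based ($\pm 1.96\,SE$) and moderator
  tests are Wald chi-square ($Q_M$) — no small-sample t adjustment;
* AIC is always computed under ML (refitting the components when the primary
  fit is REML), because models compared by AIC differ in their fixed effects;
  the parameter count is fixed effects plus variance components.

Validation: with components fixed at 0 the fit equals the closed-form
inverse-variance weighted mean to $10^{-8}$; the REML $\hat\tau^2$ matches a
brute-force grid search of a dense-matrix restricted likelihood to the grid
resolution; estimates, SEs, $Q_M$ and ML-AIC agree with `metafor::rma.mv()`
on nested two-component fits.

Publication bias is assessed with funnel data (effect vs. SE, driver as
covariate) and Egger's regression of $z_i/SE_i$ on $1/SE_i$: an intercept
different from zero (t-test, $k-2$ df) flags funnel asymmetry.

## Piecewise SEM with stratified resampling

For each of the four datasets (stressor/nutrient × diversity/abundance) the
mediation hypothesis is encoded as a directed acyclic graph over
{intensity, study type, taxonomic group, (diversity metric), $z_B$,
$z_{LD}$} with two endogenous regressions:

```
zLD ~ zB + intensity + study_type          (random = ~1 | study/obs)
zB  ~ intensity + study_type + taxon_group (+ diversity_metric)
```

both fitted with `fit_meta()` (known sampling variances, nested random
intercepts), which reproduces the weighted meta-analytic structure inside the
SEM.

**d-separation and Fisher's C.** Each missing edge between a pair of nodes
(excluding exogenous–exogenous pairs) yields one conditional-independence
claim, conditioned on the union of both nodes' parents, tested by the Wald
p-value of the omitted predictor added to the endogenous node's regression.
Fisher's C $= -2\sum \log p_i$ is chi-square with $2k$ df under the graph; a
small p-value means poor fit. The basis-set enumerator is deliberately tiny
and is cross-checked in tests against hand enumeration of the standard
graphs.

**Stratified resampling.** Studies often report several biodiversity effects
for one decomposition measurement (different taxa in the same litterbag).
At each of 1000 iterations (configurable) one biodiversity effect per
measurement is drawn uniformly; coefficients, SEs, standardised coefficients,
C and ML-AICs are averaged arithmetically across iterations, and the p-value
of the *averaged* C uses the fixed graph df. Averaging SEs is a simple mean —
no between-iteration variance inflation is added, a deliberate simplification
documented here as a limitation. Iterations whose fits fail are skipped and
counted; more than 10% failures is an error. Per-measurement residuals are
averaged across iterations for diagnostics.

**Mediation test.** The full SEM is compared with the SEM lacking the
$z_B \to z_{LD}$ edge. The mediated path is supported when the reduced model
fits poorly (p-value of its averaged C below 0.05) *and* the reduced model is
not better by more than 2 AIC units. We define
$\Delta AIC = AIC_{reduced} - AIC_{full}$, so "reduced better by ≥ 2" is
$\Delta AIC \le -2$; the sign convention is stated in every report because
both directions appear in common usage. The SEM AIC is the sum of the
sub-models' ML-AICs; since full and reduced share the $z_B$ sub-model, the
comparison reduces to the decomposition sub-model's AIC difference. (The
piecewiseSEM convention of $C + 2K$ is an alternative; the ML-AIC sum is used
here because the compared models differ only in fixed effects.)

**Standardisation and indirect effects.** Standardised path coefficients
multiply the unstandardised coefficient by the predictor/outcome SD ratio,
computed from the resampled analysis table at each iteration and then
averaged. The indirect (mediated) effect is the product of the standardised
intensity → biodiversity and biodiversity → decomposition paths, compared in
magnitude with the direct standardised intensity → decomposition path.
Between-model comparisons of path strength use *unstandardised* coefficients,
since standardisation denominators differ between datasets.

## The synthetic-data generator

`truth_config()` / `simulate_effect_table()` emulate the statistical
structure the analysis assumes: 69 case studies with ~660 observations by
default, study random intercepts in both the biodiversity and decomposition
equations (drawn independently per equation — with a nonzero mediated path
the decomposition effects still inherit study-level dependence on the
biodiversity effects through the path itself, which the SEM's random effects
must absorb; a *single* intercept shared by both equations would instead make
the observed biodiversity effect endogenous in the decomposition regression
and invalidate the mediation test's size for any estimator of this model, so
that design is deliberately not used), driver intensity drawn Uniform(−2, 3) spanning
levels below and above the quality criteria, 1–4 biodiversity observations
per decomposition measurement, moderator categories drawn with probabilities
matching the taxonomic and design composition of this literature (77%
animal), one measurement-level latent deviation shared by a
measurement's duplicated biodiversity observations (duplicates are
alternative metrics of the same community response, e.g. different taxa in
one litterbag), and observed effects $z \sim N(\zeta, 1/(n-3))$ with
within-observation sample sizes $n$ drawn from [4, 30] — the empirical
distribution of study sizes is not tabulated anywhere, so this range is an
exposed configuration choice, not an estimate. Default grand means
(stressor effects ≈ −0.3/−0.25 on diversity/abundance, nutrient effects near
zero) and path coefficients (biodiversity → decomposition 0.42) are on the
scale of the fitted quantities this literature reports.

`simulate_raw_studies()` emits the *raw* summaries instead (group means, SDs
and sizes drawn from their sampling distributions around a target Hedges' d;
gradient level means constructed to give exactly the target Pearson r; a
configurable fraction of SDs withheld), so the effect-size module itself is
exercised, not bypassed.

`apply_publication_bias()` retains each observation with probability
$\mathrm{logistic}(z/SE - 1.645)^{strength}$: 1 for every observation at
strength 0, increasingly harsh suppression of nonsignificant and negative
effects as strength grows. This is a detection test-bed, not a model of the
real selection process — the analysis only *detects* bias, it never corrects
for it. In the validation suite "strong selection" is strength 1.5 applied to
1200 null observations, retaining roughly 100 heavily asymmetric effects.

**What the generator does not emulate:** taxonomic composition, litter
chemistry, spatial or temporal structure, correlated moderators, non-linear
intensity responses, or dependence between sampling variances and effect
magnitudes. Passing tests therefore demonstrate that the *statistical
machinery* is correct and calibrated under the assumed structure — not that
the assumed structure captures every feature of the real literature.

## Known limitations

* **Regression dilution on the mediated path.** The SEM regresses one
  *observed* effect size on another; the predictor $z_B$ carries sampling
  error of variance $1/(n-3)$, which the model does not remove. The
  $z_B \to z_{LD}$ coefficient therefore estimates an attenuated association
  whenever within-observation sample sizes are modest — a property of the
  method itself, shared by any effect-size-on-effect-size regression. The
  validation suite accordingly checks *truth recovery* on the
  intensity → biodiversity path (a correctly specified regression), checks
  the mediated path's null behaviour and detection power, and demonstrates
  recovery of the mediated coefficient itself only where within-observation
  n is large enough (≥ 1000) for dilution to be negligible.
* The mean Fisher's C across resampling iterations is referred to a fixed-df
  chi-square; averaging is not a formal combination rule, it mirrors the
  resampling convention of the applied literature.
* No multiple-testing correction is applied across moderator tests; p-values
  are per-test.
* Decomposition measurements with no biodiversity partner are excluded from
  the SEM datasets but retained for grand-mean analyses.

## Problem sizes used in the validation suite

Monte Carlo checks are sized to be decisive yet quick: 100 random instances
for the closed-form oracle; 20 instances (≤ 10 studies) for the REML grid
oracle at step $10^{-4}$; $10^4$ simulations for the Fisher's C calibration;
50 replicates × 200 resampling iterations (80 studies, duplicates 1–4,
$\tau = 0.2$, near-exact effect sizes so the mediated coefficient is not
diluted — see the limitation above) each for mediated-path coverage,
mediation power (path 0.5) and size (path 0); 200 replicates for Egger power
and size. These sizes
are the package's validation design; rerunning with larger sizes only
tightens the Monte Carlo error.

```{r example, eval = FALSE}
# a complete run on synthetic data with known truth
sim <- simulate_effect_table(truth_config(seed = 1))
report <- run_pipeline(sim, iterations = 200, seed = 1)
report$grand_means
glance(report$sem$stressor_diversity$full)
```
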