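# befmeta

Multilevel meta-analysis and piecewise structural equation modelling for
syntheses of how environmental-change drivers — chemical stressors (metals,
pesticides) and nutrient enrichment — affect decomposer biodiversity,
decomposer abundance, and litter decomposition, and whether the biodiversity
change *mediates* the decomposition response.

## Who this is for

Ecologists running biodiversity–ecosystem-function (BEF) syntheses across
heterogeneous primary studies: control-impact designs and concentration
gradients, aquatic and terrestrial systems, animal and microbial decomposers,
with effect sizes extracted from published summary statistics.

## What it computes

**Effect sizes.** Fisher z-transformed correlations as the common currency.
Control–treatment records go through Hedges'
d (small-sample correction *J* = 1 − 3/(4(n<sub>t</sub>+n<sub>c</sub>−2)−1)),
the conversion r = d/√(d² + a) with a = (n<sub>t</sub>+n<sub>c</sub>)²/(n<sub>t</sub>n<sub>c</sub>),
then z = atanh(r); gradient records (≥ 4 levels) use the Pearson correlation of
level means with concentrations. Sampling variances are 1/(n−3). Mass-loss data
convert to decay rates k = −log(fraction remaining)/t; missing SDs are
approximated from the within-dataset mean–SD regression and flagged; log
response ratios are available as a sensitivity metric.

**Driver intensity.** Heterogeneous compound concentrations are standardised
against environmental quality criteria:
intensity = log₁₀([compound]<sub>treatment</sub>/[compound]<sub>criteria</sub>),
with the most-intense compound retained per observation.

**Pooling.** A weighted multilevel random-effects meta-analysis with *known*
sampling variances,

y<sub>i</sub> = x<sub>i</sub>′β + u<sub>study(i)</sub> (+ u<sub>obs(i)</sub>) + e<sub>i</sub>,  Var(e<sub>i</sub>) = v<sub>i</sub>,

variance components by REML (profiled block-diagonal likelihood, compiled
kernel), Wald Q<sub>M</sub> moderator tests, per-group grand means with 95%
CIs, funnel data and Egger regressions for publication bias.

**Mediation.** Piecewise SEM per driver-by-response dataset: two mixed
sub-models (`zLD ~ zB + intensity + study_type`,
`zB ~ intensity + study_type + taxon_group (+ diversity_metric)`, each with
nested case-study/observation random intercepts and inverse-variance
weights), d-separation basis set, Fisher's C = −2Σlog p (χ², 2k df),
stratified resampling of duplicated biodiversity effects (one per
decomposition measurement per iteration, estimates averaged across
iterations), a mediation test (reduced-model C p-value < 0.05 *and* reduced
model not better by more than 2 ML-AIC units), standardised paths and the
indirect effect (product of standardised paths).

A synthetic-data generator with known ground truth (`truth_config()`,
`simulate_effect_table()`, `simulate_raw_studies()`,
`apply_publication_bias()`) emulates the nested study→measurement→observation
structure, so the whole chain is validated end-to-end for bias, coverage,
power, size and calibration.

## Worked example

```r
library(befmeta)

sim    <- simulate_effect_table(truth_config(seed = 1))  # 69 studies, ~660 obs
report <- run_pipeline(sim, iterations = 200, seed = 1)
report$grand_means
#> # A tibble: 6 × 7
#>   response      group    estimate     se  ci_low ci_high           p
#>   <chr>         <chr>       <dbl>  <dbl>   <dbl>   <dbl>       <dbl>
#> 1 diversity     nutrient -0.0499  0.0577 -0.163   0.0633 0.388
#> 2 diversity     stressor -0.311   0.0617 -0.432  -0.190  0.000000454
#> 3 abundance     nutrient  0.00691 0.0485 -0.0881  0.102  0.887
#> 4 abundance     stressor -0.253   0.0542 -0.359  -0.147  0.00000307
#> 5 decomposition nutrient -0.00652 0.0419 -0.0887  0.0756 0.876
#> 6 decomposition stressor -0.177   0.0459 -0.267  -0.0869 0.000117
```

These are grand mean effects on the Fisher-z scale with Wald 95% CIs: under
this configuration stressors depress diversity, abundance and decomposition
(truth: −0.3, −0.25 on the biodiversity channels plus an intensity slope of
−0.1 around a mean intensity of 0.5), while nutrient effects are near zero —
the fitted means recover the generator's truth within their standard errors.

```r
glance(report$sem$stressor_diversity$full)
#> # A tibble: 1 × 10
#>   fisher_C  C_df   C_p   AIC indirect_effect direct_effect n_measurements n_studies ...
#> 1     7.01     4 0.135  99.7          0.0822        -0.241             44        27
report$sem$stressor_diversity$mediation
#> # A tibble: 1 × 6
#>   supported reduced_C_p delta_AIC poor_reduced_fit reduced_not_better ...
#> 1 FALSE          0.0581      1.93 FALSE            TRUE
```

The full SEM fits well (C = 7.01, df 4, p = 0.135: the d-separation claims
are not rejected). On this 27-study subset the mediation test is not
triggered (reduced-model p = 0.058 just misses 0.05) — with ~40 measurements
the mediated signal of 0.42 × the diluted observed association sits at the
edge of detectability, which is the realistic operating regime the generator
is built to expose. `plot_funnel()`, `plot_intensity()`, `plot_forest()` and
`autoplot()` methods draw the standard diagnostics; `tidy()`/`glance()`
return broom-style tables; `write_report()` serialises every table to CSV
plus a JSON run-metadata file.

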