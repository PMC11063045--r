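# screendca

Accuracy evaluation and decision curve analysis for community disease
screening programmes.

Automated classifiers for blinding fundus diseases — age-related macular
degeneration (AMD), diabetic retinopathy (DR), pathologic myopia (PM) —
are evaluated in three steps that this package implements as composable
stages:

1. **Diagnostic accuracy.** Per-disease sensitivity, normal-fundus
   specificity and Youden's index *J = se + sp − 1*, from record-level
   predictions (`screening_metrics()`) or directly from published
   correct-count tables (`metrics_from_published()`).
2. **Model comparison.** Omnibus Pearson χ² (uncorrected,
   df = r − 1) or exact (Fisher / Freeman–Halton) tests on r×2
   correct/incorrect tables, gated Bonferroni post-hoc pairwise
   comparisons at α′ = α/k (`compare_models()`).
3. **Clinical utility.** Decision curve analysis on a hypothetical cohort:
   for threshold probability *p\_t*,

   NB(*p\_t*) = TP/n − *p\_t*/(1 − *p\_t*) · FP/n,

   with TP = nπ·se and FP = n(1 − π)(1 − sp) in closed form, compared
   against the treat-all and treat-none reference strategies
   (`build_curves()`, `dominance_intervals()`), single-disease or combined
   multi-disease screening (`combined_screening()`), and an empirical
   record-level route (`nb_empirical()`).

A seeded synthetic cohort generator (`cohort_spec()`, `classifier_spec()`,
`simulate_cohort()`) produces record tables with the exact statistical
structure the analysis assumes, so every stage is testable without any
screening dataset. `run_pipeline()` ties the stages together from one YAML
configuration with byte-reproducible outputs.

## Worked example

Three screening models evaluated on a community test set (bundled example
counts; 287 AMD, 337 DR, 151 PM, 1115 normal images):

```r
library(screendca)

met <- metrics_from_published(fundus_screening_counts())
render_table1_style(met)
#>     model      metric         AMD          DR           PM       normal
#>  RETFound sensitivity 75.96 (218) 95.25 (321) 100.00 (151)            /
#>  RETFound specificity           /           /            / 92.47 (1031)
#>   Model S sensitivity 61.32 (176) 78.93 (266)   59.60 (90)            /
#>   Model S specificity           /           /            /  77.67 (866)
#>   Model Y sensitivity 59.23 (170) 71.22 (240)  72.19 (109)            /
#>   Model Y specificity           /           /            /  73.63 (821)
```

Each cell is the display percentage with its correct count; `/` marks
metric/class pairs that do not apply. Are the three models' AMD
sensitivities distinguishable, and which pairs differ?

```r
tabs <- counts_by_class(fundus_screening_counts())
res <- compare_models(tabs$AMD, k_pairwise = 3)
res$omnibus
#> <comparison_result> pearson_chi2 [RETFound vs Model S vs Model Y]
#>   statistic = 21.09, df = 2
#>   p = 2.63e-05 (alpha' = 0.05)  *significant*

res$pairwise[, c("model_a", "model_b", "statistic", "p_value", "significant")]
#>    model_a model_b statistic  p_value significant
#> 1 RETFound Model S    14.277 1.58e-04        TRUE
#> 2 RETFound Model Y    18.325 1.86e-05        TRUE
#> 3  Model S Model Y     0.262 6.09e-01       FALSE
```

The omnibus test rejects (χ² = 21.09); the first model beats both
commercial models at the Bonferroni level α′ = 0.05/3, which do not differ
from each other. Finally, is deploying the best model worthwhile in a
population where the three diseases have prevalences 2.6%, 1.8% and 1.0%?

```r
ret <- subset(fundus_screening_counts(), model == "RETFound")
sens <- setNames(ret$correct / ret$total, ret$class)[c("AMD", "DR", "PM")]
spec <- with(subset(ret, class == "normal"), correct / total)

curves <- build_curves(list(RETFound = list(sens = sens, spec = spec)),
                       prevalence = c(AMD = 0.026, DR = 0.018, PM = 0.010),
                       setting_label = "urban")
dominance_intervals(curves)
#> # A tibble: 2 × 3
#>   strategy   lower upper
#>   <chr>      <dbl> <dbl>
#> 1 RETFound    0.01  0.39
#> 2 treat_none  0.4   0.99
```

Referring the subjects this model flags yields the highest net benefit for
every threshold probability from 1% up to 39%; above that, the rational
strategy is to refer no one. (These prevalences are illustrative — supply
measured ones for a real analysis.)

The whole flow also runs from a config file:

```r
cfg <- system.file("extdata", "example_config.yaml", package = "screendca")
run_pipeline(cfg, "outputs/")
```

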