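---
title: "Evaluating community screening models: accuracy, comparison and net benefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating community screening models: accuracy, comparison and net benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screendca)
```

# The problem

Community screening programmes for blinding fundus diseases — age-related
macular degeneration (AMD), diabetic retinopathy (DR) and pathologic myopia
(PM) — increasingly rely on automated classifiers that assign each fundus
image one of the disease labels or "normal". Deciding whether such a
classifier is worth deploying involves three distinct statistical questions,
and `screendca` implements each as a separate, composable stage:

1. **Accuracy** — per-disease sensitivity, normal-fundus specificity and
   Youden's index, from record-level predictions or directly from published
   correct-count tables.
2. **Comparison** — are several candidate models distinguishable at all
   (omnibus test), and which pairs differ once multiplicity is controlled
   (Bonferroni post-hoc)?
3. **Clinical utility** — decision curve analysis (DCA): does referring the
   subjects a model flags produce more *net benefit* than referring everyone
   or no one, across the range of risk thresholds clinicians actually hold?

A fourth component, the synthetic cohort generator, exists so that all of the
above is testable end-to-end without access to any screening dataset.

# Accuracy metrics and their display conventions

For a class with `correct` detected out of `total`, the package reports
`100 * correct / total` rounded **half-up** to two decimals — the convention
of printed clinical tables (`round()`'s half-to-even would print 0.125 as
0.12 where such tables print 0.13). The unrounded value is always carried in
an attribute and used by downstream computation.

Youden's index is J = sensitivity + specificity − 1. By default
`youden_index()` evaluates it on the *displayed* percentage scale (each
fraction first rounded half-up to the 2-decimal percentage), because that is
how published screening tables derive the J values they print next to their
percentages; `rounding = "none"` gives the raw-fraction variant. The two can
differ by one unit in the fourth decimal — e.g. 279/337 and 875/1115 give
0.6127 on the display scale but 0.6126 unrounded — so the convention is
explicit rather than silent.

```{r youden}
youden_index(483 / 502, 430 / 517)          # display convention
youden_index(483 / 502, 430 / 517, rounding = "none")
```

The default counting rule for a disease class (`positive_rule =
"exact_class"`) credits a detection only when the image is assigned its own
class; `"any_disease"` credits any non-normal assignment. Published per-class
tables are compatible with either reading, so the default follows the
stricter, class-specific interpretation and the alternative stays available
for sensitivity analyses.

`auc_trapezoid()` is a small generic utility (rank-statistic formulation,
exactly the trapezoidal ROC area with tie averaging); the package makes no
claim about any particular model's AUC.

# Comparing models

Models scored on the same image set form an r×2 correct/incorrect
contingency table per metric. The implemented procedure:

* **Omnibus**: Pearson chi-square without continuity correction, df = r − 1.
  The correction is deliberately disabled everywhere — recomputing published
  pairwise statistics from their counts matches the uncorrected statistic
  exactly and the Yates-corrected one not at all.
* **Selection rule**: the exact route (Fisher for 2×2, Freeman–Halton for
  r×2) is taken when any expected cell count falls below 5 or any observed
  cell is 0. Published analyses state "chi-square (or Fisher's exact)"
  without a rule; this inference reproduces every published method choice
  (the exact test appears exactly where a zero cell occurs), is standard
  contingency-table practice, and is overridable by calling either test
  directly.
* **Exact tests**: two-sided p by the point-probability (Irwin) rule — the
  sum of (multivariate) hypergeometric probabilities of all tables with the
  observed margins no more probable than the observed one. Exact enumeration
  is guarded at 10,000 admissible tables (counted by dynamic programming over
  the margins); beyond that a seeded Monte-Carlo p-value is available and
  must be requested explicitly.
* **Post-hoc**: pairwise 2×2 tests run only when the omnibus p < α
  (standard gatekeeping; published analyses do not state the gating, and all
  their omnibus tests reject, so the assumption is untestable against them),
  each judged at α′ = α/k. The default k = 3 matches three models; with
  `compare_models()` the default is the number of pairs.

```{r compare}
tabs <- counts_by_class(fundus_screening_counts())
res <- compare_models(tabs$DR, alpha = 0.05, k_pairwise = 3)
res$omnibus
res$pairwise[, c("model_a", "model_b", "statistic", "p_value", "significant")]
```

Note the last pair: p ≈ 0.02 is below 0.05 but above α′ = 0.0167, so it is
correctly reported as non-significant after Bonferroni correction.

# Decision curve analysis

At probability threshold $p_t$ — the disease risk at which a clinician is
indifferent between referring and not referring — the net benefit of a
referral strategy on a cohort of $n$ subjects is

$$\mathrm{NB}(p_t) \;=\; \frac{TP}{n} \;-\; \frac{p_t}{1-p_t}\,\frac{FP}{n},$$

true positives per person minus false positives per person down-weighted by
the threshold odds. For a test with sensitivity $se$, specificity $sp$ and
disease prevalence $\pi$ the closed form uses the expected counts
$TP = n\pi\,se$ and $FP = n(1-\pi)(1-sp)$, kept fractional (expected
persons); the empirical route counts actual records. Reference strategies:
treat-all ($se=1, sp=0$, crossing zero exactly at $p_t=\pi$) and treat-none
(identically zero). Thresholds are restricted to the open interval (0, 1):
the odds weight is undefined at 1, and at 0 the net benefit degenerates to
$TP/n$, which is reported by the treat-all limit rather than a grid point.
The default grid is 1% steps from 0.01 to 0.99, matching the granularity at
which dominance ranges are conventionally quoted; net benefit is per-person,
so the curves are invariant to $n$.

**Combined multi-disease screening.** Published decision curves for
"screen for any of the targeted diseases" do not state a combination rule.
The package's rule, isolated in `combined_screening()` so it can be swapped:
with mutually exclusive diseases, combined prevalence is
$\pi = \sum_d \pi_d$, combined sensitivity the prevalence-weighted mean
$\sum_d \pi_d\,se_d / \pi$ (each diseased subject is detected at its own
disease's rate), and combined specificity is the normal-class specificity
unchanged (a normal subject is a combined false positive exactly when
flagged with any disease). This is the unique rule consistent with the
generator's forward model, which is why the closed-form and record-level
routes can be cross-checked against each other.

```{r dca}
counts <- fundus_screening_counts()
ret <- subset(counts, model == "RETFound")
sens <- setNames(ret$correct / ret$total, ret$class)[c("AMD", "DR", "PM")]
spec <- with(subset(ret, class == "normal"), correct / total)

models <- list(RETFound = list(sens = sens, spec = spec))
prev_urban <- c(AMD = 0.026, DR = 0.018, PM = 0.010)
curves <- build_curves(models, prev_urban, setting_label = "urban")
dominance_intervals(curves)
```

**Prevalence parameters are inputs, not facts the package knows.** The
urban/rural prevalences shipped in the example configuration (urban: AMD
2.6%, DR 1.8%, PM 1.0%; rural: AMD 1.9%, DR 1.3%, PM 0.5%) are illustrative
placeholders chosen to be of realistic magnitude for adult fundus-disease
screening with the urban total above the rural one; any real analysis must
supply measured prevalences. Consequently the package treats published
dominance ranges (e.g. "thresholds from 2% to 40%") as qualitative behaviour
— a high-sensitivity model dominating from low thresholds up to a crossing
point, over a wider range where prevalence is higher — not as numeric
targets, which would require the exact prevalences behind them.

# The synthetic cohort generator

`draw_true_classes()` samples each subject's class independently with the
configured prevalences (remainder to normal); `apply_classifier()` applies
the operating point as a forward model. Defaults define the reference
conditions:

* **Mutually exclusive single-label classes**, mirroring the disjoint
  per-class denominators of screening test sets.
* **A missed disease case is predicted normal** (`miss_target = "normal"`).
  Cross-disease confusions are not modelled because per-class
  sensitivity/normal-class specificity tables contain no information about
  them; `miss_target = "uniform_other"` exists for sensitivity analyses.
* **A false-positive normal receives a disease uniformly at random**
  (`false_positive_target = "uniform"`); only "any disease vs normal" enters
  every implemented statistic, so the choice is immaterial but explicit and
  seeded.
* **One explicit seed per draw**, threaded with `withr::with_seed`; the
  caller's global RNG state is never touched, and identical (spec, seed)
  yields byte-identical tables.

What passing tests on this generator do **not** show about real data: no
intra-subject (two-eye) correlation, no image-quality gradient, no
prevalence uncertainty, and cross-disease error structure assumed away. The
generator validates the arithmetic and the sampling behaviour of the
analysis stages, not the epidemiology.

One geometry note for the cross-checks: the closed form for single-disease
screening treats every non-target subject as a potential false positive at
rate 1 − specificity. The default generator only misclassifies true normals,
so closed-form and record-level net benefit coincide (i) for combined
any-disease screening on a full multi-disease cohort, and (ii) for
single-disease screening on a cohort containing that disease alone, with
false positives directed to it. The test suite checks both at cohort size
100,000, where four propagated binomial standard errors bound the
discrepancy at every grid threshold.

# Numerical and design choices

* Rounding: half-up at 2 decimals (percentages) and 4 decimals (Youden),
  display only; unrounded values flow through all computation.
* Chi-square p-values via the upper tail of the chi-square distribution
  (`pchisq`); exact-test ties compared with a 1e-7 relative tolerance.
* Degenerate inputs fail loudly: zero column margins (chi-square undefined,
  the error suggests Fisher), classes absent from a record table (no silent
  0/0), empty record tables, thresholds at 0 or 1, prevalences summing
  to ≥ 1.
* Wilson score intervals are *not* included: confidence intervals for the
  operating points are out of the package's reporting scope, and adding an
  interval method invites misreading the printed points as interval
  estimates.
* Problem sizes in the test suite: cohorts of 100,000 for the
  parameter-recovery and DCA cross-checks (the conventional hypothetical
  cohort size, also where binomial noise is small enough for 4-SD bounds to
  be tight), a few hundred for behavioural checks, and exhaustive-oracle
  tables kept at n ≤ 200 (2×2) and ≤ 10 per row (r×2), where full
  enumeration is instant.

# The pipeline

`run_pipeline()` drives everything from one YAML configuration (see
`system.file("extdata", "example_config.yaml", package = "screendca")`):
counts mode starts from a published `model,class,correct,total` table;
simulate mode draws a shared cohort and scores every configured model on it.
Outputs (`metrics.csv`, `comparison.csv`, `curves.csv`, `dominance.csv`,
`summary.txt`) each begin with a `#` provenance line carrying the seed and
the config hash; reruns under the same configuration are byte-identical, and
a failing stage removes its partial outputs and names itself in the error.

# Known limitations

* No cost-effectiveness layer on top of net benefit, and no bootstrap or
  analytic confidence bands for decision curves.
* The multi-disease combination rule is an explicit modelling choice; real
  referral pathways (e.g. per-disease referral criteria) may differ.
* Eye-level clustering (two images per subject) is not modelled anywhere.
* Exact r×2 tests beyond the enumeration guard rely on Monte-Carlo
  approximation.
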