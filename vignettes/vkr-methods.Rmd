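---
title: "Virtual knee replacement case-control analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual knee replacement case-control analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkr)
```

## The scientific question

Surgical knee replacement (KR) is the accepted hard clinical endpoint for
disease-modifying osteoarthritis drug trials, but it is rare, slow, and
driven by many non-clinical factors (insurance, patient preference, surgeon
judgement). A *virtual* knee replacement (vKR) endpoint instead defines a
KR-like symptom state purely from patient-reported outcomes: a knee-year is
a vKR case when its KOOS pain and quality-of-life (QOL) scores fall into the
pattern that, in knees that actually underwent surgery, predicted the
operation. This package implements the full analysis that asks whether knees
reaching vKR case status lost femorotibial cartilage thickness faster in the
preceding years than closely matched low-risk control knees, and provides a
synthetic cohort generator so the entire pipeline is testable without access
to restricted cohort data.

## The decision rule

For a current-year visit $t_0$ with prior visit $t_{-1}$, the composite risk
score is

$$
S = \mathrm{KP}_{t_0} + 0.54\,\max(\mathrm{QOL}_{t_0},\mathrm{QOL}_{t_{-1}})
  - 1.06\,\lvert \mathrm{KP}_{t_{-1}} - \mathrm{KP}_{t_0} \rvert
    \cdot \mathbb{1}[\mathrm{KP}_{t_0} < \mathrm{KP}_{t_{-1}}],
$$

where KP is KOOS pain (0-100, higher = better). A knee-year is a case,
attributed to the following annual visit, when all of:

1. $S < 95.7$ (strict; the threshold corresponds to 90% specificity against
   never-replaced knees),
2. current KP and QOL are both strictly worse than baseline,
3. next-year KP and QOL are both worse than *or equal to* the current values.

Boundary conventions follow the rule's wording exactly: equal pain in
consecutive years routes to the "pain not worse" branch; condition 1 and 2
are strict, condition 3 non-strict. A knee-year with any of the four
required visits missing is *not evaluable* and never imputed, and a knee
with a surgical replacement by $t_0+12$ months is handled by the exclusion
cascade, not by the classifier.

`calibrate_threshold()` recovers a threshold from data as the lower
empirical $(1-\text{specificity})$-quantile (an order statistic, no
interpolation), which guarantees an achieved false-positive rate of at most
$1-\text{specificity}$ and converging to it from below as $n$ grows.

**Maintenance at 72 months.** The verbal notion of "maintained pain and
QOL levels" one year after reaching case status does not pin down a
formula. We re-apply the sustainment comparison (condition 3)
one cycle on: a month-60 case is vKR+/+ iff
$\mathrm{KP}_{72}\le \mathrm{KP}_{60}$ and
$\mathrm{QOL}_{72}\le \mathrm{QOL}_{60}$. The choice is isolated in
`maintenance_status()` so an alternative (e.g. additionally requiring the
score threshold at $t_0 = 60$) can be slotted in.

**Percentile populations.** The 10%/20% case/control fractions are defined
over the cross-section of cascade-eligible knees scored at the defining
visit $t_0$ (48 months for month-60 cases). The reference population for
these percentiles is a design choice; the threshold 95.7 itself encodes the
high-risk cut, so `select_cases()` uses the threshold and
`select_controls()` the empirical 80th percentile of the scored eligible
population.

## Selection and matching

The exclusion cascade removes, in order: KR before 12 months, no 12-month
follow-up, no continuous health coverage, insufficient baseline KOOS data,
and no central baseline Kellgren-Lawrence (KL) reading. Each knee is removed
at the first step that applies, so counts reconcile exactly; the pipeline
writes a per-knee machine-readable exclusion log.

Matching is greedy 1:1 without replacement: cases in ascending knee-id
order; exact strata on sex, KL stratum (0-1, 2, 3, 4) and the dominant
joint-space-narrowing compartment (medial / lateral / both, plus "none"
for knees with no narrowing, which only matches "none"); within a stratum
the unused control minimising the baseline age difference within a +/-5 year
caliper is taken, ties broken by a seeded draw. Greedy matching (rather than
optimal assignment) was chosen because it is auditable, the matching design
is specified by its constraints rather than an algorithm, and the unmatched
fraction is itself a reported quantity. Age is age at baseline.

## Cartilage metrics

Sixteen femorotibial subregions (5 per tibial plateau, 3 per weight-bearing
femoral condyle) carry mean cartilage thickness in micrometres. Plate values
are weighted means of their subregions -- equal weights by default, because
subregion areas are not part of the data model, with a weight hook for users
who have them -- and compartment aggregates are tibial + femoral sums:
cMFTC = cMT + ccMF, MFTC = (medial tibial plate) + (central medial femoral
plate), with lateral analogues. Interval changes are simple differences
(loss negative); radiographic minimal joint-space width is converted from mm
to micrometres in exactly one function (`mjsw_change()`).

The location-independent thinning (thickening) score is the sum of the
negative (positive) subregion changes, so thinning + thickening equals the
total summed subregion change by construction. A smallest-detectable-change
threshold is exposed (`sdc`, default 0: every change counts) for users who
have a measurement-error estimate for their reader workflow.

Missing or unreadable images make a change undefined; analyses are
pairwise-complete per variable (the matched pair is dropped for that
variable only), with the per-variable complete-pair `n` reported per row.

## Matched-pair statistics

Per region and interval the package reports group means/SDs, a paired
t-test, and a 1:1 conditional logistic regression. The conditional
likelihood of the matched design is

$$
L(\beta)=\prod_j
\frac{e^{\beta^\top x_{\mathrm{case},j}}}
     {e^{\beta^\top x_{\mathrm{case},j}}+e^{\beta^\top x_{\mathrm{ctrl},j}}},
$$

equivalent to an intercept-free logistic model on within-pair differences
with all outcomes 1. `clogit_1to1()` maximises it by Newton-Raphson to a
gradient norm below $10^{-10}$ (with step halving only on decreases that are
resolvable at double precision). The exposure is cartilage *loss* divided by
the control-group SD of the same variable and interval, so $e^{\beta_1}$ is
an odds ratio per control-SD and OR > 1 means greater loss in cases.
Complete separation (all within-pair differences of one sign) is reported as
an error, never patched by penalisation.

Two covariances are computed: the model-based inverse observed information,
and the sandwich $A^{-1}BA^{-1}$ where $B$ sums pair-level score
contributions $(1-\sigma_j)d_j$ over clusters of pairs connected through a
shared participant. Participants can contribute two case knees (or two
control knees) to different pairs; such pairs are dependent and land in one
cluster. With all participants distinct the estimator reduces to the
ordinary independent-pairs sandwich. We deliberately cluster whole pair
scores rather than splitting them into per-knee residuals: the split
discards the within-pair covariance between the case and control
contributions and, in our clustered simulations, under-covered the sampling
variance of $\hat\beta$ by roughly 20%, while the pair-cluster version
tracks it within 10% (this is also exactly what `survival::clogit` computes
when both members of a pair are assigned the pair's cluster). Confidence
intervals are Wald on the log scale with $z=1.96$.

The BMI-adjusted variant appends within-pair differences of overweight and
obese indicators, with half-open WHO bounds ($[25,30)$, $\ge 30$; normal is
the reference), BMI taken at the start of the observation interval (falling
back to the closest earlier visit). The maintenance sensitivity analysis
compares vKR+/+ and vKR+/- knees with a two-group Kruskal-Wallis test
(mid-ranks, tie-corrected, $\chi^2_1$ p-value); when every value is
identical the statistic is 0 with p = 1 rather than an error.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes,
not any real cohort's demographics:

* **Latents.** Each knee has a symptom latent $z_s$ (correlation
  `within_person_corr` = 0.4 between a participant's knees) and a structural
  latent $z_c = \rho z_s + \sqrt{1-\rho^2}\,\varepsilon$ with
  $\rho$ = `symptom_structure_corr` = 0.9. The top `progressor_fraction`
  (default 0.10, matching the high-risk selection fraction) of each latent
  defines symptom progressors and structurally case-like knees. Setting
  $\rho = 0$ decouples cartilage loss from symptoms entirely, which the
  tests exploit.
* **Symptoms.** KOOS pain/QOL follow a participant-level random intercept
  plus a slow linear decline; progressors additionally lose roughly 20-25
  points between months 36 and 60, which is what creates first-time vKR
  cases at the month-60 assessment. After month 60 a progressor sustains its
  level with probability `maintain_prob` (0.55, reflecting the near-even split of
  sustained versus non-sustained cases seen in such cohorts) or rebounds,
  producing the vKR+/+ / vKR+/- split.
  Visit-level Gaussian noise (SD 2.5 points) is added last; values are then
  clipped to [0, 100] and the number of clipped values is recorded --
  truncation bias at the bounds is accepted and visible in `$n_clipped`.
* **Cartilage.** Annual subregion increments are Gaussian. The two central
  medial subregions split the configured two-year cMFTC change (47% cMT /
  53% ccMF, the approximate tibial/femoral ratio of central medial loss in
  osteoarthritic knees) with
  per-increment SD set so the four independent increments of a two-year
  cMFTC change reproduce the configured SD exactly. Group means/SDs default
  to summaries representative of knees approaching replacement-level
  symptoms versus low-risk knees (-151 +/- 337 vs -38 +/- 249 micrometres
  over two years). Peripheral and lateral subregions progress at fixed
  fractions of the central medial rate. Radiographic mJSW declines
  analogously on the mm scale.
* **Events.** Surgical KR probability is logistic in $z_s$ (about 2-3% of
  knees), with the knee's data truncated after the replacement month, so
  threshold calibration has true positives to work with. KL grades follow
  the configurable `klg_probs` (defaulting to a distribution typical of a
  high-risk symptomatic group: 0.26, 0.06, 0.26, 0.28, 0.14 for grades
  0-4); JSN grades are derived from the KL grade with noise.
* **Reproducibility.** Every participant draws from a seeded substream of
  the root seed, so identical configurations are byte-identical and growing
  the cohort never perturbs existing participants. Missingness
  (`inject_missingness()`) marks PRO visits and cartilage images
  independently with `missing_visit_prob`, never at month 0, using per-knee
  substreams.

What the generator does *not* emulate: realistic recruitment demographics,
femoropatellar disease, reader/processing batch effects, informative
missingness, or serial correlation of measurement error. Passing tests
therefore demonstrate the *pipeline's* correctness and calibration under the
assumed structure, not agreement with any real cohort's numbers; reported
group summaries enter only as generator defaults and sign/magnitude
fixtures. Within-knee and within-pair serial correlations of cartilage
change are rarely reported, so they are free parameters rather than
asserted values.

## Numerical conventions

* Empirical quantiles in `calibrate_threshold()` and `select_controls()` are
  order statistics (type-1, no interpolation); the control cutoff keeps
  exactly $\lfloor 0.2 n \rfloor$ knees when scores are distinct, more under
  ties.
* Newton iteration: start at 0, gradient-norm tolerance $10^{-10}$, at most
  100 iterations, divergence (|beta| > 50) and non-positive covariance
  diagnostics reported as errors; reciprocal condition numbers below
  $10^{-10}$ are treated as singular.
* Matching ties (equal age gaps) are broken by a seeded uniform draw so runs
  are reproducible end to end.
* Degenerate inputs error loudly: paired t with constant differences, empty
  score vectors, non-positive scale SDs, `t0 = 0` (no prior visit).

## Problem sizes in the shipped tests

The test suite exercises the classifier on the exhaustive 21^4 grid of
5-point KOOS values (194,481 knee-years, against an independently coded
flowchart transcription), calibrates the generator on cohorts of 2,500
participants, checks threshold specificity on 10,000 simulated knee-year
scores, verifies the conditional-logistic estimator against brute-force
likelihood maximisation on small instances and parameter recovery at 10,000
pairs, the sandwich against 500 clustered replicates, test size under the
null at 1,000 replicates, and effect recovery at 200 replicates of 500
matched pairs drawn from the generator's increment model. These sizes were
chosen so Monte-Carlo error is comfortably below the asserted tolerances.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(sim = sim_config(n_participants = 500, seed = 1), seed = 1)
res <- run_pipeline(cfg, tempdir())
res$results[res$results$variable == "cMFTC" & res$results$from_month == 24 &
              res$results$to_month == 48, ]
```

## Known limitations

* The mapping between the score threshold and the "highest 10% predicted
  probability" treats score rank as probability rank (lower score = higher
  risk); the underlying probability model is external to this package.
* Greedy matching is order-dependent by construction; the order (ascending
  knee id) is documented and deterministic.
* The sandwich estimator is asymptotic in the number of pair clusters; with
  very few clusters its usual downward small-sample bias applies.
* Equal subregion weights within plates are a simplification; supply
  area weights via `region_spec()` when available.
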