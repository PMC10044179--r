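---
title: "Personalised Advantage Index pipelines for psychotherapy allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalised Advantage Index pipelines for psychotherapy allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paialloc)
```

## The problem

Cognitive-behavioural therapy (CBT) and person-centred counselling for
depression (CFD) are the two most common high-intensity psychotherapies
offered in English primary-care mental-health services, and on average they
work about equally well. The interesting question is not *which treatment is
better* but *for whom each is better*: if some patients respond better to
CBT and others to counselling, allocating each patient to their better
treatment could improve outcomes at scale without any new treatment.

`paialloc` implements the Personalised Advantage Index (PAI) approach to
this question on routinely collected electronic healthcare records, where
the outcome is the nine-item Patient Health Questionnaire (PHQ-9, range
0--27, caseness cut-off $\ge 10$) measured at the last attended appointment.
Because real service records of this kind cannot be shared, the package
includes a first-class synthetic cohort generator with known ground truth,
so every stage of the pipeline is testable and its statistical properties
can be verified by simulation.

## The model

For patient $i$ with baseline covariates $x_i$ (sixteen sociodemographic and
clinical characteristics), service $s_i$, referral year $t_i$ and treatment
$T_i \in \{\mathrm{CFD}, \mathrm{CBT}\}$, the *prediction model* is a linear
regression fitted on the training partition:

$$
y_i = \beta_0 + x_i^\top \beta
    + \mathbb{1}[T_i = \mathrm{CBT}]\,(\tau + x_i^\top \gamma)
    + \alpha_{s_i} + \delta\, t_i + \lambda\, \hat e_i + \varepsilon_i ,
$$

where $y_i$ is the post-treatment PHQ-9, $\tau$ is the treatment main
effect, $\gamma$ are treatment-by-covariate interactions (moderation), and
$\hat e_i$ is the estimated propensity score. Every baseline characteristic
enters both as a main effect and interacted with treatment; service, year
and the propensity score enter as main effects only.

Allocation in routine care is not random, so the propensity score
$\hat e_i = \hat P(T_i = \mathrm{CBT} \mid x_i, s_i, t_i)$ is estimated by
logistic regression and added to every outcome model as a covariate in
addition to the regression adjustment: a doubly robust design. No trimming,
matching or weighting is applied; the score is only ever a covariate.

On the held-out test partition each patient is scored twice, once under each
treatment label, giving a *factual* prediction (under the received
treatment) and a *counterfactual* prediction. The PAI is

$$
\mathrm{PAI}_i = \hat y_i(\mathrm{CFD}) - \hat y_i(\mathrm{CBT}),
$$

so positive values favour CBT (its predicted score is lower) and the
magnitude is the predicted benefit of the favoured treatment in PHQ-9
points. The treatment with the lower prediction is the *optimal* treatment.
Patients whose PAI lies beyond the first or third quartile of the test-set
PAI distribution form the high-PAI half of the sample; within it, those who
actually received their indicated treatment form the *optimal* group and
the rest the *suboptimal* group. The two groups are compared on observed
outcomes: mean post-treatment PHQ-9 (simple linear regression, whose
coefficient is exactly the difference in means) and five clinical metrics
(simple logistic regression, whose fitted odds ratio is exactly the 2x2
cross-product odds ratio):

* **recovery** -- post-treatment score below the caseness cut-off
  (post $< 10$; depression-only adaptation of the service definition);
* **reliable change** -- improvement at or beyond the 6-point PHQ-9
  reliable change threshold;
* **reliable recovery** -- both of the above;
* **percent MCID** -- improvement of at least 20% of the baseline score;
* **absolute MCID** -- improvement reaching a severity-band-specific point
  threshold.

A companion *main-effects (treatment) model* -- same design without
interactions, plus the number of attended appointments as a dose adjustment
-- estimates the average CBT-vs-CFD effect, to verify the two treatments are
close to equivalent on average (the setting in which differential
allocation is worth considering at all).

## The synthetic cohort generator

`generator_config()` fixes the ground truth of a simulated service cohort;
`generate_cohort()` samples it in four seeded stages (baseline covariates,
propensity-driven treatment, linear-model outcomes, missingness). What it
emulates, and the default conditions:

* **Covariate marginals** mirror a clinical-depression service population:
  mean age 40 (SD 13), 67% female, ~80% White, mean baseline PHQ-9 18
  (SD 4, rounded and clipped to 0--27), GAD-7 14, WSAS 23, deprivation index
  centred on 21, ten services, referral years 2012--2019. The published
  literature gives marginals, not a joint distribution, so covariates are
  sampled independently unless configured otherwise -- a known divergence
  from real records, where baseline severity measures correlate strongly.
  One visible consequence: mask-and-score imputation error (NRMSE) for a
  covariate that is independent of everything else sits near 1 by
  construction, so the generator's global NRMSE is higher than a real
  cohort's would be.
* **Confounded allocation**: treatment is Bernoulli with logistic
  probability on the baseline design. Defaults give roughly 75% CBT, with
  more severe, medicated, self-referring, repeat-referral patients likelier
  to receive CBT -- the severity-driven allocation pattern seen in routine
  data.
* **Outcomes**: linear predictor plus Gaussian noise (`noise_sd`, default
  5.5 PHQ-9 points, chosen to match the observed ~6.4-point spread of
  prediction discrepancies in service data), then rounded and clipped to
  the 0--27 instrument range. Rounding happens after noise because the
  instrument is integer-valued. `round_outcomes = FALSE` exposes the latent
  continuous outcome for exact-identification studies: with rounding, a
  noise-free fit recovers coefficients only approximately, and the
  `expected_outcome(integer_scale = TRUE)` oracle integrates the Gaussian
  noise over the rounded, clipped grid when exactness on the integer scale
  is needed.
* **Moderation**: default interactions are `medication = -0.8` (medicated
  patients do better in CBT) and `employment not_working = +0.8` (patients
  out of work do better in counselling) -- the two moderators with any
  empirical support, at magnitudes small enough that individual-level
  benefit rarely reaches a clinically important difference, which is the
  substantive regime of interest. The default treatment main effect is
  -0.1: near-equivalence.
* **Missingness**: missing-completely-at-random per-column rates on a
  subset of baseline covariates (5--15%, demographics less complete than
  symptom scores), with an optional missing-at-random hook driven by a
  complete covariate. Treatment and outcomes are never made missing:
  missing outcomes are an exclusion criterion, not an imputation target.

`true_pai()` returns the generating-model PAI in closed form, and
`expected_outcome()` the expected recorded outcome under either treatment;
together they provide the oracle every pipeline property is tested against.

What passing simulations do **not** show about real data: robustness to
correlated covariates, informative missingness, service-level outcome
heterogeneity beyond an exchangeable service factor, session-by-session
trajectories, or unmeasured confounding. The generator's treatment
assignment depends only on observed covariates, so the doubly robust
adjustment is, by construction, sufficient in simulation; in real records
it cannot rule out hidden confounding.

## Cohort selection, partitioning, imputation

`apply_selection_filters()` applies the cohort definition in a fixed order,
logging attrition per rule: baseline PHQ-9 $\ge 10$ (inclusive); majority
high-intensity therapy is CBT or CFD, exact session-count ties excluded; at
least two attended appointments; most recent referral per patient; and a
recorded outcome at the last attended appointment. The order affects only
per-rule counts, never the final cohort, and the filters are idempotent.

`split_train_test()` performs a simple random 3:1 split before any
analysis; `check_balance()` verifies it with standardised mean differences
(continuous: mean difference over the average-variance pooled SD; binary:
proportion difference over the pooled binomial SD; multi-level categoricals:
the maximum over one-vs-rest binary SMDs, a conservative reduction) against
the conservative 0.1 threshold. At the ~19k scale of the motivating data a
random split passes this essentially always; at a few thousand records it
can fail by chance, in which case the pipeline warns and proceeds.

`impute()` is an iterative chained random-forest imputation for mixed-type
data: missing cells are initialised with the column mean/mode, then columns
are cycled in order of increasing missingness, each refitted as a
500-tree forest (ranger) on its observed rows with all other covariates
plus service and year as predictors, until the column-wise change in
imputed values increases for both the continuous and the categorical sets
(the previous sweep is kept), or ten sweeps. Candidate-split counts follow
the canonical forest defaults ($p/3$ regression, $\sqrt p$ classification).
0/1 indicator columns are imputed as two-level classification targets so
imputed cells only take observed values. Imputation runs separately on the
training and test partitions. Error is estimated by mask-and-score in the
same pass: 10% of observed cells in each column under imputation are
hidden, imputed alongside the truly missing cells, scored -- NRMSE
$=\sqrt{\mathrm{MSE}/\mathrm{Var}}$ pooled over continuous masked cells
(an uninformative imputation tends to 1), PFC the proportion of falsely
classified categorical cells -- and then restored, so observed data are
never altered.

## Numerical and design choices

* **Quartile rule**: linear-interpolation sample quantiles (R type 7) on
  the *test-set* PAI distribution; ties at a boundary fall into the
  no-preference set, so the high-PAI set never overshoots 50%. An exact PAI
  of zero indicates no preference regardless of the quartiles.
* **Confidence intervals** on model coefficients are normal-approximation
  (estimate $\pm 1.96$ SE); group contrasts use the t-based interval of the
  simple regression they come from.
* **Reference levels** are the most frequent category of each factor, and
  moderator profiles (`moderator_profile()`) hold all other covariates at
  the training mean/mode, profiling continuous moderators at mean and mean
  $\pm 1$ SD and 0/1 indicators at their two values. Predictions are
  invariant to reference-level choice.
* **Unseen categorical levels** at prediction time map to the reference
  level with a warning; dropping records would silently change
  denominators.
* **Dose**: the number of appointments is adjusted for in the treatment
  model, but excluded from the prediction model by default
  (`include_dose_in_prediction`) because dose is unknown at allocation
  time.
* **Degenerate inputs** fail loudly and specifically: rank-deficient
  designs name the aliased terms, separation in the propensity model names
  the cause, zero cells in an odds ratio are flagged rather than silently
  corrected, and an all-missing table is an imputation error.
* **Seeds**: every stochastic stage derives its seed from the master seed
  through `stage_seed()` (a fixed counter scheme), making full runs
  bit-reproducible; artifact directories include an MD5 manifest.
* **MCID band table**: the absolute-MCID thresholds default to 3 points for
  baseline 10--14 and 5 points for 15--27. These are package defaults
  chosen to be clinically plausible over the eligible range; published band
  tables vary, and the table is a required, documented input rather than a
  fixed constant.

## Simulation evidence and problem sizes

`simulation_study()` wraps the replicated experiments the test suite runs:
under a null scenario (no treatment effect, no moderation) the 95% CI of
the optimal-vs-suboptimal difference covers zero at its nominal rate and
the joint interaction LRT holds its size; under a strong-moderator scenario
the observed group difference tracks the oracle expectation computed from
`true_pai()`/`expected_outcome()` within Monte-Carlo error, and the LRT
detects the moderation. The shipped experiments use 100 replicates of
cohorts of 2,000 (pipeline properties) and single cohorts of 6,000--20,000
(parameter recovery, balance rates), sizes at which each property's
Monte-Carlo error is small relative to the effect being checked while a
full run stays interactive. Replicated scenarios omit baseline missingness:
imputation quality has its own dedicated contracts, and chaining 500-tree
forests inside every replicate would test nothing further.

## Limitations

The package evaluates *model-indicated* allocation retrospectively; it does
not estimate what would happen under a policy change, which needs a
randomised evaluation. The clinical metrics are depression-only adaptations
(the combined depression-plus-anxiety service definitions are out of
scope). The generator's independence and linearity assumptions are exactly
the assumptions of the analysis model, so simulations validate internal
consistency, not robustness to misspecification. And with moderation of
realistic (small) magnitude, individual-level predicted benefits rarely
exceed a minimal clinically important difference -- the method's value, if
any, is at the population scale.
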