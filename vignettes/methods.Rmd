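---
title: "Models and methods in volatileRL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in volatileRL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(volatileRL)
```

This vignette is the package's account of its science: the task and
observation models it implements, the estimation machinery, the synthetic
cohort the validation suite runs on, and the numerical and design choices
that were genuinely open.

## The task

The paradigm is a two-alternative probabilistic associative-learning task
with 180 trials in two blocks. In the *stable* block (80 trials) one shape
carries a 75% reward probability and the other 25%, constant throughout.
In the *volatile* block (100 trials) the assignment is 80/20 and reverses
every 20 trials. `task_design()` holds these constants; `make_schedule()`
realizes a schedule.

Two modelling commitments are built into the generator:

* **Coupled outcomes.** Exactly one shape is rewarded per trial, by a
  single Bernoulli draw with the block's high-shape probability. The
  printed contingencies are complementary (75/25, 80/20), which is the
  signature of coupled reversal-learning schedules; independent per-shape
  draws would produce trials where both or neither shape is rewarded and
  different marginal statistics.
* **Deterministic reversal trajectory.** The identity of the
  high-probability shape over trials is a pure function of the design;
  only the outcome draws consume randomness. Schedules with the same seed
  are bit-identical, and different seeds share the same reversal
  structure, which keeps Monte-Carlo comparisons across seeds aligned.

No-response trials are not simulated: model agents always respond. Loaders
for real data drop invalid trials before fitting (`read_trial_table()`
reports the count it removed).

## Observation models

All three models share the softmax choice rule
`P(A) = 1/(1 + exp(-beta (v_A - v_B)))`, computed via `plogis` so it is
shift-invariant and does not overflow for any realistic drive (the
contract covers `|beta (v_A - v_B)| <= 700`).

* **RP (reward–punishment)**: the chosen shape's expected value moves
  toward the outcome by `alpha_pos` after reward and `alpha_neg` after
  non-reward; the unchosen value is carried over unchanged. The update
  branch is selected by the realized outcome (reward vs. none), not by the
  sign of the prediction error — with values in [0, 1] and binary outcomes
  these coincide anyway.
* **RW (Rescorla–Wagner delta)**: the single-rate special case
  `alpha_pos = alpha_neg`; the implementation enforces the tie, and the
  test suite checks RP and RW produce identical likelihoods at equal
  rates.
* **EWA (experience-weighted attraction)**: an experience weight
  `n <- rho n + 1` and chosen-value update
  `v <- (phi n_prev v + R) / n`. This follows the parameterization used by
  the hierarchical-Bayesian RL fitting packages that popularized the model
  trio for this task family; the original reference for the paradigm does
  not print the EWA equations in its main text, so the convention is
  adopted explicitly rather than inferred.

**Initial values** are `v_A = v_B = 0.5`, the midpoint of the binary
outcome scale. The first-choice probability is 0.5 regardless of `v0`, but
later dynamics are not; 0.5 makes the first prediction error symmetric
between reward and punishment. `v0` is exposed as an argument on every
function that consumes it.

## Hierarchical estimation

Fits are performed per treatment × context cell — four independent fits —
matching how the parameters are compared downstream (each cell contributes
one parameter estimate per subject to the 2×2 mixed ANOVA).

Per model parameter there is a group-level location `mu ~ N(0, 1)` and
scale `sigma ~ N(0, 0.2)` on the unconstrained scale. Because a scale
cannot be negative, the sigma prior is interpreted as half-normal
(truncated at zero), which is the standard convention when a normal prior
is quoted for a lower-bounded scale. Subject-level deviates are
non-centered (`theta_s = mu + sigma z_s`, `z_s ~ N(0,1)`), which keeps the
sampler well-behaved when `sigma` is small, and are mapped to the native
range through the standard-normal CDF: learning rates and decays to
[0, 1], the inverse temperature to `[0, beta_max]` with `beta_max = 10` by
default (exposed in `fit_config()`).

Sampling uses JAGS through `rjags`. Chain RNGs are derived
deterministically from the configuration seed, so a fit is bit-identical
given the same seed. Convergence is *reported, not enforced*: `split_rhat()`
implements the classic split-half potential scale reduction factor and
`fit_hierarchical()` attaches it for every monitored parameter; values
below 1.1 are the conventional pass. Constant draws make the diagnostic
undefined and return `NA` rather than an error.

**Pointwise log-likelihood granularity.** The leave-one-out unit is the
subject: each column of the stored log-likelihood matrix is a subject's
summed trial log-likelihoods. Subjects are the exchangeable unit of the
hierarchical model, so subject-level LOO answers the model-comparison
question actually asked ("which observation model generalizes to a new
subject"). With 15-subject cells and a few hundred draws the Pareto k
diagnostics are often high — that is the honest behaviour of
importance-sampling LOO with few, large units, and `psis_loo()` attaches a
warning when more than half the units exceed k = 0.7.

`psis_loo()` implements Pareto-smoothed importance sampling: the largest
20% (capped at `3 sqrt(S)`) of the importance ratios are replaced by
generalized-Pareto quantiles fitted by the profile-likelihood method with
a weakly-informative shape prior, then capped at the raw maximum.
`LOOIC = -2 elpd_loo` is reported on the deviance scale; lower is better.
`compare_models()` refuses to compare fits whose input data hashes differ.

## The synthetic cohort

`default_effect_config()` encodes the qualitative effect pattern the
analysis is meant to detect: learning rates higher under volatility in
both groups; a drug (OT) advantage in reward learning rate only in the
volatile context; a punishment-learning-rate advantage in the volatile
but a disadvantage in the stable context; choice consistency higher in the
stable context with a drug advantage there only. The numeric cell means
(e.g. reward learning rate 0.15 stable / 0.45 volatile in the OT group)
are implementation choices with moderate effect sizes — the emulated study
prints no native-scale means — and only the orderings are anchored to it.
Within-cell dispersions are likewise unpublished; the defaults (SD 0.1 for
rates, 1.0 for the inverse temperature) are guesses exposed in the spec
object.

Subject parameters are drawn from normals truncated to the native ranges —
chosen over logit-normals for transparency: the spec means are directly
interpretable as approximate cell means. Trait anxiety is a unit-scaled
Gaussian score coupled to a latent choice-consistency deviate shared
across contexts through a Gaussian copula at correlation −0.27 (negative:
more anxious subjects choose less consistently), so the anxiety–beta
correlation holds in both contexts. No attempt is made to mimic
questionnaire score ranges.

ERP epochs are sums of Gaussian-bump component templates and white
Gaussian noise (an optional artifact injector adds ±100 µV excursions for
testing the rejection path). Injected group means use published values
where available: P300 3.75 (OT) vs 5.57 (PLC) µV, N2pc difference −0.29 vs
0.18 µV; ERN/FRN injections are symmetric across groups (the emulated
study found no treatment effect there). Bump centers sit on the 250 Hz
sample grid inside each component's measurement window so that noiseless
extraction is exact. White noise is the default (a 1/f option was
considered and dropped: the validation suite gains nothing from colored
noise while losing the analytic error bounds).

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: no response times, no no-response trials, no
block-order counterbalancing effects, no EEG preprocessing artifacts
(filtering distortions, ICA residuals, channel noise correlations), no
overlapping ERP components, and subject parameters that are truly
exchangeable within cell (real subjects are not). The suite validates the
*pipeline*, not the physiology.

## Group statistics

`mixed_anova_2x2()` delegates the sums-of-squares decomposition to
`stats::aov` with an `Error(subject)` stratum and reports
`partial eta^2 = SS_effect / (SS_effect + SS_error)` with each effect's own
error term; the test suite cross-checks it against an independent
cell-means decomposition. A Greenhouse–Geisser correction is a
pass-through here: a two-level within factor satisfies sphericity
trivially (epsilon = 1), and a note on the result records this. Post-hoc
simple effects carry no multiplicity correction (none is specified in the
reporting style being mirrored). The Spearman/Pearson choice is an
explicit argument, not automated normality screening; both p-values come
from the t approximation. For the Fisher z comparison of independent
correlations the subtraction order is the caller's: the two worked
examples in the validation suite use opposite orders, and rather than
guess a convention the function documents that swapping the pairs negates
z.

Zero-variance edge cases are defined rather than accidental: a zero-SS
ANOVA effect reports F = 0 even against a zero error term; an independent
t-test of two identical constant samples reports t = 0, p = 1, while
constant samples with unequal means raise an error.

## ERP measurement rules

"Voltage values exceeding ±80 µV" is read as a strict inequality: an epoch
touching exactly ±80 µV is retained. Peaks are signed extrema of the
stated polarity (minimum for ERN/FRN/N2pc, maximum for P300), not
rectified maxima, with ties broken by the earliest latency. Difference
components (ERN, FRN) default to the *peak of the difference wave* —
matching standard practice and the difference-waveform topographies the
paradigm reports — with the alternative reading (difference of
per-condition peaks) behind `peak_mode = "peak_difference"`. The N2pc
baseline is the full −100–0 ms pre-stimulus span of its epoch, since no
explicit baseline is printed for that component. All scoring is per
subject; grand-average inference belongs to the statistics layer.

## Validation problem sizes

The test suite's heavier checks run at sizes chosen to make each property
measurable while keeping the default run short:

* Convergence: one RP fit of a 15-subject × 80-trial stable cell, 4 chains,
  500 warmup + 500 draws (max group-level split-R̂ ≤ 1.1).
* Parameter recovery: ten 15-subject × 80-trial *volatile* cells sweeping
  generative means across the plausible range (reward rate 0.15–0.60,
  punishment rate 0.50–0.10, inverse temperature 2.5–6; SD 0.15/1.25),
  fitted with 2 chains, 300 + 300 draws. Volatile schedules are used
  because reversals are what identify learning rates — on a never-reversing
  block, converged behaviour is nearly alpha-invariant and subject-level
  recovery correlations are weak for any estimator — and sweeping the means
  is the standard design for a recovery study (recovery is judged across
  the parameter range, not at a point). Coverage is assessed on the
  model's native group-mean parameter (the CDF-transformed location).
* Model recovery: four RP-generated cells with clearly distinct learning
  rates, fitted by RP, RW and EWA; LOOIC must rank RP best in at least 3.
* ERP recovery: fixed injected amplitudes at noise SD 1 µV and 60
  epochs/condition over 20 seeds, with the ±0.5 µV band applied to the
  per-replicate recovered component score (subject-averaged amplitude);
  group orderings are checked at the full 37/36 cohort size with the
  published between-subject SDs.
* Null calibration: 200 null-cohort replicates; the treatment-effect
  p-value distribution must pass a KS uniformity test at alpha = 0.01.

## Known limitations

* JAGS's slice sampler needs more iterations than a gradient-based sampler
  would for the same effective sample size; the default 4 × (1000 + 1000)
  is comfortable for cell sizes up to the study scale but fits of much
  larger cohorts will be slow.
* Subject-level LOO with small cells yields high Pareto k diagnostics;
  LOOIC differences should be read alongside them.
* The EWA implementation follows one published parameterization; other EWA
  variants (e.g. with a payoff-sensitivity exponent) are out of scope, as
  are models with perseveration kernels, lapse rates, or volatility
  tracking.
* The optional loader path for real study data is untested against the
  original deposit; column conventions follow the package's own writers.
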