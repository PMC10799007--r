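# volatileRL

Reinforcement learning under stable and volatile reward contingencies: a
simulation and analysis toolkit for two-group (drug vs. placebo)
pharmaco-EEG studies of probabilistic associative learning.

## The problem this package addresses

In probabilistic reversal-learning paradigms, subjects repeatedly choose
between two shapes whose reward contingencies are either **stable** (one
shape rewarded on 75% of trials throughout an 80-trial block) or
**volatile** (an 80/20 contingency that reverses every 20 trials across a
100-trial block). Learning in such tasks is summarised by a trial-by-trial
reinforcement-learning model — here the dual-learning-rate
**reward–punishment (RP) model** — fitted hierarchically per treatment ×
context cell, and by event-related-potential (ERP) features extracted from
epoched EEG. The package implements that full analysis chain and a
synthetic-data generator that emulates the study structure (two groups of
37 and 36 subjects, context-dependent parameter effects, a trait-anxiety
covariate, and injected ERP components), so the pipeline's statistical
behaviour can be validated end to end.

## The model

Expected values of the two shapes start at `v = 0.5` and only the chosen
shape's value is updated:

```
v_chosen(t+1) = v_chosen(t) + alpha_pos * (R(t) - v_chosen(t))   after reward (R = 1)
v_chosen(t+1) = v_chosen(t) + alpha_neg * (R(t) - v_chosen(t))   after non-reward (R = 0)
v_unchosen(t+1) = v_unchosen(t)
```

with a softmax choice rule

```
P(A) = 1 / (1 + exp(-beta * (v_A - v_B)))
```

`alpha_pos`/`alpha_neg` in [0,1] are reward and punishment learning rates;
`beta >= 0` is the inverse temperature (choice consistency). The
Rescorla–Wagner (RW) delta model ties the two rates; the
experience-weighted attraction (EWA) model replaces them with value and
experience decays. Hierarchical fits place `mu ~ N(0,1)` and half-normal
`sigma ~ N(0, 0.2)` hyperpriors per parameter on the unconstrained scale,
map non-centered subject deviates through the standard-normal CDF (times
10 for `beta`), and are sampled by MCMC (JAGS), with split-R̂ convergence
diagnostics, per-subject pointwise log-likelihoods, and PSIS-LOO/LOOIC
model comparison. ERP scoring implements the study's measurement rules:
baseline correction, ±80 µV artifact rejection, per-condition averaging,
and signed peak extraction for ERN (0–60 ms, FCz, incorrect−correct), FRN
(252–352 ms, FCz, negative−positive), P300 (300–600 ms, Pz), and the
contralateral-minus-ipsilateral N2pc (200–252 ms, PO7/PO8). Group
inference uses 2×2 mixed ANOVAs with partial η², simple effects,
Spearman/Pearson correlations, and the Fisher z test for comparing
independent correlations.

## Worked example

```r
library(volatileRL)

design <- task_design()          # 80 stable (75/25) + 100 volatile (80/20) trials
sched  <- make_schedule(design, seed = 1)
reversal_points(sched)
#> [1] 100 120 140 160             # contingency reversals every 20 volatile trials

agent <- rl_params(alpha_pos = 0.4, alpha_neg = 0.3, beta = 4, model = "RP")
sim   <- simulate_choices(sched, agent, seed = 2)
choice_accuracy(sim[, c("trial", "choice")], sched)
#> [1] 0.767                       # fraction of optimal-shape choices

# a synthetic two-group study, and a hierarchical fit of one cell
spec  <- default_effect_config(); spec$n_ot <- 10L; spec$n_plc <- 10L
study <- generate_behavior(draw_cohort(spec, seed = 3), seed = 4)
cell  <- subset(study$behavior, group == "OT" & context == "volatile")
fit   <- fit_hierarchical(cell, "RP",
                          config = fit_config(chains = 2, warmup = 300,
                                              draws = 300, seed = 5))
fit
#> Hierarchical RP fit: cell OT/volatile, 10 subjects
#>   2 chains x 300 draws; max split-Rhat (group-level) = 1.0569
subset(posterior_summary(fit), grepl("native", parameter))
#>            parameter  mean    sd  q2.5 q97.5  rhat
#>  mu_native_alpha_pos 0.559 0.119 0.334 0.805 1.002
#>  mu_native_alpha_neg 0.582 0.124 0.336 0.812 0.999
#>       mu_native_beta 1.423 0.286 0.907 1.997 1.015

psis_loo(fit$loglik)
#> PSIS-LOO over 10 units (600 draws)
#>   elpd_loo = -604.9, LOOIC = 1209.8, max Pareto k = 1.00

# mixed-design group statistics on choice accuracy
acc <- accuracy_by_subject(study$behavior)
mixed_anova_2x2(data.frame(subject = acc$subject, group = acc$group,
                           context = acc$context, value = acc$accuracy))
#>             effect       F df1 df2     p    pes
#>          treatment  0.0600   1  18 0.810 0.0000
#>            context 35.2058   1  18 0.000 0.6617
#>  treatment:context  0.1840   1  18 0.673 0.0100

fisher_z_compare(-0.104, 37, 0.448, 36)
#> $z: -2.400385   $p: 0.01637785
```

The fitted group means recover the generating volatile-cell parameters
(learning rates near 0.45–0.58, low choice consistency); the context main
effect on accuracy is large (stable learning is easier than volatile),
while a 10-per-group cohort is underpowered for the small treatment
effect. The Fisher z call compares two independent correlations
(r = −0.104 at n = 37 vs r = 0.448 at n = 36) and flags a significant
difference.

A full report — behavior tables, per-cell fits, LOOIC comparison table,
ERP scores, ANOVA/correlation tables, and a reproducibility manifest — is
produced by `run_pipeline(pipeline_config(out_dir = "report"))`.

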