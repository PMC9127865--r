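---
title: "Opposing learning and context-dependent value learning: models, fitting, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opposing learning and context-dependent value learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In instrumental learning, people learn option values from outcomes that
arrive inside a *context* — the set of options currently on offer.  When two
options always appear together, their values are not learned independently:
an option that pays 64 points on average acquires a higher subjective value
when its constant partner pays 44 than when the partner pays 54, even though
its own payoff distribution is identical.  The signature of this
context-dependence is the **transfer bias**: after learning two pairs
(A1, B) and (A2, C), with A1 and A2 paying identically (N(64, 13)) and
B (N(54, 13)) better than C (N(44, 13)), subjects asked to choose between
A1 and A2 — a pair they never saw during learning — prefer A2, the option
learned against the poorer partner.

With **complete feedback** (the forgone outcome shown alongside the obtained
one) the standard explanation is outcome comparison: regret and relief enter
the learning signal.  The harder question is why the bias also appears under
**partial feedback**, where there is nothing to compare.  The package
implements, around a common task simulator and fitting machinery, a model
family whose central member — the **Opposing Learning (OL)** model — answers
that question by letting the chosen option's prediction error update the
*unchosen* option in the opposite direction, an architecture motivated by
the opposing action of dopamine on the two striatal projection-neuron
populations that encode the values of competing options.

## The task and what the generator emulates

`task_config()` encodes the three-phase design:

* **Learning.**  The two context pairs are interleaved in pseudorandom
  blocks of two (one trial per context per block), with each stimulus on the
  left in exactly half of its context's scheduled trials.  Rewards are
  truncated-normal draws; the stated bounds "±3σ and the 0–100 display
  scale" conflict for the 64-mean options (64 + 39 > 100), so the package
  intersects them: `[max(0, μ−3σ), min(100, μ+3σ)]`, on the rationale that
  outcomes were displayed on a 0–100 scale.  Sampling is by rejection, which
  is exact and rejects only ~0.3% of draws at these bounds.  The phase is
  adaptive: at least 100 trials, then it stops as soon as the *shown*
  rewards of A1 and A2 have means differing by less than 1 point; a run
  still unconverged at 300 trials is flagged `excluded` (real subjects in
  that situation were excluded from analysis).  Under partial feedback the
  shown rewards are the chosen outcomes; under complete feedback the
  counterfactual outcomes count as shown too.
* **Transfer.**  All six unordered pairs, four repetitions each, shuffled,
  sides counterbalanced within pair; no feedback, values frozen.
* **Estimation.**  Each stimulus four times; the simulated response is the
  agent's current value plus zero-mean Gaussian response noise (SD 5 points,
  configurable), clipped to 0–100.  This response model is a package
  convention — the estimation phase is simulated only so that datasets are
  structurally complete.

Not emulated (and therefore outside what any passing test shows about real
data): reaction times, confidence ratings (the column is emitted empty),
missed trials (the reader tolerates them; the simulator never produces
them), within-subject correlations between fitted parameters, and any
sequential effects beyond the model update rules themselves.

## The model space

All models choose by softmax, `P(i over j) = 1/(1+exp(−β(Q_i − Q_j)))`,
computed in log-sum-exp stable form.  Only the two stimuli of the current
context are ever updated.  Parameters all live in [0, 1]; β is also fitted
on [0, 1] because values span 0–100 points, so plausible inverse
temperatures are far below 1 (fitted cohort means are ≤ 0.37).

| key | update rule (partial feedback) | extra parameters |
|-----|-------------------------------|------------------|
| `SQL` | `Q_ch += α₁(r − Q_ch)` | — |
| `SQL2` | SQL plus `Q_un += α₂(r_un − Q_un)` (complete only) | α₂ |
| `RPD`/`RPA`/`RPM` | context value `V += α₁(r_x − V)`, then `Q_ch += α₂((r − V) − Q_ch)` | α₂ (+α₃ for the unchosen option, complete) |
| `Dif` | `Q_ch += α₁((r_fc − r_cf) − Q_ch)` (complete only) | — |
| `Hyb` | `Q_ch += α₁(r_hyb − Q_ch)`, `r_hyb = w·r_fc + (1−w)(r_fc − cf)` | w |
| `FQL` | SQL plus `Q_un ← α₂ Q_un` (retention factor) | α₂ |
| `EWA` | `N ← ρN + 1`; `Q_ch ← (Q_ch N φ + r)/N'` | ρ, φ (+δ weight on `r_un`, complete) |
| `SBE` | no point value: recency-weighted sampling of past outcomes | recency α |
| `RelAsym` | reference-point stage, then confirmatory/disconfirmatory rates | α_conf, α_disc |
| `OL1`/`OL2` | `Q_ch += α₁δ`, `Q_un −= α₂δ`, δ from the chosen option | (α₂ for OL2; +w, complete) |

Conventions worth making explicit, where the published descriptions left
the choice open:

* **Initialization.**  All Q and V start at `q0 = 0`.  This makes the OL1
  antisymmetry (`Q_un = −Q_ch` within a pair) exact from trial one and
  matches the relative-encoding interpretation; `q0` is a configuration knob
  (50, the scale midpoint, is the natural alternative for sensitivity
  checks, and is what the "greedy agents learn nearly perfectly" test uses
  to avoid lock-in on the first-sampled option).
* **Reference-point ordering.**  `V` is updated first and the option
  prediction error uses the *updated* `V` — the equations are applied in the
  order they are stated.  A regression test pins this ordering.
* **RelAsym reference.**  The reference stage uses the average contextual
  reward (`(r_ch + Q_un)/2` partial, `(r_ch + r_un)/2` complete), i.e., the
  RPA form; this makes the α_conf = α_disc degeneracy collapse exactly onto
  RPA, which the test suite asserts trajectory-for-trajectory.  The exported
  `relasym_step()` also offers the direct and max variants.  The sign
  condition for the unchosen option is deliberately flipped (a negative
  unchosen prediction error is *confirmatory*), exactly as the model is
  defined.
* **EWA.**  Experience weights are per stimulus, start at 1, and only the
  stimuli actually updated advance their weights; under partial feedback the
  counterfactual weight is fixed to 0 (there is no counterfactual outcome).
* **SBE.**  The printed recency weights `α(1−α)^(t−i)` do not sum to one;
  the package renormalizes them per option so the choice probability is a
  proper mixture (the unnormalized variant sits behind
  `normalize = FALSE`).  An option with no samples yet contributes one
  pseudo-sample at `q0` with probability 1.  The likelihood is evaluated
  exactly by the double sum — O(T²) per subject, which is unproblematic at
  ≤ 300 trials.

## Properties of the opposing-learning rule

**Conservation and relative coding.**  With equal rates (OL1) the two
increments cancel: `Q_ch + Q_un` is constant along any trajectory, so from
zero initialization `Q_un = −Q_ch` exactly and the paired values are
perfectly anti-correlated.

**The correlation law.**  For α₂ ≤ α₁ the stationary Pearson correlation
between the paired value series is −α₂/α₁ (0 for one-sided updating,
−1 at equal rates).  A subtlety the package documents because it affects
measurement: the within-run estimator converges to this stationary value
only when the series is much longer than the mixing time of the slowest
eigenmode of the coupled update (decay rate (α₁ − α₂)/2 per trial, so the
mode mixes ever more slowly as α₂ → α₁).  At 1,000 trials with a 50-trial
burn-in the endpoint ratios are measured without bias (−1 is exact by
conservation; 0 needs no mixing), but intermediate ratios are biased toward
zero; the package's validation therefore measures intermediate ratios on
20 runs × 30,000 trials, where the estimator sits within ±0.1 of the law.
`qvalue_correlation_experiment()` exposes both the within-run estimator
(default) and an across-run ensemble estimator at the final trial.

**Performance.**  Opposing updating increases the contrast between paired
values, so at moderate exploitation (β·σ well below 1 in normalized units)
accuracy increases with α₂/α₁; `run_performance_grid()` reproduces the
ordering, and the acceptance suite checks that the gain from ratio 0 to 1
exceeds twice the Monte-Carlo standard error at 200 trials × 200
repetitions.  The advantage is regime-limited: at large β the
self-reinforcing contrast makes the model bistable — an early lucky streak
on the poorer option locks the agent onto it (and, in the full task, such
runs tend to end `excluded` because the A1/A2 stopping criterion is never
met).  This is why realistic inverse temperatures for this task scale are
of order 0.01–0.1.

**The complete-feedback extension.**  Replacing the reward with the hybrid
signal `r_hyb = r_fc − (1−w) r_cf` leaves the OL architecture untouched but
changes the effective reward distributions: choosing option *i* now pays
N(μᵢ − (1−w)μⱼ, σ√(1+(1−w)²)).  So extended OL *is* plain OL on transformed
means — with the minus sign.  Note the frequently quoted plus-sign
transformation (μᵢ′ = μᵢ + (1−w)μⱼ, under which the means move closer
together) is not what the algebra gives; the package verified the reduction
numerically (simulated choice frequencies of extended OL match plain OL on
the minus-sign transform within Monte-Carlo error, and differ reliably from
the plus-sign transform), and the test suite asserts the minus-sign
equivalence distributionally.

## Fitting

`rl_fit()` fits each subject independently by maximum a posteriori: the
learning-phase negative log-likelihood plus a weakly informative
Beta(1.2, 1.2) prior penalty per parameter, minimized by L-BFGS-B on
[10⁻⁸, 1 − 10⁻⁸] with 10 restarts (configurable) drawn from the prior, and
an objective tolerance of ~10⁻⁸ (`factr = 1e7`).  The replay itself is
compiled (Rcpp); the exported R step functions define the same rules and
the suite checks all three paths (compiled, R, and an independently coded
brute-force oracle) against each other to 10⁻¹⁰ relative error.

* **Missed trials** carry no outcome in this task, so they contribute
  neither a likelihood term nor a state update.
* **OL2's coupled constraint** 0 < α₂ ≤ α₁ is not a box; the optimizer
  works on (β, α₁, κ) with α₂ = κ·α₁ and the prior applied to κ.  The
  published prior statement is "per parameter"; applying it to the ratio is
  this package's choice.
* **Transfer prediction.**  `transfer_nll()` replays learning at the MAP
  parameters, freezes the end-of-learning values, and scores the 24 transfer
  choices with the learning-phase β (a refitted transfer β is a defensible
  alternative; the MAP β is used because each subject has one fitted β).
  Both the all-pairs total and the (A1, A2)-pair total are reported, since
  the critical pair carries the context effect.
* **Information criteria** are `2·NLL + k·ln n` (BIC) and `2·NLL + 2k`
  (AIC); BIC feeds model selection because the adaptive stopping rule gives
  every subject a different n.
* **A flat likelihood ridge to know about:** at saturating contrast
  (β·ΔQ ≫ 1) the likelihood barely discriminates large learning rates from
  the generating one — overestimates of α₁ cost almost nothing, while
  underestimates of α₁ or β are heavily penalized.  Parameter-recovery
  regressions therefore tend to show slopes below 1 with positive
  intercepts for the rate parameters.

## Model selection

`random_effects_bms()` treats model identity as a random effect: Dirichlet
prior (concentration 1 per model) over population model frequencies,
multinomial subject assignments, `−BIC/2` as the subject-level log
evidence, and the standard variational posterior.  The **exceedance
probability** (xp) of a model is the posterior probability that it is the
most frequent model; for two models it is computed analytically from the
Beta posterior, otherwise by 10⁶ seeded Monte-Carlo draws.  The **Bayes
omnibus risk** (bor) compares the random-effects free energy against the
equal-frequency null, and the **protected** exceedance probability is
`pxp = (1−bor)·xp + bor/M`.  No equations for this scheme are printed in
the source study (it used the standard toolbox); the implementation follows
the standard variational references and is cross-checked in the tests
against a direct posterior-sampling oracle, exact symmetry cases, and
dominance cases.

## Recovery studies

`parameter_recovery_study()` samples synthetic subjects from per-parameter
Beta distributions, simulates them on the task, refits, and reports
per-parameter Pearson correlations and the regression
`recovered = b0 + b1·true`.  `model_recovery_study()` simulates cohorts
from every generating model, fits every candidate, selects per-subject
winners by AIC, and reports the confusion matrix `p(fit|gen)` together with
its Bayes inversion `p(gen|fit)` under a uniform prior over models
(`p_gen_given_fit()`).

Generating distributions: for the main model space (SQL, RPA, Dif, Hyb,
OL1, OL2) the moments are the cohort-level estimates reported for this
task's human cohorts, moment-matched to Beta shapes
(`default_param_moments()`, `beta_from_moments()` — infeasible mean/SD
combinations on [0, 1] are rejected naming the parameter, and SDs are
capped at 95% of the feasibility bound).  The remaining families have no
published cohort estimates for this task, so the package fixes
field-typical values once: learning-rate-like parameters 0.2–0.35 with SD
0.15–0.25, EWA decays 0.6 ± 0.2, and — importantly — FQL's α₂ is a
*retention* factor, centred at 0.9 ± 0.08 in line with fitted forgetting
rates in that literature; a fast-forgetting generator (retention ≈ 0.6)
would be atypical and would make FQL cohorts mimic opposing learning.

OL2 deserves a caveat: with α₂ sampled from the fitted range its behavior
overlaps OL1's, and it is the one family that is not reliably recoverable —
consistent with the original analysis, which could identify OL2 only when
α₂ was restricted to lie close to (but below) α₁.  The study functions
expose the generating moments so users can reproduce exactly that
manipulation.

## Validation scales and numerical choices

The shipped test suite runs every update rule against an independent
brute-force oracle (1,000 random state/feedback/parameter triples per
model, ≤10⁻¹⁰ relative error), asserts the degeneracy lattice
(Hyb(w=1)≡SQL, Hyb(w=0, complete)≡Dif, OL(α₂=0)≡SQL, FQL(α₂=1)≡SQL,
RelAsym(α_conf=α_disc)≡RPA) trajectory-for-trajectory on shared seeds, and
exercises the study-level machinery at desk scales chosen to keep the whole
suite in a few minutes: the correlation law at 20 runs × 1,000 trials
(endpoints) and 20 × 30,000 (intermediate ratios); the performance ordering
at 200 trials × 200 repetitions; parameter recovery with 30 synthetic
subjects and 10 restarts; model recovery with 5 models × 10 subjects ×
5 repetitions over 5 seeds (AIC winners, 3 restarts).  Numerical details:
softmax and its log are evaluated in the stable form; rejection sampling is
exact; the RelAsym δ = 0 tie lands in the disconfirmatory branch for both
options (the branches coincide in value there, so the tie-break is inert); seeds flow root → child
via `sample.int`, so every cohort, subject, and restart is reproducible
bit-for-bit.

## Known limitations

* Hierarchical (group-level) estimation is deliberately absent: subjects
  are fitted independently, as in the analysis this package implements.
* The estimation-phase response model and the confidence column are
  placeholders; no claims about estimation accuracy or confidence are
  testable with this generator.
* Moment-matched, independent Beta generators cannot reproduce
  within-subject correlations between fitted parameters, which real
  best-fit parameter sets have; cohort-level simulated effect sizes (e.g.,
  the transfer-bias ratio) are correspondingly noisier than
  participant-parameter resimulation.
* The β ∈ [0, 1] fitting bound is appropriate for 0–100-point value scales;
  rescaled tasks need the bound revisited (`map_fit()` exposes the prior
  and the box through its arguments).
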