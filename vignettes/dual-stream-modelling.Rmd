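---
title: "Dual-stream hierarchical Gaussian filter modelling of social and non-social learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream hierarchical Gaussian filter modelling of social and non-social learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgfsocial)
```

## The task and the modelling problem

`hgfsocial` models behaviour in a 120-trial probabilistic reward task in
which two sources of information predict which of two cards (blue or
green) wins on a given trial: the *card colour* itself, whose winning
probability follows a block schedule, and a *gaze cue* (an animated face
looking at one card), whose accuracy follows an independent block
schedule. Subjects are never told that the gaze is informative; how much
weight they spontaneously give it, and how quickly they update beliefs
about either source when contingencies change, are the quantities of
scientific interest.

In the canonical design the card contingency is stable for trials 1–60
(p = 0.73 for blue) and reverses three times in the volatile second half;
the gaze contingency is stable on trials 1–30 and 71–120 and reverses
every ten trials in between (five changes in total, making the social
cue objectively *more* volatile than the card). Two counterbalanced
variants start the gaze as helpful (73% accurate, congruent-first) or
misleading (27%, incongruent-first).

```{r}
sch <- build_schedule(schedule_config())
count_contingency_changes(sch, "gaze")
count_contingency_changes(sch, "card")
```

## Perceptual models

Learning about each stream is modelled by a three-level binary
hierarchical Gaussian filter (HGF) run independently per stream. Level 1
is the binary outcome (`u = 1`: blue wins / gaze correct), level 2 the
latent tendency `x2` with `p(u = 1) = s(x2)` (logistic sigmoid), and
level 3 the log-volatility of that tendency. Belief updates are
prediction errors weighted by precision ratios; the key derived
quantities are the dynamic learning rates

* `psi2 = 1/pi2` and its sigmoid-corrected form
  `q(psi2) = psi2 * s(mu2)(1 - s(mu2))`, an uncertainty measure for
  first-level beliefs, and
* `psi3 = pihat2/pi3`, the weight on volatility prediction errors.

Each stream has two free parameters: `omega2` (tonic level-2
log-volatility — the contingency learning-rate parameter) and `omega3`
(tonic level-3 log-volatility — the volatility learning-rate parameter).
The level-2/3 coupling `kappa` is fixed at 1 and the AR(1) coefficients
of the state evolution are fixed at 0 (the Gaussian random-walk limit,
the standard configuration for this model class); both remain
configurable arguments of `hgf_filter()` for sensitivity analyses.
Initial states are fixed at `mu2(0) = 0, sigma2(0) = 1, mu3(0) = 1,
sigma3(0) = 1`.

Numerical guards: the first-level prediction is clipped to
`[1e-8, 1 - 1e-8]` before its Bernoulli precision is formed (the
precision diverges at the boundary), and a non-positive third-level
posterior precision (which arises for strongly positive `omega`
combinations) raises a classed *rejection* condition carrying the trial
index; the fitter converts rejections into a large finite penalty
(-1e10) so that optimizer line searches never see infinities.

Two non-hierarchical comparison learners are provided: a
Rescorla–Wagner filter with a fixed learning rate per stream, and a
Sutton K1 filter whose log-gain is incremented by the product of the
current prediction error and a decaying trace of recent errors (gain
bounded to (0, 1]; meta-learning rate per stream; initial gain fixed at
0.1). With a zero meta-learning rate K1 reduces exactly to
Rescorla–Wagner.

## Response models

Decisions are modelled in the *gaze frame* (`y = 1` = follow the gaze).
The two streams' first-level predictions are merged into a combined
belief `b(t)` that following pays off: each prediction is weighted by
its Bernoulli precision, and the social precision is multiplied by the
social weighting factor `zeta` (> 0, estimated in log space). `zeta > 1`
means social information is trusted beyond its nominal reliability —
the parameter that separates groups with exaggerated social weighting.

`b(t)` enters a reward-weighted softmax: the belief is weighted by the
reward printed on the gazed-at card against the other card, with a
mixing parameter `eta` interpolating between linear and logarithmic
reward weighting, and an inverse decision temperature `gamma(t)`. Four
variants define `gamma(t)`: modulated by the predicted third-level
log-volatility of both streams (variant 1), the social stream only (2),
the non-social stream only (3), or constant (`gamma = beta`, variant 4).
Non-hierarchical learners pair with variant 4 only. Two non-learning
baselines complete the eight-model space: a win-stay-lose-shift policy
with error rate `epsilon` (stay defined on the chosen card, converted
to the gaze frame, trial 1 at 0.5) and a random-responding model with a
constant follow bias. `model_space()` returns the eight models in the
canonical order.

## Inversion and model selection

`fit_subject()` performs MAP estimation in transformed spaces (native
for the `omega`s, log for `zeta`/`beta` and the K1 meta-rates, logit
for unit-interval parameters) under Gaussian priors, using BFGS from
the prior mean plus seeded perturbed restarts (perturbation SD = prior
SD/4). The log model evidence is the Laplace approximation
`LME = log_joint(mode) + (d/2) log 2*pi - 0.5 log det(-H)` with a
central-difference Hessian (step 1e-4). Default priors are weakly
informative values conventional for this model class: `omega2 ~ N(-3, 16)`,
`omega3 ~ N(-6, 16)` (native), `log zeta, log beta, logit eta ~
N(0, 4)`, unit-interval baseline parameters `~ N(0, 1)` (logit), K1
`log mu ~ N(-2, 4)`. All are plain data.frame rows and overridable.

`rfx_bms()` implements random-effects Bayesian model selection over a
subjects-by-models LME matrix: variational Dirichlet updates (uniform
prior, convergence at `max |delta alpha| < 1e-6`), Monte-Carlo
exceedance probabilities (1e6 seeded Dirichlet draws by default,
reported with their MC standard error), and the Bayes omnibus risk from
the free-energy comparison against the equal-frequency null, giving the
protected exceedance probabilities `PXP = (1 - BOR) XP + BOR/K`. All
outputs are invariant to per-subject constant shifts of the evidences.

## Synthetic cohorts: what they emulate and what they do not

`generate_cohort()` draws subject parameters from group-level Gaussians
in estimation space, simulates a fresh experiment per subject and an
agent on it. The default generating distribution
(`default_generating_distribution()`) is `omega2 ~ N(-2.5, 1.5^2)`,
`omega3 ~ N(-6, 1)`, `log zeta ~ N(0, 1)`, `log beta ~ N(1.5, 0.7^2)`,
`logit eta ~ N(0, 1)` — magnitudes bracketing the posterior means this
task elicits from human subjects, producing agents whose choices are
structured but noisy (follow probabilities typically spanning
0.2–0.8). `two_group_cohort_spec()` shifts `log zeta` by ±1 to emulate
a high-social-weighting (clinically, borderline-type) group against a
low-weighting control group; this suffices to reproduce the
group-by-cue accuracy crossover in both directly simulated and
posterior-predictive data.

Synthetic agents differ from real participants in ways that bound what
passing tests show: they contain no missed trials, no attentional
lapses or perseveration beyond what the models express, and their
generating process *is* one of the candidate models — so recovery
results quantify estimator quality under the model, not model adequacy
for human data.

## Validation analyses and their calibration

*Parameter recovery* follows the simulate–refit–correlate procedure
with 10 simulations per subject averaged before correlating, on a
20-subject cohort (the correlation itself is too noisy to be a useful
diagnostic with only one or two replicates at this cohort size). Under
these conditions Pearson r exceeds 0.7 for `log zeta`, `log beta`,
`omega2_card` and `omega2_gaze`, while the volatility evolution rates
`omega3` recover poorly (r near 0) — an expected property of this task
length: with `omega3` near -6 the third-level trajectory accumulates
precision quickly and barely moves, leaving little signal in 120
binary choices.

*Model recovery* simulates cohorts from a generating model, fits all
eight models and asks whether `rfx_bms()` selects the generator. A
random-responding cohort is identified essentially perfectly
(XP = 1.0). A cohort generated from the full HGF with
volatility-coupled decision noise (variant 1) is *not* recovered under
the default priors and realistic generating values: because the
third-level trajectory is nearly constant, variant 1 is observationally
close to variant 4, and the K1 learner fits the realized choices about
as well as the generating model while carrying two fewer
weakly-constrained parameters — random-effects selection then prefers
K1 on Occam grounds. This is a genuine property of the model space at
these parameter magnitudes rather than an optimizer failure (refits
with extra restarts reproduce the evidence ordering, and the fitted
modes dominate the generating values in log-joint). It mirrors the
weak real-data evidence in this literature, where protected exceedance
probabilities remain modest even when raw exceedance looks decisive.

*Posterior-predictive checks* re-simulate each subject from fitted (or
supplied) parameters `n_rep` times on the subject's own experiment —
116 subjects at the study's 10 replicates yield exactly 1,160 simulated
datasets — and summarize each simulation with the same behavioural
tables as the observed data (high-probability choices by cue and phase;
advice taking by social accuracy and stability).

*The lagged regression* (`choice_sequence_glm()`) is the model-agnostic
learning-rate readout: a logistic regression of the response on the
outcomes of the previous five trials plus two expected-reward
predictors, fitted separately per cue frame and phase. The binomial
family is the default (the outcome is binary; a linear-probability fit
is available via `family = "gaussian"` for sensitivity). Trials whose
lag window crosses a phase boundary are excluded rather than
zero-padded, so phase-specific fits condition only on within-phase
history. Perfect separation (deterministic responders) triggers a
flagged ridge-penalized fallback (penalty 1e-4). The least-squares
slope of coefficient against lag index rises from stable to volatile
phases for the card cue at cohort level; the contrast is a weak effect
(mean difference ~0.07 slope units with a between-cohort SD of ~0.15
at 40 subjects), so the validation suite averages it over 12 replicate
cohorts. The social-cue contrast is directionally unstable in
synthetic agents — consistent with the observed-data finding that the
phase difference reaches significance only for the card cue.

*Belief alignment* (`zeta_alignment()`): because the realized gaze and
card outcomes encode the same event on any single trial (the gazed-at
card either wins or not), alignment of the combined belief with a
stream is scored against the stream's *generative schedule* — the
expected accuracy of `b(t)` against an outcome freshly drawn from
`p_gaze(t)` (or `p_card(t)` after mapping `b` to the card frame).
Averaged over experiments this measure is monotone over
`log zeta in -5..5`: increasing for the social stream, decreasing for
the non-social one.

## Problem sizes and numerical choices

The validation suite uses cohorts of 20 subjects (parameter recovery,
10 replicates), 30 subjects (model recovery), 50 subjects (phase
effects and lagged regression) and 116 subjects (posterior-predictive
bookkeeping); these sizes make the stochastic checks stable while
keeping a full run on a single CPU short. Optimizer restarts default to
4 for single-subject analyses; cohort-scale runs use 1–2 restarts,
which empirically reproduce the same modes on this task. Ties in the
within-subject best-model tabulation break toward the lowest model
index and are flagged. "High-probability choice" uses a `p >= 0.5`
threshold with ties counted as high for both options — inert on the
canonical schedules, which never touch 0.5.

## A worked example

```{r, eval = FALSE}
sch <- build_schedule(schedule_config())
e <- generate_experiment(sch, seed = 42)
params <- list(omega2_card = -2.5, omega2_gaze = -2.5,
               omega3_card = -6, omega3_gaze = -6,
               zeta = exp(0.5), beta = exp(1.5), eta = 0.5)
sim <- simulate_agent(e, params, model_spec("hgf", 1), seed = 7)
fit <- fit_subject(e, sim$responses, model_spec("hgf", 1),
                   n_restarts = 2, seed = 3)
fit
```

## Known limitations

* The Laplace evidence is a local approximation; strongly
  non-Gaussian posteriors (near-deterministic agents, boundary modes)
  are handled by diagnostic-flagged regularization rather than exact
  integration.
* `omega3` parameters are structurally hard to recover at 120 trials;
  analyses that interpret individual `omega3` estimates on this task
  should treat them with caution.
* Group-level inferential statistics (mixed ANOVAs) are deliberately
  out of scope: the summary tables are tidy data.frames meant to be
  passed to standard routines (`stats::aov`, `afex`, JASP, ...).
* The WSLS and random-responding baselines are minimal stochastic
  parameterizations (error rate / follow bias in logit space) chosen to
  admit a likelihood; richer perseveration kernels are not modelled.
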