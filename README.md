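# hgfsocial

Dual-stream hierarchical Gaussian filter (HGF) modelling of social and
non-social probabilistic learning, for researchers in computational
psychiatry and decision neuroscience who study how people weight advice
from others against their own experience in volatile environments.

The package models a 120-trial card-choice task in which two independent,
block-structured probability schedules carry reward information: the card
colour (non-social) and a gaze cue (social). It provides the complete
modelling pipeline:

* **Task simulation** — canonical schedules (card stable trials 1–60,
  volatile 61–120; gaze stable 1–30 and 71–120, volatile 31–70; 73%/27%
  contingency levels; 5 gaze vs 3 card contingency changes), experiment
  sampling, and group-structured synthetic cohorts.
* **Perceptual models** — a three-level binary HGF per information
  stream, with beliefs updated by precision-weighted prediction errors:
  at level *i*, `Δμ_i ∝ ψ_i δ_{i−1}` with precision weights
  `ψ2 = 1/π2`, `q(ψ2) = ψ2 s(μ2)(1−s(μ2))`, `ψ3 = π̂2/π3`. Plus
  Rescorla–Wagner and Sutton K1 comparison learners.
* **Response models** — the combined belief
  `b(t) = w_gaze μ̂1,gaze + w_card μ̂1,card` with
  `w_gaze = ζπ̂1,gaze/(ζπ̂1,gaze + π̂1,card)` (ζ = social weighting
  factor), mapped to choice through a reward-weighted softmax with
  inverse temperature `γ(t)` that is optionally modulated by the
  predicted third-level log-volatility (four variants), and
  win-stay-lose-shift / random-responding baselines — eight models in
  total.
* **Inversion** — subject-level MAP estimation under Gaussian priors in
  transformed spaces with Laplace-approximated log model evidence
  (`fit_subject()`, `fit_cohort()`).
* **Model selection** — random-effects Bayesian model selection over an
  LME matrix: expected posterior model probabilities, Monte-Carlo
  exceedance probabilities (XP), Bayes omnibus risk and protected
  exceedance probabilities (PXP) (`rfx_bms()`), plus within-subject
  best-model tabulation.
* **Validation** — parameter recovery, posterior-predictive checks,
  phase-averaged precision weights, a model-agnostic lagged logistic
  regression of choices on recent outcomes, and combined-belief
  alignment across the ζ grid.

## A worked example

Simulate one agent on the canonical congruent-first schedule and refit
the generating model:

```r
library(hgfsocial)

sch <- build_schedule(schedule_config())
e <- generate_experiment(sch, seed = 42)
params <- list(omega2_card = -2.5, omega2_gaze = -2.5,
               omega3_card = -6, omega3_gaze = -6,
               zeta = exp(0.5), beta = exp(1.5), eta = 0.5)
sim <- simulate_agent(e, params, model_spec("hgf", 1), seed = 7)
mean(sim$responses$y)   # 0.3583 — followed the gaze on ~36% of trials

fit <- fit_subject(e, sim$responses, model_spec("hgf", 1),
                   n_restarts = 2, seed = 3)
fit
#> Model hgf1 fit: LME = -81.123
#> MAP estimates (estimation space):
#> omega2_card omega2_gaze omega3_card omega3_gaze        zeta        beta
#>     -2.5917     -3.2154     -6.0912     -5.8688      0.9813      1.0943
#>         eta
#>      0.8969
```

The estimates are in estimation space (`zeta`, `beta` in log units,
`eta` in logit units): the generating `log ζ = 0.5` is recovered at
0.98 and the contingency learning rates `ω2` near their generating
values of −2.5; the log model evidence (LME) is the Laplace-approximated
marginal likelihood used for model comparison. Single-subject estimates
on 120 trials are noisy by nature — the validation suite quantifies
exactly how noisy via cohort-level recovery correlations.

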