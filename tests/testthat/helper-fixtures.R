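# Shared fixtures built in code at test time.

canonical_schedule <- function(variant = "congruent_first")
  build_schedule(schedule_config(variant = variant))

default_hgf_params <- function(log_zeta = 0, log_beta = 1.5,
                               logit_eta = 0)
  list(omega2_card = -2.5, omega2_gaze = -2.5,
       omega3_card = -6, omega3_gaze = -6,
       zeta = exp(log_zeta), beta = exp(log_beta),
       eta = 1 / (1 + exp(-logit_eta)))

simulated_subject <- function(seed = 1, spec = model_spec("hgf", 1),
                              params = default_hgf_params(),
                              variant = "congruent_first") {
  sch <- canonical_schedule(variant)
  exp1 <- generate_experiment(sch, seed)
  sim <- simulate_agent(exp1, params, spec, seed + 1000L)
  list(schedule = sch, experiment = exp1, responses = sim$responses,
       sim = sim, params = params, spec = spec)
}
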