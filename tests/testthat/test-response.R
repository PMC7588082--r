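test_that("model specs enforce the perceptual/response pairing rules", {
  expect_length(model_space(), 8L)
  expect_error(model_spec("rw", 1), "require the hgf")
  expect_error(model_spec("none", 4), "require a perceptual family")
  expect_error(model_spec("hgf", "wsls"), "baselines")
  expect_equal(model_spec("hgf", 2)$label, "hgf2")
  # parameter tables: hgf has 7 free parameters, baselines 1
  expect_equal(nrow(model_parameters(model_spec("hgf", 1))), 7L)
  expect_equal(nrow(model_parameters(model_spec("rw", 4))), 5L)
  expect_equal(nrow(model_parameters(model_spec("none", "wsls"))), 1L)
})

test_that("gaze-frame conversion flips the card prediction correctly", {
  expect_equal(gaze_frame_card_prediction(0.7, "blue"), 0.7)
  expect_equal(gaze_frame_card_prediction(0.7, "green"), 0.3)
  expect_equal(gaze_frame_card_prediction(0.5, c("blue", "green")),
               c(0.5, 0.5))
  expect_error(gaze_frame_card_prediction(0.5, "red"), "gaze_target")
})

test_that("combined_belief matches direct evaluation and its limits", {
  cb <- combined_belief(0.5, 0.5, 1)
  expect_equal(cb$w_gaze, 0.5)
  expect_equal(cb$b, 0.5)

  cb2 <- combined_belief(0.8, 0.6, 1)
  expect_equal(1 / (0.8 * 0.2), 6.25)
  expect_equal(cb2$w_gaze, 6.25 / (6.25 + 1 / 0.24), tolerance = 1e-12)
  expect_equal(cb2$w_gaze, 0.6, tolerance = 1e-12)
  expect_equal(cb2$b, 0.6 * 0.8 + 0.4 * 0.6, tolerance = 1e-12)

  # zeta -> Inf / 0 limits pull b to the single-stream predictions
  expect_equal(combined_belief(0.8, 0.6, 1e12)$b, 0.8, tolerance = 1e-6)
  expect_equal(combined_belief(0.8, 0.6, 1e-12)$b, 0.6, tolerance = 1e-6)

  # weights always sum to 1 and b stays inside (0,1), even at the
  # boundary before clipping
  withr::with_seed(3, {
    mg <- runif(50); mc <- runif(50)
    cb3 <- combined_belief(c(mg, 0, 1), c(mc, 1, 0), 2.5)
    expect_equal(cb3$w_gaze + cb3$w_card, rep(1, 52))
    expect_true(all(cb3$b > 0 & cb3$b < 1))
  })
})

test_that("decision_temperature implements the four variants", {
  expect_equal(decision_temperature(1, 0, 0, beta = 2), 2)
  expect_equal(decision_temperature(1, 1, 1, beta = 1), exp(-2))
  expect_equal(decision_temperature(2, 5, 1, beta = 2), 2 * exp(-1))
  expect_equal(decision_temperature(3, 1, 5, beta = 2), 2 * exp(-1))
  expect_equal(decision_temperature(4, beta = 3), 3)
  expect_error(decision_temperature(5, 0, 0, beta = 1), "variant")
  expect_error(decision_temperature(4, beta = -1), "beta")
})

test_that("prob_follow_gaze matches direct evaluation and is monotone in b", {
  expect_equal(prob_follow_gaze(0.5, 4, 4, 2, 0.3), 0.5)
  expect_equal(prob_follow_gaze(0.72, 5, 3, 1, 1),
               1 / (1 + exp(-(5 * 0.72 - 3 * 0.28))), tolerance = 1e-12)
  expect_equal(prob_follow_gaze(0.72, 5, 3, 1, 1), sigmoid(2.76),
               tolerance = 1e-12)
  expect_equal(prob_follow_gaze(0.9, 2, 7, 1e-12, 0.5), 0.5,
               tolerance = 1e-9)
  b <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(prob_follow_gaze(b, 5, 3, 1.2, 0.4)) > 0))
  expect_error(prob_follow_gaze(0.5, 0.5, 3, 1, 1), ">= 1")
})

test_that("full response path agrees with the straight-line oracle", {
  sub <- simulated_subject(seed = 17)
  params <- sub$params
  for (variant in 1:4) {
    spec <- model_spec("hgf", variant)
    ll <- likelihood_series(spec, params, sub$experiment, sub$responses)
    tc <- hgf_filter(sub$experiment$u_card, params$omega2_card,
                     params$omega3_card)
    tg <- hgf_filter(sub$experiment$u_gaze, params$omega2_gaze,
                     params$omega3_gaze)
    m_card <- ifelse(sub$experiment$gaze_target == "blue",
                     tc$muhat1, 1 - tc$muhat1)
    want <- oracle_response(tg$muhat1, m_card, params$zeta, variant,
                            tc$muhat3, tg$muhat3, params$beta,
                            sub$experiment$r_gaze,
                            sub$experiment$r_notgaze, params$eta)
    expect_equal(ll$p, want$p, tolerance = 1e-8,
                 label = paste("variant", variant))
    expect_equal(ll$decision$b, want$b, tolerance = 1e-8)
    expect_equal(ll$decision$gamma,
                 rep(want$gamma, length.out = 120), tolerance = 1e-8)
  }
})

test_that("likelihoods of the baselines take their analytic values", {
  sub <- simulated_subject(seed = 23)
  ll_rand <- likelihood_series(model_spec("none", "random"),
                               list(bias = 0.5), sub$experiment,
                               sub$responses)
  expect_equal(ll_rand$loglik, 120 * log(0.5))

  # a deterministic win-stay-lose-shift agent is perfectly predicted at
  # epsilon = 0 (trial 1 aside)
  sim <- simulate_agent(sub$experiment, list(epsilon = 0),
                        model_spec("none", "wsls"), seed = 3)
  ll_wsls <- likelihood_series(model_spec("none", "wsls"),
                               list(epsilon = 0), sub$experiment,
                               sim$responses)
  expect_equal(ll_wsls$p[-1][sim$responses$y[-1] == 1],
               rep(1, sum(sim$responses$y[-1] == 1)))
  expect_equal(ll_wsls$loglik, log(0.5), tolerance = 1e-5)

  # additivity: total equals the sum of per-trial Bernoulli terms
  params <- sub$params
  ll <- likelihood_series(model_spec("hgf", 1), params, sub$experiment,
                          sub$responses)
  p <- pmin(pmax(ll$p, 1e-8), 1 - 1e-8)
  y <- sub$responses$y
  expect_equal(ll$loglik, sum(y * log(p) + (1 - y) * log(1 - p)))

  # missing trials are excluded from the sum
  y2 <- sub$responses$y; y2[5:10] <- NA
  resp2 <- make_responses(y2, sub$experiment)
  ll2 <- likelihood_series(model_spec("hgf", 1), params, sub$experiment,
                           resp2)
  obs <- !resp2$missing
  expect_equal(ll2$loglik,
               sum(y2[obs] * log(p[obs]) + (1 - y2[obs]) * log(1 - p[obs])))
})

test_that("simulate_agent is deterministic and consistent", {
  sub <- simulated_subject(seed = 31)
  s1 <- simulate_agent(sub$experiment, sub$params, sub$spec, 77)
  s2 <- simulate_agent(sub$experiment, sub$params, sub$spec, 77)
  expect_identical(s1$responses, s2$responses)
  # derived fields: chosen card matches y and the gaze target
  r <- s1$responses
  e <- sub$experiment
  expect_equal(r$chosen_card == e$gaze_target, r$y == 1L)
  expect_equal(r$rewarded, as.integer(r$chosen_card == e$winning_card))

  # near-deterministic agent picks the argmax of the weighted belief
  params_det <- modifyList(sub$params, list(beta = 1e6, eta = 1))
  sdet <- simulate_agent(sub$experiment, params_det, model_spec("hgf", 4), 5)
  ll <- likelihood_series(model_spec("hgf", 4), params_det, sub$experiment,
                          sdet$responses)
  b <- ll$decision$b
  expect_equal(sdet$responses$y,
               as.integer(e$r_gaze * b - e$r_notgaze * (1 - b) > 0))
})

test_that("simulated follow frequency matches the model probability", {
  sub <- simulated_subject(seed = 41)
  params <- modifyList(sub$params, list(zeta = 1, beta = 1, eta = 0.5))
  ll <- likelihood_series(model_spec("hgf", 1), params, sub$experiment,
                          sub$responses)
  t0 <- 60L
  p0 <- ll$p[t0]
  ys <- vapply(1:1500, function(s)
    simulate_agent(sub$experiment, params, model_spec("hgf", 1),
                   s)$responses$y[t0], integer(1))
  se <- sqrt(p0 * (1 - p0) / 1500)
  expect_lt(abs(mean(ys) - p0), 3 * se)
})
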