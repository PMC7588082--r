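test_that("parameter transforms round-trip to 1e-12", {
  priors <- default_priors(model_spec("hgf", 1))
  expect_equal(unname(transform_parameters(
    c(eta = 0.5), priors, "to_estimation")["eta"]), 0)
  expect_equal(unname(transform_parameters(
    c(zeta = 0), priors, "to_native")["zeta"]), 1)  # log-space 0 -> 1
  withr::with_seed(6, {
    for (i in 1:200) {
      theta <- c(omega2_card = rnorm(1, -3, 2), zeta = rnorm(1),
                 beta = rnorm(1), eta = rnorm(1))
      native <- transform_parameters(theta, priors, "to_native")
      back <- transform_parameters(native, priors, "to_estimation")
      expect_lt(max(abs(back - theta)), 1e-12)
    }
  })
  expect_error(transform_parameters(c(eta = 1.5), priors,
                                    "to_estimation"), "\\(0,1\\)")
})

test_that("log_joint decomposes into likelihood plus prior density", {
  sub <- simulated_subject(seed = 3)
  spec <- sub$spec
  priors <- default_priors(spec)
  theta <- setNames(priors$mean + 0.1, priors$name)
  lj <- log_joint(theta, sub$experiment, sub$responses, spec, priors)
  native <- as.list(transform_parameters(theta, priors, "to_native"))
  ll <- likelihood_series(spec, native, sub$experiment, sub$responses)$loglik
  lp <- sum(dnorm(theta, priors$mean, sqrt(priors$variance), log = TRUE))
  expect_equal(lj, ll + lp, tolerance = 1e-10)

  # zero observed trials: the joint is the prior density alone
  resp0 <- make_responses(rep(NA_integer_, 120), sub$experiment)
  expect_equal(log_joint(theta, sub$experiment, resp0, spec, priors), lp,
               tolerance = 1e-10)

  # rejection penalty keeps the objective finite
  theta_bad <- theta; theta_bad["omega2_card"] <- 4
  theta_bad["omega3_card"] <- 3
  expect_equal(log_joint(theta_bad, sub$experiment, sub$responses, spec,
                         priors), -1e10)
})

test_that("MAP + Laplace recovers the conjugate Gaussian case exactly", {
  # y_i ~ N(theta, s2) with prior theta ~ N(m0, v0): posterior and
  # evidence are closed-form; the Laplace approximation is exact here.
  withr::with_seed(10, y <- rnorm(20, 1.4, 0.8))
  s2 <- 0.8^2; m0 <- 0; v0 <- 4
  logpost <- function(theta)
    sum(dnorm(y, theta, sqrt(s2), log = TRUE)) +
    dnorm(theta, m0, sqrt(v0), log = TRUE)
  res <- hgfsocial:::map_laplace(logpost, c(theta = m0), perturb_sd = 1,
                                 n_restarts = 3, seed = 2)
  n <- length(y)
  post_prec <- 1 / v0 + n / s2
  post_mean <- (m0 / v0 + sum(y) / s2) / post_prec
  # closed-form log marginal likelihood of the Gaussian-Gaussian model
  lml <- sum(dnorm(y, post_mean, sqrt(s2), log = TRUE)) +
    dnorm(post_mean, m0, sqrt(v0), log = TRUE) -
    dnorm(post_mean, post_mean, sqrt(1 / post_prec), log = TRUE)
  expect_equal(unname(res$mode), post_mean, tolerance = 1e-6)
  expect_equal(res$lme, lml, tolerance = 1e-6)
  # the evidence never exceeds the joint at the mode
  expect_lt(res$lme, res$log_joint)
})

test_that("fixed parameters are excluded from the free vector and an
           irrelevant near-point free parameter leaves the LME unchanged", {
  sub <- simulated_subject(seed = 29)
  spec <- sub$spec
  priors <- default_priors(spec)
  free <- setNames(priors$mean, priors$name)
  # two evaluations differing only in a fixed parameter's stored value
  priors_fix <- priors
  priors_fix$fixed[priors_fix$name == "eta"] <- TRUE
  th <- free[setdiff(names(free), "eta")]
  lj1 <- log_joint(th, sub$experiment, sub$responses, spec, priors_fix)
  # the fixed value itself matters (enters the likelihood) but passing
  # it inside theta must error: theta covers exactly the free set
  expect_error(log_joint(free, sub$experiment, sub$responses, spec,
                         priors_fix), "free parameters")
  expect_true(is.finite(lj1))

  # Occam consistency in the degenerate limit: a free parameter whose
  # prior collapses to a point contributes nothing to the evidence
  withr::with_seed(11, y <- rnorm(15, 0.5, 1))
  lp1 <- function(theta)
    sum(dnorm(y, theta[["a"]], 1, log = TRUE)) +
    dnorm(theta[["a"]], 0, 2, log = TRUE)
  lp2 <- function(theta)
    lp1(theta["a"]) + dnorm(theta[["irrelevant"]], 0, 1e-4, log = TRUE)
  r1 <- hgfsocial:::map_laplace(lp1, c(a = 0), perturb_sd = 1,
                                n_restarts = 2, seed = 1)
  r2 <- hgfsocial:::map_laplace(lp2, c(a = 0, irrelevant = 0),
                                perturb_sd = c(1, 1e-5),
                                n_restarts = 2, seed = 1,
                                hessian_step = 1e-6)
  expect_equal(r2$lme, r1$lme, tolerance = 1e-4)
})

test_that("fit_subject is deterministic and produces sane fits", {
  sub <- simulated_subject(seed = 19)
  f1 <- fit_subject(sub$experiment, sub$responses, sub$spec,
                    n_restarts = 2, seed = 5)
  f2 <- fit_subject(sub$experiment, sub$responses, sub$spec,
                    n_restarts = 2, seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$lme, f2$lme)
  expect_true(is.finite(f1$lme))
  expect_lt(f1$lme, f1$log_joint)
  # native-space estimates respect the domain constraints
  expect_gt(f1$estimates_native$zeta, 0)
  expect_gt(f1$estimates_native$beta, 0)
  expect_true(f1$estimates_native$eta > 0 && f1$estimates_native$eta < 1)
  expect_true(f1$diagnostics$converged)
  expect_s3_class(f1$trajectories$card, "hgfs_trajectory")
})

test_that("a near-deterministic agent's social weighting is identifiable", {
  # strong-signal regime: simulate at high beta and refit; the native
  # zeta estimate lands within a factor of 2 of truth in most replicates
  spec <- model_spec("hgf", 4)
  priors <- default_priors(spec)
  zeta_true <- exp(0.8)
  params <- modifyList(default_hgf_params(),
                       list(zeta = zeta_true, beta = 1e6,
                            eta = sigmoid(20)))
  sch <- canonical_schedule()
  hits <- 0L
  n_repl <- 10L
  for (s in seq_len(n_repl)) {
    e <- generate_experiment(sch, 100 + s)
    sim <- simulate_agent(e, params, spec, 200 + s)
    fit <- fit_subject(e, sim$responses, spec, priors, n_restarts = 2,
                       seed = s)
    ratio <- fit$estimates_native$zeta / zeta_true
    if (ratio > 0.5 && ratio < 2) hits <- hits + 1L
  }
  expect_gte(hits / n_repl, 0.8)
})

test_that("fit_cohort assembles a finite LME matrix with model labels", {
  cohort <- generate_cohort(two_group_cohort_spec(n_per_group = 1),
                            seed = 55)
  specs <- list(model_spec("hgf", 1), model_spec("none", "random"))
  fc <- fit_cohort(cohort, specs, n_restarts = 1, seed = 2)
  expect_equal(dim(fc$lme), c(2L, 2L))
  expect_equal(colnames(fc$lme), c("hgf1", "random"))
  expect_true(all(is.finite(fc$lme)))
})
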