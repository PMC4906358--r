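test_that("change-point probability matches direct two-density evaluation", {
  cfg <- model_config(hazard = 0.1, noise_sd = 10)
  # independent oracle: uniform vs Gaussian density ratio written out
  oracle <- function(delta, tau, H = 0.1, sd_n = 10, range = 300) {
    u <- 1 / range
    dens <- dnorm(delta, 0, sqrt(sd_n^2 / (1 - tau)))
    (u * H) / (u * H + dens * (1 - H))
  }
  for (tau in c(0, 0.3, 0.7)) {
    deltas <- c(0, 5, 10, 30, 80)
    expect_equal(change_point_probability(deltas, tau, cfg),
                 oracle(deltas, tau), tolerance = 1e-8)
  }
  # hand-evaluated anchors
  expect_equal(change_point_probability(0, 0, cfg), 0.0092, tolerance = 1e-2)
  expect_equal(change_point_probability(30, 0, cfg), 0.455, tolerance = 1e-2)
})

test_that("change-point probability limits and domain errors", {
  cfg0 <- model_config(hazard = 0)
  expect_equal(change_point_probability(c(-50, 0, 50), 0.5, cfg0),
               c(0, 0, 0))
  cfg <- model_config(hazard = 0.1)
  expect_gt(change_point_probability(1e6, 0, cfg), 1 - 1e-12)
  expect_error(change_point_probability(0, 1, cfg), "tau")
  expect_error(change_point_probability(0, 0, cfg, noise_sd = 0), "noise_sd")
})

test_that("omega is monotone in |delta|, hazard and tau", {
  cfg <- model_config(hazard = 0.1, noise_sd = 10)
  set.seed(1)
  for (i in 1:20) {
    tau <- runif(1, 0, 0.9)
    d <- sort(abs(rnorm(50, 0, 40)))
    om <- change_point_probability(d, tau, cfg)
    expect_true(all(diff(om) >= -1e-12))

    delta <- runif(1, 0, 60)
    hs <- sort(runif(5, 0.01, 0.9))
    om_h <- vapply(hs, function(h)
      change_point_probability(delta, tau, model_config(hazard = h)),
      numeric(1))
    expect_true(all(diff(om_h) >= -1e-12))

    # monotone in tau only where the error is small relative to the
    # outcome noise: for |delta| > the predictive s.d., widening the
    # predictive distribution raises its density at delta and lowers omega
    small_delta <- runif(1, 0, 9)
    taus <- sort(runif(5, 0, 0.95))
    om_t <- vapply(taus, function(tt)
      change_point_probability(small_delta, tt, cfg), numeric(1))
    expect_true(all(diff(om_t) >= -1e-12))
  }
})

test_that("uncertainty propagation matches conjugate-Gaussian oracles", {
  cfg <- model_config(noise_sd = 10)
  s2n <- 100
  # no change point: posterior variance of a mean after one more Gaussian
  # observation from prior variance tau*s2n
  r <- propagate_uncertainty(0, 0.5, delta = 37, cfg)
  expect_equal(r$sigma2_mu, s2n / 2, tolerance = 1e-12)
  expect_equal(r$tau, 1 / 3, tolerance = 1e-12)
  # certain change point: single-observation posterior
  r2 <- propagate_uncertainty(1, 0.8, delta = -12, cfg)
  expect_equal(r2$sigma2_mu, s2n, tolerance = 1e-12)
  expect_equal(r2$tau, 0.5, tolerance = 1e-12)
  # certainty is absorbing without change points
  r3 <- propagate_uncertainty(0, 0, delta = 5, cfg)
  expect_equal(r3$tau, 0)
  expect_error(propagate_uncertainty(-0.1, 0, 0, cfg), "omega")
})

test_that("normative update combines surprise and uncertainty", {
  expect_equal(normative_update(100, 40, 1, 0.2)$alpha, 1)
  expect_equal(normative_update(100, 40, 1, 0.2)$belief, 140)
  r <- normative_update(100, 40, 0, 0)
  expect_equal(r$alpha, 0)
  expect_equal(r$belief, 100)
  expect_equal(normative_update(0, 1, 0.5, 0.5)$alpha, 0.75)
})

test_that("catch-trial cue combination weighs by relative variance", {
  cfg <- model_config(heli_cue_sd = 10, noise_sd = 10)
  r <- catch_trial_combine(belief = 100, sigma2_mu = 100, mu = 140, cfg)
  expect_equal(r$w, 0.5)
  expect_equal(r$belief, 120)
  expect_equal(r$sigma2_mu, 50)
  # uninformative cue leaves belief nearly unchanged
  cfg_inf <- model_config(heli_cue_sd = 1e8)
  r2 <- catch_trial_combine(100, 100, 140, cfg_inf)
  expect_equal(r2$w, 1, tolerance = 1e-6)
  expect_equal(r2$belief, 100, tolerance = 1e-3)
  # near-perfect cue pins the belief to the true mean
  cfg_sharp <- model_config(heli_cue_sd = 1e-4)
  expect_equal(catch_trial_combine(100, 100, 140, cfg_sharp)$belief, 140,
               tolerance = 1e-4)
})

test_that("with no hazard the model reduces to the running mean (alpha = 1/t)", {
  cfg <- model_config(hazard = 0)
  tc <- task_config(n_trials = 200, hazard = 0, catch_rate = 0)
  blk <- generate_task_block(tc, seed = 3)
  tr <- run_model(blk, cfg, mode = "generative")
  expect_lt(max(abs(tr$alpha - 1 / seq_len(200))), 1e-10)
  expect_equal(tr$belief, cumsum(blk$bag) / seq_len(200), tolerance = 1e-10)
})

test_that("conditioned mode reproduces generative trajectories on own errors", {
  ses <- generate_task_session(task_config(), seed = 13)
  cfg <- model_config()
  g <- run_model(ses, cfg, mode = "generative")
  c1 <- run_model(ses, cfg, mode = "conditioned", observed_pe = g$delta)
  expect_equal(c1$omega, g$omega)
  expect_equal(c1$tau, g$tau)
  expect_equal(c1$alpha, g$alpha)
  expect_error(run_model(ses, cfg, mode = "conditioned"), "observed_pe")
})

test_that("uncertainty spikes after a change point and then decays", {
  cfg <- model_config()
  n <- 30
  blk <- data.frame(block = 1L, trial = 1:n, bag = 150, noise_sd = 10,
                    is_catch = FALSE, helicopter = 150)
  pe <- c(0, rep(1, 9), 120, rep(1, n - 11))  # large surprise at trial 11
  tr <- run_model(blk, cfg, mode = "conditioned", observed_pe = pe)
  expect_gt(tr$omega[11], 0.95)
  expect_gt(tr$tau[12], tr$tau[11])       # uncertainty rises after the CP
  post <- tr$tau[13:20]
  expect_true(all(diff(post) < 0))        # and decays over quiet trials
})

test_that("trajectory fields respect their invariants on long random runs", {
  cfg <- model_config()
  tc <- task_config(n_trials = 5000L)
  ses <- rbind(generate_task_block(tc, 10, block = 1, seed = 21),
               generate_task_block(tc, 25, block = 2, seed = 22))
  tr <- run_model(ses, cfg, mode = "generative")
  expect_true(all(tr$omega >= 0 & tr$omega <= 1))
  first <- c(TRUE, tr$block[-1] != tr$block[-nrow(tr)])
  expect_true(all(tr$tau[!first] >= 0 & tr$tau[!first] < 1))
  expect_equal(tr$tau[first], c(1, 1))
  expect_true(all(tr$alpha >= 0 & tr$alpha <= 1))
  expect_true(all(tr$sigma2_mu[!first] >= 0))
  expect_true(all(is.finite(tr$belief)))
  # the model tracks the helicopter better than a bucket-on-last-bag agent
  expect_lt(mean(abs(tr$belief - ses$helicopter)),
            mean(abs(ses$bag - ses$helicopter)))
})
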