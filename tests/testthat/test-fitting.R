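test_that("trial NLL matches the Gaussian log-density by hand", {
  # hand evaluation: residual 0, s.d. 2 -> 0.5*log(2*pi*4)
  expect_equal(trial_nll(5, 5, delta = 10, uv = 2, lrv = 0),
               0.5 * log(2 * pi * 4), tolerance = 1e-8)
  # general hand form
  u <- 3.7; uh <- 1.2; dl <- -20; uv <- 1.5; lrv <- 0.2
  s <- uv + lrv * abs(dl)
  expect_equal(trial_nll(u, uh, dl, uv, lrv),
               0.5 * log(2 * pi * s^2) + (u - uh)^2 / (2 * s^2),
               tolerance = 1e-8)
  # the mode of the density is at u = u_hat
  expect_true(all(trial_nll(c(4, 6), 5, 10, 2, 0) >
                    trial_nll(5, 5, 10, 2, 0)))
  # with LRV > 0 a zero residual gets costlier as |delta| grows
  expect_gt(trial_nll(0, 0, 50, 1, 0.3), trial_nll(0, 0, 5, 1, 0.3))
  expect_error(trial_nll(0, 0, 0, 0, 0), "positive")
})

test_that("mixture NLL reduces to a single Gaussian and bounds hold", {
  one <- noise_mixture_spec(grid_min = 1, grid_max = 1.0001, grid_size = 2,
                            shape = 5)
  # effectively a point mass at scale 1 with no response noise
  r <- c(-8, 0, 3, 15)
  got <- mixture_trial_nll(r, 0, delta = 0, uv = 0, lrv = 0,
                           total_sd = 10, spec = one)
  expect_equal(got, -dnorm(r, 0, 10 * one$scales[1], log = TRUE),
               tolerance = 1e-3)

  spec <- noise_mixture_spec(grid_size = 60, shape = 2)
  nll <- mixture_trial_nll(r, 0, 0, 0, 0, total_sd = 10, spec = spec)
  comp_nll <- sapply(spec$scales, function(s) -dnorm(r, 0, 10 * s, log = TRUE))
  # mixture density is sandwiched by its components
  expect_true(all(nll >= apply(comp_nll, 1, min) - 1e-10))
  for (i in seq_along(spec$scales))
    expect_true(all(nll <= comp_nll[, i] - log(spec$weights[i]) + 1e-10))
})

test_that("lower mixture shape puts more mass on extreme residuals", {
  tot <- 10
  nll_small <- mixture_trial_nll(4 * tot, 0, 0, 0, 0, tot,
                                 noise_mixture_spec(shape = 2))
  nll_large <- mixture_trial_nll(4 * tot, 0, 0, 0, 0, tot,
                                 noise_mixture_spec(shape = 50))
  expect_lt(nll_small, nll_large)
})

test_that("log posterior prefers the generating parameters", {
  d <- mk_subject_data(seed = 211, log_uu = 0, uv = 1, lrv = 0)
  truth <- flexible_params(update_variability = 1, lr_variability = 1e-3)
  off <- flexible_params(log_uu = 2, update_variability = 1,
                         lr_variability = 1e-3)
  expect_lt(negative_log_posterior(d, truth),
            negative_log_posterior(d, off))
})

test_that("likelihood is additive and the empty set leaves only the prior", {
  d <- mk_subject_data(seed = 223, log_uu = 1)
  p <- flexible_params(log_uu = 1, update_variability = 3,
                       lr_variability = 0.1)
  # duplicated session as two further blocks: identical trajectories
  blk2 <- d$block
  blk2$block <- blk2$block + 2L
  d2 <- structure(list(block = rbind(d$block, blk2),
                       bucket = c(d$bucket, d$bucket),
                       delta = c(d$delta, d$delta),
                       update = c(d$update, d$update),
                       included = c(d$included, d$included),
                       n_included = 2L * d$n_included),
                  class = "subject_data")
  prior_only <- structure(list(block = d$block[0, ], bucket = numeric(0),
                               delta = numeric(0), update = numeric(0),
                               included = logical(0), n_included = 0L),
                          class = "subject_data")
  pr <- negative_log_posterior(prior_only, p)
  expect_equal(negative_log_posterior(d2, p) - pr,
               2 * (negative_log_posterior(d, p) - pr), tolerance = 1e-8)
  # prior-only value matches the independent penalty formula
  pr_hand <- -dnorm(qlogis(p$hazard), qlogis(0.1), 2, log = TRUE) -
    dnorm(p$surprise_sens, 1, 0.5, log = TRUE) -
    dnorm(p$log_uu, 0, 2, log = TRUE)
  expect_equal(pr, pr_hand, tolerance = 1e-10)
})

test_that("the objective is a pure function of its parameters", {
  d <- mk_subject_data(seed = 227, log_uu = 1)
  grid <- seq(0, 3, length.out = 7)
  vals1 <- vapply(grid, function(lu)
    negative_log_posterior(d, flexible_params(log_uu = lu,
                                              update_variability = 3,
                                              lr_variability = 0.1)),
    numeric(1))
  vals2 <- vapply(rev(grid), function(lu)
    negative_log_posterior(d, flexible_params(log_uu = lu,
                                              update_variability = 3,
                                              lr_variability = 0.1)),
    numeric(1))
  expect_identical(vals1, rev(vals2))
})

test_that("the fit is a fixed point and reproducible given the seed", {
  d <- mk_subject_data(seed = 229, log_uu = 2)
  f1 <- fit_subject(d, n_restarts = 2, seed = 8)
  f2 <- fit_subject(d, n_restarts = 2, seed = 8)
  expect_equal(f1$log_posterior, f2$log_posterior)
  expect_equal(f1$params$log_uu, f2$params$log_uu)
  expect_true(f1$converged)
  # recorded optimum equals a fresh evaluation at the fitted parameters
  expect_equal(negative_log_posterior(d, f1$params), -f1$log_posterior,
               tolerance = 1e-10)
  expect_error(fit_subject(d, min_trials = 1e5), "included trials")
})

test_that("fitted uncertainty underestimation anticorrelates with small-error learning", {
  log_uus <- rep(c(0, 1, 2, 3), each = 3)
  rec <- numeric(length(log_uus))
  small_lr <- numeric(length(log_uus))
  for (i in seq_along(log_uus)) {
    seed <- 500 + 7 * i
    ses <- mk_session(seed)
    ag <- agent_spec("flexible",
                     params = flexible_params(log_uu = log_uus[i],
                                              update_variability = 3,
                                              lr_variability = 0.1),
                     seed = seed + 1)
    beh <- simulate_agent(ses, ag)
    d <- subject_data(ses, beh)
    rec[i] <- fit_subject(d, n_restarts = 2, seed = seed)$params$log_uu
    ds <- make_regression_dataset(ses, beh)
    wf <- sliding_window_fit(ds, estimate_heteroscedastic_weights(ds))
    lr <- term_vec(wf, "learning_rate")
    small_lr[i] <- mean(lr[1:10])
  }
  expect_gte(cor(log_uus, rec, method = "spearman"), 0.8)
  expect_lt(cor(rec, small_lr), 0)
})

test_that("model comparison recovers the generating noise family", {
  base_data <- lapply(c(601, 602, 603), function(s)
    mk_subject_data(s, log_uu = 1, max_dev = Inf))
  mix_data <- lapply(c(701, 702, 703), function(s)
    mk_subject_data(s, log_uu = 1, noise_shape = 3, max_dev = Inf,
                    n_trials = 100))
  cb <- compare_noise_models(base_data, model_ids = c("base", "noise_mixture"),
                             n_restarts = 2, seed = 1)
  cm <- compare_noise_models(mix_data, model_ids = c("base", "noise_mixture"),
                             n_restarts = 2, seed = 2)
  expect_gte(cb$tally[["base"]], 2)
  expect_gte(cm$tally[["noise_mixture"]], 2)
  expect_error(compare_noise_models(base_data, model_ids = "base"), "two")
})

test_that("parameter serialization round-trips through JSON", {
  p <- flexible_params(hazard = 0.05, surprise_sens = 0.7, log_uu = 1.3,
                       noise_scale = 1.2, noise_offset = -2,
                       noise_shape = 4, update_variability = 2.5,
                       lr_variability = 0.15)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  params_to_json(p, path)
  expect_equal(params_from_json(path), p)
})
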