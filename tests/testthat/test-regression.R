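test_that("trial exclusion rules match hand application", {
  # 5 trials, one block; trial 3 is the case under test
  blk <- data.frame(block = 1L, trial = 1:5,
                    helicopter = 120, bag = c(110, 120, 140, 130, 125),
                    noise_sd = 10, is_changepoint = FALSE,
                    is_catch = FALSE, is_gold = TRUE)
  # bucket on trial 3 is 100, bag 140; next bucket 160 is 20 beyond the
  # segment [100, 140] -> excluded
  bucket <- c(150, 115, 100, 160, 140)
  ds <- preprocess_trials(blk, bucket)
  expect_false(3 %in% ds$trial)
  expect_false(1 %in% ds$trial)  # first trial of block
  expect_false(5 %in% ds$trial)  # last trial of block
  # next bucket inside the segment -> included (distance 0)
  bucket2 <- c(150, 115, 100, 120, 140)
  expect_true(3 %in% preprocess_trials(blk, bucket2)$trial)
  # zero prediction error -> excluded regardless of the update
  blk0 <- blk; blk0$bag[3] <- 100
  expect_false(3 %in% preprocess_trials(blk0, bucket2)$trial)
})

test_that("catch trials admit updates towards the visible helicopter", {
  blk <- data.frame(block = 1L, trial = 1:5,
                    helicopter = 250, bag = c(110, 120, 140, 130, 125),
                    noise_sd = 10, is_changepoint = FALSE,
                    is_catch = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                    is_gold = TRUE)
  bucket <- c(150, 115, 100, 200, 140)  # moves towards the helicopter at 250
  expect_true(3 %in% preprocess_trials(blk, bucket)$trial)
  blk$is_catch[3] <- FALSE
  expect_false(3 %in% preprocess_trials(blk, bucket)$trial)
})

test_that("exclusions are rare for near-deterministic normative agents", {
  r <- mk_agent_run("normative", seed = 61, n_blocks = 4, uv = 1)
  ds <- preprocess_trials(r$session, r$beh)
  expect_lt(attr(ds, "excluded_fraction"), 0.05)
})

test_that("model regressors equal the agent's own latents for noise-free agents", {
  r <- mk_agent_run("normative", seed = 67, uv = 0)
  reg <- compute_model_regressors(r$session, r$beh)
  tr <- run_model(r$session, model_config(), mode = "generative")
  expect_equal(reg$surprise, tr$omega, tolerance = 1e-10)
  expect_equal(reg$uncertainty, tr$tau, tolerance = 1e-10)
})

test_that("ridge solver matches closed forms and shrinks towards zero", {
  # hand case: single column of ones, y = (1, 1), lambda = 0.1
  A <- cbind(x = c(1, 1))
  expect_equal(unname(ridge_weighted_solve(A, c(1, 1), lambda = 0.1)),
               2 / 2.1, tolerance = 1e-8)
  # lambda = 0 with unit weights is OLS
  set.seed(2)
  n <- 80
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
  y <- drop(X %*% c(1, 2, -0.5)) + rnorm(n)
  expect_equal(unname(ridge_weighted_solve(X, y, lambda = 0)),
               unname(coef(lm(y ~ a + b, data = as.data.frame(X)))),
               tolerance = 1e-8)
  # weighted solve equals lm with weights
  w <- runif(n, 0.2, 3)
  expect_equal(unname(ridge_weighted_solve(X, y, w, lambda = 0)),
               unname(coef(lm(y ~ a + b, data = as.data.frame(X),
                              weights = w))),
               tolerance = 1e-8)
  # independently computed penalized normal equations
  lam <- 0.7
  R <- diag(c(0, lam, lam))
  beta_hand <- solve(t(X) %*% diag(w) %*% X + R, t(X) %*% diag(w) %*% y)
  expect_equal(unname(ridge_weighted_solve(X, y, w, lambda = lam)),
               unname(drop(beta_hand)), tolerance = 1e-8)
  # shrinkage of non-intercept coefficients is monotone in lambda
  norms <- vapply(c(0, 0.5, 5, 50), function(l)
    sqrt(sum(ridge_weighted_solve(X, y, lambda = l)[-1]^2)), numeric(1))
  expect_true(all(diff(norms) < 1e-10))
})

test_that("heteroscedasticity weights track residual variance", {
  # homoscedastic agent: all weights about equal
  r <- mk_agent_run("fixed_learning_rate", seed = 71, n_blocks = 14,
                    uv = 5, lrv = 0)
  ds <- make_regression_dataset(r$session, r$beh)
  w <- estimate_heteroscedastic_weights(ds)
  expect_lt(sd(w) / mean(w), 0.2)
  # residual s.d. growing with |delta|: weights fall with |delta|
  r2 <- mk_agent_run("fixed_learning_rate", seed = 73, n_blocks = 14,
                     uv = 0.5, lrv = 0.5)
  ds2 <- make_regression_dataset(r2$session, r2$beh)
  w2 <- estimate_heteroscedastic_weights(ds2)
  expect_lt(cor(abs(ds2$delta), w2, method = "spearman"), -0.9)
  # tiny datasets collapse to a single window with equal weights
  ds_small <- ds[1:12, ]
  w_small <- estimate_heteroscedastic_weights(ds_small)
  expect_equal(length(unique(w_small)), 1)
})

test_that("sliding windows hold the smallest relative errors first", {
  r <- mk_agent_run("normative", seed = 79, n_blocks = 6, uv = 2)
  ds <- make_regression_dataset(r$session, r$beh)
  wf <- sliding_window_fit(ds, lambda = 0.1)
  expect_equal(length(unique(wf$bin)), 90)
  expect_setequal(unique(wf$n_trials), round(0.1 * nrow(ds)))
  med <- unique(wf[, c("bin", "bin_median_rel_err")])$bin_median_rel_err
  expect_true(all(diff(med) >= 0))
  k <- round(0.1 * nrow(ds))
  expect_equal(unique(wf$bin_median_rel_err[wf$bin == 1]),
               median(sort(ds$abs_rel_err)[1:k]))
})

test_that("non-overlapping windows equal independent per-bin OLS", {
  r <- mk_agent_run("normative", seed = 83, n_blocks = 2, uv = 3)
  ds <- make_regression_dataset(r$session, r$beh)
  n <- nrow(ds)
  wf <- sliding_window_fit(ds, weights = rep(1, n), lambda = 0,
                           n_bins = 2, window_frac = 0.5)
  ord <- order(ds$abs_rel_err)
  k <- round(0.5 * n)
  halves <- list(ord[1:k], ord[(n - k + 1):n])
  for (b in 1:2) {
    sub <- ds[halves[[b]], ]
    # independent construction: window-centred interactions residualized
    # against delta, then plain OLS
    ortho <- function(f) {
      cl <- sub$delta * (as.numeric(f) - mean(f))
      cl - sub$delta * sum(sub$delta * cl) / sum(sub$delta^2)
    }
    M <- cbind(1, sub$delta, ortho(sub$surprise), ortho(sub$uncertainty),
               ortho(sub$noise_sd), ortho(sub$is_gold), ortho(sub$is_catch),
               sub$heli_pull, sub$centre_bias)
    fit <- lm.fit(M, sub$update)
    expect_equal(sort(abs(wf$estimate[wf$bin == b & wf$term != "learning_rate"])),
                 sort(abs(unname(fit$coefficients))), tolerance = 1e-6)
  }
})

test_that("cue integration shows up in the helicopter coefficient", {
  r <- mk_agent_run("normative", seed = 89, n_blocks = 6, uv = 1)
  ds <- make_regression_dataset(r$session, r$beh)
  A <- predinf:::.design_matrix(ds)
  beta <- ridge_weighted_solve(A, ds$update, lambda = 0)
  expect_gt(beta[["heli_pull"]], 0.2)
  # an agent that ignores the cue has a near-zero helicopter coefficient
  r2 <- mk_agent_run("flexible", seed = 97, n_blocks = 6, uv = 1,
                     params = flexible_params(heli_cue_sd = 1e6,
                                              update_variability = 1))
  ds2 <- make_regression_dataset(r2$session, r2$beh)
  A2 <- predinf:::.design_matrix(ds2)
  beta2 <- ridge_weighted_solve(A2, ds2$update, lambda = 0)
  expect_lt(abs(beta2[["heli_pull"]]), 0.05)
})

test_that("normative learning rates rise with relative error magnitude", {
  wf <- mk_window_fit("normative", seed = 101)
  lr <- term_vec(wf, "learning_rate")
  expect_gt(mean(lr[81:90]), mean(lr[1:10]) + 0.1)
})
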