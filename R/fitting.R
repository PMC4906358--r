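#' Bundle one subject's data for model fitting
#'
#' Computes prediction errors and updates from the task and behaviour tables
#' and marks the trials retained by the standard exclusion rules
#' ([preprocess_trials()]). The model recursion always runs over every
#' trial (state must evolve through excluded trials); the likelihood sums
#' over included trials only.
#'
#' @param block Task table.
#' @param beh Behaviour table (or bucket vector).
#' @param max_dev Exclusion distance for [preprocess_trials()].
#' @return A list of class `subject_data` with `block`, `bucket`, `delta`,
#'   `update`, `included` (logical over trials) and `n_included`.
#' @export
subject_data <- function(block, beh, max_dev = 15) {
  bucket <- if (is.data.frame(beh)) beh$bucket else beh
  ds <- preprocess_trials(block, beh, max_dev = max_dev)
  blk <- if ("block" %in% names(block)) block$block else rep(1L, nrow(block))
  key_all <- paste(blk, block$trial)
  included <- key_all %in% paste(ds$block, ds$trial)
  nxt <- c(bucket[-1], NA_real_)
  structure(
    list(block = block, bucket = bucket, delta = block$bag - bucket,
         update = nxt - bucket, included = included,
         n_included = sum(included)),
    class = "subject_data")
}

#' Gaussian response negative log-likelihood for one trial
#'
#' The observed update is modelled as Gaussian around the model-predicted
#' update with s.d. `UV + LRV * |delta|` (update variability plus
#' learning-rate variability scaled by error magnitude).
#'
#' @param u Observed update(s).
#' @param u_hat Model-predicted update(s).
#' @param delta Prediction error(s).
#' @param uv,lrv Response-variability parameters (`UV + LRV*|delta| > 0`).
#' @return Negative log-likelihood in nats (vectorized).
#' @export
trial_nll <- function(u, u_hat, delta, uv, lrv) {
  s <- uv + lrv * abs(delta)
  if (any(s <= 0)) stop("response s.d. must be positive", call. = FALSE)
  -stats::dnorm(u, u_hat, s, log = TRUE)
}

#' Grid specification for the noise-scale mixture
#'
#' The noise-variability model represents uncertainty about the noise level
#' as a weighted mixture over scale factors on the total predictive
#' uncertainty: scales are uniformly spaced grid points on
#' `[grid_min, grid_max]` with weights proportional to an inverse-gamma
#' density (shape `nu`, scale `nu + 1`, so the density mode sits at scale
#' 1: unbiased noise perception at the mode). Lower `nu` spreads weight
#' over scales (more uncertainty about the noise level, heavier tails).
#'
#' @param grid_min,grid_max Range of the scale grid.
#' @param grid_size Number of grid points.
#' @param shape Inverse-gamma shape `nu > 0`.
#' @return A list of class `noise_mixture_spec` with `scales`, `shape` and
#'   normalized `weights`.
#' @export
noise_mixture_spec <- function(grid_min = 0.1, grid_max = 100,
                               grid_size = 200L, shape = 2) {
  if (grid_min <= 0 || grid_max <= grid_min)
    stop("invalid scale grid", call. = FALSE)
  if (shape <= 0) stop("`shape` must be positive", call. = FALSE)
  s <- seq(grid_min, grid_max, length.out = grid_size)
  lw <- .dinvgamma_log(s, shape, shape + 1)
  lw <- lw - max(lw)
  w <- exp(lw)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("mixture weights underflowed for shape ", shape, call. = FALSE)
  structure(list(scales = s, shape = shape, weights = w / tot),
            class = "noise_mixture_spec")
}

# log inverse-gamma density, shape a, scale b
.dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Mixture-of-noise-scales response negative log-likelihood
#'
#' The residual `u - u_hat` is evaluated under a weighted mixture of
#' zero-mean Gaussians whose component s.d.s are scaled versions of the
#' total predictive uncertainty, composed in quadrature with the response
#' s.d.: component i has variance
#' `(scale_i * total_sd)^2 + (UV + LRV*|delta|)^2`. Weights follow the
#' inverse-gamma spec, normalized over the grid.
#'
#' @param u,u_hat,delta,uv,lrv As in [trial_nll()] (here `uv = lrv = 0` is
#'   allowed since the mixture components have positive s.d.).
#' @param total_sd Total predictive s.d.(s), screen units.
#' @param spec A [noise_mixture_spec()].
#' @return Negative log-likelihood in nats (vectorized over trials).
#' @export
mixture_trial_nll <- function(u, u_hat, delta, uv, lrv, total_sd, spec) {
  stopifnot(inherits(spec, "noise_mixture_spec"))
  r <- u - u_hat
  resp2 <- rep((uv + lrv * abs(delta))^2, length.out = length(r))
  total_sd <- rep(total_sd, length.out = length(r))
  # trials x components matrices
  v <- outer(total_sd^2, spec$scales^2) + resp2
  ll <- -0.5 * log(2 * pi * v) - (r * r) / (2 * v)
  lw <- matrix(log(spec$weights), nrow = length(r), ncol = length(spec$scales),
               byrow = TRUE)
  M <- ll + lw
  m <- do.call(pmax, as.data.frame(M))  # row-wise max
  out <- -(m + log(rowSums(exp(M - m))))
  if (any(!is.finite(out)))
    stop("mixture likelihood degenerated (all components underflow)",
         call. = FALSE)
  out
}

#' Weak priors favouring normative learning parameters
#'
#' Independent Gaussian penalties on logit-hazard (centred on logit 0.1),
#' surprise sensitivity (centred on 1) and log uncertainty underestimation
#' (centred on 0). Response-variability and noise-perception parameters get
#' flat priors (bounds only).
#'
#' @param logit_h_sd,ss_sd,log_uu_sd Prior s.d.s.
#' @return A list of class `fit_priors`.
#' @export
default_priors <- function(logit_h_sd = 2, ss_sd = 0.5, log_uu_sd = 2) {
  structure(list(logit_h_mean = stats::qlogis(0.1), logit_h_sd = logit_h_sd,
                 ss_mean = 1, ss_sd = ss_sd,
                 log_uu_mean = 0, log_uu_sd = log_uu_sd),
            class = "fit_priors")
}

.prior_penalty <- function(params, priors) {
  -stats::dnorm(stats::qlogis(params$hazard), priors$logit_h_mean,
                priors$logit_h_sd, log = TRUE) -
    stats::dnorm(params$surprise_sens, priors$ss_mean, priors$ss_sd,
                 log = TRUE) -
    stats::dnorm(params$log_uu, priors$log_uu_mean, priors$log_uu_sd,
                 log = TRUE)
}

# shared likelihood machinery: trajectory + per-trial NLL over included trials
.data_nll <- function(data, params, model_id, mixture_spec) {
  block <- data$block
  n <- nrow(block)
  blk <- if ("block" %in% names(block)) block$block else rep(1L, n)
  mix <- if (model_id == "noise_mixture")
    mixture_spec_for(params, mixture_spec) else NULL
  tr <- .flex_traj(
    n, blk, block$bag, block$noise_sd,
    if ("is_catch" %in% names(block)) block$is_catch else logical(n),
    if ("helicopter" %in% names(block)) block$helicopter else rep(NA_real_, n),
    H = params$hazard, ss = params$surprise_sens, uu = exp(params$log_uu),
    sH2 = params$heli_cue_sd^2, smult = params$noise_scale,
    sadd = params$noise_offset, U = 1 / 300, centre = 150,
    generative = FALSE, observed_pe = data$delta,
    observed_bucket = data$bucket,
    mix_scales = mix$scales, mix_weights = mix$weights)
  inc <- data$included
  u <- data$update[inc]
  u_hat <- tr$pred_update[inc]
  d <- data$delta[inc]
  uv <- params$update_variability
  lrv <- params$lr_variability
  if (model_id == "noise_mixture") {
    sdp <- pmax(params$noise_scale * block$noise_sd + params$noise_offset, 0.5)
    total_sd <- sqrt(tr$sigma2_mu + sdp^2)[inc]
    sum(mixture_trial_nll(u, u_hat, d, uv, lrv, total_sd, mix))
  } else {
    sum(trial_nll(u, u_hat, d, uv, lrv))
  }
}

# spec with the shape overridden by the parameter vector, when set
mixture_spec_for <- function(params, spec) {
  if (is.na(params$noise_shape)) return(spec)
  noise_mixture_spec(grid_min = min(spec$scales), grid_max = max(spec$scales),
                     grid_size = length(spec$scales),
                     shape = params$noise_shape)
}

#' Negative log posterior of the flexible model for one subject
#'
#' Sum of per-trial response negative log-likelihoods over included trials
#' (Gaussian, or the noise-scale mixture for `model_id = "noise_mixture"`),
#' with the model-predicted updates obtained by running the flexible model
#' in conditioned mode over the subject's own prediction errors, plus the
#' weak prior penalties of [default_priors()].
#'
#' @param data A [subject_data()] object.
#' @param params A [flexible_params()].
#' @param model_id One of `"base"`, `"noise_scaled"`,
#'   `"noise_scaled_offset"`, `"noise_mixture"`.
#' @param priors A [default_priors()] object.
#' @param mixture_spec A [noise_mixture_spec()] (used for
#'   `"noise_mixture"`; its shape is overridden by `params$noise_shape`
#'   when that is set).
#' @return Negative log posterior in nats. With no included trials this is
#'   the prior penalty alone.
#' @export
negative_log_posterior <- function(data, params, model_id = "base",
                                   priors = default_priors(),
                                   mixture_spec = noise_mixture_spec()) {
  stopifnot(inherits(data, "subject_data"), inherits(params, "flexible_params"))
  model_id <- match.arg(model_id, c("base", "noise_scaled",
                                    "noise_scaled_offset", "noise_mixture"))
  if (model_id == "noise_mixture")
    mixture_spec <- mixture_spec_for(params, mixture_spec)
  lik <- if (data$n_included > 0)
    .data_nll(data, params, model_id, mixture_spec) else 0
  if (!is.finite(lik))
    stop("non-finite likelihood encountered during model evaluation",
         call. = FALSE)
  lik + .prior_penalty(params, priors)
}

# parameter vector <-> flexible_params, per model family
.fit_layout <- function(model_id, fit_heli_sd) {
  nm <- c("logit_h", "ss", "log_uu", "log_uv", "lrv")
  lower <- c(stats::qlogis(1e-4), 0.05, 0, log(0.05), 0)
  upper <- c(stats::qlogis(0.5), 1, 6, log(50), 3)
  start <- c(stats::qlogis(0.1), 1, 0, log(3), 0.05)
  if (model_id %in% c("noise_scaled", "noise_scaled_offset")) {
    nm <- c(nm, "log_smult"); lower <- c(lower, log(0.2))
    upper <- c(upper, log(5)); start <- c(start, 0)
  }
  if (model_id == "noise_scaled_offset") {
    nm <- c(nm, "sadd"); lower <- c(lower, -20)
    upper <- c(upper, 50); start <- c(start, 0)
  }
  if (model_id == "noise_mixture") {
    nm <- c(nm, "log_nu"); lower <- c(lower, log(0.3))
    upper <- c(upper, log(100)); start <- c(start, log(5))
  }
  if (fit_heli_sd) {
    nm <- c(nm, "log_sH"); lower <- c(lower, log(1))
    upper <- c(upper, log(300)); start <- c(start, log(10))
  }
  list(names = nm, lower = lower, upper = upper, start = start)
}

.vec_to_params <- function(x, nm) {
  g <- function(k, default) if (k %in% nm) unname(x[match(k, nm)]) else default
  flexible_params(
    hazard = stats::plogis(g("logit_h", stats::qlogis(0.1))),
    surprise_sens = g("ss", 1),
    log_uu = g("log_uu", 0),
    heli_cue_sd = exp(g("log_sH", log(10))),
    noise_scale = exp(g("log_smult", 0)),
    noise_offset = g("sadd", 0),
    noise_shape = if ("log_nu" %in% nm) exp(g("log_nu", NA)) else NA_real_,
    update_variability = exp(g("log_uv", log(1))),
    lr_variability = g("lrv", 0))
}

#' Fit the flexible model to one subject by MAP estimation
#'
#' Bound-constrained quasi-Newton (`optim` L-BFGS-B) maximization of the log
#' posterior of the subject's updates given their prediction errors, from
#' `n_restarts` jittered starting points (the first start is the normative
#' point). Uncertainty underestimation is estimated and reported in log
#' units.
#'
#' @param data A [subject_data()] object.
#' @param model_id Model family (see [negative_log_posterior()]).
#' @param n_restarts Number of optimizer starts.
#' @param seed Optional integer seed for the start jitter.
#' @param priors A [default_priors()] object.
#' @param fit_heli_sd Also fit the helicopter-cue s.d.? (fixed at 10
#'   otherwise).
#' @param mixture_spec Scale grid for the mixture family.
#' @param penalty `"bic"` (default) or `"aic"` for the model-comparison
#'   score.
#' @param min_trials Minimum number of included trials required.
#' @param control Passed to [stats::optim()] (defaults:
#'   `maxit = 200, factr = 1e8`).
#' @return An object of class `fit_result`: `params`, `log_posterior`,
#'   `log_lik`, `n_trials`, `n_params`, `converged`, `n_restarts`,
#'   `model_id`, `penalty_score`.
#' @export
fit_subject <- function(data, model_id = "base", n_restarts = 10,
                        seed = NULL, priors = default_priors(),
                        fit_heli_sd = FALSE,
                        mixture_spec = noise_mixture_spec(),
                        penalty = c("bic", "aic"), min_trials = 50,
                        control = list()) {
  stopifnot(inherits(data, "subject_data"))
  penalty <- match.arg(penalty)
  model_id <- match.arg(model_id, c("base", "noise_scaled",
                                    "noise_scaled_offset", "noise_mixture"))
  if (data$n_included < min_trials)
    stop("fewer than ", min_trials, " included trials", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lay <- .fit_layout(model_id, fit_heli_sd)
  nm <- lay$names
  ctl <- utils::modifyList(list(maxit = 200, factr = 1e8), control)

  # data-driven guess for the update-variability scale
  inc <- data$included
  uv0 <- stats::sd(data$update[inc] - 0.6 * data$delta[inc])
  start0 <- lay$start
  start0[match("log_uv", nm)] <- log(max(0.5, min(uv0, 40)))

  obj <- function(x) {
    p <- .vec_to_params(stats::setNames(x, nm), nm)
    negative_log_posterior(data, p, model_id, priors, mixture_spec)
  }
  best <- NULL
  n_ok <- 0L
  for (r in seq_len(n_restarts)) {
    x0 <- if (r == 1L) start0 else
      pmin(lay$upper, pmax(lay$lower,
        start0 + stats::runif(length(nm), -1, 1) * (lay$upper - lay$lower) / 6))
    fit <- tryCatch(
      stats::optim(x0, obj, method = "L-BFGS-B", lower = lay$lower,
                   upper = lay$upper, control = ctl),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(params = NULL, log_posterior = NA_real_,
                          log_lik = NA_real_, n_trials = data$n_included,
                          n_params = length(nm), converged = FALSE,
                          n_restarts = n_restarts, model_id = model_id,
                          penalty_score = NA_real_),
                     class = "fit_result"))
  params <- .vec_to_params(stats::setNames(best$par, nm), nm)
  nll_lik <- .data_nll(data, params, model_id,
                       mixture_spec_for(params, mixture_spec))
  k <- length(nm)
  score <- if (penalty == "bic") 2 * nll_lik + k * log(data$n_included)
           else 2 * nll_lik + 2 * k
  structure(list(params = params, log_posterior = -best$value,
                 log_lik = -nll_lik, n_trials = data$n_included,
                 n_params = k, converged = n_ok > 0L,
                 n_restarts = n_restarts, model_id = model_id,
                 penalty_score = score),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Flexible-model fit (%s): log posterior %.2f over %d trials\n",
              x$model_id, x$log_posterior, x$n_trials))
  if (!is.null(x$params))
    cat(sprintf("  H = %.4g, SS = %.3g, log-UU = %.3g, UV = %.3g, LRV = %.3g\n",
                x$params$hazard, x$params$surprise_sens, x$params$log_uu,
                x$params$update_variability, x$params$lr_variability))
  cat(sprintf("  penalty score %.2f (%d parameters)%s\n", x$penalty_score,
              x$n_params, if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Compare noise-perception model families by penalized fit
#'
#' Fits each requested model family to each subject and ranks families per
#' subject by penalized score (ties broken by fewest parameters), plus a
#' cohort-level tally of wins.
#'
#' @param data A [subject_data()] object or a list of them.
#' @param model_ids At least two of `"base"`, `"noise_scaled"`,
#'   `"noise_scaled_offset"`, `"noise_mixture"`.
#' @param n_restarts,seed,... Passed to [fit_subject()].
#' @return A list with `scores` (data.frame: subject, model_id, penalty
#'   score, log-likelihood, parameter count, winner flag) and `tally`
#'   (named wins per model).
#' @export
compare_noise_models <- function(data, model_ids = c("base", "noise_scaled",
                                                     "noise_scaled_offset",
                                                     "noise_mixture"),
                                 n_restarts = 5, seed = NULL, ...) {
  if (length(model_ids) < 2)
    stop("need at least two model families", call. = FALSE)
  if (inherits(data, "subject_data")) data <- list(data)
  if (!is.null(seed)) set.seed(seed)
  fit_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(data) * length(model_ids))
  rows <- list()
  idx <- 0L
  for (i in seq_along(data)) {
    res <- list()
    for (m in model_ids) {
      idx <- idx + 1L
      res[[m]] <- fit_subject(data[[i]], model_id = m,
                              n_restarts = n_restarts,
                              seed = fit_seeds[idx], ...)
    }
    sc <- vapply(res, `[[`, numeric(1), "penalty_score")
    np <- vapply(res, `[[`, numeric(1), "n_params")
    win <- order(sc, np)[1]
    rows[[i]] <- data.frame(
      subject = i, model_id = model_ids, penalty_score = unname(sc),
      log_lik = vapply(res, `[[`, numeric(1), "log_lik"),
      n_params = unname(np), winner = seq_along(model_ids) == win,
      row.names = NULL)
  }
  scores <- do.call(rbind, rows)
  tally <- tapply(scores$winner, scores$model_id, sum)
  list(scores = scores, tally = tally[model_ids])
}
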