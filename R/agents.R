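#' Specify a simulated agent
#'
#' An agent performs the task by computing a deterministic model update on
#' each trial and corrupting it with response noise of s.d.
#' `UV + LRV * |delta|` (update variability and learning-rate variability).
#' Named kinds preset the flexible-model deviation parameters used in model
#' simulations: `surprise_insensitive` (SS = 0.2), `low_hazard` (H = 0.001),
#' `uncertainty_underestimation` (UU = 10); `fixed_learning_rate` bypasses
#' the model and always updates by `fixed_lr * delta`; `flexible` uses
#' `params` as given.
#'
#' @param model_kind One of `"normative"`, `"surprise_insensitive"`,
#'   `"low_hazard"`, `"uncertainty_underestimation"`,
#'   `"fixed_learning_rate"`, `"flexible"`.
#' @param params A [flexible_params()]; defaults are preset by `model_kind`.
#'   Response variability is read from
#'   `params$update_variability`/`params$lr_variability`, overridable here.
#' @param update_variability,lr_variability Optional overrides for the
#'   response-noise terms.
#' @param fixed_lr Learning rate for the `fixed_learning_rate` kind.
#' @param seed Optional integer seed for the agent's response noise.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(model_kind = c("normative", "surprise_insensitive",
                                      "low_hazard",
                                      "uncertainty_underestimation",
                                      "fixed_learning_rate", "flexible"),
                       params = NULL, update_variability = NULL,
                       lr_variability = NULL, fixed_lr = 0.5, seed = NULL) {
  model_kind <- match.arg(model_kind)
  if (is.null(params)) {
    params <- switch(model_kind,
      surprise_insensitive = flexible_params(surprise_sens = 0.2),
      low_hazard = flexible_params(hazard = 0.001),
      uncertainty_underestimation = flexible_params(log_uu = log(10)),
      flexible_params())
  }
  stopifnot(inherits(params, "flexible_params"))
  if (!is.null(update_variability))
    params$update_variability <- update_variability
  if (!is.null(lr_variability)) params$lr_variability <- lr_variability
  if (params$update_variability < 0 || params$lr_variability < 0)
    stop("response-variability terms must be >= 0", call. = FALSE)
  structure(list(model_kind = model_kind, params = params,
                 fixed_lr = fixed_lr, seed = seed),
            class = "agent_spec")
}

#' Simulate an agent performing the task
#'
#' On each trial the agent experiences the prediction error implied by its
#' own (noisy) bucket position, computes the deterministic model update, and
#' realizes it with Gaussian response noise of s.d. `UV + LRV * |delta|`.
#' Bucket positions are clamped to the screen. The latent model state is
#' driven by the agent's experienced prediction errors, exactly matching the
#' assumptions of the fitting routine. If the agent's `noise_shape` is set,
#' a noise scale is additionally drawn each trial from the inverse-gamma
#' grid of [noise_mixture_spec()] and composed in quadrature with the
#' response s.d. (trialwise variability in perceived noise, the generative
#' counterpart of the `noise_mixture` fitting model).
#'
#' @param block Task table ([generate_task_block()] /
#'   [generate_task_session()]).
#' @param agent An [agent_spec()].
#' @param cfg Optional [model_config()] supplying screen bounds and outcome
#'   range.
#' @param seed Optional seed (overrides `agent$seed`).
#' @return A behaviour data.frame with columns `block`, `trial`, `bucket`
#'   (prediction on that trial), `delta` (experienced prediction error),
#'   `pred_update` (deterministic model update), `update` (realized update,
#'   after clamping).
#' @export
simulate_agent <- function(block, agent, cfg = model_config(), seed = NULL) {
  stopifnot(inherits(agent, "agent_spec"))
  if (is.null(seed)) seed <- agent$seed
  if (!is.null(seed)) set.seed(seed)
  p <- agent$params
  n <- nrow(block)
  noise <- block$noise_sd
  catch <- if ("is_catch" %in% names(block)) block$is_catch else logical(n)
  mu <- if ("helicopter" %in% names(block)) block$helicopter else
    rep(NA_real_, n)
  blk <- if ("block" %in% names(block)) block$block else rep(1L, n)
  lo <- cfg$screen_min
  hi <- cfg$screen_max
  centre <- (lo + hi) / 2
  U <- 1 / cfg$range_width
  H <- p$hazard
  ss <- p$surprise_sens
  uu <- exp(p$log_uu)
  sH2 <- p$heli_cue_sd^2
  smult <- p$noise_scale
  sadd <- p$noise_offset
  uv <- p$update_variability
  lrv <- p$lr_variability
  fixed <- agent$model_kind == "fixed_learning_rate"
  hr <- H / (1 - H)
  z <- stats::rnorm(n)
  mix_scale <- NULL
  mix <- NULL
  if (!fixed && !is.na(p$noise_shape)) {
    mix <- noise_mixture_spec(shape = p$noise_shape)
    mix_scale <- sample(mix$scales, n, replace = TRUE, prob = mix$weights)
    z2 <- stats::rnorm(n)
  }

  out_bucket <- out_delta <- out_pred <- out_upd <- numeric(n)
  tau <- 1
  bucket <- centre
  for (t in seq_len(n)) {
    if (t > 1L && blk[t] != blk[t - 1L]) {
      tau <- 1
      bucket <- centre
    }
    d <- block$bag[t] - bucket
    if (fixed) {
      u_hat <- agent$fixed_lr * d
    } else {
      sdp <- smult * noise[t] + sadd
      if (sdp < 0.5) sdp <- 0.5
      s2n <- sdp^2
      # pre-observation total predictive s.d. (flat-prior trials use the
      # post-first-observation value; they are excluded downstream)
      if (!is.null(mix_scale))
        tot_sd <- if (tau < 1) sqrt(s2n / (1 - tau)) else sqrt(2 * s2n)
      if (H <= 0) {
        omega <- 0
      } else {
        s2tot <- s2n / (1 - tau)
        if (is.null(mix)) {
          dens <- exp(-(d * d) / (2 * s2tot)) / sqrt(2 * pi * s2tot)
        } else {
          v <- mix$scales^2 * s2tot
          dens <- sum(mix$weights * exp(-(d * d) / (2 * v)) / sqrt(2 * pi * v))
        }
        omega <- (U * H) / (U * H + dens * (1 - H))
      }
      if (ss < 1 && omega > 0 && omega < 1) {
        odds <- (omega / (1 - omega))^ss * hr^(1 - ss)
        omega <- odds / (1 + odds)
      }
      alpha <- omega + (1 - omega) * tau
      pred_b <- bucket + alpha * d
      s2 <- omega * s2n + (1 - omega) * tau * s2n +
        omega * (1 - omega) * (d * (1 - tau))^2
      if (uu > 1) s2 <- s2 / uu
      if (catch[t]) {
        w <- sH2 / (sH2 + s2)
        pred_b <- w * pred_b + (1 - w) * mu[t]
        s2 <- 1 / (1 / s2 + 1 / sH2)
      }
      tau <- s2 / (s2 + s2n)
      u_hat <- pred_b - bucket
    }
    resp_sd <- uv + lrv * abs(d)
    realized <- if (resp_sd > 0) u_hat + resp_sd * z[t] else u_hat
    if (!is.null(mix_scale))
      realized <- realized + mix_scale[t] * tot_sd * z2[t]
    nxt <- bucket + realized
    if (nxt < lo) nxt <- lo
    if (nxt > hi) nxt <- hi
    out_bucket[t] <- bucket
    out_delta[t] <- d
    out_pred[t] <- u_hat
    out_upd[t] <- nxt - bucket
    bucket <- nxt
  }
  data.frame(block = blk, trial = block$trial, bucket = out_bucket,
             delta = out_delta, pred_update = out_pred, update = out_upd)
}

#' Group offsets for the synthetic cohort
#'
#' Offsets added to the older group's parameter and covariate means. The
#' defaults emulate the empirical pattern of age differences: elevated log
#' uncertainty underestimation and learning-rate variability, and lower
#' fluid-intelligence and working-memory scores, in the older group. All
#' zeros yields a null cohort.
#'
#' @param log_uu Offset on mean log uncertainty underestimation.
#' @param lr_variability Offset on mean learning-rate variability.
#' @param raven,ospan Offsets on covariate means.
#' @return A list of class `cohort_effects`.
#' @export
cohort_effects <- function(log_uu = 1.2, lr_variability = 0.15,
                           raven = -4, ospan = -12) {
  structure(list(log_uu = log_uu, lr_variability = lr_variability,
                 raven = raven, ospan = ospan),
            class = "cohort_effects")
}

#' Generate a synthetic cohort of agents with covariates
#'
#' Draws per-subject flexible-model parameters from group-specific
#' distributions (young baseline: log-UU ~ N(1.5, 0.7), LRV ~ |N(0.1,
#' 0.05)|, UV ~ logN(log 4, 0.3); older group shifted by `effects`), ages
#' (young 20-30, old 60-80) and covariate scores (Raven, OSPAN).
#'
#' @param n_young,n_old Subjects per group (>= 1).
#' @param effects A [cohort_effects()] object.
#' @param seed Optional integer seed.
#' @return A list of class `cohort` with `subjects` (one row per subject:
#'   `subject`, `group`, `age`, `raven`, `ospan`, and the drawn parameters)
#'   and `agents` (a list of [agent_spec()] objects, one per subject, each
#'   with its own derived seed).
#' @export
generate_cohort <- function(n_young, n_old, effects = cohort_effects(),
                            seed = NULL) {
  if (n_young < 1 || n_old < 1)
    stop("need at least one subject per group", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_young + n_old
  grp <- rep(c("young", "old"), c(n_young, n_old))
  old <- grp == "old"
  log_uu <- pmax(0, stats::rnorm(n, 1.5 + ifelse(old, effects$log_uu, 0), 0.7))
  lrv <- abs(stats::rnorm(n, 0.1 + ifelse(old, effects$lr_variability, 0), 0.05))
  uv <- stats::rlnorm(n, log(4), 0.3)
  age <- ifelse(old, stats::runif(n, 60, 80), stats::runif(n, 20, 30))
  raven <- stats::rnorm(n, 12 + ifelse(old, effects$raven, 0), 3)
  ospan <- stats::rnorm(n, 40 + ifelse(old, effects$ospan, 0), 10)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, n)
  agents <- vector("list", n)
  for (i in seq_len(n)) {
    agents[[i]] <- agent_spec(
      "flexible",
      params = flexible_params(log_uu = log_uu[i],
                               update_variability = uv[i],
                               lr_variability = lrv[i]),
      seed = agent_seeds[i])
  }
  subjects <- data.frame(
    subject = seq_len(n), group = grp, age = age, raven = raven,
    ospan = ospan, log_uu = log_uu, update_variability = uv,
    lr_variability = lrv, agent_seed = agent_seeds)
  structure(list(subjects = subjects, agents = agents), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n", nrow(x$subjects),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}
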