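#' Model configuration for the reduced-Bayesian learning model
#'
#' @param hazard Assumed per-trial change-point probability `H`.
#' @param noise_sd Outcome (bag) s.d. `sigma_N` in screen units. Only used as
#'   a default when the task table does not carry a `noise_sd` column.
#' @param range_width Width of the outcome range; the post-change outcome
#'   density is uniform, `U = 1/range_width`.
#' @param heli_cue_sd S.d. `sigma_H` of the Gaussian likelihood attached to
#'   the visible helicopter on catch trials.
#' @param screen_min,screen_max Screen range (sets the centre used to
#'   initialize beliefs).
#' @return An object of class `model_config`.
#' @export
model_config <- function(hazard = 0.1, noise_sd = 10, range_width = 300,
                         heli_cue_sd = 10, screen_min = 0, screen_max = 300) {
  if (hazard < 0 || hazard >= 1)
    stop("`hazard` must lie in [0, 1)", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (heli_cue_sd <= 0) stop("`heli_cue_sd` must be positive", call. = FALSE)
  if (range_width <= 0) stop("`range_width` must be positive", call. = FALSE)
  structure(
    list(hazard = hazard, noise_sd = noise_sd, range_width = range_width,
         heli_cue_sd = heli_cue_sd, screen_min = screen_min,
         screen_max = screen_max),
    class = "model_config")
}

# Canonical scalar kernels of the recursion. All model paths (normative,
# flexible, agent simulation) route arithmetic through these exact
# expressions so that trajectories agree bitwise at neutral parameters.

# Change-point probability: likelihood ratio of a uniform (post-change)
# vs Gaussian (no-change) outcome density. tau >= 1 encodes a flat prior
# (infinite predictive variance), under which the Gaussian density is 0.
.cpp_core <- function(d, tau, s2n, U, H) {
  if (H <= 0) return(rep(0, length(d)))
  s2tot <- s2n / (1 - tau)
  dens <- exp(-(d * d) / (2 * s2tot)) / sqrt(2 * pi * s2tot)
  (U * H) / (U * H + dens * (1 - H))
}

# Mixture-variance propagation of uncertainty about the helicopter mean.
.propagate_core <- function(omega, tau, d, s2n) {
  omega * s2n + (1 - omega) * tau * s2n +
    omega * (1 - omega) * (d * (1 - tau))^2
}

#' Change-point probability of a prediction error
#'
#' Posterior probability that the newest outcome followed a helicopter
#' relocation: `Omega = U*H / (U*H + N(delta; 0, s2_tot) * (1-H))` with
#' `U = 1/range_width` the uniform post-change outcome density and
#' `s2_tot = sigma_N^2 / (1 - tau)` the total predictive variance.
#'
#' @param delta Prediction error(s), screen units.
#' @param tau Relative uncertainty in `[0, 1)`.
#' @param cfg A [model_config()].
#' @param noise_sd Optional outcome s.d. overriding `cfg$noise_sd`.
#' @return Change-point probabilities in `[0, 1]`, monotone in `|delta|`,
#'   `H`, and `tau`.
#' @export
change_point_probability <- function(delta, tau, cfg, noise_sd = cfg$noise_sd) {
  if (any(tau < 0 | tau >= 1)) stop("`tau` must lie in [0, 1)", call. = FALSE)
  if (any(noise_sd <= 0)) stop("`noise_sd` must be positive", call. = FALSE)
  .cpp_core(delta, tau, noise_sd^2, 1 / cfg$range_width, cfg$hazard)
}

#' Propagate uncertainty about the helicopter location
#'
#' Mixture-variance update: the posterior over the helicopter mean is a
#' mixture of the change (variance `sigma_N^2`) and no-change (variance
#' `tau * sigma_N^2`) branches, whose means differ by `delta * (1 - tau)`:
#' `s2' = Omega*s2N + (1-Omega)*tau*s2N + Omega*(1-Omega)*(delta*(1-tau))^2`,
#' then `tau' = s2' / (s2' + s2N)`.
#'
#' @param omega Change-point probability on the current trial.
#' @param tau Relative uncertainty on the current trial.
#' @param delta Prediction error on the current trial.
#' @param cfg A [model_config()].
#' @param noise_sd Optional outcome s.d. overriding `cfg$noise_sd`.
#' @return A list with `sigma2_mu` (next-trial estimation variance) and
#'   `tau` (next-trial relative uncertainty, in `[0, 1)`).
#' @export
propagate_uncertainty <- function(omega, tau, delta, cfg,
                                  noise_sd = cfg$noise_sd) {
  if (any(omega < 0 | omega > 1)) stop("`omega` must lie in [0, 1]", call. = FALSE)
  if (any(tau < 0 | tau > 1)) stop("`tau` must lie in [0, 1]", call. = FALSE)
  if (any(noise_sd <= 0)) stop("`noise_sd` must be positive", call. = FALSE)
  s2n <- noise_sd^2
  s2 <- .propagate_core(omega, tau, delta, s2n)
  list(sigma2_mu = s2, tau = s2 / (s2 + s2n))
}

#' Normative belief update
#'
#' The learning rate combines surprise- and uncertainty-driven learning:
#' `alpha = Omega + (1 - Omega) * tau`; the belief moves by `alpha * delta`.
#'
#' @param belief Current belief about the helicopter position.
#' @param delta Prediction error.
#' @param omega Change-point probability.
#' @param tau Relative uncertainty.
#' @return A list with `belief` (updated) and `alpha` (learning rate in
#'   `[0, 1]`).
#' @export
normative_update <- function(belief, delta, omega, tau) {
  alpha <- omega + (1 - omega) * tau
  list(belief = belief + alpha * delta, alpha = alpha)
}

#' Combine the belief with the visible-helicopter cue on a catch trial
#'
#' The visible helicopter is treated as a Gaussian cue centred on the true
#' mean with s.d. `sigma_H`. The posterior weights belief and cue by their
#' relative precisions: `w = sigma_H^2 / (sigma_H^2 + sigma_mu^2)` is the
#' weight on the current belief.
#'
#' @param belief Current belief.
#' @param sigma2_mu Variance of the current belief about the helicopter.
#' @param mu True helicopter position (visible on catch trials).
#' @param cfg A [model_config()] (supplies `heli_cue_sd` and `noise_sd`).
#' @param noise_sd Optional outcome s.d. overriding `cfg$noise_sd`.
#' @return A list with `belief`, `sigma2_mu`, `tau` (all posterior) and `w`.
#' @export
catch_trial_combine <- function(belief, sigma2_mu, mu, cfg,
                                noise_sd = cfg$noise_sd) {
  sH2 <- cfg$heli_cue_sd^2
  if (sH2 <= 0 && sigma2_mu <= 0)
    stop("degenerate input: both variances are zero", call. = FALSE)
  w <- sH2 / (sH2 + sigma2_mu)
  s2 <- 1 / (1 / sigma2_mu + 1 / sH2)
  s2n <- noise_sd^2
  list(belief = w * belief + (1 - w) * mu, sigma2_mu = s2,
       tau = s2 / (s2 + s2n), w = w)
}

#' Run the normative reduced-Bayesian model over a task table
#'
#' In `generative` mode the model experiences its own prediction errors
#' (`delta_t = bag_t - belief_t`). In `conditioned` mode the change-point
#' probability and relative-uncertainty recursions are evaluated on a
#' supplied prediction-error series (e.g. a subject's own errors), which is
#' how subjective trial-by-trial regressors are obtained. State (relative
#' uncertainty, belief) starts from a flat prior (`tau = 1`, belief at screen
#' centre) and resets at every block boundary; the first outcome is therefore
#' absorbed with learning rate 1, equivalent to initializing the belief at
#' the first bag with `tau = 0.5`.
#'
#' @param block Task table from [generate_task_block()] or
#'   [generate_task_session()] (columns `block`, `bag`, `noise_sd`,
#'   `is_catch`, `helicopter`).
#' @param cfg A [model_config()].
#' @param mode `"generative"` or `"conditioned"`.
#' @param observed_pe Prediction-error series aligned to `block`
#'   (required in conditioned mode).
#' @param observed_bucket Optional bucket series aligned to `block`; when
#'   supplied it anchors predicted updates (catch-trial pull and centre bias)
#'   to the subject's actual positions.
#' @return A data.frame (the latent trajectory) with columns `block`,
#'   `trial`, `delta`, `omega`, `tau`, `sigma2_mu`, `alpha`, `belief`,
#'   `pred_update`, `w` (`NA` off catch trials). `tau`, `sigma2_mu` are the
#'   pre-observation values used on that trial; the first trial of a block
#'   carries the flat prior (`tau = 1`, infinite variance).
#' @export
run_model <- function(block, cfg, mode = c("generative", "conditioned"),
                      observed_pe = NULL, observed_bucket = NULL) {
  mode <- match.arg(mode)
  if (mode == "conditioned" && is.null(observed_pe))
    stop("conditioned mode requires `observed_pe`", call. = FALSE)
  if (!is.null(observed_pe) && length(observed_pe) != nrow(block))
    stop("`observed_pe` is not aligned to `block`", call. = FALSE)
  if (!is.null(observed_bucket) && length(observed_bucket) != nrow(block))
    stop("`observed_bucket` is not aligned to `block`", call. = FALSE)

  n <- nrow(block)
  U <- 1 / cfg$range_width
  H <- cfg$hazard
  sH2 <- cfg$heli_cue_sd^2
  centre <- (cfg$screen_min + cfg$screen_max) / 2
  noise <- if ("noise_sd" %in% names(block)) block$noise_sd else
    rep(cfg$noise_sd, n)
  catch <- if ("is_catch" %in% names(block)) block$is_catch else
    logical(n)
  mu <- if ("helicopter" %in% names(block)) block$helicopter else
    rep(NA_real_, n)
  blk <- if ("block" %in% names(block)) block$block else rep(1L, n)

  out_delta <- out_omega <- out_tau <- out_s2 <- out_alpha <-
    out_belief <- out_upd <- numeric(n)
  out_w <- rep(NA_real_, n)

  tau <- 1
  belief <- centre
  for (t in seq_len(n)) {
    if (t > 1L && blk[t] != blk[t - 1L]) {
      tau <- 1
      belief <- centre
    }
    s2n <- noise[t]^2
    B <- if (!is.null(observed_bucket)) observed_bucket[t] else belief
    d <- if (mode == "generative") block$bag[t] - B else observed_pe[t]
    out_delta[t] <- d
    out_tau[t] <- tau
    out_s2[t] <- s2n * tau / (1 - tau)
    omega <- .cpp_core(d, tau, s2n, U, H)
    alpha <- omega + (1 - omega) * tau
    pred_b <- B + alpha * d
    s2 <- .propagate_core(omega, tau, d, s2n)
    if (catch[t]) {
      w <- sH2 / (sH2 + s2)
      pred_b <- w * pred_b + (1 - w) * mu[t]
      s2 <- 1 / (1 / s2 + 1 / sH2)
      out_w[t] <- w
    }
    tau <- s2 / (s2 + s2n)
    out_omega[t] <- omega
    out_alpha[t] <- alpha
    out_upd[t] <- pred_b - B
    out_belief[t] <- pred_b
    belief <- pred_b
  }
  data.frame(block = blk, trial = block$trial, delta = out_delta,
             omega = out_omega, tau = out_tau, sigma2_mu = out_s2,
             alpha = out_alpha, belief = out_belief,
             pred_update = out_upd, w = out_w)
}
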