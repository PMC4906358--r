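#' Parameters of the flexible learning model
#'
#' A single parameterization that nests the normative model (at neutral
#' values) and its principled deviations: hazard-rate mis-estimation,
#' surprise insensitivity (tempering of the change-point likelihood ratio),
#' uncertainty underestimation (division of the estimation variance each
#' trial, stored in log units), subjective noise perception (multiplicative
#' scale, additive offset, and an inverse-gamma dispersion over noise
#' scales), and the two response-variability terms (update variability `UV`
#' and learning-rate variability `LRV`; the response s.d. on a trial is
#' `UV + LRV * |delta|`).
#'
#' @param hazard Assumed hazard rate `H`, in `(0, 1)`.
#' @param surprise_sens Surprise sensitivity `SS`, an exponent in `(0, 1]`;
#'   1 is normative.
#' @param log_uu Log uncertainty underestimation; `UU = exp(log_uu) >= 1`
#'   divides the estimation variance each trial. 0 is normative.
#' @param heli_cue_sd Helicopter-cue s.d. `sigma_H`, screen units.
#' @param noise_scale,noise_offset Perceived noise is
#'   `noise_scale * sigma_N + noise_offset` (floored at 0.5 screen units);
#'   affects the model only, never the generative task.
#' @param noise_shape Shape `nu` of the inverse-gamma dispersion over noise
#'   scales (mixture models only); `Inf` or `NA` disables the mixture.
#' @param update_variability `UV >= 0`, screen units.
#' @param lr_variability `LRV >= 0`, per unit error.
#' @return An object of class `flexible_params`.
#' @export
flexible_params <- function(hazard = 0.1, surprise_sens = 1, log_uu = 0,
                            heli_cue_sd = 10, noise_scale = 1,
                            noise_offset = 0, noise_shape = NA_real_,
                            update_variability = 0, lr_variability = 0) {
  if (hazard <= 0 || hazard >= 1)
    stop("`hazard` must lie in (0, 1)", call. = FALSE)
  if (surprise_sens <= 0 || surprise_sens > 1)
    stop("`surprise_sens` must lie in (0, 1]", call. = FALSE)
  if (log_uu < 0) stop("`log_uu` must be >= 0 (UU >= 1)", call. = FALSE)
  if (heli_cue_sd <= 0) stop("`heli_cue_sd` must be positive", call. = FALSE)
  if (noise_scale <= 0) stop("`noise_scale` must be positive", call. = FALSE)
  if (!is.na(noise_shape) && noise_shape <= 0)
    stop("`noise_shape` must be positive", call. = FALSE)
  if (update_variability < 0 || lr_variability < 0)
    stop("response-variability terms must be >= 0", call. = FALSE)
  structure(
    list(hazard = hazard, surprise_sens = surprise_sens, log_uu = log_uu,
         heli_cue_sd = heli_cue_sd, noise_scale = noise_scale,
         noise_offset = noise_offset, noise_shape = noise_shape,
         update_variability = update_variability,
         lr_variability = lr_variability),
    class = "flexible_params")
}

#' @export
print.flexible_params <- function(x, ...) {
  cat("Flexible model parameters\n")
  cat(sprintf("  H = %.4g, SS = %.3g, log-UU = %.3g (UU = %.3g), sigma_H = %.3g\n",
              x$hazard, x$surprise_sens, x$log_uu, exp(x$log_uu),
              x$heli_cue_sd))
  cat(sprintf("  noise: scale %.3g, offset %.3g, shape %s\n",
              x$noise_scale, x$noise_offset,
              if (is.na(x$noise_shape)) "-" else format(x$noise_shape)))
  cat(sprintf("  response: UV = %.3g, LRV = %.3g\n",
              x$update_variability, x$lr_variability))
  invisible(x)
}

#' Blunt the change-point probability by tempering the likelihood ratio
#'
#' Diminished surprise sensitivity is modelled by raising the change-point
#' likelihood ratio to a power `SS` in `(0, 1]` and renormalizing, which
#' compresses the posterior log-odds towards the hazard prior:
#' `odds' = (Omega/(1-Omega))^SS * (H/(1-H))^(1-SS)`. `SS = 1` is the
#' identity; the endpoints 0 and 1 are preserved; the transform is monotone
#' in `Omega`. Large surprises are discounted the most.
#'
#' @param omega Change-point probabilities in `[0, 1]`.
#' @param ss Surprise sensitivity exponent in `(0, 1]`.
#' @param hazard Assumed hazard rate (anchors the compression).
#' @return Adjusted change-point probabilities.
#' @export
apply_surprise_sensitivity <- function(omega, ss, hazard = 0.1) {
  if (ss <= 0 || ss > 1)
    stop("`ss` must lie in (0, 1]", call. = FALSE)
  if (any(omega < 0 | omega > 1))
    stop("`omega` must lie in [0, 1]", call. = FALSE)
  if (ss == 1) return(omega)
  hr <- hazard / (1 - hazard)
  inner <- omega > 0 & omega < 1
  out <- omega
  odds <- (omega[inner] / (1 - omega[inner]))^ss * hr^(1 - ss)
  out[inner] <- odds / (1 + odds)
  out
}

#' Underestimate uncertainty by dividing the estimation variance
#'
#' @param sigma2_mu Estimation variance(s).
#' @param uu Variance divisor `UU >= 1`.
#' @return `sigma2_mu / uu`.
#' @export
apply_uncertainty_underestimation <- function(sigma2_mu, uu) {
  if (uu < 1) stop("`uu` must be >= 1", call. = FALSE)
  if (any(sigma2_mu < 0)) stop("variances must be >= 0", call. = FALSE)
  sigma2_mu / uu
}

# Tight inner loop shared by run_flexible() and the fit objective. Arguments
# are plain vectors; no validation. Expressions mirror run_model()/the
# canonical kernels exactly so that neutral parameters reproduce the
# normative trajectory bitwise.
.flex_traj <- function(n, blk, bag, noise, catch, mu, H, ss, uu, sH2,
                       smult, sadd, U, centre, generative,
                       observed_pe = NULL, observed_bucket = NULL,
                       mix_scales = NULL, mix_weights = NULL) {
  out_delta <- out_omega <- out_tau <- out_s2 <- out_alpha <-
    out_belief <- out_upd <- numeric(n)
  out_w <- rep(NA_real_, n)
  hr <- H / (1 - H)
  tau <- 1
  belief <- centre
  for (t in seq_len(n)) {
    if (t > 1L && blk[t] != blk[t - 1L]) {
      tau <- 1
      belief <- centre
    }
    sdp <- smult * noise[t] + sadd
    if (sdp < 0.5) sdp <- 0.5
    s2n <- sdp^2
    B <- if (!is.null(observed_bucket)) observed_bucket[t] else belief
    d <- if (generative) bag[t] - B else observed_pe[t]
    out_delta[t] <- d
    out_tau[t] <- tau
    out_s2[t] <- s2n * tau / (1 - tau)
    if (H <= 0) {
      omega <- 0
    } else {
      s2tot <- s2n / (1 - tau)
      if (is.null(mix_scales)) {
        dens <- exp(-(d * d) / (2 * s2tot)) / sqrt(2 * pi * s2tot)
      } else {
        # dispersion over noise scales: mixture outcome-predictive density
        v <- mix_scales^2 * s2tot
        dens <- sum(mix_weights * exp(-(d * d) / (2 * v)) / sqrt(2 * pi * v))
      }
      omega <- (U * H) / (U * H + dens * (1 - H))
    }
    if (ss < 1 && omega > 0 && omega < 1) {
      odds <- (omega / (1 - omega))^ss * hr^(1 - ss)
      omega <- odds / (1 + odds)
    }
    alpha <- omega + (1 - omega) * tau
    pred_b <- B + alpha * d
    s2 <- omega * s2n + (1 - omega) * tau * s2n +
      omega * (1 - omega) * (d * (1 - tau))^2
    if (uu > 1) s2 <- s2 / uu
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
  list(delta = out_delta, omega = out_omega, tau = out_tau,
       sigma2_mu = out_s2, alpha = out_alpha, belief = out_belief,
       pred_update = out_upd, w = out_w)
}

#' Run the flexible learning model over a task table
#'
#' Identical to [run_model()] but with the hazard, surprise sensitivity,
#' uncertainty underestimation, helicopter-cue s.d. and perceived noise taken
#' from `params`. At neutral values (`hazard = cfg$hazard`,
#' `surprise_sens = 1`, `log_uu = 0`, `noise_scale = 1`, `noise_offset = 0`)
#' the trajectory is identical to the normative one.
#'
#' @param block Task table (see [run_model()]).
#' @param params A [flexible_params()].
#' @param mode `"generative"` or `"conditioned"`.
#' @param observed_pe,observed_bucket As in [run_model()].
#' @param cfg Optional [model_config()] supplying the outcome range and
#'   screen bounds (defaults to the standard 0-300 screen).
#' @return A latent-trajectory data.frame (see [run_model()]).
#' @export
run_flexible <- function(block, params, mode = c("generative", "conditioned"),
                         observed_pe = NULL, observed_bucket = NULL,
                         cfg = model_config(hazard = params$hazard)) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "flexible_params"))
  if (mode == "conditioned" && is.null(observed_pe))
    stop("conditioned mode requires `observed_pe`", call. = FALSE)
  if (!is.null(observed_pe) && length(observed_pe) != nrow(block))
    stop("`observed_pe` is not aligned to `block`", call. = FALSE)
  n <- nrow(block)
  noise <- if ("noise_sd" %in% names(block)) block$noise_sd else
    rep(cfg$noise_sd, n)
  catch <- if ("is_catch" %in% names(block)) block$is_catch else logical(n)
  mu <- if ("helicopter" %in% names(block)) block$helicopter else
    rep(NA_real_, n)
  blk <- if ("block" %in% names(block)) block$block else rep(1L, n)
  mix <- if (!is.na(params$noise_shape))
    noise_mixture_spec(shape = params$noise_shape) else NULL
  tr <- .flex_traj(
    n, blk, block$bag, noise, catch, mu,
    H = params$hazard, ss = params$surprise_sens, uu = exp(params$log_uu),
    sH2 = params$heli_cue_sd^2, smult = params$noise_scale,
    sadd = params$noise_offset, U = 1 / cfg$range_width,
    centre = (cfg$screen_min + cfg$screen_max) / 2,
    generative = (mode == "generative"),
    observed_pe = observed_pe, observed_bucket = observed_bucket,
    mix_scales = mix$scales, mix_weights = mix$weights)
  data.frame(block = blk, trial = block$trial, delta = tr$delta,
             omega = tr$omega, tau = tr$tau, sigma2_mu = tr$sigma2_mu,
             alpha = tr$alpha, belief = tr$belief,
             pred_update = tr$pred_update, w = tr$w)
}
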