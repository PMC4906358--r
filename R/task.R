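#' Task configuration for the helicopter predictive-inference task
#'
#' Bundles the generative statistics of the task: per-trial hazard of a
#' helicopter relocation, the blockwise outcome noise levels, the catch-trial
#' rate (trials on which the helicopter is visible), the screen range on which
#' all positions live, and the payout falloff used by [score_coins()].
#'
#' @param n_trials Trials per block.
#' @param noise_sds Outcome (bag) standard deviations, one per block, in
#'   screen units. Each block uses a constant noise level.
#' @param hazard Per-trial probability that the helicopter relocates.
#' @param catch_rate Per-trial probability that the helicopter is visible.
#' @param screen_min,screen_max Screen range in screen units.
#' @param coin_falloff Width `W` (screen units) of the linear payout falloff:
#'   a gold bag at distance `d` from the bucket pays
#'   `max(0, round(200 * (1 - d / W)))` coins.
#' @param bag_edge Either `"redraw"` (draw again until the bag lands on
#'   screen) or `"clip"` (truncate to the screen edge).
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_trials = 200L, noise_sds = c(10, 25), hazard = 0.1,
                        catch_rate = 0.1, screen_min = 0, screen_max = 300,
                        coin_falloff = 100, bag_edge = c("redraw", "clip")) {
  bag_edge <- match.arg(bag_edge)
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("`n_trials` must be a positive integer", call. = FALSE)
  if (!is.numeric(hazard) || hazard < 0 || hazard > 1)
    stop("`hazard` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(catch_rate) || catch_rate < 0 || catch_rate > 1)
    stop("`catch_rate` must lie in [0, 1]", call. = FALSE)
  if (screen_min >= screen_max)
    stop("`screen_min` must be smaller than `screen_max`", call. = FALSE)
  if (any(!is.finite(noise_sds)) || any(noise_sds <= 0))
    stop("`noise_sds` must be strictly positive", call. = FALSE)
  structure(
    list(n_trials = as.integer(n_trials), noise_sds = as.numeric(noise_sds),
         hazard = hazard, catch_rate = catch_rate,
         screen_min = screen_min, screen_max = screen_max,
         coin_falloff = coin_falloff, bag_edge = bag_edge),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Helicopter task configuration\n")
  cat(sprintf("  %d trials/block, noise s.d. {%s}, hazard %.3g, catch rate %.3g\n",
              x$n_trials, paste(x$noise_sds, collapse = ", "),
              x$hazard, x$catch_rate))
  cat(sprintf("  screen [%g, %g], coin falloff %g (%s at edges)\n",
              x$screen_min, x$screen_max, x$coin_falloff, x$bag_edge))
  invisible(x)
}

#' Generate one block of the helicopter task
#'
#' The helicopter starts at a uniform position and on each trial relocates to
#' a fresh uniform draw with probability `cfg$hazard`. The bag position is
#' drawn from a Gaussian centred on the helicopter with s.d. `noise_sd`;
#' draws falling off screen are redrawn (or clipped, per `cfg$bag_edge`).
#' Catch (helicopter-visible) flags and gold/rock flags are i.i.d. Bernoulli.
#'
#' @param cfg A [task_config()].
#' @param noise_sd Outcome s.d. for this block; defaults to the first entry
#'   of `cfg$noise_sds`.
#' @param block Integer block label stored in the output.
#' @param seed Optional integer seed; the block is a deterministic function
#'   of `(cfg, noise_sd, seed)`.
#' @return A data.frame with columns `block`, `trial`, `helicopter`, `bag`,
#'   `noise_sd`, `is_changepoint`, `is_catch`, `is_gold`.
#' @export
generate_task_block <- function(cfg, noise_sd = cfg$noise_sds[1], block = 1L,
                                seed = NULL) {
  stopifnot(inherits(cfg, "task_config"))
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be strictly positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_trials
  lo <- cfg$screen_min
  hi <- cfg$screen_max
  cp <- stats::runif(n) < cfg$hazard
  heli <- numeric(n)
  pos <- stats::runif(1, lo, hi)
  for (t in seq_len(n)) {
    if (cp[t]) pos <- stats::runif(1, lo, hi)
    heli[t] <- pos
  }
  bag <- stats::rnorm(n, heli, noise_sd)
  if (cfg$bag_edge == "redraw") {
    bad <- which(bag < lo | bag > hi)
    while (length(bad)) {
      bag[bad] <- stats::rnorm(length(bad), heli[bad], noise_sd)
      bad <- bad[bag[bad] < lo | bag[bad] > hi]
    }
  } else {
    bag <- pmin(pmax(bag, lo), hi)
  }
  data.frame(
    block = as.integer(block), trial = seq_len(n),
    helicopter = heli, bag = bag, noise_sd = noise_sd,
    is_changepoint = cp,
    is_catch = stats::runif(n) < cfg$catch_rate,
    is_gold = stats::runif(n) < 0.5)
}

#' Generate a full task session (one block per noise level)
#'
#' @param cfg A [task_config()].
#' @param seed Optional integer seed.
#' @param counterbalance If `TRUE`, randomize the block order of
#'   `cfg$noise_sds`.
#' @return Row-bound blocks as returned by [generate_task_block()].
#' @export
generate_task_session <- function(cfg, seed = NULL, counterbalance = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sds <- cfg$noise_sds
  if (counterbalance) sds <- sample(sds)
  out <- vector("list", length(sds))
  for (b in seq_along(sds))
    out[[b]] <- generate_task_block(cfg, noise_sd = sds[b], block = b)
  do.call(rbind, out)
}

#' Count coins earned over a block
#'
#' Gold trials pay `max(0, round(200 * (1 - d / W)))` coins, where `d` is the
#' distance between bucket and bag and `W = cfg$coin_falloff`; rock trials pay
#' nothing. A bucket exactly under the bag collects the full 200 coins.
#'
#' @param block Task table from [generate_task_block()].
#' @param beh Behaviour table with a `bucket` column aligned to `block`.
#' @param coin_falloff Falloff width `W` in screen units.
#' @return Total coin count (numeric scalar).
#' @export
score_coins <- function(block, beh, coin_falloff = 100) {
  bucket <- if (is.data.frame(beh)) beh$bucket else beh
  if (length(bucket) != nrow(block))
    stop("behaviour and task tables have different lengths", call. = FALSE)
  d <- abs(block$bag - bucket)
  coins <- pmax(0, round(200 * (1 - d / coin_falloff)))
  sum(coins[block$is_gold])
}
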