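#' Compute updates, prediction errors and trial exclusions
#'
#' Derives per-trial prediction errors `delta_t = bag_t - bucket_t` and
#' updates `u_t = bucket_{t+1} - bucket_t`, then applies three exclusion
#' rules: (1) the first and last trial of each block; (2) trials with
#' `delta = 0` (uninformative about error-driven learning); (3) trials where
#' the next bucket lands more than `max_dev` screen units away from every
#' possible delta-rule update, i.e. from the closed segment between the
#' current bucket and the bag, unioned on catch trials with the segment
#' between the bucket and the visible helicopter.
#'
#' @param block Task table.
#' @param beh Behaviour table with a `bucket` column (or a bucket vector).
#' @param max_dev Exclusion distance in screen units (default 15).
#' @return A data.frame of included trials with columns `block`, `trial`,
#'   `bucket`, `delta`, `update`, `noise_sd`, `is_catch`, `is_gold`,
#'   `helicopter`, `abs_rel_err` (`|delta|/sigma_N`), plus attributes
#'   `excluded_fraction` (among eligible, non-edge trials) and `n_total`.
#' @export
preprocess_trials <- function(block, beh, max_dev = 15) {
  bucket <- if (is.data.frame(beh)) beh$bucket else beh
  n <- nrow(block)
  if (length(bucket) != n)
    stop("behaviour and task tables have different lengths", call. = FALSE)
  blk <- if ("block" %in% names(block)) block$block else rep(1L, n)
  delta <- block$bag - bucket
  nxt <- c(bucket[-1], NA_real_)
  update <- nxt - bucket
  first <- c(TRUE, blk[-1] != blk[-n])
  last <- c(blk[-1] != blk[-n], TRUE)

  # distance from the landed bucket to the allowed delta-rule segment(s)
  seg_dist <- function(x, a, b) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    pmax(0, pmax(lo - x, x - hi))
  }
  dev <- seg_dist(nxt, bucket, block$bag)
  if ("is_catch" %in% names(block) && "helicopter" %in% names(block)) {
    dev_heli <- seg_dist(nxt, bucket, block$helicopter)
    dev <- ifelse(block$is_catch, pmin(dev, dev_heli), dev)
  }
  eligible <- !first & !last
  off_rule <- eligible & delta != 0 & dev > max_dev
  keep <- eligible & delta != 0 & !off_rule
  if (!any(keep)) stop("all trials excluded", call. = FALSE)

  out <- data.frame(
    block = blk[keep], trial = block$trial[keep], bucket = bucket[keep],
    delta = delta[keep], update = update[keep],
    noise_sd = block$noise_sd[keep],
    is_catch = if ("is_catch" %in% names(block)) block$is_catch[keep] else FALSE,
    is_gold = if ("is_gold" %in% names(block)) block$is_gold[keep] else TRUE,
    helicopter = if ("helicopter" %in% names(block)) block$helicopter[keep]
                 else NA_real_,
    abs_rel_err = abs(delta[keep]) / block$noise_sd[keep])
  attr(out, "excluded_fraction") <- sum(off_rule) / sum(eligible)
  attr(out, "n_total") <- n
  out
}

#' Model-derived surprise and uncertainty regressors
#'
#' Runs the normative model in conditioned mode over the subject's own
#' prediction errors and returns the change-point probability (surprise) and
#' relative uncertainty series, aligned to the full task table.
#'
#' @param block Task table.
#' @param beh Behaviour table (or bucket vector).
#' @param cfg A [model_config()] with the ground-truth hazard.
#' @return A data.frame with columns `surprise` and `uncertainty`, one row
#'   per trial of `block`.
#' @export
compute_model_regressors <- function(block, beh, cfg = model_config()) {
  bucket <- if (is.data.frame(beh)) beh$bucket else beh
  if (length(bucket) != nrow(block))
    stop("behaviour and task tables have different lengths", call. = FALSE)
  delta <- block$bag - bucket
  traj <- run_model(block, cfg, mode = "conditioned", observed_pe = delta,
                    observed_bucket = bucket)
  data.frame(surprise = traj$omega, uncertainty = traj$tau)
}

#' Assemble the regression dataset for one subject
#'
#' Applies [preprocess_trials()], attaches the model-derived surprise and
#' uncertainty regressors, and mean-centres the five interaction factors
#' (surprise, uncertainty, noise condition, trial value, helicopter
#' visibility) within subject over the included trials.
#'
#' @param block Task table.
#' @param beh Behaviour table (or bucket vector).
#' @param cfg A [model_config()].
#' @param max_dev Exclusion distance for [preprocess_trials()].
#' @param screen_centre Centre of the screen for the centre-bias nuisance
#'   regressor `(centre - bucket_t)`.
#' @return A regression dataset: the [preprocess_trials()] columns plus
#'   `surprise`, `uncertainty`, centred factors (`*_c`), `heli_pull`
#'   (`is_catch * (helicopter - bucket)`) and `centre_bias`.
#' @export
make_regression_dataset <- function(block, beh, cfg = model_config(),
                                    max_dev = 15, screen_centre = 150) {
  ds <- preprocess_trials(block, beh, max_dev = max_dev)
  reg <- compute_model_regressors(block, beh, cfg)
  # align by row index in the original table
  bucket <- if (is.data.frame(beh)) beh$bucket else beh
  blk <- if ("block" %in% names(block)) block$block else
    rep(1L, nrow(block))
  key_all <- paste(blk, block$trial)
  idx <- match(paste(ds$block, ds$trial), key_all)
  ds$surprise <- reg$surprise[idx]
  ds$uncertainty <- reg$uncertainty[idx]
  ds$surprise_c <- ds$surprise - mean(ds$surprise)
  ds$uncertainty_c <- ds$uncertainty - mean(ds$uncertainty)
  ds$noise_c <- ds$noise_sd - mean(ds$noise_sd)
  ds$value_c <- as.numeric(ds$is_gold) - mean(ds$is_gold)
  ds$visible_c <- as.numeric(ds$is_catch) - mean(ds$is_catch)
  ds$heli_pull <- ifelse(ds$is_catch, ds$helicopter - ds$bucket, 0)
  ds$centre_bias <- screen_centre - ds$bucket
  ds
}

# Full design matrix: overall learning rate plus interactions of the
# prediction error with the five centred factors, the helicopter pull on
# visible trials, and the centre-bias nuisance term.
.design_matrix <- function(ds) {
  cbind(intercept = 1,
        delta = ds$delta,
        delta_x_surprise = ds$delta * ds$surprise_c,
        delta_x_uncertainty = ds$delta * ds$uncertainty_c,
        delta_x_noise = ds$delta * ds$noise_c,
        delta_x_value = ds$delta * ds$value_c,
        delta_x_visible = ds$delta * ds$visible_c,
        heli_pull = ds$heli_pull,
        centre_bias = ds$centre_bias)
}

#' Penalized weighted least squares
#'
#' Solves `beta = (A' P A + R)^{-1} A' P y` where `P` is the diagonal matrix
#' of inverse-variance weights and `R = lambda * I` over all columns except
#' the intercept (the grand mean is not shrunk). With `lambda = 0` and unit
#' weights this is ordinary least squares.
#'
#' @param A Design matrix (with column names; an `intercept` column is
#'   exempt from the penalty).
#' @param y Response vector.
#' @param weights Positive observation weights (inverse residual variances);
#'   default unit weights.
#' @param lambda Ridge parameter (default 0.1).
#' @param penalize_intercept Penalize the intercept column too?
#' @return Named coefficient vector.
#' @export
ridge_weighted_solve <- function(A, y, weights = NULL, lambda = 0.1,
                                 penalize_intercept = FALSE) {
  A <- as.matrix(A)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  p <- ncol(A)
  R <- diag(lambda, p)
  if (!penalize_intercept && !is.null(colnames(A))) {
    ic <- which(colnames(A) == "intercept")
    if (length(ic)) R[ic, ic] <- 0
  }
  Aw <- A * weights
  M <- crossprod(A, Aw) + R
  b <- crossprod(Aw, y)
  beta <- tryCatch(solve(M, b), error = function(e)
    stop("singular system in penalized solve: ", conditionMessage(e),
         call. = FALSE))
  stats::setNames(drop(beta), colnames(A))
}

#' Heteroscedasticity weights from pooled initialization residuals
#'
#' Fits the full design by ordinary (unweighted, unpenalized) least squares
#' for each subject, pools the residuals across subjects, computes the
#' residual variance in sliding windows of absolute prediction-error
#' magnitude (window width `window_frac` of the pooled data, stepped by one
#' percentile), and assigns each trial the inverse variance of its nearest
#' window.
#'
#' @param datasets A single regression dataset or a list of them (one per
#'   subject), from [make_regression_dataset()].
#' @param window_frac Window width as a fraction of pooled trials.
#' @param n_windows Number of sliding windows.
#' @param var_floor Lower floor on window variances.
#' @return A list of positive weight vectors, one per dataset (a single
#'   vector if a single dataset was supplied).
#' @export
estimate_heteroscedastic_weights <- function(datasets, window_frac = 0.1,
                                             n_windows = 90,
                                             var_floor = 1e-6) {
  single <- is.data.frame(datasets)
  if (single) datasets <- list(datasets)
  res <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    A <- .design_matrix(ds)
    # a vanishing ridge keeps the initialization fit defined when a small
    # dataset leaves the design rank-deficient
    beta <- ridge_weighted_solve(A, ds$update, lambda = 1e-8)
    res[[i]] <- ds$update - drop(A %*% beta)
  }
  abs_pe <- abs(unlist(lapply(datasets, `[[`, "delta")))
  r <- unlist(res)
  n <- length(r)
  k <- max(10L, round(window_frac * n))
  if (n < 2L * k) {
    v <- max(stats::var(r), var_floor)
    out <- lapply(datasets, function(ds) rep(1 / v, nrow(ds)))
    return(if (single) out[[1]] else out)
  }
  ord <- order(abs_pe)
  r_sorted <- r[ord]
  starts <- round(seq(1, n - k + 1, length.out = n_windows))
  win_var <- numeric(n_windows)
  win_centre_pe <- numeric(n_windows)
  for (j in seq_len(n_windows)) {
    idx <- starts[j]:(starts[j] + k - 1L)
    win_var[j] <- max(stats::var(r_sorted[idx]), var_floor)
    win_centre_pe[j] <- abs_pe[ord][idx[ceiling(k / 2)]]
  }
  # nearest window by |delta| rank
  rank_all <- rank(abs_pe, ties.method = "first")
  centre_rank <- starts + (k - 1) / 2
  wins <- vapply(rank_all, function(rk)
    which.min(abs(centre_rank - rk)), integer(1))
  w_all <- 1 / win_var[wins]
  out <- vector("list", length(datasets))
  pos <- 0L
  for (i in seq_along(datasets)) {
    m <- nrow(datasets[[i]])
    out[[i]] <- w_all[pos + seq_len(m)]
    pos <- pos + m
  }
  if (single) out[[1]] else out
}

#' Sliding-window regression over relative error magnitude
#'
#' Ranks the included trials by `|delta| / sigma_N`, forms `n_bins`
#' overlapping windows each holding `window_frac` of the trials (starts
#' stepped evenly over the ranks, covering the full range), and solves the
#' full penalized weighted regression within each window. The five
#' interaction factors are re-centred within each window: inside a narrow
#' window of relative error the globally centred factors are nearly
#' constant, which would leave the prediction-error coefficient confounded
#' with its interactions; with window-local centring the per-bin `delta`
#' coefficient is the bin's learning rate and the interactions capture
#' within-bin modulation.
#'
#' @param dataset Regression dataset from [make_regression_dataset()].
#' @param weights Trial weights (e.g. from
#'   [estimate_heteroscedastic_weights()]); default unit weights.
#' @param lambda Ridge parameter.
#' @param n_bins Number of sliding bins (default 90).
#' @param window_frac Fraction of trials per bin (default 0.1).
#' @return A long-format data.frame with columns `bin`, `term`, `estimate`,
#'   `bin_median_rel_err`, `n_trials`. Besides the design-matrix
#'   coefficients, each bin carries a derived `learning_rate` term: the
#'   model-implied `d(update)/d(delta)` evaluated at the bin's mean centred
#'   factor values (the bin-level learning rate, combining the main
#'   prediction-error effect with the interaction terms). If the dataset is
#'   too small to support `n_bins` distinct windows the number of bins is
#'   reduced with a warning.
#' @export
sliding_window_fit <- function(dataset, weights = NULL, lambda = 0.1,
                               n_bins = 90, window_frac = 0.1) {
  n <- nrow(dataset)
  if (n < 1) stop("empty dataset", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  A <- .design_matrix(dataset)
  k <- max(ncol(A) + 2L, round(window_frac * n))
  if (k >= n) {
    warning("dataset too small for sliding windows; using a single bin")
    n_bins <- 1L
    k <- n
  } else if (n - k + 1L < n_bins) {
    warning("dataset too small for ", n_bins, " distinct windows; using ",
            n - k + 1L, " bins")
    n_bins <- n - k + 1L
  }
  ord <- order(dataset$abs_rel_err)
  starts <- round(seq(1, n - k + 1, length.out = n_bins))
  out <- vector("list", n_bins)
  terms <- colnames(A)
  factors <- c(delta_x_surprise = "surprise",
               delta_x_uncertainty = "uncertainty",
               delta_x_noise = "noise_sd", delta_x_value = "is_gold",
               delta_x_visible = "is_catch")
  for (j in seq_len(n_bins)) {
    idx <- ord[starts[j]:(starts[j] + k - 1L)]
    Aj <- A[idx, , drop = FALSE]
    dlt <- dataset$delta[idx]
    wj <- weights[idx]
    wdd <- sum(wj * dlt * dlt)
    for (tm in names(factors)) {
      f <- as.numeric(dataset[[factors[[tm]]]][idx])
      cl <- dlt * (f - mean(f))
      # remove the component along delta (weighted projection) so the
      # delta coefficient stays the bin's learning rate even when a factor
      # is nearly deterministic given |delta| inside the window
      cl <- cl - dlt * (sum(wj * dlt * cl) / wdd)
      Aj[, tm] <- cl
    }
    beta <- ridge_weighted_solve(Aj, dataset$update[idx], wj, lambda)
    out[[j]] <- data.frame(
      bin = j, term = c(terms, "learning_rate"),
      estimate = c(unname(beta), beta[["delta"]]),
      bin_median_rel_err = stats::median(dataset$abs_rel_err[idx]),
      n_trials = k)
  }
  do.call(rbind, out)
}

#' Reshape windowed coefficients to a subject-by-bin matrix
#'
#' @param fits A list of [sliding_window_fit()] results (one per subject).
#' @param term The coefficient to extract (e.g. `"delta"`).
#' @return A numeric matrix, subjects in rows, bins in columns.
#' @export
coef_matrix <- function(fits, term) {
  rows <- lapply(fits, function(f) f$estimate[f$term == term])
  nb <- unique(lengths(rows))
  if (length(nb) != 1)
    stop("subjects have different numbers of bins", call. = FALSE)
  do.call(rbind, rows)
}
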