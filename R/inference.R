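#' Moving-average smoothing of coefficients across bins
#'
#' Centred moving average per subject (row) with edge truncation; width 1 is
#' the identity.
#'
#' @param coeffs Numeric matrix, subjects x bins (a vector is treated as one
#'   subject).
#' @param width Odd window width in bins, `>= 1`.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_across_bins <- function(coeffs, width = 5) {
  vec <- is.null(dim(coeffs))
  if (vec) coeffs <- matrix(coeffs, nrow = 1)
  if (width < 1 || width %% 2 == 0)
    stop("`width` must be odd and >= 1", call. = FALSE)
  nb <- ncol(coeffs)
  if (width > nb) stop("`width` exceeds the number of bins", call. = FALSE)
  if (width == 1) return(if (vec) drop(coeffs) else coeffs)
  h <- (width - 1) / 2
  out <- coeffs
  for (j in seq_len(nb)) {
    idx <- max(1, j - h):min(nb, j + h)
    out[, j] <- rowMeans(coeffs[, idx, drop = FALSE])
  }
  if (vec) drop(out) else out
}

# max cluster mass in a vector of t statistics given a |t| threshold
.max_cluster_mass <- function(tv, thr) {
  sig <- abs(tv) > thr
  if (!any(sig)) return(0)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- 0
  for (i in which(r$values)) {
    mass <- r$lengths[i] * mean(abs(tv[starts[i]:ends[i]]))
    if (mass > best) best <- mass
  }
  best
}

.clusters_of <- function(tv, thr) {
  sig <- abs(tv) > thr
  if (!any(sig)) return(NULL)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(i)
               r$lengths[i] * mean(abs(tv[starts[i]:ends[i]])), numeric(1)))
}

#' Cluster-mass permutation test over binned coefficients
#'
#' Per-bin t-tests (one-sample against zero, or two-sample between groups
#' with pooled variance) define clusters as maximal runs of contiguous bins
#' with `p < alpha_forming`; the mass of a cluster is its length times the
#' mean `|t|` within it. The familywise null distribution is the maximum
#' cluster mass over `n_perm` permutations — coherent sign flips of whole
#' subjects for the one-group test, group-label flips for the two-group
#' test. Cluster p-values are `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param coeffs_a Subjects x bins matrix (group A).
#' @param coeffs_b Optional second group for a two-group test.
#' @param n_perm Number of permutations (default 10000).
#' @param alpha_forming Cluster-forming threshold (default 0.05, two-sided).
#' @param smooth_width Width for [smooth_across_bins()] applied before
#'   testing (1 = no smoothing).
#' @param seed Optional integer seed.
#' @return An object of class `cluster_test` with `clusters` (start, end,
#'   mass, p), `t` (per-bin statistics), `test` (`"one-group"` or
#'   `"two-group"`), `n_perm`, `smooth_width`, `alpha_forming`.
#' @export
cluster_mass_permutation_test <- function(coeffs_a, coeffs_b = NULL,
                                          n_perm = 10000,
                                          alpha_forming = 0.05,
                                          smooth_width = 1, seed = NULL) {
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  if (!is.null(seed)) set.seed(seed)
  A <- smooth_across_bins(as.matrix(coeffs_a), smooth_width)
  if (is.null(coeffs_b)) {
    n <- nrow(A)
    if (n < 2) stop("need at least 2 subjects", call. = FALSE)
    nb <- ncol(A)
    ssq <- colSums(A^2)
    tstat_from <- function(m) {
      v <- (ssq - n * m^2) / (n - 1)
      bad <- v <= .Machine$double.eps * pmax(ssq, 1)
      if (any(bad)) {
        warning("zero-variance bins excluded from cluster formation")
        v[bad] <- Inf
      }
      m / sqrt(v / n)
    }
    t_obs <- tstat_from(colMeans(A))
    thr <- stats::qt(1 - alpha_forming / 2, n - 1)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- (S %*% A) / n
    null_mass <- numeric(n_perm)
    for (p in seq_len(n_perm))
      null_mass[p] <- .max_cluster_mass(tstat_from(M[p, ]), thr)
    test <- "one-group"
  } else {
    B <- smooth_across_bins(as.matrix(coeffs_b), smooth_width)
    if (ncol(B) != ncol(A)) stop("bin counts differ", call. = FALSE)
    na <- nrow(A); nb_s <- nrow(B)
    if (na < 2 || nb_s < 2)
      stop("need at least 2 subjects per group", call. = FALSE)
    X <- rbind(A, B)
    n <- na + nb_s
    df <- n - 2
    X2 <- X^2
    tot1 <- colSums(X); tot2 <- colSums(X2)
    tstat_two <- function(ga) { # ga: logical membership in group A
      s1a <- colSums(X[ga, , drop = FALSE])
      s2a <- colSums(X2[ga, , drop = FALSE])
      m_a <- s1a / na
      m_b <- (tot1 - s1a) / nb_s
      ssa <- s2a - na * m_a^2
      ssb <- (tot2 - s2a) - nb_s * m_b^2
      sp2 <- (ssa + ssb) / df
      bad <- sp2 <= .Machine$double.eps * pmax(tot2, 1)
      if (any(bad)) sp2[bad] <- Inf
      (m_a - m_b) / sqrt(sp2 * (1 / na + 1 / nb_s))
    }
    ga0 <- c(rep(TRUE, na), rep(FALSE, nb_s))
    t_obs <- tstat_two(ga0)
    if (any(!is.finite(t_obs)))
      warning("zero-variance bins excluded from cluster formation")
    thr <- stats::qt(1 - alpha_forming / 2, df)
    null_mass <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      ga <- logical(n)
      ga[sample.int(n, na)] <- TRUE
      null_mass[p] <- .max_cluster_mass(tstat_two(ga), thr)
    }
    test <- "two-group"
    thr <- stats::qt(1 - alpha_forming / 2, df)
  }
  cl <- .clusters_of(t_obs, thr)
  if (!is.null(cl))
    cl$p <- vapply(cl$mass, function(m)
      (1 + sum(null_mass >= m)) / (1 + n_perm), numeric(1))
  structure(list(clusters = cl, t = t_obs, test = test, n_perm = n_perm,
                 smooth_width = smooth_width, alpha_forming = alpha_forming,
                 null_mass = null_mass),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster-mass permutation test (%s, %d permutations, smoothing %d)\n",
              x$test, x$n_perm, x$smooth_width))
  if (is.null(x$clusters)) {
    cat("  no clusters formed\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  bins %d-%d: mass %.2f, p = %.4g\n",
                  x$clusters$start[i], x$clusters$end[i],
                  x$clusters$mass[i], x$clusters$p[i]))
  }
  invisible(x)
}

#' Leave-one-subject-out coefficient extraction
#'
#' For each subject, the between-group t-statistic is computed per bin over
#' all *other* subjects; the subject's coefficient is read from the bin with
#' the maximum `|t|` (lowest bin index on ties). Selecting the bin without
#' the held-out subject avoids circular inference when the extracted values
#' are reused in group-level models.
#'
#' @param coeffs_a,coeffs_b Subjects x bins matrices for the two groups
#'   (each with at least 3 subjects).
#' @return A data.frame with `subject` (row index within its group),
#'   `group` (`"a"`/`"b"`), `bin` (selected bin) and `value`.
#' @export
loso_extract <- function(coeffs_a, coeffs_b) {
  A <- as.matrix(coeffs_a); B <- as.matrix(coeffs_b)
  if (nrow(A) < 3 || nrow(B) < 3)
    stop("need at least 3 subjects per group", call. = FALSE)
  two_t <- function(X, Y) {
    nx <- nrow(X); ny <- nrow(Y)
    mx <- colMeans(X); my <- colMeans(Y)
    vx <- apply(X, 2, stats::var); vy <- apply(Y, 2, stats::var)
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    (mx - my) / sqrt(pmax(sp2, .Machine$double.xmin) * (1 / nx + 1 / ny))
  }
  one <- function(X, Y, grp) {
    out <- vector("list", nrow(X))
    for (s in seq_len(nrow(X))) {
      tv <- if (grp == "a") two_t(X[-s, , drop = FALSE], Y)
            else two_t(Y, X[-s, , drop = FALSE])
      b <- which.max(abs(tv))  # which.max takes the first (lowest) index
      out[[s]] <- data.frame(subject = s, group = grp, bin = b,
                             value = X[s, b])
    }
    do.call(rbind, out)
  }
  rbind(one(A, B, "a"), one(B, A, "b"))
}

#' Nested F-test between two least-squares models
#'
#' `F = ((RSS_r - RSS_f) / (df_r - df_f)) / (RSS_f / df_f)`, with the
#' p-value from the F distribution on `(df_r - df_f, df_f)` degrees of
#' freedom.
#'
#' @param rss_reduced,df_reduced Residual sum of squares and residual
#'   degrees of freedom of the reduced model.
#' @param rss_full,df_full Same for the full model (must be nested:
#'   `rss_full <= rss_reduced`, `df_full < df_reduced`).
#' @return A list with `f`, `p`, `df1`, `df2`.
#' @export
nested_f_test <- function(rss_reduced, df_reduced, rss_full, df_full) {
  if (df_full >= df_reduced)
    stop("models are not nested (df_full must be < df_reduced)", call. = FALSE)
  if (rss_full > rss_reduced + 1e-8 * rss_reduced)
    stop("models are not nested (rss_full exceeds rss_reduced)", call. = FALSE)
  df1 <- df_reduced - df_full
  f <- (max(rss_reduced - rss_full, 0) / df1) / (rss_full / df_full)
  list(f = f, p = stats::pf(f, df1, df_full, lower.tail = FALSE),
       df1 = df1, df2 = df_full)
}

#' Explain age from task-derived measures and covariates
#'
#' Fits a chain of least-squares models of age — (1) intercept only, (2)
#' intercept + the task-derived predictor (LOSO-extracted coefficient or
#' fitted log-UU), (3) model 2 + Raven and OSPAN scores — and compares them
#' with nested F-tests. A significant predictor term in the (3) vs (2 with
#' covariates only) comparison indicates that the task measure relates to
#' age beyond the psychometric covariates.
#'
#' @param subjects Cohort subject table (columns `age`, `raven`, `ospan`).
#' @param predictor Numeric per-subject task measure, aligned to
#'   `subjects` rows.
#' @param conf_level Confidence level for coefficient intervals.
#' @return An object of class `age_model` with the fitted models'
#'   coefficients and confidence intervals, residual summaries, and the
#'   nested-F chain (`intercept_vs_predictor`,
#'   `covariates_vs_full` — does the predictor add to the covariates —
#'   and `predictor_vs_full`).
#' @export
age_explanatory_model <- function(subjects, predictor, conf_level = 0.95) {
  if (length(predictor) != nrow(subjects))
    stop("`predictor` is not aligned to `subjects`", call. = FALSE)
  d <- data.frame(age = subjects$age, x = predictor,
                  raven = subjects$raven, ospan = subjects$ospan)
  m1 <- stats::lm(age ~ 1, data = d)
  m2 <- stats::lm(age ~ x, data = d)
  m3 <- stats::lm(age ~ x + raven + ospan, data = d)
  m_cov <- stats::lm(age ~ raven + ospan, data = d)
  rss <- function(m) sum(stats::residuals(m)^2)
  chain <- list(
    intercept_vs_predictor = nested_f_test(rss(m1), stats::df.residual(m1),
                                           rss(m2), stats::df.residual(m2)),
    covariates_vs_full = nested_f_test(rss(m_cov), stats::df.residual(m_cov),
                                       rss(m3), stats::df.residual(m3)),
    predictor_vs_full = nested_f_test(rss(m2), stats::df.residual(m2),
                                      rss(m3), stats::df.residual(m3)))
  structure(list(
    coefficients = stats::coef(m3),
    conf_int = stats::confint(m3, level = conf_level),
    predictor_coef = unname(stats::coef(m2)["x"]),
    nested = chain, n = nrow(d),
    rss = c(intercept = rss(m1), predictor = rss(m2),
            covariates = rss(m_cov), full = rss(m3))),
    class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("Age explanatory models (n = %d)\n", x$n))
  cat(sprintf("  predictor coefficient (predictor-only model): %.3f\n",
              x$predictor_coef))
  for (nm in names(x$nested))
    cat(sprintf("  %s: F(%d, %d) = %.3f, p = %.4g\n", nm,
                x$nested[[nm]]$df1, x$nested[[nm]]$df2,
                x$nested[[nm]]$f, x$nested[[nm]]$p))
  invisible(x)
}
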