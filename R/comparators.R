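# Leave-one-out origin-constrained WLS, vectorised with rank-one downdates.
# Returns the n x d matrix of estimates without each variant, the full-sample
# fit, leverages, and the leave-one-out residuals y_i - x_i' theta^{-i}
# (= e_i / (1 - h_i)).
loo_wls <- function(X, y, omega) {
  w <- 1 / omega
  n <- nrow(X)
  d <- ncol(X)
  if (n < d + 2L) {
    stop("leave-one-out fits need at least d + 2 variants", call. = FALSE)
  }
  A <- crossprod(X, w * X)
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("weighted exposure design is rank deficient", call. = FALSE)
  })
  theta <- drop(Ainv %*% crossprod(X, w * y))
  U <- X %*% Ainv                      # row i = x_i' Ainv
  h <- w * rowSums(U * X)              # leverages, in (0, 1)
  if (any(h >= 1 - 1e-12)) {
    stop("leave-one-out fit undefined: removing a variant makes the design ",
         "rank deficient", call. = FALSE)
  }
  e <- drop(y - X %*% theta)
  theta_loo <- matrix(theta, n, d, byrow = TRUE) - U * (w * e / (1 - h))
  list(theta = theta, theta_loo = theta_loo, resid_loo = e / (1 - h),
       leverage = h)
}

#' Bonferroni-thresholded local q outlier detection
#'
#' The "Standard" (first-order weights) and "Sanderson" (second-order
#' weights) detectors: fit the IVW model under the chosen weighting scheme
#' (the second-order fit is iterative), compute the local q statistics at
#' the full-sample estimate, flag every variant whose q exceeds the
#' chi-square(1) critical value at the Bonferroni-adjusted level `alpha/n`,
#' then refit under the same scheme on the survivors. Detection is a single
#' pass at the converged fit.
#'
#' @param data an [mr_summary_data] object.
#' @param scheme `"first_order"` (Standard) or `"second_order"` (Sanderson;
#'   cross-exposure covariances are used when `data$exposure_cov` is
#'   present, otherwise treated as zero).
#' @param alpha nominal family-wise level.
#' @return an `mr_outlier_report`.
#' @export
mr_q_outliers <- function(data, scheme = c("first_order", "second_order"),
                          alpha = 0.05) {
  stopifnot(inherits(data, "mr_summary_data"))
  scheme <- match.arg(scheme)
  n <- n_variants(data)
  d <- n_exposures(data)
  if (n < d + 1L) stop("need at least d + 1 variants", call. = FALSE)
  fit <- mr_ivw(data, weights = scheme)
  het <- cochran_q(data, fit)
  thr <- bonferroni_threshold(n, alpha)
  flagged <- names(het$q_local)[het$q_local > thr]
  if (length(flagged) == n) {
    stop("every variant flagged as an outlier", call. = FALSE)
  }
  keep <- setdiff(data$variant_ids, flagged)
  post <- if (length(flagged)) mr_ivw(data[keep], weights = scheme) else fit
  new_outlier_report(
    method = if (scheme == "first_order") "standard" else "sanderson",
    data = data, statistic = het$q_local,
    p_per_variant = stats::pchisq(het$q_local, 1, lower.tail = FALSE),
    threshold = thr,
    threshold_desc = sprintf(
      "q > chi-square(1) upper %.3g quantile (Bonferroni alpha/n)", alpha / n),
    flagged = flagged, estimate_full = fit, estimate_post = post,
    alpha = alpha)
}

presso_simulate <- function(data, loo, n_sim) {
  n <- n_variants(data)
  d <- n_exposures(data)
  omega <- data$se_outcome^2
  w <- 1 / omega
  mu_y <- rowSums(data$beta_exposure * loo$theta_loo)
  stat_sim <- matrix(NA_real_, n, n_sim)
  rss_sim <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    Xs <- data$beta_exposure +
      matrix(stats::rnorm(n * d), n, d) * data$se_exposure
    ys <- stats::rnorm(n, mu_y, data$se_outcome)
    A <- crossprod(Xs, w * Xs)
    Ainv <- solve(A)
    th <- drop(Ainv %*% crossprod(Xs, w * ys))
    U <- Xs %*% Ainv
    h <- w * rowSums(U * Xs)
    e <- drop(ys - Xs %*% th)
    r <- e / (1 - h)
    stat_sim[, s] <- w * r^2
    rss_sim[s] <- sum(w * r^2)
  }
  list(stat = stat_sim, rss = rss_sim)
}

#' MR-PRESSO global heterogeneity test
#'
#' The observed residual sum of squares with leave-one-out causal estimates
#' and first-order weights, compared to its distribution under a parametric
#' simulation null: exposure associations resampled around their estimates,
#' outcome associations around the leave-one-out fitted values, with the
#' observed standard errors. The p-value is the `(r + 1) / (n_sim + 1)`
#' empirical tail fraction.
#'
#' @param data an [mr_summary_data] object with `n >= d + 2`.
#' @param n_sim number of simulated null datasets (default 1000; a warning
#'   is raised below 100).
#' @param seed optional integer seed.
#' @return list with `rss`, `p_value`, `n_sim`.
#' @export
mr_presso_global <- function(data, n_sim = 1000L, seed = NULL) {
  stopifnot(inherits(data, "mr_summary_data"))
  if (n_sim < 100L) warning("n_sim < 100 gives a coarse empirical p-value")
  if (!is.null(seed)) set.seed(seed)
  omega <- data$se_outcome^2
  loo <- loo_wls(data$beta_exposure, data$beta_outcome, omega)
  rss_obs <- sum(loo$resid_loo^2 / omega)
  sims <- presso_simulate(data, loo, n_sim)
  list(rss = rss_obs,
       p_value = (sum(sims$rss >= rss_obs) + 1) / (n_sim + 1),
       n_sim = n_sim)
}

#' MR-PRESSO outlier test
#'
#' Per-variant version of the residual-sum-of-squares test: each observed
#' leave-one-out residual term is compared to its own simulated null
#' distribution; the raw empirical p-values are Bonferroni-adjusted
#' (multiplied by n) and a variant is flagged when the adjusted value falls
#' below `alpha` -- with `n_sim` simulations this requires the observed term
#' to exceed every simulated one whenever `n_sim < n / alpha`. Reported
#' per-variant p-values are floored at `1 / n_sim` (never exactly zero).
#' Survivors are refit with first-order IVW.
#'
#' @inheritParams mr_presso_global
#' @param alpha nominal family-wise level.
#' @return an `mr_outlier_report` with extra elements `p_adjusted`,
#'   `global_rss`, `global_p`.
#' @export
mr_presso_outliers <- function(data, n_sim = 1000L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(data, "mr_summary_data"))
  if (n_sim < 100L) warning("n_sim < 100 gives a coarse empirical p-value")
  if (!is.null(seed)) set.seed(seed)
  n <- n_variants(data)
  omega <- data$se_outcome^2
  loo <- loo_wls(data$beta_exposure, data$beta_outcome, omega)
  stat_obs <- stats::setNames(loo$resid_loo^2 / omega, data$variant_ids)
  sims <- presso_simulate(data, loo, n_sim)
  exceed <- rowSums(sims$stat >= stat_obs)
  p_raw <- exceed / n_sim
  p_adj <- pmin(1, p_raw * n)
  flagged <- data$variant_ids[p_adj < alpha]
  if (length(flagged) == n) stop("every variant flagged as an outlier", call. = FALSE)
  fit <- mr_ivw(data, weights = "first_order")
  keep <- setdiff(data$variant_ids, flagged)
  post <- if (length(flagged)) mr_ivw(data[keep], weights = "first_order") else fit
  new_outlier_report(
    method = "mrpresso", data = data, statistic = stat_obs,
    p_per_variant = stats::setNames(pmax(p_raw, 1 / n_sim), data$variant_ids),
    threshold = alpha,
    threshold_desc = sprintf(
      "Bonferroni-adjusted empirical p < %.3g (%d simulations)", alpha, n_sim),
    flagged = flagged, estimate_full = fit, estimate_post = post,
    alpha = alpha, seed = seed,
    extra = list(p_adjusted = stats::setNames(p_adj, data$variant_ids),
                 n_sim = n_sim,
                 global_rss = sum(stat_obs),
                 global_p = (sum(sims$rss >= sum(stat_obs)) + 1) / (n_sim + 1)))
}

#' Radial MR outlier detection
#'
#' Univariable radial (Galbraith-plot) regression with modified second-order
#' weights `w_i = 1 / (se_y_i^2 + theta^2 se_x_i^2)`: the slope of the
#' z-statistic against the ratio-estimate precision, iterated to a fixed
#' point in `theta`, equals the IVW estimate under the same weights. Per
#' variant, the Q contribution `q_i = w_i (beta_y_i - theta beta_x_i)^2` is
#' compared to the chi-square(1) critical value at level `alpha` per variant
#' -- the convention of radial MR tooling, which makes this the most liberal
#' detector here; set `bonferroni = TRUE` for the family-wise threshold used
#' by the other detectors. Survivors are refit with the same radial scheme.
#'
#' @param data an [mr_summary_data] object with a single exposure, `n >= 3`.
#' @param alpha per-variant level (default 0.05).
#' @param bonferroni use `alpha / n` instead of `alpha` (default `FALSE`).
#' @param tol,max_iter fixed-point iteration control.
#' @return an `mr_outlier_report`.
#' @export
mr_radial <- function(data, alpha = 0.05, bonferroni = FALSE,
                      tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(data, "mr_summary_data"))
  if (n_exposures(data) != 1L) stop("radial MR is univariable (d = 1)", call. = FALSE)
  if (n_variants(data) < 3L) stop("need at least 3 variants", call. = FALSE)
  n <- n_variants(data)
  radial_fit <- function(bx, by, sx, sy) {
    theta <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
    for (it in seq_len(max_iter)) {
      w <- 1 / (sy^2 + theta^2 * sx^2)
      theta_new <- sum(w * bx * by) / sum(w * bx^2)
      if (abs(theta_new - theta) < tol) {
        return(list(theta = theta_new, w = 1 / (sy^2 + theta_new^2 * sx^2),
                    iterations = it))
      }
      theta <- theta_new
    }
    stop("radial MR did not converge in ", max_iter, " iterations; ",
         "last estimate: ", signif(theta, 6), call. = FALSE)
  }
  bx <- data$beta_exposure[, 1L]; by <- data$beta_outcome
  sx <- data$se_exposure[, 1L]; sy <- data$se_outcome
  fit <- radial_fit(bx, by, sx, sy)
  q <- stats::setNames(fit$w * (by - fit$theta * bx)^2, data$variant_ids)
  thr <- if (bonferroni) bonferroni_threshold(n, alpha) else
    stats::qchisq(alpha, 1, lower.tail = FALSE)
  flagged <- names(q)[q > thr]
  if (length(flagged) == n) stop("every variant flagged as an outlier", call. = FALSE)
  mk_est <- function(keep) {
    f <- radial_fit(bx[keep], by[keep], sx[keep], sy[keep])
    se <- 1 / sqrt(sum(f$w * bx[keep]^2))
    new_mr_estimate(f$theta, se, matrix(se^2, 1, 1), "radial",
                    "modified_second_order", data$variant_ids[keep],
                    data[data$variant_ids[keep]])
  }
  est_full <- mk_est(seq_len(n))
  keep_idx <- which(!(data$variant_ids %in% flagged))
  est_post <- if (length(flagged)) mk_est(keep_idx) else est_full
  new_outlier_report(
    method = "radial", data = data, statistic = q,
    p_per_variant = stats::pchisq(q, 1, lower.tail = FALSE),
    threshold = thr,
    threshold_desc = if (bonferroni)
      sprintf("q > chi-square(1) upper %.3g quantile (Bonferroni alpha/n)", alpha / n)
    else sprintf("q > chi-square(1) upper %.3g quantile (per-variant)", alpha),
    flagged = flagged, estimate_full = est_full, estimate_post = est_post,
    alpha = alpha)
}

#' Run one or all outlier detectors on a dataset
#'
#' Convenience front end dispatching to [mr_gcq()], [mr_q_outliers()],
#' [mr_presso_outliers()], [mr_radial()] and [mr_weighted_median()] (the
#' median is a robust estimator, not a detector: it contributes an estimate
#' with an empty flag set). With `method = "all"` every applicable method is
#' run on the same data and a comparison table (method, flagged variants,
#' estimates before/after removal) is attached.
#'
#' @param data an [mr_summary_data] object.
#' @param method one of `"gcq"`, `"standard"`, `"sanderson"`, `"mrpresso"`,
#'   `"radial"`, `"median"`, `"all"`.
#' @param alpha family-wise level passed to the detectors.
#' @param n_sim MR-PRESSO simulation count.
#' @param n_boot weighted-median bootstrap count.
#' @param seed seed for the stochastic methods.
#' @param ... further arguments passed to the selected method.
#' @return an `mr_outlier_report`, or for `"all"` a list of reports with a
#'   `comparison` data.frame attribute, class `mr_detect_all`.
#' @export
mr_detect <- function(data, method = c("gcq", "standard", "sanderson",
                                       "mrpresso", "radial", "median", "all"),
                      alpha = 0.05, n_sim = 1000L, n_boot = 1000L,
                      seed = NULL, ...) {
  method <- match.arg(method)
  run_one <- function(m) {
    switch(m,
      gcq = mr_gcq(data, alpha = alpha, ...),
      standard = mr_q_outliers(data, "first_order", alpha = alpha),
      sanderson = mr_q_outliers(data, "second_order", alpha = alpha),
      mrpresso = mr_presso_outliers(data, n_sim = n_sim, alpha = alpha,
                                    seed = seed),
      radial = mr_radial(data, alpha = alpha, ...),
      median = {
        est <- mr_weighted_median(data, n_boot = n_boot, seed = seed)
        new_outlier_report(
          method = "median", data = data,
          statistic = stats::setNames(rep(NA_real_, n_variants(data)),
                                      data$variant_ids),
          p_per_variant = rep(NA_real_, n_variants(data)),
          threshold = NA_real_,
          threshold_desc = "robust estimator; no outliers flagged",
          flagged = character(0), estimate_full = est, estimate_post = est,
          alpha = alpha, seed = seed)
      })
  }
  if (method != "all") return(run_one(method))
  methods <- c("gcq", "standard", "sanderson", "mrpresso", "median")
  if (n_exposures(data) == 1L) methods <- append(methods, "radial", after = 4L)
  reports <- lapply(stats::setNames(methods, methods), run_one)
  comparison <- do.call(rbind, lapply(methods, function(m) {
    r <- reports[[m]]
    data.frame(method = m,
               n_flagged = length(r$flagged),
               flagged = paste(r$flagged, collapse = ","),
               theta_full = paste(signif(r$estimate_full$theta, 6),
                                  collapse = ","),
               theta_post = paste(signif(r$estimate_post$theta, 6),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(reports, comparison = comparison, class = "mr_detect_all")
}

#' @export
print.mr_detect_all <- function(x, ...) {
  cat("MR outlier detection, all methods:\n")
  print(attr(x, "comparison"))
  invisible(x)
}
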