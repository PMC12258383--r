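# Median of the chi-square(1) distribution as used by the genomic-control
# inflation estimator: the conventional 0.675^2 rather than the exact
# qchisq(0.5, 1) = 0.4549364.
GC_CHISQ1_MEDIAN <- 0.675^2

new_mr_weights <- function(omega, scheme, theta_used = NULL) {
  if (!all(is.finite(omega)) || any(omega <= 0)) {
    stop("degenerate weights: every variance factor must be finite and > 0",
         call. = FALSE)
  }
  structure(list(omega = omega, scheme = scheme, theta_used = theta_used),
            class = "mr_weights")
}

#' @export
print.mr_weights <- function(x, ...) {
  cat("MR variance factors (", x$scheme, "), n = ", length(x$omega), "\n", sep = "")
  invisible(x)
}

#' First-order variance factors
#'
#' The "no measurement error" weighting: the per-variant variance factor is
#' the squared standard error of the outcome association. Cheap and always
#' available, but known to overdisperse Cochran's Q because the uncertainty
#' of the exposure associations is ignored.
#'
#' @param data an [mr_summary_data] object.
#' @return an `mr_weights` object with `omega = se_outcome^2`.
#' @export
first_order_weights <- function(data) {
  stopifnot(inherits(data, "mr_summary_data"))
  new_mr_weights(stats::setNames(data$se_outcome^2, data$variant_ids),
                 "first_order")
}

#' Second-order variance factors
#'
#' Adds the exposure-association uncertainty to the first-order factors:
#' for variant i, `omega_i = se_y_i^2 + sum_j theta_j^2 se_x_ij^2 +
#' sum_{j != k} theta_j theta_k cov_x_ijk`, i.e. the quadratic form
#' `theta' Sigma_xi theta` on top of the outcome variance. Cross-exposure
#' covariances are taken from `data$exposure_cov` when present and treated
#' as zero otherwise (the common summary-level situation).
#'
#' @param data an [mr_summary_data] object.
#' @param theta length-d causal effect vector the weights are evaluated at.
#' @return an `mr_weights` object (records `theta_used`).
#' @export
#' @examples
#' d <- mr_summary_data(beta_exposure = 1, se_exposure = 0.5,
#'                      beta_outcome = 2, se_outcome = 1)
#' second_order_weights(d, 2)$omega  # 1 + 4 * 0.25 = 2
second_order_weights <- function(data, theta) {
  stopifnot(inherits(data, "mr_summary_data"))
  theta <- as.numeric(theta)
  d <- n_exposures(data)
  n <- n_variants(data)
  if (length(theta) != d || !all(is.finite(theta))) {
    stop("'theta' must be a finite vector of length ", d, call. = FALSE)
  }
  if (is.null(data$exposure_cov)) {
    quad <- drop(data$se_exposure^2 %*% theta^2)
  } else {
    quad <- vapply(seq_len(n), function(i) {
      drop(crossprod(theta, matrix(data$exposure_cov[, , i], d, d) %*% theta))
    }, numeric(1))
  }
  omega <- data$se_outcome^2 + quad
  if (any(omega <= 0)) {
    bad <- which(omega <= 0)
    stop("second-order variance factor non-positive for variant(s) ",
         paste(data$variant_ids[bad], collapse = ", "),
         " (negative covariance terms dominate)", call. = FALSE)
  }
  new_mr_weights(stats::setNames(omega, data$variant_ids), "second_order", theta)
}

#' Cochran's Q heterogeneity statistic and its per-variant decomposition
#'
#' Computes the global heterogeneity statistic
#' `Q = sum_i (1/omega_i) (beta_y_i - sum_j theta_j beta_x_ij)^2`, which is
#' asymptotically chi-square with `n - d` degrees of freedom when every
#' instrument is valid, together with the local contributions `q_i` (each
#' asymptotically chi-square(1)) used for outlier detection. Residuals are
#' always taken at the supplied full-sample estimate of the named scheme; no
#' leave-one-out is involved here.
#'
#' @param data an [mr_summary_data] object.
#' @param estimate an `mr_estimate` (e.g. from [mr_ivw()]) evaluated on the
#'   same variant set.
#' @param weights variance factors to use; defaults to the weights stored in
#'   `estimate`.
#' @return an object of class `mr_heterogeneity`: `Q`, `df = n - d`,
#'   `p_value` (upper tail, `NA` with a flag when `df < 1`), `q_local`,
#'   `weight_scheme`, `theta_hat`.
#' @export
cochran_q <- function(data, estimate, weights = estimate$weights) {
  stopifnot(inherits(data, "mr_summary_data"), inherits(estimate, "mr_estimate"))
  if (is.null(weights)) weights <- first_order_weights(data)
  n <- n_variants(data)
  d <- n_exposures(data)
  if (!identical(sort(estimate$variants_used), sort(data$variant_ids))) {
    stop("estimate and data cover different variant sets", call. = FALSE)
  }
  if (length(weights$omega) != n) {
    stop("weights and data cover different variant sets", call. = FALSE)
  }
  resid <- drop(data$beta_outcome - data$beta_exposure %*% estimate$theta)
  q_local <- stats::setNames(resid^2 / weights$omega, data$variant_ids)
  Q <- sum(q_local)
  df <- n - d
  # survival function keeps precision in the far tail
  p <- if (df >= 1L) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  structure(list(Q = Q, df = df, p_value = p, q_local = q_local,
                 weight_scheme = weights$scheme, theta_hat = estimate,
                 df_valid = df >= 1L),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s weights): Q = %.4f on %d df", x$weight_scheme,
              x$Q, x$df))
  if (x$df_valid) cat(sprintf(", p = %.4g\n", x$p_value))
  else cat(" (no p-value: df < 1)\n")
  invisible(x)
}

#' Bonferroni-corrected chi-square(1) outlier threshold
#'
#' The critical value used by every Bonferroni-thresholded detector in this
#' package: the upper `alpha/n` quantile of the chi-square distribution with
#' one degree of freedom, so that testing all `n` per-variant statistics
#' controls the family-wise error at `alpha`.
#'
#' @param n number of variants tested (>= 1).
#' @param alpha nominal family-wise level in (0, 1); default 0.05.
#' @return scalar critical value.
#' @export
#' @examples
#' bonferroni_threshold(1)   # 3.8415 (the plain 95% point)
#' bonferroni_threshold(22)  # stricter with more variants
bonferroni_threshold <- function(n, alpha = 0.05) {
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  stats::qchisq(alpha / n, df = 1, lower.tail = FALSE)
}
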