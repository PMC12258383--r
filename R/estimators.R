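#' Per-variant ratio estimates
#'
#' The single-instrument causal estimate for each variant in a univariable
#' analysis: the variant-outcome association divided by the variant-exposure
#' association.
#'
#' @param data an [mr_summary_data] object with a single exposure.
#' @return named numeric vector of length n.
#' @export
#' @examples
#' d <- mr_summary_data(beta_exposure = c(0.2, 0.1), se_exposure = c(0.02, 0.02),
#'                      beta_outcome = c(0.4, -0.2), se_outcome = c(0.05, 0.06))
#' ratio_estimates(d)  # 2, -2
ratio_estimates <- function(data) {
  stopifnot(inherits(data, "mr_summary_data"))
  if (n_exposures(data) != 1L) {
    stop("ratio estimates are defined for a single exposure (d = 1)", call. = FALSE)
  }
  bx <- data$beta_exposure[, 1L]
  zero <- which(bx == 0)
  if (length(zero)) {
    stop("degenerate instrument(s) with zero exposure association: ",
         paste(data$variant_ids[zero], collapse = ", "), call. = FALSE)
  }
  stats::setNames(data$beta_outcome / bx, data$variant_ids)
}

# Origin-constrained weighted least squares: minimise
# sum_i (1/omega_i) (y_i - x_i' theta)^2. Returns the fit plus the pieces the
# heterogeneity statistics reuse.
wls_origin <- function(X, y, omega, dispersion = c("none", "multiplicative")) {
  dispersion <- match.arg(dispersion)
  if (!all(is.finite(omega)) || all(omega == 0)) {
    stop("weights must be finite with at least one non-zero entry", call. = FALSE)
  }
  w <- 1 / omega
  n <- nrow(X)
  d <- ncol(X)
  A <- crossprod(X, w * X)
  b <- crossprod(X, w * y)
  cv <- tryCatch(solve(A), error = function(e) {
    stop("weighted exposure design is rank deficient; risk factors are ",
         "collinear under these instruments (assumption RF2(M))", call. = FALSE)
  })
  theta <- drop(cv %*% b)
  resid <- drop(y - X %*% theta)
  if (dispersion == "multiplicative" && n > d) {
    phi <- max(1, sum(w * resid^2) / (n - d))
    cv <- cv * phi
  }
  list(theta = theta, cov = cv, se = sqrt(diag(cv)), resid = resid)
}

new_mr_estimate <- function(theta, se, cov, method, weight_scheme, variants_used,
                            data, weights = NULL, extra = list()) {
  d <- length(theta)
  names(theta) <- names(se) <- paste0("theta_", seq_len(d))
  out <- c(list(theta = theta, se_theta = se,
                p_values = 2 * stats::pnorm(-abs(theta) / se),
                cov = cov, method = method, weight_scheme = weight_scheme,
                variants_used = variants_used, n = length(variants_used), d = d,
                weights = weights, data = data), extra)
  class(out) <- "mr_estimate"
  out
}

#' Inverse-variance weighted causal effect estimation
#'
#' Fits the univariable or multivariable IVW model: origin-constrained
#' weighted least squares of the outcome associations on the exposure
#' associations, with per-variant variance factors given by the chosen
#' weighting scheme. With a single exposure this equals the classical
#' precision-weighted mean of the per-variant ratio estimates.
#'
#' First-order weights use only the outcome standard errors (the "no
#' measurement error" approximation). Second-order weights additionally carry
#' the exposure-association variances scaled by the squared causal effect
#' (plus cross-exposure covariance terms when available); because they depend
#' on the estimate itself, the fit is iterated to a fixed point starting from
#' the first-order solution.
#'
#' Standard errors are fixed-effect by default; `dispersion =
#' "multiplicative"` inflates them by the residual dispersion (floored at 1),
#' for workflows that model rather than remove heterogeneity.
#'
#' @param data an [mr_summary_data] object.
#' @param weights `"first_order"`, `"second_order"`, or an `mr_weights`
#'   object (e.g. from [first_order_weights()]) used as-is.
#' @param dispersion `"none"` (fixed-effect, default) or `"multiplicative"`.
#' @param tol,max_iter convergence control for the second-order fixed-point
#'   iteration (largest absolute change in any effect below `tol`).
#' @return an object of class `mr_estimate` with elements `theta`,
#'   `se_theta`, `p_values`, `cov`, `weights` (the `mr_weights` object the
#'   final fit used), `method`, `weight_scheme`, `variants_used`.
#' @export
#' @examples
#' d <- mr_summary_data(beta_exposure = c(1, 1), se_exposure = c(0.1, 0.1),
#'                      beta_outcome = c(1, 3), se_outcome = c(1, 1))
#' coef(mr_ivw(d))  # 2: equal-weight mean of ratios 1 and 3
mr_ivw <- function(data, weights = "first_order",
                   dispersion = c("none", "multiplicative"),
                   tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(data, "mr_summary_data"))
  dispersion <- match.arg(dispersion)
  n <- n_variants(data)
  d <- n_exposures(data)
  X <- data$beta_exposure
  y <- data$beta_outcome
  if (inherits(weights, "mr_weights")) {
    fit <- wls_origin(X, y, weights$omega, dispersion)
    return(new_mr_estimate(fit$theta, fit$se, fit$cov, "ivw", weights$scheme,
                           data$variant_ids, data, weights))
  }
  scheme <- match.arg(weights, c("first_order", "second_order"))
  w1 <- first_order_weights(data)
  fit <- wls_origin(X, y, w1$omega, dispersion)
  if (scheme == "first_order") {
    return(new_mr_estimate(fit$theta, fit$se, fit$cov, "ivw", scheme,
                           data$variant_ids, data, w1))
  }
  if (n <= d) stop("second-order fit needs more variants than exposures", call. = FALSE)
  theta <- fit$theta
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wv <- second_order_weights(data, theta)
    fit <- wls_origin(X, y, wv$omega, dispersion)
    delta <- max(abs(fit$theta - theta))
    theta <- fit$theta
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("second-order IVW did not converge in ", max_iter,
         " iterations; last estimate: ",
         paste(signif(theta, 6), collapse = ", "), call. = FALSE)
  }
  wv <- second_order_weights(data, theta)
  new_mr_estimate(fit$theta, fit$se, fit$cov, "ivw", scheme,
                  data$variant_ids, data, wv,
                  extra = list(iterations = it, converged = TRUE))
}

#' Weighted-median causal effect estimator
#'
#' Robust univariable estimator: the 50% point of the inverse-variance
#' weight CDF over the sorted per-variant ratio estimates, with linear
#' interpolation between adjacent order statistics (ties broken by variant
#' index). Consistent when at least half the total weight comes from valid
#' instruments. The standard error is obtained by parametric bootstrap,
#' resampling the exposure and outcome associations from normal
#' distributions centred at their estimates.
#'
#' @param data an [mr_summary_data] object with a single exposure.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @return an `mr_estimate` with `method = "median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(data, "mr_summary_data"))
  if (n_exposures(data) != 1L) {
    stop("the weighted-median estimator is univariable (d = 1)", call. = FALSE)
  }
  if (n_variants(data) < 3L) stop("need at least 3 variants", call. = FALSE)
  if (n_boot < 1L) stop("'n_boot' must be a positive count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bx <- data$beta_exposure[, 1L]
  by <- data$beta_outcome
  sx <- data$se_exposure[, 1L]
  sy <- data$se_outcome
  theta <- weighted_median_point(by / bx, bx^2 / sy^2)
  boot <- vapply(seq_len(n_boot), function(b) {
    bxs <- stats::rnorm(length(bx), bx, sx)
    bys <- stats::rnorm(length(by), by, sy)
    weighted_median_point(bys / bxs, bxs^2 / sy^2)
  }, numeric(1))
  se <- stats::sd(boot)
  est <- new_mr_estimate(theta, se, matrix(se^2, 1, 1), "median", "first_order",
                         data$variant_ids, data,
                         extra = list(n_boot = n_boot, seed = seed))
  if (se == 0) est$p_values[] <- NA_real_
  est
}

# 50% point of the weight CDF over sorted ratios, interpolating between the
# standardised midpoints S_i = (cumsum(w) - w/2) / sum(w).
weighted_median_point <- function(ratios, w) {
  ord <- order(ratios, seq_along(ratios))
  r <- ratios[ord]
  w <- w[ord] / sum(w[ord])
  S <- cumsum(w) - w / 2
  if (0.5 <= S[1L]) return(r[1L])
  if (0.5 >= S[length(S)]) return(r[length(r)])
  k <- max(which(S < 0.5))
  r[k] + (r[k + 1L] - r[k]) * (0.5 - S[k]) / (S[k + 1L] - S[k])
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("MR causal effect estimate (", x$method, ", ", x$weight_scheme,
      " weights)\n", sep = "")
  tab <- data.frame(estimate = x$theta, se = x$se_theta, p = x$p_values)
  print(signif(tab, 4))
  cat(x$n, "variants used\n")
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) object$theta

#' @export
vcov.mr_estimate <- function(object, ...) object$cov

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$theta - z * object$se_theta,
              object$theta + z * object$se_theta)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  rownames(ci) <- names(object$theta)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.mr_estimate <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- drop(object$data$beta_outcome -
              object$data$beta_exposure %*% object$theta)
  if (type == "pearson") {
    if (is.null(object$weights)) stop("no weights stored for this fit", call. = FALSE)
    r <- r / sqrt(object$weights$omega)
  }
  stats::setNames(r, object$data$variant_ids)
}

#' @export
summary.mr_estimate <- function(object, ...) {
  structure(list(estimate = object, het = tryCatch(
    cochran_q(object$data, object), error = function(e) NULL)),
    class = "summary.mr_estimate")
}

#' @export
print.summary.mr_estimate <- function(x, ...) {
  print(x$estimate)
  if (!is.null(x$het)) {
    cat(sprintf("Heterogeneity: Q = %.3f on %d df, p = %.3g\n",
                x$het$Q, x$het$df, x$het$p_value))
  }
  invisible(x)
}
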