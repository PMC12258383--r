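#' Configuration for the two-sample simulation study
#'
#' Assembles and validates the parameters of the individual-level generative
#' model used to benchmark the outlier detectors. The defaults are the
#' study's reduced-scale conditions: 100 SNPs, 100,000 individuals per
#' cohort, 100 replicates (the full-scale design uses 500,000 individuals
#' and 1,000 replicates; see the methods vignette). Genotypes are binomial
#' with uniform minor-allele frequencies, first-stage coefficients are
#' normal with mean 1 and variance 2, the genetic component and the
#' confounder each explain 15% of every risk factor's variance, and the
#' systematic part explains 50% of the outcome variance. Outliers arise
#' through a hidden pleiotropic risk factor loading on a fixed fraction of
#' the SNPs.
#'
#' @param n_individuals individuals per cohort (two cohorts are generated).
#' @param n_snps number of genetic variants used as instruments.
#' @param d number of observed risk factors (1 or 3 in the study design).
#' @param maf_range minor-allele-frequency range, uniform draw.
#' @param beta_x_mean,beta_x_var mean and variance of the first-stage
#'   coefficients.
#' @param r2_first_stage variance share explained by the genetic component
#'   (and, separately, by the confounder) in each risk factor.
#' @param r2_second_stage variance share of the outcome explained by the
#'   systematic part (risk factors + hidden pathway + confounder).
#' @param theta_true causal effect vector; defaults to 1 for `d = 1` and
#'   `c(0, 1, -0.5)` for `d = 3`.
#' @param pleiotropy_effect effect of the hidden pleiotropic variable on the
#'   outcome (1 in the study design).
#' @param outlier_fraction fraction `p` of SNPs loading on the hidden
#'   pathway; exactly `round(p * n_snps)` outliers per replicate.
#' @param outlier_mode `"directional"` (all loadings positive) or
#'   `"balanced"` (random signs).
#' @param outlier_strength multiplier on the loading magnitudes (the
#'   strong-outlier setting uses 4).
#' @param rho_range range of the uniform draw for the loading magnitudes.
#' @param error_correlation pairwise correlation of the first-stage errors
#'   ("medium" = 0.3).
#' @param n_replicates number of simulation replicates.
#' @param one_sample if `TRUE`, derive exposure and outcome summaries from
#'   the same cohort (default `FALSE`: two independent cohorts).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100000L, n_snps = 100L, d = 1L,
                       maf_range = c(0.01, 0.5),
                       beta_x_mean = 1, beta_x_var = 2,
                       r2_first_stage = 0.15, r2_second_stage = 0.5,
                       theta_true = NULL, pleiotropy_effect = 1,
                       outlier_fraction = 0,
                       outlier_mode = c("directional", "balanced"),
                       outlier_strength = 1, rho_range = c(2.1, 3.1),
                       error_correlation = 0.3,
                       n_replicates = 100L, one_sample = FALSE) {
  outlier_mode <- match.arg(outlier_mode)
  if (is.null(theta_true)) {
    theta_true <- if (d == 3L) c(0, 1, -0.5) else rep(1, d)
  }
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps), d = as.integer(d),
              maf_range = maf_range, beta_x_mean = beta_x_mean,
              beta_x_var = beta_x_var, r2_first_stage = r2_first_stage,
              r2_second_stage = r2_second_stage, theta_true = theta_true,
              pleiotropy_effect = pleiotropy_effect,
              outlier_fraction = outlier_fraction,
              outlier_mode = outlier_mode,
              outlier_strength = outlier_strength, rho_range = rho_range,
              error_correlation = error_correlation,
              n_replicates = as.integer(n_replicates),
              one_sample = isTRUE(one_sample))
  with(cfg, {
    stopifnot(n_individuals >= 10L, n_snps >= d + 1L, d >= 1L,
              length(theta_true) == d, n_replicates >= 1L,
              maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[1] <= maf_range[2],
              beta_x_var >= 0, outlier_strength > 0,
              rho_range[1] >= 0, rho_range[1] <= rho_range[2],
              abs(error_correlation) < 1)
    if (outlier_fraction < 0 || outlier_fraction > 1) {
      stop("'outlier_fraction' must be in [0, 1]", call. = FALSE)
    }
    if (r2_first_stage <= 0 || 2 * r2_first_stage >= 1) {
      stop("infeasible first-stage variance budget: genetic component and ",
           "confounder each explain 'r2_first_stage', jointly < 100%",
           call. = FALSE)
    }
    if (r2_second_stage <= 0 || r2_second_stage >= 1 ||
        r2_first_stage >= r2_second_stage) {
      stop("infeasible second-stage variance budget", call. = FALSE)
    }
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MR simulation configuration:\n")
  cat(sprintf("  %d SNPs x %d individuals/cohort, d = %d, theta = (%s)\n",
              x$n_snps, x$n_individuals, x$d,
              paste(x$theta_true, collapse = ", ")))
  cat(sprintf("  outliers: %.0f%% %s, strength x%g, rho ~ U(%g, %g)\n",
              100 * x$outlier_fraction, x$outlier_mode, x$outlier_strength,
              x$rho_range[1], x$rho_range[2]))
  cat(sprintf("  %d replicates\n", x$n_replicates))
  invisible(x)
}

# One cohort of individual-level data under the generative model. Returns the
# pieces needed for summary statistics.
make_cohort <- function(cfg, maf, beta_x, rho, outlier_idx) {
  N <- cfg$n_individuals
  n <- cfg$n_snps
  d <- cfg$d
  G <- gen_geno(N, maf)
  Xg <- G %*% beta_x                     # genetic component of each risk factor
  U <- stats::rnorm(N)                   # shared confounder
  var_g <- apply(Xg, 2L, stats::var)
  tot <- var_g / cfg$r2_first_stage      # total risk-factor variances
  c_u <- sqrt(cfg$r2_first_stage * tot)  # confounder explains the same share
  evar <- tot - var_g - c_u^2
  R <- matrix(cfg$error_correlation, d, d); diag(R) <- 1
  Sigma <- R * tcrossprod(sqrt(evar))
  E <- matrix(stats::rnorm(N * d), N, d) %*% chol(Sigma)
  X <- Xg + tcrossprod(U, c_u) + E
  # hidden pleiotropic pathway loading on the outlier SNPs
  Xh <- if (length(outlier_idx)) {
    drop(G[, outlier_idx, drop = FALSE] %*% rho)
  } else numeric(N)
  sys0 <- drop(X %*% cfg$theta_true) + cfg$pleiotropy_effect * Xh
  # confounder share of the outcome variance: solve kappa^2 = r2_1 * var(Y)
  # with var(Y) = var(sys0 + kappa U) / r2_2 and empirical cov(sys0, U)
  g <- stats::cov(sys0, U)
  a <- 1 - cfg$r2_first_stage / cfg$r2_second_stage
  bq <- -2 * g * cfg$r2_first_stage / cfg$r2_second_stage
  cq <- -cfg$r2_first_stage / cfg$r2_second_stage * stats::var(sys0)
  kappa <- (-bq + sqrt(bq^2 - 4 * a * cq)) / (2 * a)
  sys <- sys0 + kappa * U
  noise_var <- stats::var(sys) * (1 - cfg$r2_second_stage) / cfg$r2_second_stage
  Y <- sys + stats::rnorm(N, sd = sqrt(noise_var))
  list(G = G, X = X, Y = Y, var_sys = stats::var(sys),
       var_g = var_g, var_x = apply(X, 2L, stats::var))
}

# Per-SNP simple-regression summaries of each column of Z on each SNP,
# from column cross-products; returns coefficients, SEs and (optionally) the
# full covariance blocks between the per-SNP coefficient estimates.
snp_regressions <- function(G, Z, blocks = FALSE) {
  N <- nrow(G)
  d <- ncol(Z)
  s1 <- colSums(G)
  Sxx <- colSums(G^2) - s1^2 / N
  Zc <- sweep(Z, 2L, colMeans(Z))
  Sxy <- crossprod(G, Zc)                # n x d
  beta <- Sxy / Sxx
  Szz <- colSums(Zc^2)
  rss <- matrix(Szz, nrow(beta), d, byrow = TRUE) - beta * Sxy
  se <- sqrt(rss / ((N - 2) * Sxx))
  out <- list(beta = beta, se = se)
  if (blocks && d > 1L) {
    n <- ncol(G)
    Szz_full <- crossprod(Zc) # d x d
    arr <- array(0, dim = c(d, d, n))
    for (j in seq_len(d)) for (k in seq_len(d)) {
      arr[j, k, ] <- (Szz_full[j, k] - beta[, j] * beta[, k] * Sxx) /
        ((N - 2) * Sxx)
    }
    out$cov <- arr
    # keep the diagonal bit-identical to se^2
    for (j in seq_len(d)) out$cov[j, j, ] <- se[, j]^2
  }
  out
}

#' Simulate one two-sample summary-level dataset
#'
#' Generates individual-level data under the study's generative model --
#' binomial genotypes, normally distributed first-stage coefficients,
#' correlated first-stage errors, a shared confounder, and a hidden
#' pleiotropic variable loading on a subset of SNPs -- in two independent
#' cohorts, then derives per-SNP univariable regression summaries: exposure
#' associations (with standard errors and, for `d > 1`, covariance blocks)
#' from cohort 1 and outcome associations from cohort 2.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; the same seed reproduces the dataset
#'   bit-identically.
#' @return list with elements `data` (an [mr_summary_data]),
#'   `true_outliers` (variant ids loading on the hidden pathway), `rho`
#'   (their loadings), and `diagnostics` (realised variance shares).
#' @export
simulate_mr_data <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n <- cfg$n_snps
  maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  beta_x <- matrix(stats::rnorm(n * cfg$d, cfg$beta_x_mean,
                                sqrt(cfg$beta_x_var)), n, cfg$d)
  k <- round(cfg$outlier_fraction * n)
  outlier_idx <- if (k > 0) sort(sample.int(n, k)) else integer(0)
  rho <- numeric(0)
  if (k > 0) {
    rho <- stats::runif(k, cfg$rho_range[1], cfg$rho_range[2]) *
      cfg$outlier_strength
    if (cfg$outlier_mode == "balanced") {
      rho <- rho * sample(c(-1, 1), k, replace = TRUE)
    }
  }
  co1 <- make_cohort(cfg, maf, beta_x, rho, outlier_idx)
  co2 <- if (cfg$one_sample) co1 else make_cohort(cfg, maf, beta_x, rho, outlier_idx)
  ex <- snp_regressions(co1$G, co1$X, blocks = cfg$d > 1L)
  out <- snp_regressions(co2$G, matrix(co2$Y, ncol = 1L))
  ids <- paste0("snp_", seq_len(n))
  data <- mr_summary_data(beta_exposure = ex$beta, se_exposure = ex$se,
                          beta_outcome = out$beta[, 1L],
                          se_outcome = out$se[, 1L],
                          variant_ids = ids, exposure_cov = ex$cov)
  list(data = data,
       true_outliers = ids[outlier_idx],
       rho = rho,
       diagnostics = list(
         r2_first_stage = co1$var_g / co1$var_x,
         r2_second_stage = co2$var_sys /
           (co2$var_sys + stats::var(co2$Y) - co2$var_sys)))
}

#' Aggregate per-replicate detection records into performance metrics
#'
#' Computes, per method: mean sensitivity (flagged true outliers / true
#' outliers), mean specificity (unflagged valid instruments / valid
#' instruments), mean bias and mean squared error of the causal estimate
#' (averaged over risk factors for `d > 1`), the mean ratio of flagged to
#' true outlier counts (`p_bar`), and the mean flagged count (`a_bar`).
#' Replicates where a method failed are excluded from that method's
#' averages and counted in `n_failed`.
#'
#' @param records list of per-replicate records as produced by
#'   [run_experiment()]: each holds `true_outliers`, `all_variants`, and per
#'   method `flagged` (or `NULL` on failure) and `theta`.
#' @param theta_true true causal effect vector.
#' @return data.frame with one row per method, plus a `bias_by_exposure`
#'   attribute for multivariable runs.
#' @export
compute_metrics <- function(records, theta_true) {
  stopifnot(length(records) >= 1L)
  methods <- setdiff(names(records[[1L]]$methods), character(0))
  rows <- lapply(methods, function(m) {
    sens <- spec <- pbar <- abar <- numeric(0)
    bias_mat <- NULL
    failed <- 0L
    for (rec in records) {
      res <- rec$methods[[m]]
      if (is.null(res) || !is.null(res$error)) { failed <- failed + 1L; next }
      truth <- rec$true_outliers
      valid <- setdiff(rec$all_variants, truth)
      fl <- res$flagged
      if (!is.null(fl)) {
        if (length(truth)) {
          sens <- c(sens, length(intersect(fl, truth)) / length(truth))
          pbar <- c(pbar, length(fl) / length(truth))
        }
        spec <- c(spec, if (length(valid))
          length(setdiff(valid, fl)) / length(valid) else NA_real_)
        abar <- c(abar, length(fl))
      }
      bias_mat <- rbind(bias_mat, res$theta - theta_true)
    }
    used <- length(records) - failed
    bias_by_exp <- if (!is.null(bias_mat)) colMeans(bias_mat) else NA_real_
    mse_by_exp <- if (!is.null(bias_mat)) colMeans(bias_mat^2) else NA_real_
    data.frame(
      method = m,
      sensitivity = if (length(sens)) mean(sens) else NA_real_,
      specificity = if (length(spec)) mean(spec, na.rm = TRUE) else NA_real_,
      mean_bias = mean(bias_by_exp),
      mse = mean(mse_by_exp),
      p_bar = if (length(pbar)) mean(pbar) else NA_real_,
      a_bar = if (length(abar)) mean(abar) else NA_real_,
      mean_lambda = {
        l <- vapply(records, function(rec) {
          r <- rec$methods[[m]]
          if (is.null(r) || is.null(r$lambda)) NA_real_ else r$lambda
        }, numeric(1))
        if (all(is.na(l))) NA_real_ else mean(l, na.rm = TRUE)
      },
      n_replicates = used,
      n_failed = failed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$method
  out
}

run_one_method <- function(m, sim, alpha, n_sim, n_boot, seed) {
  tryCatch({
    switch(m,
      full = {
        fit <- mr_ivw(sim$data, weights = "first_order")
        list(flagged = NULL, theta = fit$theta)
      },
      gcq = {
        r <- mr_gcq(sim$data, alpha = alpha)
        list(flagged = r$flagged, theta = r$estimate_post$theta,
             lambda = r$lambda)
      },
      standard = {
        r <- mr_q_outliers(sim$data, "first_order", alpha = alpha)
        list(flagged = r$flagged, theta = r$estimate_post$theta)
      },
      sanderson = {
        r <- mr_q_outliers(sim$data, "second_order", alpha = alpha)
        list(flagged = r$flagged, theta = r$estimate_post$theta)
      },
      mrpresso = {
        r <- mr_presso_outliers(sim$data, n_sim = n_sim, alpha = alpha,
                                seed = seed)
        list(flagged = r$flagged, theta = r$estimate_post$theta)
      },
      radial = {
        r <- mr_radial(sim$data, alpha = alpha)
        list(flagged = r$flagged, theta = r$estimate_post$theta)
      },
      median = {
        est <- mr_weighted_median(sim$data, n_boot = n_boot, seed = seed)
        list(flagged = NULL, theta = est$theta)
      },
      stop("unknown method '", m, "'"))
  }, error = function(e) list(error = conditionMessage(e)))
}

#' Run a full simulation experiment
#'
#' Loops replicates over methods: each replicate generates a fresh
#' two-sample dataset (replicate seeds spawned deterministically from the
#' master seed, so adding a method never perturbs another's draws),
#' applies every requested detector/estimator, and records the flag sets
#' and post-removal estimates; [compute_metrics()] aggregates them.
#' Per-replicate failures of a method are logged and excluded from that
#' method's averages, never silently dropped.
#'
#' @param config a [sim_config()] object.
#' @param methods character vector from `full`, `standard`, `sanderson`,
#'   `mrpresso`, `radial`, `median`, `gcq` (radial is univariable-only).
#' @param seed master seed.
#' @param alpha family-wise level for the detectors.
#' @param n_sim MR-PRESSO simulation count per replicate.
#' @param n_boot weighted-median bootstrap count per replicate (the
#'   simulation metrics only use the point estimate, so this can be small).
#' @param verbose print progress every 10 replicates.
#' @return object of class `mr_simulation`: list with `metrics` (the
#'   aggregated data.frame), `records`, `config`, `seed`, `n_failed`.
#' @export
run_experiment <- function(config,
                           methods = c("full", "standard", "sanderson",
                                       "mrpresso", "radial", "median", "gcq"),
                           seed = 1L, alpha = 0.05, n_sim = 1000L,
                           n_boot = 100L, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"), length(methods) >= 1L)
  if (config$d > 1L && "radial" %in% methods) {
    stop("radial MR is univariable-only; drop it from 'methods' for d > 1",
         call. = FALSE)
  }
  set.seed(seed)
  z <- config$n_replicates
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * z)
  records <- vector("list", z)
  for (r in seq_len(z)) {
    sim <- simulate_mr_data(config, seed = rep_seeds[r])
    res <- lapply(stats::setNames(methods, methods), run_one_method,
                  sim = sim, alpha = alpha, n_sim = n_sim, n_boot = n_boot,
                  seed = rep_seeds[z + r])
    records[[r]] <- list(true_outliers = sim$true_outliers,
                         all_variants = sim$data$variant_ids,
                         methods = res)
    if (verbose && r %% 10L == 0L) {
      message("replicate ", r, "/", z)
    }
  }
  metrics <- compute_metrics(records, config$theta_true)
  structure(list(metrics = metrics, records = records, config = config,
                 methods = methods, seed = seed,
                 n_failed = sum(metrics$n_failed)),
            class = "mr_simulation")
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf("MR simulation experiment: %d replicates, %.0f%% %s outliers, d = %d\n",
              x$config$n_replicates, 100 * x$config$outlier_fraction,
              x$config$outlier_mode, x$config$d))
  cols <- c("method", "sensitivity", "specificity", "mean_bias", "mse",
            "p_bar", "a_bar")
  tab <- x$metrics[, cols]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 3)
  print(tab, row.names = FALSE)
  if (x$n_failed > 0) cat(x$n_failed, "method-replicate failures excluded\n")
  invisible(x)
}

#' Named scenario presets for the simulation study
#'
#' Shorthand configurations mirroring the benchmark settings: `table1`
#' (univariable directional, 5% outliers), `table2` (multivariable d = 3,
#' 10%), `table3` (univariable directional, 15%, strong loadings x4),
#' `table4` (univariable balanced, 20%), `table9` (univariable directional,
#' 50%, the breakdown regime). Fields can be overridden via `...`.
#'
#' @param scenario preset name.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()] object.
#' @export
scenario_config <- function(scenario = c("table1", "table2", "table3",
                                         "table4", "table9"), ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    table1 = list(d = 1L, outlier_fraction = 0.05, outlier_mode = "directional"),
    table2 = list(d = 3L, outlier_fraction = 0.10, outlier_mode = "directional"),
    table3 = list(d = 1L, outlier_fraction = 0.15, outlier_mode = "directional",
                  outlier_strength = 4),
    table4 = list(d = 1L, outlier_fraction = 0.20, outlier_mode = "balanced"),
    table9 = list(d = 1L, outlier_fraction = 0.50, outlier_mode = "directional"))
  do.call(sim_config, utils::modifyList(base, list(...)))
}
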