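test_that("q detectors flag planted outliers under both weighting schemes", {
  withr::local_seed(12)
  idx <- c(5, 50)
  dat <- summary_sim(n = 80, shift = c(3, -3), shift_idx = idx)
  std <- mr_q_outliers(dat, "first_order")
  san <- mr_q_outliers(dat, "second_order")
  expect_true(all(dat$variant_ids[idx] %in% std$flagged))
  expect_true(all(dat$variant_ids[idx] %in% san$flagged))
  expect_identical(std$method, "standard")
  expect_identical(san$method, "sanderson")
})

test_that("identical ratios: every detector returns an empty flag set", {
  bx <- c(1, 2, 3, 4, 5)
  dat <- mr_summary_data(bx, rep(0.01, 5), 1.5 * bx, rep(0.05, 5))
  expect_length(mr_q_outliers(dat, "first_order")$flagged, 0)
  expect_length(mr_q_outliers(dat, "second_order")$flagged, 0)
  expect_length(mr_gcq(dat, floor_lambda = TRUE)$flagged, 0)
  expect_length(mr_radial(dat)$flagged, 0)
  expect_length(mr_presso_outliers(dat, n_sim = 200, seed = 1)$flagged, 0)
})

test_that("Standard dominates Sanderson when second-order weights dominate", {
  # second-order omega_i >= first-order omega_i element-wise at the same
  # theta, so with a common threshold the Standard flag set contains the
  # Sanderson one whenever their fits agree closely
  withr::local_seed(9)
  for (r in 1:10) {
    dat <- summary_sim(n = 60, sx = 0.15, shift = runif(2, 1, 2),
                       shift_idx = sample(60, 2))
    std <- mr_q_outliers(dat, "first_order")
    san <- mr_q_outliers(dat, "second_order")
    expect_true(all(san$flagged %in% std$flagged))
  }
})

test_that("MR-PRESSO observed statistic reduces to Cochran's q at the full fit", {
  dat <- summary_sim(n = 20, seed = 44)
  omega <- dat$se_outcome^2
  loo <- gcq:::loo_wls(dat$beta_exposure, dat$beta_outcome, omega)
  fit <- mr_ivw(dat)
  het <- cochran_q(dat, fit)
  # inject the full-sample estimate in place of each leave-one-out estimate
  stat_full <- (dat$beta_outcome -
                  drop(dat$beta_exposure %*% coef(fit)))^2 / omega
  expect_equal(unname(stat_full), unname(het$q_local), tolerance = 1e-12)
  expect_equal(sum(stat_full), het$Q, tolerance = 1e-10)
  # and the leave-one-out residuals are the inflated e_i / (1 - h_i)
  e <- dat$beta_outcome - drop(dat$beta_exposure %*% loo$theta)
  expect_equal(loo$resid_loo, e / (1 - loo$leverage), tolerance = 1e-12)
})

test_that("leave-one-out estimates match refitting without each variant", {
  withr::local_seed(3)
  for (dd in 1:3) {
    n <- 12
    dat <- mr_summary_data(matrix(rnorm(n * dd, 1, 1), n, dd),
                           matrix(0.1, n, dd), rnorm(n, 1), runif(n, 0.1, 1))
    loo <- gcq:::loo_wls(dat$beta_exposure, dat$beta_outcome, dat$se_outcome^2)
    for (i in c(1, 5, n)) {
      direct <- wls_oracle(dat$beta_exposure[-i, , drop = FALSE],
                           dat$beta_outcome[-i], dat$se_outcome[-i]^2)
      expect_equal(unname(loo$theta_loo[i, ]), direct$theta, tolerance = 1e-9)
    }
  }
})

test_that("MR-PRESSO global: collinear data give RSS ~ 0 and p ~ 1", {
  bx <- c(1, 2, 3, 4, 5, 6)
  dat <- mr_summary_data(bx, rep(1e-4, 6), 2 * bx, rep(1e-4, 6))
  g <- mr_presso_global(dat, n_sim = 200, seed = 5)
  expect_lt(g$rss, 1e-10)
  expect_gt(g$p_value, 0.9)
})

test_that("MR-PRESSO flags planted outliers with floored reported p-values", {
  withr::local_seed(29)
  idx <- 7
  dat <- summary_sim(n = 50, shift = 4, shift_idx = idx)
  res <- mr_presso_outliers(dat, n_sim = 500, seed = 2)
  expect_true(dat$variant_ids[idx] %in% res$flagged)
  expect_equal(unname(res$p_per_variant[idx]), 1 / 500)  # floor, never 0
  expect_true(all(res$p_per_variant > 0))
  expect_lt(mr_presso_global(dat, n_sim = 500, seed = 2)$p_value, 0.05)
})

test_that("MR-PRESSO is deterministic given a seed and warns on tiny n_sim", {
  dat <- summary_sim(n = 30, seed = 61, shift = 3, shift_idx = 2)
  r1 <- mr_presso_outliers(dat, n_sim = 200, seed = 11)
  r2 <- mr_presso_outliers(dat, n_sim = 200, seed = 11)
  expect_identical(r1$p_per_variant, r2$p_per_variant)
  expect_identical(r1$flagged, r2$flagged)
  expect_warning(mr_presso_outliers(dat, n_sim = 50, seed = 1), "n_sim")
})

test_that("null data: MR-PRESSO flags ~ nothing at alpha = 0.05", {
  withr::local_seed(91)
  flags <- 0L
  for (r in 1:10) {
    dat <- summary_sim(n = 100, sx = 0.05)
    flags <- flags + length(mr_presso_outliers(dat, n_sim = 300, seed = r)$flagged)
  }
  expect_lte(flags, 2L)
})

test_that("radial slope equals IVW under matching weights; sigma_x = 0 ties flags", {
  # negligible exposure SEs make radial weights collapse to first order
  withr::local_seed(37)
  dat <- summary_sim(n = 40, sx = 1e-8, shift = c(2, -2), shift_idx = c(4, 30))
  rad <- mr_radial(dat, bonferroni = TRUE)
  std <- mr_q_outliers(dat, "first_order")
  expect_identical(rad$flagged, std$flagged)
  expect_equal(coef(rad$estimate_full), coef(std$estimate_full),
               tolerance = 1e-6, ignore_attr = TRUE)

  # with real exposure noise the converged radial slope equals the IVW
  # estimate computed at the same (modified second-order) weights
  dat2 <- summary_sim(n = 30, sx = 0.2, seed = 53)
  rad2 <- mr_radial(dat2)
  th <- coef(rad2$estimate_full)
  w <- 1 / (dat2$se_outcome^2 + th^2 * dat2$se_exposure[, 1]^2)
  ivw_at_w <- sum(w * dat2$beta_exposure[, 1] * dat2$beta_outcome) /
    sum(w * dat2$beta_exposure[, 1]^2)
  expect_equal(unname(th), ivw_at_w, tolerance = 1e-7)
})

test_that("radial flags planted outliers and rejects multivariable input", {
  dat <- summary_sim(n = 50, seed = 73, shift = 3, shift_idx = 10)
  expect_true(dat$variant_ids[10] %in% mr_radial(dat)$flagged)
  dat3 <- summary_sim(n = 20, d = 3, seed = 1)
  expect_error(mr_radial(dat3), "univariable")
})

test_that("flagged-count tendency across detectors: radial >= standard >= sanderson >= gcq", {
  # statistical ordering over replicates of a mildly contaminated design
  # with real exposure noise (the driver of first-order overdispersion)
  # exposure noise mild relative to outcome noise, as in a well-powered
  # exposure GWAS: the threshold convention (per-variant for radial,
  # Bonferroni for the rest) then dominates the weight differences
  withr::local_seed(101)
  counts <- matrix(0, 4, 1,
                   dimnames = list(c("radial", "standard", "sanderson", "gcq"), NULL))
  z <- 100
  for (r in seq_len(z)) {
    idx <- sample(60, 3)
    dat <- summary_sim(n = 60, sx = 0.04, sy = 0.1,
                       shift = runif(3, 1.5, 2.5), shift_idx = idx)
    counts["radial", ] <- counts["radial", ] + length(mr_radial(dat)$flagged)
    counts["standard", ] <- counts["standard", ] +
      length(mr_q_outliers(dat, "first_order")$flagged)
    counts["sanderson", ] <- counts["sanderson", ] +
      length(mr_q_outliers(dat, "second_order")$flagged)
    counts["gcq", ] <- counts["gcq", ] + length(mr_gcq(dat)$flagged)
  }
  expect_gte(counts["radial", 1], counts["standard", 1])
  expect_gte(counts["standard", 1], counts["sanderson", 1])
  expect_gte(counts["sanderson", 1], counts["gcq", 1])
})

test_that("mr_detect dispatches and assembles the all-methods comparison", {
  dat <- summary_sim(n = 40, seed = 111, shift = 3, shift_idx = 8)
  one <- mr_detect(dat, "gcq")
  expect_s3_class(one, "mr_gcq")
  allr <- mr_detect(dat, "all", n_sim = 200, n_boot = 50, seed = 4)
  comp <- attr(allr, "comparison")
  expect_setequal(comp$method,
                  c("gcq", "standard", "sanderson", "mrpresso", "radial", "median"))
  expect_length(allr$median$flagged, 0)
  expect_true(dat$variant_ids[8] %in% allr$standard$flagged)
})
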