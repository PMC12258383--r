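# Unit and property tests of the generative model at reduced cohort sizes;
# the study-scale runs live in the acceptance suite.

small_cfg <- function(...) {
  sim_config(n_individuals = 20000L, n_snps = 50L, n_replicates = 1L, ...)
}

test_that("configuration validates its variance budget and fractions", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(r2_first_stage = 0.6), "variance budget")
  expect_error(sim_config(r2_first_stage = 0.4, r2_second_stage = 0.3),
               "variance budget")
  expect_error(sim_config(outlier_fraction = 1.2), "outlier_fraction")
  expect_error(sim_config(n_snps = 2, d = 3), "n_snps")
  expect_equal(sim_config(d = 3)$theta_true, c(0, 1, -0.5))
  expect_equal(sim_config(d = 1)$theta_true, 1)
})

test_that("outlier bookkeeping: none at p = 0, exactly round(p n) otherwise", {
  s0 <- simulate_mr_data(small_cfg(outlier_fraction = 0), seed = 1)
  expect_length(s0$true_outliers, 0)
  s5 <- simulate_mr_data(small_cfg(outlier_fraction = 0.1), seed = 1)
  expect_length(s5$true_outliers, 5)
  expect_length(s5$rho, 5)
  expect_true(all(s5$rho > 0))
  sb <- simulate_mr_data(small_cfg(outlier_fraction = 0.2,
                                   outlier_mode = "balanced"), seed = 2)
  expect_length(sb$true_outliers, 10)
  expect_true(any(sb$rho < 0) && any(sb$rho > 0))
})

test_that("a fixed replicate seed reproduces the dataset bit-identically", {
  cfg <- small_cfg(outlier_fraction = 0.1)
  a <- simulate_mr_data(cfg, seed = 99)
  b <- simulate_mr_data(cfg, seed = 99)
  expect_identical(a$data$beta_exposure, b$data$beta_exposure)
  expect_identical(a$data$beta_outcome, b$data$beta_outcome)
  expect_identical(a$true_outliers, b$true_outliers)
  c <- simulate_mr_data(cfg, seed = 100)
  expect_false(identical(a$data$beta_outcome, c$data$beta_outcome))
})

test_that("realised variance shares match the design", {
  # one larger cohort: genetic share within 1 point of 15% per risk factor,
  # systematic outcome share within 2 points of 50%
  cfg <- sim_config(n_individuals = 50000L, n_snps = 100L, d = 3L,
                    n_replicates = 1L, outlier_fraction = 0.1)
  s <- simulate_mr_data(cfg, seed = 7)
  expect_true(all(abs(s$diagnostics$r2_first_stage - 0.15) < 0.01))
  expect_lt(abs(s$diagnostics$r2_second_stage - 0.50), 0.02)
})

test_that("multivariable summaries carry covariance blocks; univariable do not", {
  s3 <- simulate_mr_data(small_cfg(d = 3), seed = 3)
  expect_false(is.null(s3$data$exposure_cov))
  expect_equal(dim(s3$data$exposure_cov), c(3, 3, 50))
  # blocks feed the Sanderson weights without degeneracy
  w <- second_order_weights(s3$data, c(0, 1, -0.5))
  expect_true(all(w$omega > 0))
  s1 <- simulate_mr_data(small_cfg(), seed = 3)
  expect_null(s1$data$exposure_cov)
})

test_that("compute_metrics matches hand arithmetic on a built record set", {
  recs <- list(
    list(true_outliers = c("a", "b"), all_variants = letters[1:10],
         methods = list(det = list(flagged = c("a", "c"), theta = 1.2))),
    list(true_outliers = c("a", "b"), all_variants = letters[1:10],
         methods = list(det = list(flagged = c("a", "b"), theta = 0.8))),
    list(true_outliers = c("a", "b"), all_variants = letters[1:10],
         methods = list(det = list(error = "boom"))))
  m <- compute_metrics(recs, theta_true = 1)
  expect_equal(m["det", "sensitivity"], mean(c(1 / 2, 1)))
  expect_equal(m["det", "specificity"], mean(c(7 / 8, 1)))
  expect_equal(m["det", "mean_bias"], mean(c(0.2, -0.2)))
  expect_equal(m["det", "mse"], mean(c(0.04, 0.04)))
  expect_equal(m["det", "p_bar"], mean(c(1, 1)))
  expect_equal(m["det", "a_bar"], 2)
  expect_equal(m["det", "n_failed"], 1L)
})

test_that("degenerate detectors produce the boundary metric values", {
  rec <- list(list(true_outliers = c("a", "b"), all_variants = letters[1:5],
                   methods = list(
                     perfect = list(flagged = c("a", "b"), theta = 1),
                     everything = list(flagged = letters[1:5], theta = 1))))
  m <- compute_metrics(rec, theta_true = 1)
  expect_equal(m["perfect", c("sensitivity", "specificity", "p_bar")],
               data.frame(sensitivity = 1, specificity = 1, p_bar = 1,
                          row.names = "perfect"))
  expect_equal(m["everything", "sensitivity"], 1)
  expect_equal(m["everything", "specificity"], 0)
  expect_equal(m["everything", "a_bar"], 5)
})

test_that("run_experiment smoke contract: one row per method, failures logged", {
  cfg <- small_cfg(outlier_fraction = 0.1)
  cfg$n_replicates <- 2L
  e <- run_experiment(cfg, methods = c("full", "standard", "gcq"), seed = 5)
  expect_s3_class(e, "mr_simulation")
  expect_setequal(e$metrics$method, c("full", "standard", "gcq"))
  expect_true(all(e$metrics$n_replicates + e$metrics$n_failed == 2))
  expect_error(run_experiment(scenario_config("table2", n_replicates = 1L),
                              methods = c("full", "radial"), seed = 1),
               "univariable")
})

test_that("directional pleiotropy biases the full model; balanced does not", {
  # ordering assertion over replicates at reduced scale
  cfg_dir <- sim_config(n_individuals = 20000L, n_snps = 50L,
                        outlier_fraction = 0.2, outlier_mode = "directional",
                        n_replicates = 40L)
  cfg_bal <- sim_config(n_individuals = 20000L, n_snps = 50L,
                        outlier_fraction = 0.2, outlier_mode = "balanced",
                        n_replicates = 40L)
  e_dir <- run_experiment(cfg_dir, methods = "full", seed = 8)
  e_bal <- run_experiment(cfg_bal, methods = "full", seed = 8)
  expect_gt(e_dir$metrics["full", "mean_bias"], 0.05)
  expect_lt(abs(e_bal$metrics["full", "mean_bias"]),
            abs(e_dir$metrics["full", "mean_bias"]) / 3)
})

test_that("mean lambda grows with the outlier fraction", {
  lam <- vapply(c(0, 0.2, 0.5), function(p) {
    cfg <- sim_config(n_individuals = 40000L, n_snps = 100L,
                      outlier_fraction = p, n_replicates = 8L)
    run_experiment(cfg, methods = "gcq", seed = 13)$metrics["gcq", "mean_lambda"]
  }, numeric(1))
  expect_true(all(diff(lam) > 0))
  # in the breakdown regime the inflation estimate sits an order of
  # magnitude above its null level
  expect_gt(lam[3], 10)
})

test_that("scenario presets map to the documented designs", {
  t3 <- scenario_config("table3", n_replicates = 5L)
  expect_equal(t3$outlier_fraction, 0.15)
  expect_equal(t3$outlier_strength, 4)
  t2 <- scenario_config("table2")
  expect_equal(t2$d, 3L)
  t4 <- scenario_config("table4")
  expect_identical(t4$outlier_mode, "balanced")
})
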