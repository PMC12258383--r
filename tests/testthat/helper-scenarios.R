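# Study-condition runs shared by the acceptance tests: each scenario is run
# once per session and memoised. Reduced-scale conditions (100,000
# individuals/cohort; 100 replicates, 50 for the multivariable MR-PRESSO
# condition) as configured in scenario_config()/sim_config().

.scenario_cache <- new.env(parent = emptyenv())

scenario_run <- function(name) {
  if (!is.null(.scenario_cache[[name]])) return(.scenario_cache[[name]])
  res <- switch(name,
    dir05 = run_experiment(scenario_config("table1", n_replicates = 100L),
                           methods = c("full", "gcq"), seed = 9101),
    strong15 = run_experiment(scenario_config("table3", n_replicates = 100L),
                              methods = c("full", "standard", "sanderson", "gcq"),
                              seed = 9102),
    bal20 = run_experiment(scenario_config("table4", n_replicates = 100L),
                           methods = c("full", "gcq"), seed = 9103),
    dir20 = run_experiment(sim_config(outlier_fraction = 0.20,
                                      n_replicates = 100L),
                           methods = "full", seed = 9104),
    mvmr10 = run_experiment(scenario_config("table2", n_replicates = 50L),
                            methods = c("standard", "sanderson", "mrpresso", "gcq"),
                            seed = 9105, n_sim = 300L),
    dir50 = run_experiment(scenario_config("table9", n_replicates = 100L),
                           methods = c("full", "gcq"), seed = 9106),
    dir80 = run_experiment(sim_config(outlier_fraction = 0.80,
                                      n_replicates = 100L),
                           methods = c("full", "median", "gcq"), seed = 9107,
                           n_boot = 50L),
    null0 = run_experiment(sim_config(outlier_fraction = 0,
                                      n_replicates = 30L),
                           methods = "gcq", seed = 9108),
    stop("unknown scenario ", name))
  .scenario_cache[[name]] <- res
  res
}

metric <- function(exp, method, what) unname(exp$metrics[method, what])
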