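## Shared fixtures: lazily computed, cached across test files.
## Simulation settings are slightly coarser than production defaults to
## keep the suite fast; daily totals change by < 0.1% under refinement
## (checked in the engine tests).
.cache <- new.env(parent = emptyenv())

fast_sim <- function(model, scenario, out_dt = 0.25) {
  simulate(model, scenario = scenario, out_dt = out_dt,
           rtol = 1e-6, atol = 1e-9)
}

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

## Placebo-calibrated fit used by the scenario-replication tests.
calibrated_fit <- function() {
  cached("fit", calibrate_placebo(maxit = 80))
}

calibrated_model <- function() calibrated_fit()$model

rosenbaum_sim <- function(arm) {
  cached(paste0("ros_", arm),
         fast_sim(calibrated_model(), rosenbaum_scenarios()[[arm]]))
}

mean_treatment_stool <- function(sim) {
  d <- daily_totals(sim)
  mean(d$stool_mmol[3:9])   # collections lag dosing by one day
}

mean_treatment_urine <- function(sim) {
  d <- daily_totals(sim)
  mean(d$urine_mmol[2:8])   # urine responds within the dosing day
}

two_day_15bid <- function() {
  cached("sim_15bid_2d", {
    sc <- study_scenario("15 mg b.i.d", 2, 15)
    fast_sim(pbbm_model(), sc)
  })
}
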