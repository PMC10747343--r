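test_that("meal type selects the gastric residence time only", {
  cfg <- default_physiology()
  hi <- build_gi_model(cfg, "high_fat")
  lo <- build_gi_model(cfg, "low_fat")
  fa <- build_gi_model(cfg, "fasted")
  expect_equal(hi$compartments$mtt_h[1], 2.45)
  expect_equal(lo$compartments$mtt_h[1], 1.35)
  expect_equal(fa$compartments$mtt_h[1], 0.25)
  expect_equal(unname(transit_rates(fa)[1]), 4)
  ## non-stomach segments unchanged by meal type
  expect_equal(hi$compartments$mtt_h[-1], fa$compartments$mtt_h[-1])
  expect_equal(hi$compartments$nhe3_abundance,
               c(0, 0, 1, 1, 1.5, 1.5, 1.5, 1.5, 0.4))
})

test_that("transit rates are reciprocals of transit times", {
  cfg <- default_physiology()
  m <- build_gi_model(cfg, "low_fat")
  r <- transit_rates(m)
  expect_length(r, 9)
  expect_true(all(r > 0))
  expect_equal(unname(r), 1 / m$compartments$mtt_h)
  expect_equal(unname(r[1]), 1 / 1.35, tolerance = 1e-12)
  cfg$mtt_h[9] <- 13.5
  expect_equal(unname(transit_rates(build_gi_model(cfg))[9]),
               0.0741, tolerance = 1e-3)
  cfg$mtt_h[] <- 1
  expect_equal(unname(transit_rates(build_gi_model(cfg))[-1]), rep(1, 8))
})

test_that("invalid physiology configurations are rejected", {
  expect_error(build_gi_model(default_physiology(), "brunch"),
               "unknown meal_type|arg")
  bad <- default_physiology()
  bad$mtt_h[3] <- -1
  expect_error(build_gi_model(bad), "positive")
  bad <- default_physiology()
  bad$ph[2] <- 0.5
  expect_error(build_gi_model(bad), "pH")
})

test_that("physiology YAML round trips with overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(colon = list(mtt_h = 20, volume_ml = 8),
                        grt = list(moderate_fat = 2.0)), path)
  cfg <- read_physiology(path)
  expect_equal(cfg$mtt_h[9], 20)
  expect_equal(cfg$volume_ml[9], 8)
  expect_equal(attr(cfg, "grt")[["moderate_fat"]], 2.0)
  expect_equal(cfg$mtt_h[2], default_physiology()$mtt_h[2])
})

## A non-absorbed, non-dissolving tracer: sodium with the transporter
## switched off in a fasted gut.
tracer_sim <- function(duration_days = 5, colon_mtt = 13.5) {
  phys <- default_physiology(colon_transit_h = colon_mtt)
  m <- pbbm_model(physiology = phys,
                  nhe3 = nhe3_params(vmax_scalar = 1e-12,
                                     induction = FALSE))
  sc <- study_scenario("tracer", duration_days, meal_type = "fasted",
                       sodium_mmol = 100,
                       meal_times = c(breakfast = 1))
  sc$meal_events <- sc$meal_events[1, , drop = FALSE]  # single bolus
  fast_sim(m, sc, out_dt = 0.1)
}

test_that("a tracer bolus is conserved and recovered in faeces", {
  sim <- cached("tracer", tracer_sim())
  mb <- mass_balance(sim)
  expect_lt(max(abs(mb$na_rel_err[mb$na_intake > 0])), 1e-3)
  ## essentially everything has exited by the end of day 5
  expect_gt(utils::tail(sim$trajectory[, "stool_na"], 1), 99.5)
})

test_that("tracer mean residence time matches the sum of transit times", {
  sim <- cached("tracer", tracer_sim())
  tr <- sim$trajectory
  tt <- tr[, "time_h"]
  keep <- tt >= 1   # bolus enters at t = 1 h
  surv <- 1 - tr[keep, "stool_na"] / 100
  mrt <- sum(diff(tt[keep]) * (surv[-1] + surv[-length(surv)]) / 2)
  expected <- sum(build_gi_model(default_physiology(),
                                 "fasted")$compartments$mtt_h)
  expect_equal(mrt, expected, tolerance = 0.02)
})

test_that("longer gastric residence delays faecal exit", {
  median_exit <- function(grt) {
    phys <- default_physiology()
    grt_map <- attr(phys, "grt"); grt_map[["fasted"]] <- grt
    attr(phys, "grt") <- grt_map
    sim <- tracer_sim2(phys)
    tr <- sim$trajectory
    tr[min(which(tr[, "stool_na"] >= 50)), "time_h"]
  }
  tracer_sim2 <- function(phys) {
    m <- pbbm_model(physiology = phys,
                    nhe3 = nhe3_params(vmax_scalar = 1e-12,
                                       induction = FALSE))
    sc <- study_scenario("tracer", 5, meal_type = "fasted",
                         sodium_mmol = 100, meal_times = c(b = 1))
    sc$meal_events <- sc$meal_events[1, , drop = FALSE]
    fast_sim(m, sc, out_dt = 0.1)
  }
  t_fast <- median_exit(0.25)
  t_slow <- median_exit(3.0)
  expect_gt(t_slow, t_fast)
})
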