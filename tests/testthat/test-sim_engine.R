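test_that("sodium and tenapanor are conserved under dosing", {
  sim <- two_day_15bid()
  mb <- mass_balance(sim)
  expect_lt(max(abs(mb$na_rel_err[mb$na_intake > 0])), 1e-3)
  expect_lt(max(abs(mb$ten_rel_err[mb$ten_dosed > 0])), 1e-3)
  ## all cumulative outputs non-decreasing, all amounts non-negative
  tr <- sim$trajectory
  for (col in c("urine_na", "stool_na", "faecal_ten", "absorbed_ten"))
    expect_true(all(diff(tr[, col]) > -1e-9))
  expect_gt(min(tr[, -1]), -1e-6)
})

test_that("a placebo day conserves the three meals exactly", {
  sim <- cached("placebo_2d",
                fast_sim(pbbm_model(), placebo_scenario(2)))
  mb <- mass_balance(sim)
  i <- which.min(abs(mb$time_h - 24))
  expect_equal(mb$na_total[i], 3 * 51.7, tolerance = 1e-3)
})

test_that("an infinite-Ki override reproduces the placebo exactly", {
  m <- pbbm_model(nhe3 = nhe3_params(Ki_uM = 1e15))
  sc <- study_scenario("30 mg b.i.d", 2, 30)
  treated <- fast_sim(m, sc)
  placebo <- fast_sim(pbbm_model(), placebo_scenario(2))
  dt <- daily_totals(treated); dp <- daily_totals(placebo)
  expect_equal(dt$stool_mmol, dp$stool_mmol, tolerance = 5e-3)
  expect_equal(dt$urine_mmol, dp$urine_mmol, tolerance = 5e-3)
})

test_that("daily totals are differences of the cumulative outputs", {
  sim <- two_day_15bid()
  d <- daily_totals(sim)
  tr <- sim$trajectory
  cum_at <- function(col, t) {
    stats::approx(tr[, "time_h"], tr[, col], xout = t)$y
  }
  expect_equal(d$stool_mmol[2], cum_at("stool_na", 48) -
                 cum_at("stool_na", 24), tolerance = 1e-9)
  expect_equal(d$urine_mmol[1], cum_at("urine_na", 24), tolerance = 1e-9)
})

test_that("placebo steady state closes the daily mass balance", {
  sim <- cached("placebo_6d",
                fast_sim(pbbm_model(), placebo_scenario(6), out_dt = 0.5))
  d <- daily_totals(sim)
  ## urine + stool ~ intake at steady state
  expect_equal(d$urine_mmol[6] + d$stool_mmol[6], 3 * 51.7,
               tolerance = 0.02)
  ## day-to-day totals converge (< 1% by day 5)
  expect_lt(abs(d$urine_mmol[6] - d$urine_mmol[5]) / d$urine_mmol[6],
            0.01)
  expect_lt(abs(d$stool_mmol[6] - d$stool_mmol[5]) / d$stool_mmol[6],
            0.01)
})

test_that("change versus placebo is zero for placebo and conservative", {
  placebo <- cached("placebo_2d",
                    fast_sim(pbbm_model(), placebo_scenario(2)))
  ch0 <- cumulative_change_vs_placebo(placebo, placebo, 2)
  expect_equal(unname(ch0), c(0, 0))
  treated <- two_day_15bid()
  ch <- cumulative_change_vs_placebo(treated, placebo, 2)
  ## extra stool output is drawn from urine plus the body pool shift
  body_shift <- utils::tail(treated$trajectory[, "systemic_na"], 1) -
    utils::tail(placebo$trajectory[, "systemic_na"], 1)
  lum_shift <- sum(utils::tail(treated$trajectory[, 2:10], 1)) -
    sum(utils::tail(placebo$trajectory[, 2:10], 1))
  expect_equal(ch[["delta_stool"]],
               -(ch[["delta_urine"]] + body_shift + lum_shift),
               tolerance = 1e-3)
})

test_that("stool change grows with dose and saturates", {
  placebo <- cached("placebo_2d",
                    fast_sim(pbbm_model(), placebo_scenario(2)))
  ds <- vapply(c(15, 30, 60), function(dose) {
    sim <- fast_sim(pbbm_model(),
                    study_scenario(paste(dose, "bid"), 2, dose))
    cumulative_change_vs_placebo(sim, placebo, 2)[["delta_stool"]]
  }, 0)
  expect_true(all(diff(ds) > 0))
  ## saturating: the lowest dose already yields the bulk of the effect,
  ## and two successive dose doublings add only a small increment
  expect_lt(ds[3] - ds[1], 0.25 * ds[1])
})

test_that("halving solver tolerances moves daily totals < 0.1%", {
  sc <- study_scenario("30 mg b.i.d", 2, 30)
  a <- simulate(pbbm_model(), scenario = sc, out_dt = 0.25,
                rtol = 1e-6, atol = 1e-9)
  b <- simulate(pbbm_model(), scenario = sc, out_dt = 0.25,
                rtol = 5e-7, atol = 5e-10)
  da <- daily_totals(a); db <- daily_totals(b)
  expect_lt(max(abs(da$stool_mmol / db$stool_mmol - 1)), 1e-3)
  expect_lt(max(abs(da$urine_mmol / db$urine_mmol - 1)), 1e-3)
})

test_that("events outside the horizon and schedule mismatches error", {
  sc <- placebo_scenario(2)
  sc$meal_events$time_h[1] <- 100
  expect_error(simulate(pbbm_model(), scenario = sc), "horizon")
  a <- cached("placebo_2d", fast_sim(pbbm_model(), placebo_scenario(2)))
  b <- fast_sim(pbbm_model(), placebo_scenario(2, sodium_mmol = 40))
  expect_error(cumulative_change_vs_placebo(a, b, 2), "differ")
  expect_error(cumulative_change_vs_placebo(a, a, 5), "cover")
})

test_that("zero-order gastric emptying conserves mass and empties", {
  m <- pbbm_model(gastric_emptying = "zero_order")
  sim <- fast_sim(m, placebo_scenario(1))
  mb <- mass_balance(sim)
  expect_lt(max(abs(mb$na_rel_err[mb$na_intake > 0])), 2e-3)
  expect_gt(utils::tail(sim$trajectory[, "urine_na"], 1), 10)
})

test_that("the Monte-Carlo wrapper is seeded and reproducible", {
  sc <- placebo_scenario(1)
  s1 <- simulate(pbbm_model(), nsim = 2, seed = 42, scenario = sc,
                 out_dt = 1, rtol = 1e-5, atol = 1e-8)
  s2 <- simulate(pbbm_model(), nsim = 2, seed = 42, scenario = sc,
                 out_dt = 1, rtol = 1e-5, atol = 1e-8)
  expect_length(s1, 2)
  expect_equal(s1[[2]]$trajectory, s2[[2]]$trajectory)
  expect_false(isTRUE(all.equal(s1[[1]]$trajectory,
                                s1[[2]]$trajectory)))
})

test_that("simulation results export to tidy and daily CSV", {
  sim <- cached("placebo_2d", fast_sim(pbbm_model(), placebo_scenario(2)))
  tcsv <- tempfile(fileext = ".csv"); dcsv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tcsv, dcsv)))
  write_sim_results(sim, tcsv, dcsv)
  daily <- utils::read.csv(dcsv)
  expect_named(daily, c("day", "urine_mmol_day", "stool_mmol_day"))
  expect_equal(nrow(daily), 2)
  long <- utils::read.csv(tcsv)
  expect_named(long, c("time_h", "variable", "value"))
})
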