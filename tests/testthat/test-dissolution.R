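test_that("equilibrium solubility follows the monoprotic-base model", {
  p <- tenapanor_params()
  ## far above pKa the base is intrinsic
  expect_equal(equilibrium_solubility(10, p), 1.73e-4, tolerance = 1e-3)
  ## at pH = pKa half-ionisation doubles solubility
  expect_equal(equilibrium_solubility(6.6, p), 2 * 1.73e-4,
               tolerance = 1e-6)
  ## deep acid: the solubility-factor cap binds for the base
  expect_equal(equilibrium_solubility(1, p, "free_base"),
               1.73e-4 * 17328, tolerance = 1e-6)
  ## salt: Ksp ceiling, independently sqrt(Ksp) mM * MW
  oracle <- sqrt(43.429) * 1e-3 * 1217.97   # mg/mL
  expect_equal(equilibrium_solubility(1, p, "hcl_salt"), oracle,
               tolerance = 1e-9)
  ## continuity in pH for both forms
  for (form in c("free_base", "hcl_salt")) {
    ph <- seq(1, 9, by = 0.005)
    s <- equilibrium_solubility(ph, p, form)
    expect_lt(max(abs(diff(log(s)))), 0.05)
    expect_true(all(diff(s) <= 1e-12))  # non-increasing with pH
  }
  bad <- p; bad$S0_mg_ml <- 0
  expect_error(equilibrium_solubility(7, bad), "positive")
})

test_that("higher intrinsic solubility never dissolves less", {
  p1 <- tenapanor_params(); p2 <- tenapanor_params()
  p2$S0_mg_ml <- 10 * p1$S0_mg_ml
  ph <- seq(1, 9, by = 0.25)
  expect_true(all(equilibrium_solubility(ph, p2) >=
                    equilibrium_solubility(ph, p1)))
})

test_that("diffusion-layer rate matches the closed form and edge cases", {
  bin <- list(radius_um = 10, amount_mg = 1, density_g_ml = 1.2,
              diffusion_cm2_s = 5e-6, h_um = 10)
  ## 3*D*M/(rho*h*r) * dC, hand-evaluated: 0.045 mg/h
  expect_equal(dlm_rate(bin, S_eff = 2e-3, C_bulk = 1e-3, volume = 50),
               0.045, tolerance = 1e-10)
  ## no driving force, no solid, negative force
  expect_equal(dlm_rate(bin, 1e-3, 1e-3, 50), 0)
  expect_equal(dlm_rate(modifyList(bin, list(amount_mg = 0)),
                        2e-3, 0, 50), 0)
  expect_equal(dlm_rate(bin, 1e-3, 5e-3, 50), 0)
  ## multi-bin additivity
  two <- list(radius_um = c(10, 10), amount_mg = c(0.5, 0.5),
              density_g_ml = 1.2, diffusion_cm2_s = 5e-6, h_um = 10)
  expect_equal(dlm_rate(two, 2e-3, 1e-3), dlm_rate(bin, 2e-3, 1e-3))
  ## diffusion layer capped at the radius
  small <- modifyList(bin, list(radius_um = 5, h_um = 30))
  expect_equal(dlm_rate(small, 2e-3, 1e-3),
               dlm_rate(modifyList(bin, list(radius_um = 5, h_um = 5)),
                        2e-3, 1e-3))
  expect_error(dlm_rate(modifyList(bin, list(radius_um = 0)), 1, 0),
               "zero radius")
})

test_that("precipitation needs nucleation, then decays the excess", {
  expect_equal(precipitation_rate(1, 1, CSR = 10, PRC = 4), 0)
  expect_equal(precipitation_rate(9.9, 1, 10, 4, nucleated = FALSE), 0)
  expect_equal(precipitation_rate(2, 1, 10, 4, nucleated = TRUE), 4)
  expect_equal(precipitation_rate(11, 1, 10, 4), 40)
  expect_equal(precipitation_rate(0.5, 1, 10, 4, nucleated = TRUE), 0)
  expect_error(precipitation_rate(1, 1, CSR = 0.5, PRC = 4))
})

test_that("profile release interpolates, plateaus and validates", {
  pr <- data.frame(time_h = c(0, 1, 2), fraction_dissolved = c(0, .5, 1))
  expect_equal(release_from_profile(pr, 0, 30), 0)
  expect_equal(release_from_profile(pr, 1.5, 30), 22.5)
  expect_equal(release_from_profile(pr, 10, 30), 30)
  bad <- data.frame(time_h = c(0, 1, 2),
                    fraction_dissolved = c(0, .8, .5))
  expect_error(release_from_profile(bad, 1, 30), "monotone")
  expect_error(release_from_profile(
    data.frame(time_h = 0:2, fraction_dissolved = c(0, .5, 1.2)),
    1, 30), "\\[0, 1\\]")
})

test_that("shipped synthetic profiles load and are fast/slow", {
  fast <- read_dissolution_profile(
    system.file("extdata", "dissolution_fast_synthetic.csv",
                package = "tenapbbm"))
  slow <- read_dissolution_profile(
    system.file("extdata", "dissolution_slow_synthetic.csv",
                package = "tenapbbm"))
  expect_gte(release_from_profile(fast, 0.5, 1), 0.85)
  expect_lte(release_from_profile(slow, 2, 1), 0.65)
})
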