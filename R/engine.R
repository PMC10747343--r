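## State vector layout (9 gut segments, stomach .. colon):
##   1:9   luminal sodium, mmol
##  10:18  undissolved dosed solid, mg
##  19:27  dissolved tenapanor, mg
##  28:36  precipitated free base, mg
##  37:45  NHE3 activity fold
##  46     systemic sodium, mmol        47 systemic tenapanor, mg
##  48     cumulative urine sodium      49 cumulative stool sodium, mmol
##  50     cumulative faecal tenapanor, mg
##  51     cumulative absorbed tenapanor, mg
I_NA <- 1:9; I_SOL <- 10:18; I_DIS <- 19:27; I_PRE <- 28:36
I_ACT <- 37:45; I_SYSNA <- 46; I_SYSTEN <- 47; I_URINE <- 48
I_STOOL <- 49; I_FECTEN <- 50; I_ABSTEN <- 51
N_STATE <- 51

## Precompute everything the right-hand side needs into a flat list.
build_engine_pars <- function(model, scenario) {
  gi <- build_gi_model(model$physiology, meal_type = scenario$meal_type)
  cmp <- gi$compartments
  drug <- model$drug
  drug$form <- scenario$form
  nhe3 <- model$nhe3
  if (!scenario$induction) nhe3$Emax <- 0
  nhe3$mechanism <- scenario$inhibition
  sys <- model$systemic

  S_base <- equilibrium_solubility(cmp$ph, drug, "free_base")
  S_surf <- if (drug$form == "hcl_salt") {
    ## A dissolving salt particle self-buffers its boundary layer; its
    ## surface solubility is held at the salt-limited value rather than
    ## the bulk-pH base solubility (classic salt-dissolution treatment).
    rep(sqrt(drug$Ksp_mM2) * drug$molecular_weight / 1000, 9)
  } else {
    equilibrium_solubility(cmp$ph, drug, "free_base")
  }
  kd <- function(r_um) {
    h <- min(drug$h_eff_um, r_um)
    3 * drug$diffusion_cm2_s * 3600 /
      (drug$density_g_ml * 1000 * (h * 1e-4) * (r_um * 1e-4))
  }
  ## passive tenapanor absorption, 1/h: 2 * Papp / radius
  radius_cm <- c(0, rep(1.25, 7), 2.5)
  ka <- ifelse(radius_cm > 0, 2 * drug$Papp_cm_s * 3600 / radius_cm, 0)
  kdeg <- nhe3$kdeg_h
  if (is.infinite(kdeg)) kdeg <- 1e3  # effectively instantaneous

  hz <- NULL
  dose_times <- scenario$dose_events$time_h
  if (scenario$mode == "profile" && length(dose_times))
    hz <- profile_hazard(scenario$profile)

  list(
    kt = gi$transit_rate, vol = cmp$volume_ml, abund = cmp$nhe3_abundance,
    S_base = S_base, S_surf = S_surf, ceil = drug$CSR * S_base,
    PRC = drug$PRC_h, k_clamp = 200,
    Kdiss_sol = kd(drug$particle_radius_um),
    Kdiss_pre = kd(drug$precipitate_radius_um),
    mode = scenario$mode, hazard = hz, dose_times = sort(dose_times),
    MW = drug$molecular_weight, ka = ka,
    vmax = nhe3$vmax_scalar * nhe3$Jmax_pmol_min * 60e-9 * cmp$nhe3_abundance,
    Km = nhe3$Km_uM, Ki = nhe3$Ki_uM, mech = nhe3$mechanism,
    Emax = nhe3$Emax, EC50g = nhe3$EC50_uM^nhe3$gamma, gma = nhe3$gamma,
    kdeg = kdeg,
    kNa = sys$renal_CL_L_h / (sys$Vss_na_L_kg * sys$body_weight_kg),
    kTen = drug$hepatic_CL_L_h / (drug$Vss_L_kg * sys$body_weight_kg),
    zero_order = identical(model$gastric_emptying, "zero_order"),
    e0 = numeric(4),   # zero-order stomach emptying rates, set per segment
    gi = gi
  )
}

pbbm_rhs <- function(t, y, P) {
  na  <- pmax(y[I_NA], 0)
  sol <- pmax(y[I_SOL], 0)
  dis <- pmax(y[I_DIS], 0)
  pre <- pmax(y[I_PRE], 0)
  act <- pmax(y[I_ACT], 0)

  C_dis <- dis / P$vol                       # mg/mL
  C_na  <- na / P$vol * 1e6                  # uM
  I_uM  <- C_dis * 1e6 / P$MW

  ## dissolution of the dosed solid
  if (P$mode == "dlm") {
    diss <- P$Kdiss_sol * sol * pmax(P$S_surf - C_dis, 0)
  } else {
    ## tabulated in vitro release applies while the solid resides in the
    ## stomach or small intestine and is suspended as the local fluid
    ## saturates (in vitro curves are measured under sink-like upper-GI
    ## conditions); remainder reaching the colon is treated as
    ## unavailable
    i <- findInterval(t, P$dose_times)
    k <- if (i >= 1) P$hazard(t - P$dose_times[i]) else 0
    diss <- k * sol * pmax(1 - C_dis / P$S_base, 0)
    diss[9] <- 0
  }
  ## precipitate redissolution (fine free-base particles)
  rediss <- P$Kdiss_pre * pre * pmax(P$S_base - C_dis, 0)
  ## precipitation: nucleation above CSR * S_base, seeded growth while
  ## crystals remain; a fast clamp keeps C at the supersaturation
  ## ceiling.  Both switches are smoothed to keep the system integrable.
  w_nucl <- pmax(pmin((C_dis - P$ceil) / (0.05 * P$ceil), 1),
                 pre / (pre + 1e-6))
  prec <- w_nucl * P$PRC * pmax(C_dis - P$S_base, 0) * P$vol +
    P$k_clamp * pmax(C_dis - P$ceil, 0) * P$vol

  ## NHE3 uptake
  inh <- 1 + I_uM / P$Ki
  J <- if (P$mech == "competitive") {
    P$vmax * act * C_na / (P$Km * inh + C_na)
  } else {
    (P$vmax / inh) * act * C_na / (P$Km + C_na)
  }

  ## induction target and activity turnover
  cg <- C_na^P$gma
  tf <- 1 + P$Emax * cg / (P$EC50g + cg)

  ## serial transit (colon outflow -> faeces)
  fNa <- P$kt * na;  fSol <- P$kt * sol
  fDis <- P$kt * dis; fPre <- P$kt * pre
  if (P$zero_order) {
    ## constant-rate gastric emptying (rate fixed at the last event),
    ## switched off smoothly as the stomach empties
    sw <- function(a, e) e * a / (a + 1e-6)
    fNa[1] <- sw(na[1], P$e0[1]);  fSol[1] <- sw(sol[1], P$e0[2])
    fDis[1] <- sw(dis[1], P$e0[3]); fPre[1] <- sw(pre[1], P$e0[4])
  }
  up <- function(f) c(0, f[1:8])

  dna  <- up(fNa) - fNa - J
  dsol <- up(fSol) - fSol - diss
  ddis <- up(fDis) - fDis + diss + rediss - prec - P$ka * dis
  dpre <- up(fPre) - fPre + prec - rediss
  dact <- P$kdeg * (tf - act)

  absT <- sum(P$ka * dis)
  dsysNa  <- sum(J) - P$kNa * y[I_SYSNA]
  dsysTen <- absT - P$kTen * y[I_SYSTEN]

  list(c(dna, dsol, ddis, dpre, dact, dsysNa, dsysTen,
         P$kNa * y[I_SYSNA],           # urine
         fNa[9],                       # stool sodium
         fSol[9] + fDis[9] + fPre[9],  # faecal tenapanor
         absT))
}

#' Simulate a study scenario
#'
#' Integrates the coupled luminal sodium / tenapanor / NHE3-activity /
#' systemic ODE system over the scenario horizon, restarting the solver
#' at every dose and meal event.  Meals deliver their sodium to the
#' stomach as solution; doses deliver solid drug to the stomach (the
#' direct-profile mode releases it according to the tabulated in vitro
#' curve).  Stool output is the flux leaving the colon; urine output is
#' renal clearance times the systemic sodium concentration (tracked
#' dietary sodium only).
#'
#' With `nsim > 1` a seeded Monte-Carlo wrapper perturbs renal and
#' hepatic clearance and the NHE3 capacity lognormally with their 30%
#' coefficients of variation and returns a list of simulations.
#'
#' @param object a [pbbm_model()].
#' @param nsim number of simulations (1 = representative individual).
#' @param seed RNG seed for the Monte-Carlo wrapper.
#' @param scenario a [study_scenario()].
#' @param out_dt output grid spacing, h.
#' @param rtol,atol solver tolerances (lsoda).
#' @param ... unused.
#' @return A `pbbm_sim` object (or a list of them when `nsim > 1`):
#'   trajectories in `$trajectory` (time by state matrix), the resolved
#'   engine parameters, and the scenario.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate(pbbm_model(), scenario = placebo_scenario(2))
#' daily_totals(sim)
#' }
simulate.pbbm_model <- function(object, nsim = 1, seed = NULL,
                                scenario, out_dt = 0.1,
                                rtol = 1e-7, atol = 1e-10, ...) {
  stopifnot(inherits(scenario, "study_scenario"))
  if (nsim > 1) {
    if (!is.null(seed)) set.seed(seed)
    cvs <- object$systemic$cv
    sims <- vector("list", nsim)
    for (i in seq_len(nsim)) {
      m <- object
      sdlog <- sqrt(log(1 + cvs[["renal_CL"]]^2))
      m$systemic$renal_CL_L_h <- object$systemic$renal_CL_L_h *
        stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      m$drug$hepatic_CL_L_h <- object$drug$hepatic_CL_L_h *
        stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      m$nhe3$vmax_scalar <- object$nhe3$vmax_scalar *
        stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      sims[[i]] <- simulate(m, nsim = 1, scenario = scenario,
                            out_dt = out_dt, rtol = rtol, atol = atol)
    }
    return(sims)
  }

  P <- build_engine_pars(object, scenario)
  T_end <- 24 * scenario$duration_days
  nd <- nrow(scenario$dose_events)
  nm <- nrow(scenario$meal_events)
  ev <- rbind(
    data.frame(time = scenario$dose_events$time_h,
               what = rep("dose", nd),
               amount = scenario$dose_events$amount_mg),
    data.frame(time = scenario$meal_events$time_h,
               what = rep("meal", nm),
               amount = scenario$meal_events$sodium_mmol)
  )
  if (nrow(ev) && any(ev$time > T_end))
    stop("event outside the simulation horizon")
  ev <- ev[order(ev$time), , drop = FALSE]

  grid <- round(seq(0, T_end, by = out_dt), 10)
  bounds <- sort(unique(c(0, ev$time, T_end)))
  y <- numeric(N_STATE)
  y[I_ACT] <- 1
  rows <- vector("list", length(bounds))
  for (k in seq_along(bounds)) {
    t0 <- bounds[k]
    here <- ev$time == t0
    for (j in which(here)) {
      if (ev$what[j] == "meal") y[I_NA[1]] <- y[I_NA[1]] + ev$amount[j]
      else y[I_SOL[1]] <- y[I_SOL[1]] + ev$amount[j]
    }
    t1 <- if (k < length(bounds)) bounds[k + 1] else T_end
    if (t1 <= t0) next
    if (P$zero_order)
      P$e0 <- pmax(y[c(I_NA[1], I_SOL[1], I_DIS[1], I_PRE[1])], 0) /
        P$gi$compartments$mtt_h[1]
    tt <- unique(c(t0, grid[grid > t0 & grid < t1], t1))
    out <- deSolve::lsoda(y, tt, pbbm_rhs, P, rtol = rtol, atol = atol,
                          maxsteps = 50000)
    if (attr(out, "istate")[1] < 0)
      stop("ODE solver failure at t = ", utils::tail(out[, 1], 1),
           "; state: ", paste(signif(y, 4), collapse = ", "))
    y <- as.numeric(out[nrow(out), -1])
    keep <- out[, 1] %in% grid & out[, 1] < t1
    rows[[k]] <- out[keep, , drop = FALSE]
  }
  traj <- do.call(rbind, rows)
  traj <- rbind(traj, c(T_end, y))
  colnames(traj) <- c("time_h",
                      paste0("na_", GUT_SEGMENTS),
                      paste0("solid_", GUT_SEGMENTS),
                      paste0("dissolved_", GUT_SEGMENTS),
                      paste0("precip_", GUT_SEGMENTS),
                      paste0("activity_", GUT_SEGMENTS),
                      "systemic_na", "systemic_ten", "urine_na",
                      "stool_na", "faecal_ten", "absorbed_ten")
  res <- list(trajectory = traj, scenario = scenario, model = object,
              pars = P)
  class(res) <- "pbbm_sim"
  res
}

## Interpolate a cumulative column at an exact time on the output grid.
cum_at <- function(sim, col, t) {
  tt <- sim$trajectory[, "time_h"]
  stats::approx(tt, sim$trajectory[, col], xout = t, rule = 2)$y
}

#' Daily urine and stool sodium totals
#'
#' Day-k totals are differences of the cumulative outputs at 24k and
#' 24(k-1) hours.
#'
#' @param result a `pbbm_sim`.
#' @return `data.frame` with columns `day`, `urine_mmol`, `stool_mmol`.
#' @export
daily_totals <- function(result) {
  stopifnot(inherits(result, "pbbm_sim"))
  nd <- floor(max(result$trajectory[, "time_h"]) / 24)
  if (nd < 1) stop("result must span at least one full day")
  edges <- 24 * (0:nd)
  u <- cum_at(result, "urine_na", edges)
  s <- cum_at(result, "stool_na", edges)
  data.frame(day = 1:nd, urine_mmol = diff(u), stool_mmol = diff(s))
}

#' Cumulative treated-minus-placebo sodium change
#'
#' @param treated,placebo `pbbm_sim` objects over matching horizons.
#' @param day day (1-based) at whose end the cumulative outputs are
#'   compared.
#' @return Named numeric vector `c(delta_stool, delta_urine)`, mmol.
#' @export
cumulative_change_vs_placebo <- function(treated, placebo, day) {
  stopifnot(inherits(treated, "pbbm_sim"), inherits(placebo, "pbbm_sim"))
  t_end <- 24 * day
  if (max(treated$trajectory[, "time_h"]) < t_end ||
      max(placebo$trajectory[, "time_h"]) < t_end)
    stop("both simulations must cover the requested day")
  if (!isTRUE(all.equal(treated$scenario$meal_events,
                        placebo$scenario$meal_events)))
    stop("meal schedules differ between treated and placebo runs")
  c(delta_stool = cum_at(treated, "stool_na", t_end) -
      cum_at(placebo, "stool_na", t_end),
    delta_urine = cum_at(treated, "urine_na", t_end) -
      cum_at(placebo, "urine_na", t_end))
}

#' Luminal dissolved tenapanor concentrations
#'
#' @param result a `pbbm_sim`.
#' @return Matrix (time by segment) of dissolved tenapanor in uM.
#' @export
luminal_tenapanor_uM <- function(result) {
  stopifnot(inherits(result, "pbbm_sim"))
  dis <- result$trajectory[, paste0("dissolved_", GUT_SEGMENTS),
                           drop = FALSE]
  out <- sweep(dis, 2, result$pars$vol, "/") * 1e6 / result$pars$MW
  colnames(out) <- GUT_SEGMENTS
  out
}

#' Mass balance of a simulation
#'
#' @param result a `pbbm_sim`.
#' @return `data.frame` with, per output time, total tracked sodium and
#'   tenapanor in all pools, the cumulative intake/dose, and their
#'   relative errors.
#' @export
mass_balance <- function(result) {
  tr <- result$trajectory
  tt <- tr[, "time_h"]
  na_tot <- rowSums(tr[, paste0("na_", GUT_SEGMENTS), drop = FALSE]) +
    tr[, "systemic_na"] + tr[, "urine_na"] + tr[, "stool_na"]
  ten_tot <- rowSums(tr[, c(paste0("solid_", GUT_SEGMENTS),
                            paste0("dissolved_", GUT_SEGMENTS),
                            paste0("precip_", GUT_SEGMENTS)),
                        drop = FALSE]) +
    tr[, "faecal_ten"] + tr[, "absorbed_ten"]
  sc <- result$scenario
  intake <- vapply(tt, function(t)
    sum(sc$meal_events$sodium_mmol[sc$meal_events$time_h <= t]), 0)
  dosed <- vapply(tt, function(t)
    sum(sc$dose_events$amount_mg[sc$dose_events$time_h <= t]), 0)
  data.frame(time_h = tt, na_total = na_tot, na_intake = intake,
             na_rel_err = ifelse(intake > 0,
                                 (na_tot - intake) / intake, 0),
             ten_total = ten_tot, ten_dosed = dosed,
             ten_rel_err = ifelse(dosed > 0,
                                  (ten_tot - dosed) / dosed, 0))
}

#' @export
print.pbbm_sim <- function(x, ...) {
  cat(sprintf("PBBM simulation of '%s' (%d days)\n", x$scenario$label,
              x$scenario$duration_days))
  d <- daily_totals(x)
  cat(sprintf("  mean daily urine %.1f mmol, stool %.1f mmol (days 1-%d)\n",
              mean(d$urine_mmol), mean(d$stool_mmol), nrow(d)))
  invisible(x)
}

#' @export
summary.pbbm_sim <- function(object, ...) {
  d <- daily_totals(object)
  structure(list(label = object$scenario$label, daily = d,
                 total_urine = sum(d$urine_mmol),
                 total_stool = sum(d$stool_mmol)),
            class = "summary.pbbm_sim")
}

#' @export
print.summary.pbbm_sim <- function(x, ...) {
  cat(sprintf("Daily sodium excretion, '%s':\n", x$label))
  print(x$daily, row.names = FALSE, digits = 4)
  cat(sprintf("Cumulative: urine %.1f mmol, stool %.1f mmol\n",
              x$total_urine, x$total_stool))
  invisible(x)
}

#' @export
as.data.frame.pbbm_sim <- function(x, ...) {
  as.data.frame(x$trajectory)
}

#' Plot daily excretion of a simulation
#'
#' @param x a `pbbm_sim`.
#' @param which `"daily"` (urine and stool bars over days) or
#'   `"luminal"` (dissolved tenapanor per segment, log scale).
#' @param ... passed to the underlying plot calls.
#' @export
plot.pbbm_sim <- function(x, which = c("daily", "luminal"), ...) {
  which <- match.arg(which)
  if (which == "daily") {
    d <- daily_totals(x)
    graphics::matplot(d$day, cbind(d$urine_mmol, d$stool_mmol),
                      type = "b", pch = c(1, 16), lty = 1,
                      col = c("steelblue", "sienna"),
                      xlab = "day", ylab = "sodium excretion (mmol/day)",
                      main = x$scenario$label, ...)
    graphics::legend("topright", c("urine", "stool"), pch = c(1, 16),
                     col = c("steelblue", "sienna"), bty = "n")
  } else {
    cc <- luminal_tenapanor_uM(x)
    tt <- x$trajectory[, "time_h"]
    keep <- cc > 0
    cc[!keep] <- NA
    graphics::matplot(tt, cc, type = "l", log = "y", lty = 1,
                      xlab = "time (h)",
                      ylab = "dissolved tenapanor (uM)",
                      main = x$scenario$label, ...)
  }
  invisible(x)
}

#' Export a simulation to tidy CSV
#'
#' Writes the long-format trajectory and the daily summary.
#'
#' @param result a `pbbm_sim`.
#' @param trajectory_csv,daily_csv output paths (`NULL` to skip one).
#' @return Invisibly, the daily summary.
#' @export
write_sim_results <- function(result, trajectory_csv = NULL,
                              daily_csv = NULL) {
  if (!is.null(trajectory_csv)) {
    tr <- as.data.frame(result$trajectory)
    long <- stats::reshape(tr, direction = "long",
                           varying = list(names(tr)[-1]),
                           v.names = "value",
                           times = names(tr)[-1], timevar = "variable",
                           idvar = "time_h")
    utils::write.csv(long[order(long$time_h), c("time_h", "variable",
                                                "value")],
                     trajectory_csv, row.names = FALSE)
  }
  d <- daily_totals(result)
  if (!is.null(daily_csv))
    utils::write.csv(data.frame(day = d$day,
                                urine_mmol_day = d$urine_mmol,
                                stool_mmol_day = d$stool_mmol),
                     daily_csv, row.names = FALSE)
  invisible(d)
}
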