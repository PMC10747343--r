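#' Equilibrium solubility of tenapanor
#'
#' Monoprotic-base Henderson-Hasselbalch solubility for the free base,
#' `S0 * (1 + 10^(pKa - pH))`, capped at `S0 * SF`.  For the HCl salt the
#' ionised branch is instead bounded by the salt-limited ceiling derived
#' from the 1:1 ion product, `sqrt(Ksp) * MW` (the conventional
#' monohydrochloride treatment, without common-ion background); below
#' pHmax the ceiling binds, above it the curve rejoins the
#' Henderson-Hasselbalch branch, so the function is continuous in pH.
#'
#' @param pH bulk pH (vectorised).
#' @param params a [tenapanor_params()] list.
#' @param form `"free_base"` or `"hcl_salt"`.
#' @return Solubility in mg/mL.
#' @export
#' @examples
#' equilibrium_solubility(10, tenapanor_params())           # intrinsic
#' equilibrium_solubility(1, tenapanor_params(), "hcl_salt")
equilibrium_solubility <- function(pH, params = tenapanor_params(),
                                   form = c("free_base", "hcl_salt")) {
  form <- match.arg(form)
  if (params$S0_mg_ml <= 0) stop("intrinsic solubility must be positive")
  stopifnot(all(pH > 0), all(pH < 14))
  hh <- 1 + 10^(params$pKa - pH)
  if (form == "free_base") {
    params$S0_mg_ml * pmin(hh, params$solubility_factor)
  } else {
    ceiling_salt <- sqrt(params$Ksp_mM2) * params$molecular_weight / 1000
    pmin(params$S0_mg_ml * hh, ceiling_salt)
  }
}

#' Diffusion-layer (Nernst-Brunner) dissolution rate
#'
#' Per-bin flux `3 * D * M / (rho * h * r) * (S_eff - C_bulk)` summed
#' over bins, with the diffusion layer thickness capped at the particle
#' radius.  Negative driving force (particle growth) is suppressed to
#' zero.  The rate is zero once no solid remains and vanishes as the bulk
#' concentration approaches the surface solubility.
#'
#' @param particles list with `radius_um`, `amount_mg` (per bin, equal
#'   length), `density_g_ml`, `diffusion_cm2_s`, `h_um` (diffusion layer
#'   thickness before the radius cap).
#' @param S_eff surface solubility, mg/mL.
#' @param C_bulk bulk dissolved concentration, mg/mL.
#' @param volume compartment fluid volume, mL (kept in the signature for
#'   symmetry with the precipitation rate; the flux itself is
#'   volume-free).
#' @return Dissolution rate, mg/h.
#' @export
dlm_rate <- function(particles, S_eff, C_bulk, volume = 1) {
  stopifnot(S_eff >= 0, volume > 0)
  r <- particles$radius_um
  m <- particles$amount_mg
  if (length(r) != length(m)) stop("radius and amount bins must align")
  if (any(r < 0) || any(m < 0)) stop("radius and amount must be >= 0")
  if (any(m > 0 & r == 0))
    stop("zero radius with positive solid amount")
  live <- m > 0
  if (!any(live)) return(0)
  h <- pmin(particles$h_um, r)[live]
  k <- 3 * particles$diffusion_cm2_s * 3600 /
    (particles$density_g_ml * 1000 * (h * 1e-4) * (r[live] * 1e-4))
  sum(k * m[live]) * max(S_eff - C_bulk, 0)
}

#' Precipitation rate of supersaturated drug
#'
#' Nucleation requires the bulk concentration to exceed the critical
#' supersaturation ratio times the base solubility; once nucleated
#' (seed crystals present), the supersaturated excess decays first order
#' at rate `PRC` toward the base solubility.
#'
#' @param C_bulk dissolved concentration, mg/mL.
#' @param S_base equilibrium (free-base) solubility at local pH, mg/mL.
#' @param CSR critical supersaturation ratio (>= 1).
#' @param PRC precipitation rate constant, 1/h.
#' @param nucleated logical: has precipitation already been triggered in
#'   this pool (e.g. seed crystals present)?
#' @return Precipitation rate per mL of fluid, mg/(h mL).
#' @export
precipitation_rate <- function(C_bulk, S_base, CSR, PRC,
                               nucleated = FALSE) {
  stopifnot(CSR >= 1, PRC >= 0)
  trigger <- (C_bulk > CSR * S_base) | (nucleated & C_bulk > S_base)
  ifelse(trigger, PRC * pmax(C_bulk - S_base, 0), 0)
}

#' Drug release from a tabulated in vitro dissolution profile
#'
#' Piecewise-linear interpolation of the fraction-dissolved table times
#' the dose; beyond the last time point the final fraction is held.
#'
#' @param profile `data.frame` with columns `time_h` and
#'   `fraction_dissolved` (monotone non-decreasing, within \[0, 1\]).
#' @param t time since dosing, h (vectorised).
#' @param dose dose, mg.
#' @return Amount released up to `t`, mg.
#' @export
#' @examples
#' pr <- data.frame(time_h = c(0, 1, 2), fraction_dissolved = c(0, .5, 1))
#' release_from_profile(pr, 1.5, 30)  # 22.5
release_from_profile <- function(profile, t, dose) {
  validate_profile(profile)
  f <- stats::approx(profile$time_h, profile$fraction_dissolved, xout = t,
                     method = "linear", rule = 2)$y
  f * dose
}

validate_profile <- function(profile) {
  if (!all(c("time_h", "fraction_dissolved") %in% names(profile)))
    stop("profile needs columns time_h and fraction_dissolved")
  if (nrow(profile) < 2) stop("profile needs at least two points")
  if (is.unsorted(profile$time_h, strictly = TRUE))
    stop("profile times must be strictly increasing")
  if (is.unsorted(profile$fraction_dissolved))
    stop("fraction dissolved must be monotone non-decreasing")
  if (any(profile$fraction_dissolved < 0 |
          profile$fraction_dissolved > 1))
    stop("fraction dissolved must lie in [0, 1]")
  invisible(profile)
}

#' Read an in vitro dissolution profile from CSV
#'
#' Two columns, `time_h,fraction_dissolved`, header required.
#'
#' @param path CSV path.
#' @return A validated profile `data.frame`.
#' @export
read_dissolution_profile <- function(path) {
  pr <- utils::read.csv(path)
  validate_profile(pr)
  pr
}

## Release hazard k(t) = f'(t) / (1 - f(t)) of a profile, so that
## d(solid)/dt = -k(t) * solid reproduces the tabulated fraction released
## irrespective of how much of the dose has transited onward.  Capped to
## keep the ODE system tame as f -> 1; zero beyond the table end.
profile_hazard <- function(profile, cap = 100) {
  tt <- profile$time_h
  ff <- profile$fraction_dissolved
  n <- length(tt)
  slopes <- diff(ff) / diff(tt)
  function(tau) {
    if (tau < 0 || tau >= tt[n]) return(0)
    i <- findInterval(tau, tt, rightmost.closed = TRUE)
    f <- ff[i] + slopes[i] * (tau - tt[i])
    min(slopes[i] / max(1 - f, 1e-9), cap)
  }
}
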