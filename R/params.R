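#' @keywords internal
"_PACKAGE"

## Canonical compartment order used everywhere in the package.
GUT_SEGMENTS <- c("stomach", "duodenum", "jejunum1", "jejunum2",
                  "ileum1", "ileum2", "ileum3", "ileum4", "colon")

#' Meal-type gastric residence times
#'
#' Stomach mean residence time (h) by meal type.  The fed values follow the
#' meal-specific gastric residence times used for low- and high-fat/calorie
#' meals (1.35 h and 2.45 h); the moderate-fat value is their midpoint and
#' the fasted value is the conventional 15 min half-emptying scale.
#'
#' @return Named numeric vector of gastric residence times in hours.
#' @export
#' @examples
#' meal_grt()[["high_fat"]]
meal_grt <- function() {
  c(fasted = 0.25, low_fat = 1.35, moderate_fat = 1.90, high_fat = 2.45)
}

#' Default gut physiology configuration
#'
#' Nine-segment gut (stomach, duodenum, jejunum I-II, ileum I-IV, colon)
#' with mean transit times, resting free-water volumes, luminal pH and
#' regional relative NHE3 abundance (normalised to jejunum I; duodenum
#' carries no NHE3 flux).  Small-intestinal segments split a 3.5 h total
#' transit evenly; colonic transit defaults to 13.5 h.  Fluid volumes
#' follow the compartmental-absorption-transit convention of small
#' resting *free* water (fractional wetting of the anatomical volumes):
#' luminal concentrations -- which drive transporter saturation,
#' inhibition and induction -- refer to this free water, not to total
#' chyme volume.  The stomach row holds the fasted values;
#' [build_gi_model()] substitutes the meal-type-specific gastric
#' residence time, pH and volume.
#'
#' @param si_transit_h total small-intestinal transit time (h), divided
#'   equally over the seven small-intestinal segments.
#' @param colon_transit_h colonic mean transit time (h).
#' @param stomach_ph_fed,stomach_volume_fed stomach pH and fluid volume
#'   (mL) applied for any fed meal type.
#' @return A `data.frame` with one row per segment and columns
#'   `segment`, `mtt_h`, `volume_ml`, `ph`, `nhe3_abundance`, plus
#'   attributes `grt` (the meal-type map) and fed stomach overrides.
#' @export
default_physiology <- function(si_transit_h = 3.5, colon_transit_h = 13.5,
                               stomach_ph_fed = 5.0,
                               stomach_volume_fed = 250) {
  stopifnot(si_transit_h > 0, colon_transit_h > 0)
  si <- si_transit_h / 7
  cfg <- data.frame(
    segment = GUT_SEGMENTS,
    mtt_h = c(0.25, rep(si, 7), colon_transit_h),
    volume_ml = c(46, 9, 9, 7, 4, 4, 3, 3, 5),
    ph = c(1.5, 6.0, 6.5, 6.5, 7.0, 7.15, 7.3, 7.4, 6.8),
    nhe3_abundance = c(0, 0, 1, 1, 1.5, 1.5, 1.5, 1.5, 0.4),
    stringsAsFactors = FALSE
  )
  attr(cfg, "grt") <- meal_grt()
  attr(cfg, "stomach_ph_fed") <- stomach_ph_fed
  attr(cfg, "stomach_volume_fed") <- stomach_volume_fed
  cfg
}

#' Read a gut physiology configuration from YAML
#'
#' The file holds one entry per segment with fields `mtt_h`, `volume_ml`,
#' `ph` and `nhe3_abundance`, and optionally a `grt` meal-type map.
#' Missing segments fall back to [default_physiology()].
#'
#' @param path path to a YAML file.
#' @return A physiology configuration as from [default_physiology()].
#' @export
read_physiology <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_physiology()
  for (seg in intersect(names(raw), GUT_SEGMENTS)) {
    i <- match(seg, cfg$segment)
    for (f in intersect(names(raw[[seg]]),
                        c("mtt_h", "volume_ml", "ph", "nhe3_abundance")))
      cfg[[f]][i] <- raw[[seg]][[f]]
  }
  if (!is.null(raw$grt)) {
    grt <- attr(cfg, "grt")
    grt[names(raw$grt)] <- unlist(raw$grt)
    attr(cfg, "grt") <- grt
  }
  validate_physiology(cfg)
  cfg
}

validate_physiology <- function(cfg) {
  if (!identical(cfg$segment, GUT_SEGMENTS))
    stop("physiology must define the nine gut segments in order")
  if (any(cfg$mtt_h <= 0)) stop("mean transit times must be positive")
  if (any(cfg$volume_ml <= 0)) stop("fluid volumes must be positive")
  if (any(cfg$ph < 1 | cfg$ph > 8.5)) stop("pH must lie in [1, 8.5]")
  if (any(cfg$nhe3_abundance < 0)) stop("NHE3 abundance must be >= 0")
  invisible(cfg)
}

#' Tenapanor drug parameters
#'
#' Physicochemical, dissolution, particle and systemic parameters for
#' tenapanor hydrochloride and its free base.  Solubility follows a
#' monoprotic-base Henderson-Hasselbalch model with intrinsic solubility
#' `S0`, solubility-factor cap `SF`, and, for the HCl salt, a
#' solubility-product (`Ksp`) ceiling.  `form` selects which solid is
#' dosed; the two presets differ only in whether the salt-limited
#' solubility model is active.
#'
#' @param form `"hcl_salt"` (salt model active) or `"free_base"`.
#' @param particle_radius_um initial particle radius of the dosed solid
#'   (monodisperse bin).
#' @param precipitate_radius_um radius assigned to precipitated free base,
#'   which redissolves by the same diffusion-layer kinetics.
#' @return A list of class `drug_params`.
#' @export
#' @examples
#' tenapanor_params("free_base")$S0_mg_ml
tenapanor_params <- function(form = c("hcl_salt", "free_base"),
                             particle_radius_um = 25,
                             precipitate_radius_um = 5) {
  form <- match.arg(form)
  p <- list(
    name = "tenapanor",
    form = form,
    molecular_weight = 1217.97,   # g/mol, HCl salt
    pKa = 6.6,                    # monoprotic base
    compound_type = "monoprotic_base",
    S0_mg_ml = 1.73e-4,           # intrinsic (free base) solubility
    solubility_factor = 17328,    # cap on ionised solubility gain
    Ksp_mM2 = 43.429,             # 1:1 ion product [BH+][Cl-]
    solubility_at_pHmax = 8.267,  # mg/mL, reference measurement at pH 1
    counterion = "hydrochloric acid",
    CSR = 10,                     # critical supersaturation ratio
    PRC_h = 4,                    # precipitation rate constant, 1/h
    density_g_ml = 1.2,
    diffusion_cm2_s = 3.4e-6,     # Stokes-Einstein estimate, 37 C
    h_eff_um = 30,                # diffusion layer cap (radius-capped)
    particle_radius_um = particle_radius_um,
    precipitate_radius_um = precipitate_radius_um,
    Papp_cm_s = 0.04e-6,          # MDCK passive permeability
    fu = 0.001,
    Vss_L_kg = 0.370,
    hepatic_CL_L_h = 8.1
  )
  class(p) <- "drug_params"
  p
}

#' Read drug parameters from YAML
#'
#' Fields mirror [tenapanor_params()]; absent fields keep their defaults.
#'
#' @param path path to a YAML file.
#' @param form dosed solid form, as in [tenapanor_params()].
#' @return A `drug_params` list.
#' @export
read_drug_params <- function(path, form = "hcl_salt") {
  raw <- yaml::read_yaml(path)
  p <- tenapanor_params(form)
  for (f in intersect(names(raw), names(p))) p[[f]] <- raw[[f]]
  if (p$S0_mg_ml <= 0) stop("intrinsic solubility must be positive")
  if (p$solubility_factor < 1) stop("solubility factor must be >= 1")
  if (p$Ksp_mM2 <= 0) stop("Ksp must be positive")
  p
}

#' NHE3 transporter parameters
#'
#' Saturable apical sodium influx with nominal capacity `Jmax`
#' (pmol/min), affinity `Km`, competitive inhibition constant `Ki`
#' for tenapanor, regional relative abundance (set in the physiology
#' table), and food(sodium)-stimulated induction as a Hill function
#' (`Emax`, `EC50`, `gamma`) with first-order activity turnover `kdeg`.
#' `vmax_scalar` is the global calibration multiplier converting the
#' nominal per-transporter `Jmax` to whole-segment capacity; it is the
#' parameter adjusted by [calibrate_placebo()] (its default is the
#' package's own placebo calibration, see the methods vignette).
#'
#' @param vmax_scalar global capacity multiplier (unitless, calibrated).
#' @param Jmax_pmol_min nominal transporter capacity.
#' @param Km_uM sodium affinity (rat-derived, used as reported).
#' @param Ki_uM tenapanor inhibition constant.
#' @param Emax,EC50_uM,gamma Hill induction parameters (butyrate kinetics
#'   normalised to sodium equivalents).
#' @param kdeg_h activity turnover rate, 1/h; `Inf` selects instantaneous
#'   equilibration of activity with its induction target.
#' @param induction logical; `FALSE` zeroes `Emax`.
#' @param mechanism `"competitive"` (inhibitor scales the apparent Km) or
#'   `"noncompetitive"` (inhibitor scales capacity), for sensitivity
#'   analysis.
#' @return A list of class `nhe3_params`.
#' @export
nhe3_params <- function(vmax_scalar = 828, Jmax_pmol_min = 4900,
                        Km_uM = 4700, Ki_uM = 0.005,
                        Emax = 5.72, EC50_uM = 1500, gamma = 1.93,
                        kdeg_h = 0.25, induction = TRUE,
                        mechanism = c("competitive", "noncompetitive")) {
  mechanism <- match.arg(mechanism)
  stopifnot(Km_uM > 0, Ki_uM > 0, EC50_uM > 0, Emax >= 0, gamma > 0,
            vmax_scalar > 0, Jmax_pmol_min > 0, kdeg_h > 0)
  p <- list(vmax_scalar = vmax_scalar, Jmax_pmol_min = Jmax_pmol_min,
            Km_uM = Km_uM, Ki_uM = Ki_uM,
            Emax = if (induction) Emax else 0,
            EC50_uM = EC50_uM, gamma = gamma, kdeg_h = kdeg_h,
            induction = induction, mechanism = mechanism)
  class(p) <- "nhe3_params"
  p
}

#' Systemic disposition parameters
#'
#' One-compartment systemic pools for tracked (dietary) sodium and
#' absorbed tenapanor.  Sodium is eliminated renally; urine output is
#' renal clearance times the systemic sodium concentration.  Tenapanor is
#' cleared hepatically.  The coefficient-of-variation entries are carried
#' as metadata for the optional Monte-Carlo wrapper and do not affect the
#' representative-individual simulation.
#'
#' @param renal_CL_L_h renal clearance of sodium (L/h; calibrated against
#'   placebo urine output).
#' @param Vss_na_L_kg sodium distribution volume (L/kg).
#' @param body_weight_kg representative body weight.
#' @return A list of class `systemic_params`.
#' @export
systemic_params <- function(renal_CL_L_h = 5.5, Vss_na_L_kg = 0.495,
                            body_weight_kg = 70) {
  stopifnot(renal_CL_L_h >= 0, Vss_na_L_kg > 0, body_weight_kg > 0)
  p <- list(renal_CL_L_h = renal_CL_L_h, Vss_na_L_kg = Vss_na_L_kg,
            body_weight_kg = body_weight_kg,
            cv = c(renal_CL = 0.30, hepatic_CL = 0.30))
  class(p) <- "systemic_params"
  p
}

#' Assemble a sodium-tenapanor gut model
#'
#' Bundles physiology, drug, transporter and systemic parameter sets into
#' a model object that [simulate()][simulate.pbbm_model] integrates
#' against a [study_scenario()].
#'
#' @param physiology a physiology configuration
#'   ([default_physiology()] or [read_physiology()]).
#' @param drug a [tenapanor_params()] list (the scenario's dose form
#'   overrides the form stored here).
#' @param nhe3 an [nhe3_params()] list.
#' @param systemic a [systemic_params()] list.
#' @param gastric_emptying `"first_order"` (rate 1/GRT) or `"zero_order"`
#'   (linear emptying completing in one GRT).
#' @return An object of class `pbbm_model`.
#' @export
#' @examples
#' m <- pbbm_model()
#' print(m)
pbbm_model <- function(physiology = default_physiology(),
                       drug = tenapanor_params(),
                       nhe3 = nhe3_params(),
                       systemic = systemic_params(),
                       gastric_emptying = c("first_order", "zero_order")) {
  validate_physiology(physiology)
  gastric_emptying <- match.arg(gastric_emptying)
  m <- list(physiology = physiology, drug = drug, nhe3 = nhe3,
            systemic = systemic, gastric_emptying = gastric_emptying)
  class(m) <- "pbbm_model"
  m
}

#' @export
print.pbbm_model <- function(x, ...) {
  cat("Sodium-tenapanor gut model (9 segments)\n")
  cat(sprintf("  NHE3: Jmax %g pmol/min x scalar %g, Km %g uM, Ki %g uM\n",
              x$nhe3$Jmax_pmol_min, x$nhe3$vmax_scalar, x$nhe3$Km_uM,
              x$nhe3$Ki_uM))
  cat(sprintf("  Induction: %s (Emax %g, EC50 %g uM, gamma %g, kdeg %g/h)\n",
              if (x$nhe3$Emax > 0) "on" else "off", x$nhe3$Emax,
              x$nhe3$EC50_uM, x$nhe3$gamma, x$nhe3$kdeg_h))
  cat(sprintf("  Renal CL %g L/h, body weight %g kg\n",
              x$systemic$renal_CL_L_h, x$systemic$body_weight_kg))
  invisible(x)
}
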