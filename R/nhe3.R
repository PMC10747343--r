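#' NHE3-mediated sodium uptake flux
#'
#' Saturable apical sodium influx for one gut segment,
#' `J = s * Jmax * abundance * activity * C_Na / (Km * (1 + I/Ki) + C_Na)`
#' (competitive inhibition; the noncompetitive option divides the
#' capacity by `1 + I/Ki` instead), converted from pmol/min to mmol/h.
#' Regions with zero relative abundance (stomach, duodenum) carry no
#' flux.
#'
#' @param C_Na_uM luminal sodium concentration, uM.
#' @param C_inh_uM luminal dissolved tenapanor concentration, uM.
#' @param activity induction fold (baseline 1).
#' @param rel_abundance regional relative NHE3 abundance (jejunum I = 1).
#' @param params an [nhe3_params()] list.
#' @return Sodium uptake flux, mmol/h.
#' @export
#' @examples
#' p <- nhe3_params(vmax_scalar = 1)
#' uptake_flux(4700, 0, 1, 1, p)  # half-maximal
uptake_flux <- function(C_Na_uM, C_inh_uM, activity, rel_abundance,
                        params) {
  if (any(C_Na_uM < 0) || any(C_inh_uM < 0))
    stop("concentrations must be >= 0")
  vmax <- params$vmax_scalar * params$Jmax_pmol_min * 60e-9 *
    rel_abundance * activity
  inh <- 1 + C_inh_uM / params$Ki_uM
  if (params$mechanism == "competitive") {
    vmax * C_Na_uM / (params$Km_uM * inh + C_Na_uM)
  } else {
    (vmax / inh) * C_Na_uM / (params$Km_uM + C_Na_uM)
  }
}

#' Sodium-stimulated NHE3 induction target
#'
#' Hill function of the local luminal sodium concentration:
#' `1 + Emax * C^gamma / (EC50^gamma + C^gamma)`.
#'
#' @param C_Na_uM luminal sodium concentration, uM (vectorised).
#' @param params an [nhe3_params()] list.
#' @return Target activity fold (>= 1).
#' @export
#' @examples
#' induction_fold(1500, nhe3_params())  # Hill midpoint: 1 + Emax/2
induction_fold <- function(C_Na_uM, params) {
  stopifnot(all(C_Na_uM >= 0))
  cg <- C_Na_uM^params$gamma
  1 + params$Emax * cg / (params$EC50_uM^params$gamma + cg)
}

#' First-order turnover of NHE3 activity
#'
#' `d(activity)/dt = kdeg * (target - activity)`; with `kdeg = Inf` the
#' activity snaps to its target (instantaneous mode).
#'
#' @param activity current activity fold.
#' @param target_fold induction target from [induction_fold()].
#' @param kdeg_h turnover rate, 1/h.
#' @return d(activity)/dt, 1/h.
#' @export
activity_derivative <- function(activity, target_fold, kdeg_h) {
  stopifnot(all(activity >= 0))
  if (is.infinite(kdeg_h)) {
    d <- target_fold - activity
    return(ifelse(d == 0, 0, sign(d) * Inf))
  }
  kdeg_h * (target_fold - activity)
}
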