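check_pairs <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(predicted) < 1) stop("need at least one pair")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)) ||
      any(predicted <= 0) || any(observed <= 0))
    stop("fold-error statistics need positive predicted and observed values")
}

#' Average absolute fold error
#'
#' `10 ^ mean(|log10(pred / obs)|)`: the geometric-mean magnitude of the
#' prediction error, always >= 1 and invariant to swapping predictions
#' and observations.
#'
#' @param predicted,observed positive numeric vectors of equal length.
#' @return AAFE, unitless.
#' @export
#' @examples
#' aafe(c(2, 1), c(1, 2))  # 2
aafe <- function(predicted, observed) {
  check_pairs(predicted, observed)
  10^mean(abs(log10(predicted / observed)))
}

#' Average fold error
#'
#' `10 ^ mean(log10(pred / obs))`: the geometric-mean bias; > 1 means
#' overprediction on average, and swapping predictions and observations
#' inverts it.
#'
#' @inheritParams aafe
#' @return AFE, unitless.
#' @export
afe <- function(predicted, observed) {
  check_pairs(predicted, observed)
  10^mean(log10(predicted / observed))
}

#' Predicted/observed fold ratio
#'
#' @inheritParams aafe
#' @return `predicted / observed` (vectorised).
#' @export
fold_ratio <- function(predicted, observed) {
  check_pairs(predicted, observed)
  predicted / observed
}

#' k-fold agreement classifier
#'
#' A pair is within k-fold iff `max(ratio, 1/ratio) <= k`.
#'
#' @inheritParams aafe
#' @param k fold threshold (e.g. 1.25 or 2).
#' @return Logical vector.
#' @export
fold_within <- function(predicted, observed, k) {
  r <- fold_ratio(predicted, observed)
  pmax(r, 1 / r) <= k
}

#' Stool-versus-urine change correlation
#'
#' Ordinary least squares of the change in urine sodium on the change in
#' stool sodium across dosing regimens (cumulative change versus placebo
#' at a common day).
#'
#' @param delta_stool,delta_urine numeric vectors (mmol), one point per
#'   regimen, length >= 3.
#' @return List with `r_squared`, `slope`, `intercept`.
#' @export
change_correlation <- function(delta_stool, delta_urine) {
  if (length(delta_stool) < 3 || length(delta_urine) != length(delta_stool))
    stop("need at least three matched regimen points")
  fit <- stats::lm(delta_urine ~ delta_stool)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Reported clinical prediction/observation summary
#'
#' The published per-arm summary of model-predicted and observed daily
#' sodium excretion (mmol/day) for the three clinical studies used to
#' qualify the model: the 9-day dose-regimen study (urine and stool),
#' the 4-day food-effect study (stool) and the 7-day dose-escalation
#' study (stool), together with the fold ratios as printed.
#'
#' @return `data.frame` with columns `study`, `arm`, `urine_pred`,
#'   `urine_obs`, `urine_ratio_printed`, `stool_pred`, `stool_obs`,
#'   `stool_ratio_printed` (`NA` where a study did not report urine).
#' @export
clinical_excretion_summary <- function() {
  data.frame(
    study = c(rep("dose_regimen", 5), rep("food_effect", 3),
              rep("dose_escalation", 4)),
    arm = c("15_bid", "30_bid", "30_qd", "30_tid", "60_bid",
            "before_meal", "after_meal", "fasting",
            "3_qd", "10_qd", "30_qd", "100_qd"),
    urine_pred = c(122.5, 123.00, 147.1, 112.00, 118.8, rep(NA, 7)),
    urine_obs = c(112.30, 114.90, 143.00, 98.90, 94.80, rep(NA, 7)),
    urine_ratio_printed = c(1.09, 1.07, 1.03, 1.13, 1.25, rep(NA, 7)),
    stool_pred = c(37.00, 38.4, 14.3, 45.90, 39.30,
                   22.50, 19.70, 15.00, 6.20, 9.00, 15.00, 14.70),
    stool_obs = c(30.50, 27.00, 12.40, 41.30, 47.50,
                  25.90, 17.20, 14.10, 4.70, 9.50, 11.70, 15.40),
    stool_ratio_printed = c(1.21, 1.42, 1.16, 1.11, 0.83,
                            0.87, 1.14, 1.07, 1.33, 0.95, 1.28, 0.95),
    stringsAsFactors = FALSE
  )
}

#' Prediction-accuracy report
#'
#' Recomputes fold ratios, 1.25-/2-fold agreement, and the AAFE/AFE
#' footer for a predicted/observed table, flagging rows whose printed
#' ratio differs from the recomputed one by a rounding unit.
#'
#' @param table a `data.frame` in the layout of
#'   [clinical_excretion_summary()]; printed-ratio columns are optional.
#' @param csv optional path to also write the per-row block as CSV.
#' @return List of class `accuracy_report` with elements `rows` (per-arm
#'   ratios and flags) and `footer` (AAFE/AFE for urine and stool).
#' @export
accuracy_report <- function(table = clinical_excretion_summary(),
                            csv = NULL) {
  rows <- table
  for (side in c("urine", "stool")) {
    p <- rows[[paste0(side, "_pred")]]
    o <- rows[[paste0(side, "_obs")]]
    ok <- !is.na(p) & !is.na(o)
    ratio <- rep(NA_real_, nrow(rows))
    ratio[ok] <- p[ok] / o[ok]
    rows[[paste0(side, "_ratio")]] <- ratio
    rows[[paste0(side, "_within_1.25")]] <-
      ifelse(ok, pmax(ratio, 1 / ratio) <= 1.25, NA)
    rows[[paste0(side, "_within_2")]] <-
      ifelse(ok, pmax(ratio, 1 / ratio) <= 2, NA)
    printed <- rows[[paste0(side, "_ratio_printed")]]
    if (!is.null(printed))
      rows[[paste0(side, "_ratio_flag")]] <-
        ifelse(ok, round(ratio, 2) != printed, NA)
  }
  up <- !is.na(rows$urine_pred)
  sp <- !is.na(rows$stool_pred)
  footer <- data.frame(
    output = c("urine", "stool"),
    aafe = c(aafe(rows$urine_pred[up], rows$urine_obs[up]),
             aafe(rows$stool_pred[sp], rows$stool_obs[sp])),
    afe = c(afe(rows$urine_pred[up], rows$urine_obs[up]),
            afe(rows$stool_pred[sp], rows$stool_obs[sp])),
    n = c(sum(up), sum(sp))
  )
  if (!is.null(csv)) utils::write.csv(rows, csv, row.names = FALSE)
  structure(list(rows = rows, footer = footer),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Prediction accuracy (daily sodium excretion, mmol/day)\n")
  cols <- intersect(c("study", "arm", "urine_pred", "urine_obs",
                      "urine_ratio", "stool_pred", "stool_obs",
                      "stool_ratio"), names(x$rows))
  print(x$rows[, cols], row.names = FALSE, digits = 4)
  cat("\n")
  print(x$footer, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predicted-versus-observed plot with fold-error bands
#'
#' @param x an `accuracy_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.accuracy_report <- function(x, ...) {
  r <- x$rows
  p <- c(r$urine_pred, r$stool_pred)
  o <- c(r$urine_obs, r$stool_obs)
  ok <- !is.na(p) & !is.na(o)
  lim <- range(c(p[ok], o[ok]))
  graphics::plot(o[ok], p[ok], log = "xy", xlim = lim, ylim = lim,
                 xlab = "observed (mmol/day)",
                 ylab = "predicted (mmol/day)",
                 pch = rep(c(1, 16), c(nrow(r), nrow(r)))[ok], ...)
  graphics::abline(0, 1, untf = TRUE)
  for (k in c(1.25, 2))
    for (s in c(k, 1 / k))
      graphics::curve(s * x, from = lim[1], to = lim[2], add = TRUE,
                      lty = if (k == 1.25) 3 else 2)
  graphics::legend("topleft", c("urine", "stool"), pch = c(1, 16),
                   bty = "n")
  invisible(x)
}

#' Read an observed daily-excretion CSV
#'
#' Dialect: columns `study`, `arm`, `day`, `urine_mmol`, `stool_mmol`
#' (a `value`/`sd` pair layout is also accepted for period means).
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_observed_series <- function(path) {
  x <- utils::read.csv(path)
  need <- c("study", "arm", "day")
  if (!all(need %in% names(x)))
    stop("observed series needs columns: ", paste(need, collapse = ", "))
  x
}
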