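MEAL_TIMES <- c(breakfast = 8, lunch = 13, dinner = 19)
DEFAULT_MEAL_NA <- 51.7   # mmol sodium per meal (155.1 mmol/day)

#' Define a dosing and meal study scenario
#'
#' Expands a dosing template (strength, meals dosed at, offset relative
#' to the meal, dosing days) and a three-meals-a-day schedule into
#' absolute event lists.  Expansion is pure and deterministic.
#'
#' @param label scenario label.
#' @param duration_days simulation horizon in whole days.
#' @param dose_mg dose strength, mg (`NULL` for placebo).
#' @param dose_meals character vector of meals the drug attaches to
#'   (`"breakfast"`, `"lunch"`, `"dinner"`): b.i.d. is breakfast and
#'   dinner, t.i.d. all three, q.d. breakfast.
#' @param dose_offset_h offset of each dose from its meal, h (default
#'   -10 min, i.e. before the meal); recycled against `dose_meals`.
#' @param dosing_days integer days (1-based) on which doses are given.
#' @param form dosed solid form, `"hcl_salt"` or `"free_base"`.
#' @param mode dissolution mode: `"dlm"` (mechanistic) or `"profile"`
#'   (direct input of a tabulated in vitro profile).
#' @param profile dissolution profile `data.frame` for `mode = "profile"`.
#' @param meal_type meal type controlling the gastric residence time.
#' @param sodium_mmol sodium content per meal, mmol.
#' @param meal_times named numeric vector of meal clock times, h.
#' @param induction logical, meal-stimulated NHE3 induction on/off.
#' @param inhibition `"competitive"` or `"noncompetitive"`.
#' @return An object of class `study_scenario` with expanded
#'   `dose_events` (time_h, amount_mg, form, mode) and `meal_events`
#'   (time_h, sodium_mmol).
#' @export
#' @examples
#' s <- study_scenario("15 mg b.i.d", 9, 15, dosing_days = 2:8)
#' nrow(s$dose_events)  # 14
study_scenario <- function(label, duration_days, dose_mg = NULL,
                           dose_meals = c("breakfast", "dinner"),
                           dose_offset_h = -1 / 6,
                           dosing_days = seq_len(duration_days),
                           form = c("hcl_salt", "free_base"),
                           mode = c("dlm", "profile"), profile = NULL,
                           meal_type = "low_fat",
                           sodium_mmol = DEFAULT_MEAL_NA,
                           meal_times = MEAL_TIMES,
                           induction = TRUE,
                           inhibition = c("competitive",
                                          "noncompetitive")) {
  form <- match.arg(form)
  mode <- match.arg(mode)
  inhibition <- match.arg(inhibition)
  stopifnot(duration_days >= 1, sodium_mmol >= 0)
  if (!is.null(dose_mg)) {
    stopifnot(dose_mg > 0)
    if (any(dosing_days < 1 | dosing_days > duration_days))
      stop("dosing_days outside the simulation horizon")
  }
  if (mode == "profile") {
    if (is.null(profile)) stop("profile mode needs a dissolution profile")
    validate_profile(profile)
  }
  meals <- expand.grid(day = seq_len(duration_days),
                       clock = unname(meal_times))
  meal_events <- data.frame(
    time_h = sort(24 * (meals$day - 1) + meals$clock),
    sodium_mmol = sodium_mmol
  )
  dose_events <- data.frame(time_h = numeric(0), amount_mg = numeric(0))
  if (!is.null(dose_mg)) {
    if (!all(dose_meals %in% names(meal_times)))
      stop("unknown meal in dose_meals")
    off <- rep_len(dose_offset_h, length(dose_meals))
    tt <- as.vector(outer(meal_times[dose_meals] + off,
                          24 * (dosing_days - 1), `+`))
    dose_events <- data.frame(time_h = sort(tt), amount_mg = dose_mg)
  }
  if (any(dose_events$time_h < 0))
    stop("dose events before the simulation start")
  s <- list(label = label, duration_days = duration_days,
            dose_events = dose_events, meal_events = meal_events,
            form = form, mode = mode, profile = profile,
            meal_type = meal_type, induction = induction,
            inhibition = inhibition)
  class(s) <- "study_scenario"
  s
}

#' @export
print.study_scenario <- function(x, ...) {
  cat(sprintf("Study scenario '%s': %d day(s), %d dose event(s), %d meal event(s)\n",
              x$label, x$duration_days, nrow(x$dose_events),
              nrow(x$meal_events)))
  cat(sprintf("  form %s, mode %s, meal type %s, induction %s, %s inhibition\n",
              x$form, x$mode, x$meal_type,
              if (x$induction) "on" else "off", x$inhibition))
  invisible(x)
}

#' Placebo scenario
#'
#' Three daily meals, no drug.
#'
#' @inheritParams study_scenario
#' @return A `study_scenario`.
#' @export
placebo_scenario <- function(duration_days = 9,
                             sodium_mmol = DEFAULT_MEAL_NA,
                             meal_type = "low_fat", induction = TRUE) {
  study_scenario("placebo", duration_days, dose_mg = NULL,
                 sodium_mmol = sodium_mmol, meal_type = meal_type,
                 induction = induction)
}

#' Multiple-ascending-dose regimen scenarios
#'
#' The six arms of the 9-day dose-regimen study in healthy volunteers:
#' placebo, 15 mg b.i.d, 30 mg b.i.d, 30 mg t.i.d, 60 mg b.i.d and 30 mg
#' q.d, with dosing on days 2-8 and 24-h urine/stool collections.  Doses
#' attach 10 min before breakfast and dinner (b.i.d), all three meals
#' (t.i.d) or breakfast (q.d).
#'
#' @inheritParams study_scenario
#' @return Named list of six `study_scenario` objects.
#' @export
rosenbaum_scenarios <- function(sodium_mmol = DEFAULT_MEAL_NA,
                                induction = TRUE) {
  arm <- function(label, dose, meals)
    study_scenario(label, duration_days = 9, dose_mg = dose,
                   dose_meals = meals, dosing_days = 2:8,
                   sodium_mmol = sodium_mmol, induction = induction)
  list(
    placebo      = placebo_scenario(9, sodium_mmol, induction = induction),
    `15_bid`     = arm("15 mg b.i.d", 15, c("breakfast", "dinner")),
    `30_bid`     = arm("30 mg b.i.d", 30, c("breakfast", "dinner")),
    `30_tid`     = arm("30 mg t.i.d", 30, c("breakfast", "lunch", "dinner")),
    `60_bid`     = arm("60 mg b.i.d", 60, c("breakfast", "dinner")),
    `30_qd`      = arm("30 mg q.d", 30, "breakfast")
  )
}

#' Single-ascending-dose escalation scenarios
#'
#' Once-daily tenapanor of increasing strength (default 3, 10, 30,
#' 100 mg) for 7 days, all arms sharing an identical meal schedule.
#'
#' @param doses_mg dose strengths, mg.
#' @inheritParams study_scenario
#' @return Named list of `study_scenario` objects (plus a placebo).
#' @export
spencer_escalation <- function(doses_mg = c(3, 10, 30, 100),
                               sodium_mmol = DEFAULT_MEAL_NA) {
  out <- lapply(doses_mg, function(d)
    study_scenario(sprintf("%g mg q.d", d), duration_days = 7,
                   dose_mg = d, dose_meals = "breakfast",
                   sodium_mmol = sodium_mmol))
  names(out) <- sprintf("%g_qd", doses_mg)
  c(list(placebo = placebo_scenario(7, sodium_mmol)), out)
}

#' Food-effect (dose-timing) scenarios
#'
#' 15 mg b.i.d for 4 days with the dose given before the meal (-10 min),
#' after the meal (+30 min), or fasting (1 h before breakfast and 3 h
#' after dinner).
#'
#' @inheritParams study_scenario
#' @return Named list of three `study_scenario` objects.
#' @export
johansson_food_effect <- function(meal_type = "low_fat",
                                  sodium_mmol = DEFAULT_MEAL_NA,
                                  induction = TRUE) {
  arm <- function(label, offsets)
    study_scenario(label, duration_days = 4, dose_mg = 15,
                   dose_meals = c("breakfast", "dinner"),
                   dose_offset_h = offsets, meal_type = meal_type,
                   sodium_mmol = sodium_mmol, induction = induction)
  list(
    before  = arm("15 mg b.i.d before meal", c(-1 / 6, -1 / 6)),
    after   = arm("15 mg b.i.d after meal", c(0.5, 0.5)),
    fasting = arm("15 mg b.i.d fasting", c(-1, 3))
  )
}

#' Salt-versus-base application scenarios
#'
#' The retrospective formulation comparison: 30 mg b.i.d for 7 days as
#' HCl salt and free base under mechanistic diffusion-layer dissolution,
#' the same comparison driven by tabulated fast/slow in vitro profiles,
#' and 50 mg b.i.d extrapolations over 12 and 26 weeks.
#'
#' @param fast,slow dissolution profiles for the direct-input mode;
#'   defaults to the synthetic fixtures shipped with the package.
#' @inheritParams study_scenario
#' @return Named list of `study_scenario` objects.
#' @export
application_scenarios <- function(fast = NULL, slow = NULL,
                                  sodium_mmol = DEFAULT_MEAL_NA) {
  if (is.null(fast))
    fast <- read_dissolution_profile(
      system.file("extdata", "dissolution_fast_synthetic.csv",
                  package = "tenapbbm"))
  if (is.null(slow))
    slow <- read_dissolution_profile(
      system.file("extdata", "dissolution_slow_synthetic.csv",
                  package = "tenapbbm"))
  bid <- function(label, days, dose, form, mode = "dlm", profile = NULL)
    study_scenario(label, duration_days = days, dose_mg = dose,
                   dose_meals = c("breakfast", "dinner"), form = form,
                   mode = mode, profile = profile,
                   sodium_mmol = sodium_mmol)
  list(
    placebo_7d    = placebo_scenario(7, sodium_mmol),
    salt_dlm_7d   = bid("30 mg b.i.d HCl salt (DLM)", 7, 30, "hcl_salt"),
    base_dlm_7d   = bid("30 mg b.i.d free base (DLM)", 7, 30, "free_base"),
    fast_profile_7d = bid("30 mg b.i.d fast profile", 7, 30, "hcl_salt",
                          "profile", fast),
    slow_profile_7d = bid("30 mg b.i.d slow profile", 7, 30, "free_base",
                          "profile", slow),
    salt_dlm_12wk = bid("50 mg b.i.d HCl salt, 12 weeks", 84, 50,
                        "hcl_salt"),
    base_dlm_12wk = bid("50 mg b.i.d free base, 12 weeks", 84, 50,
                        "free_base"),
    salt_dlm_26wk = bid("50 mg b.i.d HCl salt, 26 weeks", 182, 50,
                        "hcl_salt"),
    base_dlm_26wk = bid("50 mg b.i.d free base, 26 weeks", 182, 50,
                        "free_base")
  )
}

#' Write / read a scenario as YAML
#'
#' Serialises the expanded event lists together with the scenario flags;
#' profiles travel inline.
#'
#' @param scenario a `study_scenario`.
#' @param path file path.
#' @return `read_scenario()` returns a `study_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "study_scenario"))
  x <- unclass(scenario)
  x$dose_events <- as.list(scenario$dose_events)
  x$meal_events <- as.list(scenario$meal_events)
  if (!is.null(scenario$profile)) x$profile <- as.list(scenario$profile)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  s <- list(label = x$label, duration_days = x$duration_days,
            dose_events = as.data.frame(x$dose_events),
            meal_events = as.data.frame(x$meal_events),
            form = x$form, mode = x$mode,
            profile = if (!is.null(x$profile)) as.data.frame(x$profile),
            meal_type = x$meal_type, induction = x$induction,
            inhibition = x$inhibition)
  class(s) <- "study_scenario"
  s
}
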