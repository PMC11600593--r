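# Stroke, heart-failure and mortality machinery: rate conversions,
# CHA2DS2-VASc-indexed stroke incidence, age-band heart-failure incidence,
# and the additive-hazard combination of cause-deleted background mortality
# with event-attributable mortality.

#' Convert an annual probability to a quarterly one
#'
#' Annual event probabilities are converted to the model's three-month
#' cycle by the complement-power rule `1 - (1 - p)^(1/4)`, which preserves
#' the annual probability when compounded over four cycles.
#'
#' @param p_annual Annual probability (vectorised), in \[0, 1\].
#' @return Per-cycle (three-month) probability.
#' @examples
#' annual_to_cycle_prob(0.10) # 1 - 0.9^0.25
#' @export
annual_to_cycle_prob <- function(p_annual) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    abort("p_annual must lie in [0, 1].", class = "afcem_validation_error")
  }
  1 - (1 - p_annual)^0.25
}

#' @rdname annual_to_cycle_prob
#' @param p_cycle Per-cycle probability.
#' @export
cycle_to_annual_prob <- function(p_cycle) {
  1 - (1 - p_cycle)^4
}

#' CHA2DS2-VASc score at a given age
#'
#' The cohort score starts at its configured baseline and gains the score's
#' age points: +1 at age 65 and a further +1 at age 75.
#'
#' @param age Age in years (vectorised).
#' @param baseline Baseline score before age points at model entry.
#' @return Integer score, capped at 9.
#' @export
cha2ds2vasc_at_age <- function(age, baseline = 1) {
  pmin(9L, as.integer(baseline) + (age >= 65) + (age >= 75))
}

#' Per-cycle stroke probability
#'
#' Annual stroke incidence is looked up by the cohort's current
#' CHA2DS2-VASc score, multiplied by the health-state-specific relative
#' risk, and converted to a quarterly probability.
#'
#' @param state Rhythm state group: `"nsr"`, `"st"`, `"lt"` or `"permanent"`.
#' @param age Current cohort age in years.
#' @param params An `af_params` object.
#' @return Per-cycle stroke probability.
#' @export
stroke_cycle_probability <- function(state, age, params) {
  state <- arg_match0(state, c("nsr", "st", "lt", "permanent"))
  annual_to_cycle_prob(pmin(1, stroke_annual_rate(state, age, params)))
}

# Annual stroke incidence x state RR (before cycle conversion); used on the
# hazard side of the mortality combination as well.
stroke_annual_rate <- function(state, age, params) {
  score <- cha2ds2vasc_at_age(age, params$demographics$baseline_cha2ds2vasc)
  tab <- params$risks$stroke$annual_incidence_by_score
  if (score + 1L > length(tab)) {
    abort(sprintf("No stroke incidence configured for CHA2DS2-VASc score %d.", score),
          class = "afcem_validation_error")
  }
  tab[[score + 1L]] * params$risks$stroke$rr_by_state[[state]]
}

#' Split stroke events by severity
#'
#' @param stroke_mass Total stroke event mass (expected events per person).
#' @param split Proportions over (non-disabling, moderate, severe); must
#'   sum to one.
#' @return Named vector of event mass by severity; sums exactly to
#'   `stroke_mass`.
#' @export
split_stroke_severity <- function(stroke_mass, split) {
  if (length(split) != 3 || any(split < 0) || abs(sum(split) - 1) > 1e-8) {
    abort("Severity split must be three non-negative proportions summing to 1.",
          class = "afcem_validation_error")
  }
  out <- stroke_mass * split
  names(out) <- c("non_disabling", "moderate", "severe")
  out
}

#' Per-cycle heart-failure onset probability
#'
#' General-population annual incidence is looked up by age band, multiplied
#' by the state relative risk (greater than one only in permanent AF by
#' default) and converted to a quarterly probability.
#'
#' @inheritParams stroke_cycle_probability
#' @return Per-cycle probability of heart-failure onset.
#' @export
hf_cycle_probability <- function(state, age, params) {
  state <- arg_match0(state, c("nsr", "st", "lt", "permanent"))
  hf <- params$risks$hf
  band <- findInterval(age, hf$age_band_lower)
  rr <- if (state == "permanent") hf$rr_permanent else 1
  annual_to_cycle_prob(pmin(1, hf$annual_incidence[[band]] * rr))
}

#' Combined per-cycle death probability
#'
#' Mortality combines the sex-weighted, cause-deleted background life-table
#' probability with event-attributable mortality on the hazard scale:
#' total annual hazard = background hazard + stroke incidence hazard x
#' case fatality + heart-failure prevalence x excess mortality hazard.
#' The combined annual probability is then converted to the quarterly
#' cycle. In the no-event limit this conserves the life table exactly.
#'
#' @param age Current age in years.
#' @param state Rhythm state group (drives the stroke incidence term).
#' @param params An `af_params` object.
#' @param hf_prevalence Fraction of the living cohort with prevalent heart
#'   failure.
#' @param stroke_naive_fraction Fraction of the living cohort still at risk
#'   of a first stroke (1 - prior-stroke prevalence).
#' @return Per-cycle death probability, in \[0, 1\].
#' @export
combine_mortality <- function(age, state, params, hf_prevalence = 0,
                              stroke_naive_fraction = 1) {
  q_bg <- background_annual_mortality(age, params)
  h_bg <- -log(1 - pmin(q_bg, 1 - 1e-12))
  q_stroke <- pmin(1 - 1e-12, stroke_annual_rate(state, age, params))
  h_stroke <- -log(1 - q_stroke) * params$risks$stroke$case_fatality *
    stroke_naive_fraction
  q_hf_excess <- pmin(1 - 1e-12, params$risks$hf$excess_annual_mortality)
  h_hf <- -log(1 - q_hf_excess) * hf_prevalence
  annual_to_cycle_prob(1 - exp(-(h_bg + h_stroke + h_hf)))
}

# Sex-weighted background annual mortality at (integer-floored) age.
background_annual_mortality <- function(age, params) {
  lt <- params$life_table
  a <- floor(age)
  wm <- params$demographics$male_fraction
  male <- lt$sex == "male"
  q_m <- lt$annual_mortality[male][match(a, lt$age[male])]
  q_f <- lt$annual_mortality[!male][match(a, lt$age[!male])]
  if (any(is.na(q_m)) || any(is.na(q_f))) {
    abort(sprintf("Life table does not cover age %g.", age),
          class = "afcem_validation_error")
  }
  wm * q_m + (1 - wm) * q_f
}

#' Read a life table from CSV
#'
#' Strict schema: columns `age` (integer years), `sex` (`"male"`/`"female"`)
#' and `annual_mortality` (probability). The table is assumed cause-deleted
#' (stroke- and heart-failure deaths removed) since event-attributable
#' mortality is added back by [combine_mortality()].
#'
#' @param path CSV file path.
#' @return A tibble of class `af_life_table`.
#' @export
read_life_table <- function(path) {
  lt <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("age", "sex", "annual_mortality")
  if (!identical(sort(intersect(names(lt), required)), sort(required))) {
    abort(sprintf("Life table '%s' must have columns %s.", path,
                  paste(required, collapse = ", ")),
          class = "afcem_format_error")
  }
  if (!all(lt$sex %in% c("male", "female"))) {
    abort("Life table 'sex' must be 'male' or 'female'.",
          class = "afcem_format_error")
  }
  if (any(lt$annual_mortality < 0 | lt$annual_mortality > 1)) {
    abort("Life table mortality probabilities must lie in [0, 1].",
          class = "afcem_validation_error")
  }
  class(lt) <- c("af_life_table", class(lt))
  lt
}

#' Write a life table to CSV
#'
#' @param life_table Life-table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  readr::write_csv(life_table[, c("age", "sex", "annual_mortality")], path)
  invisible(path)
}
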