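# Discounting, per-cycle cost and QALY accrual, and cost-effectiveness
# summary metrics (ICER, NMB, NNT, cost per event avoided).

#' Discount factor for a model cycle
#'
#' Costs and benefits are discounted at an annual rate from model entry
#' (time zero); cycle `t` (0-based quarterly index) receives weight
#' `(1 + rate)^(-t * cycle_length)`.
#'
#' @param cycle_index 0-based global cycle index (vectorised).
#' @param rate Annual discount rate (>= 0).
#' @param cycle_length Cycle length in years.
#' @return Discount factor(s) in (0, 1].
#' @examples
#' discount_factor(160, 0.03) # 1.03^-40
#' @export
discount_factor <- function(cycle_index, rate, cycle_length = 0.25) {
  stopifnot(all(rate >= 0))
  (1 + rate)^(-cycle_index * cycle_length)
}

# Per-arm constants reused every cycle: per-state healthcare contact cost
# (unit costs x per-cycle utilisation rates, cardioversions included),
# pharmacy cost per person-cycle, state utility decrements, norm pieces.
pricing_constants <- function(params, arm) {
  cst <- params$costs
  util <- params$risks$utilization
  groups <- c("nsr", "st", "lt", "permanent")
  util_cost_group <- vapply(groups, function(g) {
    util$hospitalization[[arm]][[g]] * cst$cv_hospitalization +
      util$ed_visit[[arm]][[g]] * cst$ed_visit +
      util$outpatient[[arm]][[g]] * cst$outpatient +
      util$pharm_cardioversion[[arm]][[g]] * cst$pharm_cardioversion +
      util$elec_cardioversion[[arm]][[g]] * cst$elec_cardioversion
  }, numeric(1))
  u <- params$utilities
  decr_group <- c(nsr = 0, st = u$decrement_st_episodic,
                  lt = u$decrement_lt_persistent,
                  permanent = u$decrement_permanent)
  sev_split <- params$risks$stroke$severity_split
  nyha_split <- params$risks$hf$nyha_split
  list(
    util_cost_state = util_cost_group[state_group_of()[1:13]],
    util_cost_group = util_cost_group,
    pharma = cst$pharma_per_cycle[[arm]],
    ablation_cost = cst$ablation_procedure,
    stroke_acute = cst$stroke_acute,
    stroke_lt = cst$stroke_longterm_per_cycle,
    hf_cost = cst$hf_per_cycle,
    # prior-stroke and HF masses are carried as totals per state; severity
    # and NYHA composition equals the incident split (uniform attrition)
    hf_cost_mean = sum(nyha_split * cst$hf_per_cycle),
    hf_decr_mean = sum(nyha_split * u$hf_decrement),
    stroke_long_decr_mean = sum(sev_split * u$stroke_long_decrement),
    decr_state = decr_group[state_group_of()[1:13]],
    stroke_short_decr = u$stroke_short_decrement,
    stroke_long_decr = u$stroke_long_decrement,
    hf_decr = u$hf_decrement,
    norm_w = params$demographics$male_fraction * u$norm_at_ref[["male"]] +
      (1 - params$demographics$male_fraction) * u$norm_at_ref[["female"]],
    norm_slope = u$norm_slope_per_year,
    norm_ref_age = u$norm_ref_age,
    norm_floor = u$norm_floor,
    cl = params$settings$cycle_length,
    r_cost = params$settings$discount_rate_costs,
    r_eff = params$settings$discount_rate_effects
  )
}

# Sex-weighted baseline utility norm at a given age.
baseline_norm <- function(pc, age) {
  max(pc$norm_floor, pc$norm_w - pc$norm_slope * (age - pc$norm_ref_age))
}

# One cycle of cost and QALY accrual (internal; `accrue_cycle()` is the
# documented wrapper). All quantities are per person of the entry cohort;
# `stroked_state` and `hf_state` are per-state sequela masses (severity /
# NYHA composition taken from the incident splits via the precomputed
# means, or overridable through `pc` for explicit masses).
price_cycle <- function(pc, occ_eff, stroked_state, hf_state, strokes_sev,
                        ablations, blanked, age, g_idx) {
  alive <- sum(occ_eff)
  cost_reablation <- ablations * pc$ablation_cost
  cost_healthcare <- sum(occ_eff * pc$util_cost_state) +
    blanked * (pc$util_cost_group[["st"]] - pc$util_cost_group[["nsr"]])
  cost_pharma <- alive * pc$pharma
  cost_ae <- sum(strokes_sev * pc$stroke_acute) +
    sum(stroked_state) * pc$stroke_lt + sum(hf_state) * pc$hf_cost_mean

  norm <- baseline_norm(pc, age)
  # per-state utility mass: baseline norm minus the rhythm-state decrement,
  # minus long-term AE decrements on the sequela masses; floored at zero
  # per state
  qaly_state <- pmax(0, occ_eff * (norm - pc$decr_state) -
                       stroked_state * pc$stroke_long_decr_mean -
                       hf_state * pc$hf_decr_mean)
  qaly <- max(0, pc$cl * (sum(qaly_state) -
                            sum(strokes_sev * pc$stroke_short_decr)))
  life_years <- pc$cl * alive

  df_c <- discount_factor(g_idx, pc$r_cost, pc$cl)
  df_e <- discount_factor(g_idx, pc$r_eff, pc$cl)
  cost_total <- cost_reablation + cost_healthcare + cost_pharma + cost_ae
  c(cost_initial = 0,
    cost_reablation = cost_reablation,
    cost_healthcare = cost_healthcare,
    cost_pharma = cost_pharma,
    cost_ae = cost_ae,
    cost_total = cost_total,
    cost_initial_disc = 0,
    cost_reablation_disc = cost_reablation * df_c,
    cost_healthcare_disc = cost_healthcare * df_c,
    cost_pharma_disc = cost_pharma * df_c,
    cost_ae_disc = cost_ae * df_c,
    cost_total_disc = cost_total * df_c,
    qaly = qaly, qaly_disc = qaly * df_e,
    life_years = life_years, life_years_disc = life_years * df_e)
}

#' Accrue costs and QALYs for one cycle
#'
#' Applies the per-cycle accrual rules to a given occupancy vector and
#' event tally: healthcare contact and pharmacy costs per living
#' person-cycle, procedure cost per ablation event, severity-specific
#' acute stroke costs, long-term stroke and NYHA-specific heart-failure
#' costs on the prevalence accumulators, and utility-weighted QALYs
#' (baseline sex-weighted norm minus state and adverse-event decrements,
#' floored at zero per state).
#'
#' @param occupancy Occupancy over the 14 states (proportions).
#' @param events Named list/vector with `strokes` (length-3 by severity,
#'   or a scalar split by the configured severity proportions),
#'   `ablations`, and optionally `cv_pharm`, `cv_elec`.
#' @param params An `af_params` object.
#' @param arm Treatment arm.
#' @param cycle_index 0-based global cycle (drives age and discounting).
#' @param stroke_mass,hf_mass Prevalence accumulators (fractions of the
#'   entry cohort with prior stroke by severity / prevalent HF by NYHA).
#' @return A one-row tibble of cost categories, QALYs and life-years,
#'   discounted and undiscounted.
#' @export
accrue_cycle <- function(occupancy, events, params, arm, cycle_index = 0,
                         stroke_mass = c(0, 0, 0), hf_mass = c(0, 0, 0, 0)) {
  arm <- match_arm(arm)
  stopifnot(length(occupancy) == 14)
  pc <- pricing_constants(params, arm)
  strokes <- events$strokes %||% 0
  if (length(strokes) == 1) {
    strokes <- split_stroke_severity(strokes, params$risks$stroke$severity_split)
  }
  # explicit severity/NYHA masses override the incident-split composition
  if (sum(stroke_mass) > 0) {
    pc$stroke_long_decr_mean <- sum(stroke_mass * pc$stroke_long_decr) / sum(stroke_mass)
  }
  if (sum(hf_mass) > 0) {
    pc$hf_cost_mean <- sum(hf_mass * pc$hf_cost) / sum(hf_mass)
    pc$hf_decr_mean <- sum(hf_mass * pc$hf_decr) / sum(hf_mass)
  }
  occ_liv <- occupancy[1:13]
  alive <- sum(occ_liv)
  spread <- if (alive > 0) occ_liv / alive else numeric(13)
  age <- params$demographics$baseline_age +
    cycle_index * params$settings$cycle_length
  row <- price_cycle(pc, occ_eff = occ_liv,
                     stroked_state = spread * sum(stroke_mass),
                     hf_state = spread * sum(hf_mass),
                     strokes_sev = strokes,
                     ablations = events$ablations %||% 0,
                     blanked = events$blanked %||% 0,
                     age = age, g_idx = cycle_index)
  tibble::as_tibble(as.list(row))
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost Incremental cost (treatment minus comparator).
#' @param delta_effect Incremental effect in QALYs.
#' @return A list with `icer` (numeric, `NA` when dominance applies or the
#'   effect difference is zero) and `label`: `"none"` for an ordinary
#'   ratio, `"dominant"` (cheaper and more effective), `"dominated"`
#'   (costlier and less effective), or `"undefined"` (zero effect
#'   difference).
#' @examples
#' compute_icer(360, 0.16)
#' compute_icer(-100, 0.1)$label
#' @export
compute_icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    return(list(icer = NA_real_, label = "undefined"))
  }
  if (delta_cost < 0 && delta_effect > 0) {
    return(list(icer = NA_real_, label = "dominant"))
  }
  if (delta_cost > 0 && delta_effect < 0) {
    return(list(icer = NA_real_, label = "dominated"))
  }
  list(icer = delta_cost / delta_effect, label = "none")
}

#' Net monetary benefit
#'
#' @inheritParams compute_icer
#' @param wtp Willingness-to-pay threshold in euro per QALY.
#' @return `wtp * delta_effect - delta_cost`, in euro.
#' @export
compute_nmb <- function(delta_cost, delta_effect, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_effect - delta_cost
}

#' Event-avoidance metrics
#'
#' Number needed to treat and cost per event avoided from lifetime event
#' rates in the two arms: NNT is the ceiling of the reciprocal absolute
#' risk difference; cost per event avoided divides the incremental cost by
#' the rate reduction (negative when the treatment arm has more events).
#'
#' @param rate_treat,rate_comp Lifetime expected events per person in the
#'   treatment (cryoablation) and comparator (AAD) arm.
#' @param delta_cost Incremental cost per person.
#' @param event Label for the event type.
#' @return One-row tibble: rates, absolute and relative difference, `nnt`
#'   (`NA` when the rates are identical) and `cost_per_event_avoided`.
#' @examples
#' event_metrics(0.261, 0.275, 360)
#' @export
event_metrics <- function(rate_treat, rate_comp, delta_cost, event = "event") {
  diff <- rate_treat - rate_comp
  tibble::tibble(
    event = event,
    rate_treat = rate_treat,
    rate_comp = rate_comp,
    absolute_difference = diff,
    relative_difference = if (rate_comp != 0) diff / rate_comp else NA_real_,
    nnt = if (diff != 0) ceiling(1 / abs(diff)) else NA_real_,
    cost_per_event_avoided = if (diff != 0) delta_cost / (-diff) else NA_real_
  )
}

#' @rdname event_metrics
#' @param trace_treat,trace_comp `af_trace` objects over identical horizons.
#' @export
compute_event_metrics <- function(trace_treat, trace_comp, delta_cost) {
  stopifnot(nrow(trace_treat$trace) == nrow(trace_comp$trace))
  rate <- function(tr, cols) sum(as.matrix(tr$trace[, cols]))
  stroke_cols <- c("strokes_non_disabling", "strokes_moderate", "strokes_severe")
  dplyr::bind_rows(
    event_metrics(rate(trace_treat, stroke_cols), rate(trace_comp, stroke_cols),
                  delta_cost, event = "stroke"),
    event_metrics(rate(trace_treat, "hf_onsets"), rate(trace_comp, "hf_onsets"),
                  delta_cost, event = "heart_failure")
  )
}

#' Per-arm totals with cost-category breakdown
#'
#' Sums the year-one decision-tree accruals and the Markov-phase accruals
#' into the five reporting categories (initial procedure, re-ablations,
#' healthcare contacts, pharmaceuticals, AF-related adverse events) plus
#' QALY and life-year totals; the grand total equals the category sum
#' exactly.
#'
#' @param allocation `af_allocation` for the arm.
#' @param trace `af_trace` for the arm.
#' @return A tibble with columns `component`, `undiscounted`, `discounted`.
#' @export
summarize_arm <- function(allocation, trace) {
  y1 <- allocation$year1
  mk <- trace$trace
  comp <- function(col) {
    c(y1[[col]] + sum(mk[[col]]),
      y1[[paste0(col, "_disc")]] + sum(mk[[paste0(col, "_disc")]]))
  }
  rows <- rbind(
    initial_procedure = comp("cost_initial"),
    reablations = comp("cost_reablation"),
    healthcare_contacts = comp("cost_healthcare"),
    pharmaceuticals = comp("cost_pharma"),
    adverse_events = comp("cost_ae")
  )
  rows <- rbind(rows, total_cost = colSums(rows),
                qalys = comp("qaly"), life_years = comp("life_years"))
  tibble::tibble(component = rownames(rows),
                 undiscounted = unname(rows[, 1]),
                 discounted = unname(rows[, 2]))
}
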