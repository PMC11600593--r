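# Cohort engine: per-cycle transition matrices over the 14-state space and
# the quarterly cohort trace. The decision tree reuses the same machinery
# (progression disabled), so year-one and lifetime dynamics cannot drift
# apart.
#
# Within-cycle convention: death acts first as a competing risk (probability
# from `combine_mortality()`, which folds in state-specific stroke case
# fatality and prevalence-weighted heart-failure excess mortality); rhythm
# and ablation transitions then apply to survivors. Stroke and HF sequelae
# are carried as cohort-level prevalence accumulators rather than expanding
# the state space.

# Total ablations received by a cohort member sitting in substate k:
# the cryoablation arm's index procedure counts toward the cap of 3 but not
# toward k itself.
total_ablations_in_state <- function(k, arm) {
  k + as.integer(arm == "cryoablation")
}

# Survivor-conditional transition rows over the 13 living states, constant
# across cycles for a given arm. Returns the 13x13 matrix, the per-state
# re-ablation rate, the NSR recurrence probabilities (needed by the
# blanking redirect) and whether any row had to be renormalised.
build_survivor_rows <- function(params, arm, progression = TRUE) {
  r <- params$risks
  max_abl <- params$settings$max_total_ablations
  P <- matrix(0, 13, 13, dimnames = list(af_states()[1:13], af_states()[1:13]))
  ablrate <- numeric(13)
  p_rec_nsr <- numeric(4)
  capped <- FALSE

  rr_idx <- function(total) min(total, 3L) + 1L

  for (k in 0:3) {
    total <- total_ablations_in_state(k, arm)
    can_ablate <- total < max_abl # guarantees k + 1 <= 3
    succ <- r$ablation_success

    # NSR_k: recurrence to ST_k
    i <- IDX_NSR[k + 1]
    p_rec <- min(1, r$recurrence[[arm]] * r$rr_recurrence_by_count[rr_idx(total)])
    p_rec_nsr[k + 1] <- p_rec
    P[i, IDX_ST[k + 1]] <- p_rec
    P[i, i] <- 1 - p_rec

    # ST_k: resolution, re-ablation (success -> NSR_{k+1}, failure ->
    # ST_{k+1}), progression to LT_k
    i <- IDX_ST[k + 1]
    p_res <- min(1, r$resolution[[arm]] * r$rr_resolution_by_count[rr_idx(total)])
    p_abl <- if (can_ablate) r$reablation[[arm]][["st"]] else 0
    p_prog <- if (progression) r$progression_st_lt else 0
    ablrate[i] <- p_abl
    out <- c(p_res, p_abl * succ, p_abl * (1 - succ), p_prog)
    if (sum(out) > 1) {
      out <- out / sum(out)
      capped <- TRUE
    }
    P[i, IDX_NSR[k + 1]] <- out[1]
    if (p_abl > 0) {
      P[i, IDX_NSR[k + 2]] <- out[2]
      P[i, IDX_ST[k + 2]] <- P[i, IDX_ST[k + 2]] + out[3]
    }
    P[i, IDX_LT[k + 1]] <- out[4]
    P[i, i] <- P[i, i] + 1 - sum(out)

    # LT_k: optional remission to ST_k, re-ablation, progression to permanent
    i <- IDX_LT[k + 1]
    p_abl <- if (can_ablate) r$reablation[[arm]][["lt"]] else 0
    p_prog <- if (progression) r$progression_lt_perm else 0
    p_rem <- r$remission_lt_st
    ablrate[i] <- p_abl
    out <- c(p_rem, p_abl * succ, p_abl * (1 - succ), p_prog)
    if (sum(out) > 1) {
      out <- out / sum(out)
      capped <- TRUE
    }
    P[i, IDX_ST[k + 1]] <- P[i, IDX_ST[k + 1]] + out[1]
    if (p_abl > 0) {
      P[i, IDX_NSR[k + 2]] <- P[i, IDX_NSR[k + 2]] + out[2]
      P[i, IDX_ST[k + 2]] <- P[i, IDX_ST[k + 2]] + out[3]
    }
    P[i, IDX_PERM] <- out[4]
    P[i, i] <- P[i, i] + 1 - sum(out)
  }
  P[IDX_PERM, IDX_PERM] <- 1
  list(P = P, ablrate = ablrate, p_rec_nsr = p_rec_nsr, capped = capped)
}

# Age-indexed lookup tables over the 13 living states for event
# probabilities and hazard components; entries change only when the
# cohort's integer age changes. Formulas identical to
# `stroke_cycle_probability()` / `hf_cycle_probability()` /
# `combine_mortality()`.
age_lookup <- function(params, cycle_ages) {
  fa <- floor(cycle_ages)
  ua <- unique(fa)
  grp4 <- c("nsr", "st", "lt", "permanent")
  groups <- state_group_of()[1:13]
  p_stroke4 <- vapply(ua, function(a) {
    vapply(grp4, stroke_cycle_probability, numeric(1), age = a, params = params)
  }, numeric(4))
  p_hf4 <- vapply(ua, function(a) {
    vapply(grp4, hf_cycle_probability, numeric(1), age = a, params = params)
  }, numeric(4))
  h_stroke4 <- vapply(ua, function(a) {
    vapply(grp4, function(g) {
      -log(1 - min(1 - 1e-12, stroke_annual_rate(g, a, params))) *
        params$risks$stroke$case_fatality
    }, numeric(1))
  }, numeric(4))
  h_bg <- vapply(ua, function(a) {
    -log(1 - min(background_annual_mortality(a, params), 1 - 1e-12))
  }, numeric(1))
  list(
    idx = match(fa, ua),
    p_stroke13 = p_stroke4[match(groups, grp4), , drop = FALSE],
    p_hf13 = p_hf4[match(groups, grp4), , drop = FALSE],
    h_stroke13 = h_stroke4[match(groups, grp4), , drop = FALSE],
    h_bg = h_bg,
    h_hf = -log(1 - min(1 - 1e-12, params$risks$hf$excess_annual_mortality))
  )
}

# Per-cycle death probability for the 13 living states, with per-state
# stroke-naive fractions and HF prevalences. Same additive-hazard formula
# as `combine_mortality()`, vectorised.
death_prob_vec <- function(params, age, hf_prev13, naive_frac13) {
  groups <- state_group_of()[1:13]
  q_bg <- background_annual_mortality(age, params)
  h_bg <- -log(1 - min(q_bg, 1 - 1e-12))
  h_stroke_g <- vapply(c("nsr", "st", "lt", "permanent"), function(g) {
    -log(1 - min(1 - 1e-12, stroke_annual_rate(g, age, params))) *
      params$risks$stroke$case_fatality
  }, numeric(1))
  h_hf <- -log(1 - min(1 - 1e-12, params$risks$hf$excess_annual_mortality))
  1 - exp(-(h_bg + h_stroke_g[groups] * naive_frac13 + h_hf * hf_prev13) / 4)
}

#' Build a one-cycle transition matrix
#'
#' Assembles the full 14x14 transition matrix for one quarterly cycle, one
#' arm and one cohort age: recurrence/resolution probabilities scaled by
#' the ablation-count relative risks (capped into \[0, 1\]), re-ablation
#' flows `ST_k`/`LT_k -> NSR_{k+1}` (success) or `ST_{k+1}` (failure) while
#' total ablations remain below three, progression `ST -> LT -> permanent`,
#' and the per-cycle death probability from [combine_mortality()] with the
#' remaining mass scaled proportionally.
#'
#' @param params An `af_params` object.
#' @param arm `"cryoablation"` or `"aad"`.
#' @param age Cohort age in years.
#' @param hf_prevalence,stroke_naive_fraction Prevalence accumulators fed
#'   into the mortality combination (defaults: no prevalent disease).
#' @param progression Include the chronicity progression transitions
#'   (disabled inside the year-one decision tree).
#' @return A 14x14 row-stochastic matrix; rows/columns ordered as
#'   [af_states()], death absorbing.
#' @export
build_transition_matrix <- function(params, arm, age, hf_prevalence = 0,
                                    stroke_naive_fraction = 1,
                                    progression = TRUE) {
  arm <- match_arm(arm)
  rows <- build_survivor_rows(params, arm, progression)
  if (rows$capped) {
    inform("Transition probabilities exceeded 1 and were renormalised proportionally.")
  }
  d <- death_prob_vec(params, age, rep(hf_prevalence, 13),
                      rep(stroke_naive_fraction, 13))
  M <- matrix(0, 14, 14, dimnames = list(af_states(), af_states()))
  M[1:13, 1:13] <- rows$P * (1 - d)
  M[1:13, IDX_DEAD] <- d
  M[IDX_DEAD, IDX_DEAD] <- 1
  M
}

# ---- cohort engine ---------------------------------------------------------

# Runs the cohort recursion for n_cycles quarterly cycles. `start_occ` is a
# 14-vector of proportions; `global_cycle_offset` positions the run on the
# model clock for discounting (the tree runs at offset 0, the Markov phase
# at offset 4). Sequela bookkeeping: `naive` (never had a stroke) and
# `hffree` (no prevalent heart failure) are per-state mass vectors
# propagated with the same survivor matrices, so the per-state prior-stroke
# mass is occ - naive and HF mass is occ - hffree; this makes the cohort
# recursion the exact expectation of the individual-level process.
# `newly_ablated` carries the NSR mass ablated in the previous cycle (for
# the blanking redirect).
run_engine <- function(params, arm, n_cycles, start_occ,
                       global_cycle_offset = 0, progression = TRUE,
                       naive = NULL, hffree = NULL,
                       newly_ablated = numeric(4)) {
  arm <- match_arm(arm)
  stopifnot(length(start_occ) == 14, abs(sum(start_occ) - 1) < 1e-9)
  if (is.null(naive)) naive <- start_occ[1:13]
  if (is.null(hffree)) hffree <- start_occ[1:13]
  s <- params$settings
  blanking <- isTRUE(s$blanking_period_active)
  hcc <- isTRUE(s$half_cycle_correction)
  baseline_age <- params$demographics$baseline_age
  rows <- build_survivor_rows(params, arm, progression)
  sev_split <- params$risks$stroke$severity_split
  groups <- state_group_of()[1:13]
  pricing <- pricing_constants(params, arm)
  util <- params$risks$utilization
  rate_pcv <- util$pharm_cardioversion[[arm]][groups]
  rate_ecv <- util$elec_cardioversion[[arm]][groups]

  occ <- as.numeric(start_occ)
  occ_hist <- matrix(NA_real_, n_cycles + 1, 14,
                     dimnames = list(NULL, af_states()))
  occ_hist[1, ] <- occ
  out <- vector("list", n_cycles)

  # event and hazard lookups only change with integer cohort age
  g_indices <- global_cycle_offset + seq_len(n_cycles) - 1
  cycle_ages <- baseline_age + g_indices * s$cycle_length
  lk <- age_lookup(params, cycle_ages)

  for (cyc in seq_len(n_cycles)) {
    g_idx <- g_indices[cyc]
    time <- g_idx * s$cycle_length
    age <- cycle_ages[cyc]
    occ_liv <- occ[1:13]
    alive <- sum(occ_liv)
    pos <- occ_liv > 1e-15
    naive_frac <- ifelse(pos, pmin(1, naive / pmax(occ_liv, 1e-300)), 1)
    hf_prev <- ifelse(pos, pmin(1, 1 - hffree / pmax(occ_liv, 1e-300)), 0)
    stroked <- pmax(0, occ_liv - naive)
    hf_state <- pmax(0, occ_liv - hffree)

    a <- lk$idx[cyc]
    d <- 1 - exp(-(lk$h_bg[a] + lk$h_stroke13[, a] * naive_frac +
                     lk$h_hf * hf_prev) / 4)

    # events on start-of-cycle occupancy
    p_stroke <- lk$p_stroke13[, a]
    p_hf <- lk$p_hf13[, a]
    strokes_total <- sum(naive * p_stroke)
    strokes_sev <- split_stroke_severity(strokes_total, sev_split)
    hf_onsets <- sum(hffree * p_hf)
    ablations <- sum(occ_liv * (1 - d) * rows$ablrate)
    cv_pharm <- sum(occ_liv * rate_pcv)
    cv_elec <- sum(occ_liv * rate_ecv)
    deaths <- sum(occ_liv * d)

    # survivor propagation (flags ride along with the same matrices)
    surv <- occ_liv * (1 - d)
    occ_next_liv <- as.numeric(surv %*% rows$P)
    naive_next <- as.numeric((naive * (1 - p_stroke) * (1 - d)) %*% rows$P)
    hffree_next <- as.numeric((hffree * (1 - p_hf) * (1 - d)) %*% rows$P)
    dead_next <- occ[IDX_DEAD] + deaths

    # newly-ablated inflow into NSR_{k+1} (success branch)
    new_abl <- numeric(4)
    for (k in 0:2) {
      inflow <- surv[IDX_ST[k + 1]] * rows$ablrate[IDX_ST[k + 1]] +
        surv[IDX_LT[k + 1]] * rows$ablrate[IDX_LT[k + 1]]
      new_abl[k + 2] <- inflow * params$risks$ablation_success
    }

    # blanking: recurrences among mass ablated in the immediately
    # preceding cycle return to NSR accounting; their healthcare
    # utilisation for the episode still accrues (handled in pricing).
    blank_k <- numeric(4)
    if (blanking && any(newly_ablated > 0)) {
      blank_k <- newly_ablated * (1 - d[IDX_NSR]) * rows$p_rec_nsr
      occ_next_liv[IDX_ST] <- occ_next_liv[IDX_ST] - blank_k
      occ_next_liv[IDX_NSR] <- occ_next_liv[IDX_NSR] + blank_k
      # the blanking redirect moves flag-carrying mass proportionally
      flow_st <- occ_next_liv[IDX_ST] + blank_k
      shift <- function(vec) {
        frac <- ifelse(flow_st > 1e-15, vec[IDX_ST] / flow_st, 0)
        moved <- frac * blank_k
        vec[IDX_ST] <- vec[IDX_ST] - moved
        vec[IDX_NSR] <- vec[IDX_NSR] + moved
        vec
      }
      naive_next <- shift(naive_next)
      hffree_next <- shift(hffree_next)
    }
    blanked <- sum(blank_k)

    occ_next <- c(occ_next_liv, dead_next)

    occ_eff <- if (hcc) (occ_liv + occ_next[1:13]) / 2 else occ_liv
    accrual <- price_cycle(pricing, occ_eff,
                           stroked_state = stroked, hf_state = hf_state,
                           strokes_sev = strokes_sev, ablations = ablations,
                           blanked = blanked, age = age, g_idx = g_idx)

    occ <- occ_next
    naive <- naive_next
    hffree <- hffree_next
    newly_ablated <- new_abl
    occ_hist[cyc + 1, ] <- occ
    out[[cyc]] <- c(
      cycle = g_idx, time = time, age = age,
      strokes_non_disabling = unname(strokes_sev[1]),
      strokes_moderate = unname(strokes_sev[2]),
      strokes_severe = unname(strokes_sev[3]),
      hf_onsets = hf_onsets, reablations = ablations,
      cv_pharm = cv_pharm, cv_elec = cv_elec, deaths = deaths,
      blanked_recurrences = blanked,
      stroke_prevalence_mass = sum(stroked),
      hf_prevalence_mass = sum(hf_state),
      accrual)
  }

  trace <- tibble::as_tibble(do.call(rbind, out))
  list(trace = trace, occupancy = occ_hist, occ_final = occ,
       naive = naive, hffree = hffree,
       newly_ablated = newly_ablated)
}

#' Run the lifetime Markov phase
#'
#' Propagates the cohort from its year-one allocation over 160 quarterly
#' cycles (40 years), rebuilding event probabilities as the cohort ages
#' across CHA2DS2-VASc and heart-failure age bands, and accruing
#' discounted and undiscounted costs and QALYs each cycle.
#'
#' @param params An `af_params` object.
#' @param allocation An `af_allocation` from [run_decision_tree()].
#' @param arm `"cryoablation"` or `"aad"`.
#' @return An `af_trace` object: list with `trace` (one row per cycle:
#'   events, prevalence masses, cost/QALY accruals discounted and
#'   undiscounted), `occupancy` (161 x 14 matrix of proportions) and the
#'   final prevalence accumulators.
#' @export
run_markov <- function(params, allocation, arm) {
  arm <- match_arm(arm)
  stopifnot(inherits(allocation, "af_allocation"))
  n_cycles <- round(params$settings$horizon / params$settings$cycle_length)
  res <- run_engine(params, arm, n_cycles,
                    start_occ = allocation$occupancy,
                    global_cycle_offset = round(params$settings$tree_horizon /
                                                  params$settings$cycle_length),
                    progression = TRUE,
                    naive = allocation$naive,
                    hffree = allocation$hffree,
                    newly_ablated = allocation$newly_ablated)
  structure(c(res, list(arm = arm)), class = "af_trace")
}

#' @export
print.af_trace <- function(x, ...) {
  cat(sprintf("<af_trace> %s arm, %d cycles\n", x$arm, nrow(x$trace)))
  cat(sprintf("  final dead fraction: %.3f\n", x$occ_final[IDX_DEAD]))
  cat(sprintf("  undiscounted cost %.0f, QALYs %.2f per person\n",
              sum(x$trace$cost_total), sum(x$trace$qaly)))
  invisible(x)
}

#' Time spent in each rhythm state
#'
#' Undiscounted person-years per rhythm state group (substates pooled):
#' cycle length times the sum of start-of-cycle occupancy over cycles.
#'
#' @param trace An `af_trace` (or the result of [run_decision_tree()]).
#' @param cycle_length Cycle length in years.
#' @return A tibble with columns `group` and `years`.
#' @export
time_in_states <- function(trace, cycle_length = 0.25) {
  occ <- trace$occupancy
  n <- nrow(occ) - 1L # accrual cycles: start-of-cycle rows
  groups <- state_group_of()
  years <- vapply(STATE_GROUPS, function(g) {
    cycle_length * sum(occ[seq_len(n), groups == g, drop = FALSE])
  }, numeric(1))
  tibble::tibble(group = STATE_GROUPS, years = unname(years))
}

#' Mean number of re-ablations per person
#'
#' Cumulative expected re-ablation procedures (the cryoablation arm's index
#' procedure is not counted), reported at twelve months and at the full
#' horizon.
#'
#' @param allocation Year-one allocation from [run_decision_tree()].
#' @param trace Markov trace from [run_markov()].
#' @return A tibble with columns `at` (`"12 months"`, `"horizon"`) and
#'   `reablations`.
#' @export
lifetime_ablations <- function(allocation, trace) {
  y1 <- allocation$year1_reablations
  tibble::tibble(
    at = c("12 months", "horizon"),
    reablations = c(y1, y1 + sum(trace$trace$reablations))
  )
}
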