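# Year-one decision tree: four quarterly periods evaluated with the same
# per-cycle transition machinery as the Markov engine (progression to the
# chronic states disabled), producing the initial Markov allocation over
# NSR_k / ST_k / death together with year-one costs, QALYs and the
# re-ablation count.

#' Run the year-one decision tree
#'
#' The cohort enters symptomatic (configurable via
#' `demographics.initial_af_fraction`). The cryoablation arm receives the
#' index procedure at entry — the procedure cost is charged undiscounted
#' at time zero, the index ablation counts toward the cap of three total
#' procedures but not toward the re-ablation substate `k`, and the cohort
#' starts in `NSR_0` with the ablation success probability (else `ST_0`).
#' The AAD arm enters on drug therapy and reaches NSR through resolution.
#' Four quarterly periods are then evaluated with recurrence, resolution,
#' re-ablation and death; every re-ablation (and any AAD-arm ablation)
#' charges the procedure cost and increments `k`.
#'
#' @param params An `af_params` object.
#' @param arm `"cryoablation"` or `"aad"`.
#' @param validate Validate `params` first (disable inside tight loops that
#'   already validated).
#' @return An `af_allocation`: end-of-year occupancy over the 14 states
#'   (mass only in `NSR_k`, `ST_k`, dead), year-one accruals by category
#'   (discounted and undiscounted), mean re-ablations, the prevalence
#'   accumulators handed to the Markov phase, and the four-period trace.
#' @export
run_decision_tree <- function(params, arm, validate = TRUE) {
  arm <- match_arm(arm)
  if (validate) validate_parameters(params)
  af <- params$demographics$initial_af_fraction
  occ0 <- numeric(14)
  newly_ablated <- numeric(4)
  cost_entry <- 0
  if (arm == "cryoablation") {
    succ <- params$risks$ablation_success
    occ0[IDX_NSR[1]] <- succ
    occ0[IDX_ST[1]] <- 1 - succ
    newly_ablated[1] <- 1 # whole cohort freshly ablated at entry
    cost_entry <- params$costs$ablation_procedure
  } else {
    occ0[IDX_NSR[1]] <- 1 - af
    occ0[IDX_ST[1]] <- af
  }

  n_tree <- round(params$settings$tree_horizon / params$settings$cycle_length)
  res <- run_engine(params, arm, n_tree, occ0,
                    global_cycle_offset = 0, progression = FALSE,
                    newly_ablated = newly_ablated)

  accrual_cols <- c("cost_initial", "cost_reablation", "cost_healthcare",
                    "cost_pharma", "cost_ae", "cost_total",
                    "cost_initial_disc", "cost_reablation_disc",
                    "cost_healthcare_disc", "cost_pharma_disc",
                    "cost_ae_disc", "cost_total_disc",
                    "qaly", "qaly_disc", "life_years", "life_years_disc")
  year1 <- colSums(res$trace[, accrual_cols])
  # entry procedure at t = 0: undiscounted by definition
  year1["cost_initial"] <- year1["cost_initial"] + cost_entry
  year1["cost_initial_disc"] <- year1["cost_initial_disc"] + cost_entry
  year1["cost_total"] <- year1["cost_total"] + cost_entry
  year1["cost_total_disc"] <- year1["cost_total_disc"] + cost_entry

  structure(list(
    arm = arm,
    occupancy = res$occ_final,
    year1 = year1,
    year1_reablations = sum(res$trace$reablations),
    naive = res$naive,
    hffree = res$hffree,
    newly_ablated = res$newly_ablated,
    trace = res$trace,
    occupancy_history = res$occupancy
  ), class = "af_allocation")
}

#' @export
print.af_allocation <- function(x, ...) {
  cat(sprintf("<af_allocation> %s arm after year one\n", x$arm))
  occ <- x$occupancy
  nz <- occ > 1e-12
  cat("  occupancy:", paste(sprintf("%s %.3f", af_states()[nz], occ[nz]),
                            collapse = ", "), "\n")
  cat(sprintf("  year-1 cost %.0f (disc %.0f), QALYs %.3f, re-ablations %.3f\n",
              x$year1[["cost_total"]], x$year1[["cost_total_disc"]],
              x$year1[["qaly"]], x$year1_reablations))
  invisible(x)
}

#' Apply the post-ablation blanking rule to period event tallies
#'
#' Under a 12-week blanking period, AF recurrences detected in the first
#' quarter after an ablation reflect transient inflammation and are not
#' counted as treatment failure: that recurrence mass returns to NSR
#' accounting, while the episode's healthcare utilisation still accrues.
#'
#' @param period_events List with `recurrences` (total recurrence mass in
#'   the period) and `recurrences_post_ablation` (the portion arising
#'   within the first quarter after an ablation).
#' @param cycle_index 0-based quarterly period index (kept for audit).
#' @param active Is the blanking period active? If `FALSE` the tallies are
#'   returned unchanged with zero blanked mass.
#' @return The tallies with `recurrences` reduced to true failures and a
#'   `blanked` component holding the discounted-as-transient mass.
#' @export
apply_blanking <- function(period_events, cycle_index = 0, active = TRUE) {
  post <- period_events$recurrences_post_ablation %||% 0
  if (!active) {
    period_events$blanked <- 0
    return(period_events)
  }
  if (post > period_events$recurrences + 1e-12) {
    abort("Post-ablation recurrences cannot exceed total recurrences.",
          class = "afcem_validation_error")
  }
  period_events$blanked <- post
  period_events$recurrences <- period_events$recurrences - post
  period_events
}
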