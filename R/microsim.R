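# Individual-level microsimulation of the same stochastic process the
# cohort engine integrates in expectation: walkers move through the
# 14-state space under the survivor-conditional transition rows, draw
# stroke / heart-failure / death events cycle by cycle, and carry sequela
# flags. Used as the sampling-based cross-check of the cohort recursion
# (occupancy, cumulative events and accruals must agree within Monte-Carlo
# error).

#' Microsimulation cross-check of the cohort engine
#'
#' Simulates `n_walkers` individuals through the year-one decision tree
#' and the 40-year Markov phase for one arm, with per-walker stroke and
#' heart-failure sequela flags. Per-state stroke-naive fractions and HF
#' prevalences feeding the mortality combination are recomputed
#' empirically from the walker population each cycle, so the simulation is
#' an independent sampling path of the model rather than a re-evaluation
#' of the cohort recursion. The blanking period is not supported here
#' (base-case dynamics only).
#'
#' @param params An `af_params` object.
#' @param arm `"cryoablation"` or `"aad"`.
#' @param n_walkers Number of simulated individuals.
#' @param seed RNG seed.
#' @param n_batches Number of equal walker batches used to estimate
#'   Monte-Carlo standard errors of totals.
#' @return A list: `occupancy` (per-cycle proportions, `(cycles+1) x 14`),
#'   `events` (cumulative expected strokes by severity, HF onsets,
#'   re-ablations, deaths, per person, with batch SEs),
#'   `batch` (per-batch tibble of totals: state-group years, events,
#'   undiscounted cost and QALYs) and `n_cycles`.
#' @export
run_microsim <- function(params, arm, n_walkers = 1e5, seed = 1L,
                         n_batches = 10L) {
  arm <- match_arm(arm)
  if (isTRUE(params$settings$blanking_period_active)) {
    abort("run_microsim covers base-case dynamics; disable the blanking period.",
          class = "afcem_validation_error")
  }
  set.seed(as.integer(seed))
  n <- as.integer(n_walkers)
  s <- params$settings
  n_tree <- round(s$tree_horizon / s$cycle_length)
  n_markov <- round(s$horizon / s$cycle_length)
  n_cycles <- n_tree + n_markov
  batch <- rep_len(seq_len(n_batches), n)

  rows_tree <- build_survivor_rows(params, arm, progression = FALSE)
  rows_markov <- build_survivor_rows(params, arm, progression = TRUE)
  # cumulative transition probabilities per living state
  cum_rows <- function(rows) lapply(1:13, function(i) cumsum(rows$P[i, ]))
  cum_tree <- cum_rows(rows_tree)
  cum_markov <- cum_rows(rows_markov)
  sev_split <- params$risks$stroke$severity_split
  nyha_split <- params$risks$hf$nyha_split
  groups <- state_group_of()[1:13]
  pc <- pricing_constants(params, arm)
  state_k <- state_k_of()

  # entry
  state <- integer(n)
  if (arm == "cryoablation") {
    state <- ifelse(runif(n) < params$risks$ablation_success,
                    IDX_NSR[1], IDX_ST[1])
  } else {
    af <- params$demographics$initial_af_fraction
    state <- ifelse(runif(n) < af, IDX_ST[1], IDX_NSR[1])
  }
  stroke_flag <- integer(n) # 0 none, 1..3 severity
  hf_flag <- logical(n)

  occ_counts <- matrix(0, n_cycles + 1, 14)
  occ_counts[1, ] <- tabulate(state, 14)
  ev_names <- c("strokes_non_disabling", "strokes_moderate", "strokes_severe",
                "hf_onsets", "reablations", "deaths")
  ev_batch <- matrix(0, n_batches, length(ev_names),
                     dimnames = list(NULL, ev_names))
  group_years <- matrix(0, n_batches, 5,
                        dimnames = list(NULL, STATE_GROUPS))
  cost_batch <- numeric(n_batches)
  qaly_batch <- numeric(n_batches)

  # entry procedure cost (cryoablation arm), undiscounted = discounted at t=0
  if (arm == "cryoablation") {
    cost_batch <- cost_batch + tabulate(batch, n_batches) *
      params$costs$ablation_procedure / (n / n_batches)
  }

  for (cyc in seq_len(n_cycles)) {
    in_markov <- cyc > n_tree
    cum_P <- if (in_markov) cum_markov else cum_tree
    rows <- if (in_markov) rows_markov else rows_tree
    g_idx <- cyc - 1L
    age <- params$demographics$baseline_age + g_idx * s$cycle_length

    alive_idx <- which(state != IDX_DEAD)
    if (length(alive_idx) == 0) {
      occ_counts[(cyc + 1):(n_cycles + 1), IDX_DEAD] <- n
      break
    }
    st_alive <- state[alive_idx]

    # empirical per-state sequela composition
    occ_n <- tabulate(st_alive, 13)
    naive_n <- tabulate(st_alive[stroke_flag[alive_idx] == 0], 13)
    hffree_n <- tabulate(st_alive[!hf_flag[alive_idx]], 13)
    naive_frac <- ifelse(occ_n > 0, naive_n / pmax(occ_n, 1), 1)
    hf_prev <- ifelse(occ_n > 0, 1 - hffree_n / pmax(occ_n, 1), 0)

    d <- death_prob_vec(params, age, hf_prev, naive_frac)
    p_stroke_g <- vapply(c("nsr", "st", "lt", "permanent"),
                         stroke_cycle_probability, numeric(1),
                         age = age, params = params)
    p_hf_g <- vapply(c("nsr", "st", "lt", "permanent"),
                     hf_cycle_probability, numeric(1),
                     age = age, params = params)
    p_stroke <- p_stroke_g[groups]
    p_hf <- p_hf_g[groups]

    # per-batch accrual on start-of-cycle population
    bt <- batch[alive_idx]
    scale <- n_batches / n # to per-person units within each batch
    for (b in seq_len(n_batches)) {
      sel <- bt == b
      if (!any(sel)) next
      occ_b <- tabulate(st_alive[sel], 13) * scale
      stroked_b <- tabulate(st_alive[sel & stroke_flag[alive_idx] > 0], 13) * scale
      hf_b <- tabulate(st_alive[sel & hf_flag[alive_idx]], 13) * scale
      group_years[b, ] <- group_years[b, ] +
        s$cycle_length * vapply(STATE_GROUPS, function(g) {
          sum(occ_b[which(groups == g)])
        }, numeric(1))
      acc <- price_cycle(pc, occ_b, stroked_b, hf_b,
                         strokes_sev = c(0, 0, 0), ablations = 0,
                         blanked = 0, age = age, g_idx = g_idx)
      cost_batch[b] <- cost_batch[b] + acc[["cost_total"]]
      qaly_batch[b] <- qaly_batch[b] + acc[["qaly"]]
    }

    # stroke events among stroke-naive walkers
    eligible <- stroke_flag[alive_idx] == 0
    u <- runif(length(alive_idx))
    stroke_hit <- eligible & u < p_stroke[st_alive]
    if (any(stroke_hit)) {
      sev <- 1L + findInterval(runif(sum(stroke_hit)),
                               cumsum(sev_split)[1:2] + 1e-15)
      stroke_flag[alive_idx[stroke_hit]] <- sev
      sev_tab <- vapply(1:3, function(k) {
        tabulate(bt[stroke_hit][sev == k], n_batches)
      }, numeric(n_batches))
      ev_batch[, 1:3] <- ev_batch[, 1:3] + sev_tab
      # acute stroke costs and short-term decrements per batch
      for (b in seq_len(n_batches)) {
        sv <- sev[bt[stroke_hit] == b]
        if (length(sv)) {
          cost_batch[b] <- cost_batch[b] +
            sum(pc$stroke_acute[sv]) * scale *
            discount_weight_identity()
          qaly_batch[b] <- qaly_batch[b] -
            s$cycle_length * sum(pc$stroke_short_decr[sv]) * scale
        }
      }
    }

    # heart-failure onsets among HF-free walkers
    hf_hit <- !hf_flag[alive_idx] & runif(length(alive_idx)) < p_hf[st_alive]
    if (any(hf_hit)) {
      hf_flag[alive_idx[hf_hit]] <- TRUE
      ev_batch[, "hf_onsets"] <- ev_batch[, "hf_onsets"] +
        tabulate(bt[hf_hit], n_batches)
    }

    # death draw (state-level probability; mean-field contract)
    dies <- runif(length(alive_idx)) < d[st_alive]
    ev_batch[, "deaths"] <- ev_batch[, "deaths"] + tabulate(bt[dies], n_batches)
    state[alive_idx[dies]] <- IDX_DEAD

    # survivor transitions
    surv_idx <- alive_idx[!dies]
    st_surv <- state[surv_idx]
    new_state <- st_surv
    for (si in unique(st_surv)) {
      sel <- st_surv == si
      dest <- 1L + findInterval(runif(sum(sel)), cum_P[[si]][1:12] + 1e-15)
      new_state[sel] <- dest
    }
    # re-ablation events: moves from ST_k / LT_k to substate k+1
    from_k <- state_k[st_surv]
    to_k <- state_k[new_state]
    abl <- (st_surv %in% c(IDX_ST, IDX_LT)) & !is.na(to_k) &
      !is.na(from_k) & to_k == from_k + 1L
    if (any(abl)) {
      nab <- tabulate(batch[surv_idx][abl], n_batches)
      ev_batch[, "reablations"] <- ev_batch[, "reablations"] + nab
      cost_batch <- cost_batch + nab * scale * pc$ablation_cost
    }
    state[surv_idx] <- new_state
    occ_counts[cyc + 1, ] <- tabulate(state, 14)
  }

  per_batch_n <- n / n_batches
  batch_tbl <- tibble::as_tibble(ev_batch / per_batch_n) %>%
    dplyr::bind_cols(tibble::as_tibble(group_years)) %>%
    dplyr::mutate(cost = cost_batch, qaly = qaly_batch,
                  batch = seq_len(n_batches), .before = 1)
  ev_mean <- colMeans(ev_batch / per_batch_n)
  ev_se <- apply(ev_batch / per_batch_n, 2, sd) / sqrt(n_batches)
  list(
    occupancy = occ_counts / n,
    events = tibble::tibble(event = ev_names, mean = unname(ev_mean),
                            se = unname(ev_se)),
    batch = batch_tbl,
    n_cycles = n_cycles,
    n_walkers = n
  )
}

# Acute costs in the microsim accrue with the same time-zero convention as
# the engine (events priced undiscounted here; discounted totals are not
# part of the cross-check).
discount_weight_identity <- function() 1
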