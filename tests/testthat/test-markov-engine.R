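test_that("transition matrix structure: stochastic rows, absorbing death, no k decrease", {
  p <- af_parameters()
  for (arm in af_arms()) {
    M <- build_transition_matrix(p, arm, age = 60, hf_prevalence = 0.1)
    expect_equal(dim(M), c(14, 14))
    expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
    expect_true(all(M >= 0 & M <= 1))
    expect_identical(unname(M[14, ]), c(rep(0, 13), 1)) # death absorbing
    # permanent: no exit except death
    expect_identical(unname(M[13, 1:12]), rep(0, 12))
    # no direct NSR -> permanent jumps
    expect_identical(unname(M[1:4, 13]), rep(0, 4))
    # substate index never decreases
    ss <- state_space()
    for (i in 1:12) {
      for (j in 1:12) {
        if (ss$k[j] < ss$k[i]) expect_identical(M[i, j], 0)
      }
    }
  }
})

test_that("zero event probabilities and mortality give the identity matrix", {
  p <- zero_event_params()
  M <- build_transition_matrix(p, "aad", age = 60)
  expect_equal(M, diag(14), ignore_attr = TRUE)
})

test_that("no re-ablation once the cap of three total procedures is reached", {
  p <- af_parameters()
  ss <- state_space()
  # cryoablation: index procedure counts, so k = 2 already means 3 total
  M <- build_transition_matrix(p, "cryoablation", age = 60)
  for (k_max in 2:3) {
    from_st <- which(ss$state == paste0("st_", k_max))
    expect_identical(sum(M[from_st, grepl(paste0("_", k_max + 1, "$"),
                                          ss$state)]), 0)
  }
  # AAD arm may still ablate from k = 2 but not from k = 3: with
  # resolution switched off, any ST_3 -> NSR_3 flow could only be an
  # ablation, and there must be none
  p_nores <- param_set(p, "risks.resolution", c(cryoablation = 0, aad = 0))
  M2 <- build_transition_matrix(p_nores, "aad", age = 60)
  expect_gt(M2[ss$state == "st_2", ss$state == "nsr_3"], 0)
  expect_identical(unname(M2[ss$state == "st_3", ss$state == "nsr_3"]), 0)
})

test_that("degenerate allocations propagate trivially", {
  p <- af_parameters()
  # all mass dead: zero accruals, occupancy constant
  alloc <- run_decision_tree(p, "aad")
  alloc$occupancy <- c(rep(0, 13), 1)
  alloc$naive <- rep(0, 13)
  alloc$hffree <- rep(0, 13)
  tr <- run_markov(p, alloc, "aad")
  expect_identical(sum(tr$trace$cost_total), 0)
  expect_identical(sum(tr$trace$qaly), 0)
  expect_true(all(tr$occupancy[, 14] == 1))

  # identity dynamics: occupancy constant over all cycles
  p0 <- zero_event_params()
  alloc0 <- run_decision_tree(p0, "aad")
  tr0 <- run_markov(p0, alloc0, "aad")
  expect_true(all(apply(tr0$occupancy, 2, function(col) {
    max(abs(col - col[1]))
  }) < 1e-12))
})

test_that("occupancy conservation and absorbing death hold for random draws", {
  base <- af_parameters()
  for (seed in 1:6) {
    set.seed(seed)
    p <- draw_parameter_set(base)
    for (arm in af_arms()) {
      alloc <- run_decision_tree(p, arm, validate = FALSE)
      tr <- run_markov(p, alloc, arm)
      occ <- full_occupancy(alloc, tr)
      expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
      expect_true(all(occ >= -1e-12))
      expect_true(all(diff(occ[, 14]) >= -1e-12)) # dead monotone
      expect_true(all(diff(tr$occupancy[, 14]) >= -1e-12))
    }
  }
})

test_that("raising the recurrence RR increases total time in AF states", {
  p <- af_parameters()
  af_years <- vapply(c(0.8, 1.0, 1.3, 1.7), function(mult) {
    pm <- param_set(p, "risks.rr_recurrence_by_count",
                    pmin(5, p$risks$rr_recurrence_by_count * mult))
    alloc <- run_decision_tree(pm, "cryoablation", validate = FALSE)
    tr <- run_markov(pm, alloc, "cryoablation")
    tis <- time_in_states(tr)
    sum(tis$years[tis$group %in% c("st", "lt", "permanent")])
  }, numeric(1))
  expect_true(all(diff(af_years) > 0))
})

test_that("time in states pools substates and conserves the horizon", {
  p <- zero_event_params()
  alloc <- run_decision_tree(p, "aad") # all mass stays in ST_0
  tis_tree <- time_in_states(list(occupancy = alloc$occupancy_history))
  expect_equal(tis_tree$years[tis_tree$group == "st"], 1.0)

  tr <- run_markov(p, alloc, "aad")
  tis <- time_in_states(tr)
  expect_equal(sum(tis$years), 40)
  expect_equal(tis$years[tis$group == "st"], 40)

  pbase <- af_parameters()
  alloc <- run_decision_tree(pbase, "cryoablation")
  tr <- run_markov(pbase, alloc, "cryoablation")
  tis <- time_in_states(tr)
  expect_equal(sum(tis$years), 40) # living + dead years = horizon
})

test_that("re-ablation counts start at zero, rise with the rate, stay capped", {
  p0 <- zero_event_params()
  alloc <- run_decision_tree(p0, "cryoablation")
  tr <- run_markov(p0, alloc, "cryoablation")
  expect_identical(lifetime_ablations(alloc, tr)$reablations, c(0, 0))

  p <- af_parameters()
  totals <- vapply(c(0.02, 0.05, 0.09), function(rate) {
    pm <- param_set(p, "risks.reablation.aad",
                    c(st = rate, lt = rate / 2))
    alloc <- run_decision_tree(pm, "aad", validate = FALSE)
    tr <- run_markov(pm, alloc, "aad")
    la <- lifetime_ablations(alloc, tr)
    expect_gte(la$reablations[2], la$reablations[1])
    la$reablations[2]
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
  expect_true(all(totals < 3))
})

test_that("cohort engine matches an individual-level microsimulation", {
  p <- af_parameters()
  arm <- "cryoablation"
  alloc <- run_decision_tree(p, arm)
  tr <- run_markov(p, alloc, arm)
  ms <- run_microsim(p, arm, n_walkers = 2e4, seed = 2024)
  cohort_occ <- full_occupancy(alloc, tr)
  groups <- state_space()$group
  for (cyc in c(5, 45, 165)) {
    co <- tapply(cohort_occ[cyc, ], groups, sum)
    mo <- tapply(ms$occupancy[cyc, ], groups, sum)
    se <- sqrt(pmax(co * (1 - co), 1e-8) / ms$n_walkers)
    expect_lt(max(abs(mo - co) / se), 4)
  }
  sc <- c("strokes_non_disabling", "strokes_moderate", "strokes_severe")
  cohort_strokes <- sum(as.matrix(alloc$trace[, sc])) +
    sum(as.matrix(tr$trace[, sc]))
  ms_strokes <- sum(ms$events$mean[1:3])
  expect_lt(abs(ms_strokes - cohort_strokes) / sqrt(sum(ms$events$se[1:3]^2)), 4)
})
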