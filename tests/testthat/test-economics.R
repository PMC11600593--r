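test_that("discount factors follow (1+r)^(-t/4) from model entry", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(4, 0.03), 1 / 1.03)
  expect_equal(discount_factor(4, 0.03), 0.970874, tolerance = 1e-6)
  expect_identical(discount_factor(160, 0.03), 1.03^-40)
  expect_equal(discount_factor(160, 0.03), 0.306557, tolerance = 1e-6)
  expect_identical(discount_factor(37, 0), 1)
  expect_error(discount_factor(1, -0.01))
})

test_that("cycle accrual prices occupancy, events and sequelae", {
  p <- af_parameters()
  # flat utility norm so the expected QALY is exact arithmetic
  p <- param_set(p, "utilities.norm_at_ref", c(male = 0.85, female = 0.85))
  p <- param_set(p, "utilities.norm_slope_per_year", 0)

  dead <- c(rep(0, 13), 1)
  acc <- accrue_cycle(dead, list(), p, "cryoablation")
  expect_true(all(as.numeric(acc) == 0))

  # one person-cycle in ST_0: QALY = 0.25 * (0.85 - 0.08)
  occ <- numeric(14); occ[5] <- 1
  acc <- accrue_cycle(occ, list(), p, "cryoablation")
  expect_equal(acc$qaly, 0.25 * (0.85 - 0.08))
  expect_equal(acc$life_years, 0.25)

  # pharmacy per person-cycle differs by arm: 69 vs 89
  expect_equal(accrue_cycle(occ, list(), p, "cryoablation")$cost_pharma, 69)
  expect_equal(accrue_cycle(occ, list(), p, "aad")$cost_pharma, 89)

  # an ablation event charges the procedure cost under re-ablations
  acc <- accrue_cycle(occ, list(ablations = 0.5), p, "aad")
  expect_equal(acc$cost_reablation, 0.5 * 8121)

  # acute stroke severity costs and the long-term sequela cost
  acc <- accrue_cycle(occ, list(strokes = c(0.01, 0.01, 0.01)), p, "aad",
                      stroke_mass = c(0.1, 0.1, 0.1))
  expect_equal(acc$cost_ae,
               0.01 * (1204 + 2864 + 5168) + 0.3 * 391)

  # discounting: cycle 4 at 3% is one year back
  acc0 <- accrue_cycle(occ, list(), p, "aad", cycle_index = 0)
  acc4 <- accrue_cycle(occ, list(), p, "aad", cycle_index = 4)
  expect_equal(acc4$cost_total_disc, acc0$cost_total * (1 / 1.03))
  expect_equal(acc4$qaly_disc, acc4$qaly / 1.03)
})

test_that("ICER handles dominance quadrants and zero effect", {
  expect_identical(compute_icer(-100, 0.1)$label, "dominant")
  expect_identical(compute_icer(100, -0.1)$label, "dominated")
  expect_identical(compute_icer(0, 0)$label, "undefined")
  expect_true(is.na(compute_icer(0, 0)$icer))
  r <- compute_icer(360, 0.16)
  expect_identical(r$label, "none")
  expect_equal(r$icer, 2250)
})

test_that("NMB is linear and algebraically consistent with the ICER", {
  expect_identical(compute_nmb(0, 0, 35000), 0)
  expect_equal(compute_nmb(191, 0.18, 35000), 6109)
  set.seed(42)
  dc <- runif(2000, -5000, 5000)
  de <- runif(2000, 1e-6, 0.5)
  wtp <- runif(2000, 0, 1e5)
  nmb <- compute_nmb(dc, de, wtp)
  icer <- dc / de
  expect_identical(nmb > 0, icer < wtp)
})

test_that("event metrics reproduce NNT and cost-per-event arithmetic", {
  m <- event_metrics(0.261, 0.275, 360, "stroke")
  expect_identical(m$nnt, 72)
  expect_equal(round(100 * m$relative_difference, 1), -5.1)
  expect_equal(m$cost_per_event_avoided, 360 / 0.014)

  same <- event_metrics(0.2, 0.2, 100)
  expect_true(is.na(same$nnt))
  expect_true(is.na(same$cost_per_event_avoided))

  # treatment arm with more events: cost per event avoided goes negative
  worse <- event_metrics(0.25, 0.2, 100)
  expect_lt(worse$cost_per_event_avoided, 0)
})

test_that("per-arm breakdown bookkeeping closes exactly", {
  p <- af_parameters()
  for (arm in af_arms()) {
    alloc <- run_decision_tree(p, arm)
    tr <- run_markov(p, alloc, arm)
    s <- summarize_arm(alloc, tr)
    cats <- c("initial_procedure", "reablations", "healthcare_contacts",
              "pharmaceuticals", "adverse_events")
    for (col in c("undiscounted", "discounted")) {
      expect_equal(sum(s[[col]][s$component %in% cats]),
                   s[[col]][s$component == "total_cost"], tolerance = 1e-9)
    }
    # discounted <= undiscounted, QALYs <= life years
    expect_true(all(s$discounted <= s$undiscounted + 1e-9))
    expect_lt(s$discounted[s$component == "qalys"],
              s$discounted[s$component == "life_years"])
  }

  # zero-cost parameters give a zero total
  p0 <- af_parameters()
  for (path in grep("^costs", param_paths(p0), value = TRUE)) {
    p0 <- param_set(p0, path, 0)
  }
  alloc <- run_decision_tree(p0, "cryoablation")
  tr <- run_markov(p0, alloc, "cryoablation")
  s <- summarize_arm(alloc, tr)
  expect_identical(s$undiscounted[s$component == "total_cost"], 0)
})

test_that("discounting equals the undiscounted totals only at rate zero", {
  p <- af_parameters()
  p0 <- param_set(p, "settings.discount_rate_costs", 0)
  p0 <- param_set(p0, "settings.discount_rate_effects", 0)
  cea <- run_cea(p0)
  b <- cea$breakdown
  expect_equal(b$discounted_cryoablation, b$undiscounted_cryoablation,
               tolerance = 1e-12)
  cea3 <- run_cea(p)
  b3 <- cea3$breakdown
  expect_true(b3$discounted_aad[b3$component == "total_cost"] <
                b3$undiscounted_aad[b3$component == "total_cost"])
})
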