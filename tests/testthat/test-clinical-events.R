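test_that("annual-to-cycle conversion follows the complement-power rule", {
  expect_identical(annual_to_cycle_prob(0), 0)
  expect_identical(annual_to_cycle_prob(1), 1)
  expect_equal(annual_to_cycle_prob(0.10), 1 - 0.9^0.25)
  expect_equal(annual_to_cycle_prob(0.10), 0.025996, tolerance = 1e-4)
  expect_error(annual_to_cycle_prob(1.2), class = "afcem_validation_error")
  expect_error(annual_to_cycle_prob(-0.1), class = "afcem_validation_error")

  # compounding four cycles recovers the annual probability; monotone
  grid <- seq(0, 1, by = 0.01)
  pc <- annual_to_cycle_prob(grid)
  expect_lt(max(abs(cycle_to_annual_prob(pc) - grid)), 1e-12)
  expect_true(all(diff(pc) > 0))
  expect_true(all(pc >= 0 & pc <= 1))
})

test_that("CHA2DS2-VASc gains its age points at 65 and 75", {
  expect_identical(cha2ds2vasc_at_age(c(57.5, 64.9, 65, 74.9, 75, 90),
                                      baseline = 1),
                   c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(cha2ds2vasc_at_age(80, baseline = 8), 9L) # capped
})

test_that("stroke probability combines score lookup, state RR and conversion", {
  p <- af_parameters()
  p0 <- param_set(p, "risks.stroke.rr_by_state.nsr", 0)
  expect_identical(stroke_cycle_probability("nsr", 60, p0), 0)

  # neutral RR reduces to the converted score incidence
  q <- p$risks$stroke$annual_incidence_by_score[[2]] # score 1 at age 60
  expect_equal(stroke_cycle_probability("nsr", 60, p), annual_to_cycle_prob(q))

  # age crossing 65 moves the score lookup up a row
  q2 <- p$risks$stroke$annual_incidence_by_score[[3]]
  expect_equal(stroke_cycle_probability("nsr", 66, p), annual_to_cycle_prob(q2))

  # hazard-scale approximate proportionality at small rates
  p_small <- param_set(p, "risks.stroke.annual_incidence_by_score",
                       rep(0.001, 10))
  one <- stroke_cycle_probability("st", 60,
                                  param_set(p_small, "risks.stroke.rr_by_state.st", 1))
  two <- stroke_cycle_probability("st", 60,
                                  param_set(p_small, "risks.stroke.rr_by_state.st", 2))
  expect_equal(two / one, 2, tolerance = 0.01)

  # a truncated incidence table must raise a missing-band error
  p_short <- param_set(p, "risks.stroke.annual_incidence_by_score",
                       c(0.002, 0.006, 0.012))
  expect_error(stroke_cycle_probability("nsr", 80, p_short), "score")
})

test_that("stroke severity split conserves mass", {
  out <- split_stroke_severity(0.01, c(0.5, 0.3, 0.2))
  expect_equal(unname(out), c(0.005, 0.003, 0.002))
  expect_identical(unname(split_stroke_severity(0.4, c(1, 0, 0))),
                   c(0.4, 0, 0))
  for (mass in c(0, 1e-4, 0.3)) {
    expect_equal(sum(split_stroke_severity(mass, c(0.2, 0.5, 0.3))), mass)
  }
  expect_error(split_stroke_severity(0.1, c(0.5, 0.5)),
               class = "afcem_validation_error")
  expect_error(split_stroke_severity(0.1, c(0.7, 0.2, 0.2)),
               class = "afcem_validation_error")
})

test_that("heart-failure probability is age-banded with a permanent-state RR", {
  p <- af_parameters()
  p0 <- param_set(p, "risks.hf.annual_incidence", rep(0, 5))
  expect_identical(hf_cycle_probability("nsr", 60, p0), 0)

  # permanent-state RR scales the annual rate exactly before conversion
  p_a <- param_set(p, "risks.hf.rr_permanent", 1.0)
  p_b <- param_set(p, "risks.hf.rr_permanent", 1.1)
  qa <- cycle_to_annual_prob(hf_cycle_probability("permanent", 72, p_a))
  qb <- cycle_to_annual_prob(hf_cycle_probability("permanent", 72, p_b))
  expect_equal(qb / qa, 1.1, tolerance = 1e-12)

  # non-permanent states ignore the permanent RR
  expect_identical(hf_cycle_probability("st", 72, p_a),
                   hf_cycle_probability("st", 72, p_b))

  # quarterly probability never exceeds the annual one
  for (age in c(58, 65, 75, 85, 95)) {
    band <- findInterval(age, p$risks$hf$age_band_lower)
    expect_lte(hf_cycle_probability("nsr", age, p),
               p$risks$hf$annual_incidence[[band]])
  }
})

test_that("combined mortality adds hazards and conserves the life table", {
  p <- zero_event_params(q_mort = 0)
  expect_identical(combine_mortality(60, "nsr", p), 0)

  p4 <- zero_event_params(q_mort = 0.04)
  expect_equal(combine_mortality(60, "nsr", p4), 1 - 0.96^0.25)
  expect_lt(abs(combine_mortality(60, "nsr", p4) - 0.010152), 1e-5)

  # monotone non-decreasing in each hazard component, and at least the
  # largest single component
  base <- af_parameters()
  d_bg <- combine_mortality(70, "nsr", zero_event_params(0.04))
  d_all <- combine_mortality(70, "st", af_parameters(flat_life_table(0.04)),
                             hf_prevalence = 0.2)
  d_hf_only <- combine_mortality(70, "st",
                                 zero_event_params(0.0), hf_prevalence = 0.2)
  expect_gte(d_all, max(d_bg, d_hf_only))
  expect_gt(combine_mortality(70, "st", base, hf_prevalence = 0.3),
            combine_mortality(70, "st", base, hf_prevalence = 0.1))
  expect_gt(combine_mortality(70, "st", base, stroke_naive_fraction = 1),
            combine_mortality(70, "st", base, stroke_naive_fraction = 0.2))

  # sex weighting: with male q=0.1, female q=0 and weight 0.65 the
  # weighted annual probability is 0.065
  lt <- flat_life_table(0)
  lt$annual_mortality[lt$sex == "male"] <- 0.1
  psex <- zero_event_params()
  psex$life_table <- lt
  expect_equal(cycle_to_annual_prob(combine_mortality(60, "nsr", psex)),
               0.065, tolerance = 1e-12)
  expect_error(combine_mortality(200, "nsr", base), "cover age")
})

test_that("life-table CSV reader enforces its schema", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(flat_life_table(0.01), tmp)
  lt <- read_life_table(tmp)
  expect_s3_class(lt, "af_life_table")
  expect_equal(nrow(lt), 222)

  readr::write_csv(data.frame(age = 1, gender = "m", annual_mortality = 0.1),
                   tmp)
  expect_error(read_life_table(tmp), class = "afcem_format_error")
  readr::write_csv(data.frame(age = 1, sex = "male", annual_mortality = 1.5),
                   tmp)
  expect_error(read_life_table(tmp), class = "afcem_validation_error")
})

test_that("pure background mortality reproduces the closed-form survivor curve", {
  p <- zero_event_params(q_mort = 0.03)
  alloc <- run_decision_tree(p, "aad")
  tr <- run_markov(p, alloc, "aad")
  occ <- full_occupancy(alloc, tr)
  surv <- 1 - occ[, 14]
  q_cycle <- 1 - 0.97^0.25
  expected <- (1 - q_cycle)^(0:(nrow(occ) - 1))
  expect_lt(max(abs(surv - expected)), 1e-9)
})
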