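test_that("packaged configuration carries the published base-case inputs", {
  cfg <- system.file("extdata", "config.json", package = "afcem")
  expect_true(nzchar(cfg))
  p <- load_parameters(cfg, quiet = TRUE)
  expect_identical(p$costs$ablation_procedure, 8121)
  expect_identical(unname(p$costs$pharma_per_cycle), c(69, 89))
  expect_identical(p$utilities$decrement_lt_persistent,
                   p$utilities$decrement_st_episodic)
  expect_identical(p$settings$cycle_length, 0.25)
  expect_identical(p$settings$max_total_ablations, 3)
})

test_that("serialisation round-trips every numeric field losslessly", {
  p <- af_parameters()
  tmp <- withr::local_tempfile(fileext = ".json")
  save_parameters(p, tmp)
  p2 <- load_parameters(tmp, quiet = TRUE)
  expect_identical(tibble::as_tibble(p)$value, tibble::as_tibble(p2)$value)
  expect_identical(p$life_table$annual_mortality,
                   p2$life_table$annual_mortality)
  # second round trip is a fixed point
  tmp2 <- withr::local_tempfile(fileext = ".json")
  save_parameters(p2, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("partial YAML configs merge onto defaults with a defaulting log", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("costs:", "  ablation_procedure: 9000"), tmp)
  expect_message(p <- load_parameters(tmp), "filled with packaged defaults")
  expect_identical(p$costs$ablation_procedure, 9000)
  expect_identical(p$costs$ed_visit, 32) # default retained
})

test_that("invalid inputs fail validation naming the offending field", {
  p <- af_parameters()
  bad <- param_set(p, "risks.recurrence.aad", 1.3)
  err <- expect_error(validate_parameters(bad), class = "afcem_validation_error")
  expect_match(conditionMessage(err), "risks.recurrence")

  bad <- param_set(p, "risks.stroke.severity_split",
                   c(non_disabling = 0.6, moderate = 0.3, severe = 0.2))
  expect_error(validate_parameters(bad), "severity_split")

  bad <- param_set(p, "settings.horizon", 40.1)
  expect_error(validate_parameters(bad), "multiple of cycle_length")

  short_lt <- af_parameters(life_table = {
    lt <- flat_life_table(0.01)
    lt[lt$age <= 80, ]
  })
  expect_error(validate_parameters(short_lt), "life_table")

  expect_error(load_parameters(withr::local_tempfile()), class = "afcem_io_error")
  bad_json <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad_json)
  expect_error(load_parameters(bad_json), class = "afcem_format_error")
})

test_that("parameter paths resolve list nodes, named and positional elements", {
  p <- af_parameters()
  expect_identical(param_get(p, "costs.stroke_acute.moderate"), 2864)
  expect_identical(param_get(p, "risks.rr_recurrence_by_count.2"), 0.85)
  p2 <- param_set(p, "costs.stroke_acute.moderate", 3000)
  expect_identical(param_get(p2, "costs.stroke_acute.moderate"), 3000)
  expect_identical(param_get(p, "costs.stroke_acute.moderate"), 2864) # pure
  expect_error(param_get(p, "costs.nonexistent"), class = "afcem_path_error")
  expect_error(param_set(p, "risks.bogus.path", 1), class = "afcem_path_error")
})

test_that("apply_scenario is pure and implements set/multiply/toggle", {
  p <- af_parameters()
  expect_identical(apply_scenario(p, scenario_spec("identity", list())), p)

  sc <- scenario_spec("stroke down 30%", list(
    list(path = "risks.stroke.annual_incidence_by_score", op = "multiply",
         value = 0.7)))
  p2 <- apply_scenario(p, sc)
  expect_equal(p2$risks$stroke$annual_incidence_by_score[4], 0.020 * 0.7)
  expect_equal(p$risks$stroke$annual_incidence_by_score[4], 0.020)

  sc <- scenario_spec("rr up", list(
    list(path = "risks.rr_recurrence_by_count", op = "multiply",
         value = 1.10, subset = 2:4)))
  p3 <- apply_scenario(param_set(p, "risks.rr_recurrence_by_count",
                                 c(1, 1.2, 1.2, 1.2)), sc)
  expect_equal(p3$risks$rr_recurrence_by_count, c(1, 1.32, 1.32, 1.32))

  # repeated application to the same base is identical
  expect_identical(apply_scenario(p, sc), apply_scenario(p, sc))

  expect_error(apply_scenario(p, scenario_spec("bad", list(
    list(path = "no.such.param", op = "set", value = 1)))),
    class = "afcem_path_error")
})

test_that("the seven built-in scenarios all validate against the base case", {
  p <- af_parameters()
  specs <- builtin_scenarios(p)
  expect_length(specs, 7)
  for (sc in specs) {
    p2 <- apply_scenario(p, sc)
    expect_s3_class(p2, "af_params")
  }
  blank <- apply_scenario(p, specs$blanking_period)
  expect_true(blank$settings$blanking_period_active)
  lit <- apply_scenario(p, specs$stroke_rr_literature)
  expect_equal(lit$risks$stroke$rr_by_state,
               p$risks$stroke$rr_by_state_literature)
  succ <- apply_scenario(p, specs$ablation_success_down_30)
  expect_equal(succ$risks$ablation_success, p$risks$ablation_success * 0.7)
})
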