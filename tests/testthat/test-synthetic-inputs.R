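test_that("Gompertz life tables match the closed form and are monotone", {
  lt <- generate_life_table(a = 2e-5, b = 0.1, max_age = 110)
  expect_equal(nrow(lt), 222)
  q80 <- lt$annual_mortality[lt$age == 80 & lt$sex == "male"]
  expect_equal(q80, 1 - exp(-2e-5 * exp(0.1 * 80)), tolerance = 1e-12)
  for (sx in c("male", "female")) {
    expect_true(all(diff(lt$annual_mortality[lt$sex == sx]) >= 0))
  }
  # b -> 0 limit: constant annual probability 1 - exp(-a)
  lt0 <- generate_life_table(a = 0.01, b = 1e-12)
  expect_equal(unique(round(lt0$annual_mortality, 10)),
               round(1 - exp(-0.01), 10))
  # sex-specific parameters produce distinct columns
  lt2 <- generate_life_table(a = c(male = 3e-5, female = 1e-5), b = 0.1)
  expect_gt(lt2$annual_mortality[lt2$age == 70 & lt2$sex == "male"],
            lt2$annual_mortality[lt2$age == 70 & lt2$sex == "female"])
  expect_error(synth_config(gompertz_b = -1), class = "afcem_validation_error")
})

test_that("generated parameter sets are deterministic and valid under fuzzing", {
  cfg <- synth_config(seed = 42)
  p1 <- generate_parameter_set(cfg)
  p2 <- generate_parameter_set(cfg)
  expect_identical(tibble::as_tibble(p1)$value, tibble::as_tibble(p2)$value)

  # arm ordering of the synthetic regime
  expect_lt(p1$risks$recurrence[["cryoablation"]], p1$risks$recurrence[["aad"]])
  expect_lt(p1$risks$reablation$cryoablation[["st"]],
            p1$risks$reablation$aad[["st"]])
  expect_true(all(diff(p1$risks$rr_recurrence_by_count) < 0))

  # null arm effect: identical clinical probabilities
  p_null <- generate_parameter_set(synth_config(seed = 1, recurrence_hr = 1))
  expect_equal(p_null$risks$recurrence[["cryoablation"]],
               p_null$risks$recurrence[["aad"]], tolerance = 1e-12)

  for (seed in seq_len(150)) {
    p <- generate_parameter_set(synth_config(seed = seed, jitter_sd = 0.25))
    expect_s3_class(validate_parameters(p), "af_params")
  }
})

test_that("coefficient blocks are lower-triangular and positive-definite", {
  blk <- generate_coefficient_block(4, 0, seed = 3)
  expect_true(all(abs(blk$chol[upper.tri(blk$chol)]) < 1e-12))
  expect_true(all(abs(blk$chol[lower.tri(blk$chol)]) < 1e-12)) # rho = 0: diagonal
  expect_identical(generate_coefficient_block(4, 0.3, seed = 9),
                   generate_coefficient_block(4, 0.3, seed = 9))
  for (seed in seq_len(60)) {
    blk <- generate_coefficient_block(5, 0.4, seed = seed)
    ev <- eigen(blk$chol %*% t(blk$chol), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > 0))
    expect_true(all(diag(blk$chol) > 0))
  }
})

test_that("null-effect configuration yields symmetric arms through the pipeline", {
  p <- generate_parameter_set(synth_config(seed = 4, recurrence_hr = 1,
                                           reablation_st_cryo = 0,
                                           reablation_st_aad = 0,
                                           resolution_cryo = 0.22,
                                           resolution_aad = 0.22))
  p <- param_set(p, "risks.rr_recurrence_by_count", rep(1, 4))
  p <- param_set(p, "risks.rr_resolution_by_count", rep(1, 4))
  p <- param_set(p, "risks.ablation_success", 0)
  cea <- run_cea(p)
  expect_equal(cea$delta_qaly, 0, tolerance = 1e-10)
  # incremental cost nets to the procedure cost plus the pharmacy delta
  aad_ly_disc_cycles <- cea$breakdown$discounted_aad[
    cea$breakdown$component == "life_years"] / 0.25
  expected <- 8121 + (69 - 89) * aad_ly_disc_cycles
  expect_equal(cea$delta_cost, expected, tolerance = 1e-8)
})

test_that("calibration is monotone-improving and recovers injected parameters", {
  p <- af_parameters()
  # already-optimal targets: input returned unchanged with zero objective
  current <- afcem:::calibration_summaries(p, "reablations_aad")
  res <- calibrate(p, targets = current, free = "risks.reablation.aad.st",
                   budget = 5)
  expect_identical(res$objective, 0)
  expect_identical(tibble::as_tibble(res$params)$value,
                   tibble::as_tibble(p)$value)

  # single free parameter, monotone target: recover a shifted value
  target <- afcem:::calibration_summaries(p, "st_years_aad")
  p_wrong <- param_set(p, "risks.recurrence.aad",
                       p$risks$recurrence[["aad"]] * 1.5)
  res <- calibrate(p_wrong, targets = target, free = "risks.recurrence.aad",
                   budget = 35, tolerance = 0.005)
  expect_lte(res$objective,
             afcem:::calibration_summaries(p_wrong, "st_years_aad") |>
               (\(x) sum(abs(x - target) / abs(target)))())
  recovered <- res$params$risks$recurrence[["aad"]]
  expect_equal(recovered, p$risks$recurrence[["aad"]], tolerance = 0.1)
})

test_that("synth_init writes a runnable configuration directory", {
  dir <- withr::local_tempdir()
  paths <- synth_init(dir, synth_config(seed = 77))
  expect_true(file.exists(paths[["config"]]))
  expect_true(file.exists(paths[["life_table"]]))
  p <- load_parameters(paths[["config"]], quiet = TRUE)
  expect_s3_class(validate_parameters(p), "af_params")
  expect_equal(max(p$life_table$age), 110)
})
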