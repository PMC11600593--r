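# Fixtures built in code: a flat life table and a parameter set with every
# clinical event switched off (useful for forced-path and conservation
# checks).

flat_life_table <- function(q = 0) {
  grid <- expand.grid(age = 0:110, sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  tibble::tibble(age = grid$age, sex = grid$sex, annual_mortality = q)
}

zero_event_params <- function(q_mort = 0) {
  p <- af_parameters(life_table = flat_life_table(q_mort))
  p <- param_set(p, "risks.recurrence", c(cryoablation = 0, aad = 0))
  p <- param_set(p, "risks.resolution", c(cryoablation = 0, aad = 0))
  p <- param_set(p, "risks.progression_st_lt", 0)
  p <- param_set(p, "risks.progression_lt_perm", 0)
  p <- param_set(p, "risks.reablation",
                 list(cryoablation = c(st = 0, lt = 0),
                      aad = c(st = 0, lt = 0)))
  p <- param_set(p, "risks.stroke.annual_incidence_by_score", rep(0, 10))
  p <- param_set(p, "risks.hf.annual_incidence", rep(0, 5))
  p <- param_set(p, "risks.hf.excess_annual_mortality", 0)
  p
}

# Combined tree + Markov occupancy history (165 x 14) for one arm.
full_occupancy <- function(allocation, trace) {
  n_tree <- nrow(allocation$occupancy_history) - 1L
  rbind(allocation$occupancy_history[seq_len(n_tree), , drop = FALSE],
        trace$occupancy)
}
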