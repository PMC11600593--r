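# Probabilistic sensitivity analysis: moment-matched gamma/beta
# distributions for cost, probability and utility parameters,
# Cholesky-correlated coefficient draws for the transition probabilities,
# the iteration loop and uncertainty summaries (credible intervals, CEAC,
# probabilities of cost-effectiveness and cost saving).

#' Moment-matched gamma parameters
#'
#' Cost parameters are sampled from gamma distributions fitted by moment
#' matching: `shape = mean^2 / se^2`, `scale = se^2 / mean`, so the fitted
#' distribution reproduces the configured mean and variance exactly.
#'
#' @param mean Distribution mean (> 0).
#' @param se Standard error (> 0).
#' @return List with `shape` and `scale`.
#' @examples
#' fit_gamma(8121, 812.1) # 10% uncertainty: shape 100
#' @export
fit_gamma <- function(mean, se) {
  if (mean <= 0 || se <= 0) {
    abort("fit_gamma requires mean > 0 and se > 0.",
          class = "afcem_validation_error")
  }
  list(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Moment-matched beta parameters
#'
#' Probability and utility parameters are sampled from beta distributions
#' fitted by moment matching: with `nu = mean (1 - mean) / se^2 - 1`,
#' `alpha = mean * nu` and `beta = (1 - mean) * nu`.
#'
#' @param mean Distribution mean in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @return List with `alpha` and `beta`.
#' @examples
#' fit_beta(0.5, 0.1) # alpha = beta = 12
#' @export
fit_beta <- function(mean, se) {
  if (mean <= 0 || mean >= 1) {
    abort("fit_beta requires 0 < mean < 1.", class = "afcem_validation_error")
  }
  if (se^2 >= mean * (1 - mean)) {
    abort(sprintf(
      "fit_beta: se^2 = %.4g violates the bound mean*(1-mean) = %.4g.",
      se^2, mean * (1 - mean)), class = "afcem_validation_error")
  }
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Correlated coefficient draw
#'
#' Draws `mean + L z` with independent standard-normal deviates `z` and a
#' lower-triangular Cholesky factor `L` of the coefficient covariance, the
#' mechanism used to propagate regression uncertainty.
#'
#' @param mean_vector Coefficient means.
#' @param cholesky_factor Lower-triangular factor, dimensions matching
#'   `mean_vector`.
#' @param z Optional standard-normal vector (drawn from the active RNG
#'   stream when omitted).
#' @return Numeric coefficient draw.
#' @export
sample_coefficients <- function(mean_vector, cholesky_factor, z = NULL) {
  d <- length(mean_vector)
  if (!is.matrix(cholesky_factor) || any(dim(cholesky_factor) != d)) {
    abort("cholesky_factor dimensions must match mean_vector.",
          class = "afcem_validation_error")
  }
  if (max(abs(cholesky_factor[upper.tri(cholesky_factor)])) > 1e-12) {
    abort("cholesky_factor must be lower-triangular.",
          class = "afcem_validation_error")
  }
  if (is.null(z)) z <- rnorm(d)
  as.numeric(mean_vector + cholesky_factor %*% z)
}

rdraw_gamma <- function(mean, se) {
  if (se == 0 || mean == 0) return(mean)
  f <- fit_gamma(mean, se)
  rgamma(1, shape = f$shape, scale = f$scale)
}

rdraw_beta <- function(mean, se) {
  if (se == 0 || mean == 0 || mean >= 1) return(mean)
  f <- fit_beta(mean, se)
  rbeta(1, f$alpha, f$beta)
}

# Parameter paths sampled by family. The 10% expert-uncertainty rule sets
# se = se_fraction * mean for every sampled scalar; the four base
# recurrence/resolution probabilities are drawn jointly on the logit scale
# through the Cholesky coefficient block instead.
psa_gamma_paths <- function(params) {
  c(param_paths(list(costs = params$costs), NULL),
    paste0("risks.rr_recurrence_by_count.", 2:4),
    paste0("risks.rr_resolution_by_count.", 2:4),
    paste0("risks.stroke.rr_by_state.", c("st", "lt", "permanent")),
    "risks.hf.rr_permanent",
    param_paths(list(risks = list(utilization = params$risks$utilization)), NULL))
}

psa_beta_paths <- function(params) {
  c("utilities.norm_at_ref.male", "utilities.norm_at_ref.female",
    "utilities.decrement_st_episodic", "utilities.decrement_permanent",
    paste0("utilities.stroke_short_decrement.", c("moderate", "severe")),
    paste0("utilities.stroke_long_decrement.", c("moderate", "severe")),
    paste0("utilities.hf_decrement.", c("nyha2", "nyha3", "nyha4")),
    "risks.progression_st_lt", "risks.progression_lt_perm",
    "risks.remission_lt_st", "risks.ablation_success",
    paste0("risks.reablation.cryoablation.", c("st", "lt")),
    paste0("risks.reablation.aad.", c("st", "lt")),
    paste0("risks.stroke.annual_incidence_by_score.", seq_along(params$risks$stroke$annual_incidence_by_score)),
    "risks.stroke.case_fatality",
    paste0("risks.hf.annual_incidence.", seq_along(params$risks$hf$annual_incidence)),
    "risks.hf.excess_annual_mortality")
}

# Vector-index paths like "risks.rr_recurrence_by_count.2": resolve the
# element by position when the final component is an integer.
psa_get <- function(params, path) {
  keys <- split_path(path)
  last <- keys[length(keys)]
  if (grepl("^[0-9]+$", last)) {
    vec <- param_get(params, paste(keys[-length(keys)], collapse = "."))
    vec[[as.integer(last)]]
  } else {
    param_get(params, path)
  }
}

psa_set <- function(params, path, value) {
  keys <- split_path(path)
  last <- keys[length(keys)]
  if (grepl("^[0-9]+$", last)) {
    parent <- paste(keys[-length(keys)], collapse = ".")
    vec <- param_get(params, parent)
    vec[[as.integer(last)]] <- value
    param_set(params, parent, vec)
  } else {
    param_set(params, path, value)
  }
}

#' Draw one parameter-set realisation
#'
#' Samples every uncertain parameter: gamma for costs, relative risks and
#' utilisation rates; beta for probabilities and utilities (severity and
#' NYHA splits are sampled component-wise and renormalised to the
#' simplex); and the base recurrence/resolution probabilities jointly on
#' the logit scale through the configured Cholesky coefficient block. The
#' LT-persistent utility decrement is kept tied to the ST-episodic one.
#' Standard errors follow the expert-uncertainty rule
#' `se = se_fraction * mean`; with `se_fraction = 0` and a zero-scale
#' block the draw is the deterministic parameter set.
#'
#' @param params Base `af_params`.
#' @param se_fraction Relative standard error applied to every sampled
#'   scalar (defaults to `params$psa$expert_se_fraction`).
#' @return A new `af_params` realisation (not re-validated; invariants are
#'   preserved by construction).
#' @export
draw_parameter_set <- function(params, se_fraction = NULL) {
  f <- se_fraction %||% params$psa$expert_se_fraction
  p <- params
  if (f > 0) {
    for (path in psa_gamma_paths(params)) {
      m <- as.numeric(psa_get(params, path))
      p <- psa_set(p, path, rdraw_gamma(m, f * m))
    }
    for (path in psa_beta_paths(params)) {
      m <- as.numeric(psa_get(params, path))
      p <- psa_set(p, path, rdraw_beta(m, f * m))
    }
    # splits: component-wise beta then renormalise to the simplex
    for (path in c("risks.stroke.severity_split", "risks.hf.nyha_split")) {
      split <- param_get(params, path)
      drawn <- vapply(split, function(m) rdraw_beta(m, f * m), numeric(1))
      p <- param_set(p, path, drawn / sum(drawn))
    }
    p <- param_set(p, "utilities.decrement_lt_persistent",
                   p$utilities$decrement_st_episodic)
  }
  block <- params$psa$coefficient_block
  if (!is.null(block) && (block$scale %||% 1) > 0) {
    means <- c(params$risks$recurrence, params$risks$resolution)
    draw <- plogis(sample_coefficients(qlogis(means),
                                       block$scale * block$chol))
    p <- param_set(p, "risks.recurrence",
                   c(cryoablation = draw[1], aad = draw[2]))
    p <- param_set(p, "risks.resolution",
                   c(cryoablation = draw[3], aad = draw[4]))
  }
  p
}

#' Run the probabilistic sensitivity analysis
#'
#' Repeats the full deterministic pipeline (tree + Markov, both arms)
#' under sampled parameter sets and summarises the uncertainty: means and
#' 95% credible intervals (empirical 2.5/97.5 percentiles) of per-arm and
#' incremental costs and QALYs, the mean ICER (ratio of mean increments),
#' the probability of cost-effectiveness at the configured
#' willingness-to-pay, the probability of cost saving, and the CEAC.
#' One root seed spawns per-iteration substreams, so a fixed seed gives a
#' bit-identical result.
#'
#' @param params Base `af_params`.
#' @param n_iterations Number of PSA iterations (default from
#'   `params$psa$n_iterations`, 5000 in the base configuration).
#' @param seed Root seed.
#' @param se_fraction Relative standard error for sampled scalars; see
#'   [draw_parameter_set()].
#' @param wtp_grid Willingness-to-pay grid for the CEAC (euro/QALY).
#' @return An `af_psa` object: `$iterations` (per-iteration tibble),
#'   `$summary` (one-row tibble, see [glance()]), `$ceac` (tibble of
#'   probability cost-effective by WTP) and `$seed`.
#' @export
run_psa <- function(params, n_iterations = NULL, seed = 1L,
                    se_fraction = NULL,
                    wtp_grid = seq(0, 100000, by = 2500)) {
  n <- as.integer(n_iterations %||% params$psa$n_iterations)
  stopifnot(n >= 1)
  validate_parameters(params)
  wtp <- params$settings$wtp
  set.seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(iter_seeds[i])
    p_i <- draw_parameter_set(params, se_fraction)
    cea <- tryCatch(
      run_cea(p_i, validate = FALSE),
      error = function(e) {
        abort(sprintf("PSA iteration %d (seed %d) failed: %s",
                      i, iter_seeds[i], conditionMessage(e)),
              class = "afcem_psa_error", parent = e)
      })
    g <- glance(cea)
    rows[[i]] <- tibble::tibble(
      iteration = i, seed = iter_seeds[i],
      cost_cryoablation = g$cost_cryoablation, cost_aad = g$cost_aad,
      qaly_cryoablation = g$qaly_cryoablation, qaly_aad = g$qaly_aad,
      delta_cost = g$delta_cost, delta_qaly = g$delta_qaly)
  }
  iterations <- dplyr::bind_rows(rows) %>%
    dplyr::mutate(nmb = compute_nmb(.data$delta_cost, .data$delta_qaly, wtp))

  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  mean_dc <- mean(iterations$delta_cost)
  mean_dq <- mean(iterations$delta_qaly)
  summary <- tibble::tibble(
    n_iterations = n,
    cost_cryoablation = mean(iterations$cost_cryoablation),
    cost_cryoablation_lo = ci(iterations$cost_cryoablation)[1],
    cost_cryoablation_hi = ci(iterations$cost_cryoablation)[2],
    cost_aad = mean(iterations$cost_aad),
    cost_aad_lo = ci(iterations$cost_aad)[1],
    cost_aad_hi = ci(iterations$cost_aad)[2],
    qaly_cryoablation = mean(iterations$qaly_cryoablation),
    qaly_cryoablation_lo = ci(iterations$qaly_cryoablation)[1],
    qaly_cryoablation_hi = ci(iterations$qaly_cryoablation)[2],
    qaly_aad = mean(iterations$qaly_aad),
    qaly_aad_lo = ci(iterations$qaly_aad)[1],
    qaly_aad_hi = ci(iterations$qaly_aad)[2],
    delta_cost = mean_dc,
    delta_cost_lo = ci(iterations$delta_cost)[1],
    delta_cost_hi = ci(iterations$delta_cost)[2],
    delta_qaly = mean_dq,
    delta_qaly_lo = ci(iterations$delta_qaly)[1],
    delta_qaly_hi = ci(iterations$delta_qaly)[2],
    icer = if (mean_dq != 0) mean_dc / mean_dq else NA_real_,
    prob_cost_effective = mean(iterations$nmb > 0),
    prob_cost_saving = mean(iterations$delta_cost < 0),
    wtp = wtp
  )
  res <- structure(list(iterations = iterations, summary = summary,
                        seed = as.integer(seed), wtp = wtp),
                   class = "af_psa")
  res$ceac <- ceac(res, wtp_grid)
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations with
#' positive net monetary benefit.
#'
#' @param psa_result An `af_psa` object.
#' @param wtp_grid Non-empty numeric grid of WTP values (euro/QALY).
#' @return A tibble with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa_result, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1)
  it <- psa_result$iterations
  tibble::tibble(
    wtp = unname(wtp_grid),
    prob_cost_effective = unname(vapply(wtp_grid, function(w) {
      mean(compute_nmb(it$delta_cost, it$delta_qaly, w) > 0)
    }, numeric(1)))
  )
}

#' @export
print.af_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<af_psa> %d iterations (seed %d)\n", s$n_iterations, x$seed))
  cat(sprintf("  delta cost %.0f (%.0f to %.0f), delta QALY %.3f (%.3f to %.3f)\n",
              s$delta_cost, s$delta_cost_lo, s$delta_cost_hi,
              s$delta_qaly, s$delta_qaly_lo, s$delta_qaly_hi))
  cat(sprintf("  mean ICER %.0f; P(cost-effective at %s) = %.1f%%; P(cost saving) = %.1f%%\n",
              s$icer, format(s$wtp, big.mark = ","),
              100 * s$prob_cost_effective, 100 * s$prob_cost_saving))
  invisible(x)
}

#' Per-iteration PSA results
#'
#' @param x An `af_psa` object.
#' @param ... Unused.
#' @return The per-iteration tibble (costs and QALYs per arm, increments,
#'   net monetary benefit).
#' @exportS3Method generics::tidy
#' @export
tidy.af_psa <- function(x, ...) x$iterations

#' One-row PSA summary
#'
#' @param x An `af_psa` object.
#' @param ... Unused.
#' @return One-row tibble with means, 95% credible intervals, mean ICER
#'   and the probabilities of cost-effectiveness and cost saving.
#' @exportS3Method generics::glance
#' @export
glance.af_psa <- function(x, ...) x$summary

#' Cost-effectiveness plane
#'
#' Scatter of the incremental cost/QALY cloud with the willingness-to-pay
#' threshold line.
#'
#' @param object An `af_psa` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.af_psa <- function(object, ...) {
  ggplot2::ggplot(object$iterations,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.af_psa
#' @param psa_result An `af_psa` object.
#' @export
plot_ceac <- function(psa_result) {
  ggplot2::ggplot(psa_result$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = psa_result$wtp, linetype = "dashed") +
    ggplot2::labs(x = "Willingness-to-pay (EUR/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
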