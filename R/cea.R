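# Deterministic cost-effectiveness pipeline: decision tree + Markov phase
# for both arms, category breakdown, incremental results, event-avoidance
# metrics and state-occupancy summaries.

#' Run the full deterministic cost-effectiveness analysis
#'
#' Evaluates both arms through the year-one decision tree and the 40-year
#' Markov phase, and assembles the deterministic results: per-arm cost
#' breakdown and QALY/life-year totals (discounted at the configured
#' rates), incremental cost and QALYs, ICER with dominance handling, net
#' monetary benefit at the configured willingness-to-pay, stroke and
#' heart-failure avoidance metrics, time spent in each rhythm state and
#' re-ablation counts.
#'
#' @param params An `af_params` object.
#' @param validate Validate `params` before running.
#' @return An object of class `af_cea`. Use [glance()] for the one-row
#'   summary, [tidy()] for the per-arm cost breakdown, `$additional` for
#'   the state-time/ablation/event table and [autoplot()] for figures.
#' @examples
#' \donttest{
#' cea <- run_cea(af_parameters())
#' glance(cea)
#' }
#' @export
run_cea <- function(params, validate = TRUE) {
  if (validate) validate_parameters(params)
  arms <- af_arms()
  runs <- lapply(setNames(arms, arms), function(arm) {
    allocation <- run_decision_tree(params, arm, validate = FALSE)
    trace <- run_markov(params, allocation, arm)
    list(allocation = allocation, trace = trace,
         summary = summarize_arm(allocation, trace))
  })

  breakdown <- purrr::imap(runs, function(r, arm) {
    dplyr::mutate(r$summary, arm = arm, .before = 1)
  }) %>%
    dplyr::bind_rows() %>%
    tidyr::pivot_wider(names_from = "arm",
                       values_from = c("undiscounted", "discounted")) %>%
    dplyr::mutate(
      incremental = .data$discounted_cryoablation - .data$discounted_aad)

  val <- function(component, col) {
    unname(breakdown[[col]][breakdown$component == component])
  }
  delta_cost <- val("total_cost", "incremental")
  delta_qaly <- val("qalys", "incremental")
  icer <- compute_icer(delta_cost, delta_qaly)
  nmb <- compute_nmb(delta_cost, delta_qaly, params$settings$wtp)

  events <- compute_lifetime_events(runs)
  metrics <- dplyr::bind_rows(
    event_metrics(events$stroke[["cryoablation"]], events$stroke[["aad"]],
                  delta_cost, "stroke"),
    event_metrics(events$hf[["cryoablation"]], events$hf[["aad"]],
                  delta_cost, "heart_failure"))

  state_time <- purrr::imap(runs, function(r, arm) {
    tree_t <- time_in_states(list(occupancy = r$allocation$occupancy_history),
                             params$settings$cycle_length)
    markov_t <- time_in_states(r$trace, params$settings$cycle_length)
    tibble::tibble(arm = arm, group = tree_t$group,
                   years = tree_t$years + markov_t$years)
  }) %>% dplyr::bind_rows()

  ablations <- purrr::imap(runs, function(r, arm) {
    dplyr::mutate(lifetime_ablations(r$allocation, r$trace), arm = arm,
                  .before = 1)
  }) %>% dplyr::bind_rows()

  structure(list(
    arms = runs,
    breakdown = breakdown,
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    delta_life_years = val("life_years", "incremental"),
    icer = icer$icer, dominance = icer$label, nmb = nmb,
    wtp = params$settings$wtp,
    event_metrics = metrics,
    state_time = state_time,
    ablations = ablations,
    params = params
  ), class = "af_cea")
}

# Lifetime expected events per person (tree + Markov).
compute_lifetime_events <- function(runs) {
  stroke_cols <- c("strokes_non_disabling", "strokes_moderate", "strokes_severe")
  one <- function(r, cols) {
    sum(as.matrix(r$allocation$trace[, cols])) + sum(as.matrix(r$trace$trace[, cols]))
  }
  list(stroke = purrr::map_dbl(runs, one, cols = stroke_cols),
       hf = purrr::map_dbl(runs, one, cols = "hf_onsets"))
}

#' @export
print.af_cea <- function(x, ...) {
  cat("<af_cea> deterministic cost-effectiveness results (per patient, discounted)\n")
  print(glance(x))
  invisible(x)
}

#' One-row summary of a deterministic CE analysis
#'
#' @param x An `af_cea` object.
#' @param ... Unused.
#' @return A one-row tibble: per-arm discounted cost and QALYs,
#'   incremental cost and QALYs, ICER (NA under dominance), dominance
#'   label and net monetary benefit.
#' @exportS3Method generics::glance
#' @export
glance.af_cea <- function(x, ...) {
  g <- function(component, col) {
    x$breakdown[[col]][x$breakdown$component == component]
  }
  tibble::tibble(
    cost_cryoablation = g("total_cost", "discounted_cryoablation"),
    cost_aad = g("total_cost", "discounted_aad"),
    qaly_cryoablation = g("qalys", "discounted_cryoablation"),
    qaly_aad = g("qalys", "discounted_aad"),
    delta_cost = x$delta_cost,
    delta_qaly = x$delta_qaly,
    icer = x$icer,
    dominance = x$dominance,
    nmb = x$nmb
  )
}

#' Tidy cost-component breakdown
#'
#' @param x An `af_cea` object.
#' @param ... Unused.
#' @return A tibble with one row per reporting component (five cost
#'   categories, total, QALYs, life-years) and discounted per-arm and
#'   incremental columns.
#' @exportS3Method generics::tidy
#' @export
tidy.af_cea <- function(x, ...) {
  dplyr::select(x$breakdown, "component",
                cryoablation = "discounted_cryoablation",
                aad = "discounted_aad", "incremental")
}

#' Plot the discounted cost breakdown per arm
#'
#' @param object An `af_cea` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.af_cea <- function(object, ...) {
  categories <- c("initial_procedure", "reablations", "healthcare_contacts",
                  "pharmaceuticals", "adverse_events")
  df <- tidy(object) %>%
    dplyr::filter(.data$component %in% categories) %>%
    tidyr::pivot_longer(c("cryoablation", "aad"),
                        names_to = "arm", values_to = "cost")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$cost,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Discounted cost per patient (EUR)",
                  fill = "Component") +
    ggplot2::theme_minimal()
}

#' Plot cohort occupancy over time
#'
#' Stacked-area view of the Markov-phase occupancy for one arm.
#'
#' @param cea An `af_cea` object.
#' @param arm Arm to plot.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(cea, arm = "cryoablation") {
  arm <- match_arm(arm)
  occ <- cea$arms[[arm]]$trace$occupancy
  df <- tibble::as_tibble(occ) %>%
    dplyr::mutate(cycle = dplyr::row_number() - 1L) %>%
    tidyr::pivot_longer(-"cycle", names_to = "state", values_to = "share") %>%
    dplyr::mutate(group = sub("_[0-3]$", "", .data$state)) %>%
    dplyr::group_by(.data$cycle, .data$group) %>%
    dplyr::summarise(share = sum(.data$share), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle * 0.25,
                                   y = .data$share,
                                   fill = .data$group)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Years since Markov entry", y = "Cohort share",
                  fill = "State", title = paste0(arm, " arm")) +
    ggplot2::theme_minimal()
}
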