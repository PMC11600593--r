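# Scenario analysis: named parameter overrides applied as pure
# transformations of a base parameter set.

#' Define a scenario
#'
#' A scenario is a named list of overrides, each addressing a parameter by
#' dot-path (see [param_get()]) with one of three transforms: `set`
#' (replace), `multiply` (scale, element-wise over an optional `subset` of
#' a vector parameter) or `toggle` (negate a logical flag).
#'
#' @param name Scenario label.
#' @param overrides List of overrides, each a list with elements `path`,
#'   `op` (`"set"`, `"multiply"` or `"toggle"`), optionally `value` and
#'   `subset` (integer indices into a vector parameter).
#' @return An object of class `af_scenario`.
#' @examples
#' sc <- scenario_spec("cheap_procedure",
#'   list(list(path = "costs.ablation_procedure", op = "set", value = 5000)))
#' apply_scenario(af_parameters(), sc)$costs$ablation_procedure
#' @export
scenario_spec <- function(name, overrides = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  for (ov in overrides) {
    if (!is.list(ov) || is.null(ov$path) || is.null(ov$op)) {
      abort("Each override needs at least 'path' and 'op'.",
            class = "afcem_validation_error")
    }
    arg_match0(ov$op, c("set", "multiply", "toggle"))
  }
  structure(list(name = name, overrides = overrides), class = "af_scenario")
}

#' @export
print.af_scenario <- function(x, ...) {
  cat(sprintf("<af_scenario> %s (%d override%s)\n", x$name,
              length(x$overrides), if (length(x$overrides) == 1) "" else "s"))
  for (ov in x$overrides) {
    cat(sprintf("  %s %s%s\n", ov$op, ov$path,
                if (!is.null(ov$value)) paste0(" ", paste(ov$value, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' Pure: the base set is never modified, repeated application to the same
#' base yields the identical result, and only the listed paths change.
#'
#' @param base An `af_params` object.
#' @param scenario An `af_scenario` from [scenario_spec()] or
#'   [builtin_scenarios()].
#' @param validate Re-validate the modified set (default `TRUE`).
#' @return A new, validated `af_params` object.
#' @export
apply_scenario <- function(base, scenario, validate = TRUE) {
  stopifnot(inherits(scenario, "af_scenario"))
  params <- base
  for (ov in scenario$overrides) {
    current <- param_get(params, ov$path)
    new_value <- switch(ov$op,
      set = {
        if (!is.null(ov$subset)) {
          current[ov$subset] <- ov$value
          current
        } else if (is.numeric(current) && length(current) > 1 &&
                   length(ov$value) == length(current)) {
          setNames(as.numeric(ov$value), names(current))
        } else {
          ov$value
        }
      },
      multiply = {
        if (!is.null(ov$subset)) {
          current[ov$subset] <- current[ov$subset] * ov$value
          current
        } else {
          current * ov$value
        }
      },
      toggle = {
        if (!is.logical(current)) {
          abort(sprintf("Cannot toggle non-logical parameter '%s'.", ov$path),
                class = "afcem_validation_error")
        }
        !current
      }
    )
    params <- param_set(params, ov$path, new_value)
  }
  if (validate) validate_parameters(params)
  params
}

#' Built-in scenario analyses
#'
#' The seven deterministic scenario analyses explored around the base case:
#' \enumerate{
#'   \item a 12-week post-ablation blanking period is implemented;
#'   \item the relative risks of AF recurrence by prior ablation count are
#'     increased by 10%;
#'   \item the relative risks of AF resolution by prior ablation count are
#'     increased by 10%;
#'   \item the ablation success rate is decreased proportionally by 30%;
#'   \item the incidence rate of stroke is decreased proportionally by 30%;
#'   \item the health-state-specific stroke relative risks are replaced by
#'     literature-sourced values (taken from the configuration field
#'     `risks.stroke.rr_by_state_literature`, a synthetic stand-in by
#'     default);
#'   \item the relative risk of developing heart failure in the permanent
#'     state is increased by 10%.
#' }
#'
#' @param params Base parameter set; only needed to source the
#'   literature stroke relative risks (scenario 6).
#' @return A named list of seven `af_scenario` objects.
#' @export
builtin_scenarios <- function(params = af_parameters()) {
  list(
    blanking_period = scenario_spec(
      "Blanking period implemented",
      list(list(path = "settings.blanking_period_active", op = "toggle"))),
    rr_recurrence_up_10 = scenario_spec(
      "RR of AF recurrence by prior ablations +10%",
      list(list(path = "risks.rr_recurrence_by_count", op = "multiply",
                value = 1.10, subset = 2:4))),
    rr_resolution_up_10 = scenario_spec(
      "RR of AF resolution by prior ablations +10%",
      list(list(path = "risks.rr_resolution_by_count", op = "multiply",
                value = 1.10, subset = 2:4))),
    ablation_success_down_30 = scenario_spec(
      "Ablation success rate -30% (proportionally)",
      list(list(path = "risks.ablation_success", op = "multiply", value = 0.70))),
    stroke_incidence_down_30 = scenario_spec(
      "Stroke incidence rate -30% (proportionally)",
      list(list(path = "risks.stroke.annual_incidence_by_score",
                op = "multiply", value = 0.70))),
    stroke_rr_literature = scenario_spec(
      "Health-state stroke RRs from published literature",
      list(list(path = "risks.stroke.rr_by_state", op = "set",
                value = param_get(params, "risks.stroke.rr_by_state_literature")))),
    hf_rr_permanent_up_10 = scenario_spec(
      "RR of heart failure in permanent state +10%",
      list(list(path = "risks.hf.rr_permanent", op = "multiply", value = 1.10)))
  )
}
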