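# Artifact readers/writers and the high-level run commands behind the
# command-line front-end (inst/cli/afcem.R): deterministic run, PSA and
# scenario table, each writing CSV/JSON outputs plus a run manifest.
#
# CSV dialect: UTF-8, comma-separated, '.' decimal, mandatory header,
# unformatted floats (machine round-trip safe).

write_result_csv <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a result CSV written by this package
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_result_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

# Run manifest: config hash, seeds, scenario, package version, timestamp
# and output list, written alongside every output set.
write_manifest <- function(dir, config_path, outputs, seed = NULL,
                           scenario = NULL) {
  manifest <- list(
    package = "afcem",
    version = as.character(utils::packageVersion("afcem")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_path %||% NA_character_,
    config_md5 = if (!is.null(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    } else NA_character_,
    seed = seed %||% NA_integer_,
    scenario = scenario %||% NA_character_,
    outputs = basename(outputs)
  )
  path <- file.path(dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

report_placeholders <- function(params) {
  inform(sprintf("Using %d synthetic placeholder parameter group(s): %s",
                 length(params$meta$placeholders),
                 paste(params$meta$placeholders, collapse = ", ")))
}

resolve_params <- function(config) {
  if (inherits(config, "af_params")) return(config)
  load_parameters(config)
}

#' Deterministic model run with file outputs
#'
#' Runs both arms deterministically (optionally under a named built-in
#' scenario) and writes: the cost-breakdown table, the additional-outcome
#' table (state time, life years, event rates, ablation counts), one trace
#' CSV per arm, and a run manifest.
#'
#' @param config Path to a JSON/YAML configuration, or an `af_params`
#'   object.
#' @param output_dir Output directory (created if needed).
#' @param scenario Optional name of a built-in scenario (see
#'   [builtin_scenarios()]).
#' @return Invisibly, the paths written.
#' @export
cem_run <- function(config, output_dir, scenario = NULL) {
  params <- resolve_params(config)
  report_placeholders(params)
  if (!is.null(scenario)) {
    specs <- builtin_scenarios(params)
    if (!scenario %in% names(specs)) {
      abort(sprintf("Unknown scenario '%s'. Valid names: %s", scenario,
                    paste(names(specs), collapse = ", ")),
            class = "afcem_usage_error")
    }
    params <- apply_scenario(params, specs[[scenario]])
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cea <- run_cea(params)

  paths <- character(0)
  p <- file.path(output_dir, "breakdown.csv")
  write_result_csv(cea$breakdown, p)
  paths <- c(paths, p)

  additional <- dplyr::bind_rows(
    tidyr::pivot_wider(cea$state_time, names_from = "arm",
                       values_from = "years") %>%
      dplyr::mutate(outcome = paste0("years_", .data$group)) %>%
      dplyr::select("outcome", "cryoablation", "aad"),
    tidyr::pivot_wider(cea$ablations, names_from = "arm",
                       values_from = "reablations") %>%
      dplyr::mutate(outcome = paste0("reablations_", gsub(" ", "_", .data$at))) %>%
      dplyr::select("outcome", "cryoablation", "aad"),
    cea$event_metrics %>%
      dplyr::transmute(outcome = paste0("lifetime_", .data$event, "_rate"),
                       cryoablation = .data$rate_treat, aad = .data$rate_comp)
  ) %>%
    dplyr::mutate(incremental = .data$cryoablation - .data$aad)
  p <- file.path(output_dir, "additional_outcomes.csv")
  write_result_csv(additional, p)
  paths <- c(paths, p)

  for (arm in af_arms()) {
    p <- file.path(output_dir, paste0("trace_", arm, ".csv"))
    write_result_csv(cea$arms[[arm]]$trace$trace, p)
    paths <- c(paths, p)
  }

  summary_path <- file.path(output_dir, "summary.json")
  jsonlite::write_json(c(as.list(glance(cea)),
                         list(event_metrics = cea$event_metrics)),
                       summary_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, summary_path)

  config_path <- if (is.character(config)) config else NULL
  write_manifest(output_dir, config_path, paths, scenario = scenario)
  invisible(c(paths, file.path(output_dir, "manifest.json")))
}

#' Probabilistic sensitivity analysis with file outputs
#'
#' Writes the cost-effectiveness plane CSV (per-iteration increments), the
#' CEAC CSV, a summary JSON (means, credible intervals, mean ICER,
#' probabilities of cost-effectiveness and cost saving) and the manifest.
#'
#' @inheritParams cem_run
#' @param n_iterations PSA iterations (default: configuration value, 5000
#'   in the base case).
#' @param seed Root seed.
#' @return Invisibly, the paths written.
#' @export
cem_psa <- function(config, output_dir, n_iterations = NULL, seed = 1L) {
  params <- resolve_params(config)
  report_placeholders(params)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  psa <- run_psa(params, n_iterations = n_iterations, seed = seed)

  paths <- character(0)
  p <- file.path(output_dir, "ce_plane.csv")
  write_result_csv(psa$iterations, p)
  paths <- c(paths, p)
  p <- file.path(output_dir, "ceac.csv")
  write_result_csv(psa$ceac, p)
  paths <- c(paths, p)
  p <- file.path(output_dir, "psa_summary.json")
  jsonlite::write_json(as.list(psa$summary), p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  config_path <- if (is.character(config)) config else NULL
  write_manifest(output_dir, config_path, paths, seed = seed)
  invisible(c(paths, file.path(output_dir, "manifest.json")))
}

#' Scenario analysis table with file outputs
#'
#' Runs the base case plus every built-in scenario deterministically and
#' writes one row each: incremental cost, incremental QALYs and the ICER
#' (`"Dominant"`/`"Dominated"` instead of a number where one arm
#' dominates).
#'
#' @inheritParams cem_run
#' @return Invisibly, the scenario table (also written to
#'   `scenarios.csv`).
#' @export
cem_scenarios <- function(config, output_dir) {
  params <- resolve_params(config)
  report_placeholders(params)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- builtin_scenarios(params)
  rows <- purrr::imap(c(list(base_case = NULL), specs), function(spec, id) {
    p <- if (is.null(spec)) params else apply_scenario(params, spec)
    g <- glance(run_cea(p, validate = FALSE))
    tibble::tibble(
      scenario = id,
      label = if (is.null(spec)) "Deterministic base case" else spec$name,
      delta_cost = g$delta_cost, delta_qaly = g$delta_qaly,
      icer = dplyr::case_when(
        g$dominance == "dominant" ~ "Dominant",
        g$dominance == "dominated" ~ "Dominated",
        g$dominance == "undefined" ~ "Undefined",
        .default = format(round(g$icer), scientific = FALSE, trim = TRUE)
      ))
  }) %>% dplyr::bind_rows()
  p <- file.path(output_dir, "scenarios.csv")
  write_result_csv(rows, p)
  config_path <- if (is.character(config)) config else NULL
  write_manifest(output_dir, config_path, p)
  invisible(rows)
}
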