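#' Run the full base-case analysis
#'
#' Executes both diagnostic strategies end-to-end — cohort classification,
#' cycle-0 allocation, Markov cohort run — and performs the incremental
#' analysis with the PET strategy as reference (the published sign
#' convention: the incremental columns describe CT/MRI relative to PET).
#' Optionally writes a results table (CSV and JSON), per-cycle traces, and a
#' reproducibility manifest to an output directory.
#'
#' @param config optional path to a YAML/JSON configuration for
#'   [load_parameters()]; mutually exclusive with `p`.
#' @param p a [model_parameters()] object (default: packaged base case).
#' @param life_table a [life_table()].
#' @param output_dir optional directory for result files (created if needed).
#' @param use_defaults passed to [load_parameters()].
#' @return A list of class `base_case_result`: `cea` (the [incremental_analysis()]
#'   with `a` = PET, `b` = CT/MRI), `traces` (per strategy), `table` (the
#'   results table as a data frame), and `manifest`.
#' @export
run_base_case <- function(config = NULL,
                          p = suppressWarnings(model_parameters()),
                          life_table = default_life_table(),
                          output_dir = NULL, use_defaults = FALSE) {
  if (!is.null(config)) p <- load_parameters(config, use_defaults = use_defaults)
  pet <- run_strategy(p, "pet", life_table)
  ctmri <- run_strategy(p, "ctmri", life_table)
  cea <- incremental_analysis(a = pet$result, b = ctmri$result)

  table <- data.frame(
    strategy = c(pet$result$label, ctmri$result$label),
    cumulative_discounted_cost = c(pet$result$cost, ctmri$result$cost),
    incremental_cost = c(NA_real_, cea$incremental_cost),
    cumulative_discounted_effectiveness = c(pet$result$effectiveness,
                                            ctmri$result$effectiveness),
    incremental_effectiveness = c(NA_real_, cea$incremental_effectiveness),
    net_monetary_benefit = c(pet$result$nmb, ctmri$result$nmb)
  )
  manifest <- run_manifest(config = config, p = p)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table, file.path(output_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(table = table,
           dominance = cea$dominance,
           dominant_strategy = if (cea$dominance == "dominated")
             pet$result$label else if (cea$dominance == "dominant")
               ctmri$result$label else NA_character_),
      file.path(output_dir, "results.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
    export_trace(pet$trace, file.path(output_dir, "trace_pet.csv"))
    export_trace(ctmri$trace, file.path(output_dir, "trace_ctmri.csv"))
    jsonlite::write_json(unclass(manifest),
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(list(cea = cea, traces = list(pet = pet$trace, ctmri = ctmri$trace),
                 table = table, manifest = manifest, parameters = p),
            class = "base_case_result")
}

#' @export
print.base_case_result <- function(x, ...) {
  print(x$cea)
  invisible(x)
}

#' Reproducibility manifest for a model run
#'
#' Records everything needed to reproduce a run byte-for-byte on an identical
#' numeric environment: the configuration source, the structural variant, the
#' life-table source, the seed (if any randomness was involved), the package
#' version and a timestamp.
#'
#' @param config configuration file path or `NULL`.
#' @param p the parameter set used.
#' @param life_table_source description of the life-table source.
#' @param seed RNG seed or `NA` for deterministic runs.
#' @return A named list of class `run_manifest`.
#' @export
run_manifest <- function(config = NULL, p, life_table_source = "packaged",
                         seed = NA_integer_) {
  structure(
    list(config = if (is.null(config)) "packaged base case" else
      normalizePath(config, mustWork = FALSE),
      structure_variant = unclass(p$structure),
      life_table_source = life_table_source,
      seed = seed,
      tool_version = as.character(utils::packageVersion("ipmncea")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "run_manifest"
  )
}

#' Write tornado data to CSV
#'
#' One row per parameter: bounds and the incremental cost/effectiveness of the
#' PET strategy versus CT/MRI at each bound.
#'
#' @param tornado a [one_way_dsa()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_tornado <- function(tornado, path) {
  utils::write.csv(as.data.frame(tornado), path, row.names = FALSE)
  invisible(path)
}

#' Tornado diagram
#'
#' Horizontal-bar display of a one-way deterministic sensitivity analysis,
#' for either the incremental-cost or incremental-effectiveness outcome
#' (PET strategy minus CT/MRI). Requires ggplot2.
#'
#' @param tornado a [one_way_dsa()] result.
#' @param outcome `"cost"` or `"effectiveness"`.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, outcome = c("cost", "effectiveness")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_tornado() requires the ggplot2 package", call. = FALSE)
  outcome <- match.arg(outcome)
  lo <- if (outcome == "cost") tornado$dcost_low else tornado$deff_low
  hi <- if (outcome == "cost") tornado$dcost_high else tornado$deff_high
  base <- if (outcome == "cost") attr(tornado, "base_dcost") else
    attr(tornado, "base_deff")
  d <- data.frame(parameter = tornado$parameter,
                  ymin = pmin(lo, hi), ymax = pmax(lo, hi))
  d$parameter <- factor(d$parameter,
                        levels = rev(d$parameter[order(d$ymax - d$ymin,
                                                       decreasing = TRUE)]))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$ymin, xmax = .data$ymax),
                            linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(
      x = if (outcome == "cost") "incremental cost, PET vs CT/MRI (USD)"
      else "incremental effectiveness, PET vs CT/MRI (QALY)",
      y = NULL) +
    ggplot2::theme_minimal()
}

#' Net-monetary-benefit curves over a parameter sweep
#'
#' Plots both strategies' NMB against the swept parameter value (the threshold
#' figure). Requires ggplot2.
#'
#' @param sweep a [threshold_sweep()] result.
#' @param parameter axis label for the swept parameter.
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep, parameter = "parameter value") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_threshold_sweep() requires the ggplot2 package", call. = FALSE)
  d <- data.frame(value = rep(sweep$value, 2L),
                  nmb = c(sweep$nmb_pet, sweep$nmb_ctmri),
                  strategy = rep(c("Add. FDG-PET/CT", "CT/MRI"),
                                 each = nrow(sweep)))
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$nmb,
                                  colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = parameter, y = "net monetary benefit (USD)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
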