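#' Validate a pipeline configuration
#'
#' Checks every field of a pipeline configuration against its invariants and
#' reports all problems at once. Defaults mirror the reference estimation
#' protocol: 10,000 posterior draws, burn-in 5,000 (iterative engine),
#' 95% equal-tailed credible intervals.
#'
#' @param config a named list (e.g. parsed from YAML/JSON) with fields:
#'   \code{mode} (\code{"simulate"}, \code{"records"} or
#'   \code{"cell_counts"}); \code{seed}; \code{S}; \code{engine}
#'   (\code{"conjugate"} or \code{"gibbs"}); \code{burn_in}; \code{chains};
#'   \code{output_dir}; and one section named after the mode. The
#'   \code{simulate} section holds \code{level}, \code{n_per_race},
#'   \code{prevalence} (lists \code{non_black}, \code{black} of four
#'   percentages), \code{missing_rates} and \code{outcomes} (per outcome
#'   either \code{cell_probs}, eight probabilities in \code{[x, m1, m2]}
#'   array order, or calibration targets \code{baseline}, \code{te_target},
#'   \code{cde_targets}). The \code{records} section holds \code{path},
#'   \code{units}, \code{sentinels}, \code{col_map}; the \code{cell_counts}
#'   section holds \code{path}.
#' @return The config with defaults filled in, invisibly classed
#'   \code{"pipeline_config"}; aggregated error otherwise.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  defaults <- list(seed = 1L, S = 10000, engine = "conjugate",
                   burn_in = 5000, chains = 2, output_dir = "pomediate_out")
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]

  modes <- c("simulate", "records", "cell_counts")
  declared <- intersect(modes, names(config))
  if (is.null(config$mode)) {
    if (length(declared) == 1L) config$mode <- declared
    else push(sprintf("exactly one input mode required; found sections: %s",
                      if (length(declared)) paste(declared, collapse = ", ") else "none"))
  } else if (!config$mode %in% modes) {
    push(sprintf("mode must be one of %s (got '%s')",
                 paste(modes, collapse = ", "), config$mode))
  } else if (length(setdiff(declared, config$mode)) > 0) {
    push(sprintf("config declares sections for more than one input mode: %s",
                 paste(declared, collapse = ", ")))
  }
  if (!is.numeric(config$S) || config$S < 100)
    push(sprintf("S must be a number >= 100 (got %s)", deparse(config$S)))
  if (!is.numeric(config$burn_in) || config$burn_in < 0)
    push("burn_in must be a non-negative number")
  if (!config$engine %in% c("conjugate", "gibbs"))
    push(sprintf("engine must be 'conjugate' or 'gibbs' (got '%s')", config$engine))
  if (!is.numeric(config$seed) || is.na(config$seed))
    push("seed must be an integer")

  if (identical(config$mode, "simulate")) {
    sim <- config$simulate
    if (is.null(sim)) push("mode 'simulate' requires a simulate: section")
    else {
      if (is.null(sim$level) || !sim$level %in% c("record", "cell"))
        push("simulate.level must be 'record' or 'cell'")
      if (is.null(sim$n_per_race) || !is.numeric(unlist(sim$n_per_race)))
        push("simulate.n_per_race must be one or two counts")
      if (is.null(sim$prevalence$non_black) || is.null(sim$prevalence$black))
        push("simulate.prevalence must list non_black and black percentages")
      if (is.null(sim$outcomes) || !length(sim$outcomes))
        push("simulate.outcomes must name at least one outcome")
      for (oc in names(sim$outcomes)) {
        oc_spec <- sim$outcomes[[oc]]
        if (is.null(oc_spec$cell_probs) && is.null(oc_spec$te_target))
          push(sprintf("outcome '%s' needs cell_probs or calibration targets", oc))
      }
    }
  }
  if (identical(config$mode, "records") &&
      (is.null(config$records$path)))
    push("mode 'records' requires records.path")
  if (identical(config$mode, "cell_counts") && is.null(config$cell_counts$path))
    push("mode 'cell_counts' requires cell_counts.path")

  if (length(errs))
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  class(config) <- "pipeline_config"
  invisible(config)
}

# Build the generator_config described by a validated simulate: section.
config_generator <- function(config) {
  sim <- config$simulate
  prev <- prevalence_table(rbind(as.numeric(unlist(sim$prevalence$non_black)),
                                 as.numeric(unlist(sim$prevalence$black))))
  probs <- lapply(sim$outcomes, function(oc_spec) {
    if (!is.null(oc_spec$cell_probs)) return(cell_probs(as.numeric(unlist(oc_spec$cell_probs))))
    calibrate_cell_probs(prev, te_target = oc_spec$te_target,
                         cde_targets = oc_spec$cde_targets,
                         baseline = if (is.null(oc_spec$baseline)) 0.05 else oc_spec$baseline)
  })
  mr <- if (is.null(sim$missing_rates)) 0 else unlist(sim$missing_rates)
  if (!length(mr)) mr <- 0
  generator_config(as.numeric(unlist(sim$n_per_race)), prev, probs,
                   missing_rates = mr, seed = config$seed, level = sim$level)
}

#' Run the full mediation pipeline
#'
#' Orchestrates generate/read, prepare, infer and report: obtains cell-count
#' tables from the configured input mode (simulated records, simulated cell
#' counts, a record-level CSV/TSV, or a pre-aggregated count table), fits
#' \code{\link{po_mediate}}, and writes the artifacts: a deletion log
#' (JSON), a mediator prevalence table (TSV), the disparity decomposition
#' report (TSV) and a run manifest (JSON) that suffices to reproduce every
#' output byte-for-byte.
#'
#' @param config a config list, a \code{"pipeline_config"}, or a path to a
#'   YAML file; see \code{\link{validate_config}}.
#' @param output_dir optional override of the configured output directory.
#' @param seed optional override of the configured master seed.
#' @return Invisibly, a list with the \code{fit}, the \code{prevalence}
#'   table, the \code{deletion_log} (or \code{NULL} for cell-level input)
#'   and the vector of written \code{artifacts}.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(unclass(config))
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(output_dir)) config$output_dir <- output_dir
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  art <- character(0)
  del_log <- NULL

  if (config$mode == "simulate" && config$simulate$level == "cell") {
    cells <- simulate_cell_counts(config_generator(config))
    prev <- prevalence_table(cells[[1L]])
  } else {
    records <- if (config$mode == "simulate") {
      simulate_records(config_generator(config))
    } else if (config$mode == "records") {
      rc <- config$records
      read_birth_records(rc$path,
                         col_map = unlist(rc$col_map),
                         units = if (is.null(rc$units)) "metric" else rc$units,
                         sentinels = if (is.null(rc$sentinels)) c(999, 9999, 99.9)
                         else as.numeric(unlist(rc$sentinels)))
    } else NULL
    if (!is.null(records)) {
      prepared <- filter_records(records)
      del_log <- prepared$log
      message(sprintf("deletion log: input=%d missing_outcome=%d missing_anthro=%d retained=%d",
                      del_log$input, del_log$missing_outcome,
                      del_log$missing_anthro, del_log$retained))
      oc_names <- if (config$mode == "simulate") names(config$simulate$outcomes)
      else outcome_fields()
      cells <- stats::setNames(lapply(oc_names, function(oc)
        aggregate_cells(prepared, oc)), oc_names)
    } else {
      cells <- read_cell_counts(config$cell_counts$path)
    }
    prev <- prevalence_table(cells[[1L]])
  }

  fit <- po_mediate(cells, S = config$S, seed = config$seed,
                    engine = config$engine, burn_in = config$burn_in,
                    chains = config$chains)
  report <- summary(fit)

  te_zero <- vapply(fit$outcomes, function(o)
    sum(vapply(o$pa, function(p) attr(p, "n_undefined"), numeric(1))), numeric(1))
  if (any(te_zero > 0))
    message("undefined PA draws (TE = 0) excluded: ",
            paste(sprintf("%s=%d", names(te_zero)[te_zero > 0],
                          te_zero[te_zero > 0]), collapse = ", "))

  p <- function(f) file.path(config$output_dir, f)
  if (!is.null(del_log)) {
    jsonlite::write_json(unclass(del_log), p("deletion_log.json"), auto_unbox = TRUE)
    art <- c(art, p("deletion_log.json"))
  }
  write_prevalence_tsv(prev, p("prevalence.tsv"))
  utils::write.table(as.data.frame(report), p("report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("pomediate")),
                   r_version = R.version.string,
                   te_zero_draws = as.list(te_zero))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  art <- c(art, p("prevalence.tsv"), p("report.tsv"), p("manifest.json"))

  invisible(list(fit = fit, prevalence = prev, deletion_log = del_log,
                 artifacts = art))
}
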