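#' Read a model configuration from YAML
#'
#' The configuration schema mirrors the constructors:
#' ```yaml
#' stage_values:
#'   utility: {A: 0.83, B: 0.34, C: 0.03}
#'   cycle_cost: {A: 22, B: 104, C: 134}
#'   intervention_cycle_cost: 290
#' model_spec:
#'   n_cycles: 6
#'   qaly_convention: per_cycle_sum
#'   discount_rate: 0
#'   death_probability_override: 0.005
#' thresholds:
#'   gdp_per_capita: 1658
#'   multipliers: [1, 3]
#'   exchange_rate: 270
#' calibration_targets:
#'   intervention: {qaly_units: 4.05, cost: 1979}
#'   comparator:   {qaly_units: 2.93, cost: 429}
#' psa: {n_iterations: 1000}
#' seed: 1
#' ```
#' Unknown top-level keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return List with `values` ([stage_values()]), `spec` ([model_spec()]),
#'   `thresholds` ([threshold_spec()]), `targets` (named list of
#'   [calibration_target()]s or `NULL`), `n_iterations`, `seed`.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("stage_values", "model_spec", "thresholds",
             "calibration_targets", "psa", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))

  sv <- raw$stage_values
  values <- stage_values(
    utility = unlist(sv$utility),
    cycle_cost = unlist(sv$cycle_cost),
    intervention_cycle_cost = sv$intervention_cycle_cost %||% 290
  )
  ms <- raw$model_spec %||% list()
  spec <- model_spec(
    n_cycles = ms$n_cycles %||% 6,
    qaly_convention = ms$qaly_convention %||% "per_cycle_sum",
    discount_rate = ms$discount_rate %||% 0,
    death_probability_override = ms$death_probability_override
  )
  th <- raw$thresholds %||% list()
  thresholds <- threshold_spec(
    gdp_per_capita = th$gdp_per_capita %||% 1658,
    multipliers = unlist(th$multipliers %||% c(1, 3)),
    exchange_rate = th$exchange_rate %||% 270
  )
  targets <- NULL
  if (!is.null(raw$calibration_targets)) {
    ct <- raw$calibration_targets
    targets <- list(
      intervention = calibration_target(
        "pharmacist", ct$intervention$qaly_units, ct$intervention$cost,
        has_intervention = TRUE,
        tolerance = ct$intervention$tolerance %||% 0.01),
      comparator = calibration_target(
        "usual_care", ct$comparator$qaly_units, ct$comparator$cost,
        has_intervention = FALSE,
        tolerance = ct$comparator$tolerance %||% 0.01)
    )
  }
  list(values = values, spec = spec, thresholds = thresholds,
       targets = targets,
       n_iterations = raw$psa$n_iterations %||% 1000L,
       seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CSV with a reproducibility header
#'
#' Prepends comment lines recording the package version, seed and a hash
#' of the writing call's inputs, then the CSV body. Two runs with the same
#' inputs produce byte-identical files.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header (may be `NA`).
#' @param note Optional extra header line.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, seed = NA, note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("pharmcea"))
  hash <- sum(utils::head(
    as.integer(charToRaw(paste(utils::capture.output(utils::str(df)),
                               collapse = ""))), 10000))
  writeLines(sprintf("# pharmcea %s | seed: %s | content-hash: %d",
                     version, as.character(seed), hash), con)
  if (!is.null(note)) writeLines(paste0("# ", note), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
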