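#' Two-strategy cost-effectiveness model bundle
#'
#' Packages everything needed to evaluate the intervention-versus-usual-care
#' comparison: both arm specifications, the run settings, and the shared
#' stage values. Sensitivity and probabilistic analyses perturb a bundle
#' and re-evaluate it.
#'
#' @param intervention,comparator [arm_spec()] objects.
#' @param spec A [model_spec()].
#' @param values A [stage_values()] shared by both arms.
#' @return Object of class `ce_bundle`.
#' @export
ce_bundle <- function(intervention, comparator, spec, values) {
  stopifnot(inherits(intervention, "arm_spec"),
            inherits(comparator, "arm_spec"),
            inherits(spec, "model_spec"), inherits(values, "stage_values"))
  structure(list(intervention = intervention, comparator = comparator,
                 spec = spec, values = values),
            class = "ce_bundle")
}

#' Evaluate both arms of a bundle
#' @param bundle A [ce_bundle()].
#' @return List with `intervention` and `comparator` [arm_outcome()]s.
#' @export
bundle_outcomes <- function(bundle) {
  stopifnot(inherits(bundle, "ce_bundle"))
  list(
    intervention = trace_outcome(
      run_cohort(bundle$intervention, bundle$spec, bundle$values)),
    comparator = trace_outcome(
      run_cohort(bundle$comparator, bundle$spec, bundle$values))
  )
}

#' ICER of a bundle
#' @param bundle A [ce_bundle()].
#' @return A `ce_result` (see [icer()]).
#' @export
bundle_icer <- function(bundle) {
  out <- bundle_outcomes(bundle)
  icer(out$intervention, out$comparator)
}

# Recognised perturbation targets and where each one lives in the bundle.
bundle_targets <- function() {
  c("utility_A", "utility_B", "utility_C",
    "cost_A", "cost_B", "cost_C", "intervention_cost")
}

#' Set a single model input inside a bundle
#'
#' Targets: `utility_A/B/C` (stage utilities, clipped to \[0, 1\]),
#' `cost_A/B/C` (per-cycle stage costs, USD), and `intervention_cost`
#' (per-cycle pharmacist cost, USD, intervention arm only).
#'
#' @param bundle A [ce_bundle()].
#' @param target One of [bundle_targets()] (internal enumeration above).
#' @param value New value.
#' @return The modified bundle.
#' @export
set_parameter <- function(bundle, target, value) {
  stopifnot(inherits(bundle, "ce_bundle"))
  if (!target %in% bundle_targets())
    stop(sprintf("unknown parameter target '%s'", target))
  v <- bundle$values
  if (startsWith(target, "utility_")) {
    st <- sub("utility_", "", target)
    v$utility[st] <- min(max(value, 0), 1)
  } else if (startsWith(target, "cost_")) {
    st <- sub("cost_", "", target)
    if (value < 0) stop("stage cost must be non-negative")
    v$cycle_cost[st] <- value
  } else {
    if (value < 0) stop("intervention cost must be non-negative")
    v$intervention_cycle_cost <- value
  }
  bundle$values <- v
  bundle
}

#' Read a single model input from a bundle
#' @inheritParams set_parameter
#' @return Current value of the target.
#' @export
get_parameter <- function(bundle, target) {
  stopifnot(inherits(bundle, "ce_bundle"))
  v <- bundle$values
  if (startsWith(target, "utility_")) v$utility[[sub("utility_", "", target)]]
  else if (startsWith(target, "cost_")) v$cycle_cost[[sub("cost_", "", target)]]
  else if (target == "intervention_cost") v$intervention_cycle_cost
  else stop(sprintf("unknown parameter target '%s'", target))
}
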