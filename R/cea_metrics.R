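#' Arm-level outcome pair
#'
#' @param name Arm label.
#' @param cost Total cost in USD (>= 0).
#' @param effect Total effectiveness in QALY-units (>= 0).
#' @return Object of class `arm_outcome`.
#' @export
arm_outcome <- function(name, cost, effect) {
  stopifnot(cost >= 0, effect >= 0)
  structure(list(name = name, cost = as.numeric(cost),
                 effect = as.numeric(effect)),
            class = "arm_outcome")
}

#' Outcomes of a cohort trace
#' @param trace A `cohort_trace`.
#' @return An [arm_outcome()].
#' @export
trace_outcome <- function(trace) {
  arm_outcome(trace$arm, trace$total_cost, trace$total_qaly_units)
}

#' Incremental cost-effectiveness ratio
#'
#' Computes the incremental cost and effect of the intervention relative
#' to the comparator and classifies the sign pattern. The ratio is
#' reported only where it is meaningful (both differences non-zero and
#' neither strategy dominant); sign patterns where one strategy is both
#' cheaper and more effective are labelled as dominance instead of
#' returning a misleading negative ratio.
#'
#' @param intervention,comparator [arm_outcome()] objects.
#' @return Object of class `ce_result`: `delta_cost`, `delta_effect`,
#'   `icer` (`NA` unless classification is `icer_defined`), and
#'   `classification` in `{icer_defined, intervention_dominant,
#'   intervention_dominated, equal_effect}`.
#' @examples
#' icer(arm_outcome("pharm", 1979, 4.05), arm_outcome("usual", 429, 2.93))
#' @export
icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "arm_outcome"),
            inherits(comparator, "arm_outcome"))
  dc <- intervention$cost - comparator$cost
  de <- intervention$effect - comparator$effect
  classification <-
    if (de == 0 && dc == 0) "equal_effect"
    else if (de == 0) if (dc < 0) "intervention_dominant" else "intervention_dominated"
    else if (de > 0 && dc <= 0) "intervention_dominant"
    else if (de < 0 && dc >= 0) "intervention_dominated"
    else "icer_defined"
  structure(
    list(intervention = intervention$name, comparator = comparator$name,
         delta_cost = dc, delta_effect = de,
         icer = if (classification == "icer_defined") dc / de else NA_real_,
         classification = classification),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost %.2f USD, dEffect %.4f QALY-units (%s)\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_effect,
              x$classification))
  if (!is.na(x$icer)) cat(sprintf("  ICER: %.1f USD per QALY-unit\n", x$icer))
  invisible(x)
}

#' Net monetary benefit of an arm
#'
#' `effect * wtp - cost`. The incremental NMB between two arms at the same
#' threshold equals `nmb(intervention, wtp) - nmb(comparator, wtp)`, and is
#' non-negative exactly when the ICER is at or below the threshold
#' (for positive incremental effect).
#'
#' @param arm An [arm_outcome()].
#' @param wtp Willingness-to-pay threshold in USD per QALY-unit (>= 0).
#' @return NMB in USD.
#' @examples
#' nmb(arm_outcome("pharm", 1979, 4.05), 1658)
#' @export
nmb <- function(arm, wtp) {
  stopifnot(inherits(arm, "arm_outcome"))
  if (any(wtp < 0)) stop("willingness-to-pay must be non-negative")
  arm$effect * wtp - arm$cost
}

#' Incremental net monetary benefit
#' @inheritParams nmb
#' @param intervention,comparator [arm_outcome()] objects.
#' @return Incremental NMB in USD.
#' @export
incremental_nmb <- function(intervention, comparator, wtp) {
  nmb(intervention, wtp) - nmb(comparator, wtp)
}

#' Willingness-to-pay threshold settings
#'
#' Defaults follow the Pakistani base case: GDP per capita 1658 USD (2022),
#' thresholds at 1x and 3x GDP per QALY gained, exchange rate 270 PKR/USD.
#'
#' @param gdp_per_capita USD.
#' @param multipliers Positive factors applied to GDP per capita.
#' @param exchange_rate PKR per USD.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(gdp_per_capita = 1658, multipliers = c(1, 3),
                           exchange_rate = 270) {
  stopifnot(gdp_per_capita > 0, all(multipliers > 0), exchange_rate > 0)
  structure(list(gdp_per_capita = gdp_per_capita,
                 multipliers = multipliers,
                 exchange_rate = exchange_rate),
            class = "threshold_spec")
}

#' GDP-multiple willingness-to-pay thresholds
#' @param spec A [threshold_spec()].
#' @return Numeric vector of thresholds in USD per QALY-unit.
#' @examples
#' wtp_thresholds(threshold_spec())  # 1658 and 4974
#' @export
wtp_thresholds <- function(spec = threshold_spec()) {
  stopifnot(inherits(spec, "threshold_spec"))
  spec$gdp_per_capita * spec$multipliers
}

#' Convert between USD and PKR
#'
#' USD is the canonical internal currency; PKR figures are derived output
#' at a flat exchange rate.
#'
#' @param amount Non-negative amount(s).
#' @param direction `"usd_to_pkr"` or `"pkr_to_usd"`.
#' @param exchange_rate PKR per USD (default 270).
#' @return Converted amount(s).
#' @export
convert_currency <- function(amount,
                             direction = c("usd_to_pkr", "pkr_to_usd"),
                             exchange_rate = 270) {
  direction <- match.arg(direction)
  if (any(amount < 0)) stop("amount must be non-negative")
  if (direction == "usd_to_pkr") amount * exchange_rate
  else amount / exchange_rate
}
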