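#' One-way sensitivity parameter
#'
#' @param name Display name.
#' @param base Base-case value.
#' @param low,high Bounds of the plausible range (`low <= base <= high`).
#' @param kind One of `"utility"`, `"cost"`, `"probability"`.
#' @param target Bundle target this parameter perturbs (see
#'   [set_parameter()]); defaults to `name`.
#' @return Object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, base, low, high,
                           kind = c("utility", "cost", "probability"),
                           target = name) {
  kind <- match.arg(kind)
  if (!(low <= base && base <= high)) stop("need low <= base <= high")
  if (kind == "utility") {
    low <- min(max(low, 0), 1); high <- min(max(high, 0), 1)
    base <- min(max(base, 0), 1)
  }
  structure(list(name = name, base = base, low = low, high = high,
                 kind = kind, target = target),
            class = "parameter_spec")
}

#' Default one-way parameter set
#'
#' Utilities and the intervention cost are varied by +/-20% of base
#' (utilities clipped at 1); stage costs use their plausible ranges,
#' which are also +/-20% of base.
#'
#' @param values A [stage_values()] giving the base-case inputs.
#' @return List of [parameter_spec()]s covering all seven model inputs.
#' @export
default_dsa_parameters <- function(values = stage_values()) {
  u <- values$utility; cc <- values$cycle_cost
  ic <- values$intervention_cycle_cost
  specs <- list(
    parameter_spec("utility_A", u[["A"]], 0.8 * u[["A"]],
                   min(1.2 * u[["A"]], 1), "utility"),
    parameter_spec("utility_B", u[["B"]], 0.8 * u[["B"]],
                   min(1.2 * u[["B"]], 1), "utility"),
    parameter_spec("utility_C", u[["C"]], 0.8 * u[["C"]],
                   min(1.2 * u[["C"]], 1), "utility"),
    parameter_spec("cost_A", cc[["A"]], 0.8 * cc[["A"]], 1.2 * cc[["A"]], "cost"),
    parameter_spec("cost_B", cc[["B"]], 0.8 * cc[["B"]], 1.2 * cc[["B"]], "cost"),
    parameter_spec("cost_C", cc[["C"]], 0.8 * cc[["C"]], 1.2 * cc[["C"]], "cost"),
    parameter_spec("intervention_cost", ic, 0.8 * ic, 1.2 * ic, "cost")
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs both arms with the parameter at its low and high bounds, all
#' other inputs at base. Endpoints where the comparison degenerates into
#' dominance are recorded by classification label with an `NA` ICER rather
#' than a number.
#'
#' @param bundle A [ce_bundle()] whose base case yields a defined ICER.
#' @param param A [parameter_spec()].
#' @return Object of class `tornado_entry`: parameter, icer_at_low,
#'   icer_at_high, classification at each endpoint, and
#'   `spread = |icer_at_high - icer_at_low|` (`NA` if either endpoint is
#'   not a ratio).
#' @export
one_way <- function(bundle, param) {
  stopifnot(inherits(bundle, "ce_bundle"), inherits(param, "parameter_spec"))
  at <- function(value) bundle_icer(set_parameter(bundle, param$target, value))
  lo <- at(param$low)
  hi <- at(param$high)
  structure(
    list(parameter = param$name, base = param$base,
         low = param$low, high = param$high,
         icer_at_low = lo$icer, icer_at_high = hi$icer,
         classification_low = lo$classification,
         classification_high = hi$classification,
         spread = if (is.na(lo$icer) || is.na(hi$icer)) NA_real_
                  else abs(hi$icer - lo$icer)),
    class = "tornado_entry"
  )
}

#' Order tornado entries by influence
#'
#' Stable sort by descending spread, ties broken alphabetically by
#' parameter name; entries with an undefined spread (a dominance endpoint)
#' sort last.
#'
#' @param entries List of `tornado_entry` objects (or the result of
#'   mapping [one_way()] over a parameter list).
#' @return data.frame with one row per parameter, ordered, columns
#'   parameter, base, low, high, icer_low, icer_high, spread.
#' @export
tornado <- function(entries) {
  if (length(entries) == 0L) stop("no tornado entries supplied")
  if (inherits(entries, "tornado_entry")) entries <- list(entries)
  df <- do.call(rbind, lapply(entries, function(e) {
    data.frame(parameter = e$parameter, base = e$base,
               low = e$low, high = e$high,
               icer_low = e$icer_at_low, icer_high = e$icer_at_high,
               spread = e$spread)
  }))
  ord <- order(is.na(df$spread), -ifelse(is.na(df$spread), -Inf, df$spread),
               df$parameter)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Solve for the parameter value at which the ICER crosses a threshold
#'
#' Bisection on `ICER(x) - wtp` over `bracket`, to an absolute tolerance
#' of `tol` on the parameter. Returns `NULL` when the sign does not change
#' over the bracket. The returned solution is re-evaluated and reported
#' with a convergence flag (`|ICER(x*) - wtp| <= 0.5` USD/QALY-unit).
#'
#' @param bundle A [ce_bundle()].
#' @param param A [parameter_spec()] naming the input to solve over.
#' @param wtp Threshold in USD per QALY-unit.
#' @param bracket Length-2 numeric search interval (defaults to
#'   `c(param$low, param$high)`).
#' @param tol Absolute tolerance on the parameter (default 1e-6).
#' @return `NULL` if no crossing, else a list with `parameter`, `wtp`,
#'   `crossing_value`, `icer_at_crossing`, `converged`.
#' @export
threshold_crossing <- function(bundle, param, wtp,
                               bracket = c(param$low, param$high),
                               tol = 1e-6) {
  stopifnot(inherits(bundle, "ce_bundle"), inherits(param, "parameter_spec"),
            length(bracket) == 2L, bracket[1] < bracket[2])
  f <- function(x) {
    r <- bundle_icer(set_parameter(bundle, param$target, x))
    if (is.na(r$icer))
      stop(sprintf("comparison degenerates to '%s' at %s = %.6g; shrink the bracket",
                   r$classification, param$name, x))
    r$icer - wtp
  }
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo == 0) { root <- bracket[1] }
  else if (fhi == 0) { root <- bracket[2] }
  else if (sign(flo) == sign(fhi)) return(NULL)
  else {
    lo <- bracket[1]; hi <- bracket[2]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    root <- (lo + hi) / 2
  }
  icer_at <- f(root) + wtp
  list(parameter = param$name, wtp = wtp, crossing_value = root,
       icer_at_crossing = icer_at,
       converged = abs(icer_at - wtp) <= 0.5)
}
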