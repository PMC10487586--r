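#' Base-case cost-effectiveness summary
#'
#' Runs both arms of a bundle and assembles the per-arm totals, the
#' incremental comparison, and net monetary benefit at each
#' willingness-to-pay threshold, in USD and PKR.
#'
#' @param bundle A [ce_bundle()].
#' @param thresholds A [threshold_spec()].
#' @return List with `arms` (data.frame: arm, cost_usd, cost_pkr, effect,
#'   one NMB column per threshold) and `incremental` (one-row data.frame:
#'   delta_cost_usd, delta_effect, icer_usd_per_qaly, icer_pkr_per_qaly,
#'   classification, incremental NMB per threshold).
#' @export
run_base_case <- function(bundle, thresholds = threshold_spec()) {
  out <- bundle_outcomes(bundle)
  wtps <- wtp_thresholds(thresholds)
  rate <- thresholds$exchange_rate
  arm_row <- function(a) {
    row <- data.frame(arm = a$name, cost_usd = a$cost,
                      cost_pkr = convert_currency(a$cost, exchange_rate = rate),
                      effect = a$effect)
    for (w in wtps) row[[sprintf("nmb_usd_at_%g", w)]] <- nmb(a, w)
    row
  }
  arms <- rbind(arm_row(out$intervention), arm_row(out$comparator))
  ce <- icer(out$intervention, out$comparator)
  inc <- data.frame(
    delta_cost_usd = ce$delta_cost,
    delta_effect = ce$delta_effect,
    icer_usd_per_qaly = ce$icer,
    icer_pkr_per_qaly = if (is.na(ce$icer)) NA_real_
      else convert_currency(ce$icer, exchange_rate = rate),
    classification = ce$classification
  )
  for (w in wtps)
    inc[[sprintf("inmb_usd_at_%g", w)]] <-
      incremental_nmb(out$intervention, out$comparator, w)
  list(arms = arms, incremental = inc)
}

#' One-way sensitivity analysis report
#'
#' Runs [one_way()] for every parameter, orders the tornado, and solves
#' the threshold crossing for each parameter whose ICER spans `wtp`
#' inside its plausible range.
#'
#' @param bundle A [ce_bundle()].
#' @param params List of [parameter_spec()]s (default
#'   [default_dsa_parameters()]).
#' @param wtp Threshold for crossing solves, USD per QALY-unit.
#' @return List with `tornado` (ordered data.frame) and `crossings`
#'   (data.frame: parameter, wtp, crossing_value, icer_at_crossing,
#'   converged; zero rows if none cross).
#' @export
run_dsa <- function(bundle, params = default_dsa_parameters(bundle$values),
                    wtp = 1658) {
  if (length(params) == 0L) stop("no sensitivity parameters supplied")
  entries <- lapply(params, function(p) one_way(bundle, p))
  tor <- tornado(entries)
  crossings <- do.call(rbind, lapply(params, function(p) {
    cr <- threshold_crossing(bundle, p, wtp)
    if (is.null(cr)) NULL
    else data.frame(parameter = cr$parameter, wtp = cr$wtp,
                    crossing_value = cr$crossing_value,
                    icer_at_crossing = cr$icer_at_crossing,
                    converged = cr$converged)
  }))
  if (is.null(crossings))
    crossings <- data.frame(parameter = character(0), wtp = numeric(0),
                            crossing_value = numeric(0),
                            icer_at_crossing = numeric(0),
                            converged = logical(0))
  rownames(crossings) <- NULL
  list(tornado = tor, crossings = crossings)
}

#' Probabilistic sensitivity analysis report
#'
#' Runs the PSA and derives the cost-effectiveness plane table and the
#' acceptability curve over a threshold grid.
#'
#' @param bundle A [ce_bundle()].
#' @param n Iterations (default 1000).
#' @param seed Integer seed.
#' @param wtp Threshold for the plane export (default 1658 USD/QALY-unit).
#' @param wtp_grid Ascending grid for the CEAC (default 0 to 3x GDP in
#'   steps of about 100 USD).
#' @param dists,transition_counts Passed to [run_psa()].
#' @return List with `result` (`psa_result`), `plane`, `ceac`.
#' @export
run_psa_report <- function(bundle, n = 1000L, seed = 1L, wtp = 1658,
                           wtp_grid = seq(0, 4974, by = 100),
                           dists = default_psa_distributions(bundle$values),
                           transition_counts = NULL) {
  result <- run_psa(bundle, dists = dists, n = n, seed = seed,
                    transition_counts = transition_counts)
  list(result = result,
       plane = ce_plane_export(result, wtp),
       ceac = ceac(result, wtp_grid))
}
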