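#' Fit a beta distribution from a mean and plausible range
#'
#' Method-of-moments fit treating the plausible range as a 95% interval:
#' `sd = (high - low) / 3.92`. Errors if the implied variance is
#' infeasible for a beta with the requested mean.
#'
#' @param mean Target mean in (0, 1).
#' @param low,high Plausible range, `low < high`.
#' @return Named numeric `c(shape1, shape2)`.
#' @examples
#' fit_beta(0.83, 0.67, 0.99)
#' @export
fit_beta <- function(mean, low, high) {
  if (!(mean > 0 && mean < 1)) stop("beta mean must lie strictly in (0, 1)")
  if (!(low < high)) stop("need low < high")
  sd <- (high - low) / 3.92
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop(sprintf("variance %.4g infeasible for a beta with mean %.4g", v, mean))
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Fit a gamma distribution from a mean and plausible range
#'
#' Method-of-moments fit with `sd = (high - low) / 3.92`:
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#'
#' @param mean Target mean (> 0).
#' @param low,high Plausible range, `low < high`.
#' @return Named numeric `c(shape, scale)`.
#' @examples
#' fit_gamma(290, 232, 348)
#' @export
fit_gamma <- function(mean, low, high) {
  if (!(mean > 0)) stop("gamma mean must be positive")
  if (!(low < high)) stop("need low < high")
  sd <- (high - low) / 3.92
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Parameter distribution for probabilistic sensitivity analysis
#'
#' @param parameter Bundle target name (see [set_parameter()]).
#' @param family `"beta"` (utilities) or `"gamma"` (costs).
#' @param mean Base-case value.
#' @param low,high Plausible range interpreted as a 95% interval.
#' @return Object of class `dist_spec` carrying the fitted shape
#'   parameters.
#' @export
dist_spec <- function(parameter, family = c("beta", "gamma"),
                      mean, low, high) {
  family <- match.arg(family)
  fitted <- if (family == "beta") fit_beta(mean, low, high)
            else fit_gamma(mean, low, high)
  structure(list(parameter = parameter, family = family, mean = mean,
                 low = low, high = high, fitted = fitted),
            class = "dist_spec")
}

#' Draw from a fitted parameter distribution
#' @param d A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; beta draws are defensively
#'   clipped to \[0, 1\].
#' @export
draw_dist <- function(d, n = 1L) {
  stopifnot(inherits(d, "dist_spec"))
  if (d$family == "beta")
    pmin(pmax(stats::rbeta(n, d$fitted[["shape1"]], d$fitted[["shape2"]]), 0), 1)
  else
    stats::rgamma(n, shape = d$fitted[["shape"]], scale = d$fitted[["scale"]])
}

#' Base-case PSA distribution set
#'
#' Beta distributions for the three stage utilities and gamma
#' distributions for the three stage costs and the intervention cost,
#' moment-matched to the base-case plausible ranges (+/-20% of base, the
#' published plausible ranges).
#'
#' @param values A [stage_values()].
#' @return Named list of [dist_spec()]s keyed by bundle target.
#' @export
default_psa_distributions <- function(values = stage_values()) {
  u <- values$utility; cc <- values$cycle_cost
  ic <- values$intervention_cycle_cost
  specs <- list(
    dist_spec("utility_A", "beta", u[["A"]], 0.8 * u[["A"]],
              min(1.2 * u[["A"]], 1)),
    dist_spec("utility_B", "beta", u[["B"]], 0.8 * u[["B"]], 1.2 * u[["B"]]),
    dist_spec("utility_C", "beta", u[["C"]], 0.8 * u[["C"]], 1.2 * u[["C"]]),
    dist_spec("cost_A", "gamma", cc[["A"]], 0.8 * cc[["A"]], 1.2 * cc[["A"]]),
    dist_spec("cost_B", "gamma", cc[["B"]], 0.8 * cc[["B"]], 1.2 * cc[["B"]]),
    dist_spec("cost_C", "gamma", cc[["C"]], 0.8 * cc[["C"]], 1.2 * cc[["C"]]),
    dist_spec("intervention_cost", "gamma", ic, 0.8 * ic, 1.2 * ic)
  )
  names(specs) <- vapply(specs, `[[`, "", "parameter")
  specs
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the model: each iteration draws every parameter
#' independently from its fitted distribution, rebuilds both arms, runs
#' the cohort model, and records the incremental cost and effect.
#' Transition probabilities stay at their (calibrated) point values
#' unless `transition_counts` is supplied, in which case each iteration
#' additionally redraws each arm's matrix from Dirichlet row posteriors
#' via [dirichlet_row_uncertainty()].
#'
#' @param bundle A [ce_bundle()].
#' @param dists Named list of [dist_spec()]s (names = bundle targets).
#' @param n Number of iterations (base case 1000).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @param transition_counts Optional list with elements `intervention` and
#'   `comparator`, each a 4x4 transition count matrix.
#' @return Object of class `psa_result`: `samples` (data.frame with
#'   iteration, delta_cost, delta_qaly), `draws` (per-iteration parameter
#'   draws, for audit), `seed`, `n`, and the deterministic base `ce_result`.
#' @export
run_psa <- function(bundle, dists = default_psa_distributions(bundle$values),
                    n = 1000L, seed = 1L, transition_counts = NULL) {
  stopifnot(inherits(bundle, "ce_bundle"), n >= 1)
  bad <- setdiff(names(dists), bundle_targets())
  if (length(bad) > 0L)
    stop(sprintf("distribution names not model parameters: %s",
                 paste(bad, collapse = ", ")))
  set.seed(as.integer(seed))
  draws <- as.data.frame(lapply(dists, draw_dist, n = n))
  dc <- numeric(n); dq <- numeric(n)
  for (i in seq_len(n)) {
    b <- bundle
    for (p in names(dists)) b <- set_parameter(b, p, draws[i, p])
    if (!is.null(transition_counts)) {
      b$intervention$matrix <-
        dirichlet_row_uncertainty(transition_counts$intervention)
      b$comparator$matrix <-
        dirichlet_row_uncertainty(transition_counts$comparator)
    }
    out <- bundle_outcomes(b)
    dc[i] <- out$intervention$cost - out$comparator$cost
    dq[i] <- out$intervention$effect - out$comparator$effect
  }
  structure(
    list(samples = data.frame(iteration = seq_len(n),
                              delta_cost = dc, delta_qaly = dq),
         draws = cbind(iteration = seq_len(n), draws),
         seed = as.integer(seed), n = as.integer(n),
         base_result = bundle_icer(bundle)),
    class = "psa_result"
  )
}

#' Probability that the intervention is cost-effective at a threshold
#'
#' Share of PSA samples with non-negative incremental net monetary
#' benefit: `delta_qaly * wtp - delta_cost >= 0`.
#'
#' @param result A `psa_result`.
#' @param wtp Threshold in USD per QALY-unit.
#' @return Fraction in \[0, 1\].
#' @export
fraction_cost_effective <- function(result, wtp) {
  stopifnot(inherits(result, "psa_result"), nrow(result$samples) > 0)
  s <- result$samples
  mean(s$delta_qaly * wtp - s$delta_cost >= 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param result A `psa_result`.
#' @param wtp_grid Strictly ascending thresholds in USD per QALY-unit.
#' @return data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(result, wtp_grid) {
  if (length(wtp_grid) == 0L) stop("empty willingness-to-pay grid")
  if (is.unsorted(wtp_grid, strictly = TRUE))
    stop("willingness-to-pay grid must be strictly ascending")
  data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w)
      fraction_cost_effective(result, w), numeric(1))
  )
}

#' Cost-effectiveness plane scatter table
#'
#' Labels each PSA sample with its plane quadrant (NE = costlier and more
#' effective, etc.) and whether it falls at or below the threshold line
#' (non-negative incremental NMB).
#'
#' @param result A `psa_result`.
#' @param wtp Threshold in USD per QALY-unit.
#' @return data.frame: iteration, delta_cost, delta_qaly, quadrant,
#'   below_threshold.
#' @export
ce_plane_export <- function(result, wtp) {
  stopifnot(inherits(result, "psa_result"), nrow(result$samples) > 0)
  s <- result$samples
  quadrant <- ifelse(s$delta_qaly >= 0,
                     ifelse(s$delta_cost >= 0, "NE", "SE"),
                     ifelse(s$delta_cost >= 0, "NW", "SW"))
  data.frame(iteration = s$iteration,
             delta_cost = s$delta_cost, delta_qaly = s$delta_qaly,
             quadrant = quadrant,
             below_threshold = s$delta_qaly * wtp - s$delta_cost >= 0)
}
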