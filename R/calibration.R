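#' Arm-level calibration target
#'
#' The target outcomes an arm's transition matrix and initial stage split
#' must reproduce: total QALY-units and total USD cost over the horizon.
#'
#' @param arm Arm label.
#' @param qaly_units Target accumulated utility units.
#' @param cost Target total cost, USD.
#' @param has_intervention Whether the arm carries the per-cycle
#'   intervention cost.
#' @param tolerance Relative tolerance on each target (default 0.01).
#' @return Object of class `calibration_target`.
#' @export
calibration_target <- function(arm, qaly_units, cost,
                               has_intervention = FALSE, tolerance = 0.01) {
  stopifnot(qaly_units >= 0, cost >= 0, tolerance >= 0)
  structure(list(arm = arm, qaly_units = qaly_units, cost = cost,
                 has_intervention = isTRUE(has_intervention),
                 tolerance = tolerance),
            class = "calibration_target")
}

#' Check that a calibration target is reachable
#'
#' Computes the feasibility envelope implied by the stage values and
#' horizon: accumulated QALY-units cannot exceed `n_cycles * max utility`,
#' and the stage-cost residual (target cost minus the maximal intervention
#' add-on, when applicable) must fall inside
#' `[0, n_cycles * max alive-state cost]` — the lower bound is 0 because
#' death accrues no cost.
#'
#' @param target A [calibration_target()].
#' @param values A [stage_values()].
#' @param spec A [model_spec()].
#' @return List with `feasible` flag, the computed bounds, and a reason
#'   string when infeasible. Never silently clamps.
#' @export
feasibility_check <- function(target, values, spec) {
  stopifnot(inherits(target, "calibration_target"),
            inherits(values, "stage_values"), inherits(spec, "model_spec"))
  n <- spec$n_cycles
  qaly_max <- n * max(values$utility)
  intervention_total <- if (target$has_intervention)
    n * values$intervention_cycle_cost else 0
  residual <- target$cost - intervention_total
  cost_residual_bounds <- c(0, n * max(values$cycle_cost))
  reasons <- character(0)
  if (target$qaly_units > qaly_max)
    reasons <- c(reasons, sprintf(
      "target QALY-units %.3f exceeds maximum %.3f (= %d cycles x %.2f)",
      target$qaly_units, qaly_max, n, max(values$utility)))
  # the intervention add-on shrinks with deaths, so the residual may fall
  # below target_cost - n * intervention_cost without being infeasible;
  # only a residual above the all-alive maximum stage cost is unreachable
  if (residual > cost_residual_bounds[2])
    reasons <- c(reasons, sprintf(
      "stage-cost residual %.2f exceeds maximum %.2f", residual,
      cost_residual_bounds[2]))
  if (target$has_intervention && target$cost == 0 &&
      values$intervention_cycle_cost > 0 && target$qaly_units > 0)
    reasons <- c(reasons,
                 "zero cost target incompatible with mandatory intervention cost")
  list(feasible = length(reasons) == 0L,
       qaly_max = qaly_max,
       intervention_total = intervention_total,
       cost_residual = residual,
       cost_residual_bounds = cost_residual_bounds,
       reasons = reasons)
}

# softmax over a numeric vector; invariant to shifts, sums to 1
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# unconstrained parameter vector -> (transition_matrix, initial distribution)
# theta: 3 alive rows x 4 logits, then 3 logits for the initial split over
# the alive states (the cohort enters alive)
theta_to_model <- function(theta, pin_initial = NULL) {
  m <- diag(4)
  for (r in 1:3) m[r, ] <- softmax(theta[(4 * r - 3):(4 * r)])
  m <- transition_matrix(m)
  init <- if (is.null(pin_initial)) c(softmax(theta[13:15]), 0)
          else pin_initial
  list(matrix = m, initial = init)
}

#' Calibrate one arm's transition matrix to outcome targets
#'
#' The trial's per-arm transition matrices are not published, so they are
#' recovered by optimisation: alive transition rows (and, unless pinned,
#' the initial stage split) are parameterised by softmax transforms of
#' unconstrained logits — guaranteeing valid row-stochastic matrices by
#' construction — and a quasi-Newton search minimises the sum of squared
#' relative errors on (QALY-units, cost). Multiple seeded random starts
#' guard against local minima.
#'
#' The inverse problem is under-determined: the calibrated matrix is a
#' matrix consistent with the targets, not an estimate of the (unknown)
#' trial matrix. Only the match between model outputs and targets is
#' claimed.
#'
#' @param target A [calibration_target()].
#' @param values A [stage_values()].
#' @param spec A [model_spec()].
#' @param seed Integer seed for the random starts.
#' @param n_starts Number of random starts (default 10).
#' @param maxit Iteration cap per start (default 2000).
#' @param pin_initial Optional fixed initial distribution (length 4,
#'   D = 0) to calibrate the matrix alone.
#' @return Object of class `calibration_result`: `matrix`,
#'   `initial_distribution`, `achieved_qaly_units`, `achieved_cost`,
#'   `objective`, `converged`, `seed`, and the `arm_spec` ready for use.
#' @export
calibrate_arm <- function(target, values, spec, seed = 1L,
                          n_starts = 10L, maxit = 2000L,
                          pin_initial = NULL) {
  stopifnot(inherits(target, "calibration_target"))
  fc <- feasibility_check(target, values, spec)
  if (!fc$feasible)
    stop(sprintf("infeasible calibration target for arm '%s': %s",
                 target$arm, paste(fc$reasons, collapse = "; ")))
  n_par <- if (is.null(pin_initial)) 15L else 12L
  evaluate <- function(theta) {
    mod <- theta_to_model(c(theta, numeric(15 - length(theta))), pin_initial)
    arm <- arm_spec(target$arm, mod$matrix, mod$initial,
                    has_intervention = target$has_intervention)
    tr <- run_cohort(arm, spec, values)
    c(qaly = tr$total_qaly_units, cost = tr$total_cost)
  }
  objective <- function(theta) {
    got <- evaluate(theta)
    rq <- if (target$qaly_units > 0)
      (got[["qaly"]] - target$qaly_units) / target$qaly_units
      else got[["qaly"]]
    rc <- if (target$cost > 0) (got[["cost"]] - target$cost) / target$cost
      else got[["cost"]]
    rq^2 + rc^2
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    theta0 <- stats::rnorm(n_par, sd = 1)
    fit <- stats::optim(theta0, objective, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    # polish with Nelder-Mead to escape flat BFGS exits
    fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-16) break
  }
  got <- evaluate(best$par)
  mod <- theta_to_model(c(best$par, numeric(15 - length(best$par))),
                        pin_initial)
  rel_err <- c(
    qaly = abs(got[["qaly"]] - target$qaly_units) / max(target$qaly_units, 1),
    cost = abs(got[["cost"]] - target$cost) / max(target$cost, 1)
  )
  structure(
    list(arm = target$arm,
         matrix = mod$matrix,
         initial_distribution = mod$initial,
         achieved_qaly_units = got[["qaly"]],
         achieved_cost = got[["cost"]],
         target = target,
         relative_errors = rel_err,
         objective = best$value,
         converged = all(rel_err <= target$tolerance),
         seed = as.integer(seed),
         arm_spec = arm_spec(target$arm, mod$matrix, mod$initial,
                             has_intervention = target$has_intervention)),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration of arm '%s': %s\n  QALY-units %.4f (target %.4f), cost %.2f (target %.2f)\n  objective %.3g, seed %d\n",
    x$arm, if (x$converged) "converged" else "NOT converged",
    x$achieved_qaly_units, x$target$qaly_units,
    x$achieved_cost, x$target$cost, x$objective, x$seed))
  invisible(x)
}

#' Flatten a calibration result to a one-row table
#' @param result A `calibration_result`.
#' @return data.frame with arm, matrix rows, initial distribution,
#'   achieved vs target values, objective, converged, seed.
#' @export
calibration_table <- function(result) {
  stopifnot(inherits(result, "calibration_result"))
  m <- unclass(result$matrix)
  cols <- as.list(as.vector(t(m)))
  names(cols) <- paste0("p_", rep(hiv_states(), each = 4),
                        rep(hiv_states(), times = 4))
  init <- as.list(result$initial_distribution)
  names(init) <- paste0("init_", hiv_states())
  data.frame(
    arm = result$arm,
    cols, init,
    achieved_qaly_units = result$achieved_qaly_units,
    target_qaly_units = result$target$qaly_units,
    achieved_cost = result$achieved_cost,
    target_cost = result$target$cost,
    objective = result$objective,
    converged = result$converged,
    seed = result$seed
  )
}
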