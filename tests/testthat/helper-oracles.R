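# Shared fixtures and independent oracles for the test suite.

# random row-stochastic 4x4 with absorbing death row
random_valid_matrix <- function() {
  m <- matrix(stats::runif(16), 4, 4)
  m <- m / rowSums(m)
  m[4, ] <- c(0, 0, 0, 1)
  transition_matrix(m)
}

random_distribution <- function(k = 4) {
  d <- stats::runif(k)
  d / sum(d)
}

# explicit double-loop oracle for one cohort step
oracle_step <- function(dist, m) {
  out <- numeric(4)
  for (s in 1:4) for (r in 1:4) out[s] <- out[s] + dist[r] * m[r, s]
  out
}

# naive matrix-power + dot-product oracle for run_cohort totals
oracle_run_cohort <- function(arm, spec, values) {
  m <- unclass(arm$matrix)
  if (!is.null(spec$death_probability_override))
    m <- unclass(apply_death_probability(transition_matrix(m),
                                         spec$death_probability_override))
  n <- spec$n_cycles
  scale <- if (spec$qaly_convention == "calendar_weighted")
    spec$cycle_length_months / 12 else 1
  qaly <- 0; cost <- 0
  for (t in 0:(n - 1)) {
    pw <- diag(4)
    if (t > 0) for (k in 1:t) pw <- pw %*% m
    occ <- as.numeric(arm$initial_distribution %*% pw)
    disc <- (1 + spec$discount_rate)^-(t * spec$cycle_length_months / 12)
    qaly <- qaly + sum(occ * values$utility) * scale * disc
    c_t <- sum(occ * values$cycle_cost)
    if (arm$has_intervention)
      c_t <- c_t + (1 - occ[4]) * values$intervention_cycle_cost
    cost <- cost + c_t * disc
  }
  list(total_qaly_units = qaly, total_cost = cost)
}

# calibrating the reproduction model is reused across files; memoise it
.repro_cache <- new.env(parent = emptyenv())
get_repro <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.repro_cache[[key]]))
    .repro_cache[[key]] <- reproduction_model(seed = seed)
  .repro_cache[[key]]
}
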