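#' Configuration of a synthetic two-arm stage-trajectory trial
#'
#' Emulates the structure of the source randomised trial: two arms of
#' HIV-positive participants whose WHO stage is observed every two
#' months, with loss to follow-up. Defaults mirror the trial's size
#' (33 per arm) but observe six cycles so a full year of transitions is
#' available for estimation.
#'
#' @param n_per_arm Participants per arm (default 33).
#' @param n_cycles_observed Number of observed transitions per subject
#'   before censoring (default 6).
#' @param matrices Named list of ground-truth `transition_matrix` objects,
#'   one per arm.
#' @param initial_distributions Named list of length-4 stage-split vectors
#'   (D entry 0), one per arm; a single vector is recycled to both arms.
#' @param dropout_probability Per-cycle probability of loss to follow-up,
#'   independent of state (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = 33L, n_cycles_observed = 6L,
                         matrices, initial_distributions,
                         dropout_probability = 0.05, seed = 1L) {
  stopifnot(n_per_arm >= 1, n_cycles_observed >= 1,
            dropout_probability >= 0, dropout_probability <= 1)
  matrices <- lapply(matrices, validate_transition_matrix)
  if (is.numeric(initial_distributions))
    initial_distributions <- stats::setNames(
      rep(list(initial_distributions), length(matrices)), names(matrices))
  initial_distributions <- lapply(initial_distributions, function(d) {
    d <- as.numeric(d)
    if (length(d) == 3L) d <- c(d, 0)
    stopifnot(length(d) == 4L, all(d >= 0), abs(sum(d) - 1) < 1e-9)
    d
  })
  stopifnot(identical(sort(names(matrices)),
                      sort(names(initial_distributions))))
  structure(list(n_per_arm = as.integer(n_per_arm),
                 n_cycles_observed = as.integer(n_cycles_observed),
                 matrices = matrices,
                 initial_distributions = initial_distributions,
                 dropout_probability = dropout_probability,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Simulate per-subject stage trajectories
#'
#' Each subject starts from a draw of the arm's initial stage split and
#' each cycle moves by a categorical draw from the current stage's
#' transition row. Censoring (loss to follow-up) is drawn independently
#' each cycle; a censored subject contributes no further observations.
#' Death is recorded as an observed absorbing transition: a dead subject's
#' sequence stays in D (no further transitions are counted out of D by
#' [estimate_matrix()]).
#'
#' @param cfg A [trial_config()].
#' @return Object of class `trajectory_set`: data.frame with columns
#'   subject_id, arm, cycle (0-based), state, censored (TRUE on a
#'   subject's last row when lost to follow-up before the final cycle).
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  set.seed(cfg$seed)
  states <- hiv_states()
  rows <- list()
  sid0 <- 0L
  for (arm in names(cfg$matrices)) {
    m <- unclass(cfg$matrices[[arm]])
    n <- cfg$n_per_arm
    cur <- sample.int(4L, n, replace = TRUE,
                      prob = cfg$initial_distributions[[arm]])
    active <- rep(TRUE, n)
    state_seq <- matrix(NA_integer_, nrow = n,
                        ncol = cfg$n_cycles_observed + 1L)
    state_seq[, 1] <- cur
    last_obs <- rep(cfg$n_cycles_observed, n)
    for (t in seq_len(cfg$n_cycles_observed)) {
      dropped <- active & stats::runif(n) < cfg$dropout_probability
      last_obs[dropped] <- pmin(last_obs[dropped], t - 1L)
      active <- active & !dropped
      if (!any(active)) break
      prev <- cur
      for (s in 1:4) {
        idx <- which(active & prev == s)
        if (length(idx) == 0L) next
        cur[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = m[s, ])
      }
      state_seq[active, t + 1L] <- cur[active]
    }
    lens <- last_obs + 1L
    subj <- rep(seq_len(n), times = lens)
    cyc <- sequence(lens) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sid0 + subj,
      arm = arm,
      cycle = cyc,
      state = states[state_seq[subj + cyc * n]],
      censored = cyc == rep(last_obs, times = lens) &
        rep(last_obs, times = lens) < cfg$n_cycles_observed
    )
    sid0 <- sid0 + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trajectory_set", class(out))
  out
}

#' Estimate a transition matrix from observed trajectories
#'
#' Row-wise maximum-likelihood estimate: `p[r][s] = n(r -> s) / n(r -> .)`
#' over consecutive observed stage pairs. The death row is forced
#' absorbing. Alive rows with zero observed exposure are returned as
#' uniform-over-self placeholders and flagged in `undefined_rows` rather
#' than silently imputed.
#'
#' @param traj A `trajectory_set` (optionally pre-filtered).
#' @param arm Optional arm label to subset on.
#' @return List with `matrix` (a `transition_matrix`), `counts` (4x4
#'   transition counts), and `undefined_rows` (character vector of alive
#'   states with no observed exits).
#' @export
estimate_matrix <- function(traj, arm = NULL) {
  stopifnot(is.data.frame(traj), nrow(traj) > 0)
  if (!is.null(arm)) {
    traj <- traj[traj$arm == arm, , drop = FALSE]
    if (nrow(traj) == 0L) stop(sprintf("no trajectories for arm '%s'", arm))
  }
  states <- hiv_states()
  traj <- traj[order(traj$subject_id, traj$cycle), , drop = FALSE]
  n <- nrow(traj)
  counts <- matrix(0, 4, 4, dimnames = list(states, states))
  if (n >= 2L) {
    same <- traj$subject_id[-n] == traj$subject_id[-1] &
      traj$cycle[-1] - traj$cycle[-n] == 1L
    from <- match(traj$state[-n], states)[same]
    to <- match(traj$state[-1], states)[same]
    tab <- tabulate((from - 1L) * 4L + to, nbins = 16L)
    counts <- matrix(tab, 4, 4, byrow = TRUE,
                     dimnames = list(states, states))
  }
  if (any(counts[4, 1:3] > 0)) stop("observed a transition out of death")
  m <- matrix(0, 4, 4, dimnames = list(states, states))
  undefined <- character(0)
  for (r in 1:3) {
    tot <- sum(counts[r, ])
    if (tot == 0) {
      m[r, r] <- 1  # placeholder; flagged below
      undefined <- c(undefined, states[r])
    } else m[r, ] <- counts[r, ] / tot
  }
  m[4, ] <- c(0, 0, 0, 1)
  list(matrix = transition_matrix(m), counts = counts,
       undefined_rows = undefined)
}

#' Transition counts as a long table
#' @param counts 4x4 count matrix from [estimate_matrix()].
#' @param arm Optional arm label column value.
#' @return data.frame with columns arm (if given), from_state, to_state, n.
#' @export
counts_table <- function(counts, arm = NULL) {
  df <- data.frame(
    from_state = rep(hiv_states(), times = 4),
    to_state = rep(hiv_states(), each = 4),
    n = as.vector(counts)
  )
  if (!is.null(arm)) df <- cbind(arm = arm, df)
  df
}

#' Sample a transition matrix from Dirichlet row posteriors
#'
#' Each alive row is drawn from a Dirichlet with parameters
#' `counts + prior`, a conjugate posterior under a flat prior over the
#' destination simplex; the death row stays fixed absorbing. Used for the
#' optional PSA mode that propagates transition-probability uncertainty
#' from (synthetic) trial counts.
#'
#' @param counts 4x4 non-negative transition count matrix.
#' @param prior Prior weight added to each cell (default 1).
#' @return A validated `transition_matrix`.
#' @export
dirichlet_row_uncertainty <- function(counts, prior = 1) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(4L, 4L)),
            all(counts >= 0), prior > 0)
  m <- matrix(0, 4, 4)
  for (r in 1:3) {
    g <- stats::rgamma(4, shape = counts[r, ] + prior, rate = 1)
    m[r, ] <- g / sum(g)
  }
  m[4, ] <- c(0, 0, 0, 1)
  transition_matrix(m)
}
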