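two_arm_config <- function(...) {
  m_int <- transition_matrix(rbind(c(0.85, 0.10, 0.04, 0.01),
                                   c(0.30, 0.60, 0.09, 0.01),
                                   c(0.10, 0.30, 0.58, 0.02),
                                   c(0, 0, 0, 1)))
  m_usc <- transition_matrix(rbind(c(0.70, 0.25, 0.04, 0.01),
                                   c(0.10, 0.75, 0.13, 0.02),
                                   c(0.02, 0.18, 0.77, 0.03),
                                   c(0, 0, 0, 1)))
  trial_config(matrices = list(pharmacist = m_int, usual_care = m_usc),
               initial_distributions = c(0.5, 0.4, 0.1, 0), ...)
}

test_that("identity dynamics give constant sequences; certain dropout gives length-1 sequences", {
  ident <- trial_config(matrices = list(arm1 = transition_matrix(diag(4))),
                        initial_distributions = c(0.5, 0.3, 0.2, 0),
                        dropout_probability = 0, seed = 2)
  traj <- simulate_trajectories(ident)
  for (id in unique(traj$subject_id))
    expect_equal(length(unique(traj$state[traj$subject_id == id])), 1L)
  expect_false(any(traj$censored))

  all_drop <- two_arm_config(dropout_probability = 1, seed = 3)
  traj2 <- simulate_trajectories(all_drop)
  expect_true(all(table(traj2$subject_id) == 1))
  expect_true(all(traj2$censored))
  expect_true(all(traj2$cycle == 0))
})

test_that("trajectories never leave death and are seed-deterministic", {
  cfg <- two_arm_config(n_per_arm = 200, dropout_probability = 0.05, seed = 5)
  traj <- simulate_trajectories(cfg)
  expect_true(all(traj$state %in% hiv_states()))
  o <- order(traj$subject_id, traj$cycle)
  traj <- traj[o, ]
  n <- nrow(traj)
  same <- traj$subject_id[-n] == traj$subject_id[-1]
  expect_false(any(traj$state[-n][same] == "D" & traj$state[-1][same] != "D"))
  expect_identical(traj, {
    t2 <- simulate_trajectories(cfg); t2[order(t2$subject_id, t2$cycle), ]
  })
})

test_that("cycle-wise state frequencies match the cohort model at large n", {
  cfg <- two_arm_config(n_per_arm = 100000, n_cycles_observed = 6,
                        dropout_probability = 0, seed = 11)
  traj <- simulate_trajectories(cfg)
  for (arm in names(cfg$matrices)) {
    trace <- run_cohort(
      arm_spec(arm, cfg$matrices[[arm]], cfg$initial_distributions[[arm]]),
      model_spec(n_cycles = 7), stage_values())
    sub <- traj[traj$arm == arm, ]
    for (t in c(0, 3, 6)) {
      at_t <- sub$state[sub$cycle == t]
      for (s in 1:4) {
        p <- trace$occupancy[t + 1, s]
        se <- sqrt(max(p * (1 - p), 1e-12) / length(at_t))
        expect_lt(abs(mean(at_t == hiv_states()[s]) - p), 3 * se + 1e-9)
      }
    }
  }
})

test_that("estimate_matrix counts transitions row-wise", {
  traj <- data.frame(
    subject_id = rep(1:4, each = 2),
    arm = "a",
    cycle = rep(0:1, times = 4),
    state = c("A", "A", "A", "B", "A", "A", "A", "B"),
    censored = FALSE
  )
  est <- estimate_matrix(traj)
  expect_equal(unname(est$matrix[1, ]), c(0.5, 0.5, 0, 0))
  expect_equal(est$counts[1, 1], 2)
  expect_equal(est$counts[1, 2], 2)
  expect_setequal(est$undefined_rows, c("B", "C"))

  # identity-generated data estimate back to the identity on observed rows
  ident <- trial_config(matrices = list(a = transition_matrix(diag(4))),
                        initial_distributions = c(0.4, 0.3, 0.3, 0),
                        dropout_probability = 0, seed = 9)
  est2 <- estimate_matrix(simulate_trajectories(ident))
  expect_equal(unclass(est2$matrix), diag(4), ignore_attr = TRUE)
})

test_that("the estimator is consistent: entries within 0.01 at n = 10,000", {
  cfg <- two_arm_config(n_per_arm = 10000, n_cycles_observed = 6,
                        dropout_probability = 0, seed = 13)
  traj <- simulate_trajectories(cfg)
  for (arm in names(cfg$matrices)) {
    est <- estimate_matrix(traj, arm = arm)
    expect_length(est$undefined_rows, 0)
    expect_true(all(abs(unclass(est$matrix) -
                        unclass(cfg$matrices[[arm]])) < 0.01))
  }
})

test_that("Dirichlet row sampling concentrates at the MLE for large counts and stays valid", {
  counts <- matrix(c(8, 1, 0.5, 0.5,
                     2, 6, 1.5, 0.5,
                     0.5, 2, 7, 0.5,
                     0, 0, 0, 0), 4, 4, byrow = TRUE) * 1e5
  set.seed(15)
  mle <- counts[1:3, ] / rowSums(counts[1:3, ])
  for (i in 1:10) {
    m <- dirichlet_row_uncertainty(counts)
    expect_s3_class(validate_transition_matrix(m), "transition_matrix")
    expect_true(all(abs(unclass(m)[1:3, ] - mle) < 0.01))
  }
  # zero counts: uniform rows in expectation
  set.seed(16)
  draws <- replicate(2000, unclass(dirichlet_row_uncertainty(
    matrix(0, 4, 4)))[1, 1])
  expect_lt(abs(mean(draws) - 0.25), 0.01)
})

test_that("end-to-end recovery: simulate, estimate, rerun reproduces the generating outcomes", {
  cfg <- two_arm_config(n_per_arm = 20000, n_cycles_observed = 6,
                        dropout_probability = 0.05, seed = 19)
  traj <- simulate_trajectories(cfg)
  values <- stage_values()
  spec <- model_spec()
  for (arm in names(cfg$matrices)) {
    est <- estimate_matrix(traj, arm = arm)
    truth <- run_cohort(
      arm_spec(arm, cfg$matrices[[arm]], cfg$initial_distributions[[arm]],
               has_intervention = arm == "pharmacist"),
      spec, values)
    refit <- run_cohort(
      arm_spec(arm, est$matrix, cfg$initial_distributions[[arm]],
               has_intervention = arm == "pharmacist"),
      spec, values)
    expect_equal(refit$total_qaly_units, truth$total_qaly_units,
                 tolerance = 0.02)
    expect_equal(refit$total_cost, truth$total_cost, tolerance = 0.02)
  }
})

test_that("counts_table exports the long count format", {
  counts <- matrix(1:16, 4, 4, dimnames = list(hiv_states(), hiv_states()))
  tab <- counts_table(counts, arm = "a")
  expect_equal(nrow(tab), 16)
  expect_equal(tab$n[tab$from_state == "A" & tab$to_state == "A"], 1)
  expect_equal(sum(tab$n), sum(counts))
})
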