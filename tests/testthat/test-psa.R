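test_that("fit_beta moment-matches the plausible range as a 95% interval", {
  # symmetric range around 0.5 gives equal shapes
  sh <- fit_beta(0.5, 0.3, 0.7)
  expect_equal(sh[["shape1"]], sh[["shape2"]], tolerance = 1e-12)

  # stage-A utility inputs: mean and sd recovered by numerical integration
  sh <- fit_beta(0.83, 0.67, 0.99)
  mean_num <- stats::integrate(function(x)
    x * stats::dbeta(x, sh[1], sh[2]), 0, 1, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(x)
    x^2 * stats::dbeta(x, sh[1], sh[2]), 0, 1, rel.tol = 1e-10)$value
  expect_equal(mean_num, 0.83, tolerance = 1e-6)
  expect_equal(sqrt(m2 - mean_num^2), (0.99 - 0.67) / 3.92, tolerance = 1e-6)
  expect_equal(sqrt(m2 - mean_num^2), 0.0816, tolerance = 1e-3)

  expect_error(fit_beta(1.2, 0.5, 0.9), "in \\(0, 1\\)")
  expect_error(fit_beta(0.01, 0, 1), "infeasible")
})

test_that("fit_gamma satisfies the moment identities", {
  sh <- fit_gamma(290, 232, 348)
  expect_equal(sh[["shape"]] * sh[["scale"]], 290, tolerance = 1e-6)
  expect_equal(sqrt(sh[["shape"]]) * sh[["scale"]], (348 - 232) / 3.92,
               tolerance = 1e-9)
  expect_error(fit_gamma(0, -1, 1), "positive")

  # collapsed range concentrates the draws at the mean
  d <- dist_spec("cost_A", "gamma", 22, 22 - 1e-4, 22 + 1e-4)
  set.seed(1)
  expect_true(all(abs(draw_dist(d, 500) - 22) < 1e-3))
})

test_that("sampled parameter means obey the CLT around the base case", {
  d <- dist_spec("intervention_cost", "gamma", 290, 232, 348)
  set.seed(123)
  x <- draw_dist(d, 10000)
  se <- ((348 - 232) / 3.92) / sqrt(10000)
  expect_lt(abs(mean(x) - 290), 2 * se + 1e-12)
})

test_that("degenerate-range PSA reproduces the deterministic base case", {
  b <- get_repro()$bundle
  eps <- 1e-6
  tight <- lapply(default_psa_distributions(b$values), function(d) {
    dist_spec(d$parameter, d$family, d$mean, d$mean - eps, d$mean + eps)
  })
  names(tight) <- vapply(tight, `[[`, "", "parameter")
  res <- run_psa(b, dists = tight, n = 20, seed = 4)
  det <- bundle_icer(b)
  expect_true(all(abs(res$samples$delta_cost - det$delta_cost) < 1e-3))
  expect_true(all(abs(res$samples$delta_qaly - det$delta_effect) < 1e-3))
})

test_that("identical seeds give bit-identical PSA results", {
  b <- get_repro()$bundle
  r1 <- run_psa(b, n = 50, seed = 99)
  r2 <- run_psa(b, n = 50, seed = 99)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$draws, r2$draws)
  r3 <- run_psa(b, n = 50, seed = 100)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("fraction_cost_effective equals a counting-loop oracle", {
  b <- get_repro()$bundle
  res <- run_psa(b, n = 200, seed = 17)
  for (wtp in c(0, 500, 1383.9, 1658, 4974)) {
    n_ok <- 0L
    for (i in seq_len(nrow(res$samples))) {
      s <- res$samples[i, ]
      if (s$delta_qaly * wtp - s$delta_cost >= 0) n_ok <- n_ok + 1L
    }
    expect_equal(fraction_cost_effective(res, wtp), n_ok / nrow(res$samples))
  }
  # wtp = 0 counts cost-saving samples only
  expect_equal(fraction_cost_effective(res, 0),
               mean(res$samples$delta_cost <= 0))
})

test_that("the CEAC is monotone for all-positive incremental effect and matches the sorted-ratio oracle", {
  b <- get_repro()$bundle
  res <- run_psa(b, n = 300, seed = 23)
  expect_true(all(res$samples$delta_qaly > 0))
  grid <- seq(0, 6000, by = 250)
  curve <- ceac(res, grid)
  expect_true(all(diff(curve$probability) >= 0))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  # sorted-threshold oracle: P(cost-effective at w) = share of ratio <= w
  ratios <- sort(res$samples$delta_cost / res$samples$delta_qaly)
  oracle <- vapply(grid, function(w) mean(ratios <= w), numeric(1))
  expect_equal(curve$probability, oracle)
  # at very large wtp every positive-effect sample is acceptable
  expect_equal(fraction_cost_effective(res, 1e9), 1)
  expect_error(ceac(res, numeric(0)), "empty")
  expect_error(ceac(res, c(2, 1)), "ascending")
})

test_that("the CEAC crosses near its median at the deterministic ICER", {
  b <- get_repro()$bundle
  res <- run_psa(b, n = 1000, seed = 31)
  det <- bundle_icer(b)$icer
  p <- fraction_cost_effective(res, det)
  expect_gte(p, 0.35)
  expect_lte(p, 0.65)
})

test_that("the CE plane export partitions samples into quadrants", {
  b <- get_repro()$bundle
  res <- run_psa(b, n = 100, seed = 41)
  plane <- ce_plane_export(res, 1658)
  expect_equal(nrow(plane), 100)
  expect_equal(sum(table(plane$quadrant)), 100)
  ne <- plane$quadrant == "NE"
  expect_true(all(plane$delta_cost[ne] >= 0 & plane$delta_qaly[ne] >= 0))
  # hand-labelled points
  fake <- res
  fake$samples <- data.frame(iteration = 1:2,
                             delta_cost = c(100, -10),
                             delta_qaly = c(0.5, 0.5))
  pl <- ce_plane_export(fake, 1658)
  expect_equal(pl$quadrant, c("NE", "SE"))
  expect_true(all(pl$below_threshold))
})

test_that("unknown distribution names are rejected", {
  b <- get_repro()$bundle
  bad <- list(nonsense = dist_spec("utility_A", "beta", 0.5, 0.4, 0.6))
  expect_error(run_psa(b, dists = bad, n = 2, seed = 1),
               "not model parameters")
})

test_that("the Dirichlet transition-sampling mode runs and stays valid", {
  b <- get_repro()$bundle
  counts <- matrix(c(30, 5, 1, 1,
                     10, 20, 3, 1,
                     2, 8, 12, 2,
                     0, 0, 0, 0), 4, 4, byrow = TRUE)
  res <- run_psa(b, n = 10, seed = 8,
                 transition_counts = list(intervention = counts,
                                          comparator = counts))
  expect_equal(nrow(res$samples), 10)
  expect_true(all(is.finite(res$samples$delta_cost)))
})
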