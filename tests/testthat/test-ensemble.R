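test_that("the Gaussian prior over the grid matches direct density evaluation", {
  g <- build_cost_grid(3, 12) # delta = 9
  w <- prior_weights(g)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # independent route: normal density at the unclipped grid positions
  dens <- dnorm(g$formula_values, mean = g$c_mu, sd = g$delta / 2)
  expect_equal(w, dens / sum(dens), tolerance = 1e-12)
  # centre is the maximum; symmetric; invariant to c_mu and delta
  expect_equal(which.max(w), 10)
  expect_equal(w, rev(w))
  expect_equal(w, prior_weights(build_cost_grid(700, 700.004)),
               tolerance = 1e-9)
  expect_equal(w[10], 0.0918, tolerance = 1e-3)
  expect_equal(w[17], 0.0274, tolerance = 1e-3) # seven steps above the mean

  expect_warning(u <- prior_weights(build_cost_grid(5, 5)), "uniform")
  expect_equal(u, rep(1 / 19, 19))
})

test_that("posterior weights follow Bayes' rule and are shift-invariant", {
  # two components, direct formula
  p <- posterior_weights(c(0.5, 0.5), log(c(0.2, 0.8)))
  expect_equal(p$posterior, c(0.2, 0.8))
  expect_equal(p$evidence * exp(p$log_shift), 0.5 * 0.2 + 0.5 * 0.8,
               tolerance = 1e-12)
  # three components against L*p / sum(L*p) evaluated directly
  prior3 <- c(0.2, 0.3, 0.5)
  lik3 <- c(0.1, 0.6, 0.3)
  p3 <- posterior_weights(prior3, log(lik3))
  expect_equal(p3$posterior, prior3 * lik3 / sum(prior3 * lik3))
  # uniform prior with equal LL -> uniform posterior
  expect_equal(posterior_weights(rep(1 / 3, 3), rep(-40, 3))$posterior,
               rep(1 / 3, 3))
  # adding a constant to all LL leaves the posterior unchanged
  ll <- c(-120, -80, -95)
  for (shift in c(-500, 500)) {
    expect_equal(posterior_weights(prior3, ll + shift)$posterior,
                 posterior_weights(prior3, ll)$posterior, tolerance = 1e-12)
  }
  expect_error(posterior_weights(c(0.7, 0.7), c(-1, -1)), "sum to 1")
  expect_error(posterior_weights(c(0.5, 0.5), c(-Inf, -Inf)), "-Inf")
})

test_that("a fitted ensemble is internally consistent and deterministic", {
  tab <- generate_cohort(n_patients = 8, n_controls = 9, n_voxels = 30,
                         effect_size = 2.5, seed = 21)
  ens <- fit_ensemble(tab)
  expect_length(ens$models, 19)
  expect_equal(sum(ens$prior), 1, tolerance = 1e-12)
  expect_equal(sum(ens$posterior), 1, tolerance = 1e-12)
  # posterior is elementwise proportional to likelihood x prior
  lik <- exp(ens$log_likelihoods - max(ens$log_likelihoods))
  expect_equal(ens$posterior, lik * ens$prior / sum(lik * ens$prior),
               tolerance = 1e-12)
  # run coefficients are the posterior-weighted model coefficients
  beta <- sapply(ens$models, `[[`, "coefficients")
  expect_equal(ens$run_coefficients, drop(beta %*% ens$posterior))
  # the Gaussian prior down-weights the high-cost tail: with near-equal
  # likelihoods the posterior cannot pile onto the top of the grid
  expect_lt(sum(ens$posterior[15:19]), sum(ens$posterior[6:14]))
  # determinism
  ens2 <- fit_ensemble(tab)
  expect_identical(ens$posterior, ens2$posterior)
  expect_identical(ens$run_coefficients, ens2$run_coefficients)
})

test_that("duplicating every training subject rescales the grid, not the models", {
  # doubling each subject halves the cost at which any given solution is
  # optimal, so the grid shifts down by ~2x while the member models (and
  # hence predictions) carry the same information; the posterior sharpens
  # because the log-likelihood doubles, so H agrees approximately, not
  # bit-exactly.
  tab <- make_hard_table(n_per_class = 7, margin = 0.3, seed = 31)
  test <- make_hard_table(n_per_class = 4, margin = 0.3, seed = 32)
  m <- feature_matrix(tab)
  dup <- cohort_features(rbind(m, m), rep(feature_labels(tab), 2),
                         subject_ids = c(tab$subject_id,
                                         paste0(tab$subject_id, "_dup")))
  expect_equal(log10(find_c_mu(dup)), log10(find_c_mu(tab) / 2),
               tolerance = 0.01)
  ens1 <- fit_ensemble(tab)
  ens2 <- fit_ensemble(dup)
  p1 <- ensemble_predict(ens1, test)
  p2 <- ensemble_predict(ens2, test)
  expect_equal(p1$ensemble_probability, p2$ensemble_probability,
               tolerance = 0.1)
  confident <- abs(p1$ensemble_probability - 0.5) > 0.1
  expect_equal(p1$predicted_label[confident], p2$predicted_label[confident])
})

test_that("ensemble probabilities are convex combinations with a strict 0.5 rule", {
  tab <- generate_cohort(n_patients = 8, n_controls = 8, n_voxels = 25,
                         seed = 41)
  test <- generate_cohort(n_patients = 5, n_controls = 5, n_voxels = 25,
                          seed = 42)
  ens <- fit_ensemble(tab)
  pred <- ensemble_predict(ens, test)
  probs <- sapply(ens$models, predict_probability, x = feature_matrix(test))
  expect_true(all(pred$ensemble_probability >= apply(probs, 1, min) - 1e-12))
  expect_true(all(pred$ensemble_probability <= apply(probs, 1, max) + 1e-12))
  expect_equal(pred$predicted_label,
               as.integer(pred$ensemble_probability > 0.5))
  # H reproduces the hand-computed weighted average of the model outputs
  expect_equal(pred$ensemble_probability,
               drop(probs %*% ens$posterior), ignore_attr = TRUE)

  # column mismatch is refused
  other <- generate_cohort(n_patients = 5, n_controls = 5, n_voxels = 24,
                           seed = 42)
  expect_error(ensemble_predict(ens, other), "do not match")
})

test_that("a point-mass prior reduces the ensemble to a single model", {
  tab <- generate_cohort(n_patients = 8, n_controls = 8, n_voxels = 25,
                         seed = 51)
  test <- generate_cohort(n_patients = 6, n_controls = 6, n_voxels = 25,
                          seed = 52)
  point <- replace(rep(0, 19), 5, 1)
  ens <- fit_ensemble(tab, prior = point)
  expect_equal(ens$posterior, point)
  pred <- ensemble_predict(ens, test)
  single <- predict_probability(ens$models[[5]], test)
  expect_equal(pred$ensemble_probability, single, ignore_attr = TRUE)
  expect_equal(pred$predicted_label, as.integer(single > 0.5),
               ignore_attr = TRUE)
})

test_that("run-coefficient aggregation is a convex combination per voxel", {
  tab <- generate_cohort(n_patients = 6, n_controls = 6, n_voxels = 15,
                         seed = 61)
  ens <- fit_ensemble(tab)
  beta <- sapply(ens$models, `[[`, "coefficients")
  agg <- aggregate_run_coefficients(ens)
  expect_identical(agg$voxel_index, voxel_index_map(tab))
  expect_true(all(agg$beta >= apply(beta, 1, min) - 1e-12))
  expect_true(all(agg$beta <= apply(beta, 1, max) + 1e-12))
})
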