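test_that("stratified folds preserve the class ratio to within one subject", {
  labels <- rep(c(1L, 0L), c(32, 36))
  plan <- stratified_folds(labels, k = 5, seed = 7)
  expect_equal(sort(plan$subject), 1:68) # every subject exactly once
  sizes <- table(plan$label, plan$fold)
  expect_setequal(as.integer(sizes["1", ]), c(7, 7, 6, 6, 6))
  expect_setequal(as.integer(sizes["0", ]), c(8, 7, 7, 7, 7))

  # determinism and seed sensitivity
  expect_identical(plan, stratified_folds(labels, 5, seed = 7))
  expect_false(identical(plan$fold, stratified_folds(labels, 5, seed = 8)$fold))

  # property over random class sizes: per-class fold sizes differ by <= 1
  withr::with_seed(13, {
    for (rep in 1:10) {
      n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
      pl <- stratified_folds(rep(c(1L, 0L), c(n1, n0)), k = 5,
                             seed = sample.int(1e6, 1))
      per <- table(pl$label, pl$fold)
      expect_lte(max(per["1", ]) - min(per["1", ]), 1)
      expect_lte(max(per["0", ]) - min(per["0", ]), 1)
    }
  })

  # k equal to the class size gives one subject of that class per fold
  loo <- stratified_folds(rep(c(1L, 0L), c(5, 5)), k = 5, seed = 1)
  expect_true(all(table(loo$label, loo$fold) == 1))
  expect_error(stratified_folds(c(1, 1, 0, 0), k = 5), "at least k")
})

test_that("metrics match the confusion-matrix definitions", {
  # TP=12, FN=4, TN=15, FP=3
  preds <- tibble::tibble(
    true_label = rep(c(1, 1, 0, 0), c(12, 4, 15, 3)),
    predicted_label = rep(c(1, 0, 0, 1), c(12, 4, 15, 3))
  )
  m <- compute_metrics(preds)
  expect_equal(m$accuracy, 27 / 34)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 15 / 18)
  expect_equal(m$f1, 24 / 31)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(12, 3, 15, 4))

  perfect <- tibble::tibble(true_label = c(1, 0), predicted_label = c(1, 0))
  expect_equal(unlist(compute_metrics(perfect)[1:4]), rep(1, 4),
               ignore_attr = TRUE)

  all_control <- tibble::tibble(true_label = c(1, 1, 0),
                                predicted_label = c(0, 0, 0))
  m2 <- compute_metrics(all_control)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)

  # missing class: rate undefined, warned, not silently 0
  expect_warning(m3 <- compute_metrics(
    tibble::tibble(true_label = c(1, 1), predicted_label = c(1, 0))
  ), "specificity undefined")
  expect_true(is.nan(m3$specificity))
})

test_that("one CV iteration predicts every subject exactly once", {
  tab <- generate_cohort(n_patients = 7, n_controls = 8, n_voxels = 40,
                         effect_size = 2, seed = 71)
  it <- run_iteration(tab, k = 5, seed = 3)
  expect_setequal(it$predictions$subject_id, tab$subject_id)
  expect_equal(nrow(it$predictions), nrow(tab))

  # pooled accuracy equals the subject-weighted mean of per-fold accuracies
  per_fold <- dplyr::summarise(
    dplyr::group_by(it$predictions, fold),
    n = dplyr::n(), acc = mean(predicted_label == true_label)
  )
  expect_equal(it$metrics$accuracy, weighted.mean(per_fold$acc, per_fold$n))

  # determinism under the same seed
  it2 <- run_iteration(tab, k = 5, seed = 3)
  expect_identical(it$metrics, it2$metrics)
  expect_identical(it$beta_iteration, it2$beta_iteration)
})

test_that("experiment aggregates follow the printed per-voxel formulas", {
  tab <- generate_cohort(n_patients = 6, n_controls = 7, n_voxels = 25,
                         effect_size = 2, seed = 81)
  res <- run_experiment(tab, n_iterations = 4, base_seed = 10)
  b <- res$beta_iterations
  expect_equal(res$coefficients$beta_mean, colMeans(b))
  # population standard deviation (denominator N)
  expect_equal(res$coefficients$beta_sd,
               sqrt(colMeans(sweep(b, 2, colMeans(b))^2)))
  expect_equal(res$coefficients$n_pos, colSums(b > 0))
  expect_equal(res$coefficients$n_neg, colSums(b < 0))
  # trichotomy: zeros belong to neither count
  expect_true(all(res$coefficients$n_pos + res$coefficients$n_neg <= 4))
  expect_true(all(res$misclassification$n_misclassified >= 0 &
                    res$misclassification$n_misclassified <= 4))
  expect_equal(res$seeds, 10 + 1:4)

  # single iteration: beta_mean = beta_I, beta_sd = 0
  one <- run_experiment(tab, n_iterations = 1, base_seed = 10)
  expect_equal(one$coefficients$beta_sd, rep(0, 25))
  expect_equal(one$coefficients$beta_mean, drop(one$beta_iterations))

  # bit-reproducibility under the same base seed
  res2 <- run_experiment(tab, n_iterations = 4, base_seed = 10)
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$misclassification, res2$misclassification)
})

test_that("paired comparison counts strict wins and refuses unpaired input", {
  tab_a <- generate_cohort(n_patients = 6, n_controls = 7, n_voxels = 25,
                           effect_size = 2.5, seed = 91, measure_tag = "strong")
  tab_b <- generate_cohort(n_patients = 6, n_controls = 7, n_voxels = 25,
                           effect_size = 0, seed = 91, measure_tag = "null")
  res_a <- run_experiment(tab_a, n_iterations = 3, base_seed = 5)
  res_b <- run_experiment(tab_b, n_iterations = 3, base_seed = 5)
  cmp <- compare_measures(res_a, res_b)
  w <- cmp$wins
  expect_true(all(w$wins >= 0 & w$wins <= 3))
  # identical tables tie on every iteration: zero strict wins
  cmp_tie <- compare_measures(a = res_a, b = res_a)
  expect_true(all(cmp_tie$wins$wins == 0))
  # different seeds are refused
  res_c <- run_experiment(tab_b, n_iterations = 3, base_seed = 6)
  expect_error(compare_measures(res_a, res_c), "paired")
})

test_that("permuted labels drive accuracy to chance on a small cohort", {
  tab <- generate_cohort(n_patients = 8, n_controls = 8, n_voxels = 30,
                         effect_size = 2.5, seed = 101)
  null_tab <- permute_labels(tab, seed = 9)
  res <- run_experiment(null_tab, n_iterations = 8, base_seed = 3)
  expect_gt(mean(res$metrics$accuracy), 0.2)
  expect_lt(mean(res$metrics$accuracy), 0.8)
})
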