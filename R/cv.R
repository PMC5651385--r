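#' Stratified fold assignment
#'
#' Partitions subjects into `k` folds preserving the patient-to-control ratio:
#' within each class, subjects are shuffled by the seeded generator and dealt
#' round-robin into the folds, so per-class fold sizes differ by at most one.
#'
#' @param labels Integer vector of group labels (patient = 1, control = 0).
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the same seed always yields the same plan.
#' @return A tibble with one row per subject: `subject` (position in
#'   `labels`), `label`, `fold` (1..k).
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf(
      "Each class needs at least k = %d subjects for %d-fold stratification (smallest class has %d).",
      k, k, min(tab)
    ), call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      shuffled <- sample(idx)
      fold[shuffled] <- rep_len(seq_len(k), length(idx))
    }
  })
  tibble::tibble(subject = seq_along(labels), label = labels, fold = fold)
}

#' Classification metrics with patient as the positive class
#'
#' Computes the confusion counts and the four headline rates from a
#' prediction table: accuracy \eqn{(TP+TN)/n}, sensitivity \eqn{TP/(TP+FN)},
#' specificity \eqn{TN/(TN+FP)} and F1 \eqn{2TP/(2TP+FP+FN)}. If a class is
#' absent the corresponding rate is `NaN` with a warning, never silently 0.
#'
#' @param predictions A tibble with `true_label` and `predicted_label`
#'   columns (as returned by [ensemble_predict()]).
#' @return A one-row tibble: `accuracy`, `f1`, `sensitivity`, `specificity`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' compute_metrics(tibble::tibble(
#'   true_label = c(1, 1, 0, 0), predicted_label = c(1, 0, 0, 1)
#' ))
compute_metrics <- function(predictions) {
  stopifnot(nrow(predictions) > 0)
  y <- predictions$true_label
  p <- predictions$predicted_label
  tp <- sum(y == 1 & p == 1)
  fp <- sum(y == 0 & p == 1)
  tn <- sum(y == 0 & p == 0)
  fn <- sum(y == 1 & p == 0)
  if (tp + fn == 0) warning("No patients in the prediction set; sensitivity undefined.", call. = FALSE)
  if (tn + fp == 0) warning("No controls in the prediction set; specificity undefined.", call. = FALSE)
  tibble::tibble(
    accuracy = (tp + tn) / length(y),
    f1 = 2 * tp / (2 * tp + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' One iteration of stratified k-fold cross-validation
#'
#' Assigns folds with [stratified_folds()], then for each of the `k` runs
#' fits the full ensemble on the training folds (the cost grid is
#' recalculated for every run's training set) and predicts the held-out
#' fold. Metrics are computed on the pooled out-of-fold predictions — each
#' subject is predicted exactly once per iteration. The iteration
#' coefficient vector is the mean of the `k` run vectors,
#' \eqn{\beta_I = \frac{1}{k} \sum_R \beta_R}.
#'
#' @param table A [cohort_features()] tibble.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold allocation.
#' @param ... Passed to [fit_ensemble()].
#' @return List with `metrics` (one-row tibble), `predictions` (one row per
#'   subject, with its `fold`), and `beta_iteration` (numeric vector, one per
#'   voxel).
#' @export
run_iteration <- function(table, k = 5, seed = 1, ...) {
  stopifnot(inherits(table, "cohort_features"))
  plan <- stratified_folds(feature_labels(table), k = k, seed = seed)
  beta_runs <- matrix(0, length(voxel_index_map(table)), k)
  preds <- vector("list", k)
  for (r in seq_len(k)) {
    test_idx <- plan$subject[plan$fold == r]
    train <- subset_subjects(table, setdiff(plan$subject, test_idx))
    test <- subset_subjects(table, test_idx)
    ens <- tryCatch(
      fit_ensemble(train, ...),
      error = function(e) {
        stop(sprintf("Ensemble fit failed on fold %d: %s", r,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    preds[[r]] <- dplyr::mutate(ensemble_predict(ens, test), fold = r)
    beta_runs[, r] <- ens$run_coefficients
  }
  predictions <- dplyr::bind_rows(preds)
  list(
    metrics = compute_metrics(predictions),
    predictions = predictions,
    beta_iteration = rowMeans(beta_runs)
  )
}

#' Repeated stratified k-fold cross-validation experiment
#'
#' Runs [run_iteration()] `n_iterations` times; iteration `t` uses seed
#' `base_seed + t`, so every iteration has a unique random fold allocation
#' and experiments on different measures can be paired exactly by sharing
#' `base_seed`. Per voxel, the iteration coefficient vectors are aggregated
#' into the mean \eqn{\beta_\mu}, the population standard deviation
#' \eqn{\beta_\sigma = \sqrt{\frac{1}{N}\sum_t (\beta_{I=t} - \beta_\mu)^2}}
#' (denominator `N = n_iterations`), and the strict sign counts
#' \eqn{\beta_+ = \#\{t : \beta_{I=t} > 0\}} and
#' \eqn{\beta_- = \#\{t : \beta_{I=t} < 0\}} (exact zeros count in neither).
#' Per subject, misclassifications are tallied across iterations.
#'
#' @param table A [cohort_features()] tibble.
#' @param n_iterations Number of experimental iterations (the study design
#'   uses 1,000).
#' @param base_seed Integer base seed.
#' @param k Number of folds (default 5).
#' @param keep_beta_iterations Keep the full iterations-by-voxels coefficient
#'   matrix? Default `TRUE`.
#' @param ... Passed to [fit_ensemble()].
#' @return A `cv_experiment` object: list with `metrics` (tibble, one row per
#'   iteration), `misclassification` (tibble, one row per subject:
#'   `subject_id`, `label`, `n_misclassified`, `n_iterations`),
#'   `coefficients` (tibble, one row per voxel: `voxel_index`, `beta_mean`,
#'   `beta_sd`, `n_pos`, `n_neg`), optionally `beta_iterations`, plus the
#'   `measure_tag`, `seeds`, `k` and `n_iterations` used.
#' @export
run_experiment <- function(table, n_iterations = 1000, base_seed = 1, k = 5,
                           keep_beta_iterations = TRUE, ...) {
  stopifnot(inherits(table, "cohort_features"), n_iterations >= 1)
  n_vox <- length(voxel_index_map(table))
  seeds <- base_seed + seq_len(n_iterations)
  beta_mat <- matrix(0, n_iterations, n_vox)
  metrics <- vector("list", n_iterations)
  miss <- integer(nrow(table))
  for (t in seq_len(n_iterations)) {
    it <- run_iteration(table, k = k, seed = seeds[t], ...)
    metrics[[t]] <- dplyr::mutate(it$metrics, iteration = t, seed = seeds[t],
                                  .before = 1)
    beta_mat[t, ] <- it$beta_iteration
    wrong <- it$predictions$subject_id[
      it$predictions$predicted_label != it$predictions$true_label]
    miss <- miss + as.integer(table$subject_id %in% wrong)
  }
  beta_mean <- colMeans(beta_mat)
  beta_sd <- sqrt(colMeans(sweep(beta_mat, 2, beta_mean)^2))
  out <- list(
    metrics = dplyr::bind_rows(metrics),
    misclassification = tibble::tibble(
      subject_id = table$subject_id,
      label = feature_labels(table),
      n_misclassified = miss,
      n_iterations = n_iterations
    ),
    coefficients = tibble::tibble(
      voxel_index = voxel_index_map(table),
      beta_mean = beta_mean,
      beta_sd = beta_sd,
      n_pos = colSums(beta_mat > 0),
      n_neg = colSums(beta_mat < 0)
    ),
    measure_tag = measure_tag(table),
    n_iterations = n_iterations,
    base_seed = base_seed,
    seeds = seeds,
    k = k
  )
  if (keep_beta_iterations) out$beta_iterations <- beta_mat
  structure(out, class = "cv_experiment")
}

#' @export
print.cv_experiment <- function(x, ...) {
  cat(sprintf(
    "# Cross-validation experiment [%s]: %d iterations of stratified %d-fold CV\n",
    x$measure_tag, x$n_iterations, x$k
  ))
  print(glance(x))
  invisible(x)
}

#' Paired comparison of measures across CV iterations
#'
#' Compares experiments run on the same subjects with the same iteration
#' seeds (so fold allocations are identical) and, per iteration, records
#' which measure achieved strictly higher accuracy and F1. Ties count as no
#' win for either measure.
#'
#' @param ... Two or more `cv_experiment` objects (optionally named), or a
#'   single list of them. Names default to each experiment's measure tag.
#' @return A `measure_comparison` object: list with `per_iteration` (tibble
#'   of each measure's accuracy/F1 per iteration) and `wins` (tibble of
#'   strict win counts per measure and metric out of `n_iterations`).
#' @export
compare_measures <- function(...) {
  results <- list(...)
  if (length(results) == 1 && !inherits(results[[1]], "cv_experiment")) {
    results <- results[[1]]
  }
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, logical(1), "cv_experiment")))
  nm <- names(results)
  tags <- vapply(results, `[[`, character(1), "measure_tag")
  if (is.null(nm) || any(nm == "")) nm <- make.unique(tags)
  seeds <- lapply(results, `[[`, "seeds")
  if (!all(vapply(seeds, identical, logical(1), seeds[[1]]))) {
    stop("Experiments use different iteration seeds; comparison must be paired.",
         call. = FALSE)
  }
  subj <- lapply(results, function(r) r$misclassification$subject_id)
  if (!all(vapply(subj, identical, logical(1), subj[[1]]))) {
    stop("Experiments were run on different subjects; comparison must be paired.",
         call. = FALSE)
  }

  per_it <- purrr::map2_dfr(results, nm, function(r, name) {
    dplyr::mutate(
      dplyr::select(r$metrics, iteration, accuracy, f1),
      measure = name, .before = 1
    )
  })
  wide_acc <- tidyr::pivot_wider(
    dplyr::select(per_it, measure, iteration, accuracy),
    names_from = measure, values_from = accuracy
  )
  wide_f1 <- tidyr::pivot_wider(
    dplyr::select(per_it, measure, iteration, f1),
    names_from = measure, values_from = f1
  )
  strict_wins <- function(wide) {
    m <- as.matrix(wide[, nm, drop = FALSE])
    vapply(seq_along(nm), function(j) {
      sum(apply(m, 1, function(row) row[j] > max(row[-j])))
    }, numeric(1))
  }
  wins <- tibble::tibble(
    measure = rep(nm, 2),
    metric = rep(c("accuracy", "f1"), each = length(nm)),
    wins = c(strict_wins(wide_acc), strict_wins(wide_f1)),
    n_iterations = results[[1]]$n_iterations
  )
  structure(
    list(per_iteration = per_it, wins = wins, measures = nm),
    class = "measure_comparison"
  )
}

#' @export
print.measure_comparison <- function(x, ...) {
  cat(sprintf("# Paired measure comparison over %d iterations\n",
              x$wins$n_iterations[1]))
  print(x$wins)
  invisible(x)
}
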