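#' Gaussian prior weights over the 19-point cost grid
#'
#' The prior over models is a Gaussian centred at `c_mu` with standard
#' deviation \eqn{\Delta / 2}, evaluated at the *unclipped* grid positions
#' \eqn{C_\mu + \Delta i / 9} and normalized to sum to 1. Substituting the
#' grid formula shows the weights reduce to
#' \eqn{w_i \propto \exp(-2 (i/9)^2)}, invariant to both `c_mu` and `delta`:
#' the grid centre always carries the largest weight (about 0.092) and the
#' weight decays symmetrically towards the tails, down-weighting the
#' strongly-fitting high-cost models to guard against over-fitting (the
#' weight seven steps above the centre is already about 0.027).
#'
#' @param grid A `cost_grid` from [build_cost_grid()].
#' @return Numeric vector of 19 non-negative weights summing to 1. When
#'   `delta == 0` all 19 models are identical and the prior is uniform, with
#'   a warning.
#' @export
#' @examples
#' w <- prior_weights(build_cost_grid(10, 19))
#' w[10]  # centre weight
prior_weights <- function(grid) {
  stopifnot(inherits(grid, "cost_grid"))
  if (grid$delta == 0) {
    warning("delta = 0: degenerate grid, using a uniform prior over 19 identical models.",
            call. = FALSE)
    return(rep(1 / 19, 19))
  }
  w <- exp(-(grid$formula_values - grid$c_mu)^2 / (2 * (grid$delta / 2)^2))
  w / sum(w)
}

#' Posterior model weights and evidence from prior and log-likelihoods
#'
#' Bayes' rule over the model grid:
#' \eqn{p(C \mid D) = L(D \mid C)\, p(C) / p(D)} with the evidence
#' \eqn{p(D) = \sum_c L(D \mid C = c)\, p(C = c)} (a dot product). Computed
#' in log space: the log-likelihoods are shifted by their maximum before
#' exponentiation so the posterior never underflows even with dozens of
#' training subjects; the posterior is exactly shift-invariant and the
#' evidence is reported on the shifted scale with the shift recorded.
#'
#' @param prior Non-negative weights summing to 1.
#' @param log_likelihoods Finite log-likelihoods, same length as `prior`.
#' @return List with `posterior` (sums to 1), `evidence` (on the shifted
#'   scale, i.e. `exp(log_evidence - log_shift)`), `log_evidence` and
#'   `log_shift = max(log_likelihoods)`.
#' @export
posterior_weights <- function(prior, log_likelihoods) {
  stopifnot(length(prior) == length(log_likelihoods))
  if (abs(sum(prior) - 1) > 1e-8) {
    stop("`prior` must sum to 1.", call. = FALSE)
  }
  if (all(log_likelihoods == -Inf)) {
    stop("All model log-likelihoods are -Inf; posterior undefined.",
         call. = FALSE)
  }
  if (any(!is.finite(log_likelihoods) & log_likelihoods != -Inf)) {
    stop("`log_likelihoods` must be finite (or -Inf).", call. = FALSE)
  }
  m <- max(log_likelihoods)
  lik <- exp(log_likelihoods - m)
  num <- lik * prior
  evidence <- sum(num)
  list(
    posterior = num / evidence,
    evidence = evidence,
    log_evidence = m + log(evidence),
    log_shift = m
  )
}

#' Fit the Bayesian-weighted SVM ensemble on a training table
#'
#' The full per-run procedure: find the minimum separating cost (`c_mu`) and
#' the minimum maximal-fit cost (`c_max`), build the 19-value cost grid, fit
#' one probabilistic linear SVM per grid value, and combine them with
#' Gaussian-prior Bayesian model averaging. The run coefficient vector is the
#' posterior-weighted average of the 19 models' coefficient vectors,
#' \eqn{\beta_R = \sum_c p(C = c \mid D)\, \beta_{C = c}}. Deterministic
#' given `train`.
#'
#' @param train A [cohort_features()] tibble with both classes.
#' @param prior Optional prior weights overriding the Gaussian default (e.g.
#'   a point mass for single-model comparisons); length 19, sums to 1.
#' @param ... Passed to [fit_linear_svm()] (e.g. `link`, `scale_features`)
#'   and the grid search.
#' @return An `svm_ensemble` object: list with the `grid`, the 19 `models`,
#'   `prior`, `log_likelihoods`, `posterior`, `evidence` (+ `log_evidence`,
#'   `log_shift`) and `run_coefficients`.
#' @export
fit_ensemble <- function(train, prior = NULL, ...) {
  validate_two_classes(train)
  c_mu <- find_c_mu(train, ...)
  c_max <- find_c_max(train, c_mu, ...)
  grid <- build_cost_grid(c_mu, as.numeric(c_max))
  grid$ll_profile <- attr(c_max, "profile")

  models <- lapply(grid$values, function(cost) fit_linear_svm(train, cost, ...))
  ll <- vapply(models, `[[`, numeric(1), "log_likelihood")

  if (is.null(prior)) {
    prior <- if (grid$delta == 0) {
      suppressWarnings(prior_weights(grid))
    } else {
      prior_weights(grid)
    }
  } else {
    stopifnot(length(prior) == 19, abs(sum(prior) - 1) < 1e-8)
  }
  post <- posterior_weights(prior, ll)

  beta <- vapply(models, `[[`, numeric(length(models[[1]]$coefficients)),
                 "coefficients")
  beta <- matrix(beta, ncol = length(models)) # voxels x 19
  structure(
    list(
      grid = grid,
      models = models,
      prior = prior,
      log_likelihoods = ll,
      posterior = post$posterior,
      evidence = post$evidence,
      log_evidence = post$log_evidence,
      log_shift = post$log_shift,
      run_coefficients = drop(beta %*% post$posterior),
      voxel_index_map = voxel_index_map(train),
      n_train = nrow(train)
    ),
    class = "svm_ensemble"
  )
}

#' @export
print.svm_ensemble <- function(x, ...) {
  cat(sprintf(
    "# Bayesian SVM ensemble: 19 models, c_mu = %.4g, c_max = %.4g\n# posterior mass at centre = %.3f, log evidence = %.2f, %d training subjects\n",
    x$grid$c_mu, x$grid$c_max, x$posterior[10], x$log_evidence, x$n_train
  ))
  invisible(x)
}

#' Ensemble predictions for a test table
#'
#' For each test subject the ensemble probability is the posterior-weighted
#' average of the 19 models' patient probabilities,
#' \eqn{H_i = \sum_c p(C = c \mid D)\, p(1 \mid C = c, D, i)}; the subject is
#' predicted patient iff \eqn{H_i > 0.5} (exactly 0.5 predicts control — the
#' rule is a strict inequality).
#'
#' @param ensemble An `svm_ensemble` from [fit_ensemble()].
#' @param test A [cohort_features()] tibble whose voxel columns match the
#'   training table's.
#' @return A tibble with one row per test subject: `subject_id`,
#'   `true_label`, `ensemble_probability`, `predicted_label`.
#' @export
ensemble_predict <- function(ensemble, test) {
  stopifnot(inherits(ensemble, "svm_ensemble"),
            inherits(test, "cohort_features"))
  if (!identical(voxel_index_map(test), ensemble$voxel_index_map)) {
    stop("Test table voxel columns do not match the training table's.",
         call. = FALSE)
  }
  x <- feature_matrix(test)
  probs <- vapply(ensemble$models, predict_probability,
                  numeric(nrow(x)), x = x)
  probs <- matrix(probs, nrow = nrow(x)) # subjects x 19
  h <- drop(probs %*% ensemble$posterior)
  tibble::tibble(
    subject_id = test$subject_id,
    true_label = feature_labels(test),
    ensemble_probability = h,
    predicted_label = as.integer(h > 0.5)
  )
}

#' Posterior-weighted run coefficient vector
#'
#' \eqn{\beta_R = \sum_c p(C = c \mid D)\, \beta_{C = c}}: a convex
#' combination of the 19 models' per-voxel coefficient vectors, already
#' computed at fit time and returned here as a tibble for mapping back to
#' image space. Negative coefficients mark voxels where controls have higher
#' intensities than patients.
#'
#' @param ensemble An `svm_ensemble`.
#' @return A tibble with `voxel_index` (0-based) and `beta` columns.
#' @export
aggregate_run_coefficients <- function(ensemble) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  tibble::tibble(
    voxel_index = ensemble$voxel_index_map,
    beta = ensemble$run_coefficients
  )
}

#' Export an ensemble's grid, prior, likelihood and posterior for audit
#'
#' @param ensemble An `svm_ensemble`.
#' @param path Optional JSON output path (requires \pkg{jsonlite}).
#' @return The audit list, invisibly when written.
#' @export
ensemble_audit <- function(ensemble, path = NULL) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  out <- list(
    c_mu = ensemble$grid$c_mu,
    c_max = ensemble$grid$c_max,
    delta = ensemble$grid$delta,
    cost = ensemble$grid$values,
    clipped = ensemble$grid$clipped,
    prior = ensemble$prior,
    log_likelihood = ensemble$log_likelihoods,
    posterior = ensemble$posterior,
    log_evidence = ensemble$log_evidence,
    ll_profile = ensemble$grid$ll_profile
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
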