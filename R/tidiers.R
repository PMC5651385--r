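#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a probabilistic linear SVM
#'
#' @param x A `psvm` from [fit_linear_svm()].
#' @param ... Unused.
#' @return A tibble with one row per voxel term (`term = "v<index>"`,
#'   `voxel_index`, `estimate`) plus a final `(Intercept)` row.
#' @export
tidy.psvm <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("v", x$voxel_index_map), "(Intercept)"),
    voxel_index = c(x$voxel_index_map, NA_integer_),
    estimate = c(x$coefficients, x$intercept)
  )
}

#' @rdname tidy.psvm
#' @return `glance()`: a one-row tibble with `cost`, `n_voxels`, `n_train`,
#'   `n_support`, `log_likelihood`, `n_errors`, `link`.
#' @export
glance.psvm <- function(x, ...) {
  tibble::tibble(
    cost = x$cost,
    n_voxels = length(x$coefficients),
    n_train = x$n_train,
    n_support = x$n_support,
    log_likelihood = x$log_likelihood,
    n_errors = x$n_errors,
    link = x$link
  )
}

#' Tidy a Bayesian SVM ensemble
#'
#' @param x An `svm_ensemble` from [fit_ensemble()].
#' @param ... Unused.
#' @return One row per grid model: `index` (-9..9), `cost`, `clipped`,
#'   `prior`, `log_likelihood`, `posterior`.
#' @export
tidy.svm_ensemble <- function(x, ...) {
  tibble::tibble(
    index = x$grid$index,
    cost = x$grid$values,
    clipped = x$grid$clipped,
    prior = x$prior,
    log_likelihood = x$log_likelihoods,
    posterior = x$posterior
  )
}

#' @rdname tidy.svm_ensemble
#' @return `glance()`: one row with `c_mu`, `c_max`, `delta`, `n_clipped`,
#'   `log_evidence`, `n_train`, `n_voxels`.
#' @export
glance.svm_ensemble <- function(x, ...) {
  tibble::tibble(
    c_mu = x$grid$c_mu,
    c_max = x$grid$c_max,
    delta = x$grid$delta,
    n_clipped = sum(x$grid$clipped),
    log_evidence = x$log_evidence,
    n_train = x$n_train,
    n_voxels = length(x$run_coefficients)
  )
}

#' Tidy a cross-validation experiment
#'
#' @param x A `cv_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return The per-voxel coefficient aggregates: `voxel_index`, `beta_mean`,
#'   `beta_sd`, `n_pos`, `n_neg`.
#' @export
tidy.cv_experiment <- function(x, ...) x$coefficients

#' @rdname tidy.cv_experiment
#' @return `glance()`: a one-row summary in the style of a performance
#'   table — mean and SD of each metric over iterations, plus `measure`,
#'   `n_iterations`, `k`.
#' @export
glance.cv_experiment <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    measure = x$measure_tag,
    n_iterations = x$n_iterations,
    k = x$k,
    accuracy = mean(m$accuracy), accuracy_sd = stats::sd(m$accuracy),
    f1 = mean(m$f1), f1_sd = stats::sd(m$f1),
    sensitivity = mean(m$sensitivity), sensitivity_sd = stats::sd(m$sensitivity),
    specificity = mean(m$specificity), specificity_sd = stats::sd(m$specificity)
  )
}

#' @export
tidy.measure_comparison <- function(x, ...) x$per_iteration

#' @export
glance.measure_comparison <- function(x, ...) {
  tidyr::pivot_wider(x$wins, names_from = metric, values_from = wins,
                     names_prefix = "wins_")
}
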