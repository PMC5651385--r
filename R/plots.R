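#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Audit plot of an ensemble's prior, likelihood and posterior
#'
#' Three stacked panels over the 19-point cost grid: the Gaussian prior
#' p(C), the (shift-normalized) likelihood L(D|C), and the posterior model
#' weights p(C|D), showing how the data's fit and the regularizing prior
#' combine.
#'
#' @param object An `svm_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.svm_ensemble <- function(object, ...) {
  d <- tidy(object)
  lik <- exp(d$log_likelihood - max(d$log_likelihood))
  long <- tidyr::pivot_longer(
    dplyr::mutate(d, likelihood = lik / sum(lik)),
    cols = c("prior", "likelihood", "posterior"),
    names_to = "quantity", values_to = "weight"
  )
  long$quantity <- factor(long$quantity,
                          levels = c("prior", "likelihood", "posterior"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cost, y = .data$weight)) +
    ggplot2::geom_col(width = min(diff(sort(unique(d$cost))),
                                  na.rm = TRUE) * 0.8) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "cost C", y = "normalized weight",
                  title = "Model weights over the cost grid") +
    ggplot2::theme_minimal()
}

#' Plot the log-likelihood-versus-cost profile of an ensemble's grid search
#'
#' Raw and median-filtered training log-likelihood against cost (log scale),
#' with `c_mu` and `c_max` marked — the plateau-detection picture behind the
#' grid construction.
#'
#' @param ensemble An `svm_ensemble` whose grid retains its `ll_profile`.
#' @return A ggplot.
#' @export
plot_ll_profile <- function(ensemble) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  prof <- ensemble$grid$ll_profile
  if (is.null(prof)) stop("Ensemble grid carries no log-likelihood profile.",
                          call. = FALSE)
  long <- tidyr::pivot_longer(prof, cols = -cost,
                              names_to = "series", values_to = "ll")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cost, y = .data$ll,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(ensemble$grid$c_mu,
                                       ensemble$grid$c_max),
                        colour = "red", alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cost C (log scale)", y = "training log-likelihood",
                  title = "Fit versus cost: plateau detection") +
    ggplot2::theme_minimal()
}

#' Plots of a cross-validation experiment
#'
#' `autoplot()` shows the distribution of each performance metric over
#' iterations; `plot_misclassification()` the per-subject misclassification
#' counts (how often each subject was wrongly predicted across iterations),
#' grouped by true label.
#'
#' @param object,experiment A `cv_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$metrics, iteration, accuracy, f1, sensitivity,
                  specificity),
    cols = -iteration, names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = NULL, y = "value per iteration",
      title = sprintf("%s: %d iterations of stratified %d-fold CV",
                      object$measure_tag, object$n_iterations, object$k)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cv_experiment
#' @export
plot_misclassification <- function(experiment) {
  stopifnot(inherits(experiment, "cv_experiment"))
  d <- dplyr::mutate(
    experiment$misclassification,
    group = ifelse(.data$label == 1, "patient", "control")
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$subject_id, -.data$n_misclassified),
    y = .data$n_misclassified, fill = .data$group
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subject", y = "times misclassified",
                  title = sprintf("Misclassification counts over %d iterations",
                                  experiment$n_iterations)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Paired accuracy comparison between measures
#'
#' One line per iteration connecting each measure's accuracy, the paired
#' picture behind the win counts.
#'
#' @param object A `measure_comparison` from [compare_measures()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.measure_comparison <- function(object, ...) {
  ggplot2::ggplot(object$per_iteration,
                  ggplot2::aes(x = .data$measure, y = .data$accuracy,
                               group = .data$iteration)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "accuracy per iteration",
                  title = "Paired per-iteration accuracy by measure") +
    ggplot2::theme_minimal()
}
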