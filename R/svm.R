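#' Fit a probabilistic linear SVM at a fixed cost
#'
#' Fits a soft-margin linear-kernel support-vector machine to the training
#' table at regularization cost `cost`, with patients (label 1) on the
#' positive side of the decision function, and attaches a logistic link that
#' maps the real-valued score \eqn{w \cdot x + b} to a probability of being a
#' patient.
#'
#' The default link is the plain logistic \eqn{p = 1 / (1 + e^{-score})},
#' which makes the training log-likelihood a pure function of the SVM fit.
#' `link = "platt"` instead fits Platt's sigmoid
#' \eqn{p = 1 / (1 + e^{a\,score + b})} to the training scores by logistic
#' regression, for sensitivity analysis.
#'
#' @param train A [cohort_features()] tibble containing both classes.
#' @param cost Positive cost (regularization) parameter; larger values fit
#'   the training data harder.
#' @param link `"logistic"` (default) or `"platt"`.
#' @param scale_features Standardize each voxel column to mean 0, sd 1 using
#'   training statistics? Default `FALSE`: voxels of one measure share a
#'   physical unit.
#'
#' @return A `psvm` object: list with `cost`, `coefficients` (one per voxel),
#'   `intercept`, `link`, training `log_likelihood` and `n_errors`, and the
#'   training dimensions. Solved by the deterministic convex (SMO) solver in
#'   \pkg{e1071} at tolerance 1e-6.
#' @export
#' @examples
#' tab <- cohort_features(matrix(c(-1, -1.2, 1, 0.8)), c(0, 0, 1, 1))
#' fit <- fit_linear_svm(tab, cost = 100)
#' fit$coefficients > 0
fit_linear_svm <- function(train, cost, link = c("logistic", "platt"),
                           scale_features = FALSE) {
  stopifnot(inherits(train, "cohort_features"))
  link <- match.arg(link)
  if (!is.numeric(cost) || length(cost) != 1 || !is.finite(cost) || cost <= 0) {
    stop("`cost` must be a single positive number.", call. = FALSE)
  }
  y <- feature_labels(train)
  if (length(unique(y)) < 2) {
    stop("Training set contains a single class; cannot fit an SVM.",
         call. = FALSE)
  }
  x <- feature_matrix(train)

  center <- NULL
  scale_ <- NULL
  if (scale_features) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }

  fit <- e1071::svm(
    x = x, y = factor(y, levels = c(0, 1)),
    type = "C-classification", kernel = "linear",
    cost = cost, scale = FALSE, tolerance = 1e-6, shrinking = FALSE
  )
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's decision value is positive for the first class it saw in the
  # data; normalize so score > 0 means patient.
  positive_class <- fit$levels[fit$labels[1]]
  if (positive_class != "1") {
    w <- -w
    b <- -b
  }
  if (scale_features) {
    # fold standardization into (w, b) so score(x) works on raw features
    w <- w / scale_
    b <- b - sum(w * center)
  }

  model <- structure(
    list(
      cost = cost,
      coefficients = unname(w),
      intercept = unname(b),
      link = link,
      platt = NULL,
      voxel_index_map = voxel_index_map(train),
      n_train = nrow(train),
      n_support = nrow(fit$SV)
    ),
    class = "psvm"
  )

  if (link == "platt") {
    s <- svm_score(model, feature_matrix(train))
    # guard the separable case where glm would diverge
    platt_fit <- suppressWarnings(
      stats::glm(y ~ s, family = stats::binomial())
    )
    model$platt <- list(
      a = unname(stats::coef(platt_fit)[2]),
      b = unname(stats::coef(platt_fit)[1])
    )
  }

  model$n_errors <- training_error_count(model, train)
  model$log_likelihood <- training_log_likelihood(model, train)
  model
}

#' @export
print.psvm <- function(x, ...) {
  cat(sprintf(
    "# Probabilistic linear SVM: cost = %g, %d voxels, %d support vectors, %s link\n# training LL = %.4f, training errors = %d\n",
    x$cost, length(x$coefficients), x$n_support, x$link,
    x$log_likelihood, x$n_errors
  ))
  invisible(x)
}

svm_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$coefficients)) {
    stop(sprintf(
      "Feature vector has %d voxels but the model expects %d.",
      ncol(x), length(model$coefficients)
    ), call. = FALSE)
  }
  drop(x %*% model$coefficients) + model$intercept
}

link_probability <- function(model, score) {
  p <- if (model$link == "platt" && !is.null(model$platt)) {
    stats::plogis(model$platt$a * score + model$platt$b)
  } else {
    stats::plogis(score)
  }
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Patient probability for feature vectors under a fitted SVM
#'
#' Applies the model's logistic link to the decision score:
#' \eqn{p(\mathrm{patient}) = 1 / (1 + e^{-(w \cdot x + b)})}, clipped to
#' \[1e-12, 1 - 1e-12\] so log-likelihoods stay finite. By construction
#' `p(patient) + p(control) = 1`.
#'
#' @param model A `psvm` from [fit_linear_svm()].
#' @param x A feature vector, a feature matrix (rows = subjects), or a
#'   [cohort_features()] tibble.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, x) {
  stopifnot(inherits(model, "psvm"))
  if (inherits(x, "cohort_features")) x <- feature_matrix(x)
  link_probability(model, svm_score(model, x))
}

#' Training-set log-likelihood of a probabilistic SVM
#'
#' \eqn{LL = \sum_i [y_i \log p_i + (1 - y_i) \log(1 - p_i)]} over the
#' training subjects, with probabilities clipped to \[1e-12, 1 - 1e-12\].
#' This is the model-fit score profiled over cost when locating the maximal
#' fit, and (exponentiated) the model likelihood entering the Bayesian
#' weights.
#'
#' @param model A `psvm`.
#' @param train A [cohort_features()] tibble.
#' @return A non-positive number.
#' @export
training_log_likelihood <- function(model, train) {
  stopifnot(inherits(train, "cohort_features"))
  p <- predict_probability(model, train)
  y <- feature_labels(train)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Count training misclassifications of a fitted SVM
#'
#' A subject is predicted patient iff its score is strictly positive (a score
#' of exactly 0 predicts control, consistent with the strict `> 0.5` ensemble
#' rule).
#'
#' @inheritParams training_log_likelihood
#' @return Non-negative integer count of misclassified training subjects.
#' @export
training_error_count <- function(model, train) {
  stopifnot(inherits(train, "cohort_features"))
  s <- svm_score(model, feature_matrix(train))
  pred <- as.integer(s > 0)
  sum(pred != feature_labels(train))
}

#' Export a fitted SVM as a JSON-ready list
#'
#' @param model A `psvm`.
#' @return A plain list (cost, intercept, coefficients, link spec) suitable
#'   for `jsonlite::write_json()`.
#' @export
svm_as_list <- function(model) {
  stopifnot(inherits(model, "psvm"))
  list(
    cost = model$cost,
    intercept = model$intercept,
    coefficients = model$coefficients,
    voxel_index_map = model$voxel_index_map,
    link = model$link,
    platt = model$platt
  )
}
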