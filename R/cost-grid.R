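#' Minimum cost that separates the training set
#'
#' Finds the smallest SVM cost whose fitted model commits zero training
#' classification errors — the centre of the data-driven cost grid. The
#' search brackets the error-to-zero transition (doubling upward from
#' `c = 1` when needed) and then bisects in log10 space until the bracket
#' endpoints agree to 1% relative tolerance; the zero-error endpoint is
#' returned. The search is floored at `lower_cap`: when even that cost
#' separates the training set (common when voxels far outnumber subjects),
#' `lower_cap` itself is returned as the minimum probed separating cost.
#'
#' @param train A [cohort_features()] tibble, both classes present.
#' @param cap Upper search limit; if no zero-error cost exists below it the
#'   data are declared not linearly separable.
#' @param lower_cap Probe floor for the minimum (default 1e-4).
#' @param ... Passed to [fit_linear_svm()].
#' @return A positive number (`c_mu`).
#' @export
find_c_mu <- function(train, cap = 1e8, lower_cap = 1e-4, ...) {
  validate_two_classes(train)
  n_err <- function(cost) fit_linear_svm(train, cost, ...)$n_errors

  if (n_err(lower_cap) == 0) return(lower_cap)
  if (n_err(1) == 0) {
    c_lo <- lower_cap
    c_hi <- 1
  } else {
    c_hi <- 2
    while (n_err(c_hi) > 0) {
      c_hi <- c_hi * 2
      if (c_hi > cap) {
        stop(sprintf(
          "No cost up to %g fits the training set without classification error: not linearly separable.",
          cap
        ), call. = FALSE)
      }
    }
    c_lo <- c_hi / 2
  }
  # bisection in log10 space: c_lo errs, c_hi separates
  while (c_hi / c_lo > 1.01) {
    mid <- 10^((log10(c_lo) + log10(c_hi)) / 2)
    if (n_err(mid) == 0) c_hi <- mid else c_lo <- mid
  }
  c_hi
}

#' Training log-likelihood profiled over candidate costs
#'
#' @param train A [cohort_features()] tibble.
#' @param candidates Increasing positive costs.
#' @param ... Passed to [fit_linear_svm()].
#' @return A tibble with columns `cost`, `log_likelihood` and the
#'   length-3-median-filtered `log_likelihood_smooth`.
#' @export
ll_profile <- function(train, candidates, ...) {
  if (is.unsorted(candidates)) {
    stop("`candidates` must be sorted ascending.", call. = FALSE)
  }
  ll <- vapply(candidates,
               function(cost) fit_linear_svm(train, cost, ...)$log_likelihood,
               numeric(1))
  tibble::tibble(
    cost = candidates,
    log_likelihood = ll,
    log_likelihood_smooth = median_filter3(ll)
  )
}

#' Length-3 median filter
#'
#' Replaces each interior element by the median of its 3-point window;
#' endpoints pass through unchanged. Used to smooth slight noise deviations
#' in the log-likelihood-versus-cost profile before plateau detection.
#' Monotone sequences are fixed points.
#'
#' @param values Numeric vector, length >= 1.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' median_filter3(c(-5, -1, -4, -1, -1))
median_filter3 <- function(values) {
  n <- length(values)
  if (n < 3) return(values)
  out <- values
  for (k in 2:(n - 1)) out[k] <- stats::median(values[(k - 1):(k + 1)])
  out
}

#' Minimum cost achieving the maximal training fit
#'
#' Scans a log-spaced candidate set upward from `c_mu`, smooths the training
#' log-likelihood profile with a length-3 median filter, and returns the
#' smallest candidate whose smoothed log-likelihood reaches the plateau
#' (within `tol_flat` of the profile maximum). The fit increases roughly
#' monotonically with cost until the solution stops changing, so the plateau
#' is well defined for separable data.
#'
#' @param train A [cohort_features()] tibble.
#' @param c_mu Output of [find_c_mu()].
#' @param n_candidates Number of log-spaced candidates in the initial scan
#'   (default 40); the candidate density per decade is kept when the scan
#'   extends.
#' @param span Initial scan upper limit as a multiple of `c_mu` (default
#'   1e4). If the smoothed profile is still rising at the top of the window,
#'   the scan extends itself (same density) until the plateau appears or
#'   `cap` is reached.
#' @param cap Absolute upper cost limit (default 1e8); a profile still rising
#'   there is an error.
#' @param tol_flat Plateau tolerance; default `1e-6 * max(1, |max smoothed LL|)`.
#' @param ... Passed to [fit_linear_svm()].
#' @return A positive number (`c_max >= c_mu`) with the profile tibble
#'   attached as attribute `"profile"`.
#' @export
find_c_max <- function(train, c_mu, n_candidates = 40, span = 1e4,
                       cap = 1e8, tol_flat = NULL, ...) {
  stopifnot(c_mu > 0)
  per_decade <- max(1, (n_candidates - 1) / log10(span))
  fit_ll <- function(costs) {
    vapply(costs,
           function(cost) fit_linear_svm(train, cost, ...)$log_likelihood,
           numeric(1))
  }
  costs <- 10^seq(log10(c_mu), log10(min(c_mu * span, cap)),
                  length.out = max(2, n_candidates))
  ll <- fit_ll(costs)
  repeat {
    sm <- median_filter3(ll)
    flat_tol <- if (is.null(tol_flat)) 1e-6 * max(1, abs(max(sm))) else tol_flat
    first <- which(sm >= max(sm) - flat_tol)[1]
    if (first < length(costs)) {
      prof <- tibble::tibble(cost = costs, log_likelihood = ll,
                             log_likelihood_smooth = sm)
      return(structure(costs[first], profile = prof))
    }
    if (max(costs) >= cap) {
      stop(sprintf(
        "Training fit is still improving at the scan cap %g; rerun with a larger `cap`.",
        cap
      ), call. = FALSE)
    }
    # still rising at the window top: extend one decade at the same density
    n_new <- ceiling(per_decade)
    ext <- max(costs) * 10^(seq_len(n_new) / per_decade)
    ext <- pmin(ext[ext <= cap * (1 + 1e-9)], cap)
    if (length(ext) == 0) ext <- cap
    costs <- c(costs, ext)
    ll <- c(ll, fit_ll(ext))
  }
}

#' Build the 19-value cost grid
#'
#' The grid is \eqn{C_\mu + \Delta \cdot i / 9} for \eqn{i = -9, \dots, 9}
#' with \eqn{\Delta = C_{max} - C_\mu}: 19 equally spaced costs centred on
#' the minimum separating cost, reaching the maximal-fit cost at the top.
#' Whenever \eqn{\Delta \ge C_\mu} the lower tail of the linear formula dips
#' to zero or below; such values are clipped to `1e-6 * c_mu` (and flagged)
#' rather than re-spacing the grid, preserving the linear formula elsewhere.
#'
#' @param c_mu Minimum separating cost (grid centre).
#' @param c_max Minimum maximal-fit cost (grid top), `c_max >= c_mu`.
#' @return A `cost_grid` object: list with `c_mu`, `c_max`, `delta`, the 19
#'   `values`, the unclipped `formula_values`, the grid `index` (-9..9) and a
#'   logical `clipped` flag per value.
#' @export
#' @examples
#' build_cost_grid(10, 19)$values  # 1, 2, ..., 19
build_cost_grid <- function(c_mu, c_max) {
  if (!(c_mu > 0)) stop("`c_mu` must be positive.", call. = FALSE)
  if (c_max < c_mu) {
    stop("`c_max` must be at least `c_mu`.", call. = FALSE)
  }
  delta <- c_max - c_mu
  index <- -9:9
  formula_values <- c_mu + delta * index / 9
  clipped <- formula_values <= 0
  values <- ifelse(clipped, 1e-6 * c_mu, formula_values)
  structure(
    list(
      c_mu = c_mu, c_max = c_max, delta = delta,
      index = index,
      values = values,
      formula_values = formula_values,
      clipped = clipped
    ),
    class = "cost_grid"
  )
}

#' @export
print.cost_grid <- function(x, ...) {
  cat(sprintf(
    "# Cost grid: c_mu = %g, c_max = %g, delta = %g; 19 values in [%g, %g]%s\n",
    x$c_mu, x$c_max, x$delta, min(x$values), max(x$values),
    if (any(x$clipped)) sprintf(" (%d clipped to %g)", sum(x$clipped),
                                1e-6 * x$c_mu) else ""
  ))
  invisible(x)
}
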