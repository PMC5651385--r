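# Independent brute-force oracles used to pin down expected values.

# Hard-margin maximum-margin linear SVM by KKT enumeration: for every
# candidate support set S (size 2..d+1, both classes represented) solve the
# equality system
#   sum_j a_j y_j <x_j, x_i> + b = y_i   (i in S),   sum_j a_j y_j = 0
# and keep the feasible solution (a >= 0, all margins >= 1) with minimal
# ||w||. Only intended for <= 6 points.
oracle_hard_margin <- function(x, y) {
  stopifnot(nrow(x) <= 6, all(y %in% c(-1, 1)))
  n <- nrow(x)
  d <- ncol(x)
  gram <- x %*% t(x)
  best <- NULL
  for (m in 2:min(n, d + 1)) {
    for (s in utils::combn(n, m, simplify = FALSE)) {
      if (length(unique(y[s])) < 2) next
      a_mat <- rbind(cbind(gram[s, s, drop = FALSE] *
                             outer(rep(1, m), y[s]), 1),
                     c(y[s], 0))
      rhs <- c(y[s], 0)
      sol <- tryCatch(solve(a_mat, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha <- sol[seq_len(m)]
      b <- sol[m + 1]
      if (any(alpha < -1e-9)) next
      w <- drop(t(x[s, , drop = FALSE]) %*% (alpha * y[s]))
      if (any(y * (drop(x %*% w) + b) < 1 - 1e-6)) next
      if (is.null(best) || sum(w^2) < best$wsq - 1e-12) {
        best <- list(w = w, b = b, wsq = sum(w^2))
      }
    }
  }
  best
}

# Smallest cost on a dense log grid whose fitted SVM makes no training error.
oracle_c_mu_grid <- function(train, n_points = 200, lo = 1e-4, hi = 1e8) {
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_points)
  for (cost in grid) {
    if (fit_linear_svm(train, cost)$n_errors == 0) return(cost)
  }
  stop("oracle: no separating cost on the grid")
}

# find_c_max rule evaluated on a denser candidate grid.
oracle_c_max_dense <- function(train, c_mu, factor = 10, span = 1e4) {
  find_c_max(train, c_mu, n_candidates = 40 * factor, span = span)
}

# Separable cohort whose minimum separating cost is interior (not at the
# probe floor): the separating direction (x2 - x1) is near-orthogonal to the
# class-mean difference, so weakly regularized fits misclassify and the
# zero-error transition happens at a finite cost ~ 1/margin^2.
make_hard_table <- function(n_per_class = 6, margin = 0.2, seed = 1) {
  withr::with_seed(seed, {
    z <- rnorm(2 * n_per_class)
    e <- rnorm(2 * n_per_class, sd = 0.01)
  })
  y <- rep(c(-1, 1), each = n_per_class)
  cohort_features(cbind(z, z + y * margin + e), as.integer(y == 1))
}

# Small separable cohort: one informative feature plus noise columns.
make_separable_table <- function(n_per_class = 6, n_voxels = 3, gap = 1,
                                 seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(2 * n_per_class * n_voxels, sd = 0.1),
                2 * n_per_class, n_voxels)
  })
  labels <- rep(c(0L, 1L), each = n_per_class)
  m[, 1] <- m[, 1] + ifelse(labels == 1, gap, -gap)
  cohort_features(m, labels)
}
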