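#' Deterministic k-fold assignment
#'
#' Shuffles the indices with the seeded generator and deals them into `k`
#' folds whose sizes differ by at most one.
#'
#' @param n Number of records.
#' @param k Number of folds, between 2 and `n`.
#' @param seed Integer seed.
#' @return Integer vector of length `n` with fold labels in `1:k`.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  check_number(n, "n", 1)
  check_number(k, "k", 2)
  if (k > n) stopf("k = %d folds cannot partition n = %d records", k, n)
  with_seed(seed, {
    folds <- integer(n)
    folds[sample.int(n)] <- rep(seq_len(k), length.out = n)
    folds
  })
}

#' Cross-validated mean squared error
#'
#' For each fold, fits on the remaining records and predicts the held-out
#' ones; returns the mean of squared residuals pooled over all held-out
#' points, on the scale of `y` (the pipeline computes it on the normalized
#' target scale, where normalization precedes fitting).
#'
#' @param x Numeric matrix of inputs.
#' @param y Numeric target vector.
#' @param folds Fold labels from [kfold_indices()].
#' @param config A [svr_config()] used for every fold's fit.
#' @param fitter Fitting routine `function(x, y)` returning either an object
#'   with a `predict` method or a plain prediction `function(x)`. Defaults to
#'   the package's epsilon-SVR; swapping it isolates the cross-validation
#'   arithmetic from the model.
#' @return Scalar CV mean squared error.
#' @export
cv_mse <- function(x, y, folds, config = svr_config(),
                   fitter = function(x, y) svr_fit(x, y, config)) {
  x <- as.matrix(x)
  if (length(folds) != nrow(x) || length(y) != nrow(x)) {
    stopf("x, y and folds disagree in length")
  }
  sq_sum <- 0
  for (f in unique(folds)) {
    held <- folds == f
    if (sum(!held) < 2L) stopf("fold %s leaves fewer than 2 training records", f)
    model <- fitter(x[!held, , drop = FALSE], y[!held])
    pred <- if (is.function(model)) {
      model(x[held, , drop = FALSE])
    } else {
      stats::predict(model, x[held, , drop = FALSE])
    }
    sq_sum <- sq_sum + sum((pred - y[held])^2)
  }
  sq_sum / length(y)
}

#' Grid specification for hyperparameter search
#'
#' Candidate penalty parameters c and kernel parameters g, both enumerated in
#' log2 space (the conventional SVR search lattice). The kernel parameter
#' relates to the Gaussian width as \eqn{g = 1/\sigma^2}.
#'
#' @param log2_C Exponents of the penalty candidates; default -2..10.
#' @param log2_gamma Exponents of the kernel-parameter candidates; default
#'   -8..4.
#' @param k Number of cross-validation folds; default 5.
#' @param seed Seed for the shared fold assignment.
#' @return Object of class `welan_grid_spec`.
#' @export
grid_spec <- function(log2_C = -2:10, log2_gamma = -8:4, k = 5L, seed = 1L) {
  if (length(log2_C) == 0L || length(log2_gamma) == 0L) stopf("empty grid")
  check_number(k, "k", 2)
  structure(list(C = sort(2^log2_C), gamma = sort(2^log2_gamma),
                 k = as.integer(k), seed = seed),
            class = "welan_grid_spec")
}

#' Grid search of (c, g) by cross-validated MSE
#'
#' Evaluates [cv_mse()] at every (penalty, kernel parameter) cell of the
#' grid, all cells sharing one fold assignment, and returns the cell with
#' minimum CVmse. Ties are broken towards the smallest penalty, then the
#' smallest kernel parameter (the smoother model), so the winner does not
#' depend on enumeration order.
#'
#' @param x Numeric matrix of training inputs (normalized).
#' @param y Training targets (normalized).
#' @param grid A [grid_spec()].
#' @param epsilon,kkt_tolerance,max_passes Passed to each cell's
#'   [svr_config()].
#' @return Object of class `welan_grid`: data frame `table` (C, gamma, sigma,
#'   cvmse), the winning `best` row, fold labels and the spec.
#' @export
grid_search <- function(x, y, grid = grid_spec(), epsilon = 0.01,
                        kkt_tolerance = 1e-6, max_passes = 100000L) {
  stopifnot(inherits(grid, "welan_grid_spec"))
  x <- as.matrix(x)
  n <- nrow(x)
  folds <- kfold_indices(n, grid$k, grid$seed)
  cells <- expand.grid(gamma = grid$gamma, C = grid$C,
                       KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  cells <- cells[order(cells$C, cells$gamma), , drop = FALSE]
  cells$sigma <- 1 / sqrt(cells$gamma)
  cells$cvmse <- vapply(seq_len(nrow(cells)), function(i) {
    cfg <- svr_config(C = cells$C[i], epsilon = epsilon, sigma = cells$sigma[i],
                      kkt_tolerance = kkt_tolerance, max_passes = max_passes)
    cv_mse(x, y, folds, cfg)
  }, numeric(1))
  best <- cells[which.min(cells$cvmse), , drop = FALSE]
  structure(list(table = cells, best = best, folds = folds, spec = grid),
            class = "welan_grid")
}

#' @export
print.welan_grid <- function(x, ...) {
  cat(sprintf("Grid search over %d cells, %d-fold CV\n",
              nrow(x$table), x$spec$k))
  cat(sprintf("  best: C = %g, g = %g (sigma = %g), CVmse = %.6g\n",
              x$best$C, x$best$gamma, x$best$sigma, x$best$cvmse))
  invisible(x)
}

#' Export grid-search results as CSV
#'
#' One row per grid cell (C, gamma, sigma, cvmse), suitable for contour
#' plotting of the CVmse surface.
#'
#' @param grid_result A `welan_grid` object.
#' @param path CSV file path.
#' @export
write_grid <- function(grid_result, path) {
  if (!inherits(grid_result, "welan_grid")) stopf("not a welan_grid object")
  utils::write.csv(grid_result$table, path, row.names = FALSE)
  invisible(path)
}

#' Squared correlation accuracy score
#'
#' The square of the Pearson correlation between predictions and observed
#' targets, the model-accuracy index used for the held-out test split. As a
#' squared correlation it is invariant to affine rescaling of either
#' argument, so it is identical on the normalized and the raw g/L scale.
#'
#' @param predictions,targets Numeric vectors of equal length (>= 2).
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 27/28
r_squared <- function(predictions, targets) {
  if (length(predictions) != length(targets)) {
    stopf("predictions and targets differ in length")
  }
  if (length(targets) < 2L) stopf("need at least two points")
  if (stats::sd(targets) == 0) stopf("targets are constant; r^2 is undefined")
  if (stats::sd(predictions) == 0) stopf("predictions are constant; r^2 is undefined")
  stats::cor(predictions, targets)^2
}
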