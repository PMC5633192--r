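#' Configuration for the epsilon-SVR solver
#'
#' @param C Penalty parameter weighting deviations beyond the epsilon tube;
#'   larger values fit the training data more tightly. Must be positive.
#' @param epsilon Half-width of the insensitive tube on the (normalized)
#'   target scale; residuals smaller than `epsilon` incur no loss. Default
#'   0.01 on a \[0, 1\] target.
#' @param sigma Width of the Gaussian radial-basis kernel
#'   \eqn{K(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / \sigma^2)}. Note the
#'   denominator is \eqn{\sigma^2}, not \eqn{2\sigma^2}; the grid-search
#'   kernel parameter g maps as \eqn{g = 1/\sigma^2}.
#' @param kkt_tolerance Convergence tolerance on the maximum violation of the
#'   optimality (KKT) conditions of the dual problem.
#' @param max_passes Cap on pairwise solver updates before giving up.
#' @return Object of class `welan_svr_config`.
#' @export
svr_config <- function(C = 1, epsilon = 0.01, sigma = 1,
                       kkt_tolerance = 1e-6, max_passes = 100000L) {
  check_number(C, "C", 0, strict_lower = TRUE)
  check_number(epsilon, "epsilon", 0)
  check_number(sigma, "sigma", 0, strict_lower = TRUE)
  check_number(kkt_tolerance, "kkt_tolerance", 0, strict_lower = TRUE)
  check_number(max_passes, "max_passes", 1)
  structure(list(C = C, epsilon = epsilon, sigma = sigma,
                 kkt_tolerance = kkt_tolerance,
                 max_passes = as.integer(max_passes)),
            class = "welan_svr_config")
}

#' Gaussian radial-basis kernel
#'
#' \eqn{K(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / \sigma^2)}: 1 at zero distance,
#' decaying towards 0, symmetric in its arguments.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param sigma Kernel width, positive.
#' @return Kernel value in (0, 1].
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), sigma = 1)  # exp(-1)
rbf_kernel <- function(xi, xj, sigma) {
  check_number(sigma, "sigma", 0, strict_lower = TRUE)
  if (length(xi) != length(xj)) stopf("xi and xj differ in length")
  exp(-sum((xi - xj)^2) / sigma^2)
}

#' Kernel (Gram) matrix of a point set
#'
#' @param points Numeric matrix, one point per row.
#' @param sigma Kernel width.
#' @return Symmetric positive semidefinite matrix with unit diagonal.
#' @export
gram_matrix <- function(points, sigma) {
  check_number(sigma, "sigma", 0, strict_lower = TRUE)
  points <- as.matrix(points)
  if (nrow(points) < 1L) stopf("need at least one point")
  sq <- rowSums(points^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(points)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma^2)
}

cross_kernel <- function(a, b, sigma) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma^2)
}

# Dual objective in net-coefficient form: at any point with the
# complementarity alpha_i * alpha_i^* = 0 the dual of epsilon-SVR reduces to
#   0.5 beta' K beta + epsilon * sum|beta| - y' beta,  beta_i = alpha_i - alpha_i^*.
dual_objective <- function(beta, gram, y, epsilon) {
  as.numeric(0.5 * crossprod(beta, gram %*% beta) +
               epsilon * sum(abs(beta)) - sum(y * beta))
}

# Feasible bias interval [lo_i, hi_i] implied by each training point's KKT
# condition, given d = y - K beta. The solution is optimal iff the intervals
# intersect: max(lo) <= min(hi).
kkt_bias_bounds <- function(beta, d, C, epsilon, bnd_eps) {
  lo <- rep(-Inf, length(beta))
  hi <- rep(Inf, length(beta))
  at_upper <- beta >= C - bnd_eps
  at_lower <- beta <= -C + bnd_eps
  at_zero <- abs(beta) <= bnd_eps
  free_pos <- !at_upper & !at_zero & beta > 0
  free_neg <- !at_lower & !at_zero & beta < 0
  hi[at_upper] <- d[at_upper] - epsilon
  lo[at_lower] <- d[at_lower] + epsilon
  lo[at_zero] <- d[at_zero] - epsilon
  hi[at_zero] <- d[at_zero] + epsilon
  lo[free_pos] <- hi[free_pos] <- d[free_pos] - epsilon
  lo[free_neg] <- hi[free_neg] <- d[free_neg] + epsilon
  list(lo = lo, hi = hi)
}

# Best feasible step delta for the pair (i, j): beta_i <- beta_i + delta,
# beta_j <- beta_j - delta (preserving sum(beta) = 0). The objective restricted
# to delta is piecewise quadratic with kinks where beta_i + delta or
# beta_j - delta crosses zero; the exact minimizer is found by checking the
# stationary point of each smooth piece plus the kinks and box ends.
pair_step <- function(beta, grad, gram, i, j, C, epsilon) {
  eta <- gram[i, i] + gram[j, j] - 2 * gram[i, j]
  gdiff <- grad[i] - grad[j]
  d_lo <- max(-C - beta[i], beta[j] - C)
  d_hi <- min(C - beta[i], beta[j] + C)
  cand <- c(d_lo, d_hi,
            min(max(-beta[i], d_lo), d_hi),
            min(max(beta[j], d_lo), d_hi))
  if (eta > 0) {
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      cand <- c(cand, min(max(-(gdiff + epsilon * (s1 - s2)) / eta, d_lo), d_hi))
    }
  }
  phi <- function(delta) {
    0.5 * eta * delta^2 + gdiff * delta +
      epsilon * (abs(beta[i] + delta) - abs(beta[i]) +
                   abs(beta[j] - delta) - abs(beta[j]))
  }
  vals <- vapply(cand, phi, numeric(1))
  best <- which.min(vals)
  list(delta = cand[best], decrease = -vals[best])
}

#' Solve the epsilon-SVR dual problem
#'
#' Minimizes the dual quadratic program
#' \deqn{\min_{\alpha,\alpha^*} \tfrac12 \sum_{ij} (\alpha_i-\alpha_i^*)
#'   (\alpha_j-\alpha_j^*) K_{ij} + \epsilon \sum_i (\alpha_i+\alpha_i^*)
#'   - \sum_i y_i (\alpha_i-\alpha_i^*)}
#' subject to \eqn{\sum_i (\alpha_i - \alpha_i^*) = 0} and
#' \eqn{0 \le \alpha_i, \alpha_i^* \le C}, by sequential minimal optimization:
#' exact analytic updates of the maximally KKT-violating pair of net
#' coefficients \eqn{\beta_i = \alpha_i - \alpha_i^*}, initialized at zero and
#' maintaining the equality constraint throughout. Convergence is declared
#' when the maximum KKT violation (the gap between the largest lower and
#' smallest upper bound on the bias implied by the individual optimality
#' conditions) drops below `kkt_tolerance`. Working in net coefficients makes
#' the complementarity \eqn{\alpha_i \alpha_i^* = 0} hold exactly by
#' construction.
#'
#' @param targets Numeric vector of training targets (normalized scale).
#' @param gram Kernel matrix of the training points.
#' @param config A [svr_config()].
#' @return Object of class `welan_dual`: list with `alpha`, `alpha_star`,
#'   `beta`, `objective`, `iterations`, `converged`, `max_violation`.
#' @export
solve_dual <- function(targets, gram, config) {
  stopifnot(inherits(config, "welan_svr_config"))
  gram <- as.matrix(gram)
  n <- length(targets)
  if (nrow(gram) != n || ncol(gram) != n) {
    stopf("gram must be %d x %d to match the targets", n, n)
  }
  C <- config$C
  epsilon <- config$epsilon
  tol <- config$kkt_tolerance
  bnd_eps <- 1e-10 * max(1, C)

  beta <- numeric(n)
  u <- numeric(n)            # u = gram %*% beta, kept incrementally
  iterations <- 0L
  converged <- FALSE
  violation <- Inf

  repeat {
    d <- targets - u
    bb <- kkt_bias_bounds(beta, d, C, epsilon, bnd_eps)
    i_up <- which.max(bb$lo)
    i_low <- which.min(bb$hi)
    violation <- bb$lo[i_up] - bb$hi[i_low]
    if (violation < tol) {
      converged <- TRUE
      break
    }
    if (iterations >= config$max_passes) break
    grad <- u - targets    # gradient of the smooth part of the objective
    step <- pair_step(beta, grad, gram, i_up, i_low, C, epsilon)
    if (step$decrease <= 0) {
      # Maximal pair made no progress (e.g. duplicated points); scan i_up and
      # i_low against all partners for the best available decrease.
      best <- list(decrease = 0)
      pair <- NULL
      for (i in c(i_up, i_low)) {
        for (j in seq_len(n)[-i]) {
          s <- pair_step(beta, grad, gram, i, j, C, epsilon)
          if (s$decrease > best$decrease) {
            best <- s
            pair <- c(i, j)
          }
        }
      }
      if (is.null(pair) || best$decrease <= 0) break
      i_up <- pair[1L]; i_low <- pair[2L]; step <- best
    }
    delta <- step$delta
    beta[i_up] <- beta[i_up] + delta
    beta[i_low] <- beta[i_low] - delta
    u <- u + delta * (gram[, i_up] - gram[, i_low])
    iterations <- iterations + 1L
  }
  if (!converged) {
    warnf("dual solver did not converge: KKT violation %.3g after %d updates",
          violation, iterations)
  }
  structure(list(alpha = pmax(beta, 0), alpha_star = pmax(-beta, 0),
                 beta = beta,
                 objective = dual_objective(beta, gram, targets, epsilon),
                 iterations = iterations, converged = converged,
                 max_violation = max(violation, 0)),
            class = "welan_dual")
}

#' Bias of the fitted regression function
#'
#' Averages the boundary conditions of the standard support vectors (points
#' with a dual coefficient strictly inside (0, C)):
#' \eqn{b = y_i - \sum_j \beta_j K_{ji} - \epsilon} on the \eqn{\alpha} side
#' and \eqn{+ \epsilon} on the \eqn{\alpha^*} side, averaged over all
#' \eqn{N_{NSV}} such points. If no standard support vector exists the
#' midpoint of the KKT-feasible bias interval is used, with a warning.
#'
#' @param solution A `welan_dual` solution.
#' @param gram Training kernel matrix.
#' @param targets Training targets.
#' @param epsilon Tube half-width used in the fit.
#' @param C Penalty parameter used in the fit.
#' @return List with `b` and `n_standard_sv`.
#' @export
compute_bias <- function(solution, gram, targets, epsilon, C) {
  beta <- solution$beta
  u <- as.numeric(as.matrix(gram) %*% beta)
  d <- targets - u
  bnd_eps <- 1e-10 * max(1, C)
  free_pos <- beta > bnd_eps & beta < C - bnd_eps
  free_neg <- beta < -bnd_eps & beta > -C + bnd_eps
  estimates <- c(d[free_pos] - epsilon, d[free_neg] + epsilon)
  if (length(estimates) > 0L) {
    return(list(b = mean(estimates), n_standard_sv = length(estimates)))
  }
  warnf("no standard support vectors; using the midpoint of the feasible bias interval")
  bb <- kkt_bias_bounds(beta, d, C, epsilon, bnd_eps)
  list(b = (max(bb$lo) + min(bb$hi)) / 2, n_standard_sv = 0L)
}

#' Fit an epsilon-SVR surrogate
#'
#' Composes the kernel matrix, the dual solver ([solve_dual()]) and the bias
#' computation ([compute_bias()]) into a trained surrogate. Inputs are
#' expected on the normalized scale; attach the scaling afterwards (or via
#' `scaling =`) so that [evaluate_fitness()] can map raw candidate conditions
#' through the model.
#'
#' @param x Numeric matrix of training inputs (rows = records, normalized).
#' @param y Numeric vector of training targets (normalized).
#' @param config A [svr_config()].
#' @param scaling Optional `welan_scaling` to attach to the model.
#' @return Object of class `welan_svr`: support vectors `x_sv`, net dual
#'   coefficients `beta_sv`, bias `b`, `sigma`, `config`, `scaling` and
#'   `diagnostics` (support-vector counts, dual objective, iterations,
#'   convergence flag).
#' @export
#' @examples
#' x <- matrix(seq(0, 1, length.out = 8))
#' y <- sin(2 * x[, 1])
#' m <- svr_fit(x, y, svr_config(C = 10, epsilon = 0.01, sigma = 0.5))
#' predict(m, matrix(0.5))
svr_fit <- function(x, y, config = svr_config(), scaling = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("x and y disagree in length")
  if (nrow(x) < 2L) stopf("need at least two training records")
  gram <- gram_matrix(x, config$sigma)
  sol <- solve_dual(y, gram, config)
  bias <- compute_bias(sol, gram, y, config$epsilon, config$C)
  sv <- which(abs(sol$beta) > 1e-8)
  structure(list(x_sv = x[sv, , drop = FALSE],
                 beta_sv = sol$beta[sv],
                 b = bias$b,
                 sigma = config$sigma,
                 config = config,
                 scaling = scaling,
                 diagnostics = list(n_train = length(y),
                                    n_sv = length(sv),
                                    n_standard_sv = bias$n_standard_sv,
                                    dual_objective = sol$objective,
                                    iterations = sol$iterations,
                                    converged = sol$converged)),
            class = "welan_svr")
}

#' Predict with a fitted surrogate
#'
#' Kernel expansion over the support vectors:
#' \eqn{f(x) = \sum_{i \in SV} \beta_i K(x_i, x) + b}.
#'
#' @param object A `welan_svr` model.
#' @param newdata Matrix of points (rows), on the same (normalized) scale as
#'   the training inputs.
#' @param ... Unused.
#' @return Numeric vector of predictions on the normalized target scale.
#' @export
predict.welan_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(object$x_sv) == 0L) {
    return(rep(object$b, nrow(newdata)))
  }
  if (ncol(newdata) != ncol(object$x_sv)) {
    stopf("newdata has %d columns; model expects %d",
          ncol(newdata), ncol(object$x_sv))
  }
  as.numeric(cross_kernel(newdata, object$x_sv, object$sigma) %*%
               object$beta_sv + object$b)
}

#' @export
print.welan_svr <- function(x, ...) {
  d <- x$diagnostics
  cat("epsilon-SVR surrogate (Gaussian RBF kernel)\n")
  cat(sprintf("  C = %g, epsilon = %g, sigma = %g\n",
              x$config$C, x$config$epsilon, x$sigma))
  cat(sprintf("  %d support vectors (%d standard) of %d training records\n",
              d$n_sv, d$n_standard_sv, d$n_train))
  cat(sprintf("  dual objective %.6g, %d solver updates, converged: %s\n",
              d$dual_objective, d$iterations, d$converged))
  if (!is.null(x$scaling)) cat("  scaling attached\n")
  invisible(x)
}

#' Serialize a fitted surrogate to JSON
#'
#' Stores support vectors, net dual coefficients, bias, kernel width and the
#' attached scaling so that the genetic-algorithm stage (or another session)
#' can reproduce predictions bit-identically.
#'
#' @param model A `welan_svr` model.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "welan_svr")) stopf("not a welan_svr model")
  obj <- list(x_sv = model$x_sv, beta_sv = model$beta_sv, b = model$b,
              sigma = model$sigma,
              config = unclass(model$config),
              diagnostics = model$diagnostics)
  if (!is.null(model$scaling)) {
    obj$scaling <- list(x_min = as.list(model$scaling$x_min),
                        x_max = as.list(model$scaling$x_max),
                        y_min = model$scaling$y_min,
                        y_max = model$scaling$y_max)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling <- NULL
  if (!is.null(obj$scaling)) {
    scaling <- make_scaling(unlist(obj$scaling$x_min), unlist(obj$scaling$x_max),
                            obj$scaling$y_min, obj$scaling$y_max)
  }
  cfg <- svr_config(C = obj$config$C, epsilon = obj$config$epsilon,
                    sigma = obj$config$sigma,
                    kkt_tolerance = obj$config$kkt_tolerance,
                    max_passes = obj$config$max_passes)
  structure(list(x_sv = as.matrix(obj$x_sv), beta_sv = as.numeric(obj$beta_sv),
                 b = obj$b, sigma = obj$sigma, config = cfg, scaling = scaling,
                 diagnostics = obj$diagnostics),
            class = "welan_svr")
}
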