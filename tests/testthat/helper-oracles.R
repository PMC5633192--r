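# Shared fixtures and independent oracles for the test suite.

fixture_raw <- function() {
  read_table(system.file("extdata", "table1_raw.csv", package = "welanopt"))
}

fixture_normalized <- function() {
  read_table(system.file("extdata", "table2_normalized.csv", package = "welanopt"))
}

# Exact solution of the epsilon-SVR dual by active-set enumeration, entirely
# independent of the SMO solver. In net coefficients beta_i = alpha_i -
# alpha_i^* the dual is min 0.5 b'Kb + eps*sum|b| - y'b over the box
# [-C, C]^n with sum(b) = 0. Every optimum has each coordinate at -C, 0, +C,
# or free with a fixed sign; for each of the 5^n configurations the free
# coordinates solve an equality-constrained linear system, and the best
# feasible candidate is the global optimum (the objective is convex).
# Tractable for n <= 6.
qp_enum_oracle <- function(y, gram, C, epsilon) {
  n <- length(y)
  obj <- function(beta) {
    0.5 * sum(beta * (gram %*% beta)) + epsilon * sum(abs(beta)) - sum(y * beta)
  }
  states <- as.matrix(expand.grid(rep(list(1:5), n)))
  best_obj <- Inf
  best_beta <- numeric(n)
  for (r in seq_len(nrow(states))) {
    st <- states[r, ]
    beta <- numeric(n)
    beta[st == 1] <- -C
    beta[st == 5] <- C
    free <- which(st == 2 | st == 4)
    s <- ifelse(st == 4, 1, -1)[free]
    if (length(free) > 0L) {
      fixed <- setdiff(seq_len(n), free)
      A <- rbind(cbind(gram[free, free, drop = FALSE], 1),
                 c(rep(1, length(free)), 0))
      rhs_top <- y[free] - epsilon * s
      if (length(fixed) > 0L) {
        rhs_top <- rhs_top - gram[free, fixed, drop = FALSE] %*% beta[fixed]
      }
      sol <- tryCatch(solve(A, c(rhs_top, -sum(beta))), error = function(e) NULL)
      if (is.null(sol)) next
      bF <- sol[seq_along(free)]
      if (any(sign(bF) * s < 0) || any(abs(bF) > C)) next
      beta[free] <- bF
    } else if (abs(sum(beta)) > 1e-12) {
      next
    }
    o <- obj(beta)
    if (o < best_obj) {
      best_obj <- o
      best_beta <- beta
    }
  }
  list(objective = best_obj, beta = best_beta)
}

# Scaling for the printed-record fixture: three condition columns (kh2po4,
# mgso4, liquid volume) are constant across the 25 printed records, so their
# extrema cannot be fitted from the fixture; the encoding ranges of the
# condition space stand in for them.
fixture_scaling <- function() {
  raw <- fixture_raw()
  variable <- c("glucose", "yeast", "ph", "temperature", "rotational_speed",
                "inoculation_amount", "production")
  sc <- fit_scaling(raw, columns = variable)
  b <- ga_bounds("wide")
  constant <- c("kh2po4", "mgso4", "liquid_volume")
  make_scaling(c(sc$x_min, stats::setNames(b[constant, "lo"], constant)),
               c(sc$x_max, stats::setNames(b[constant, "hi"], constant)))
}

# Random small epsilon-SVR instance for oracle comparisons.
random_svr_instance <- function(n_max = 6L) {
  n <- sample(2:n_max, 1L)
  list(x = matrix(stats::runif(n * 3), n),
       y = stats::runif(n, -1, 1),
       C = 2^stats::runif(1, -2, 4),
       epsilon = stats::runif(1, 0, 0.2),
       sigma = 2^stats::runif(1, -1, 1))
}

# Separable concave quadratic response with known argmax, the ground truth
# for optimizer-recovery tests. Scaled so fitness spans its full range
# (peak down to 0) inside the bounds, giving proportional selection full
# discrimination.
quadratic_fitness <- function(optimum, peak, weights) {
  force(optimum); force(peak); force(weights)
  function(genes) {
    delta <- genes - matrix(optimum, nrow(genes), length(optimum), byrow = TRUE)
    pmax(0, peak - as.numeric(delta^2 %*% weights))
  }
}
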