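#' Search bounds for the nine condition genes
#'
#' Two named presets ship with the package: `"wide"`, the initial encoding
#' ranges for the nine condition variables, and `"narrow"`, the refined
#' ranges read off the high-yield (> 30 g/L) fermentation records. A custom
#' 9 x 2 matrix (columns `lo`, `hi`, rows named as [condition_names()]) is
#' accepted anywhere a preset is.
#'
#' @param preset `"wide"` or `"narrow"`, or a 9 x 2 numeric matrix.
#' @return 9 x 2 numeric matrix with columns `lo` and `hi`.
#' @export
#' @examples
#' ga_bounds("wide")["glucose", ]
ga_bounds <- function(preset = c("wide", "narrow")) {
  if (is.matrix(preset)) return(validate_bounds(preset))
  preset <- match.arg(preset)
  vals <- switch(preset,
    wide = c(5, 95,  1, 10,  1, 6,  0.1, 1,  25, 125,
             2, 12,  25, 35,  125, 250,  1, 10),
    narrow = c(55, 60,  2.5, 3.1,  5, 5.5,  0.1, 0.3,  48, 51.5,
               6.7, 7.15,  32, 33,  176, 179,  4.85, 5.15))
  b <- matrix(vals, ncol = 2, byrow = TRUE,
              dimnames = list(condition_names(), c("lo", "hi")))
  validate_bounds(b)
}

validate_bounds <- function(bounds) {
  if (!is.matrix(bounds) || ncol(bounds) != 2L ||
      nrow(bounds) != length(condition_names())) {
    stopf("bounds must be a %d x 2 matrix", length(condition_names()))
  }
  if (is.null(rownames(bounds))) rownames(bounds) <- condition_names()
  colnames(bounds) <- c("lo", "hi")
  if (any(bounds[, "lo"] >= bounds[, "hi"])) {
    stopf("each gene bound must satisfy lo < hi (violated for: %s)",
          paste(rownames(bounds)[bounds[, "lo"] >= bounds[, "hi"]], collapse = ", "))
  }
  bounds
}

#' Configuration of the adaptive genetic algorithm
#'
#' Defaults are the study-scale settings: population 300, 500 generations,
#' crossover probability decaying from 0.9 to 0.6 and mutation probability
#' bounded by 0.1 and 0.001.
#'
#' @param pop_size Population size K (>= 2).
#' @param t_gen Maximum number of generations T_Gen (>= 0; with 0 the search
#'   reduces to scoring the initial population).
#' @param pc_max,pc_min Upper/lower crossover-probability bounds.
#' @param pm_max,pm_min Upper/lower mutation-probability bounds.
#' @param elitism Copy the best-ever individual into each new generation
#'   (guarantees monotone best fitness)? Default `TRUE`.
#' @param seed Integer seed driving the whole run.
#' @return Object of class `welan_ga_config`.
#' @export
ga_config <- function(pop_size = 300L, t_gen = 500L,
                      pc_max = 0.9, pc_min = 0.6,
                      pm_max = 0.1, pm_min = 0.001,
                      elitism = TRUE, seed = 1L) {
  check_number(pop_size, "pop_size", 2)
  check_number(t_gen, "t_gen", 0)
  check_number(pc_min, "pc_min", 0, pc_max, strict_lower = TRUE)
  check_number(pc_max, "pc_max", pc_min, 1)
  check_number(pm_min, "pm_min", 0, pm_max, strict_lower = TRUE)
  check_number(pm_max, "pm_max", pm_min, 1)
  structure(list(pop_size = as.integer(pop_size), t_gen = as.integer(t_gen),
                 pc_max = pc_max, pc_min = pc_min,
                 pm_max = pm_max, pm_min = pm_min,
                 elitism = isTRUE(elitism), seed = seed),
            class = "welan_ga_config")
}

#' Adaptive crossover probability schedule
#'
#' The crossover probability depends only on the generation counter:
#' \eqn{m_{tmp} = P_{c,max} \cdot 2^{-t/T_{Gen}}}, floored at
#' \eqn{P_{c,min}}. It decays from \eqn{P_{c,max}} at t = 0 and reaches the
#' floor once \eqn{2^{-t/T_{Gen}} \le P_{c,min}/P_{c,max}}.
#'
#' @param t Current generation, in `0:t_gen`.
#' @param config A [ga_config()].
#' @return Probability in \[`pc_min`, `pc_max`\].
#' @export
#' @examples
#' crossover_prob(0, ga_config())     # 0.9
#' crossover_prob(500, ga_config())   # floored at 0.6
crossover_prob <- function(t, config) {
  stopifnot(inherits(config, "welan_ga_config"))
  check_number(t, "t", 0, config$t_gen)
  ratio <- if (config$t_gen == 0) 0 else t / config$t_gen
  m_tmp <- config$pc_max * 2^(-ratio)
  if (m_tmp > config$pc_min) m_tmp else config$pc_min
}

#' Adaptive mutation probability
#'
#' Depends on both the generation and the individual's fitness gap to the
#' population best:
#' \deqn{m_{tmp} = \exp\!\left(-\left|\frac{f_{max} - f(x_i)}{f_{max}}\right|\right)
#'   \cdot \frac{1}{1 + t/T_{Gen}} \cdot P_{m,max},}
#' floored at \eqn{P_{m,min}}. Fit individuals late in the run mutate least.
#' A degenerate population with `f_max = 0` leaves the relative gap
#' undefined; the maximal-exploration rate `pm_max` is returned with a
#' warning.
#'
#' @param f_i Fitness of the individual (>= 0).
#' @param f_max Maximum fitness in the current population (>= `f_i`).
#' @param t Current generation, in `0:t_gen`.
#' @param config A [ga_config()].
#' @return Probability in \[`pm_min`, `pm_max`\].
#' @export
#' @examples
#' mutation_prob(1, 1, 0, ga_config())  # 0.1
mutation_prob <- function(f_i, f_max, t, config) {
  stopifnot(inherits(config, "welan_ga_config"))
  check_number(t, "t", 0, config$t_gen)
  if (any(f_i < 0) || any(f_max < f_i)) stopf("need 0 <= f_i <= f_max")
  if (f_max == 0) {
    warnf("f_max = 0: mutation probability set to pm_max")
    return(config$pm_max)
  }
  ratio <- if (config$t_gen == 0) 0 else t / config$t_gen
  m_tmp <- exp(-abs((f_max - f_i) / f_max)) * (1 / (1 + ratio)) * config$pm_max
  ifelse(m_tmp > config$pm_min, m_tmp, config$pm_min)
}

#' Initialize a random population
#'
#' @param bounds Bounds matrix or preset name (see [ga_bounds()]).
#' @param pop_size Number of individuals K.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return `pop_size` x 9 matrix, each gene uniform within its bound.
#' @export
init_population <- function(bounds, pop_size, seed = NULL) {
  bounds <- ga_bounds(bounds)
  check_number(pop_size, "pop_size", 2)
  with_seed(seed, {
    pop <- sapply(seq_len(nrow(bounds)), function(j) {
      stats::runif(pop_size, bounds[j, "lo"], bounds[j, "hi"])
    })
    pop <- matrix(pop, nrow = pop_size,
                  dimnames = list(NULL, rownames(bounds)))
    pop
  })
}

#' Fitness of candidate conditions under a surrogate
#'
#' Normalizes the raw-unit genes with the model's attached scaling, predicts
#' the normalized production with the kernel expansion, denormalizes back to
#' g/L, and floors at zero (predicted yields are physically non-negative and
#' roulette selection requires non-negative weights). Candidates outside the
#' scaling's fitted range are extrapolated by the same affine map; the
#' fraction of such candidates is attached as attribute `"extrapolated"`.
#'
#' @param genes Matrix of candidates (rows) in raw condition units, columns
#'   ordered as [condition_names()], or a single candidate vector.
#' @param model A `welan_svr` model with scaling attached.
#' @return Numeric vector of predicted productions (g/L), floored at 0.
#' @export
evaluate_fitness <- function(genes, model) {
  if (!inherits(model, "welan_svr")) stopf("model must be a welan_svr object")
  if (is.null(model$scaling)) stopf("model has no scaling attached")
  if (is.null(dim(genes))) genes <- matrix(genes, nrow = 1)
  vars <- condition_names()
  if (ncol(genes) != length(vars)) stopf("candidates must have %d genes", length(vars))
  colnames(genes) <- vars
  norm <- genes
  extrapolated <- FALSE
  for (v in vars) {
    p <- scaling_column(model$scaling, v)
    if (any(genes[, v] < p$x_min | genes[, v] > p$x_max)) extrapolated <- TRUE
    norm[, v] <- normalize_column(genes[, v], model$scaling, v)
  }
  pred <- stats::predict(model, norm)
  yield <- denormalize_column(pred, model$scaling, production_name())
  structure(pmax(yield, 0), extrapolated = extrapolated)
}

#' Roulette (fitness-proportional) selection
#'
#' Draws K individuals with replacement, each selected with probability
#' \eqn{P(x_i) = f(x_i) / \sum_k f(x_k)}. A population whose total fitness is
#' zero is sampled uniformly, with a warning.
#'
#' @param population Matrix of individuals (rows).
#' @param fitness Non-negative fitness vector, one value per row.
#' @return List with the selected `population` matrix and matching `fitness`.
#' @export
roulette_select <- function(population, fitness) {
  if (nrow(population) != length(fitness)) {
    stopf("population and fitness disagree in length")
  }
  if (any(fitness < 0)) stopf("roulette selection needs non-negative fitness")
  total <- sum(fitness)
  k <- nrow(population)
  if (total == 0) {
    warnf("total fitness is zero; selecting uniformly")
    idx <- sample.int(k, k, replace = TRUE)
  } else {
    # Inverse-CDF sampling of the fitness-proportional distribution.
    idx <- findInterval(stats::runif(k), cumsum(fitness) / total) + 1L
  }
  list(population = population[idx, , drop = FALSE], fitness = fitness[idx])
}

#' Segment crossover pass over an ordered population
#'
#' Walks the population from the first individual. With probability
#' `crossover_prob(t, config)` the individual exchanges a gene segment with
#' the next adjacent individual: two integers in 1..9 are drawn, the smaller
#' is the start and the larger the end position (inclusive; equal endpoints
#' swap one gene), and the segment is swapped. After a crossover the walk
#' advances by two individuals, otherwise by one; the last individual has no
#' partner and never initiates a crossover. Gene values are conserved
#' position-wise across each crossed pair.
#'
#' @param population Matrix of individuals (rows).
#' @param t Current generation.
#' @param config A [ga_config()].
#' @return The recombined population matrix.
#' @export
crossover_pass <- function(population, t, config) {
  k <- nrow(population)
  n_genes <- ncol(population)
  pc <- crossover_prob(t, config)
  i <- 1L
  while (i < k) {
    if (stats::runif(1) < pc) {
      pos <- sort(sample.int(n_genes, 2L, replace = TRUE))
      seg <- pos[1L]:pos[2L]
      tmp <- population[i, seg]
      population[i, seg] <- population[i + 1L, seg]
      population[i + 1L, seg] <- tmp
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  population
}

#' Single-locus mutation pass
#'
#' Each individual mutates with its own adaptive probability
#' [mutation_prob()] (which requires the population to be evaluated): one
#' uniformly chosen gene is redrawn uniformly within its bound.
#'
#' @param population Matrix of individuals (rows), in raw units.
#' @param fitness Fitness vector of the population (>= 0).
#' @param t Current generation.
#' @param config A [ga_config()].
#' @param bounds Bounds matrix or preset name.
#' @return The mutated population matrix.
#' @export
mutation_pass <- function(population, fitness, t, config, bounds) {
  bounds <- ga_bounds(bounds)
  k <- nrow(population)
  if (length(fitness) != k) stopf("population and fitness disagree in length")
  f_max <- max(fitness)
  pm <- if (f_max == 0) {
    rep(mutation_prob(0, 0, t, config), k)
  } else {
    mutation_prob(fitness, f_max, t, config)
  }
  mutate <- stats::runif(k) < pm
  for (i in which(mutate)) {
    j <- sample.int(ncol(population), 1L)
    population[i, j] <- stats::runif(1, bounds[j, "lo"], bounds[j, "hi"])
  }
  population
}

#' Run the adaptive genetic algorithm
#'
#' Maximizes predicted production over the bounded condition space: an
#' initial uniform population is evolved for `t_gen` generations of roulette
#' selection, adaptive segment crossover, and adaptive single-locus mutation,
#' each individual scored by the surrogate. Crossed offspring are re-scored
#' before mutation, since the mutation probability depends on current
#' fitness. With elitism the best-ever individual replaces the generation's
#' worst, making the best fitness trace non-decreasing.
#'
#' @param model A `welan_svr` model with scaling attached, or any
#'   `function(genes_matrix) -> fitness` (g/L, non-negative) for searches over
#'   a known response surface.
#' @param bounds Bounds matrix or preset name (see [ga_bounds()]).
#' @param config A [ga_config()]; its `seed` drives the entire run, which is
#'   fully reproducible from (config, bounds, model).
#' @return Object of class `welan_ga`: `best` (list of `genes`, `fitness`),
#'   `trace` data frame (generation 0..t_gen, best and mean fitness), the
#'   `config` and `bounds`.
#' @export
#' @examples
#' b <- cbind(lo = rep(0, 9), hi = rep(10, 9))
#' rownames(b) <- condition_names()
#' peak <- function(g) pmax(0, 30 - rowSums((g - 5)^2))
#' res <- evolve(peak, b, ga_config(pop_size = 30, t_gen = 20, seed = 1))
#' res$best$fitness
evolve <- function(model, bounds, config = ga_config()) {
  stopifnot(inherits(config, "welan_ga_config"))
  bounds <- ga_bounds(bounds)
  fitness_fn <- if (is.function(model)) {
    model
  } else {
    function(genes) evaluate_fitness(genes, model)
  }
  with_seed(config$seed, {
    pop <- init_population(bounds, config$pop_size)
    fit <- as.numeric(fitness_fn(pop))
    best_i <- which.max(fit)
    best <- list(genes = stats::setNames(pop[best_i, ], rownames(bounds)),
                 fitness = fit[best_i])
    trace <- data.frame(generation = 0:config$t_gen, best = NA_real_,
                        mean = NA_real_)
    trace$best[1L] <- max(fit)
    trace$mean[1L] <- mean(fit)
    for (t in seq_len(config$t_gen)) {
      sel <- roulette_select(pop, fit)
      pop <- crossover_pass(sel$population, t, config)
      fit <- as.numeric(fitness_fn(pop))
      pop <- mutation_pass(pop, fit, t, config, bounds)
      fit <- as.numeric(fitness_fn(pop))
      if (config$elitism && best$fitness > max(fit)) {
        worst <- which.min(fit)
        pop[worst, ] <- best$genes
        fit[worst] <- best$fitness
      }
      gen_best <- which.max(fit)
      if (fit[gen_best] > best$fitness) {
        best <- list(genes = stats::setNames(pop[gen_best, ], rownames(bounds)),
                     fitness = fit[gen_best])
      }
      trace$best[t + 1L] <- max(fit)
      trace$mean[t + 1L] <- mean(fit)
    }
    structure(list(best = best, trace = trace, config = config,
                   bounds = bounds),
              class = "welan_ga")
  })
}

#' @export
print.welan_ga <- function(x, ...) {
  cat(sprintf("Adaptive GA: K = %d, T_Gen = %d, seed = %s, elitism = %s\n",
              x$config$pop_size, x$config$t_gen, format(x$config$seed),
              x$config$elitism))
  cat(sprintf("  best predicted production: %.4f g/L\n", x$best$fitness))
  cat("  best conditions:\n")
  print(round(x$best$genes, 4))
  invisible(x)
}

#' Export a GA run as CSV trace and JSON summary
#'
#' @param result A `welan_ga` object.
#' @param trace_path CSV path for the per-generation best/mean trace.
#' @param summary_path Optional JSON path for the best individual and config.
#' @export
write_ga_result <- function(result, trace_path, summary_path = NULL) {
  if (!inherits(result, "welan_ga")) stopf("not a welan_ga object")
  utils::write.csv(result$trace, trace_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(best_genes = as.list(result$best$genes),
           best_fitness = result$best$fitness,
           config = unclass(result$config)),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(trace_path)
}
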