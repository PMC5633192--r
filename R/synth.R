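#' Specification of a synthetic fermentation surface
#'
#' Defines a smooth response surface with a single interior optimum from
#' which fermentation records are simulated: conditions drawn uniformly
#' within the bounds and production
#' \deqn{y = \max\left(0,\; y^* - \sum_j w_j (x_j - x^*_j)^2 +
#'   \varepsilon\right), \quad \varepsilon \sim N(0, \sigma_{noise}^2),}
#' a separable concave quadratic (the simplest surface with a unique interior
#' maximum, which keeps optimum-recovery tests sharp). A Gaussian-peak
#' alternative, \eqn{y^* \exp(-\sum_j w_j (x_j - x^*_j)^2 / y^*)}, with the
#' same curvature at the peak, is available via `surface = "gaussian"`.
#'
#' The defaults emulate the real study population: 67 records whose peak
#' yield (42 g/L) and curvature are chosen so the simulated yields span the
#' three yield levels in roughly the observed proportions (about one tenth
#' low, a majority mid, a third high), with the optimum near the
#' high-yield medium composition and measurement noise of 0.5 g/L.
#'
#' @param n Number of records; default 67.
#' @param noise_sd Standard deviation of additive yield noise (g/L).
#' @param bounds Bounds matrix or preset name for the condition draws.
#' @param optimum Named 9-vector x*, strictly inside the bounds.
#' @param peak Peak yield y* at the optimum (g/L), positive.
#' @param curvature Per-variable weights w_j (yield loss per squared raw
#'   unit); defaults to `24 / width_j^2`, i.e. a drop of 24 g/L at one full
#'   bound-width from the optimum in any single variable. This scale makes
#'   the simulated yield-level proportions match the real study population
#'   (about 12% low, 58% mid, 30% high).
#' @param surface `"quadratic"` (default) or `"gaussian"`.
#' @param seed Integer seed.
#' @return Object of class `welan_synth_spec`.
#' @export
synth_spec <- function(n = 67L, noise_sd = 0.5, bounds = "wide",
                       optimum = NULL, peak = 42, curvature = NULL,
                       surface = c("quadratic", "gaussian"), seed = 1L) {
  bounds <- ga_bounds(bounds)
  surface <- match.arg(surface)
  check_number(n, "n", 1)
  check_number(noise_sd, "noise_sd", 0)
  check_number(peak, "peak", 0, strict_lower = TRUE)
  if (is.null(optimum)) {
    optimum <- c(glucose = 55, yeast = 3, kh2po4 = 5.2, mgso4 = 0.3,
                 liquid_volume = 50, ph = 7, temperature = 32.5,
                 rotational_speed = 177, inoculation_amount = 5)
  }
  optimum <- optimum[condition_names()]
  if (any(is.na(optimum))) stopf("optimum must name all nine conditions")
  inside <- optimum > bounds[, "lo"] & optimum < bounds[, "hi"]
  if (!all(inside)) {
    stopf("optimum must be strictly inside the bounds (violated for: %s)",
          paste(condition_names()[!inside], collapse = ", "))
  }
  width <- bounds[, "hi"] - bounds[, "lo"]
  if (is.null(curvature)) curvature <- 24 / width^2
  curvature <- stats::setNames(as.numeric(curvature), condition_names())
  if (any(curvature < 0)) stopf("curvature weights must be non-negative")
  structure(list(n = as.integer(n), noise_sd = noise_sd, bounds = bounds,
                 optimum = optimum, peak = peak, curvature = curvature,
                 surface = surface, seed = seed),
            class = "welan_synth_spec")
}

synth_surface <- function(spec, genes) {
  drop <- as.numeric(
    (genes - matrix(spec$optimum, nrow(genes), 9, byrow = TRUE))^2 %*%
      spec$curvature)
  switch(spec$surface,
         quadratic = spec$peak - drop,
         gaussian = spec$peak * exp(-drop / spec$peak))
}

#' Noise-free yield of the synthetic surface
#'
#' Evaluates the deterministic response surface of a [synth_spec()] at one or
#' more candidate condition vectors (raw units), without the additive noise
#' or the floor at zero. Exposes the generator's ground truth for
#' optimum-recovery checks.
#'
#' @param spec A [synth_spec()].
#' @param genes Matrix of candidates (rows) or a single 9-vector, columns
#'   ordered as [condition_names()].
#' @return Numeric vector of surface yields (g/L).
#' @export
#' @examples
#' sp <- synth_spec(n = 10)
#' synth_yield(sp, sp$optimum)  # the peak
synth_yield <- function(spec, genes) {
  if (!inherits(spec, "welan_synth_spec")) stopf("not a welan_synth_spec")
  if (is.null(dim(genes))) genes <- matrix(genes, nrow = 1)
  if (ncol(genes) != 9L) stopf("candidates must have 9 genes")
  synth_surface(spec, as.matrix(genes))
}

#' Generate synthetic fermentation records
#'
#' Draws `spec$n` condition vectors uniformly within the bounds and computes
#' productions from the noisy surface defined by [synth_spec()]. The ground
#' truth (optimum location and peak yield) is retained in the returned
#' attribute `"spec"` for recovery tests.
#'
#' @param spec A [synth_spec()].
#' @return Data frame of fermentation records with attribute `"spec"`.
#' @export
#' @examples
#' d <- synth_generate(synth_spec(n = 30, seed = 7))
#' table(assign_level(d$production))
synth_generate <- function(spec) {
  if (!inherits(spec, "welan_synth_spec")) stopf("not a welan_synth_spec")
  with_seed(spec$seed, {
    genes <- init_population(spec$bounds, max(spec$n, 2L))[seq_len(spec$n), ,
                                                           drop = FALSE]
    noise <- if (spec$noise_sd > 0) {
      stats::rnorm(spec$n, sd = spec$noise_sd)
    } else {
      numeric(spec$n)
    }
    production <- pmax(0, synth_surface(spec, genes) + noise)
    out <- as.data.frame(genes)
    out[[production_name()]] <- production
    attr(out, "spec") <- spec
    out
  })
}
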