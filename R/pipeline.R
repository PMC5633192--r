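#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings: data source, normalization scope,
#' stratified split, hyperparameter grid, solver settings, GA settings and
#' search bounds. Two presets cover the common cases: `"reduced"` (default)
#' uses a light search suitable for routine runs and tests (population 60,
#' 50 generations, 3-fold CV); `"study_scale"` uses the full study-scale
#' search (population 300, 500 generations, 5-fold CV).
#'
#' @param data A data frame of fermentation records, a CSV path for
#'   [read_table()], or a [synth_spec()] to simulate records.
#' @param train_frac Training fraction of the stratified split.
#' @param split_seed Seed of the stratified split.
#' @param scaling_scope Fit the min-max scaling on `"train"` records only
#'   (default; prevents test-set leakage) or on `"all"` records.
#' @param grid A [grid_spec()], or `NULL` for the preset default.
#' @param epsilon Tube half-width on the normalized target scale.
#' @param kkt_tolerance,max_passes Solver settings; see [svr_config()].
#' @param ga A [ga_config()], or `NULL` for the preset default.
#' @param bounds Bounds preset name or matrix for the GA search.
#' @param preset `"reduced"` or `"study_scale"`.
#' @param out_dir Directory for artifacts (model, grid table, GA trace,
#'   report), or `NULL` to skip persistence.
#' @return Object of class `welan_pipeline_config`.
#' @export
pipeline_config <- function(data, train_frac = 0.7, split_seed = 1L,
                            scaling_scope = c("train", "all"),
                            grid = NULL, epsilon = 0.01,
                            kkt_tolerance = 1e-6, max_passes = 100000L,
                            ga = NULL, bounds = "wide",
                            preset = c("reduced", "study_scale"),
                            out_dir = NULL) {
  preset <- match.arg(preset)
  scaling_scope <- match.arg(scaling_scope)
  if (is.null(grid)) {
    grid <- grid_spec(k = if (preset == "study_scale") 5L else 3L,
                      seed = split_seed)
  }
  if (is.null(ga)) {
    ga <- if (preset == "study_scale") {
      ga_config(pop_size = 300L, t_gen = 500L, seed = split_seed)
    } else {
      ga_config(pop_size = 60L, t_gen = 50L, seed = split_seed)
    }
  }
  structure(list(data = data, train_frac = train_frac, split_seed = split_seed,
                 scaling_scope = scaling_scope, grid = grid, epsilon = epsilon,
                 kkt_tolerance = kkt_tolerance, max_passes = max_passes,
                 ga = ga, bounds = ga_bounds(bounds), preset = preset,
                 out_dir = out_dir),
            class = "welan_pipeline_config")
}

pipeline_data <- function(data) {
  if (inherits(data, "welan_synth_spec")) return(synth_generate(data))
  if (is.character(data)) return(read_table(data))
  check_records(data, require_production = TRUE)
}

#' Run the full optimization pipeline
#'
#' Executes, in order: data loading (or simulation), yield-level stratified
#' 70/30 split, min-max normalization, grid search of (c, g) by k-fold
#' cross-validated MSE, final epsilon-SVR fit on the training records,
#' accuracy scoring (squared correlation on the held-out test records), and
#' the adaptive-GA search for yield-maximizing conditions. The run is a pure
#' function of the configuration and its seeds.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `welan_report`: test-set `r2`, winning
#'   hyperparameters, the fitted `model`, the `ga` result, predicted optimal
#'   conditions and production, the improvement over the best observed
#'   record, split counts and seeds.
#' @export
#' @examples
#' cfg <- pipeline_config(synth_spec(n = 40, seed = 3),
#'                        grid = grid_spec(log2_C = 0:4, log2_gamma = -4:0,
#'                                         k = 3),
#'                        ga = ga_config(pop_size = 30, t_gen = 20, seed = 3))
#' \donttest{
#' rep <- run_pipeline(cfg)
#' rep$predicted_production
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "welan_pipeline_config"))
  records <- pipeline_data(config$data)
  if (nrow(records) < 10L) stopf("pipeline needs at least 10 records")

  split <- stratified_split(records, config$train_frac, config$split_seed)
  scaling <- fit_scaling(
    if (config$scaling_scope == "train") split$train else records)
  train_n <- normalize_data(split$train, scaling)
  test_n <- normalize_data(split$test, scaling)
  x_tr <- as.matrix(train_n[, condition_names()])
  y_tr <- train_n[[production_name()]]

  grid_res <- grid_search(x_tr, y_tr, config$grid, epsilon = config$epsilon,
                          kkt_tolerance = config$kkt_tolerance,
                          max_passes = config$max_passes)
  best_cfg <- svr_config(C = grid_res$best$C, epsilon = config$epsilon,
                         sigma = grid_res$best$sigma,
                         kkt_tolerance = config$kkt_tolerance,
                         max_passes = config$max_passes)
  model <- svr_fit(x_tr, y_tr, best_cfg, scaling = scaling)

  pred_test <- stats::predict(model, as.matrix(test_n[, condition_names()]))
  r2 <- r_squared(pred_test, test_n[[production_name()]])

  ga_res <- evolve(model, config$bounds, config$ga)
  best_observed <- max(records[[production_name()]])
  report <- structure(
    list(r2 = r2,
         best_C = grid_res$best$C, best_gamma = grid_res$best$gamma,
         best_sigma = grid_res$best$sigma, cvmse = grid_res$best$cvmse,
         optimum = ga_res$best$genes,
         predicted_production = ga_res$best$fitness,
         best_observed = best_observed,
         improvement_pct = report_improvement(ga_res$best$fitness,
                                              best_observed),
         counts = split$counts, seeds = list(split = config$split_seed,
                                             folds = config$grid$seed,
                                             ga = config$ga$seed),
         model = model, grid = grid_res, ga = ga_res, scaling = scaling),
    class = "welan_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_table(split$train, p("train.csv"))
    write_table(split$test, p("test.csv"))
    write_scaling(scaling, p("scaling.json"))
    write_grid(grid_res, p("grid.csv"))
    write_model(model, p("model.json"))
    write_ga_result(ga_res, p("ga_trace.csv"), p("ga_summary.json"))
    jsonlite::write_json(
      list(r2 = r2, best_C = report$best_C, best_gamma = report$best_gamma,
           cvmse = report$cvmse, optimum = as.list(report$optimum),
           predicted_production = report$predicted_production,
           best_observed = best_observed,
           improvement_pct = report$improvement_pct, seeds = report$seeds),
      p("report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.welan_report <- function(x, ...) {
  cat("Welan gum condition-optimization report\n")
  cat(sprintf("  test-set r^2: %.4f (n_test = %d)\n", x$r2, sum(x$counts$n_test)))
  cat(sprintf("  selected c = %g, g = %g (sigma = %g), CVmse = %.6g\n",
              x$best_C, x$best_gamma, x$best_sigma, x$cvmse))
  cat(sprintf("  predicted maximal production: %.4f g/L (best observed %.4f g/L, %+.1f%%)\n",
              x$predicted_production, x$best_observed, x$improvement_pct))
  cat("  predicted optimal conditions:\n")
  print(round(x$optimum, 4))
  invisible(x)
}

#' Relative improvement of a predicted yield over a reference
#'
#' `100 * (predicted - reference) / reference`, rounded half-to-even to
#' `digits` decimals.
#'
#' @param predicted Predicted yield (g/L).
#' @param reference Reference yield (g/L), positive.
#' @param digits Decimal places of the result; default 1.
#' @return Percentage improvement.
#' @export
#' @examples
#' report_improvement(31.65, 30.63)  # 3.3
report_improvement <- function(predicted, reference, digits = 1L) {
  check_number(reference, "reference", 0, strict_lower = TRUE)
  check_number(predicted, "predicted")
  round(100 * (predicted - reference) / reference, digits)
}
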