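#' Fit min-max scaling parameters
#'
#' Records the per-column minimum and maximum of the supplied data, together
#' with the normalized-scale endpoints (`y_min`, `y_max`), for the affine map
#'
#' \deqn{y = (y_{max} - y_{min}) \frac{x - x_{min}}{x_{max} - x_{min}} + y_{min}.}
#'
#' By default each condition column and the production column are scaled to
#' \[0, 1\]. Fitting on the training subset only (rather than the full table)
#' avoids information leaking from the test records into the model; either
#' choice can be expressed by passing the corresponding data here.
#'
#' @param records Data frame of fermentation records.
#' @param columns Columns to scale; defaults to the nine conditions plus
#'   production where present.
#' @param y_min,y_max Normalized-scale endpoints; defaults 0 and 1.
#' @return Object of class `welan_scaling`: list with named numeric vectors
#'   `x_min`, `x_max` and scalars `y_min`, `y_max`.
#' @export
#' @examples
#' d <- read_table(system.file("extdata", "table1_raw.csv", package = "welanopt"))
#' sc <- fit_scaling(d)
#' sc$x_min[["inoculation_amount"]]
fit_scaling <- function(records, columns = NULL, y_min = 0, y_max = 1) {
  if (!is.data.frame(records)) stopf("records must be a data frame")
  if (is.null(columns)) {
    columns <- intersect(c(condition_names(), production_name()), names(records))
  }
  if (length(columns) == 0L) stopf("no columns to scale")
  if (y_max <= y_min) stopf("y_max must exceed y_min")
  x_min <- x_max <- stats::setNames(numeric(length(columns)), columns)
  for (col in columns) {
    v <- records[[col]]
    if (is.null(v)) stopf("column '%s' not found", col)
    if (any(!is.finite(v))) stopf("column '%s' has non-finite values", col)
    x_min[col] <- min(v)
    x_max[col] <- max(v)
    if (x_max[col] == x_min[col]) {
      stopf("column '%s' is constant (min == max == %g); cannot scale", col, x_min[col])
    }
  }
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "welan_scaling")
}

#' Build scaling parameters from known extrema
#'
#' Constructs a `welan_scaling` object directly from per-column minima and
#' maxima, e.g. extrema recovered by inverting the normalization from a pair
#' of (raw, normalized) values when the full dataset is not available.
#'
#' @param x_min,x_max Named numeric vectors of per-column extrema.
#' @inheritParams fit_scaling
#' @return Object of class `welan_scaling`.
#' @export
make_scaling <- function(x_min, x_max, y_min = 0, y_max = 1) {
  if (is.null(names(x_min)) || is.null(names(x_max)) ||
      !identical(names(x_min), names(x_max))) {
    stopf("x_min and x_max must be named identically")
  }
  if (y_max <= y_min) stopf("y_max must exceed y_min")
  bad <- names(x_min)[x_max <= x_min]
  if (length(bad) > 0L) {
    stopf("x_max must exceed x_min (violated for: %s)", paste(bad, collapse = ", "))
  }
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "welan_scaling")
}

#' @export
print.welan_scaling <- function(x, ...) {
  cat("Min-max scaling to [", x$y_min, ", ", x$y_max, "]\n", sep = "")
  print(data.frame(column = names(x$x_min), x_min = unname(x$x_min),
                   x_max = unname(x$x_max)), row.names = FALSE)
  invisible(x)
}

scaling_column <- function(scaling, column) {
  if (!inherits(scaling, "welan_scaling")) stopf("not a welan_scaling object")
  if (!column %in% names(scaling$x_min)) {
    stopf("column '%s' has no fitted scaling", column)
  }
  list(x_min = scaling$x_min[[column]], x_max = scaling$x_max[[column]],
       y_min = scaling$y_min, y_max = scaling$y_max)
}

#' Normalize or denormalize a column of values
#'
#' `normalize_column()` applies the affine min-max map for one column;
#' `denormalize_column()` is its exact algebraic inverse. Values outside
#' \[`x_min`, `x_max`\] are extrapolated by the same affine map.
#'
#' @param values Numeric vector.
#' @param scaling A `welan_scaling` object.
#' @param column Column name within `scaling`.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' sc <- make_scaling(c(ph = 2), c(ph = 10))
#' normalize_column(c(2, 6, 10), sc, "ph")
#' denormalize_column(c(0, 0.5, 1), sc, "ph")
normalize_column <- function(values, scaling, column) {
  p <- scaling_column(scaling, column)
  (p$y_max - p$y_min) * (values - p$x_min) / (p$x_max - p$x_min) + p$y_min
}

#' @rdname normalize_column
#' @export
denormalize_column <- function(values, scaling, column) {
  p <- scaling_column(scaling, column)
  (values - p$y_min) / (p$y_max - p$y_min) * (p$x_max - p$x_min) + p$x_min
}

#' Normalize or denormalize every scaled column of a table
#'
#' @param records Data frame whose scaled columns are to be transformed.
#' @inheritParams normalize_column
#' @return Data frame with the scaled columns transformed; other columns pass
#'   through unchanged.
#' @export
normalize_data <- function(records, scaling) {
  for (col in intersect(names(scaling$x_min), names(records))) {
    records[[col]] <- normalize_column(records[[col]], scaling, col)
  }
  records
}

#' @rdname normalize_data
#' @export
denormalize_data <- function(records, scaling) {
  for (col in intersect(names(scaling$x_min), names(records))) {
    records[[col]] <- denormalize_column(records[[col]], scaling, col)
  }
  records
}

#' Serialize scaling parameters to JSON
#'
#' The sidecar lets downstream stages (e.g. the genetic-algorithm search)
#' denormalize surrogate predictions with bit-identical parameters.
#'
#' @param scaling A `welan_scaling` object.
#' @param path JSON file path.
#' @export
write_scaling <- function(scaling, path) {
  if (!inherits(scaling, "welan_scaling")) stopf("not a welan_scaling object")
  jsonlite::write_json(
    list(x_min = as.list(scaling$x_min), x_max = as.list(scaling$x_max),
         y_min = scaling$y_min, y_max = scaling$y_max),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_scaling(unlist(obj$x_min), unlist(obj$x_max), obj$y_min, obj$y_max)
}
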