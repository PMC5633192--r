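#' Names of the nine culture-condition variables
#'
#' The controllable fermentation variables, in the order they are encoded as
#' genes by the genetic algorithm: glucose (g/L), yeast extract (g/L),
#' KH2PO4 (g/L), MgSO4 (g/L), liquid volume (mL), pH, temperature (deg C),
#' rotational speed (rpm) and inoculation amount (%).
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' condition_names()
condition_names <- function() {
  c("glucose", "yeast", "kh2po4", "mgso4", "liquid_volume",
    "ph", "temperature", "rotational_speed", "inoculation_amount")
}

#' @rdname condition_names
#' @export
production_name <- function() "production"

#' Validate a table of fermentation records
#'
#' Checks that a data frame carries the nine condition columns (and optionally
#' the production column) with finite numeric values, and that productions are
#' non-negative where present.
#'
#' @param records Data frame of fermentation records.
#' @param require_production Require the production column to be present?
#' @return `records`, invisibly, with columns reordered canonically.
#' @export
check_records <- function(records, require_production = FALSE) {
  if (!is.data.frame(records)) stopf("records must be a data frame")
  missing_cols <- setdiff(condition_names(), names(records))
  if (length(missing_cols) > 0L) {
    stopf("missing condition column(s): %s", paste(missing_cols, collapse = ", "))
  }
  has_prod <- production_name() %in% names(records)
  if (require_production && !has_prod) {
    stopf("missing column '%s'", production_name())
  }
  cols <- c(condition_names(), if (has_prod) production_name())
  for (col in cols) {
    v <- records[[col]]
    if (!is.numeric(v)) stopf("column '%s' is not numeric", col)
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stopf("non-finite value in column '%s', row %d", col, bad[1L])
    }
  }
  if (has_prod && any(records[[production_name()]] < 0)) {
    stopf("negative production value (row %d)",
          which(records[[production_name()]] < 0)[1L])
  }
  invisible(records[, cols, drop = FALSE])
}

#' Read or write a fermentation table
#'
#' CSV with a header row naming the nine condition columns
#' (see [condition_names()]) and, optionally, a `production` column. Candidate
#' condition sets (e.g. points to be scored by a fitted surrogate) may omit
#' production. Values round-trip losslessly through [write_table()].
#'
#' @param path File path.
#' @return For `read_table`, a data frame of validated records.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("empty file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("no records in %s", path)
  missing_cols <- setdiff(condition_names(), names(df))
  if (length(missing_cols) > 0L) {
    stopf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  cols <- c(condition_names(),
            if (production_name() %in% names(df)) production_name())
  for (col in cols) {
    v <- df[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L) {
        stopf("%s: non-numeric cell in column '%s', row %d ('%s')",
              path, col, bad[1L], v[bad[1L]])
      }
      df[[col]] <- num
    }
  }
  check_records(df[, cols, drop = FALSE])
  df[, cols, drop = FALSE]
}

#' @param records Data frame of fermentation records.
#' @rdname read_table
#' @export
write_table <- function(records, path) {
  records <- check_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign yield levels to production values
#'
#' Productions are classed into three levels: low for values in \[0, 5) g/L,
#' mid for \[5, 20\] g/L and high above 20 g/L. The boundaries follow the
#' convention that every production belongs to exactly one level and "more
#' than 20 g/L" is strict.
#'
#' @param production Numeric vector of productions (g/L), all non-negative.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
#' @examples
#' assign_level(c(0, 4.59, 6.25, 20, 20.5))
assign_level <- function(production) {
  if (!is.numeric(production)) stopf("production must be numeric")
  if (any(!is.finite(production))) stopf("production must be finite")
  if (any(production < 0)) stopf("negative production is not a valid yield")
  out <- ifelse(production < 5, "low", ifelse(production <= 20, "mid", "high"))
  factor(out, levels = c("low", "mid", "high"))
}

#' Stratified train/test split by yield level
#'
#' Records are grouped by yield level ([assign_level()]); within each level the
#' order is randomly shuffled by the seeded generator and the first
#' `floor(train_frac * n_level)` records go to the training set, the remainder
#' to the test set.
#'
#' @param records Data frame of fermentation records with production.
#' @param train_frac Training fraction, strictly between 0 and 1. Default 0.7.
#' @param seed Integer seed driving the within-level shuffle.
#' @return An object of class `welan_split`: list with `train`, `test`,
#'   `counts` (per-level train/test counts) and `seed`.
#' @export
#' @examples
#' d <- read_table(system.file("extdata", "table1_raw.csv", package = "welanopt"))
#' s <- stratified_split(d, seed = 1)
#' s$counts
stratified_split <- function(records, train_frac = 0.7, seed = 1L) {
  records <- check_records(records, require_production = TRUE)
  check_number(train_frac, "train_frac", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  lev <- assign_level(records[[production_name()]])
  idx_train <- integer(0)
  idx_test <- integer(0)
  counts <- data.frame(level = levels(lev), n = 0L, n_train = 0L, n_test = 0L)
  with_seed(seed, {
    for (lv in levels(lev)) {
      idx <- which(lev == lv)
      n <- length(idx)
      if (n == 0L) next
      idx <- idx[sample.int(n)]
      n_tr <- floor(train_frac * n)
      idx_train <- c(idx_train, idx[seq_len(n_tr)])
      idx_test <- c(idx_test, idx[setdiff(seq_len(n), seq_len(n_tr))])
      counts[counts$level == lv, c("n", "n_train", "n_test")] <-
        as.integer(c(n, n_tr, n - n_tr))
    }
  })
  if (sum(counts$n > 0L) < 2L) {
    warnf("all records fall in a single yield level; stratification degenerates to a plain split")
  }
  structure(list(train = records[sort(idx_train), , drop = FALSE],
                 test = records[sort(idx_test), , drop = FALSE],
                 counts = counts, seed = seed),
            class = "welan_split")
}

#' @export
print.welan_split <- function(x, ...) {
  cat("Stratified fermentation-record split (seed ", x$seed, ")\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}
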