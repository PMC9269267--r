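#' Read a growth series from CSV
#'
#' Expects a comma-separated file (header required, '.' decimal, UTF-8)
#' with one time column and one size column.  Rows with missing or
#' non-numeric values are rejected with their row numbers.
#'
#' @param path Path to the CSV file.
#' @param time_column,size_column Column names (defaults `"time"`,
#'   `"size"`).
#' @param label Series label; defaults to the file name.
#' @return A [growth_series()].
#' @export
read_growth_csv <- function(path, time_column = "time", size_column = "size",
                            label = NULL) {
  df <- read_checked_csv(path)
  for (col in c(time_column, size_column))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s (columns: %s)", col, path,
                   paste(names(df), collapse = ", ")), call. = FALSE)
  t_raw <- df[[time_column]]; s_raw <- df[[size_column]]
  tt <- suppressWarnings(as.numeric(as.character(t_raw)))
  ss <- suppressWarnings(as.numeric(as.character(s_raw)))
  bad <- which(!is.finite(tt) | !is.finite(ss))
  if (length(bad))
    stop(sprintf("non-numeric or missing values in %s at data row(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  growth_series(tt, ss, label = if (is.null(label)) basename(path) else label)
}

#' Write a growth series to CSV
#'
#' @param series A [growth_series()].
#' @param path Output path.
#' @param time_column,size_column Column names to write.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(series, path, time_column = "time",
                             size_column = "size") {
  series <- as_growth_series(series)
  df <- data.frame(series$times, series$sizes)
  names(df) <- c(time_column, size_column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a leaf outline from CSV
#'
#' Boundary coordinates, one `x,y` pair per row, header `x,y`.  Compatible
#' with coordinates exported from digitised leaf scans.
#'
#' @param path Path to the CSV file.
#' @return A [leaf_outline()].
#' @export
read_leaf_csv <- function(path) {
  df <- read_checked_csv(path)
  for (col in c("x", "y"))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
  xx <- suppressWarnings(as.numeric(as.character(df$x)))
  yy <- suppressWarnings(as.numeric(as.character(df$y)))
  bad <- which(!is.finite(xx) | !is.finite(yy))
  if (length(bad))
    stop(sprintf("non-numeric or missing values in %s at data row(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  leaf_outline(cbind(x = xx, y = yy))
}

#' @rdname read_leaf_csv
#' @param outline A [leaf_outline()].
#' @param path Output path.
#' @export
write_leaf_csv <- function(outline, path) {
  if (!inherits(outline, "leaf_outline")) outline <- leaf_outline(outline)
  utils::write.csv(as.data.frame(outline$points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

read_checked_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("cannot parse %s as CSV: %s", path,
                                conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  df
}

#' Build a serializable report for a growth fit
#'
#' Collects the estimates, goodness of fit, optional model comparison and
#' provenance (input file hash, seed, package version) into a plain list
#' that round-trips losslessly through JSON.
#'
#' @param fit A `"growth_fit"`.
#' @param comparison Optional `"growth_comparison"`.
#' @param input_path Optional path of the input data file (hashed into the
#'   provenance block).
#' @return A list of class `"fit_report"`.
#' @export
fit_report <- function(fit, comparison = NULL, input_path = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  rep <- list(
    dataset = fit$series$label,
    model = fit$model,
    parameters = as.list(fit$params),
    fixed = list(x_min = !is.null(fit$fix_x_min)),
    rss = fit$rss, rmse = fit$rmse, n = fit$n,
    converged = fit$converged,
    n_restarts_used = fit$n_restarts_used,
    provenance = report_provenance(input_path, fit$seed))
  if (!is.null(comparison)) {
    stopifnot(inherits(comparison, "growth_comparison"))
    rep$comparison <- list(rmse_be = comparison$rmse_be,
                           rmse_mbe = comparison$rmse_mbe,
                           ape_percent = comparison$ape_percent,
                           preferred = comparison$preferred)
  }
  class(rep) <- c("fit_report", "list")
  rep
}

#' @rdname fit_report
#' @param leaf A `"leaf_fit"`.
#' @param seed Seed recorded in the provenance block.
#' @export
leaf_report <- function(leaf, input_path = NULL, seed = NA_integer_) {
  stopifnot(inherits(leaf, "leaf_fit"))
  structure(list(
    model = "MBE-leaf",
    upper_parameters = as.list(leaf$upper_params),
    lower_parameters = as.list(leaf$lower_params),
    symmetric = leaf$symmetric,
    rss = leaf$rss, rmse = leaf$rmse, n = leaf$n,
    leaf_length = leaf$leaf_length,
    registration = list(translation = as.numeric(leaf$registration$translation),
                        angle = leaf$registration$angle),
    provenance = report_provenance(input_path, seed)),
    class = c("fit_report", "list"))
}

report_provenance <- function(input_path, seed) {
  list(input = if (is.null(input_path)) NA_character_ else input_path,
       input_md5 = if (is.null(input_path) || !file.exists(input_path))
         NA_character_ else unname(tools::md5sum(input_path)),
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
       tool = "mbegrowth",
       version = as.character(utils::packageVersion("mbegrowth")))
}

#' Write / read a fit report as JSON
#'
#' @param report A `"fit_report"` list.
#' @param path Output path.
#' @return `path` (write) or the report list (read), invisibly for write.
#' @export
write_fit_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = c("fit_report", "list"))
}
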