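# CSV readers/writers and run provenance. All files are comma-separated,
# UTF-8, '.' decimal, mandatory header row.

#' Read an incidence CSV
#'
#' Schema: `town_id`, `x_m`, `y_m`, `year`, `incidence_per_1e5` (planar metre
#' coordinates, integer year labels, rate per 100,000); optional extra
#' columns are kept. Zero incidence is allowed; negative incidence, missing
#' or non-numeric cells, and duplicated (town, year) pairs are rejected with
#' the offending row named.
#'
#' @param path Path to a CSV file.
#' @return Data frame of validated records with the rate column renamed to
#'   `incidence`.
#' @export
read_incidence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("town_id", "x_m", "y_m", "year", "incidence_per_1e5")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("read_incidence_csv: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("x_m", "y_m", "year", "incidence_per_1e5")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("read_incidence_csv: non-numeric value in column %s at data row %d",
                   col, if (is.na(bad)) 1L else bad))
    }
    if (anyNA(v)) {
      stop(sprintf("read_incidence_csv: missing value in column %s at data row %d",
                   col, which(is.na(v))[1]))
    }
  }
  if (any(df$incidence_per_1e5 < 0)) {
    stop("read_incidence_csv: negative incidence at data row ",
         which(df$incidence_per_1e5 < 0)[1])
  }
  key <- paste(df$town_id, df$year)
  if (anyDuplicated(key)) {
    stop("read_incidence_csv: duplicate (town_id, year) at data row ",
         which(duplicated(key))[1])
  }
  names(df)[names(df) == "incidence_per_1e5"] <- "incidence"
  df
}

#' Write an incidence CSV
#'
#' Inverse of [read_incidence_csv()]; round-trips records exactly (full
#' double precision).
#'
#' @param records Data frame with `town_id`, `x_m`, `y_m`, `year` and
#'   `incidence` (or `incidence_per_1e5`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence_csv <- function(records, path) {
  if (!is.null(records$incidence) && is.null(records$incidence_per_1e5)) {
    names(records)[names(records) == "incidence"] <- "incidence_per_1e5"
  }
  cols <- c("town_id", "x_m", "y_m", "year", "incidence_per_1e5")
  stopifnot(all(cols %in% names(records)))
  utils::write.csv(format(records[, cols], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write run provenance
#'
#' Every pipeline run directory gets a `run_config.json` with the package
#' version and the fully resolved configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Named list of resolved settings.
#' @param extra Optional named list of additional provenance (e.g. the
#'   estimated velocity).
#' @return The JSON path, invisibly.
#' @export
write_run_config <- function(out_dir, config, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "run_config.json")
  payload <- c(list(package = "stproj",
                    version = as.character(utils::packageVersion("stproj"))),
               list(config = strip_classes(config)), strip_classes(extra))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

#' Write a lag-bin grid to CSV
#'
#' @param grid A [empirical_covariance()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lag_grid_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fitted covariance model as structured text
#'
#' @param fit A [fit_cov_model()] result.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_cov_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(family = fit$family, parameters = unclass(fit$model),
         aic = fit$aic, wrss = fit$wrss, n_bins = fit$n_bins),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
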