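#' @title Tidy observation tables and their CSV schema
#' @description A time-series table is the package's tidy exchange format
#'   for observations: one row per measurement with columns
#'   \code{time_h} (hours, >= 0), \code{condition} (label, e.g.
#'   \code{"shaking"}/\code{"static"}), \code{replicate} (integer >= 1),
#'   \code{variable} (one of \code{log10_cfu_biofilm},
#'   \code{log10_cfu_plankton}, \code{coverage_pct}, \code{od595}) and
#'   \code{value}. Coverage values must lie in [0, 100].
#' @param time_h,condition,replicate,variable,value column vectors
#'   (recycled to a common length).
#' @return A \code{data.frame} of class \code{"timeseries_table"}.
#' @export
timeseries_table <- function(time_h, condition, replicate, variable, value) {
  df <- data.frame(time_h = as.numeric(time_h),
                   condition = as.character(condition),
                   replicate = as.integer(replicate),
                   variable = as.character(variable),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  validate_timeseries(df)
  class(df) <- c("timeseries_table", "data.frame")
  df
}

ts_variables <- c("log10_cfu_biofilm", "log10_cfu_plankton",
                  "coverage_pct", "od595")

#' Validate a time-series table against the schema
#'
#' Checks column presence and the per-row invariants; offending rows are
#' named by row number.
#'
#' @param df a data frame in the time-series layout.
#' @return \code{df}, invisibly, if valid; otherwise an error.
#' @export
validate_timeseries <- function(df) {
  need <- c("time_h", "condition", "replicate", "variable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         "; expected header: ", paste(need, collapse = ","), call. = FALSE)
  bad_row <- function(ok, what) {
    if (any(!ok))
      stop(what, " in row(s): ",
           paste(utils::head(which(!ok), 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  bad_row(is.finite(df$time_h) & df$time_h >= 0, "negative or missing time_h")
  bad_row(!is.na(df$replicate) & df$replicate >= 1, "replicate must be >= 1")
  bad_row(df$variable %in% ts_variables,
          paste0("unknown variable (expected one of ",
                 paste(ts_variables, collapse = ", "), ")"))
  cov <- df$variable == "coverage_pct"
  bad_row(!cov | (df$value >= 0 & df$value <= 100),
          "coverage_pct outside [0, 100]")
  invisible(df)
}

#' Read a time-series table from CSV
#'
#' Expects the header \code{time_h,condition,replicate,variable,value};
#' lines starting with \code{#} before the header are treated as metadata
#' comments. Rows violating the schema are reported with their row numbers.
#'
#' @param path file path.
#' @return A \code{"timeseries_table"}.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_timeseries(df)
  if (nrow(df) > 0) {
    df$replicate <- as.integer(df$replicate)
    df$time_h <- as.numeric(df$time_h)
    df$value <- as.numeric(df$value)
  }
  class(df) <- c("timeseries_table", "data.frame")
  df
}

#' Write a time-series table to CSV
#'
#' @param table a \code{"timeseries_table"}.
#' @param path output file path.
#' @param meta optional named character vector written as \code{# key: value}
#'   comment lines before the header (e.g. the RNG seed).
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(table, path, meta = NULL) {
  validate_timeseries(table)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise model parameters to JSON (and back)
#'
#' Keys are exactly the field names of \code{\link{population_params}}.
#'
#' @param params a \code{"population_params"} object.
#' @param path output file path.
#' @return \code{path} (write) or a \code{"population_params"} (read).
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "population_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(population_params, as.list(x))
}

#' Export and import population trajectories as CSV
#'
#' Header \code{time_h,rho_b,rho_p,c_b,c_p}; metadata (step size, condition)
#' stored as \code{#} comment lines.
#'
#' @param trajectory a \code{"biofilm_trajectory"} from
#'   \code{\link{simulate_population}}.
#' @param path file path.
#' @return \code{path} (write) or a data frame (read).
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_h: %s", attr(trajectory, "dt")), con)
  cond <- attr(trajectory, "condition")
  if (!is.na(cond)) writeLines(sprintf("# condition: %s", cond), con)
  utils::write.csv(as.data.frame(trajectory), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_h", "rho_b", "rho_p", "c_b", "c_p")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df
}
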