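#' Read a daily mortality time series
#'
#' Reads a delimited text file (comma or tab separated, header required)
#' with columns `date` (ISO 8601), `deaths` (nonnegative integer counts)
#' and `temperature` (degrees C), and validates it: dates must be
#' consecutive calendar days with no gaps. Errors name the offending
#' column, value and line.
#'
#' @param path Path to the file.
#' @return A validated tibble with columns `date` (`Date`), `deaths`
#'   (integer), `temperature` (double).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  need <- c("date", "deaths", "temperature")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("Missing column(s): %s.", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    i <- which(is.na(dates))[1L]
    stop(sprintf("Unparseable date '%s' on line %d.", raw$date[i], i + 1L),
         call. = FALSE)
  }
  deaths <- suppressWarnings(as.numeric(raw$deaths))
  if (anyNA(deaths) || any(deaths < 0) || any(deaths != round(deaths))) {
    i <- which(is.na(deaths) | deaths < 0 | deaths != round(deaths))[1L]
    stop(sprintf("Invalid death count '%s' on line %d (need a nonnegative integer).",
                 raw$deaths[i], i + 1L), call. = FALSE)
  }
  temperature <- suppressWarnings(as.numeric(raw$temperature))
  if (anyNA(temperature)) {
    i <- which(is.na(temperature))[1L]
    stop(sprintf("Invalid temperature '%s' on line %d.", raw$temperature[i], i + 1L),
         call. = FALSE)
  }
  gaps <- which(diff(as.integer(dates)) != 1L)
  if (length(gaps)) {
    stop(sprintf("Date series has a gap after %s (line %d).",
                 format(dates[gaps[1L]]), gaps[1L] + 1L), call. = FALSE)
  }
  tibble::tibble(date = dates, deaths = as.integer(deaths),
                 temperature = temperature)
}

#' Write a daily mortality time series
#'
#' Inverse of [read_timeseries()]: writes `date`, `deaths`, `temperature`
#' as comma-separated text with ISO dates.
#'
#' @param data Data frame with the three columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  stopifnot(all(c("date", "deaths", "temperature") %in% names(data)))
  out <- data.frame(date = format(as.Date(data$date), "%Y-%m-%d"),
                    deaths = as.integer(data$deaths),
                    temperature = data$temperature)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
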