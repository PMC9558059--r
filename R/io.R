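#' Read and write right-censored survival tables
#'
#' The on-disk format is a delimited text table with header columns
#' `time` (positive reals) and `event` (1 = failure observed,
#' 0 = right-censored).  Comma and tab delimiters are auto-detected
#' from the header line.  Validation errors name the offending data
#' row.
#'
#' @param path file to read or write.
#' @return `read_survival_csv()`: a [survival_records()] object.
#'   `write_survival_csv()`: `path`, invisibly (comma-delimited).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_survival_csv(survival_records(c(5, 8), c(1, 0)), f)
#' read_survival_csv(f)
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("time", "event"), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(df$time))
  event <- suppressWarnings(as.numeric(df$event))
  bad <- which(is.na(time) | !is.finite(time) | time <= 0)
  if (length(bad)) {
    stop(sprintf("row %d: time must be a positive number (got '%s')",
                 bad[1L], df$time[bad[1L]]), call. = FALSE)
  }
  bad <- which(is.na(event) | !(event %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("row %d: event must be 0 (censored) or 1 (failure), got '%s'",
                 bad[1L], df$event[bad[1L]]), call. = FALSE)
  }
  survival_records(time, event)
}

#' @rdname read_survival_csv
#' @param d a [survival_records()] object (or anything
#'   [as_survival_records()] accepts).
#' @export
write_survival_csv <- function(d, path) {
  rec <- as_survival_records(d)
  utils::write.csv(as.data.frame(rec)[, c("time", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
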