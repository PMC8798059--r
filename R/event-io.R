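#' Read and write event tables
#'
#' Delimited-text (tab-separated) persistence for the two event-table
#' schemas: phase segments (`filament_id`, `condition`, `t_start_s`,
#' `t_end_s`, `slope_um_min`, `phase`) and nucleation records (`seed_id`,
#' `lag_s`, `censored`). Round trips are lossless; unknown extra columns
#' are preserved. A missing mandatory column or a malformed row raises an
#' error naming the column or line.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return Readers return the data frame; writers return `path` invisibly.
#' @export
write_event_table <- function(x, path) {
  required <- c("filament_id", "condition", "t_start_s", "t_end_s",
                "slope_um_min", "phase")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("segment table missing column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  tab <- read_checked_table(
    path,
    required = c("filament_id", "condition", "t_start_s", "t_end_s",
                 "slope_um_min", "phase"),
    numeric_cols = c("t_start_s", "t_end_s", "slope_um_min")
  )
  bad <- which(tab$t_end_s <= tab$t_start_s)
  if (length(bad) > 0) {
    stop(sprintf("malformed row at line %d of %s: t_end_s <= t_start_s",
                 bad[1] + 1, path))
  }
  tab
}

#' @rdname write_event_table
#' @export
write_nucleation_table <- function(x, path) {
  required <- c("seed_id", "lag_s", "censored")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("nucleation table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_nucleation_table <- function(path) {
  tab <- read_checked_table(path,
                            required = c("seed_id", "lag_s", "censored"),
                            numeric_cols = "lag_s")
  tab$seed_id <- utils::type.convert(tab$seed_id, as.is = TRUE)
  tab$censored <- as.logical(tab$censored)
  if (anyNA(tab$censored)) {
    stop(sprintf("malformed row at line %d of %s: bad 'censored' flag",
                 which(is.na(tab$censored))[1] + 1, path))
  }
  if (any(tab$lag_s[!tab$censored] <= 0)) {
    stop("nucleation table has non-positive observed lags")
  }
  tab
}

read_checked_table <- function(path, required, numeric_cols) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("table ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & !is.na(tab[[col]]) & nzchar(tab[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("malformed row at line %d of %s: '%s' is not numeric in column %s",
                   bad[1] + 1, path, tab[[col]][bad[1]], col))
    }
    tab[[col]] <- val
  }
  tab
}
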