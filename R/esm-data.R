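# Long-format ESM data: validation, reading, writing ----------------------

#' Construct a validated ESM dataset
#'
#' Bundles long-format experience sampling records — one row per momentary
#' affect report — with the bounds of the response scale. Validation rejects
#' out-of-bounds affect values, missing fields, and duplicate timestamps
#' within a person (the sampling app enforces at least one hour between
#' consecutive reports, so a duplicate indicates corrupted data and is an
#' error, not something to deduplicate). Rows are returned sorted by
#' `(person_id, timestamp)`.
#'
#' Timestamps are timezone-naive local clock time by convention: the
#' time-of-day windows used by [filter_time_window()] ("morning" is 6 a.m.
#' to 12 p.m., etc.) are meant in the participant's local time, so the
#' package stores clock time as UTC-labelled `POSIXct` and never converts
#' between zones.
#'
#' @param x Data frame with columns `person_id`, `timestamp` (POSIXct or
#'   ISO-8601 strings), and `affect`.
#' @param bounds Length-2 numeric, the response-scale bounds
#'   (default `c(0, 100)`, the 0 "very unhappy" to 100 "very happy" slider).
#' @return A tibble of class `esm_dataset` with a `bounds` attribute.
#' @seealso [read_esm_csv()], [scale_bounds()]
#' @export
#' @examples
#' df <- data.frame(
#'   person_id = "p1",
#'   timestamp = c("2023-01-02 09:30:00", "2023-01-02 14:00:00"),
#'   affect = c(60, 72)
#' )
#' esm_dataset(df)
esm_dataset <- function(x, bounds = c(0, 100)) {
  if (!is.data.frame(x)) stop("`x` must be a data frame of ESM records")
  required <- c("person_id", "timestamp", "affect")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  check_bounds(bounds)
  x <- tibble::as_tibble(as.data.frame(x)[required])
  x$person_id <- as.character(x$person_id)
  if (!inherits(x$timestamp, "POSIXct")) {
    x$timestamp <- parse_timestamps(x$timestamp)
  }
  attr(x$timestamp, "tzone") <- "UTC"
  x$affect <- as.numeric(x$affect)
  if (anyNA(x$person_id) || anyNA(x$timestamp)) {
    stop("ESM records contain missing person identifiers or timestamps")
  }
  if (anyNA(x$affect)) {
    stop("missing affect value in row ", which(is.na(x$affect))[1])
  }
  bad <- which(x$affect < bounds[1] | x$affect > bounds[2])
  if (length(bad)) {
    stop(sprintf("affect value %g in row %d outside scale bounds [%g, %g]",
                 x$affect[bad[1]], bad[1], bounds[1], bounds[2]))
  }
  ord <- order(x$person_id, x$timestamp, method = "radix")
  x <- x[ord, ]
  dup <- duplicated(x[c("person_id", "timestamp")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate timestamp for person '%s' at %s",
                 x$person_id[i], format(x$timestamp[i], "%Y-%m-%d %H:%M:%S")))
  }
  attr(x, "bounds") <- as.numeric(bounds)
  class(x) <- c("esm_dataset", class(x))
  x
}

check_bounds <- function(bounds) {
  if (!is.numeric(bounds) || length(bounds) != 2 || anyNA(bounds) ||
      bounds[1] >= bounds[2]) {
    stop("`bounds` must be two numbers (lower, upper) with lower < upper")
  }
  invisible(bounds)
}

# Accepts "YYYY-mm-dd HH:MM[:SS]" with an optional ISO-8601 "T" separator.
parse_timestamps <- function(ts, line_offset = 0L) {
  s <- gsub("T", " ", as.character(ts), fixed = TRUE)
  out <- rep(NA_real_, length(s))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")) {
    need <- is.na(out)
    if (!any(need)) break
    out[need] <- as.numeric(as.POSIXct(strptime(s[need], fmt, tz = "UTC")))
  }
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    where <- if (line_offset > 0) paste0("line ", i + line_offset) else paste0("row ", i)
    stop(sprintf("unparseable timestamp at %s: '%s'", where, s[i]))
  }
  as.POSIXct(out, origin = "1970-01-01", tz = "UTC")
}

#' Read long-format ESM records from CSV
#'
#' Expects header columns `person_id`, `timestamp` (ISO-8601, minute or
#' second resolution), and `affect`. Parse and validation failures name the
#' offending line. The returned dataset is sorted by `(person_id,
#' timestamp)` regardless of on-disk order.
#'
#' @inheritParams esm_dataset
#' @param path Path to a CSV file.
#' @return An [esm_dataset()].
#' @export
read_esm_csv <- function(path, bounds = c(0, 100)) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("person_id", "timestamp", "affect")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  affect <- suppressWarnings(as.numeric(raw$affect))
  bad <- which(is.na(affect))
  if (length(bad)) {
    stop(sprintf("malformed affect value at line %d: '%s'",
                 bad[1] + 1L, raw$affect[bad[1]]))
  }
  ts <- parse_timestamps(raw$timestamp, line_offset = 1L)
  esm_dataset(
    tibble::tibble(person_id = raw$person_id, timestamp = ts, affect = affect),
    bounds = bounds
  )
}

#' Write ESM records to CSV
#'
#' Inverse of [read_esm_csv()]: `read_esm_csv(write_esm_csv(x, p))`
#' round-trips a valid dataset exactly (timestamps at second precision).
#'
#' @param x An [esm_dataset()] or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esm_csv <- function(x, path) {
  x <- as_esm(x)
  out <- data.frame(
    person_id = x$person_id,
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    affect = x$affect
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table to CSV
#'
#' Thin tidy-CSV writer used by the command-line interface for accuracy
#' curves, power grids, and other result tables. An empty table yields a
#' header-only file.
#'
#' @param rows Data frame of results sharing one schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data frame")
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Scale bounds of an ESM dataset
#'
#' @param x An [esm_dataset()] or plain data frame (plain frames get the
#'   default 0-100 slider bounds).
#' @return Length-2 numeric `(lower, upper)`.
#' @export
scale_bounds <- function(x) {
  b <- attr(x, "bounds")
  if (is.null(b)) c(0, 100) else b
}

as_esm <- function(x) {
  if (inherits(x, "esm_dataset")) x else esm_dataset(x)
}

#' @export
print.esm_dataset <- function(x, ...) {
  b <- scale_bounds(x)
  cat(sprintf("ESM dataset: %d reports from %d person(s), scale [%g, %g]\n",
              nrow(x), length(unique(x$person_id)), b[1], b[2]))
  y <- x
  class(y) <- setdiff(class(y), "esm_dataset")
  attr(y, "bounds") <- NULL
  print(y, ...)
  invisible(x)
}

# Internal: split a dataset into per-person records with precomputed
# numeric time, decimal clock hour, and day of week (0 = Sunday).
person_split <- function(x) {
  x <- as_esm(x)
  if (nrow(x) == 0) return(list())
  lt <- as.POSIXlt(x$timestamp, tz = "UTC")
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  wday <- lt$wday
  tnum <- as.numeric(x$timestamp)
  ids <- unique(x$person_id)
  idx <- split(seq_len(nrow(x)), factor(x$person_id, levels = ids))
  lapply(idx, function(i) {
    list(id = x$person_id[i[1]], t = tnum[i], x = x$affect[i],
         hour = hour[i], wday = wday[i])
  })
}

# Internal: a single person's records, sorted, strictly increasing in time.
as_series_df <- function(series) {
  if (!is.data.frame(series)) {
    stop("`series` must be a data frame with 'timestamp' and 'affect' columns")
  }
  if (!all(c("timestamp", "affect") %in% names(series))) {
    stop("`series` needs 'timestamp' and 'affect' columns")
  }
  if ("person_id" %in% names(series) &&
      length(unique(series$person_id)) > 1) {
    stop("`series` must contain records from a single person")
  }
  if (!inherits(series$timestamp, "POSIXct")) {
    series$timestamp <- parse_timestamps(series$timestamp)
  }
  series <- series[order(series$timestamp), , drop = FALSE]
  if (nrow(series) > 1 && any(diff(as.numeric(series$timestamp)) <= 0)) {
    stop("timestamps within a series must be strictly increasing")
  }
  series
}
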