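# Sampling strategies ------------------------------------------------------
#
# Five ways to pick which of a person's reports enter a measure estimate:
# random draws, temporally close runs, temporally distant (equally spaced)
# selections, specific time-of-day windows, and specific days of the week.
# Every strategy returns a subset of the input rows in strictly increasing
# time; nothing is fabricated.

TIME_WINDOWS <- c("morning", "afternoon", "evening", "night")
DAY_FILTERS <- c("weekday", "weekend")
STRATEGIES <- c("random", "close", "distant", "time_window", "day_filter")

#' Describe a sampling plan
#'
#' A validated bundle of strategy plus parameters. `window` is required for
#' (and only for) the `time_window` strategy, `days` for `day_filter`.
#' Close and distant sampling are deterministic — there is exactly one
#' qualifying subset per person — so their replicate count is forced to 1.
#'
#' @param strategy One of `"random"`, `"close"`, `"distant"`,
#'   `"time_window"`, `"day_filter"`.
#' @param n_obs Number of observations per person, an integer >= 3.
#' @param window Time-of-day window for `time_window`: `"morning"`
#'   (6 a.m.-12 p.m.), `"afternoon"` (12-4 p.m.), `"evening"` (4-8 p.m.),
#'   or `"night"` (8 p.m.-6 a.m.).
#' @param days `"weekday"` (Mon-Fri) or `"weekend"` (Sat-Sun) for
#'   `day_filter`.
#' @param replicates Resampling replicates for the stochastic strategies.
#' @param seed Optional integer seed recorded with the plan.
#' @return A `sampling_plan` object.
#' @export
#' @examples
#' sampling_plan("time_window", n_obs = 10, window = "morning")
sampling_plan <- function(strategy, n_obs, window = NULL, days = NULL,
                          replicates = 1000L, seed = NULL) {
  strategy <- match.arg(strategy, STRATEGIES)
  n_obs <- as.integer(n_obs)
  if (is.na(n_obs) || n_obs < 3) stop("`n_obs` must be an integer >= 3")
  if (strategy == "time_window") {
    if (is.null(window)) stop("`window` must be set for the time_window strategy")
    window <- match.arg(window, TIME_WINDOWS)
  } else if (!is.null(window)) {
    stop("`window` is only meaningful for the time_window strategy")
  }
  if (strategy == "day_filter") {
    if (is.null(days)) stop("`days` must be set for the day_filter strategy")
    days <- match.arg(days, DAY_FILTERS)
  } else if (!is.null(days)) {
    stop("`days` is only meaningful for the day_filter strategy")
  }
  replicates <- if (strategy %in% c("close", "distant")) 1L else as.integer(replicates)
  if (is.na(replicates) || replicates < 1) stop("`replicates` must be >= 1")
  structure(
    list(strategy = strategy, n_obs = n_obs, window = window, days = days,
         replicates = replicates, seed = seed),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  extras <- c(
    if (!is.null(x$window)) paste0("window = ", x$window),
    if (!is.null(x$days)) paste0("days = ", x$days),
    paste0("replicates = ", x$replicates),
    if (!is.null(x$seed)) paste0("seed = ", x$seed)
  )
  cat(sprintf("Sampling plan: %s, n_obs = %d (%s)\n",
              x$strategy, x$n_obs, paste(extras, collapse = ", ")))
  invisible(x)
}

#' Random subsample of a person's reports
#'
#' Draws `n` reports without replacement, returned in temporal order. Uses
#' the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param series A single person's data frame of ESM records.
#' @param n Number of reports to draw.
#' @return The selected rows, time-ordered.
#' @family sampling strategies
#' @export
random_subsample <- function(series, n) {
  df <- as_series_df(series)
  m <- nrow(df)
  if (n > m) stop("insufficient data: need ", n, " reports, have ", m)
  df[sort.int(sample.int(m, n)), , drop = FALSE]
}

#' Temporally close subsample
#'
#' The run of `n` consecutive reports collected within the shortest
#' possible time span, subject to every adjacent gap being at most
#' `max_gap` hours. Ties go to the earliest such run. There is exactly one
#' close subsample per person, so no resampling is involved.
#'
#' @inheritParams random_subsample
#' @param max_gap Maximum allowed gap between adjacent reports, in hours.
#' @return The selected rows; errors if no qualifying run exists.
#' @family sampling strategies
#' @export
close_subsample <- function(series, n, max_gap = 24) {
  df <- as_series_df(series)
  idx <- close_idx(as.numeric(df$timestamp), n, max_gap)
  df[idx, , drop = FALSE]
}

close_idx <- function(t, n, max_gap = 24) {
  m <- length(t)
  if (n < 1) stop("`n` must be at least 1")
  if (n > m) stop("insufficient data: need ", n, " reports, have ", m)
  if (n == 1) return(1L)
  cap <- max_gap * 3600
  g <- diff(t)
  best <- NA_integer_
  best_span <- Inf
  for (i in seq_len(m - n + 1)) {
    gg <- g[i:(i + n - 2)]
    if (max(gg) > cap) next
    span <- t[i + n - 1] - t[i]
    if (span < best_span) { # strict < keeps the earliest window on ties
      best_span <- span
      best <- i
    }
  }
  if (is.na(best)) {
    stop("no run of ", n, " consecutive reports with all gaps <= ",
         max_gap, " h")
  }
  best:(best + n - 1L)
}

#' Temporally distant (equally spaced) subsample
#'
#' Divides the person's observation window (first to last report) into
#' `n - 1` equal intervals, defining `n` grid instants, and returns the `n`
#' distinct reports that minimise the total absolute deviation between
#' report times and grid instants, subject to temporal order (solved
#' exactly by dynamic programming; ties go to earlier reports). With `n =
#' 2` this is always the first and last report. Deterministic, like
#' [close_subsample()].
#'
#' @inheritParams random_subsample
#' @return The selected rows.
#' @family sampling strategies
#' @export
distant_subsample <- function(series, n) {
  df <- as_series_df(series)
  idx <- distant_idx(as.numeric(df$timestamp), n)
  df[idx, , drop = FALSE]
}

distant_idx <- function(t, n) {
  m <- length(t)
  if (n < 2) stop("`n` must be at least 2 for distant sampling")
  if (n > m) stop("insufficient data: need ", n, " reports, have ", m)
  grid <- t[1] + (seq_len(n) - 1) * (t[m] - t[1]) / (n - 1)
  # dp[j] = minimal cost of assigning grid points 1..k with point k -> report j
  dp_prev <- rep(Inf, m)
  dp_prev[seq_len(m - n + 1)] <- abs(t[seq_len(m - n + 1)] - grid[1])
  ptr <- matrix(0L, n, m)
  if (n > 1) {
    for (k in 2:n) {
      dp_cur <- rep(Inf, m)
      best_val <- Inf
      best_j <- 0L
      for (j in k:(m - n + k)) {
        if (dp_prev[j - 1] < best_val) { # strict < keeps earliest on ties
          best_val <- dp_prev[j - 1]
          best_j <- j - 1L
        }
        dp_cur[j] <- best_val + abs(t[j] - grid[k])
        ptr[k, j] <- best_j
      }
      dp_prev <- dp_cur
    }
  }
  j <- which.min(dp_prev) # first minimum = earliest report on ties
  idx <- integer(n)
  idx[n] <- j
  if (n > 1) {
    for (k in n:2) idx[k - 1] <- ptr[k, idx[k]]
  }
  idx
}

# Internal half-open time-of-day windows; together they partition the day.
in_window <- function(hour, window) {
  switch(window,
    morning = hour >= 6 & hour < 12,
    afternoon = hour >= 12 & hour < 16,
    evening = hour >= 16 & hour < 20,
    night = hour >= 20 | hour < 6,
    stop("unknown time window: '", window, "'")
  )
}

in_days <- function(wday, days) {
  # POSIXlt convention: 0 = Sunday ... 6 = Saturday
  switch(days,
    weekday = wday >= 1 & wday <= 5,
    weekend = wday == 0 | wday == 6,
    stop("unknown day filter: '", days, "'")
  )
}

#' Keep reports falling in a time-of-day window
#'
#' Windows are half-open in local clock time so that the four windows
#' partition the day: morning `[06:00, 12:00)`, afternoon `[12:00, 16:00)`,
#' evening `[16:00, 20:00)`, night `[20:00, 06:00)` (wrapping midnight). A
#' report at exactly 12:00 is afternoon, not morning.
#'
#' @param series Data frame of ESM records (one person or a whole dataset).
#' @param window `"morning"`, `"afternoon"`, `"evening"`, or `"night"`.
#' @return The matching rows; may be empty.
#' @family sampling strategies
#' @export
filter_time_window <- function(series, window) {
  window <- match.arg(window, TIME_WINDOWS)
  if (!is.data.frame(series) || !"timestamp" %in% names(series)) {
    stop("`series` must be a data frame with a 'timestamp' column")
  }
  ts <- if (inherits(series$timestamp, "POSIXct")) series$timestamp else parse_timestamps(series$timestamp)
  lt <- as.POSIXlt(ts, tz = "UTC")
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  keep_rows(series, in_window(hour, window))
}

#' Keep reports falling on weekdays or weekends
#'
#' @inheritParams filter_time_window
#' @param days `"weekday"` (Monday-Friday) or `"weekend"` (Saturday-Sunday).
#' @return The matching rows; may be empty.
#' @family sampling strategies
#' @export
filter_days <- function(series, days) {
  days <- match.arg(days, DAY_FILTERS)
  if (!is.data.frame(series) || !"timestamp" %in% names(series)) {
    stop("`series` must be a data frame with a 'timestamp' column")
  }
  ts <- if (inherits(series$timestamp, "POSIXct")) series$timestamp else parse_timestamps(series$timestamp)
  wd <- as.POSIXlt(ts, tz = "UTC")$wday
  keep_rows(series, in_days(wd, days))
}

keep_rows <- function(x, keep) {
  out <- x[keep, , drop = FALSE]
  if (inherits(x, "esm_dataset")) {
    attr(out, "bounds") <- attr(x, "bounds")
    class(out) <- class(x)
  }
  out
}

#' Restrict a dataset to persons with enough reports under a filter
#'
#' Applies an optional time-of-day window and/or day-of-week filter and
#' keeps only persons for whom at least `min_reports` reports survive
#' (the eligibility rule for the specific-times and specific-days
#' conditions).
#'
#' @param x An [esm_dataset()] or compatible data frame.
#' @param window Optional time-of-day window, see [filter_time_window()].
#' @param days Optional day filter, see [filter_days()].
#' @param min_reports Minimum surviving reports per person, default 30.
#' @param filtered If `TRUE`, return only the filter-surviving reports of
#'   eligible persons; if `FALSE` (default), return all their reports.
#' @return The restricted dataset.
#' @family sampling strategies
#' @export
eligible_persons <- function(x, window = NULL, days = NULL,
                             min_reports = 30L, filtered = FALSE) {
  x <- as_esm(x)
  sub <- x
  if (!is.null(window)) sub <- filter_time_window(sub, window)
  if (!is.null(days)) sub <- filter_days(sub, days)
  counts <- table(sub$person_id)
  keep_ids <- names(counts)[counts >= min_reports]
  src <- if (filtered) sub else x
  keep_rows(src, src$person_id %in% keep_ids)
}

#' Bias-correct window-restricted estimates
#'
#' Estimates computed from reports restricted to a time window or day set
#' can carry a level shift (affect tends to run higher in the evening, for
#' example). The correction adds a single window fixed effect,
#' `full_pop_mean - window_pop_mean_full`, to every person's estimate:
#' `full_pop_mean` is the population mean of the measure computed from all
#' records, and `window_pop_mean_full` the population mean computed from
#' all window-restricted records, both over the same eligible persons.
#' After correction the population mean of window-restricted full-record
#' estimates equals `full_pop_mean` exactly, and — being an additive shift
#' — the relative ordering of persons is untouched.
#'
#' @param window_estimates Numeric vector of per-person window-based
#'   estimates.
#' @param window_pop_mean_full Population mean of the measure over all
#'   window-restricted records of the eligible persons.
#' @param full_pop_mean Population mean of the measure over all records of
#'   the same persons.
#' @return `window_estimates` shifted by the bias term.
#' @family sampling strategies
#' @export
#' @examples
#' debias(c(40, 55, 70), window_pop_mean_full = 55, full_pop_mean = 58)
debias <- function(window_estimates, window_pop_mean_full, full_pop_mean) {
  if (!is.numeric(window_estimates)) {
    stop("`window_estimates` must be numeric")
  }
  if (length(window_pop_mean_full) != 1 || length(full_pop_mean) != 1 ||
      is.na(window_pop_mean_full) || is.na(full_pop_mean)) {
    stop("population means must be single non-missing numbers computed on the same eligible-person set")
  }
  window_estimates + (full_pop_mean - window_pop_mean_full)
}
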