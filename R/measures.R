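# The seven affect dynamics measures --------------------------------------
#
# All measures are order-based: any adjacent pair of retained observations
# counts as "successive" regardless of the elapsed time between them
# (overnight and multi-day gaps included).

# Internal: coerce a series to an ordered numeric value vector.
series_values <- function(series, min_n, what) {
  if (is.data.frame(series)) {
    series <- as_series_df(series)$affect
  }
  if (!is.numeric(series)) {
    stop("`series` must be a numeric vector or a data frame of ESM records")
  }
  x <- as.numeric(series)
  if (anyNA(x)) stop(what, ": series contains missing values")
  if (length(x) < min_n) {
    stop(what, " requires at least ", min_n, " observations, got ", length(x))
  }
  x
}

#' Trait affect: the within-person mean
#'
#' @param series Numeric vector of affect reports in temporal order, or a
#'   single person's data frame of ESM records.
#' @return The arithmetic mean.
#' @family affect dynamics measures
#' @export
#' @examples
#' mean_affect(c(10, 20, 30))
mean_affect <- function(series) {
  x <- series_values(series, 1L, "mean_affect")
  sum(x) / length(x)
}

#' Affect variability: the within-person standard deviation
#'
#' Defaults to the population divisor `n`; a sample-divisor (`n - 1`)
#' variant is available because conventions differ across the ESM
#' literature.
#'
#' @inheritParams mean_affect
#' @param divisor `"n"` (population, default) or `"n-1"` (sample).
#' @family affect dynamics measures
#' @export
#' @examples
#' sd_affect(c(2, 4, 4, 4, 5, 5, 7, 9))  # 2
sd_affect <- function(series, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  x <- series_values(series, 2L, "sd_affect")
  m <- mean(x)
  if (divisor == "n") sqrt(sum((x - m)^2) / length(x)) else stats::sd(x)
}

#' Relative standard deviation for bounded scales
#'
#' Mean-corrected variability: the within-person SD divided by the maximum
#' SD attainable at that mean for a variable bounded in `bounds`,
#' `sqrt((M - lower) * (upper - M))` (the population form, which does not
#' depend on n and is therefore comparable across subsample sizes). The
#' result lies in `[0, 1]`. When the mean sits exactly on a bound the
#' maximum is zero; with zero SD this is a 0/0 case and returns `NA`.
#'
#' @inheritParams sd_affect
#' @param bounds Scale bounds, default `c(0, 100)`.
#' @family affect dynamics measures
#' @export
#' @examples
#' rel_sd(c(40, 60))           # 0.2
#' rel_sd(c(0, 100, 0, 100))   # 1
rel_sd <- function(series, bounds = c(0, 100), divisor = c("n", "n-1")) {
  x <- series_values(series, 2L, "rel_sd")
  check_bounds(bounds)
  if (any(x < bounds[1] | x > bounds[2])) {
    stop("rel_sd: values outside the stated bounds")
  }
  s <- sd_affect(x, divisor)
  m <- mean(x)
  mx2 <- (m - bounds[1]) * (bounds[2] - m)
  if (mx2 <= 0) {
    if (s == 0) return(NA_real_)
    stop("rel_sd: mean at a scale bound with positive SD is impossible for bounded data")
  }
  s / sqrt(mx2)
}

#' Affect instability: root mean square of successive differences
#'
#' `sqrt(sum((x_i - x_{i+1})^2) / (n - 1))` over the `n - 1` successive
#' pairs of a temporally ordered series.
#'
#' @inheritParams mean_affect
#' @family affect dynamics measures
#' @export
#' @examples
#' rmssd(c(0, 10, 0, 10))  # 10
rmssd <- function(series) {
  x <- series_values(series, 2L, "rmssd")
  d <- diff(x)
  sqrt(sum(d * d) / length(d))
}

#' Affect instability: Teager-Kaiser energy operator
#'
#' `sum(x_i^2 - x_{i-1} * x_{i+1}) / (n - 2)` over the interior points of a
#' temporally ordered series; sensitive to mood spikes spanning three
#' consecutive reports. Unlike the other measures it is not invariant to
#' adding a constant to the series.
#'
#' @inheritParams mean_affect
#' @family affect dynamics measures
#' @export
#' @examples
#' tkeo(c(1, 2, 3))  # 1
tkeo <- function(series) {
  x <- series_values(series, 3L, "tkeo")
  n <- length(x)
  sum(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]) / (n - 2)
}

#' PAC threshold: 90th percentile of pooled absolute successive changes
#'
#' Pools the absolute successive differences of every person's series and
#' takes the 90th percentile (linear interpolation between order
#' statistics, quantile type 7). The probability of acute change ([pac()])
#' counts changes strictly exceeding this threshold.
#'
#' @param x An [esm_dataset()]/data frame of records, a list of per-person
#'   numeric value vectors, or a single numeric vector.
#' @param prob Percentile, default 0.9.
#' @param min_diffs Minimum number of pooled differences required.
#' @return A `pac_threshold` object with elements `d90` and `n_diffs`.
#' @family affect dynamics measures
#' @export
#' @examples
#' compute_d90(list(1:6, c(3, 9, 2, 8, 4, 10)))
compute_d90 <- function(x, prob = 0.9, min_diffs = 10L) {
  d <- pooled_absdiffs(x)
  if (length(d) < min_diffs) {
    stop("need at least ", min_diffs,
         " pooled successive differences for the PAC threshold, got ",
         length(d))
  }
  structure(
    list(d90 = stats::quantile(d, prob, names = FALSE, type = 7),
         n_diffs = length(d), prob = prob),
    class = "pac_threshold"
  )
}

pooled_absdiffs <- function(x) {
  vals <- if (is.data.frame(x)) {
    lapply(person_split(x), `[[`, "x")
  } else if (is.list(x)) {
    x
  } else {
    list(as.numeric(x))
  }
  abs(unlist(
    lapply(vals, function(v) if (length(v) >= 2) diff(as.numeric(v)) else numeric(0)),
    use.names = FALSE
  ))
}

as_d90 <- function(threshold) {
  if (inherits(threshold, "pac_threshold")) return(threshold$d90)
  if (is.numeric(threshold) && length(threshold) == 1 && !is.na(threshold) &&
      threshold >= 0) {
    return(as.numeric(threshold))
  }
  stop("`threshold` must be a pac_threshold object or a single non-negative number")
}

#' @export
print.pac_threshold <- function(x, ...) {
  cat(sprintf("PAC threshold: d%.2g = %g (from %d pooled successive differences)\n",
              x$prob, x$d90, x$n_diffs))
  invisible(x)
}

#' Affect instability: probability of acute change
#'
#' The fraction of successive changes whose absolute value strictly exceeds
#' the pooled 90th-percentile threshold `d90`; lies in `[0, 1]`.
#'
#' @inheritParams mean_affect
#' @param threshold A [compute_d90()] result or a single non-negative number.
#' @family affect dynamics measures
#' @export
#' @examples
#' pac(c(0, 10, 90, 80), threshold = 50)  # 1/3
pac <- function(series, threshold) {
  x <- series_values(series, 2L, "pac")
  mean(abs(diff(x)) > as_d90(threshold))
}

#' Affect inertia: lag-1 autocorrelation
#'
#' `sum((x_i - M)(x_{i+1} - M)) / sum((x_i - M)^2)` over a temporally
#' ordered series; lies in `[-1, 1]`. Undefined (returns `NA`) for a
#' constant series, where the denominator is zero.
#'
#' @inheritParams mean_affect
#' @family affect dynamics measures
#' @export
#' @examples
#' ar1(c(0, 10, 0, 10))    # -0.75
#' ar1(c(1, 2, 3, 4, 5))   # 0.4
ar1 <- function(series) {
  x <- series_values(series, 3L, "ar1")
  m <- mean(x)
  dev <- x - m
  ss <- sum(dev * dev)
  if (ss == 0) return(NA_real_)
  n <- length(x)
  sum(dev[-n] * dev[-1]) / ss
}

# Internal workhorse: all seven measures for one value vector, as an
# unnamed numeric(7) in MEASURES order. Measures whose minimum series
# length is not met, PAC without a threshold, and AR1 on a constant series
# come back NA (explicit undefined markers, never silently 0).
all_measures_vec <- function(x, lo, hi, d90 = NA_real_, sample_sd = FALSE) {
  n <- length(x)
  m <- sum(x) / n
  dev <- x - m
  ss <- sum(dev * dev)
  sdv <- if (n >= 2) sqrt(ss / (if (sample_sd) n - 1 else n)) else NA_real_
  mx2 <- (m - lo) * (hi - m)
  rsd <- if (n >= 2 && mx2 > 0) sdv / sqrt(mx2) else NA_real_
  d <- if (n >= 2) x[-1] - x[-n] else numeric(0)
  rms <- if (n >= 2) sqrt(sum(d * d) / (n - 1)) else NA_real_
  tk <- if (n >= 3) sum(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]) / (n - 2) else NA_real_
  pc <- if (n >= 2 && !is.na(d90)) mean(abs(d) > d90) else NA_real_
  a1 <- if (n >= 3 && ss > 0) sum(dev[-n] * dev[-1]) / ss else NA_real_
  c(m, sdv, rsd, rms, tk, pc, a1)
}

# Internal: one named measure for one value vector.
estimate_measure <- function(x, measure, lo, hi, d90 = NA_real_,
                             sample_sd = FALSE) {
  all_measures_vec(x, lo, hi, d90, sample_sd)[match(measure, MEASURES)]
}

#' Compute all seven affect dynamics measures per person
#'
#' Applies the seven measures to every person in the dataset. PAC uses a
#' single dataset-level threshold: by default the pooled [compute_d90()] of
#' the data at hand. Measures whose minimum series length is not met (mean
#' needs 1 report; SD, relative SD, RMSSD and PAC need 2; TKEO and AR1 need
#' 3) and AR1 for constant series are returned as `NA`.
#'
#' @param x An [esm_dataset()] or compatible data frame.
#' @param d90 Optional PAC threshold ([compute_d90()] result or number).
#'   When `NULL`, computed from `x`.
#' @param sd_divisor Divisor convention for SD and relative SD.
#' @return A tibble with columns `person_id`, `n`, and one column per
#'   measure in [affect_measures()] order.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_persons = 3, days_per_person = 5,
#'                                         seed = 1))$data
#' compute_measures(ds)
compute_measures <- function(x, d90 = NULL, sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  xd <- as_esm(x)
  b <- scale_bounds(xd)
  ps <- person_split(xd)
  d90v <- if (is.null(d90)) compute_d90(xd)$d90 else as_d90(d90)
  est <- t(vapply(
    ps,
    function(p) all_measures_vec(p$x, b[1], b[2], d90v,
                                 sample_sd = sd_divisor == "n-1"),
    numeric(7L)
  ))
  colnames(est) <- MEASURES
  out <- data.frame(
    person_id = vapply(ps, `[[`, "", "id"),
    n = vapply(ps, function(p) length(p$x), 0L),
    est,
    check.names = FALSE, row.names = NULL
  )
  tibble::as_tibble(out)
}
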