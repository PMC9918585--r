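# Subsample-versus-truth RMSE engine ---------------------------------------
#
# "Truth" is each person's measure computed from their full record (>= 50
# reports by default). Accuracy of a sampling strategy at n observations is
# the per-person RMSE of subsample-based estimates against that truth,
# averaged over persons, with a percentile-bootstrap CI over the per-person
# RMSEs.

#' True measure values from full records
#'
#' Computes all seven measures per person from the complete records,
#' restricted to persons with at least `min_reports` reports (persons below
#' the cut are dropped with a message). PAC uses the pooled threshold of the
#' retained full records.
#'
#' @param x An [esm_dataset()] or compatible data frame.
#' @param min_reports Minimum full-record length, default 50.
#' @param d90 Optional fixed PAC threshold; computed from the retained
#'   records when `NULL`.
#' @return A tibble as from [compute_measures()].
#' @export
true_measures <- function(x, min_reports = 50L, d90 = NULL) {
  x <- as_esm(x)
  counts <- table(x$person_id)
  drop_ids <- names(counts)[counts < min_reports]
  if (length(drop_ids)) {
    message(length(drop_ids), " person(s) below the ", min_reports,
            "-report cut excluded from true-measure estimation")
  }
  kept <- keep_rows(x, !(x$person_id %in% drop_ids))
  if (nrow(kept) == 0) stop("no person meets the ", min_reports, "-report cut")
  compute_measures(kept, d90 = d90)
}

#' Per-person estimation RMSE for one measure under a sampling plan
#'
#' For the stochastic strategies (random draws, possibly applied after a
#' time/day filter by the caller) the RMSE over `replicates` resampled
#' estimates against `truth`: `sqrt(mean((est_r - truth)^2))`. Close and
#' distant sampling select exactly one subset per person, so their "RMSE"
#' is the single absolute error `|est - truth|`.
#'
#' @param series A single person's data frame of ESM records.
#' @param measure One of [affect_measures()].
#' @param n Number of observations per estimate.
#' @param truth The person's true measure value (from the full record).
#' @param strategy `"random"`, `"close"`, or `"distant"`.
#' @param replicates Resampling replicates for `"random"`.
#' @param bounds Scale bounds (for the relative SD).
#' @param d90 PAC threshold; required when `measure = "pac"`.
#' @param max_gap Close-sampling gap cap in hours.
#' @return A single non-negative number, or `NA` if every replicate left
#'   the measure undefined.
#' @export
person_rmse <- function(series, measure, n, truth,
                        strategy = c("random", "close", "distant"),
                        replicates = 1000L, bounds = c(0, 100), d90 = NULL,
                        max_gap = 24) {
  measure <- match.arg(measure, MEASURES)
  strategy <- match.arg(strategy)
  df <- as_series_df(series)
  xv <- df$affect
  tt <- as.numeric(df$timestamp)
  d90v <- if (is.null(d90)) NA_real_ else as_d90(d90)
  if (measure == "pac" && is.na(d90v)) {
    stop("pac requires a `d90` threshold")
  }
  if (strategy %in% c("close", "distant")) {
    idx <- if (strategy == "close") close_idx(tt, n, max_gap) else distant_idx(tt, n)
    est <- estimate_measure(xv[idx], measure, bounds[1], bounds[2], d90v)
    return(abs(est - truth))
  }
  m <- length(xv)
  if (n > m) stop("insufficient data: need ", n, " reports, have ", m)
  ests <- vapply(seq_len(replicates), function(r) {
    estimate_measure(xv[sort.int(sample.int(m, n))], measure,
                     bounds[1], bounds[2], d90v)
  }, numeric(1))
  ests <- ests[!is.na(ests)]
  if (!length(ests)) return(NA_real_)
  sqrt(mean((ests - truth)^2))
}

#' Percentile bootstrap CI for a mean
#'
#' @param values Numeric vector (at least 2 non-missing values).
#' @param reps Bootstrap resamples, default 2000.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, reps = 2000L, level = 0.95) {
  values <- values[!is.na(values)]
  k <- length(values)
  if (k < 2) stop("need at least 2 values to bootstrap a CI")
  draws <- matrix(values[sample.int(k, k * reps, replace = TRUE)], k, reps)
  means <- colMeans(draws)
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Accuracy curves: mean RMSE by number of observations
#'
#' The core accuracy engine. For each `n` in `n_obs` and each requested
#' measure, computes every eligible person's estimation RMSE against their
#' full-record truth under the given strategy, then averages over persons
#' and attaches a percentile-bootstrap CI over the per-person RMSEs.
#'
#' Strategy semantics:
#' * `random` — `replicates` random draws of `n` reports per person.
#' * `close` / `distant` — one deterministic subset per person (absolute
#'   error); persons with no qualifying close run are excluded per cell.
#' * `time_window` / `day_filter` — random draws restricted to the filter;
#'   persons need at least `min_window` surviving reports, and estimates
#'   are bias-corrected with [debias()] unless `debias_estimates = FALSE`.
#'
#' Truth always uses the full records and the full-data PAC threshold. PAC
#' estimates use, per replicate, a threshold recomputed from the pooled
#' subsamples of that replicate (`d90_mode = "resample"`, the default) or
#' the fixed full-data threshold (`"fixed"`).
#'
#' @param x An [esm_dataset()] or compatible data frame.
#' @param measures Measures to report, a subset of [affect_measures()].
#' @param strategy One of `"random"`, `"close"`, `"distant"`,
#'   `"time_window"`, `"day_filter"`.
#' @param n_obs Integer vector of observation counts, default `3:30`.
#' @param replicates Resampling replicates for stochastic strategies.
#' @param window,days Filter parameters for the respective strategies.
#' @param min_full Minimum full-record length defining the person pool.
#' @param min_window Minimum filter-surviving reports for eligibility.
#' @param debias_estimates Apply the window fixed-effect correction.
#' @param d90_mode `"resample"` or `"fixed"` (see above).
#' @param max_gap Close-sampling gap cap in hours.
#' @param ci Compute bootstrap CIs (set `FALSE` to skip for speed).
#' @param ci_reps,level Bootstrap resamples and confidence level.
#' @return A tibble with one row per (measure, n_obs): columns `measure`,
#'   `strategy`, `window`, `days`, `n_obs`, `mean_rmse`, `ci_lower`,
#'   `ci_upper`, `n_persons`, `replicates`. Cells with fewer than 2
#'   eligible persons are omitted with a warning.
#' @export
rmse_curve <- function(x,
                       measures = MEASURES,
                       strategy = c("random", "close", "distant",
                                    "time_window", "day_filter"),
                       n_obs = 3:30, replicates = 1000L,
                       window = NULL, days = NULL,
                       min_full = 50L, min_window = 30L,
                       debias_estimates = TRUE,
                       d90_mode = c("resample", "fixed"),
                       max_gap = 24, ci = TRUE, ci_reps = 2000L,
                       level = 0.95) {
  strategy <- match.arg(strategy)
  d90_mode <- match.arg(d90_mode)
  measures <- match.arg(measures, MEASURES, several.ok = TRUE)
  x <- as_esm(x)
  b <- scale_bounds(x)
  persons <- person_split(x)
  persons <- persons[vapply(persons, function(p) length(p$x), 0L) >= min_full]
  if (length(persons) < 2) {
    stop("need at least 2 persons with >= ", min_full, " reports")
  }
  full_d90 <- stats::quantile(pooled_absdiffs(lapply(persons, `[[`, "x")),
                              0.9, names = FALSE, type = 7)
  truth <- t(vapply(persons, function(p) all_measures_vec(p$x, b[1], b[2], full_d90),
                    numeric(7L)))

  filtered <- strategy %in% c("time_window", "day_filter")
  if (strategy == "time_window") {
    if (is.null(window)) stop("`window` must be set for the time_window strategy")
    window <- match.arg(window, TIME_WINDOWS)
    pool <- lapply(persons, function(p) which(in_window(p$hour, window)))
  } else if (strategy == "day_filter") {
    if (is.null(days)) stop("`days` must be set for the day_filter strategy")
    days <- match.arg(days, DAY_FILTERS)
    pool <- lapply(persons, function(p) which(in_days(p$wday, days)))
  } else {
    pool <- lapply(persons, function(p) seq_along(p$x))
  }
  if (filtered) {
    keep <- vapply(pool, length, 0L) >= min_window
    persons <- persons[keep]
    pool <- pool[keep]
    truth <- truth[keep, , drop = FALSE]
    if (length(persons) < 2) {
      stop("fewer than 2 persons have >= ", min_window,
           " reports under this filter")
    }
  }
  P <- length(persons)

  bias <- rep(0, 7L)
  if (filtered && debias_estimates) {
    pooled_vals <- mapply(function(p, idx) p$x[idx], persons, pool,
                          SIMPLIFY = FALSE)
    wd90 <- stats::quantile(pooled_absdiffs(pooled_vals), 0.9,
                            names = FALSE, type = 7)
    wfull <- t(vapply(seq_len(P), function(i) {
      all_measures_vec(pooled_vals[[i]], b[1], b[2], wd90)
    }, numeric(7L)))
    bias <- colMeans(truth, na.rm = TRUE) - colMeans(wfull, na.rm = TRUE)
  }

  jm <- match(measures, MEASURES)
  rows <- list()
  for (n in as.integer(n_obs)) {
    pr <- person_rmse_matrix(persons, pool, truth, bias, n, strategy,
                             replicates, b, full_d90, d90_mode, max_gap)
    for (j in jm) {
      v <- pr[, j]
      v <- v[!is.na(v)]
      if (length(v) < 2) {
        warning("cell (", MEASURES[j], ", n_obs = ", n,
                ") has fewer than 2 eligible persons; omitted")
        next
      }
      ciq <- if (ci) bootstrap_ci(v, ci_reps, level) else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        measure = MEASURES[j], strategy = strategy,
        window = if (is.null(window)) NA_character_ else window,
        days = if (is.null(days)) NA_character_ else days,
        n_obs = n, mean_rmse = mean(v),
        ci_lower = unname(ciq[1]), ci_upper = unname(ciq[2]),
        n_persons = length(v),
        replicates = if (strategy %in% c("close", "distant")) 1L else as.integer(replicates)
      )
    }
  }
  do.call(rbind, rows)
}

# Internal: matrix of per-person RMSEs (P x 7) for one n under one strategy.
person_rmse_matrix <- function(persons, pool, truth, bias, n, strategy,
                               replicates, b, full_d90, d90_mode, max_gap) {
  P <- length(persons)
  feasible <- which(vapply(pool, length, 0L) >= n)
  if (strategy %in% c("close", "distant")) {
    sel <- vector("list", P)
    for (p in feasible) {
      idx <- tryCatch(
        if (strategy == "close") close_idx(persons[[p]]$t, n, max_gap)
        else distant_idx(persons[[p]]$t, n),
        error = function(e) NULL
      )
      if (!is.null(idx)) sel[[p]] <- persons[[p]]$x[idx]
    }
    have <- which(!vapply(sel, is.null, TRUE))
    if (!length(have)) return(matrix(NA_real_, P, 7L))
    d90n <- if (d90_mode == "resample") {
      d <- pooled_absdiffs(sel[have])
      if (length(d)) stats::quantile(d, 0.9, names = FALSE, type = 7) else full_d90
    } else full_d90
    est <- matrix(NA_real_, P, 7L)
    for (p in have) est[p, ] <- all_measures_vec(sel[[p]], b[1], b[2], d90n)
    est <- est + rep(bias, each = P)
    return(abs(est - truth))
  }
  # stochastic strategies: accumulate squared errors over replicates
  sq <- matrix(0, P, 7L)
  cnt <- matrix(0L, P, 7L)
  for (r in seq_len(replicates)) {
    vals <- vector("list", P)
    for (p in feasible) {
      pick <- pool[[p]][sort.int(sample.int(length(pool[[p]]), n))]
      vals[[p]] <- persons[[p]]$x[pick]
    }
    d90r <- if (d90_mode == "resample") {
      d <- pooled_absdiffs(vals[feasible])
      if (length(d)) stats::quantile(d, 0.9, names = FALSE, type = 7) else full_d90
    } else full_d90
    est <- matrix(NA_real_, P, 7L)
    for (p in feasible) est[p, ] <- all_measures_vec(vals[[p]], b[1], b[2], d90r)
    est <- est + rep(bias, each = P)
    e2 <- (est - truth)^2
    ok <- !is.na(e2)
    sq[ok] <- sq[ok] + e2[ok]
    cnt <- cnt + ok
  }
  out <- sqrt(sq / cnt)
  out[cnt == 0L] <- NA_real_
  out
}

#' Between-person SD benchmarks for RMSE curves
#'
#' How big is an estimation RMSE? The yardstick is the between-person
#' standard deviation of the true measure (population divisor): thresholds
#' at 1, 0.5, and 0.3 of that SD give the accuracy bands the curves are
#' read against.
#'
#' @param truths Tibble of true measures as from [true_measures()].
#' @param multiples Threshold multiples, default `c(1, 0.5, 0.3)`.
#' @return A tibble with columns `measure`, `between_person_sd`,
#'   `multiple`, `threshold`; measures with fewer than 2 defined values are
#'   excluded.
#' @export
benchmark_thresholds <- function(truths, multiples = c(1, 0.5, 0.3)) {
  present <- intersect(MEASURES, names(truths))
  rows <- list()
  for (m in present) {
    v <- truths[[m]]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    sdb <- sqrt(mean((v - mean(v))^2))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      measure = m, between_person_sd = sdb,
      multiple = multiples, threshold = multiples * sdb
    )
  }
  if (!length(rows)) stop("no measure has at least 2 defined true values")
  do.call(rbind, rows)
}

#' Smallest number of observations reaching an accuracy threshold
#'
#' Scans an accuracy curve for the smallest `n_obs` whose mean RMSE is at
#' or below `threshold`.
#'
#' @param curves A tibble from [rmse_curve()] for a single measure and
#'   strategy, sorted by `n_obs`.
#' @param threshold Accuracy threshold (same units as the measure).
#' @return The smallest qualifying `n_obs`, or `NA` if the threshold is
#'   never reached within the curve's range.
#' @export
min_n_for_accuracy <- function(curves, threshold) {
  if (!is.data.frame(curves) || nrow(curves) == 0) {
    stop("`curves` must be a non-empty accuracy-curve table")
  }
  if (length(unique(curves$measure)) > 1 ||
      length(unique(curves$strategy)) > 1) {
    stop("`curves` must cover a single measure and strategy")
  }
  curves <- curves[order(curves$n_obs), ]
  hit <- which(curves$mean_rmse <= threshold)
  if (!length(hit)) NA_integer_ else as.integer(curves$n_obs[hit[1]])
}
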