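# Synthetic ESM data with known ground truth --------------------------------
#
# Emulates the sampling regime of a smartphone ESM study: a few
# notifications per day at random times inside a personal day window, at
# least one hour apart, answered on a bounded 0-100 slider. Person-level
# heterogeneity in trait level, within-person volatility, and inertia is
# layered over diurnal and weekend structure; the generating parameters
# are returned alongside the data so estimators can be validated against
# ground truth.

#' Configuration for the synthetic ESM generator
#'
#' Defaults mirror the emulated study's regime — 4 questionnaires daily
#' between 9 a.m. and 10 p.m., every day of the week, at least 1 h between
#' consecutive notifications, integer slider responses on 0-100 — with
#' person-level distributions chosen as plausible for momentary happiness
#' data (the real population distributions are unpublished; these are
#' placeholders, see the methods vignette): person means around 60 with SD
#' 15, lognormal within-person innovation scales with median about 9
#' points, and lag-1 persistence around 0.35.
#'
#' @param n_persons Number of persons.
#' @param days_per_person Days of observation per person (integer, or a
#'   zero-argument function drawing one integer per person).
#' @param beeps_per_day Notifications per day, default 4.
#' @param day_window Daily sampling window in decimal hours, default
#'   `c(9, 22)` (9 a.m. to 10 p.m.).
#' @param min_gap_minutes Minimum gap between consecutive notifications,
#'   default 60.
#' @param trait_mean,trait_sd Population distribution of person means.
#' @param within_sd_log_mean,within_sd_log_sd Lognormal parameters of the
#'   person-specific AR(1) innovation scale.
#' @param phi_mean,phi_sd Population distribution of the person-specific
#'   lag-1 persistence (draws truncated to (-0.95, 0.95)).
#' @param diurnal_amplitude Amplitude (scale points) of a sinusoidal
#'   time-of-day component.
#' @param diurnal_peak_hour Clock hour at which the diurnal component
#'   peaks, default 18 (affect tends to run higher in the evening).
#' @param weekend_shift Additive shift (scale points) on Saturdays and
#'   Sundays.
#' @param bounds Response-scale bounds; latent values are clipped to them.
#' @param round_to_integer Round observed values to integers, mimicking a
#'   slider (default `TRUE`).
#' @param start_date First observation day (a Monday by default so weekday
#'   and weekend structure is deterministic).
#' @param seed Optional integer seed used by [generate_dataset()].
#' @return A validated `synthetic_config` object.
#' @export
#' @examples
#' synthetic_config(n_persons = 10, days_per_person = 14, seed = 42)
synthetic_config <- function(n_persons = 100L,
                             days_per_person = 30L,
                             beeps_per_day = 4L,
                             day_window = c(9, 22),
                             min_gap_minutes = 60L,
                             trait_mean = 60, trait_sd = 15,
                             within_sd_log_mean = log(9),
                             within_sd_log_sd = 0.35,
                             phi_mean = 0.35, phi_sd = 0.15,
                             diurnal_amplitude = 5,
                             diurnal_peak_hour = 18,
                             weekend_shift = 2,
                             bounds = c(0, 100),
                             round_to_integer = TRUE,
                             start_date = "2023-01-02",
                             seed = NULL) {
  check_bounds(bounds)
  if (!is.numeric(day_window) || length(day_window) != 2 ||
      day_window[1] < 0 || day_window[2] > 24 ||
      day_window[1] >= day_window[2]) {
    stop("`day_window` must be increasing clock hours within [0, 24]")
  }
  n_persons <- as.integer(n_persons)
  if (is.na(n_persons) || n_persons < 0) stop("`n_persons` must be >= 0")
  beeps_per_day <- as.integer(beeps_per_day)
  if (is.na(beeps_per_day) || beeps_per_day < 1) {
    stop("`beeps_per_day` must be >= 1")
  }
  min_gap_minutes <- as.numeric(min_gap_minutes)
  if (is.na(min_gap_minutes) || min_gap_minutes < 0) {
    stop("`min_gap_minutes` must be >= 0")
  }
  window_h <- day_window[2] - day_window[1]
  # strict: random beep times need positive slack beyond the packed gaps
  if (beeps_per_day > 1 && (beeps_per_day - 1) * min_gap_minutes / 60 >= window_h) {
    stop("infeasible schedule: ", beeps_per_day, " beeps with ",
         min_gap_minutes, " min spacing do not fit in a ",
         window_h, " h window")
  }
  if (!is.function(days_per_person)) {
    days_per_person <- as.integer(days_per_person)
    if (is.na(days_per_person) || days_per_person < 1) {
      stop("`days_per_person` must be >= 1 (or a sampling function)")
    }
  }
  if (trait_sd < 0 || within_sd_log_sd < 0 || phi_sd < 0 ||
      diurnal_amplitude < 0) {
    stop("scale parameters must be non-negative")
  }
  if (abs(phi_mean) >= 1) stop("`phi_mean` must lie in (-1, 1)")
  structure(
    list(n_persons = n_persons, days_per_person = days_per_person,
         beeps_per_day = beeps_per_day, day_window = as.numeric(day_window),
         min_gap_minutes = min_gap_minutes,
         trait_mean = trait_mean, trait_sd = trait_sd,
         within_sd_log_mean = within_sd_log_mean,
         within_sd_log_sd = within_sd_log_sd,
         phi_mean = phi_mean, phi_sd = phi_sd,
         diurnal_amplitude = diurnal_amplitude,
         diurnal_peak_hour = diurnal_peak_hour,
         weekend_shift = weekend_shift,
         bounds = as.numeric(bounds),
         round_to_integer = isTRUE(round_to_integer),
         start_date = start_date, seed = seed),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  days <- if (is.function(x$days_per_person)) "<function>" else x$days_per_person
  cat(sprintf(
    paste0("Synthetic ESM config: %d persons, %s day(s) x %d beeps ",
           "(%.3g-%.3g h window, >= %g min apart), scale [%g, %g]\n"),
    x$n_persons, days, x$beeps_per_day, x$day_window[1], x$day_window[2],
    x$min_gap_minutes, x$bounds[1], x$bounds[2]))
  cat(sprintf("  trait ~ N(%g, %g); innovation scale ~ lognormal(%g, %g); phi ~ N(%g, %g)\n",
              x$trait_mean, x$trait_sd, x$within_sd_log_mean,
              x$within_sd_log_sd, x$phi_mean, x$phi_sd))
  cat(sprintf("  diurnal amplitude %g (peak %g h), weekend shift %g%s\n",
              x$diurnal_amplitude, x$diurnal_peak_hour, x$weekend_shift,
              if (x$round_to_integer) ", integer responses" else ""))
  invisible(x)
}

resolve_days <- function(config) {
  d <- if (is.function(config$days_per_person)) {
    as.integer(config$days_per_person())
  } else {
    config$days_per_person
  }
  if (is.na(d) || d < 1) stop("days_per_person must resolve to an integer >= 1")
  d
}

#' Generate one person's notification schedule
#'
#' Per day, `beeps_per_day` instants drawn uniformly at random inside the
#' day window subject to all consecutive gaps being at least
#' `min_gap_minutes` (drawn as sorted uniforms on the gap-reduced window,
#' then spaced back out — uniform over the feasible configurations).
#' Strictly increasing overall. Uses the current RNG state.
#'
#' @param config A [synthetic_config()].
#' @param days Number of days; defaults to the config's `days_per_person`.
#' @return A `POSIXct` vector of notification times.
#' @export
generate_schedule <- function(config, days = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(days)) days <- resolve_days(config)
  w0 <- config$day_window[1]
  W <- config$day_window[2] - w0
  k <- config$beeps_per_day
  g <- config$min_gap_minutes / 60
  if (k > 1 && (k - 1) * g >= W) {
    stop("infeasible schedule: ", k, " beeps with ", config$min_gap_minutes,
         " min spacing do not fit in a ", W, " h window")
  }
  origin <- as.numeric(as.POSIXct(paste(config$start_date, "00:00:00"),
                                  tz = "UTC"))
  out <- numeric(days * k)
  for (d in seq_len(days)) {
    u <- sort(stats::runif(k, 0, W - (k - 1) * g))
    hrs <- w0 + u + (seq_len(k) - 1) * g
    out[((d - 1) * k + 1):(d * k)] <- origin + (d - 1) * 86400 + hrs * 3600
  }
  as.POSIXct(out, origin = "1970-01-01", tz = "UTC")
}

#' Generate one synthetic person
#'
#' Draws person-level parameters (trait mean `mu`, innovation scale
#' `sigma`, persistence `phi`), a notification schedule, and the affect
#' series: a stationary AR(1) state in beep order (persistence applies
#' between consecutive reports regardless of elapsed time, matching the
#' order-based estimators) plus a sinusoidal diurnal component and a
#' weekend shift around `mu`, clipped to the scale bounds and optionally
#' rounded. Uses the current RNG state.
#'
#' @param config A [synthetic_config()].
#' @param person_id Identifier for the generated person.
#' @return A list with `series` (tibble of records) and `truth` (one-row
#'   tibble: `person_id`, `mu`, `sigma`, `phi`, `stationary_sd`).
#' @export
generate_person <- function(config, person_id = "P0001") {
  stopifnot(inherits(config, "synthetic_config"))
  mu <- stats::rnorm(1, config$trait_mean, config$trait_sd)
  sigma <- stats::rlnorm(1, config$within_sd_log_mean, config$within_sd_log_sd)
  phi <- stats::rnorm(1, config$phi_mean, config$phi_sd)
  phi <- max(-0.95, min(0.95, phi))
  ts <- generate_schedule(config)
  m <- length(ts)
  lt <- as.POSIXlt(ts, tz = "UTC")
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  weekend <- lt$wday == 0 | lt$wday == 6
  innov <- stats::rnorm(m, 0, sigma)
  innov[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
  state <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  diurnal <- config$diurnal_amplitude *
    cos(2 * pi * (hour - config$diurnal_peak_hour) / 24)
  v <- mu + diurnal + config$weekend_shift * weekend + state
  v <- pmin(pmax(v, config$bounds[1]), config$bounds[2])
  if (config$round_to_integer) v <- round(v)
  list(
    series = tibble::tibble(person_id = person_id, timestamp = ts, affect = v),
    truth = tibble::tibble(person_id = person_id, mu = mu, sigma = sigma,
                           phi = phi,
                           stationary_sd = sigma / sqrt(1 - phi^2))
  )
}

#' Generate a synthetic ESM dataset with ground truth
#'
#' `n_persons` independent persons from [generate_person()]. When the
#' config carries a `seed` it is applied first, making the output a pure
#' function of the config.
#'
#' @param config A [synthetic_config()].
#' @return A list with `data` (an [esm_dataset()]) and `truth` (a tibble
#'   with one row per person: `person_id`, `mu`, `sigma`, `phi`,
#'   `stationary_sd`).
#' @export
#' @examples
#' out <- generate_dataset(synthetic_config(n_persons = 2,
#'                                          days_per_person = 3, seed = 7))
#' out$truth
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$n_persons == 0) {
    empty <- tibble::tibble(person_id = character(),
                            timestamp = as.POSIXct(character(), tz = "UTC"),
                            affect = numeric())
    return(list(data = esm_dataset(empty, config$bounds),
                truth = tibble::tibble(person_id = character(), mu = numeric(),
                                       sigma = numeric(), phi = numeric(),
                                       stationary_sd = numeric())))
  }
  ids <- sprintf("P%04d", seq_len(config$n_persons))
  gens <- lapply(ids, function(id) generate_person(config, id))
  data <- esm_dataset(do.call(rbind, lapply(gens, `[[`, "series")),
                      bounds = config$bounds)
  truth <- do.call(rbind, lapply(gens, `[[`, "truth"))
  list(data = data, truth = truth)
}
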