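# Monte Carlo power engine --------------------------------------------------
#
# Power to detect a Pearson correlation between an affect dynamics measure
# and an outcome, as a function of the number of participants and the
# number of observations per participant. Each simulation draws a fresh
# outcome variable against the full person population at the target
# correlation, resamples participants (with replacement by default),
# re-estimates the measure from a random subsample of each participant's
# reports, and tests the correlation; power is the proportion of
# simulations with a significant positive correlation.

#' Simulate an outcome with a target correlation
#'
#' Builds a Gaussian-noise outcome against `y`: standardized `y` mixed with
#' Gaussian noise orthogonalized against it, `r * y_std + sqrt(1 - r^2) *
#' e_std`. In `"exact"` mode (default) the noise is empirically
#' orthogonalized and standardized, so the sample Pearson correlation with
#' `y` equals `r_target` to numerical tolerance; in `"population"` mode the
#' noise is raw standard-normal, so the correlation is `r_target` only in
#' expectation. The returned vector has mean 0 and (in exact mode) unit
#' sample SD.
#'
#' @param y Numeric vector (length >= 3, non-constant).
#' @param r_target Target Pearson correlation in `[-1, 1]`.
#' @param mode `"exact"` or `"population"`.
#' @return Numeric vector of the same length as `y`.
#' @export
#' @examples
#' set.seed(1)
#' z <- simulate_outcome(rnorm(100), 0.5)
#' cor(z, z) # placeholder; see tests for the r recovery property
simulate_outcome <- function(y, r_target, mode = c("exact", "population")) {
  mode <- match.arg(mode)
  if (!is.numeric(y) || length(y) < 3) {
    stop("`y` must be a numeric vector of length >= 3")
  }
  if (!is.numeric(r_target) || length(r_target) != 1 || is.na(r_target) ||
      abs(r_target) > 1) {
    stop("`r_target` must be a single number in [-1, 1]")
  }
  y0 <- y - mean(y)
  ssy <- sum(y0^2)
  if (ssy == 0) stop("`y` must not be constant")
  n <- length(y)
  yt <- y0 / sqrt(ssy)
  if (mode == "population") {
    return(r_target * yt * sqrt(n - 1) + sqrt(1 - r_target^2) * stats::rnorm(n))
  }
  if (abs(r_target) == 1) {
    return(sign(r_target) * yt * sqrt(n - 1))
  }
  repeat {
    e <- stats::rnorm(n)
    e0 <- e - mean(e)
    ep <- e0 - sum(e0 * yt) * yt
    sse <- sum(ep^2)
    if (sse > 0) break
  }
  (r_target * yt + sqrt(1 - r_target^2) * ep / sqrt(sse)) * sqrt(n - 1)
}

#' Two-tailed t-test on a Pearson correlation
#'
#' Computes `r`, the t statistic `r * sqrt((n - 2) / (1 - r^2))`, its
#' two-tailed p value on `n - 2` degrees of freedom, and the
#' significant-positive flag used by the power engine: `p < alpha` AND
#' `r > 0`.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), both non-constant.
#' @param alpha Significance level, default 0.05.
#' @return A list with elements `r`, `t`, `p`, `significant_positive`,
#'   `n`, `alpha`.
#' @export
#' @examples
#' pearson_test(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
pearson_test <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("inputs must not contain missing values")
  x0 <- x - mean(x)
  y0 <- y - mean(y)
  ssx <- sum(x0^2)
  ssy <- sum(y0^2)
  if (ssx == 0 || ssy == 0) stop("constant input: correlation undefined")
  r <- sum(x0 * y0) / sqrt(ssx * ssy)
  r <- max(-1, min(1, r))
  if (1 - r^2 < .Machine$double.eps) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, t = t, p = p,
       significant_positive = (p < alpha) && (r > 0),
       n = n, alpha = alpha)
}

# Internal: shared preparation for power_cell / power_grid.
power_prep <- function(x, min_full) {
  x <- as_esm(x)
  b <- scale_bounds(x)
  persons <- person_split(x)
  persons <- persons[vapply(persons, function(p) length(p$x), 0L) >= min_full]
  if (length(persons) < 3) {
    stop("need at least 3 persons with >= ", min_full, " reports")
  }
  full_d90 <- stats::quantile(pooled_absdiffs(lapply(persons, `[[`, "x")),
                              0.9, names = FALSE, type = 7)
  truth <- t(vapply(persons, function(p) all_measures_vec(p$x, b[1], b[2], full_d90),
                    numeric(7L)))
  colnames(truth) <- MEASURES
  list(persons = persons, truth = truth, bounds = b, full_d90 = full_d90)
}

# Internal power engine for one cell.
power_sims <- function(prep, measure, n_participants, n_obs, r_target,
                       alpha, n_sims, mode, pairing, replace, d90_mode,
                       positive_only) {
  truth_vec <- prep$truth[, measure]
  ok <- !is.na(truth_vec)
  persons <- prep$persons[ok]
  truth_vec <- truth_vec[ok]
  P <- length(persons)
  if (P < 3) stop("fewer than 3 persons have a defined '", measure, "'")
  if (!replace && n_participants > P) {
    stop("n_participants = ", n_participants, " exceeds the ", P,
         "-person pool and `replace` is FALSE")
  }
  if (!is.null(n_obs)) {
    short <- vapply(persons, function(p) length(p$x), 0L) < n_obs
    if (any(short)) {
      persons <- persons[!short]
      truth_vec <- truth_vec[!short]
      P <- length(persons)
      if (P < 3) stop("fewer than 3 persons have >= ", n_obs, " reports")
    }
  }
  b <- prep$bounds
  hits <- 0L
  used <- 0L
  for (s in seq_len(n_sims)) {
    ids <- if (replace) sample.int(P, n_participants, replace = TRUE)
           else sample.int(P, n_participants)
    if (pairing == "population") {
      ypop <- simulate_outcome(truth_vec, r_target, mode)
      yv <- ypop[ids]
    } else {
      tv <- truth_vec[ids]
      if (stats::sd(tv) == 0) next
      yv <- simulate_outcome(tv, r_target, mode)
    }
    if (is.null(n_obs)) {
      est <- truth_vec[ids]
    } else {
      vals <- lapply(ids, function(i) {
        p <- persons[[i]]
        p$x[sort.int(sample.int(length(p$x), n_obs))]
      })
      d90s <- if (measure == "pac") {
        if (d90_mode == "resample") {
          d <- pooled_absdiffs(vals)
          if (length(d)) stats::quantile(d, 0.9, names = FALSE, type = 7)
          else prep$full_d90
        } else prep$full_d90
      } else NA_real_
      est <- vapply(vals, function(v) {
        estimate_measure(v, measure, b[1], b[2], d90s)
      }, numeric(1))
    }
    def <- !is.na(est)
    if (sum(def) < 3 || stats::sd(est[def]) == 0 || stats::sd(yv[def]) == 0) next
    pt_ <- pearson_test(est[def], yv[def], alpha)
    sig <- if (positive_only) pt_$significant_positive else pt_$p < alpha
    hits <- hits + sig
    used <- used + 1L
  }
  if (used == 0) stop("no valid simulation in this cell")
  power <- hits / used
  list(power = power, mc_se = sqrt(power * (1 - power) / used), n_sims = used)
}

#' Power for one (participants x observations) design cell
#'
#' Per simulation: a fresh outcome variable is generated against the full
#' person population's true measure values at `r_target`
#' ([simulate_outcome()]); `n_participants` persons are resampled (with
#' replacement by default) and paired with their outcome values; the
#' measure is re-estimated for each sampled participant from a fresh random
#' subsample of `n_obs` of their reports (or taken as the true value when
#' `n_obs = NULL`, the noiseless case); and [pearson_test()] is run between
#' estimates and outcomes. Power is the proportion of simulations with a
#' significant positive correlation.
#'
#' With `pairing = "resampled"` the outcome is instead generated against
#' the resampled participants' own true values — sensible together with
#' `mode = "population"` (with `mode = "exact"` the per-dataset sample
#' correlation is then pinned at `r_target` and power degenerates).
#'
#' @param x An [esm_dataset()] or compatible data frame.
#' @param measure One of [affect_measures()].
#' @param n_participants Participants per simulated dataset.
#' @param n_obs Observations per participant, or `NULL` for noiseless
#'   (full-record) measures.
#' @param r_target Target correlation.
#' @param alpha Significance level.
#' @param n_sims Simulated datasets, default 2500.
#' @param min_full Minimum full-record length for the person pool.
#' @param mode Outcome construction, see [simulate_outcome()].
#' @param pairing `"population"` (default; outcomes drawn against the full
#'   pool each simulation) or `"resampled"`.
#' @param replace Resample participants with replacement (required when
#'   `n_participants` exceeds the pool).
#' @param d90_mode PAC threshold handling, as in [rmse_curve()].
#' @param positive_only Count only significant positive correlations
#'   (default); `FALSE` counts any two-tailed rejection.
#' @return A one-row tibble: `measure`, `n_participants`, `n_obs`,
#'   `r_target`, `alpha`, `power`, `mc_se`, `n_sims`.
#' @export
power_cell <- function(x, measure, n_participants, n_obs, r_target,
                       alpha = 0.05, n_sims = 2500L, min_full = 50L,
                       mode = c("exact", "population"),
                       pairing = c("population", "resampled"),
                       replace = TRUE,
                       d90_mode = c("resample", "fixed"),
                       positive_only = TRUE) {
  measure <- match.arg(measure, MEASURES)
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  d90_mode <- match.arg(d90_mode)
  if (!is.numeric(r_target) || abs(r_target) >= 1) {
    stop("`r_target` must lie strictly inside (-1, 1)")
  }
  prep <- power_prep(x, min_full)
  res <- power_sims(prep, measure, n_participants, n_obs, r_target, alpha,
                    n_sims, mode, pairing, replace, d90_mode, positive_only)
  tibble::tibble(
    measure = measure, n_participants = as.integer(n_participants),
    n_obs = if (is.null(n_obs)) NA_integer_ else as.integer(n_obs),
    r_target = r_target, alpha = alpha,
    power = res$power, mc_se = res$mc_se, n_sims = res$n_sims
  )
}

#' Power over a (participants x observations) design grid
#'
#' Runs [power_cell()] over the Cartesian product of designs, measures and
#' effect sizes. Defaults follow the canonical grids: participants 10, 20,
#' 40, ..., 5120 (doubling), observations 5 to 50 in steps of 5, and weak /
#' medium / strong effects r = 0.10, 0.30, 0.50. Cells that fail (e.g. no
#' person has enough reports) are skipped with a warning and the rest
#' continue.
#'
#' @inheritParams power_cell
#' @param measures Measures to analyse.
#' @param n_participants,n_obs Integer vectors spanning the grid.
#' @param r_targets Effect sizes.
#' @return A tibble of [power_cell()] rows.
#' @export
power_grid <- function(x, measures = MEASURES,
                       n_participants = c(10L, 20L, 40L, 80L, 160L, 320L,
                                          640L, 1280L, 2560L, 5120L),
                       n_obs = seq(5L, 50L, by = 5L),
                       r_targets = c(0.10, 0.30, 0.50),
                       alpha = 0.05, n_sims = 2500L, min_full = 50L,
                       mode = c("exact", "population"),
                       pairing = c("population", "resampled"),
                       replace = TRUE,
                       d90_mode = c("resample", "fixed"),
                       positive_only = TRUE) {
  measures <- match.arg(measures, MEASURES, several.ok = TRUE)
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  d90_mode <- match.arg(d90_mode)
  if (!length(n_participants) || !length(n_obs) || !length(r_targets)) {
    stop("design grids must be non-empty")
  }
  prep <- power_prep(x, min_full)
  rows <- list()
  for (m in measures) {
    for (r in r_targets) {
      for (np in n_participants) {
        for (no in n_obs) {
          res <- tryCatch(
            power_sims(prep, m, np, no, r, alpha, n_sims, mode, pairing,
                       replace, d90_mode, positive_only),
            error = function(e) {
              warning("cell (", m, ", n_participants = ", np,
                      ", n_obs = ", no, ", r = ", r, ") failed: ",
                      conditionMessage(e))
              NULL
            }
          )
          if (is.null(res)) next
          rows[[length(rows) + 1L]] <- tibble::tibble(
            measure = m, n_participants = as.integer(np),
            n_obs = as.integer(no), r_target = r, alpha = alpha,
            power = res$power, mc_se = res$mc_se, n_sims = res$n_sims
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Minimal designs achieving a target power
#'
#' For each number of participants in a power grid, the smallest grid
#' `n_obs` whose power reaches `power_threshold` (`NA` when unreachable).
#' Monte Carlo noise can produce inversions — a larger sample apparently
#' needing more observations — so an isotonic cleanup enforces the minimal
#' `n_obs` to be non-increasing in `n_participants`.
#'
#' @param cells A [power_grid()] result covering a single measure,
#'   `r_target`, and `alpha`.
#' @param power_threshold Target power, default 0.80.
#' @return A tibble with columns `measure`, `r_target`, `alpha`,
#'   `power_threshold`, `n_participants`, `min_n_obs`.
#' @export
minimal_designs <- function(cells, power_threshold = 0.80) {
  if (!is.data.frame(cells) || nrow(cells) == 0) {
    stop("`cells` must be a non-empty power-grid table")
  }
  for (col in c("measure", "r_target", "alpha")) {
    if (length(unique(cells[[col]])) > 1) {
      stop("`cells` must come from a single (measure, r_target, alpha) grid; ",
           "got multiple values of '", col, "'")
    }
  }
  parts <- sort(unique(cells$n_participants))
  minobs <- vapply(parts, function(np) {
    sub <- cells[cells$n_participants == np, ]
    hit <- sub$n_obs[sub$power >= power_threshold]
    if (length(hit)) min(hit) else Inf
  }, numeric(1))
  # isotonic cleanup: non-increasing in n_participants
  for (i in seq_along(minobs)[-1]) {
    minobs[i] <- min(minobs[i], minobs[i - 1])
  }
  tibble::tibble(
    measure = cells$measure[1], r_target = cells$r_target[1],
    alpha = cells$alpha[1], power_threshold = power_threshold,
    n_participants = as.integer(parts),
    min_n_obs = as.integer(replace(minobs, !is.finite(minobs), NA))
  )
}

#' Benchmark effect sizes: measure-covariate correlations
#'
#' Pairwise-complete Pearson correlations between each affect dynamics
#' measure (true, full-record values) and each person-level covariate —
#' the kind of table used to anchor a plausible effect size before a power
#' analysis.
#'
#' @param truths Tibble from [true_measures()] (must contain `person_id`).
#' @param covariates Data frame with `person_id` plus one column per
#'   covariate.
#' @return A tibble with columns `measure`, `covariate`, `r`, `n`; pairs
#'   with fewer than 3 complete observations get `r = NA`.
#' @export
effect_benchmarks <- function(truths, covariates) {
  if (!"person_id" %in% names(truths) || !"person_id" %in% names(covariates)) {
    stop("both tables need a 'person_id' column")
  }
  mcols <- intersect(MEASURES, names(truths))
  ccols <- setdiff(names(covariates), "person_id")
  if (!length(mcols) || !length(ccols)) {
    stop("nothing to correlate: need measure and covariate columns")
  }
  merged <- merge(as.data.frame(truths)[c("person_id", mcols)],
                  as.data.frame(covariates)[c("person_id", ccols)],
                  by = "person_id")
  rows <- list()
  for (m in mcols) {
    for (cv in ccols) {
      a <- merged[[m]]
      bb <- merged[[cv]]
      keep <- !is.na(a) & !is.na(bb)
      n <- sum(keep)
      r <- if (n >= 3 && stats::sd(a[keep]) > 0 && stats::sd(bb[keep]) > 0) {
        stats::cor(a[keep], bb[keep])
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        measure = m, covariate = cv, r = r, n = n
      )
    }
  }
  do.call(rbind, rows)
}
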