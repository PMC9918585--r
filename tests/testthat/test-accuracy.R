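# Subsample-vs-truth RMSE engine.

test_that("true_measures applies the full-record cut", {
  ds <- make_dataset(list(
    make_series(random_series(49)),
    make_series(random_series(50), person = "p2")
  ))
  expect_message(tm <- true_measures(ds, min_reports = 50), "excluded")
  expect_equal(tm$person_id, "p2")
  tm_all <- true_measures(ds, min_reports = 1)
  expect_equal(sort(tm_all$person_id), c("p1", "p2"))
  expect_true(all(tm_all$person_id %in% unique(ds$person_id)))
})

test_that("person_rmse reduces to the absolute error for single estimates", {
  s <- make_series(random_series(20))
  truth <- mean_affect(s$affect)
  # estimator that always returns truth: full-length subsample
  expect_equal(person_rmse(s, "mean", n = 20, truth = truth,
                           replicates = 3), 0)
  # single replicate with a known offset: est - truth = 2
  expect_equal(person_rmse(s, "mean", n = 20, truth = truth - 2,
                           replicates = 1), 2)
  # deterministic strategies return |est - truth|
  est_close <- mean_affect(close_subsample(s, 5)$affect)
  expect_equal(person_rmse(s, "mean", n = 5, truth = est_close + 1.5,
                           strategy = "close"), 1.5)
})

test_that("person_rmse is the root mean square over replicate errors", {
  # two-point series forces estimates {0, 10}; truth 5 gives errors {-5, +5}
  s <- make_series(c(0, 10))
  r <- person_rmse(s, "mean", n = 1, truth = 5, replicates = 400)
  expect_equal(r, 5)
  # errors {+1, -1} around truth -> RMSE 1 regardless of mix
  r2 <- person_rmse(make_series(c(4, 6)), "mean", n = 1, truth = 5,
                    replicates = 400)
  expect_equal(r2, 1)
})

test_that("person_rmse with exhaustive replicates matches a brute-force oracle", {
  withr::local_seed(71)
  x <- random_series(8)
  s <- make_series(x)
  truth <- mean_affect(x)
  combos <- utils::combn(8, 3)
  brute <- sqrt(mean(apply(combos, 2, function(i) (mean(x[i]) - truth)^2)))
  # many replicates approximate the uniform-over-subsets enumeration
  est <- person_rmse(s, "mean", n = 3, truth = truth, replicates = 6000)
  expect_equal(est, brute, tolerance = 0.05)
})

test_that("bootstrap CI is degenerate for constant inputs and nests across levels", {
  ci <- bootstrap_ci(rep(4.2, 10))
  expect_equal(unname(ci), c(4.2, 4.2))
  withr::local_seed(81)
  v <- runif(40)
  withr::local_seed(82)
  ci95 <- bootstrap_ci(v, reps = 1000, level = 0.95)
  withr::local_seed(82)
  ci99 <- bootstrap_ci(v, reps = 1000, level = 0.99)
  expect_lte(ci99[1], ci95[1])
  expect_gte(ci99[2], ci95[2])
  expect_gte(mean(v), ci95[1])
  expect_lte(mean(v), ci95[2])
  expect_error(bootstrap_ci(3), "at least 2")
})

test_that("mean RMSE is the average of per-person RMSEs on a toy set", {
  withr::local_seed(91)
  series <- lapply(1:3, function(i) {
    make_series(random_series(60), person = paste0("p", i))
  })
  ds <- make_dataset(series)
  d90 <- compute_d90(ds)$d90
  withr::local_seed(92)
  cu <- rmse_curve(ds, measures = "mean", n_obs = 5, replicates = 200,
                   min_full = 50, ci = FALSE, d90_mode = "fixed")
  withr::local_seed(92)
  per <- vapply(series, function(s) {
    person_rmse(s, "mean", n = 5, truth = mean_affect(s$affect),
                replicates = 200, d90 = d90)
  }, numeric(1))
  # same replicate budget and seed stream differ in draw order, so compare
  # statistically rather than bitwise
  expect_equal(cu$mean_rmse, mean(per), tolerance = 0.1)
  expect_equal(cu$n_persons, 3L)
})

test_that("exhaustive random subsample at full length recovers truth exactly", {
  withr::local_seed(101)
  ds <- make_dataset(list(
    make_series(random_series(50)),
    make_series(random_series(50), person = "p2")
  ))
  cu <- rmse_curve(ds, measures = c("mean", "sd", "rmssd", "ar1"),
                   n_obs = 50, replicates = 5, ci = FALSE,
                   d90_mode = "fixed")
  expect_true(all(cu$mean_rmse < 1e-12))
})

test_that("identical persons give a zero-width bootstrap CI", {
  withr::local_seed(111)
  x <- random_series(50)
  ds <- make_dataset(list(make_series(x), make_series(x, person = "p2")))
  cu <- rmse_curve(ds, measures = "mean", n_obs = 50, replicates = 3,
                   ci = TRUE, ci_reps = 100, d90_mode = "fixed")
  expect_equal(cu$ci_lower, cu$ci_upper)
  expect_lte(cu$ci_lower, cu$mean_rmse)
  expect_gte(cu$ci_upper, cu$mean_rmse)
})

test_that("benchmark thresholds scale the between-person SD", {
  truths <- tibble::tibble(person_id = c("a", "b"), mean = c(0, 10),
                           sd = c(3, 3))
  bt <- benchmark_thresholds(truths)
  m <- bt[bt$measure == "mean", ]
  expect_equal(m$between_person_sd, rep(5, 3)) # population divisor
  expect_equal(m$threshold, c(5, 2.5, 1.5))
  expect_true(all(diff(m$threshold) < 0))
  s <- bt[bt$measure == "sd", ]
  expect_equal(s$threshold, c(0, 0, 0)) # identical truths
})

test_that("min_n_for_accuracy finds the first crossing", {
  curves <- tibble::tibble(measure = "mean", strategy = "random",
                           n_obs = c(3L, 4L, 5L),
                           mean_rmse = c(5, 0.9, 0.5))
  expect_equal(min_n_for_accuracy(curves, 1.0), 4L)
  expect_true(is.na(min_n_for_accuracy(curves, 0.1)))
  expect_equal(min_n_for_accuracy(curves, 10), 3L)
  expect_error(min_n_for_accuracy(curves[0, ], 1), "non-empty")
  two <- rbind(curves, within(curves, measure <- "sd"))
  expect_error(min_n_for_accuracy(two, 1), "single measure")
})

test_that("time-window curves debias and respect eligibility", {
  withr::local_seed(121)
  # persons with a strong morning/evening level difference
  mk <- function(id, shift) {
    times <- sort(c((0:39) * 86400 + 9.5 * 3600 + runif(40, 0, 3600),
                    (0:39) * 86400 + 18 * 3600 + runif(40, 0, 3600)))
    lt <- as.POSIXlt(as.POSIXct("2023-01-02", tz = "UTC") + times, tz = "UTC")
    level <- ifelse(lt$hour < 12, 40, 60) + shift
    make_series(round(level + rnorm(80, 0, 5)), times = times,
                person = id, start = "2023-01-02 00:00:00")
  }
  ds <- make_dataset(lapply(1:6, function(i) mk(paste0("p", i), 2 * i)))
  cu_raw <- rmse_curve(ds, measures = "mean", strategy = "time_window",
                       window = "morning", n_obs = 10, replicates = 150,
                       min_full = 50, min_window = 30, ci = FALSE,
                       debias_estimates = FALSE)
  cu_deb <- rmse_curve(ds, measures = "mean", strategy = "time_window",
                       window = "morning", n_obs = 10, replicates = 150,
                       min_full = 50, min_window = 30, ci = FALSE)
  # morning-only estimates are ~10 points low; debiasing must help a lot
  expect_gt(cu_raw$mean_rmse, 5)
  expect_lt(cu_deb$mean_rmse, cu_raw$mean_rmse / 2)
  expect_equal(cu_deb$n_persons, 6L)
  expect_equal(cu_deb$window, "morning")
})
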