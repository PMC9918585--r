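# Sampling strategies: selection correctness, filters, eligibility, debias.

test_that("random subsampling returns ordered subsets and is seed-reproducible", {
  s <- make_series(random_series(10))
  expect_equal(random_subsample(s, 10)$affect, s$affect)
  withr::local_seed(5)
  a <- random_subsample(s, 3)
  withr::local_seed(5)
  b <- random_subsample(s, 3)
  expect_equal(a, b)
  expect_equal(nrow(a), 3L)
  expect_true(all(diff(as.numeric(a$timestamp)) > 0))
  expect_true(all(a$affect %in% s$affect))
  expect_error(random_subsample(s, 11), "insufficient data")
})

test_that("close sampling picks the earliest shortest qualifying run", {
  # hourly reports over 3 days: every 5-run spans 4 h, earliest returned
  s <- make_series(random_series(72), times = 3600 * (0:71))
  cs <- close_subsample(s, 5)
  expect_equal(as.numeric(cs$timestamp), as.numeric(s$timestamp[1:5]))

  # 30 h gap mid-series: the window must come from the denser side
  times <- c(0, 1, 2, 3, 4, 4 + 30, 4 + 31, 4 + 32) * 3600
  s2 <- make_series(random_series(8), times = times)
  cs2 <- close_subsample(s2, 5)
  expect_equal(as.numeric(cs2$timestamp) - as.numeric(s2$timestamp[1]),
               times[1:5])
  expect_equal(brute_close(times, 5)$idx, 1:5)

  # n = 2 with gaps (1 h, 26 h, 2 h): the 1 h pair wins
  times3 <- c(0, 1, 27, 29) * 3600
  cs3 <- close_subsample(make_series(c(1, 2, 3, 4), times = times3), 2)
  expect_equal(cs3$affect, c(1, 2))

  # no qualifying run
  times4 <- c(0, 30, 60, 90) * 3600
  expect_error(close_subsample(make_series(1:4, times = times4), 2),
               "no run")
})

test_that("distant sampling hits grid-aligned reports and endpoints", {
  # reports exactly on the grid are selected
  s <- make_series(random_series(5), times = c(0, 6, 12, 18, 24) * 3600)
  expect_equal(distant_subsample(s, 5), s, ignore_attr = TRUE)
  expect_equal(distant_subsample(s, 3)$affect, s$affect[c(1, 3, 5)])
  # n = 2 always selects the first and last report
  irr <- make_series(random_series(7), times = c(0, 5, 7, 20, 31, 50, 61) * 3600)
  expect_equal(distant_subsample(irr, 2)$affect, irr$affect[c(1, 7)])
})

test_that("close and distant selections match exhaustive search on random instances", {
  withr::local_seed(61)
  for (i in 1:120) {
    m <- sample(4:12, 1)
    t <- sort(sample.int(90, m)) * 3600
    n <- sample(2:(m - 1), 1)
    s <- make_series(random_series(m), times = t)

    bd <- brute_distant(t, n)
    got <- distant_idx(t, n)
    grid <- t[1] + (seq_len(n) - 1) * (t[m] - t[1]) / (n - 1)
    expect_equal(sum(abs(t[got] - grid)), bd$cost, tolerance = 1e-9)
    expect_true(all(diff(got) > 0))

    bc <- brute_close(t, n)
    gc <- tryCatch(close_idx(t, n), error = function(e) NULL)
    if (is.null(bc$idx)) {
      expect_null(gc)
    } else {
      expect_equal(t[gc[n]] - t[gc[1]], bc$span)
      expect_equal(gc, bc$idx) # both tie-break to the earliest run
    }
  }
})

test_that("time windows partition the day with half-open boundaries", {
  times <- c(3, 6, 11.99, 12, 15.5, 16, 19.99, 20, 23.5) * 3600
  s <- make_series(seq_along(times) * 10, times = times,
                   start = "2023-01-02 00:00:00")
  m <- filter_time_window(s, "morning")
  a <- filter_time_window(s, "afternoon")
  e <- filter_time_window(s, "evening")
  n <- filter_time_window(s, "night")
  expect_equal(m$affect, c(20, 30))   # 06:00 in, 12:00 out
  expect_equal(a$affect, c(40, 50))   # 12:00 in
  expect_equal(e$affect, c(60, 70))
  expect_equal(n$affect, c(10, 80, 90)) # 03:00 wraps into night
  expect_equal(sort(c(m$affect, a$affect, e$affect, n$affect)), s$affect)
  expect_error(filter_time_window(s, "dawn"), "should be one of")
})

test_that("day filters partition reports into weekday and weekend", {
  # start 2023-01-02 is a Monday; days 0..6 cover a full week
  times <- (0:6) * 86400 + 12 * 3600
  s <- make_series(10 * (1:7), times = times, start = "2023-01-02 00:00:00")
  wd <- filter_days(s, "weekday")
  we <- filter_days(s, "weekend")
  expect_equal(wd$affect, 10 * (1:5))
  expect_equal(we$affect, 10 * (6:7))
  expect_equal(sort(c(wd$affect, we$affect)), s$affect)
  # empty results are allowed
  expect_equal(nrow(filter_days(s[6:7, ], "weekday")), 0L)
})

test_that("eligibility keeps exactly the persons clearing the minimum", {
  mk <- function(id, n_morning, n_evening) {
    times <- c(if (n_morning) (seq_len(n_morning) - 1) * 86400 + 9 * 3600,
               if (n_evening) (seq_len(n_evening) - 1) * 86400 + 17 * 3600)
    make_series(random_series(n_morning + n_evening), times = sort(times),
                person = id, start = "2023-01-02 00:00:00")
  }
  ds <- make_dataset(list(mk("p29", 29, 10), mk("p30", 30, 10)))
  kept <- eligible_persons(ds, window = "morning", min_reports = 30)
  expect_equal(unique(kept$person_id), "p30")
  expect_equal(nrow(kept), 40L) # full records of the eligible person
  keptf <- eligible_persons(ds, window = "morning", min_reports = 30,
                            filtered = TRUE)
  expect_equal(nrow(keptf), 30L) # only the filter-surviving reports
  # min_reports = 0 is the identity on persons
  all_kept <- eligible_persons(ds, window = "morning", min_reports = 0)
  expect_equal(sort(unique(all_kept$person_id)), c("p29", "p30"))
})

test_that("debias is an additive shift with the zero-bias fixed point", {
  est <- c(a = 40, b = 55, c = 70)
  expect_equal(debias(est, 55, 55), est)
  shifted <- debias(est, 55, 58)
  expect_equal(shifted - est, rep(3, 3), ignore_attr = TRUE)
  expect_equal(order(shifted), order(est))
  expect_equal(mean(debias(est, mean(est), 60)), 60)
  expect_error(debias(est, NA, 60), "same eligible-person set")
})

test_that("sampling plans validate their strategy-parameter pairing", {
  p <- sampling_plan("time_window", 10, window = "morning")
  expect_equal(p$window, "morning")
  expect_error(sampling_plan("random", 10, window = "morning"), "only meaningful")
  expect_error(sampling_plan("time_window", 10), "must be set")
  expect_error(sampling_plan("day_filter", 10), "must be set")
  expect_error(sampling_plan("random", 2), ">= 3")
  # deterministic strategies force a single replicate
  expect_equal(sampling_plan("close", 10, replicates = 500)$replicates, 1L)
  expect_equal(sampling_plan("distant", 10, replicates = 500)$replicates, 1L)
})
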