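# Independent naive-loop oracles and brute-force searches used to validate
# the package's vectorized implementations. Deliberately written with
# explicit loops and no shared code with R/.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / length(x))
}

oracle_rel_sd <- function(x, lo = 0, hi = 100) {
  m <- oracle_mean(x)
  oracle_sd(x) / sqrt((m - lo) * (hi - m))
}

oracle_rmssd <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) s <- s + (x[i] - x[i + 1])^2
  sqrt(s / (n - 1))
}

oracle_tkeo <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 2:(n - 1)) s <- s + x[i]^2 - x[i - 1] * x[i + 1]
  s / (n - 2)
}

oracle_pac <- function(x, d90) {
  n <- length(x)
  hits <- 0
  for (i in 1:(n - 1)) {
    if (abs(x[i + 1] - x[i]) > d90) hits <- hits + 1
  }
  hits / (n - 1)
}

oracle_ar1 <- function(x) {
  n <- length(x)
  m <- oracle_mean(x)
  num <- 0
  den <- 0
  for (i in 1:n) den <- den + (x[i] - m)^2
  for (i in 1:(n - 1)) num <- num + (x[i] - m) * (x[i + 1] - m)
  num / den
}

# Linear-interpolation percentile (the type-7 definition), written out.
oracle_percentile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Brute-force close sampling: scan every contiguous run of length n.
brute_close <- function(t, n, max_gap_h = 24) {
  m <- length(t)
  best <- NULL
  best_span <- Inf
  for (i in seq_len(m - n + 1)) {
    idx <- i:(i + n - 1)
    ok <- TRUE
    if (n > 1) {
      for (k in 1:(n - 1)) {
        if (t[idx[k + 1]] - t[idx[k]] > max_gap_h * 3600) ok <- FALSE
      }
    }
    if (!ok) next
    span <- t[idx[n]] - t[idx[1]]
    if (span < best_span) {
      best_span <- span
      best <- idx
    }
  }
  list(idx = best, span = best_span)
}

# Brute-force distant sampling: exhaustive search over all order-preserving
# index n-tuples.
brute_distant <- function(t, n) {
  m <- length(t)
  grid <- t[1] + (seq_len(n) - 1) * (t[m] - t[1]) / (n - 1)
  combos <- utils::combn(m, n)
  best_cost <- Inf
  best <- NULL
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    cost <- sum(abs(t[idx] - grid))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- idx
    }
  }
  list(idx = best, cost = best_cost)
}

# Random test series and single-person record frames.
random_series <- function(n, lo = 0, hi = 100) {
  round(runif(n, lo, hi))
}

make_series <- function(values, times = NULL, person = "p1",
                        start = "2023-01-02 09:00:00") {
  n <- length(values)
  t0 <- as.POSIXct(start, tz = "UTC")
  ts <- if (is.null(times)) t0 + (seq_len(n) - 1) * 3600 else t0 + times
  data.frame(person_id = person, timestamp = ts, affect = values)
}

make_dataset <- function(series_list, bounds = c(0, 100)) {
  esm_dataset(do.call(rbind, series_list), bounds = bounds)
}

# Fisher-z closed-form power approximation for the two-tailed Pearson test
# counting only positive rejections.
fisher_z_power <- function(r, n, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  pnorm(atanh(r) * sqrt(n - 3) - z)
}
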