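# Statistical ERP measures: window scans, fractional latency geometry,
# localizer windows, table assembly.

gauss_trace <- function(times, mu, sigma, amp = 1) {
  amp * exp(-(times - mu)^2 / (2 * sigma^2))
}

test_that("peak, mean and latency measures match exhaustive window scans", {
  set.seed(11)
  times <- seq(-200, 600, by = 1000 / 256)
  for (rep in 1:40) {
    trace <- rnorm(length(times))
    pol <- sample(c(-1, 1), 1)
    comp <- if (pol < 0) "N170" else "P2"
    a <- sort(runif(2, -150, 550))
    w <- component_window(comp, "occipital", a[1], a[2] + 20, polarity = pol)
    idx <- seq(which.min(abs(times - w$t_start)),
               which.min(abs(times - w$t_end)))
    aligned <- pol * trace[idx]
    expect_identical(peak_amplitude(trace, times, w),
                     pol * max(aligned))
    expect_identical(mean_amplitude(trace, times, w), mean(trace[idx]))
    expect_identical(peak_latency(trace, times, w),
                     times[idx][which.max(aligned)])
  }
})

test_that("fractional latency of a Gaussian bump hits the closed-form half-maximum", {
  times <- seq(-200, 600, by = 1000 / 256)
  mu <- 110; sigma <- 22
  trace <- gauss_trace(times, mu, sigma, amp = 6)
  w <- component_window("P1", "occipital", mu - 3 * sigma, mu + 3 * sigma)
  expected <- mu - sigma * sqrt(2 * log(2))
  expect_equal(fractional_peak_latency(trace, times, w), expected,
               tolerance = (1000 / 256) / abs(expected))
})

test_that("fractional latency boundary behaviour follows the contract", {
  times <- seq(0, 100, by = 10)
  w <- component_window("P1", "occipital", 10, 90)
  # constant trace never falls below its own half-peak -> window start
  expect_identical(fractional_peak_latency(rep(2, length(times)), times, w), 10)
  # step from 0 to A between two samples -> interpolated half-rise point
  step <- c(0, 0, 0, 0, 0, 4, 4, 4, 4, 4, 4)   # rises between 40 and 50 ms
  expect_equal(fractional_peak_latency(step, times, w), 45)
  # ties in the peak resolve to the earliest sample
  expect_identical(peak_latency(step, times, w), 50)
})

test_that("a monotone rising trace peaks at the window end", {
  times <- seq(0, 400, by = 4)
  trace <- times / 100
  w <- component_window("P3", "central", 100, 330)
  expect_identical(peak_latency(trace, times, w), 328)
})

test_that("latency measures shift with the trace (and window) by whole samples", {
  times <- seq(-200, 600, by = 1000 / 256)
  dt <- 1000 / 256
  trace <- gauss_trace(times, 140, 30, amp = 4) +
    0.3 * sin(times / 40)
  w <- component_window("P1", "occipital", 60, 220)
  k <- 7
  shifted <- c(rep(trace[1], k), trace[seq_len(length(trace) - k)])
  w2 <- component_window("P1", "occipital", 60 + k * dt, 220 + k * dt)
  expect_equal(peak_latency(shifted, times, w2),
               peak_latency(trace, times, w) + k * dt, tolerance = 1e-9)
  expect_equal(fractional_peak_latency(shifted, times, w2),
               fractional_peak_latency(trace, times, w) + k * dt,
               tolerance = 1e-6)
})

test_that("measure invariants hold on random traces", {
  set.seed(23)
  times <- seq(-200, 600, by = 1000 / 256)
  for (rep in 1:25) {
    trace <- cumsum(rnorm(length(times), sd = 0.3))
    for (comp in c("P1", "N170", "P3")) {
      w <- default_component_windows()[[comp]]
      pa <- peak_amplitude(trace, times, w)
      fl <- fractional_peak_latency(trace, times, w)
      pl <- peak_latency(trace, times, w)
      # the aligned peak dominates the aligned mean whenever the window
      # holds any value of the component's polarity (aligned peak >= 0)
      ma <- mean_amplitude(trace, times, w)
      if (w$polarity * pa >= 0 && w$polarity * ma >= 0) {
        expect_lte(w$polarity * ma, w$polarity * pa)
      }
      # latencies agree up to the half-sample quantisation of the window
      # endpoints (the no-crossing fallback returns the nominal start)
      expect_lte(fl, pl + 1000 / 256 / 2)
      expect_gte(fl, w$t_start - 1000 / 256 / 2)
      expect_lte(pl, w$t_end + 1000 / 256 / 2)
    }
  }
})

test_that("windows outside the trace raise errors", {
  times <- seq(0, 100, by = 10)
  w <- component_window("P3", "central", 300, 500)
  expect_error(peak_amplitude(rnorm(11), times, w), "outside")
})

test_that("collapsed localizer windows bracket the canonical components", {
  times <- seq(-200, 700, by = 1000 / 256)
  occ <- gauss_trace(times, 100, 15, 4) - gauss_trace(times, 170, 18, 4) +
    gauss_trace(times, 235, 25, 3)
  cen <- gauss_trace(times, 340, 45, 4) - gauss_trace(times, 150, 30, 1.5)
  ga <- cbind(occipital = occ, parietal = 0 * occ, central = cen,
              frontal = 0 * occ)
  win <- collapsed_localizer_windows(ga, times)
  expect_true(win$P1$t_start < 100 && 100 < win$P1$t_end)
  expect_true(win$N170$t_start < 170 && 170 < win$N170$t_end)
  expect_true(win$P2$t_start < 235 && 235 < win$P2$t_end)
  expect_true(win$P3$t_start < 340 && 340 < win$P3$t_end)

  # sign flip leaves the recovered boundaries identical
  win_flipped <- collapsed_localizer_windows(-ga, times)
  for (nm in names(win)) {
    expect_equal(win_flipped[[nm]]$t_start, win[[nm]]$t_start)
    expect_equal(win_flipped[[nm]]$t_end, win[[nm]]$t_end)
  }

  # an all-positive grand average has no crossings: fall back with a warning
  ga_pos <- ga; ga_pos[] <- abs(ga) + 1
  msgs <- capture_warnings(win_fb <- collapsed_localizer_windows(ga_pos, times))
  expect_length(msgs, 4L)
  expect_true(all(grepl("default", msgs)))
  expect_equal(win_fb$P1$t_start, 50)
  expect_equal(win_fb$P3$t_end, 500)
})

test_that("the feature table has 16 documented columns with correct values", {
  prof <- quiet_profiles(white = 0, pink = 0)
  # zero out residual per-trial variability for exact amplitude recovery
  for (g in names(prof)) {
    for (s in c("components_frequent", "components_rare")) {
      prof[[g]][[s]] <- lapply(prof[[g]][[s]], function(cs) {
        cs$latency_sd_between <- 0
        cs$latency_jitter_within <- 0
        cs$amplitude_sd <- 0
        cs
      })
    }
  }
  cfg <- simulation_config(n_young = 1, n_older = 0,
                           trials_per_participant = 20, n_rare = 5)
  es <- simulate_participant(prof$young, cfg, 6)
  tab <- build_erp_features(es)
  expect_identical(ncol(tab$values), 16L)
  expect_identical(colnames(tab$values)[1], "P1_peak_amplitude")
  rare <- tab$labels == 1L
  expect_equal(unique(tab$values[rare, "P3_peak_amplitude"]), 5,
               tolerance = 1e-3)
  expect_equal(unique(tab$values[!rare, "P3_peak_amplitude"]), 1.5,
               tolerance = 1e-3)
  # N170 amplitude is reported with its negative sign
  expect_lt(max(tab$values[rare, "N170_peak_amplitude"]), 0)
})

test_that("the configured older-group P3 delay is recovered from fractional latencies", {
  prof <- quiet_profiles(white = 0.2, pink = 0.4)
  # isolate the measurement: no participant-level offset, small jitter
  for (g in names(prof)) {
    for (s in c("components_frequent", "components_rare")) {
      prof[[g]][[s]] <- lapply(prof[[g]][[s]], function(cs) {
        cs$latency_sd_between <- 0
        cs$latency_jitter_within <- 5
        cs$amplitude_sd <- 0.2
        cs
      })
    }
  }
  cfg <- simulation_config(n_young = 1, n_older = 1,
                           trials_per_participant = 40, n_rare = 40 - 1)
  # nearly all trials rare so the P3 is present in the measured trials
  young <- simulate_participant(prof$young, cfg, 31)
  older <- simulate_participant(prof$older, cfg, 32)
  w <- component_window("P3", "central", 250, 550)
  fl <- function(es) {
    rare <- which(es$labels == 1L)
    mean(vapply(rare, function(tr) {
      fractional_peak_latency(es$voltages[tr, , "central"], es$times, w)
    }, numeric(1)))
  }
  gap <- fl(older) - fl(young)
  expect_equal(gap, 60, tolerance = 2 * (1000 / 256) / 60)
})

test_that("ERP tables survive a text round-trip", {
  cfg <- simulation_config(n_young = 1, n_older = 0, fs = 128,
                           epoch_len_samples = 96,
                           trials_per_participant = 15, n_rare = 3)
  es <- simulate_participant(default_group_profiles()$young, cfg, 9)
  tab <- build_erp_features(es)
  prefix <- file.path(withr::local_tempdir(), "erp")
  write_erp_features(tab, prefix)
  back <- read_erp_features(prefix)
  expect_equal(back$values, tab$values, tolerance = 1e-9)
  expect_identical(back$labels, tab$labels)
})
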