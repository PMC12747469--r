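# analytic gain of the configured IIR at frequency f (Hz)
.iir_gain <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

# steady-state amplitude of a sinusoid at f in a filtered trace
.sine_amp <- function(y, f, fs) {
  n <- length(y); keep <- (n %/% 2):n
  t <- (keep - 1) / fs
  co <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  sqrt(sum(stats::lm.fit(co, y[keep])$coefficients^2))
}

test_that("band-pass gain matches the analytic frequency response", {
  cfg <- ripple_config()
  det <- ripple_detector(cfg)
  expect_equal(filter_ripple_band(det, rep(0, 100)), rep(0, 100))

  fs <- 1500; t <- (0:(6 * fs - 1)) / fs
  det <- ripple_detector(cfg)
  y200 <- filter_ripple_band(det, sin(2 * pi * 200 * t))
  expect_equal(.sine_amp(y200, 200, fs),
               .iir_gain(cfg$bp_b, cfg$bp_a, 200, fs), tolerance = 0.02)
  det <- ripple_detector(cfg)
  y10 <- filter_ripple_band(det, sin(2 * pi * 10 * t))
  expect_lt(.sine_amp(y10, 10, fs), 0.02)      # out of band: strongly attenuated
  expect_error(ripple_config(band = c(150, 900)), "configuration error")
})

test_that("streaming chunked filtering equals a whole-trace causal pass", {
  set.seed(61)
  fs <- 1500
  x <- rnorm(3 * fs)
  cfg <- ripple_config(baseline_window_s = 1)
  whole <- ripple_detector(cfg)
  ref <- process_lfp(whole, seq_along(x), x)
  for (rep in 1:3) {
    chunked <- ripple_detector(cfg)
    cuts <- sort(sample(length(x) - 1, 20))
    idx <- split(seq_along(x), findInterval(seq_along(x), cuts + 1))
    got_f <- c(); got_z <- c()
    for (i in idx) {
      r <- process_lfp(chunked, i, x[i])
      got_f <- c(got_f, r$filtered); got_z <- c(got_z, r$z)
    }
    expect_identical(got_f, ref$filtered)     # sample-exact, any chunking
    expect_identical(got_z, ref$z)
  }
})

test_that("power envelope settles near half the squared in-band amplitude", {
  fs <- 1500; t <- (0:(6 * fs - 1)) / fs
  cfg <- ripple_config()
  det <- ripple_detector(cfg)
  A <- 3
  xf <- filter_ripple_band(det, A * sin(2 * pi * 200 * t))
  env <- power_estimate(det, xf)
  g <- .iir_gain(cfg$bp_b, cfg$bp_a, 200, fs)
  expect_equal(mean(tail(env, fs)), (A * g)^2 / 2, tolerance = 0.05)
  # squaring makes the envelope invariant to a sign flip
  det2 <- ripple_detector(cfg)
  xf2 <- filter_ripple_band(det2, -A * sin(2 * pi * 200 * t))
  expect_equal(power_estimate(det2, xf2), env, tolerance = 1e-12)
  det3 <- ripple_detector(cfg)
  expect_equal(power_estimate(det3, filter_ripple_band(det3, rep(0, 50))),
               rep(0, 50))
})

test_that("z-scoring uses the frozen baseline mean and sd", {
  set.seed(13)
  fs <- 100
  cfg <- ripple_config(fs_lfp = fs, band = c(20, 40), baseline_window_s = 2)
  det <- ripple_detector(cfg)
  base <- abs(rnorm(2 * fs, 10, 2))
  invisible(ripple_zscore(det, base))
  mu <- mean(base); s <- sd(base)
  expect_equal(ripple_zscore(det, mu), 0, tolerance = 1e-12)
  expect_equal(ripple_zscore(det, mu + 3 * s), 3, tolerance = 1e-9)
  # running z equals an offline z-score built from the same baseline segment
  post <- abs(rnorm(300, 10, 2))
  det2 <- ripple_detector(cfg)
  got <- c(ripple_zscore(det2, base), ripple_zscore(det2, post))
  offline <- (c(base, post) - mu) / s
  offline[seq_along(base)] <- NA
  expect_equal(got, offline, tolerance = 1e-9)
  # degenerate baseline
  det3 <- ripple_detector(cfg)
  expect_error(ripple_zscore(det3, rep(1, 2 * fs)), "degenerate")
})

test_that("the onset/offset state machine traces events as specified", {
  cfg <- ripple_config(z_threshold = 3, z_end_threshold = 1)
  det <- ripple_detector(cfg)
  ev <- detect_events(det, c(0, 0, 4, 5, 4, 0), 0:5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_timestamp, 2)
  expect_equal(ev$end_timestamp, 4)
  expect_equal(ev$peak_z, 5)
  expect_gte(ev$peak_z, cfg$z_threshold)

  det <- ripple_detector(cfg)
  expect_equal(nrow(detect_events(det, c(0, 1, 2, 2.9, 0), 1:5)), 0)

  # events split across chunks close correctly
  det <- ripple_detector(cfg)
  e1 <- detect_events(det, c(0, 4, 5), 1:3)
  expect_equal(nrow(e1), 0)                    # still open
  e2 <- detect_events(det, c(4, 0), 4:5)
  expect_equal(e2$start_timestamp, 2)
  expect_equal(e2$end_timestamp, 4)
})

test_that("injected bursts are recalled and clean noise yields no events", {
  sim <- sim_config(duration_s = 40, fs_lfp = 1500, seed = 5,
                    ripple_times_s = seq(12, 36, by = 5))
  l <- simulate_lfp(sim)
  cfg <- burst_fixture_ripple_config()
  r <- detect_ripples(l$lfp$timestamp, l$lfp$value, cfg)
  # 100% recall of bursts whose offline peak z clears the threshold by >= 1
  expect_true(all(vapply(l$truth$start_s, function(t0) {
    i <- which(l$lfp$timestamp / sim$ticks_per_s >= t0 &
               l$lfp$timestamp / sim$ticks_per_s <= t0 + 0.1)
    max(r$z[i], na.rm = TRUE) >= cfg$z_threshold + 1
  }, logical(1))))
  on_err <- vapply(l$truth$start_s, function(t0) {
    d <- r$events$start_timestamp / sim$ticks_per_s - t0
    d <- d[abs(d) < 0.1]
    if (length(d)) min(abs(d)) else Inf
  }, numeric(1))
  expect_equal(nrow(r$events), length(sim$ripple_times_s))
  expect_true(all(on_err <= 0.020))

  # matched trace without injections: no detections at this operating point
  sim0 <- sim_config(duration_s = 40, fs_lfp = 1500, seed = 5)
  l0 <- simulate_lfp(sim0)
  r0 <- detect_ripples(l0$lfp$timestamp, l0$lfp$value, cfg)
  expect_equal(nrow(r0$events), 0)

  # conditional invariant: any noise trace whose offline max z stays below a
  # threshold yields zero events at that threshold
  thr <- max(r0$z, na.rm = TRUE) + 0.5
  cfg2 <- ripple_config(z_threshold = thr, z_end_threshold = 0)
  r2 <- detect_ripples(l0$lfp$timestamp, l0$lfp$value, cfg2)
  expect_equal(nrow(r2$events), 0)
})
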