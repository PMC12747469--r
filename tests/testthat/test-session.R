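# one small session shared by the tests below
sess <- local({
  sim <- sim_config(duration_s = 90, task1_end_s = 45, seed = 7,
                    ripple_times_s = c(50, 60, 70))
  dir <- tempfile("session")
  paths <- simulate_session(sim, dir)
  cfg <- session_config(
    geometry = sim$geometry, spikes = paths$spikes, lfp = paths$lfp,
    position = paths$position, output = file.path(dir, "records.bin"),
    task1_end_s = 45, ripple = burst_fixture_ripple_config(),
    event = event_config(target_bins = 25:40, offtarget_bins = 9:24))
  list(sim = sim, paths = paths, cfg = cfg, report = run_session(cfg))
})

test_that("spike accounting balances: encoded + decoded + dropped = ingested", {
  cnt <- sess$report$counts
  expect_equal(cnt[["spikes_encoded"]] + cnt[["spikes_decoded"]] +
                 cnt[["spikes_dropped"]], cnt[["spikes_ingested"]])
  expect_equal(cnt[["spikes_ingested"]],
               nrow(read.csv(sess$paths$spikes)))
})

test_that("decoder bins tile task-2 LFP time and spikes are counted once", {
  recs <- read_records(sess$report$output)
  dec <- recs[["1"]]
  cfg <- sess$cfg
  dtt <- cfg$dt_ms / 1000 * cfg$ticks_per_s
  lfp <- read.csv(sess$paths$lfp)
  t0 <- min(lfp$timestamp)
  k_total <- floor((max(lfp$timestamp) - t0) / dtt)
  delay <- cfg$dt_delay_ms / 1000 * cfg$ticks_per_s
  # warm-up: bins whose spike window is not yet fully inside task 2
  k_min <- ceiling((45 * cfg$ticks_per_s - t0 + delay) / dtt) + 1
  expect_equal(nrow(dec), k_total - k_min + 1)
  # contiguous half-open windows: left edge = previous right edge
  expect_equal(dec$bin_timestamp_l[-1], dec$bin_timestamp_r[-nrow(dec)])
  expect_true(all(diff(dec$bin_timestamp_r) == dtt))
  # each decoded spike lands in exactly one bin
  expect_equal(sum(dec$spike_count), sess$report$counts[["spikes_decoded"]])
  # posteriors are normalised at every step
  P <- as.matrix(dec[grep("^x\\d+$", names(dec))])
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
})

test_that("dropped spikes are logged to records and match the report", {
  recs <- read_records(sess$report$output)
  expect_equal(nrow(recs[["5"]]), sess$report$counts[["spikes_dropped"]])
  expect_true(all(recs[["5"]]$elec_grp_id %in% sess$report$groups))
})

test_that("per-channel peak amplitude is the default mark", {
  wf <- rbind(c(1, -7, 3), c(2, 5, -4))
  expect_equal(waveform_to_mark(wf), c(-7, 5))
})

test_that("session report counts match fixture ground truth", {
  expect_equal(sess$report$counts[["ripples"]], 3)
  got <- sort(sess$report$ripple_events$start_timestamp) / 30000
  expect_true(all(abs(got - sess$sim$ripple_times_s) <= 0.020))
})

test_that("decoding recovers position on the synthetic session", {
  off <- decode_offline(sess$report$output, sess$sim$geometry,
                        sess$paths$truth_position)
  expect_lte(attr(off, "median_movement_error_cm"), 10)
})

test_that("replaying identical inputs produces a bit-identical record file", {
  cfg2 <- sess$cfg
  cfg2$output <- tempfile(fileext = ".bin")
  run_session(cfg2)
  expect_identical(unname(tools::md5sum(sess$report$output)),
                   unname(tools::md5sum(cfg2$output)))
})

test_that("an empty spike stream decodes from the no-spike likelihood only", {
  dir <- tempfile("empty"); dir.create(dir)
  # keep one encoding spike per group so models can freeze, none in task 2
  spk <- read.csv(sess$paths$spikes)
  spk <- spk[spk$timestamp < 45 * 30000, ]
  f <- file.path(dir, "spikes.csv"); write.csv(spk, f, row.names = FALSE)
  cfg <- sess$cfg
  cfg$spikes <- f
  cfg$output <- file.path(dir, "records.bin")
  rep2 <- run_session(cfg)
  expect_equal(rep2$counts[["spikes_decoded"]], 0)
  expect_equal(rep2$counts[["events"]], 0)
  recs <- read_records(cfg$output)
  lik <- as.matrix(recs[["2"]][grep("^x\\d+$", names(recs[["2"]]))])
  # every bin's likelihood equals the closed-form no-spike factor
  expect_true(all(abs(sweep(lik, 2, lik[1, ], "-")) < 1e-12))
})

test_that("inputs ending before the task boundary are rejected", {
  cfg <- sess$cfg
  cfg$task1_end_s <- 1000
  expect_error(run_session(cfg), "task-1 boundary")
})

test_that("offline MAP summary breaks ties to the lowest bin and flags them", {
  f <- tempfile(fileext = ".bin")
  nb <- 5
  w <- record_writer(f, record_schema(
    1, c("bin_timestamp_l", "bin_timestamp_r", "velocity", "mapped_pos",
         "spike_count", "task_state", "vel_thresh", "frozen_model",
         paste0("x", 0:(nb - 1))),
    paste0("qqdqqqd?", strrep("d", nb))))
  delta <- c(0, 0, 1, 0, 0)
  unif <- rep(1 / nb, nb)
  write_record(w, 1, c(list(0, 180, 10, 2, 1, 2, 4, TRUE), as.list(delta)))
  write_record(w, 1, c(list(180, 360, 10, 2, 0, 2, 4, TRUE), as.list(unif)))
  close_records(w)
  g <- track_geometry(rbind(c(0, 0, 25, 0)))
  out <- decode_offline(f, g)
  expect_equal(out$map_bin, c(2L, 0L))
  expect_equal(out$map_tied, c(FALSE, TRUE))
})

test_that("YAML round-trip builds an equivalent session configuration", {
  y <- tempfile(fileext = ".yaml")
  opts <- default_session_options()
  opts$inputs <- list(spikes = sess$paths$spikes, lfp = sess$paths$lfp,
                      position = sess$paths$position)
  opts$output <- file.path(tempfile("ydir"), "records.bin")
  opts$task1_end_s <- 45
  opts$event <- utils::modifyList(opts$event, list(
    enabled = TRUE, target_bins = 25:40, offtarget_bins = 9:24))
  yaml::write_yaml(opts, y)
  cfg <- read_session_config(y)
  expect_s3_class(cfg, "session_config")
  expect_equal(cfg$geometry$n_bins, 41L)
  expect_equal(cfg$event$n_window, 6L)
  dir.create(dirname(cfg$output), recursive = TRUE, showWarnings = FALSE)
  rep2 <- run_session(cfg)
  expect_gt(rep2$counts[["posterior_bins"]], 0)
})
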