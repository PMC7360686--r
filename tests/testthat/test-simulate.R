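test_that("silent spec yields an empty raster; seeds give exact determinism", {
  spec <- network_spec(n_electrodes = 10, n_hubs = 1, hub_out_degree = 3,
                       burst_rate_per_min = 0, background_rate_hz = 0)
  sim <- generate_mea_recording(spec, duration_s = 10, seed = 1)
  expect_equal(nrow(sim$raster), 0)
  expect_equal(n_electrodes(sim$raster), 10)

  spec2 <- network_spec(n_electrodes = 15, n_hubs = 2, hub_out_degree = 4,
                        burst_rate_per_min = 5)
  a <- generate_mea_recording(spec2, duration_s = 60, seed = 7)
  b <- generate_mea_recording(spec2, duration_s = 60, seed = 7)
  expect_identical(a$raster, b$raster)
  expect_identical(a$truth, b$truth)
  c <- generate_mea_recording(spec2, duration_s = 60, seed = 8)
  expect_false(identical(a$raster, c$raster))

  # serialized output is byte-identical too
  fa <- withr::local_tempfile(fileext = ".tsv")
  fb <- withr::local_tempfile(fileext = ".tsv")
  write_spike_table(a$raster, fa, sidecar = NULL)
  write_spike_table(b$raster, fb, sidecar = NULL)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("the deterministic transmission limit lands at exactly t0 + delay", {
  adj <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  delays <- matrix(c(NA, 0.005, NA, NA), 2, 2, byrow = TRUE)
  spec <- network_spec(
    n_electrodes = 2, electrode_ids = c("h", "f"), hub_ids = "h",
    adjacency = adj, delays = delays, jitter_sd_s = 0,
    background_rate_hz = 0, packet_n_spikes = 1,
    initiation_times = list(h = 0.100)
  )
  sim <- generate_mea_recording(spec, duration_s = 1, seed = 1)
  expect_equal(sim$raster$spike_time_s[sim$raster$electrode_id == "h"], 0.100)
  expect_equal(sim$raster$spike_time_s[sim$raster$electrode_id == "f"], 0.105)
})

test_that("pure background firing follows Poisson count statistics", {
  spec <- network_spec(n_electrodes = 59, n_hubs = 2, hub_out_degree = 5,
                       w = 0, background_rate_hz = 1, burst_rate_per_min = 0)
  counts <- vapply(1:20, function(s) {
    nrow(generate_mea_recording(spec, duration_s = 300, seed = s)$raster)
  }, 0)
  mu <- 59 * 300  # rate * electrodes * duration
  se_mean <- sqrt(mu / 20)
  expect_lt(abs(mean(counts) - mu), 3 * se_mean)
})

test_that("ground truth is consistent with the emitted raster", {
  spec <- network_spec(n_electrodes = 12, n_hubs = 2, hub_out_degree = 4,
                       w = 0.8, burst_rate_per_min = 5)
  sim <- generate_mea_recording(spec, duration_s = 120, seed = 9)
  # every planted initiation's packet spikes appear on the hub electrode
  for (k in seq_len(nrow(sim$truth$initiations))) {
    h <- sim$truth$initiations$hub[k]
    t0 <- sim$truth$initiations$t_s[k]
    packet <- t0 + (0:9) * 0.005
    packet <- packet[packet <= raster_duration(sim$raster)]
    hub_spikes <- sim$raster$spike_time_s[sim$raster$electrode_id == h]
    expect_true(all(vapply(packet, function(t) any(abs(hub_spikes - t) < 1e-9), TRUE)))
  }
  # planted edge table mirrors the adjacency matrix
  expect_equal(nrow(sim$truth$edges), sum(sim$truth$adjacency > 0))
  expect_true(all(sim$truth$edges$w == 0.8))
  expect_true(all(sim$truth$edges$src %in% sim$truth$hub_ids))
  # disjoint follower sets: no follower appears twice
  expect_false(any(duplicated(sim$truth$edges$dst)))
})

test_that("calcium generator honours activity flags, kernel shape and rates", {
  # no active cells: pure noise around baseline
  quiet <- generate_calcium_traces(
    calcium_spec(n_cells = 10, active_fraction = 0, noise_sd = 0.05),
    duration_s = 60, seed = 1
  )
  expect_equal(nrow(quiet$truth$events), 0)
  expect_lt(max(abs(unclass(quiet$traces) / 100 - 1)), 0.3)

  # noise-free single event: analytic kernel, peak equals the amplitude
  one <- generate_calcium_traces(
    calcium_spec(n_cells = 1, active_fraction = 1, event_rate_per_min = 0.4,
                 event_duration_s = 6.2, noise_sd = 0, drift_per_min = 0),
    duration_s = 120, seed = 3
  )
  expect_gte(nrow(one$truth$events), 1)
  tr <- as.numeric(unclass(one$traces)[1, ])
  peak_dff <- max(tr / 100 - 1)
  # instant rise sampled at 2 Hz: the peak frame sits within half a frame of
  # the true peak, so it sees the amplitude decayed by at most exp(-0.5/tau)
  spec1 <- calcium_spec(event_duration_s = 6.2, noise_sd = 0)
  expect_lte(peak_dff, 1 + 1e-9)
  expect_gte(peak_dff, exp(-0.5 / spec1$decay_tau_s) - 1e-9)

  # planted event counts: rate 2/min over 300 s, mean per active cell near 10
  sim <- generate_calcium_traces(
    calcium_spec(n_cells = 100, active_fraction = 1, event_rate_per_min = 2,
                 event_duration_s = 6.2),
    duration_s = 300, seed = 5
  )
  per_cell <- table(sim$truth$events$cell_id)
  expect_lt(abs(mean(per_cell) - 10), 3 * sqrt(10 / 100))

  # determinism
  again <- generate_calcium_traces(
    calcium_spec(n_cells = 100, active_fraction = 1, event_rate_per_min = 2,
                 event_duration_s = 6.2),
    duration_s = 300, seed = 5
  )
  expect_identical(unclass(sim$traces), unclass(again$traces))
})

test_that("condition presets carry the planted group statistics", {
  sham <- condition_preset("sham_DIV28")
  expect_equal(sham$calcium$event_rate_per_min, 2.49)
  expect_equal(sham$calcium$active_fraction, 0.687)
  expect_equal(sham$calcium$event_duration_s, 6.2)

  ab <- condition_preset("abeta_DIV28")
  expect_equal(ab$calcium$event_duration_s, 13.24)
  expect_equal(ab$calcium$active_fraction, 0.1718)

  fad <- condition_preset("fiveXFAD_DIV21")
  expect_equal(fad$calcium$active_fraction, 0.443)
  expect_equal(fad$calcium$event_rate_per_min, 1.16)

  # sham MEA calibration: expected small-burst count over 5 minutes
  s21 <- condition_preset("sham_DIV21")$network
  expect_equal(s21$n_hubs * s21$burst_rate_per_min * 5, 217.5)
  expect_equal(s21$n_electrodes, 59)

  expect_error(condition_preset("mystery_group"), "sham_DIV21")
})
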