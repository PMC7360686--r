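test_that("TSR bins spikes with the half-open convention and conserves counts", {
  r <- spike_raster(
    data.frame(electrode_id = c("A", "A", "B", "C"),
               spike_time_s = c(0.01, 0.02, 0.03, 0.06)),
    duration_s = 0.1
  )
  b <- compute_tsr(r, 0.05)
  expect_equal(b$tsr, c(3L, 1L))
  expect_equal(b$active_electrodes, c(2L, 1L))
  expect_equal(sum(b$tsr), nrow(r))

  # spike exactly on a bin edge lands in the later bin
  edge <- spike_raster(data.frame(electrode_id = "A", spike_time_s = 0.05),
                       duration_s = 0.2)
  expect_equal(compute_tsr(edge, 0.05)$tsr, c(0L, 1L, 0L, 0L))

  # empty raster: all-zero bins, ceil(duration / width) of them
  silent <- spike_raster(data.frame(electrode_id = character(), spike_time_s = numeric()),
                         duration_s = 1.0, electrode_ids = "A")
  bs <- compute_tsr(silent, 0.05)
  expect_equal(nrow(bs), 20)
  expect_true(all(bs$tsr == 0))
})

# build a raster that puts `spikes[b]` spikes on `electrodes[b]` distinct
# electrodes in bin b
raster_from_bins <- function(spikes, electrodes, bin_w = 0.05) {
  rows <- purrr::map_dfr(seq_along(spikes), function(b) {
    if (spikes[b] == 0) return(NULL)
    el <- rep(paste0("e", seq_len(electrodes[b])), length.out = spikes[b])
    tibble::tibble(
      electrode_id = el,
      spike_time_s = (b - 1) * bin_w + seq(0, 0.04, length.out = spikes[b])
    )
  })
  spike_raster(rows, duration_s = length(spikes) * bin_w,
               electrode_ids = paste0("e", 1:10))
}

test_that("the network-burst criterion needs both spike and electrode counts", {
  one <- raster_from_bins(5, 4)
  b1 <- detect_network_bursts(compute_tsr(one))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$total_spikes, 5L)
  expect_equal(b1$size_class, "small")

  few_el <- raster_from_bins(5, 2)
  expect_equal(nrow(detect_network_bursts(compute_tsr(few_el))), 0)
})

test_that("contiguous qualifying bins merge into one burst classed by its peak", {
  r <- raster_from_bins(c(0, 40, 120, 40, 0), c(0, 8, 10, 8, 0))
  bursts <- detect_network_bursts(compute_tsr(r))
  expect_equal(nrow(bursts), 1)
  expect_equal(bursts$total_spikes, 200L)
  expect_equal(bursts$peak_bin_spikes, 120L)
  expect_equal(bursts$size_class, "large")
  expect_equal(bursts$start_bin, 2L)
  expect_equal(bursts$end_bin, 4L)

  # a sub-threshold bin splits bursts at the default gap tolerance
  r2 <- raster_from_bins(c(40, 0, 40), c(8, 0, 8))
  expect_equal(nrow(detect_network_bursts(compute_tsr(r2))), 2)
  expect_equal(nrow(detect_network_bursts(compute_tsr(r2), max_gap_bins = 1)), 1)
})

test_that("burst summaries normalise to the 5- and 10-minute windows", {
  bursts <- tibble::tibble(
    start_bin = 1:13, end_bin = 1:13, start_s = 0, end_s = 0,
    total_spikes = rep(50L, 13), peak_bin_spikes = c(rep(50L, 10), rep(150L, 3)),
    size_class = c(rep("small", 10), rep("large", 3))
  )
  s <- summarize_bursts(bursts, duration_s = 300)
  expect_equal(s$n_small_per_5min, 10)
  expect_equal(s$n_large_per_10min, 6)
  expect_equal(s$mean_spikes_per_burst, 50)

  none <- summarize_bursts(bursts[0, ], duration_s = 300)
  expect_equal(none$n_small_per_5min, 0)
  expect_true(is.na(none$mean_spikes_per_burst))
})

test_that("burst detection matches the brute-force oracle on random rasters", {
  for (seed in 1:40) {
    r <- random_raster(seed)
    binned <- compute_tsr(r)
    got <- detect_network_bursts(binned)
    want <- oracle_bursts(binned)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start_bin, want$start_bin)
      expect_equal(got$end_bin, want$end_bin)
      expect_equal(got$total_spikes, want$total_spikes)
      expect_equal(got$peak_bin_spikes, want$peak_bin_spikes)
      expect_equal(got$size_class, want$size_class)
    }
  }
})

test_that("detection is invariant to relabeling and bin-aligned time shifts", {
  r <- random_raster(99, n_electrodes = 6, duration_s = 30)
  base <- detect_network_bursts(compute_tsr(r))

  relab <- spike_raster(
    data.frame(electrode_id = paste0("X", r$electrode_id),
               spike_time_s = r$spike_time_s),
    duration_s = raster_duration(r),
    electrode_ids = paste0("X", electrode_ids(r))
  )
  shifted <- spike_raster(
    data.frame(electrode_id = r$electrode_id, spike_time_s = r$spike_time_s + 0.5),
    duration_s = raster_duration(r) + 0.5, electrode_ids = electrode_ids(r)
  )
  got_relab <- detect_network_bursts(compute_tsr(relab))
  got_shift <- detect_network_bursts(compute_tsr(shifted))
  expect_equal(got_relab$start_bin, base$start_bin)
  expect_equal(got_relab$total_spikes, base$total_spikes)
  expect_equal(got_shift$start_bin, base$start_bin + 10L)
  expect_equal(got_shift$total_spikes, base$total_spikes)
})

test_that("spikes inside burst extents never exceed the raster total", {
  for (seed in c(3, 17, 31)) {
    r <- random_raster(seed)
    bursts <- detect_network_bursts(compute_tsr(r))
    expect_lte(sum(bursts$total_spikes), nrow(r))
  }
})

test_that("every planted burst packet is recovered with zero background", {
  spec <- network_spec(n_electrodes = 20, n_hubs = 2, hub_out_degree = 6,
                       w = 1, background_rate_hz = 0, burst_rate_per_min = 4)
  sim <- generate_mea_recording(spec, duration_s = 300, seed = 5)
  init <- sim$truth$initiations$t_s
  # keep the property clean: packets separated by more than one bin
  expect_true(min(diff(sort(init))) > 0.1)
  bursts <- detect_network_bursts(compute_tsr(sim$raster))
  expect_equal(nrow(bursts), length(init))
})
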