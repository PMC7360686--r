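#' Total spiking rate in fixed time bins
#'
#' Bins all spikes from all electrodes into fixed, non-sliding time bins
#' anchored at t = 0 (default width 50 ms) and counts, per bin, the total
#' spike count (the TSR) and the number of distinct electrodes that fired.
#' Bins are half-open `[k*w, (k+1)*w)`; a spike exactly at the recording end
#' is placed in the last bin so that no spike is ever lost. The last partial
#' bin is included.
#'
#' @param raster A [spike_raster()].
#' @param bin_width_s Bin width in seconds.
#' @return A `binned_activity` tibble with columns `bin` (1-based), `t_start`,
#'   `tsr` and `active_electrodes`, one row per bin, plus attributes
#'   `bin_width_s`, `duration_s`, `n_electrodes` and `total_spikes`.
#'   `sum(tsr)` always equals the number of spikes in the raster.
#' @examples
#' r <- spike_raster(
#'   data.frame(electrode_id = c("A", "A", "B", "C"),
#'              spike_time_s = c(0.01, 0.02, 0.03, 0.06)),
#'   duration_s = 0.1
#' )
#' compute_tsr(r)
#' @export
compute_tsr <- function(raster, bin_width_s = 0.05) {
  if (!is.numeric(bin_width_s) || bin_width_s <= 0) {
    abort("`bin_width_s` must be positive.")
  }
  duration_s <- raster_duration(raster)
  n_bins <- max(1L, as.integer(ceiling(duration_s / bin_width_s - 1e-9)))
  bin <- pmin(floor(raster$spike_time_s / bin_width_s) + 1L, n_bins)
  tsr <- tabulate(bin, nbins = n_bins)
  uniq <- !duplicated(data.frame(raster$electrode_id, bin))
  active <- tabulate(bin[uniq], nbins = n_bins)
  structure(
    tibble(
      bin = seq_len(n_bins),
      t_start = (seq_len(n_bins) - 1) * bin_width_s,
      tsr = as.integer(tsr),
      active_electrodes = as.integer(active)
    ),
    class = c("binned_activity", class(tibble())),
    bin_width_s = bin_width_s,
    duration_s = duration_s,
    n_electrodes = n_electrodes(raster),
    total_spikes = nrow(raster)
  )
}

#' Detect network bursts from binned activity
#'
#' A bin qualifies as burst activity when it holds at least `min_spikes`
#' spikes from at least `min_electrodes` distinct electrodes (the classical
#' network-burst criterion: no fewer than four spikes from different
#' electrodes within one 50-ms bin). Each maximal run of contiguous
#' qualifying bins forms one network burst; by default a single sub-threshold
#' bin splits bursts (`max_gap_bins = 0`), and a positive `max_gap_bins`
#' merges runs separated by at most that many sub-threshold bins.
#'
#' Bursts are classified by their peak 50-ms bin: `small` when the peak bin
#' holds 4-100 spikes, `large` when it holds 101 or more. `total_spikes`
#' counts the whole burst extent, which is why mean spikes per burst can far
#' exceed the per-bin class boundary.
#'
#' @param binned A `binned_activity` tibble from [compute_tsr()].
#' @param min_spikes Minimum spikes per qualifying bin.
#' @param min_electrodes Minimum distinct firing electrodes per qualifying bin.
#' @param max_gap_bins Sub-threshold bins tolerated inside one burst.
#' @param large_threshold Peak-bin spike count at and above which a burst is
#'   `large` (default 101).
#' @return A `network_bursts` tibble ordered by start time, one row per
#'   burst: `start_bin`, `end_bin`, `start_s`, `end_s`, `total_spikes`,
#'   `peak_bin_spikes`, `size_class`. Bursts never overlap.
#' @export
detect_network_bursts <- function(binned, min_spikes = 4, min_electrodes = 4,
                                  max_gap_bins = 0, large_threshold = 101) {
  bin_w <- attr(binned, "bin_width_s")
  qual <- binned$tsr >= min_spikes & binned$active_electrodes >= min_electrodes
  empty <- tibble(
    start_bin = integer(), end_bin = integer(),
    start_s = numeric(), end_s = numeric(),
    total_spikes = integer(), peak_bin_spikes = integer(), size_class = character()
  )
  out <- if (!any(qual)) {
    empty
  } else {
    idx <- which(qual)
    grp <- cumsum(c(1L, as.integer(diff(idx) > max_gap_bins + 1L)))
    purrr::map_dfr(split(idx, grp), function(b) {
      ext <- seq(min(b), max(b))
      peak <- max(binned$tsr[b])
      tibble(
        start_bin = min(b), end_bin = max(b),
        start_s = (min(b) - 1L) * bin_w, end_s = max(b) * bin_w,
        total_spikes = sum(binned$tsr[ext]),
        peak_bin_spikes = as.integer(peak),
        size_class = if (peak >= large_threshold) "large" else "small"
      )
    })
  }
  structure(
    dplyr::arrange(out, .data$start_bin),
    class = c("network_bursts", class(tibble())),
    duration_s = attr(binned, "duration_s"),
    bin_width_s = bin_w,
    min_spikes = min_spikes,
    min_electrodes = min_electrodes,
    large_threshold = large_threshold
  )
}

#' Summarize detected network bursts
#'
#' Normalises burst counts to the reporting windows used for cultured-network
#' MEA recordings: small bursts per 5 minutes and large bursts per 10
#' minutes, plus the mean number of spikes per burst (over the whole burst
#' extent). With no bursts the rates are 0 and the mean is `NA`.
#'
#' @param bursts A `network_bursts` tibble from [detect_network_bursts()].
#' @param duration_s Recording duration in seconds; defaults to the value
#'   carried by `bursts`.
#' @param spikes_per_burst_scope Average spikes per burst over `"all"` bursts
#'   (default) or `"small"` bursts only.
#' @return A one-row `burst_summary` tibble: `n_small`, `n_large`,
#'   `n_small_per_5min`, `n_large_per_10min`, `mean_spikes_per_burst`,
#'   `duration_s`.
#' @export
summarize_bursts <- function(bursts, duration_s = attr(bursts, "duration_s"),
                             spikes_per_burst_scope = c("all", "small")) {
  spikes_per_burst_scope <- match.arg(spikes_per_burst_scope)
  if (is.null(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive (pass it explicitly if unattributed).")
  }
  n_small <- sum(bursts$size_class == "small")
  n_large <- sum(bursts$size_class == "large")
  in_scope <- if (spikes_per_burst_scope == "small") {
    bursts$total_spikes[bursts$size_class == "small"]
  } else {
    bursts$total_spikes
  }
  structure(
    tibble(
      n_small = n_small,
      n_large = n_large,
      n_small_per_5min = n_small * 300 / duration_s,
      n_large_per_10min = n_large * 600 / duration_s,
      mean_spikes_per_burst = if (length(in_scope) > 0) mean(in_scope) else NA_real_,
      duration_s = duration_s
    ),
    class = c("burst_summary", class(tibble()))
  )
}
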