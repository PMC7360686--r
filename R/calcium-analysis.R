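#' Baseline-normalised fluorescence (dF/F)
#'
#' Converts raw fluorescence traces to dF/F with a running-percentile
#' baseline: per cell, `F0(t)` is the `baseline_percentile`-th percentile of
#' the raw trace in a centred window of `baseline_window_s` seconds (default
#' 8th percentile over 60 s, which tracks slow drift while ignoring
#' transients), and `dF/F = (F - F0) / F0`. `F0` is floored at a small
#' positive constant so near-zero baselines cannot blow up the ratio. For
#' speed the running percentile is evaluated on a coarse frame stride and
#' linearly interpolated; the stride (default 5 frames = 2.5 s at 2 Hz) is
#' far below the baseline time scale.
#'
#' @param traces A [calcium_traces()] object of raw fluorescence.
#' @param baseline_window_s Baseline window length in seconds (>= 2 frames).
#' @param baseline_percentile Percentile (0-100) used as the baseline.
#' @param stride_frames Evaluation stride of the running percentile.
#' @return A [calcium_traces()] object of dF/F values (`dff` flag set).
#' @export
compute_dff <- function(traces, baseline_window_s = 60, baseline_percentile = 8,
                        stride_frames = 5) {
  rate <- frame_rate(traces)
  n_frames <- ncol(traces)
  win <- round(baseline_window_s * rate)
  if (win < 2) abort("`baseline_window_s` must span at least 2 frames.")
  if (all(traces <= 0)) abort("raw fluorescence is non-positive everywhere.")
  win <- min(win, n_frames)
  half <- win %/% 2
  at <- unique(c(seq(1L, n_frames, by = max(1L, as.integer(stride_frames))), n_frames))
  floor_f0 <- 1e-6 * max(abs(traces))
  p <- baseline_percentile / 100
  m <- unclass(traces)
  dff <- m
  for (r in seq_len(nrow(m))) {
    x <- m[r, ]
    f0_at <- vapply(at, function(k) {
      w <- x[max(1L, k - half):min(n_frames, k + half)]
      as.numeric(quantile(w, probs = p, names = FALSE, type = 7))
    }, 0)
    f0 <- if (length(at) > 1) {
      stats::approx(at, f0_at, xout = seq_len(n_frames), rule = 2)$y
    } else {
      rep(f0_at, n_frames)
    }
    f0 <- pmax(f0, floor_f0)
    dff[r, ] <- (x - f0) / f0
  }
  out <- calcium_traces(dff, frame_rate_hz = rate, cell_ids = rownames(traces), dff = TRUE)
  attr(out, "baseline_percentile") <- baseline_percentile
  out
}

#' Detect calcium transient events
#'
#' Threshold-crossing event detection on dF/F traces. Per cell the noise SD
#' is estimated robustly from the first difference of the trace
#' (`1.4826 * mad(diff(x)) / sqrt(2)`), which is insensitive to the slow
#' transients themselves. A percentile baseline leaves the dF/F noise floor
#' sitting above zero by a known amount (`-qnorm(p) * sigma` for the `p`-th
#' percentile under Gaussian noise), so when the input carries the
#' `baseline_percentile` attribute written by [compute_dff()] the threshold
#' is raised by exactly that offset; this keeps the detection level at
#' `threshold_sd` noise SDs above the true baseline without estimating a
#' centre from the (event-contaminated) trace itself. An event is a maximal
#' run of frames whose (median-prefiltered) dF/F exceeds the threshold and
#' that lasts at least `min_duration_s`. The 3-frame running-median prefilter
#' suppresses single-frame noise excursions that would otherwise split one
#' transient in two; events separated by at least one sub-threshold frame are
#' distinct. Onset and offset sit at the threshold crossings, so the reported
#' duration is the time spent above threshold.
#'
#' @param dff A [calcium_traces()] object of dF/F values (see [compute_dff()]).
#' @param threshold_sd Detection threshold in units of the per-cell noise SD.
#' @param min_duration_s Minimum event duration in seconds.
#' @param smooth_frames Width of the running-median prefilter (odd; 1
#'   disables it).
#' @return A `calcium_events` tibble: `cell_id`, `onset_s`, `offset_s`,
#'   `duration_s`, `peak_dff` (peak taken on the unfiltered trace), ordered
#'   by cell then onset; attributes carry the detector parameters, `n_cells`
#'   and the recording duration.
#' @export
detect_events <- function(dff, threshold_sd = 2.5, min_duration_s = 1.0,
                          smooth_frames = 3) {
  rate <- frame_rate(dff)
  dt <- 1 / rate
  if (ncol(dff) < 2) abort("need at least 2 frames to detect events.")
  if (smooth_frames %% 2 == 0) abort("`smooth_frames` must be odd.")
  min_frames <- max(1L, as.integer(ceiling(min_duration_s * rate - 1e-9)))
  bp <- attr(dff, "baseline_percentile")
  floor_sds <- if (!is.null(bp) && bp < 50) -stats::qnorm(bp / 100) else 0
  m <- unclass(dff)
  out <- purrr::map_dfr(seq_len(nrow(m)), function(r) {
    x <- m[r, ]
    sigma <- mad(diff(x)) / sqrt(2)
    thr <- (floor_sds + threshold_sd) * sigma
    xs <- if (smooth_frames > 1 && length(x) >= smooth_frames) {
      runmed(x, smooth_frames, endrule = "median")
    } else {
      x
    }
    above <- xs > thr
    if (!any(above)) return(NULL)
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & runs$lengths >= min_frames
    if (!any(keep)) return(NULL)
    purrr::map_dfr(which(keep), function(k) {
      fr <- starts[k]:ends[k]
      tibble(
        cell_id = rownames(m)[r],
        onset_s = (starts[k] - 1L) * dt,
        offset_s = ends[k] * dt,
        duration_s = length(fr) * dt,
        peak_dff = max(x[fr])
      )
    })
  })
  if (nrow(out) == 0) {
    out <- tibble(cell_id = character(), onset_s = numeric(), offset_s = numeric(),
                  duration_s = numeric(), peak_dff = numeric())
  }
  structure(
    dplyr::arrange(out, .data$cell_id, .data$onset_s),
    class = c("calcium_events", class(tibble())),
    n_cells = nrow(dff),
    duration_s = trace_duration(dff),
    frame_rate_hz = rate,
    threshold_sd = threshold_sd,
    min_duration_s = min_duration_s,
    smooth_frames = smooth_frames
  )
}

#' Summarize calcium network activity
#'
#' The three standard statistics of spontaneous network calcium activity:
#' percentage of functionally active cells (cells with at least one detected
#' event), event rate in events/min, and mean event duration in seconds. The
#' rate averages over active cells only by default (matching how nonzero
#' oscillation frequencies are reported alongside large inactive fractions);
#' `rate_scope = "all"` averages over every cell instead.
#'
#' @param events A `calcium_events` tibble from [detect_events()].
#' @param n_cells Total number of cells imaged; defaults to the value carried
#'   by `events`.
#' @param duration_s Recording duration in seconds; defaults likewise.
#' @param rate_scope `"active"` (default) or `"all"`.
#' @return A one-row `calcium_summary` tibble: `n_cells`, `n_active`,
#'   `pct_active`, `mean_rate_per_min`, `mean_duration_s`. With no events the
#'   rate and duration are `NA`.
#' @export
summarize_calcium <- function(events, n_cells = attr(events, "n_cells"),
                              duration_s = attr(events, "duration_s"),
                              rate_scope = c("active", "all")) {
  rate_scope <- match.arg(rate_scope)
  if (is.null(n_cells) || n_cells <= 0) abort("`n_cells` must be positive.")
  if (is.null(duration_s) || duration_s <= 0) abort("`duration_s` must be positive.")
  minutes <- duration_s / 60
  per_cell <- dplyr::count(events, .data$cell_id)
  n_active <- nrow(per_cell)
  rate <- if (nrow(events) == 0) {
    NA_real_
  } else if (rate_scope == "active") {
    mean(per_cell$n / minutes)
  } else {
    sum(per_cell$n) / minutes / n_cells
  }
  structure(
    tibble(
      n_cells = as.integer(n_cells),
      n_active = n_active,
      pct_active = 100 * n_active / n_cells,
      mean_rate_per_min = rate,
      mean_duration_s = if (nrow(events) > 0) mean(events$duration_s) else NA_real_
    ),
    class = c("calcium_summary", class(tibble()))
  )
}
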