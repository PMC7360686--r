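#' Planted calcium-activity specification
#'
#' Generative model for synthetic somatic calcium traces: a fraction of cells
#' is active; each active cell receives transient events whose waveform is an
#' instant rise to `amplitude` (in dF/F units) followed by exponential decay.
#' The decay constant is solved so that the time spent above the nominal
#' detection threshold (`threshold_sd_nominal * noise_sd`) equals
#' `event_duration_s` — the planted duration is defined at the detector's
#' threshold level, since only that duration is observable. Event times form
#' a Poisson-with-dead-time renewal process: consecutive events are separated
#' by at least the event duration plus one frame (a transient must decay
#' before the next is distinguishable), with exponential gaps rescaled so the
#' mean rate equals `event_rate_per_min` exactly. Inactive cells are
#' noise-only. Traces carry additive Gaussian noise and a linear baseline
#' drift.
#'
#' @param n_cells Number of cell ROIs.
#' @param active_fraction Probability a cell is active, in `[0, 1]`.
#' @param event_rate_per_min Event rate of active cells (events/min).
#' @param event_duration_s Planted above-threshold event duration (seconds).
#' @param amplitude Peak dF/F of one transient.
#' @param noise_sd Additive noise SD in dF/F units.
#' @param drift_per_min Linear baseline drift, as a fraction of baseline per
#'   minute.
#' @param baseline Raw-fluorescence baseline (arbitrary units).
#' @param frame_rate_hz Imaging rate (default 2 Hz).
#' @param threshold_sd_nominal Detector threshold (in noise SDs) the planted
#'   duration is defined against.
#' @return A `calcium_spec` list.
#' @seealso [generate_calcium_traces()], [condition_preset()]
#' @export
calcium_spec <- function(n_cells = 100, active_fraction = 0.687,
                         event_rate_per_min = 2.49, event_duration_s = 6.2,
                         amplitude = 1.0, noise_sd = 0.05, drift_per_min = 0.01,
                         baseline = 100, frame_rate_hz = 2,
                         threshold_sd_nominal = 2.5) {
  if (active_fraction < 0 || active_fraction > 1) {
    abort("`active_fraction` must be in [0, 1].")
  }
  if (event_rate_per_min < 0 || event_duration_s < 0) abort("rates and durations must be >= 0.")
  if (noise_sd < 0 || amplitude <= 0 || baseline <= 0 || frame_rate_hz <= 0) {
    abort("`amplitude`, `baseline`, `frame_rate_hz` must be positive; `noise_sd` >= 0.")
  }
  theta <- threshold_sd_nominal * noise_sd
  if (theta <= 0 || theta >= amplitude) theta <- amplitude / 100
  structure(
    list(
      n_cells = n_cells, active_fraction = active_fraction,
      event_rate_per_min = event_rate_per_min, event_duration_s = event_duration_s,
      amplitude = amplitude, noise_sd = noise_sd, drift_per_min = drift_per_min,
      baseline = baseline, frame_rate_hz = frame_rate_hz,
      threshold_sd_nominal = threshold_sd_nominal,
      threshold_level = theta,
      decay_tau_s = if (event_duration_s > 0) {
        event_duration_s / log(amplitude / theta)
      } else {
        0.5
      }
    ),
    class = "calcium_spec"
  )
}

# renewal event times with dead time; mean interval = 60 / rate
plant_event_times <- function(rate_per_min, duration_s, min_gap_s) {
  if (rate_per_min <= 0) return(numeric(0))
  mean_int <- 60 / rate_per_min
  if (mean_int <= min_gap_s) {
    abort(sprintf(
      "event rate %.3g/min too high for %.3g s events: mean interval below the dead time.",
      rate_per_min, min_gap_s
    ))
  }
  times <- runif(1, 0, mean_int)
  while (TRUE) {
    nxt <- times[length(times)] + min_gap_s + rexp(1, 1 / (mean_int - min_gap_s))
    if (nxt > duration_s) break
    times <- c(times, nxt)
  }
  times[times <= duration_s]
}

#' Generate synthetic calcium traces with planted events
#'
#' Simulates raw fluorescence traces from a [calcium_spec()] and returns the
#' planted ground truth. Randomness is split per cell from `seed`, so
#' identical `(spec, duration_s, seed)` give identical traces.
#'
#' @param spec A [calcium_spec()].
#' @param duration_s Recording length in seconds (at least 2 frames).
#' @param seed Integer seed.
#' @return A list with `traces` (a [calcium_traces()] of raw fluorescence)
#'   and `truth`: `cells` (tibble `cell_id, active`) and `events` (tibble
#'   `cell_id, t_s, duration_s` of planted events).
#' @export
generate_calcium_traces <- function(spec, duration_s = 300, seed = 1) {
  if (!inherits(spec, "calcium_spec")) abort("`spec` must be a calcium_spec.")
  n_frames <- round(duration_s * spec$frame_rate_hz)
  if (n_frames < 2) abort("recording must span at least 2 frames.")
  tt <- (seq_len(n_frames) - 1) / spec$frame_rate_hz
  ids <- sprintf("cell_%03d", seq_len(spec$n_cells))
  min_gap <- spec$event_duration_s + 1 / spec$frame_rate_hz
  traces <- matrix(0, spec$n_cells, n_frames, dimnames = list(ids, NULL))
  active <- logical(spec$n_cells)
  events <- vector("list", spec$n_cells)
  for (c_i in seq_len(spec$n_cells)) {
    set.seed(sub_seed(seed, 500000 + c_i))
    active[c_i] <- runif(1) < spec$active_fraction
    ev <- if (active[c_i]) {
      plant_event_times(spec$event_rate_per_min, duration_s, min_gap)
    } else {
      numeric(0)
    }
    events[[c_i]] <- ev
    s <- rep(0, n_frames)
    for (te in ev) {
      on <- tt >= te
      s[on] <- s[on] + spec$amplitude * exp(-(tt[on] - te) / spec$decay_tau_s)
    }
    drift <- spec$drift_per_min * tt / 60
    noise <- if (spec$noise_sd > 0) rnorm(n_frames, 0, spec$noise_sd) else 0
    traces[c_i, ] <- spec$baseline * (1 + drift + s + noise)
  }
  truth_events <- purrr::map_dfr(seq_len(spec$n_cells), function(c_i) {
    if (length(events[[c_i]]) == 0) return(NULL)
    tibble(cell_id = ids[c_i], t_s = events[[c_i]], duration_s = spec$event_duration_s)
  })
  if (nrow(truth_events) == 0) {
    truth_events <- tibble(cell_id = character(), t_s = numeric(), duration_s = numeric())
  }
  list(
    traces = calcium_traces(traces, frame_rate_hz = spec$frame_rate_hz, cell_ids = ids),
    truth = list(
      cells = tibble(cell_id = ids, active = active),
      events = truth_events
    )
  )
}
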