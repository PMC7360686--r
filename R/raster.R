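#' Spike raster objects
#'
#' A spike raster is the canonical container for an MEA recording: one row per
#' spike, columns `electrode_id` (character) and `spike_time_s` (seconds from
#' recording start), carried as a tibble together with the recording duration
#' and the full declared electrode set (so that silent electrodes are retained
#' throughout the pipeline — they can never become hubs, but they stay in every
#' matrix and graph).
#'
#' All times are in seconds; acquisition sample indices must be converted on
#' ingest (e.g. divide by the 20 kHz sampling rate). Electrode labels are
#' opaque strings. Duplicate spike times on one electrode are kept — they
#' contribute to all counts — but are reported by [validate_raster()].
#'
#' @param spikes A data frame with columns `electrode_id` and `spike_time_s`.
#' @param duration_s Recording length in seconds (> 0).
#' @param electrode_ids Optional character vector declaring the full electrode
#'   set, including electrodes with zero spikes. Defaults to the electrodes
#'   present in `spikes`.
#' @param metadata A list of recording metadata, see [recording_metadata()].
#' @return A `spike_raster`: a tibble of spikes sorted by electrode then time,
#'   with attributes `duration_s`, `electrode_ids` and `metadata`.
#' @examples
#' r <- spike_raster(
#'   data.frame(electrode_id = c("A", "A", "B"), spike_time_s = c(0.01, 0.02, 0.03)),
#'   duration_s = 1
#' )
#' n_electrodes(r)
#' @export
spike_raster <- function(spikes, duration_s, electrode_ids = NULL,
                         metadata = recording_metadata()) {
  if (!is.data.frame(spikes)) {
    abort("`spikes` must be a data frame with columns electrode_id, spike_time_s.")
  }
  if (nrow(spikes) == 0 && !all(c("electrode_id", "spike_time_s") %in% names(spikes))) {
    spikes <- tibble(electrode_id = character(), spike_time_s = numeric())
  }
  missing_cols <- setdiff(c("electrode_id", "spike_time_s"), names(spikes))
  if (length(missing_cols) > 0) {
    abort(paste0("`spikes` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1 || !is.finite(duration_s) ||
      duration_s <= 0) {
    abort("`duration_s` must be a single positive number.")
  }
  spikes <- as_tibble(spikes)[, c("electrode_id", "spike_time_s")]
  spikes$electrode_id <- as.character(spikes$electrode_id)
  spikes$spike_time_s <- as.numeric(spikes$spike_time_s)
  if (anyNA(spikes$electrode_id) || anyNA(spikes$spike_time_s)) {
    abort("`spikes` contains missing electrode ids or spike times.")
  }
  bad <- spikes$spike_time_s < 0 | spikes$spike_time_s > duration_s
  if (any(bad)) {
    abort(sprintf(
      "%d spike time(s) outside [0, duration_s]; first offender: electrode %s at %g s.",
      sum(bad), spikes$electrode_id[which(bad)[1]], spikes$spike_time_s[which(bad)[1]]
    ))
  }
  electrode_ids <- as.character(electrode_ids %||% sort(unique(spikes$electrode_id)))
  undeclared <- setdiff(unique(spikes$electrode_id), electrode_ids)
  if (length(undeclared) > 0) {
    abort(paste0(
      "spikes reference electrode(s) not in `electrode_ids`: ",
      paste(head(undeclared, 5), collapse = ", ")
    ))
  }
  spikes <- dplyr::arrange(spikes, .data$electrode_id, .data$spike_time_s)
  structure(
    spikes,
    class = c("spike_raster", class(tibble())),
    duration_s = duration_s,
    electrode_ids = electrode_ids,
    metadata = metadata
  )
}

#' Recording metadata
#'
#' Acquisition-level metadata attached to a [spike_raster()]. The defaults
#' mirror a standard 60-electrode MEA setup: 59 recording channels sampled at
#' 20 kHz on a grid with 200 um electrode pitch.
#'
#' @param sampling_rate_hz Acquisition rate in Hz.
#' @param electrode_pitch_um Electrode spacing in micrometres (informational).
#' @param condition Experimental group label (free text or a preset token).
#' @param div Day in vitro of the recording.
#' @return A named list of class `recording_metadata`.
#' @export
recording_metadata <- function(sampling_rate_hz = 20000, electrode_pitch_um = 200,
                               condition = NA_character_, div = NA_integer_) {
  if (!is.na(sampling_rate_hz) && sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be positive.")
  }
  structure(
    list(
      sampling_rate_hz = sampling_rate_hz,
      electrode_pitch_um = electrode_pitch_um,
      condition = condition,
      div = div
    ),
    class = "recording_metadata"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "<spike_raster> %d spikes, %d electrodes, %.6g s\n",
    nrow(x), length(attr(x, "electrode_ids")), attr(x, "duration_s")
  ))
  NextMethod()
}

#' Raster accessors
#'
#' @param raster A [spike_raster()].
#' @return `raster_duration()` the recording length in seconds;
#'   `electrode_ids()` the declared electrode labels; `n_electrodes()` their
#'   count; `spike_times_list()` a named list of sorted spike-time vectors, one
#'   per declared electrode (silent electrodes give `numeric(0)`).
#' @export
raster_duration <- function(raster) attr(raster, "duration_s")

#' @rdname raster_duration
#' @export
electrode_ids <- function(raster) attr(raster, "electrode_ids")

#' @rdname raster_duration
#' @export
n_electrodes <- function(raster) length(attr(raster, "electrode_ids"))

#' @rdname raster_duration
#' @export
spike_times_list <- function(raster) {
  ids <- electrode_ids(raster)
  out <- split(raster$spike_time_s, factor(raster$electrode_id, levels = ids))
  lapply(out, as.numeric)
}

#' Validate a spike raster
#'
#' Checks the raster invariants and reports violations instead of raising:
#' spike times inside `[0, duration_s]`, per-electrode sortedness, spikes on
#' declared electrodes only, positive duration. Duplicate identical spike
#' times on one electrode are permitted (they count as spikes) but reported at
#' warning severity.
#'
#' @param raster A [spike_raster()] (or something shaped like one).
#' @return A tibble with columns `electrode_id`, `rule`, `severity`
#'   (`"error"` or `"warning"`) and `message`; zero rows when the raster is
#'   fully valid.
#' @export
validate_raster <- function(raster) {
  out <- tibble(
    electrode_id = character(), rule = character(),
    severity = character(), message = character()
  )
  viol <- function(id, rule, severity, msg) {
    tibble(electrode_id = id, rule = rule, severity = severity, message = msg)
  }
  dur <- attr(raster, "duration_s")
  ids <- attr(raster, "electrode_ids")
  if (is.null(dur) || !is.finite(dur) || dur <= 0) {
    out <- dplyr::bind_rows(out, viol(NA_character_, "positive_duration", "error",
                                      "duration_s must be a positive finite number"))
    dur <- Inf
  }
  undeclared <- setdiff(unique(raster$electrode_id), ids)
  for (id in undeclared) {
    out <- dplyr::bind_rows(out, viol(id, "declared_electrode", "error",
                                      "spikes on an electrode absent from electrode_ids"))
  }
  by_el <- split(raster$spike_time_s, raster$electrode_id)
  for (id in names(by_el)) {
    tt <- by_el[[id]]
    n_out <- sum(tt < 0 | tt > dur)
    if (n_out > 0) {
      out <- dplyr::bind_rows(out, viol(id, "time_in_range", "error",
        sprintf("%d spike time(s) outside [0, %g]", n_out, dur)))
    }
    if (is.unsorted(tt)) {
      out <- dplyr::bind_rows(out, viol(id, "sorted_times", "error",
                                        "spike times are not sorted non-decreasing"))
    }
    n_dup <- sum(duplicated(tt))
    if (n_dup > 0) {
      out <- dplyr::bind_rows(out, viol(id, "duplicate_times", "warning",
        sprintf("%d duplicated spike time(s); duplicates are kept and counted", n_dup)))
    }
  }
  out
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read and write spike tables
#'
#' Spike tables are delimited text (TSV, or CSV when the file extension is
#' `.csv`) with header columns `electrode_id` and `spike_time_s`. Recording
#' metadata travels in a JSON sidecar (`<path>.json` by default) holding
#' `duration_s`, `electrode_ids`, and acquisition fields; `duration_s` and
#' `electrode_ids` arguments override the sidecar. Times are sorted per
#' electrode on load; no spike is ever silently dropped.
#'
#' @param path Path to the spike table.
#' @param duration_s Recording duration in seconds; required unless present in
#'   the sidecar.
#' @param electrode_ids Optional declared electrode set (keeps silent
#'   electrodes).
#' @param metadata A [recording_metadata()] list.
#' @param sidecar Path to the JSON sidecar; `NULL` disables sidecar handling.
#' @return `read_spike_table()` a [spike_raster()]; `write_spike_table()` the
#'   input raster, invisibly, after writing the table (and sidecar).
#' @export
read_spike_table <- function(path, duration_s = NULL, electrode_ids = NULL,
                             metadata = NULL, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) abort(paste0("No such spike table: ", path))
  side <- NULL
  if (!is.null(sidecar) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  duration_s <- duration_s %||% side$duration_s
  if (is.null(duration_s)) {
    abort("`duration_s` not given and no sidecar provides it.")
  }
  electrode_ids <- electrode_ids %||% side$electrode_ids
  if (is.null(metadata)) {
    metadata <- recording_metadata(
      sampling_rate_hz = side$sampling_rate_hz %||% 20000,
      electrode_pitch_um = side$electrode_pitch_um %||% 200,
      condition = side$condition %||% NA_character_,
      div = side$div %||% NA_integer_
    )
  }
  # parse problems are escalated to errors below, so readr's own warning
  # about them is redundant
  tab <- suppressWarnings(readr::read_delim(
    path, delim = delim_for(path), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      electrode_id = readr::col_character(),
      spike_time_s = readr::col_double()
    )
  ))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Malformed spike table %s: row %d, column %d (%s).",
      path, probs$row[1], probs$col[1], probs$expected[1]
    ))
  }
  spike_raster(tab, duration_s = duration_s, electrode_ids = electrode_ids,
               metadata = metadata)
}

#' @param raster A [spike_raster()] to serialize.
#' @rdname read_spike_table
#' @export
write_spike_table <- function(raster, path, sidecar = paste0(path, ".json")) {
  tab <- as_tibble(raster)
  readr::write_delim(tab, path, delim = delim_for(path))
  if (!is.null(sidecar)) {
    md <- attr(raster, "metadata")
    jsonlite::write_json(
      list(
        duration_s = raster_duration(raster),
        electrode_ids = electrode_ids(raster),
        sampling_rate_hz = md$sampling_rate_hz,
        electrode_pitch_um = md$electrode_pitch_um,
        condition = md$condition,
        div = md$div
      ),
      sidecar, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    )
  }
  invisible(raster)
}
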