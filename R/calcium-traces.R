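#' Calcium trace sets
#'
#' Container for somatic calcium-imaging traces: a cells-by-frames numeric
#' matrix of fluorescence intensity (arbitrary units, or dF/F after
#' [compute_dff()]) plus the imaging frame rate. The default 2 Hz frame rate
#' matches confocal time-series imaging of OGB-1-loaded cultures.
#'
#' @param traces Numeric matrix, one row per cell ROI, one column per frame.
#' @param frame_rate_hz Imaging rate in Hz.
#' @param cell_ids Optional ROI labels; default `cell_1 ... cell_n`.
#' @param dff Logical flag: are these baseline-normalised dF/F traces?
#' @return A `calcium_traces` object (matrix with attributes).
#' @export
calcium_traces <- function(traces, frame_rate_hz = 2, cell_ids = NULL, dff = FALSE) {
  traces <- as.matrix(traces)
  if (!is.numeric(traces) || any(!is.finite(traces))) {
    abort("`traces` must be a finite numeric matrix (cells x frames).")
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    abort("`frame_rate_hz` must be positive.")
  }
  cell_ids <- as.character(cell_ids %||% rownames(traces) %||%
                             paste0("cell_", seq_len(nrow(traces))))
  if (length(cell_ids) != nrow(traces)) {
    abort("`cell_ids` length must equal the number of trace rows.")
  }
  rownames(traces) <- cell_ids
  structure(traces, class = c("calcium_traces", "matrix", "array"),
            frame_rate_hz = frame_rate_hz, dff = dff)
}

#' @export
print.calcium_traces <- function(x, ...) {
  cat(sprintf(
    "<calcium_traces%s> %d cells x %d frames @ %g Hz (%.6g s)\n",
    if (isTRUE(attr(x, "dff"))) " dF/F" else "",
    nrow(x), ncol(x), attr(x, "frame_rate_hz"), trace_duration(x)
  ))
  invisible(x)
}

#' Calcium trace accessors
#'
#' @param traces A [calcium_traces()] object.
#' @return `frame_rate()` the imaging rate in Hz; `trace_duration()` the
#'   recording length in seconds; `frame_times()` the time of each frame
#'   (frame k spans `[(k-1), k) / rate`, timestamped at its start);
#'   `cell_ids()` the ROI labels.
#' @export
frame_rate <- function(traces) attr(traces, "frame_rate_hz")

#' @rdname frame_rate
#' @export
trace_duration <- function(traces) ncol(traces) / attr(traces, "frame_rate_hz")

#' @rdname frame_rate
#' @export
frame_times <- function(traces) (seq_len(ncol(traces)) - 1) / frame_rate(traces)

#' @rdname frame_rate
#' @export
cell_ids <- function(traces) rownames(traces)

#' @describeIn calcium_traces Long-format view: one row per (cell, frame).
#' @param x A `calcium_traces` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.calcium_traces <- function(x, ...) {
  tibble(
    cell_id = rep(rownames(x), times = ncol(x)),
    frame = rep(seq_len(ncol(x)), each = nrow(x)),
    time_s = rep(frame_times(x), each = nrow(x)),
    value = as.vector(x)
  )
}

#' Read and write calcium trace matrices
#'
#' Trace matrices are delimited text (TSV, or CSV for a `.csv` extension):
#' first column `cell_id`, remaining columns one frame each. The frame rate is
#' stored in a JSON sidecar (`<path>.json`) and can be overridden by argument.
#'
#' @param path File path.
#' @param frame_rate_hz Imaging rate in Hz; overrides the sidecar.
#' @param sidecar Sidecar path, `NULL` to disable.
#' @return `read_trace_matrix()` a [calcium_traces()] object;
#'   `write_trace_matrix()` its input, invisibly.
#' @export
read_trace_matrix <- function(path, frame_rate_hz = NULL, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) abort(paste0("No such trace matrix: ", path))
  side <- NULL
  if (!is.null(sidecar) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  frame_rate_hz <- frame_rate_hz %||% side$frame_rate_hz %||% 2
  tab <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                           progress = FALSE)
  if (names(tab)[1] != "cell_id") abort("First column of a trace matrix must be `cell_id`.")
  m <- as.matrix(tab[, -1, drop = FALSE])
  calcium_traces(m, frame_rate_hz = frame_rate_hz, cell_ids = tab$cell_id,
                 dff = isTRUE(side$dff))
}

#' @param traces A [calcium_traces()] object.
#' @rdname read_trace_matrix
#' @export
write_trace_matrix <- function(traces, path, sidecar = paste0(path, ".json")) {
  tab <- as_tibble(unclass(traces)[, , drop = FALSE], .name_repair = "minimal")
  names(tab) <- paste0("f", seq_len(ncol(tab)))
  tab <- dplyr::bind_cols(tibble(cell_id = rownames(traces)), tab)
  readr::write_delim(tab, path, delim = delim_for(path))
  if (!is.null(sidecar)) {
    jsonlite::write_json(
      list(frame_rate_hz = frame_rate(traces), dff = isTRUE(attr(traces, "dff"))),
      sidecar, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(traces)
}
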