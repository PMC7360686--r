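#' Delay-scan parameters for connectivity inference
#'
#' Candidate axonal delays and the coincidence window used by
#' [cross_correlation_matrix()]. For each ordered electrode pair the
#' transmitted-spike proportion is evaluated at every delay `tau` on the grid
#' with coincidence window `[tau - delta/2, tau + delta/2]`, and the maximum
#' over the grid is kept. The defaults (1-20 ms in 1-ms steps, delta = 2 ms)
#' cover the conduction delays expected at a 200-um electrode pitch.
#'
#' @param tau_grid_s Candidate delays in seconds, all > 0.
#' @param delta_s Coincidence window width in seconds, > 0.
#' @return A `delay_params` list.
#' @export
delay_params <- function(tau_grid_s = seq(0.001, 0.020, by = 0.001), delta_s = 0.002) {
  if (length(tau_grid_s) < 1 || any(tau_grid_s <= 0)) {
    abort("`tau_grid_s` must be a non-empty vector of positive delays.")
  }
  if (!is.numeric(delta_s) || delta_s <= 0) abort("`delta_s` must be positive.")
  structure(list(tau_grid_s = as.numeric(tau_grid_s), delta_s = as.numeric(delta_s)),
            class = "delay_params")
}

#' Count delayed synchronous spikes between two trains
#'
#' Counts postsynaptic spikes `t_j` for which at least one presynaptic spike
#' `t_i` satisfies `t_j - t_i` in the half-open window
#' `[tau - delta/2, tau + delta/2)`. Each postsynaptic spike is counted at
#' most once, so the count never exceeds the number of postsynaptic spikes:
#' this is the numerator `n_synchr` of the transmitted-spike proportion.
#'
#' The half-open convention makes consecutive windows on a delay grid with
#' step = delta/2-compatible spacing partition the lag axis, so a lag sitting
#' exactly on a window boundary belongs to exactly one side and the
#' maximising delay is unique up to genuine data ties. Boundaries are
#' evaluated with a 1-ns tolerance so that lags formed by subtracting floats
#' (e.g. 0.105 - 0.100) resolve as their real-number values would.
#'
#' @param pre_times,post_times Sorted numeric spike-time vectors (seconds).
#' @param tau_s Candidate axonal delay in seconds.
#' @param delta_s Coincidence window width in seconds.
#' @return Integer count of matched postsynaptic spikes.
#' @examples
#' count_delayed_synchronous(c(0, 0.1, 0.2), c(0.005, 0.105, 0.3),
#'                           tau_s = 0.005, delta_s = 0.002)  # 2
#' @export
count_delayed_synchronous <- function(pre_times, post_times, tau_s, delta_s) {
  if (length(post_times) == 0 || length(pre_times) == 0) return(0L)
  # lag in [tau - d/2 - eps, tau + d/2 - eps)  <=>  pre in (lo, hi] below
  eps <- 1e-9
  hi <- post_times - tau_s + delta_s / 2 + eps
  lo <- post_times - tau_s - delta_s / 2 + eps
  sum(findInterval(hi, pre_times) > findInterval(lo, pre_times))
}

# per-pair scan over the delay grid; returns matched-post-spike count per tau
scan_delays <- function(pre, post, tau_grid, delta) {
  vapply(tau_grid, function(tau) count_delayed_synchronous(pre, post, tau, delta), 0L)
}

#' Delayed-synchrony cross-correlation matrix
#'
#' For every ordered electrode pair (i presynaptic, j postsynaptic) computes
#' the proportion of transmitted spikes
#' \deqn{C_{ij} = n_{synchr,ij} / n_j,}
#' where `n_synchr` is the number of spikes of j preceded by a spike of i at
#' an axonal delay `tau` (within `tau +/- delta/2`) and `n_j` is the total
#' number of spikes received by j. The proportion is maximised over the
#' candidate-delay grid in `params` and the maximising delay is recorded; ties
#' resolve to the smallest delay. Silent electrodes give zero rows and
#' columns (`C_ij` is defined as 0 when `n_j = 0`, flagged via `n_post`).
#'
#' @param raster A [spike_raster()] with at least two declared electrodes.
#' @param params A [delay_params()] object.
#' @param spike_scope Use `"all"` spikes (default) or only spikes inside
#'   detected network-burst extents (`"burst"`, using the default burst
#'   criterion).
#' @return A `connectivity_result`: list with `c_matrix` (n x n, zero
#'   diagonal), `best_tau_s`, `n_synchr` (matrices), `n_post` (per-electrode
#'   received-spike counts), `electrode_ids`, `params` and `spike_scope`.
#' @seealso [select_edges()], [hub_analysis()], [build_graph()]
#' @export
cross_correlation_matrix <- function(raster, params = delay_params(),
                                     spike_scope = c("all", "burst")) {
  spike_scope <- match.arg(spike_scope)
  ids <- electrode_ids(raster)
  n <- length(ids)
  if (n < 2) abort("connectivity needs at least 2 declared electrodes.")
  if (spike_scope == "burst") {
    bursts <- detect_network_bursts(compute_tsr(raster))
    keep <- rep(FALSE, nrow(raster))
    for (b in seq_len(nrow(bursts))) {
      keep <- keep | (raster$spike_time_s >= bursts$start_s[b] &
                        raster$spike_time_s < bursts$end_s[b])
    }
    raster <- spike_raster(as_tibble(raster)[keep, ],
                           duration_s = raster_duration(raster),
                           electrode_ids = ids, metadata = attr(raster, "metadata"))
  }
  tt <- spike_times_list(raster)
  n_post <- lengths(tt)
  tau_grid <- params$tau_grid_s
  delta <- params$delta_s
  c_matrix <- matrix(0, n, n, dimnames = list(ids, ids))
  best_tau <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  n_synchr <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    post <- tt[[j]]
    if (length(post) == 0) next
    for (i in seq_len(n)) {
      if (i == j) next
      pre <- tt[[i]]
      if (length(pre) == 0) next
      counts <- scan_delays(pre, post, tau_grid, delta)
      k <- which.max(counts)
      n_synchr[i, j] <- counts[k]
      c_matrix[i, j] <- counts[k] / length(post)
      best_tau[i, j] <- tau_grid[k]
    }
  }
  structure(
    list(c_matrix = c_matrix, best_tau_s = best_tau, n_synchr = n_synchr,
         n_post = setNames(as.integer(n_post), ids),
         electrode_ids = ids, params = params, spike_scope = spike_scope),
    class = "connectivity_result"
  )
}

#' @export
print.connectivity_result <- function(x, ...) {
  nz <- sum(x$c_matrix > 0)
  cat(sprintf(
    "<connectivity_result> %d electrodes, %d nonzero C_ij (max %.3f), %d delays x delta %.3g s\n",
    length(x$electrode_ids), nz, max(x$c_matrix), length(x$params$tau_grid_s),
    x$params$delta_s
  ))
  invisible(x)
}

#' @describeIn cross_correlation_matrix Long view: one row per ordered
#'   off-diagonal pair with `c_ij`, `best_tau_s`, `n_synchr`, `n_post`.
#' @param x A `connectivity_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.connectivity_result <- function(x, ...) {
  ids <- x$electrode_ids
  grid <- expand.grid(pre = ids, post = ids, stringsAsFactors = FALSE)
  grid <- grid[grid$pre != grid$post, ]
  idx <- cbind(match(grid$pre, ids), match(grid$post, ids))
  out <- tibble(
    pre = grid$pre, post = grid$post,
    c_ij = x$c_matrix[idx],
    best_tau_s = x$best_tau_s[idx],
    n_synchr = x$n_synchr[idx],
    n_post = x$n_post[grid$post]
  )
  dplyr::arrange(out, .data$pre, .data$post)
}

#' @describeIn cross_correlation_matrix One-row summary of the matrix.
#' @exportS3Method generics::glance
glance.connectivity_result <- function(x, ...) {
  off <- x$c_matrix[row(x$c_matrix) != col(x$c_matrix)]
  tibble(
    n_electrodes = length(x$electrode_ids),
    n_pairs = length(off),
    n_nonzero = sum(off > 0),
    mean_c = mean(off),
    max_c = max(off),
    n_silent = sum(x$n_post == 0)
  )
}

#' Select the strongest connections
#'
#' Keeps the largest `fraction` (default 5%) of the off-diagonal `C_ij`
#' coefficients: `k = max(1, floor(fraction * M))` edges over the `M = n(n-1)`
#' ordered pairs. Ties at the cutoff are broken deterministically by higher
#' `n_synchr`, then by lexicographic (src, dst) label. Edges with `C_ij = 0`
#' are never selected, reducing `k` if necessary.
#'
#' @param result A `connectivity_result` from [cross_correlation_matrix()].
#' @param fraction Proportion of ordered pairs to keep.
#' @return A `selected_edges` tibble: `src`, `dst`, `weight` (the `C_ij`),
#'   `tau_s`, `n_synchr`, ordered strongest-first, with attributes `fraction`
#'   and `k_nominal`.
#' @export
select_edges <- function(result, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1].")
  }
  pairs <- tidy(result)
  m <- nrow(pairs)
  k <- max(1L, as.integer(floor(fraction * m)))
  ranked <- dplyr::arrange(pairs, dplyr::desc(.data$c_ij), dplyr::desc(.data$n_synchr),
                           .data$pre, .data$post)
  ranked <- ranked[ranked$c_ij > 0, , drop = FALSE]
  sel <- head(ranked, k)
  structure(
    tibble(src = sel$pre, dst = sel$post, weight = sel$c_ij,
           tau_s = sel$best_tau_s, n_synchr = sel$n_synchr),
    class = c("selected_edges", class(tibble())),
    fraction = fraction, k_nominal = k
  )
}

#' Hub analysis of the selected connections
#'
#' Counts, per electrode, the number of selected connections it takes part in
#' (in-degree plus out-degree) and flags hubs: electrodes with at least
#' `hub_min_connections` significant connections (default 10, the working
#' definition of an active hub in cultured hippocampal networks). Also
#' reports the mean number of connections per hub; when no electrode reaches
#' the hub threshold the mean falls back to the `fallback_top_n` highest-degree
#' connected electrodes, and to 0 when there are no connections at all.
#'
#' @param edges A `selected_edges` tibble from [select_edges()].
#' @param all_nodes Electrode labels to report (keeps isolated electrodes).
#' @param hub_min_connections Minimum connections for hub status.
#' @param fallback_top_n Number of top-degree nodes averaged when no hub
#'   qualifies.
#' @return A `hub_table` tibble with `electrode_id`, `n_connections`,
#'   `is_hub`, sorted by decreasing degree, with attributes
#'   `mean_hub_connections` and `hub_min_connections`. See
#'   [mean_hub_connections()].
#' @export
hub_analysis <- function(edges, all_nodes, hub_min_connections = 10,
                         fallback_top_n = 5) {
  all_nodes <- as.character(all_nodes)
  deg <- table(factor(c(edges$src, edges$dst), levels = all_nodes))
  out <- tibble(
    electrode_id = all_nodes,
    n_connections = as.integer(deg),
    is_hub = as.integer(deg) >= hub_min_connections
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$n_connections), .data$electrode_id)
  mean_hub <- if (any(out$is_hub)) {
    mean(out$n_connections[out$is_hub])
  } else if (any(out$n_connections > 0)) {
    mean(head(out$n_connections[out$n_connections > 0], fallback_top_n))
  } else {
    0
  }
  structure(
    out,
    class = c("hub_table", class(tibble())),
    mean_hub_connections = mean_hub,
    hub_min_connections = hub_min_connections
  )
}

#' @describeIn hub_analysis The mean number of connections per hub carried by
#'   a `hub_table`.
#' @param hub_table A `hub_table`.
#' @export
mean_hub_connections <- function(hub_table) attr(hub_table, "mean_hub_connections")

#' @describeIn hub_analysis One-row hub summary.
#' @param x A `hub_table`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.hub_table <- function(x, ...) {
  tibble(
    n_nodes = nrow(x),
    n_hubs = sum(x$is_hub),
    mean_hub_connections = attr(x, "mean_hub_connections"),
    max_connections = if (nrow(x) > 0) max(x$n_connections) else NA_integer_
  )
}

#' Build the functional graph
#'
#' Assembles the [functional_graph()] of a recording from a connectivity
#' result and its selected edges: every electrode becomes a node (isolated
#' electrodes retained) with its significant-connection count, matching
#' [hub_analysis()] exactly; edges carry the connection weight `C_ij` and the
#' maximising delay.
#'
#' @param result A `connectivity_result`.
#' @param edges A `selected_edges` tibble; defaults to [select_edges()] at the
#'   5% fraction.
#' @return A [functional_graph()].
#' @export
build_graph <- function(result, edges = select_edges(result)) {
  ids <- result$electrode_ids
  deg <- table(factor(c(edges$src, edges$dst), levels = ids))
  functional_graph(
    nodes = tibble(electrode_id = ids, n_connections = as.integer(deg)),
    edges = tibble(src = edges$src, dst = edges$dst,
                   weight = edges$weight, tau_s = edges$tau_s)
  )
}
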