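#' Planted hub-network specification for synthetic MEA recordings
#'
#' Describes the generative model behind a synthetic MEA recording: a small
#' set of hub electrodes initiates network bursts (Poisson in time); each
#' initiation emits a regular spike packet at the hub; every spike at
#' electrode i triggers a spike at electrode j with probability `w_ij` after
#' the axonal delay `tau_ij` plus Gaussian jitter (one synaptic hop by
#' default); independent Poisson background firing is added on every
#' electrode.
#'
#' The wiring can be given explicitly (`adjacency`, `delays`, `hub_ids`) or
#' sampled at generation time from the summary parameters: `n_hubs` hubs each
#' wired to `hub_out_degree` followers drawn disjointly from the non-hub
#' electrodes (so no follower listens to two hubs, which keeps the planted
#' connections separable), with uniform transmission probability `w` and
#' per-edge delays uniform in `delay_range_s`.
#'
#' @param n_electrodes Number of electrodes (default 59).
#' @param n_hubs Number of planted hubs.
#' @param hub_out_degree Followers per hub.
#' @param w Transmission probability on each planted edge, in `[0, 1]`.
#' @param delay_range_s Range the per-edge axonal delays are drawn from.
#' @param jitter_sd_s SD of the Gaussian jitter added to each transmitted
#'   spike's delay.
#' @param background_rate_hz Per-electrode homogeneous Poisson background
#'   rate.
#' @param burst_rate_per_min Burst-initiation rate per hub, per minute.
#' @param packet_n_spikes Spikes in one initiation packet.
#' @param packet_interval_s Interval between packet spikes.
#' @param multi_hop Should transmitted spikes re-propagate? Default `FALSE`.
#' @param background_transmits Should isolated background spikes also
#'   propagate along the planted edges? Default `FALSE`: network recruitment
#'   is a property of burst packets, and a transmitting background would add
#'   one extra mini-burst per hub background spike, inflating the calibrated
#'   burst rate.
#' @param electrode_ids Optional electrode labels (default `el_01 ...`).
#' @param hub_ids,adjacency,delays Optional explicit wiring: hub labels, an
#'   `n x n` matrix of transmission probabilities, and a matching matrix of
#'   positive delays (seconds).
#' @param initiation_times Optional named list (hub id -> numeric times)
#'   overriding the Poisson burst initiations; useful for deterministic
#'   checks.
#' @return A `network_spec` list.
#' @seealso [generate_mea_recording()], [condition_preset()]
#' @export
network_spec <- function(n_electrodes = 59, n_hubs = 5, hub_out_degree = 10,
                         w = 0.8, delay_range_s = c(0.002, 0.010),
                         jitter_sd_s = 0.001, background_rate_hz = 0.2,
                         burst_rate_per_min = 8.7, packet_n_spikes = 10,
                         packet_interval_s = 0.005, multi_hop = FALSE,
                         background_transmits = FALSE,
                         electrode_ids = NULL, hub_ids = NULL,
                         adjacency = NULL, delays = NULL,
                         initiation_times = NULL) {
  electrode_ids <- as.character(
    electrode_ids %||% sprintf("el_%02d", seq_len(n_electrodes))
  )
  n_electrodes <- length(electrode_ids)
  if (!is.null(adjacency)) {
    if (!all(dim(adjacency) == n_electrodes)) abort("`adjacency` must be n x n.")
    if (any(adjacency < 0 | adjacency > 1)) abort("`adjacency` entries must be in [0, 1].")
    if (is.null(delays) || !all(dim(delays) == dim(adjacency))) {
      abort("explicit `adjacency` needs a matching `delays` matrix.")
    }
    if (any(delays[adjacency > 0] <= 0)) abort("delays on planted edges must be > 0.")
    dimnames(adjacency) <- dimnames(delays) <- list(electrode_ids, electrode_ids)
  }
  if (!is.null(hub_ids) && !all(hub_ids %in% electrode_ids)) {
    abort("`hub_ids` must be a subset of the electrode set.")
  }
  if (w < 0 || w > 1) abort("`w` must be in [0, 1].")
  if (background_rate_hz < 0 || burst_rate_per_min < 0) abort("rates must be >= 0.")
  if (jitter_sd_s < 0) abort("`jitter_sd_s` must be >= 0.")
  if (any(delay_range_s <= 0) || delay_range_s[2] < delay_range_s[1]) {
    abort("`delay_range_s` must be positive and increasing.")
  }
  structure(
    list(
      n_electrodes = n_electrodes, electrode_ids = electrode_ids,
      n_hubs = n_hubs, hub_out_degree = hub_out_degree, w = w,
      delay_range_s = delay_range_s, jitter_sd_s = jitter_sd_s,
      background_rate_hz = background_rate_hz,
      burst_rate_per_min = burst_rate_per_min,
      packet_n_spikes = packet_n_spikes, packet_interval_s = packet_interval_s,
      multi_hop = multi_hop, background_transmits = background_transmits,
      hub_ids = hub_ids,
      adjacency = adjacency, delays = delays,
      initiation_times = initiation_times
    ),
    class = "network_spec"
  )
}

# deterministic sub-seed derivation so each random component owns a stream
# and results do not depend on iteration order; kept below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919 + 12345) %% 2147483647)
}

# materialize hub wiring: disjoint follower sets, uniform delays
materialize_wiring <- function(spec, seed) {
  ids <- spec$electrode_ids
  n <- length(ids)
  if (!is.null(spec$adjacency)) {
    adj <- spec$adjacency
    del <- spec$delays
    hubs <- spec$hub_ids %||% ids[rowSums(adj > 0) > 0]
    return(list(adjacency = adj, delays = del, hub_ids = hubs))
  }
  set.seed(sub_seed(seed, 1))
  n_hubs <- spec$n_hubs
  deg <- spec$hub_out_degree
  if (n_hubs * deg > n - n_hubs) {
    abort("cannot wire disjoint followers: n_hubs * hub_out_degree exceeds non-hub electrodes.")
  }
  hubs <- spec$hub_ids %||% sample(ids, n_hubs)
  followers <- sample(setdiff(ids, hubs), n_hubs * deg)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  del <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (h in seq_len(n_hubs)) {
    fs <- followers[((h - 1) * deg + 1):(h * deg)]
    adj[hubs[h], fs] <- spec$w
    del[hubs[h], fs] <- runif(deg, spec$delay_range_s[1], spec$delay_range_s[2])
  }
  list(adjacency = adj, delays = del, hub_ids = hubs)
}

#' Generate a synthetic MEA recording with planted connectivity
#'
#' Simulates a spike raster from a [network_spec()]: Poisson burst
#' initiations at each hub emit regular spike packets; spikes propagate along
#' the planted edges with the edge's transmission probability, delay and
#' jitter (single hop unless `multi_hop`); homogeneous Poisson background
#' firing is added everywhere. Spikes that would land past the recording end
#' are truncated. All randomness derives from `seed` through per-component
#' sub-streams, so identical `(spec, duration_s, seed)` give bit-identical
#' output.
#'
#' @param spec A [network_spec()].
#' @param duration_s Recording length in seconds.
#' @param seed Integer seed.
#' @return A list with `raster` (a [spike_raster()]) and `truth`: the planted
#'   `hub_ids`, `adjacency`, `delays`, the planted edge table
#'   (`src, dst, w, delay_s`), and the burst `initiations`
#'   (tibble `hub, t_s`).
#' @export
generate_mea_recording <- function(spec, duration_s = 300, seed = 1) {
  if (!inherits(spec, "network_spec")) abort("`spec` must be a network_spec.")
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  ids <- spec$electrode_ids
  n <- length(ids)
  wiring <- materialize_wiring(spec, seed)
  adj <- wiring$adjacency
  del <- wiring$delays
  hubs <- wiring$hub_ids

  # burst initiations and hub packets
  init <- purrr::map_dfr(seq_along(hubs), function(hi) {
    h <- hubs[hi]
    t0 <- if (!is.null(spec$initiation_times)) {
      as.numeric(spec$initiation_times[[h]] %||% numeric(0))
    } else {
      set.seed(sub_seed(seed, 100 + match(h, ids)))
      n_ev <- rpois(1, spec$burst_rate_per_min / 60 * duration_s)
      sort(runif(n_ev, 0, duration_s))
    }
    if (length(t0) == 0) return(NULL)
    tibble(hub = h, t_s = t0)
  })
  if (nrow(init) == 0) init <- tibble(hub = character(), t_s = numeric())

  packet_offsets <- (seq_len(spec$packet_n_spikes) - 1) * spec$packet_interval_s
  packets <- lapply(setNames(vector("list", n), ids), function(x) numeric(0))
  for (h in unique(init$hub)) {
    tt <- as.vector(outer(packet_offsets, init$t_s[init$hub == h], `+`))
    packets[[h]] <- sort(tt[tt <= duration_s])
  }

  # background firing, one Poisson stream per electrode; background spikes
  # do not recruit the network unless background_transmits is set
  background <- lapply(setNames(vector("list", n), ids), function(x) numeric(0))
  for (e in seq_len(n)) {
    if (spec$background_rate_hz > 0) {
      set.seed(sub_seed(seed, 1000 + e))
      n_bg <- rpois(1, spec$background_rate_hz * duration_s)
      background[[e]] <- sort(runif(n_bg, 0, duration_s))
    }
  }

  # propagation: generation 0 = packet spikes (plus background if it
  # transmits); transmitted spikes re-enter the queue only under multi_hop
  edges <- which(adj > 0, arr.ind = TRUE)
  transmitted <- lapply(setNames(vector("list", n), ids), function(x) numeric(0))
  queue <- if (isTRUE(spec$background_transmits)) {
    lapply(seq_len(n), function(e) sort(c(packets[[e]], background[[e]])))
  } else {
    packets
  }
  hop <- 0L
  while (any(lengths(queue) > 0)) {
    nxt <- lapply(setNames(vector("list", n), ids), function(x) numeric(0))
    if (nrow(edges) > 0) {
      for (k in seq_len(nrow(edges))) {
        i <- edges[k, 1]; j <- edges[k, 2]
        src <- queue[[i]]
        if (length(src) == 0) next
        set.seed(sub_seed(seed, 10000 + hop * 4000 + (i - 1) * 59 + j))
        fired <- runif(length(src)) < adj[i, j]
        if (!any(fired)) next
        tt <- src[fired] + del[i, j] + rnorm(sum(fired), 0, spec$jitter_sd_s)
        tt <- tt[tt >= 0 & tt <= duration_s]
        nxt[[j]] <- c(nxt[[j]], tt)
      }
    }
    for (e in seq_len(n)) transmitted[[e]] <- c(transmitted[[e]], nxt[[e]])
    hop <- hop + 1L
    if (!spec$multi_hop || hop > 25L) break
    queue <- nxt
  }

  spikes <- purrr::map_dfr(ids, function(e) {
    tt <- sort(c(packets[[e]], background[[e]], transmitted[[e]]))
    if (length(tt) == 0) return(NULL)
    tibble(electrode_id = e, spike_time_s = tt)
  })
  if (nrow(spikes) == 0) {
    spikes <- tibble(electrode_id = character(), spike_time_s = numeric())
  }
  raster <- spike_raster(spikes, duration_s = duration_s, electrode_ids = ids,
                         metadata = recording_metadata())
  edge_tbl <- if (nrow(edges) > 0) {
    tibble(src = ids[edges[, 1]], dst = ids[edges[, 2]],
           w = adj[edges], delay_s = del[edges])
  } else {
    tibble(src = character(), dst = character(), w = numeric(), delay_s = numeric())
  }
  list(
    raster = raster,
    truth = list(
      hub_ids = hubs, adjacency = adj, delays = del,
      edges = dplyr::arrange(edge_tbl, .data$src, .data$dst),
      initiations = init
    )
  )
}
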