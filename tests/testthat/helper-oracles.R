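# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain loops so the package implementations are checked
# against a second, slower route.

# burst detection oracle: test every bin, then merge contiguous runs by
# walking the bin sequence once
oracle_bursts <- function(binned, min_spikes = 4, min_electrodes = 4) {
  qual <- logical(nrow(binned))
  for (b in seq_len(nrow(binned))) {
    qual[b] <- binned$tsr[b] >= min_spikes && binned$active_electrodes[b] >= min_electrodes
  }
  out <- list()
  b <- 1
  while (b <= length(qual)) {
    if (qual[b]) {
      e <- b
      while (e < length(qual) && qual[e + 1]) e <- e + 1
      peak <- max(binned$tsr[b:e])
      out[[length(out) + 1]] <- data.frame(
        start_bin = b, end_bin = e,
        total_spikes = sum(binned$tsr[b:e]),
        peak_bin_spikes = peak,
        size_class = if (peak >= 101) "large" else "small"
      )
      b <- e + 1
    } else {
      b <- b + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(start_bin = integer(), end_bin = integer(),
                      total_spikes = integer(), peak_bin_spikes = integer(),
                      size_class = character()))
  }
  do.call(rbind, out)
}

# delayed-synchrony oracle: explicit double loop over (post, pre) spikes,
# same half-open window convention with the 1-ns boundary tolerance
oracle_count_synchr <- function(pre, post, tau, delta) {
  n <- 0L
  for (tj in post) {
    hit <- FALSE
    for (ti in pre) {
      lag <- tj - ti
      if (lag >= tau - delta / 2 - 1e-9 && lag < tau + delta / 2 - 1e-9) hit <- TRUE
    }
    if (hit) n <- n + 1L
  }
  n
}

# full C matrix oracle: triple loop over (pair, tau); returns list of matrices
oracle_cc_matrix <- function(raster, tau_grid, delta) {
  ids <- electrode_ids(raster)
  tt <- spike_times_list(raster)
  n <- length(ids)
  cmat <- matrix(0, n, n, dimnames = list(ids, ids))
  btau <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || length(tt[[j]]) == 0 || length(tt[[i]]) == 0) next
      best <- 0L
      best_tau <- NA_real_
      for (tau in tau_grid) {
        cnt <- oracle_count_synchr(tt[[i]], tt[[j]], tau, delta)
        if (cnt > best) {
          best <- cnt
          best_tau <- tau
        }
      }
      if (best > 0) {
        cmat[i, j] <- best / length(tt[[j]])
        btau[i, j] <- best_tau
      } else if (length(tt[[i]]) > 0) {
        btau[i, j] <- tau_grid[1]
      }
    }
  }
  list(c_matrix = cmat, best_tau_s = btau)
}

# random test raster with mixed firing rates
random_raster <- function(seed, n_electrodes = NULL, duration_s = NULL) {
  set.seed(seed)
  n_el <- n_electrodes %||% sample(2:10, 1)
  dur <- duration_s %||% runif(1, 5, 60)
  ids <- paste0("e", seq_len(n_el))
  rates <- runif(n_el, 0, 8)
  spikes <- do.call(rbind, lapply(seq_len(n_el), function(e) {
    k <- rpois(1, rates[e] * dur)
    if (k == 0) return(NULL)
    data.frame(electrode_id = ids[e], spike_time_s = sort(runif(k, 0, dur)))
  }))
  if (is.null(spikes)) {
    spikes <- data.frame(electrode_id = character(), spike_time_s = numeric())
  }
  spike_raster(spikes, duration_s = dur, electrode_ids = ids)
}

`%||%` <- rlang::`%||%`
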