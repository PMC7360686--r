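#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the groups to process (preset
#' tokens for simulation, or explicit input files), replicate count, analysis
#' parameters and the output directory. All analysis parameters default to
#' the standard values used throughout the package.
#'
#' @param groups Character vector of [condition_preset()] tokens, or a named
#'   list whose elements are either a token string or a list with fields
#'   `spike_tables` and/or `trace_matrices` (paths to existing recordings).
#' @param out_dir Output directory (created if missing).
#' @param n_replicates Simulated recordings per group (ignored for file
#'   inputs).
#' @param duration_s Simulated recording length in seconds.
#' @param seed Master seed; every replicate derives its own sub-seed.
#' @param analyses Which branches to run: `"mea"`, `"calcium"` or both.
#' @param bin_width_s,min_spikes,min_electrodes Burst-detection parameters.
#' @param params Connectivity [delay_params()].
#' @param top_fraction Edge-selection fraction.
#' @param hub_min_connections Hub threshold.
#' @param threshold_sd,min_duration_s Calcium event-detection parameters.
#' @param n_cells Cells per simulated calcium recording.
#' @return A `run_config` list.
#' @export
run_config <- function(groups, out_dir, n_replicates = 3, duration_s = 300,
                       seed = 1, analyses = c("mea", "calcium"),
                       bin_width_s = 0.05, min_spikes = 4, min_electrodes = 4,
                       params = delay_params(), top_fraction = 0.05,
                       hub_min_connections = 10, threshold_sd = 2.5,
                       min_duration_s = 1.0, n_cells = 100) {
  if (is.character(groups)) {
    groups <- setNames(as.list(groups), groups)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be named (or a character vector of preset tokens).")
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(
    list(groups = groups, out_dir = out_dir, n_replicates = n_replicates,
         duration_s = duration_s, seed = seed, analyses = analyses,
         bin_width_s = bin_width_s, min_spikes = min_spikes,
         min_electrodes = min_electrodes, params = params,
         top_fraction = top_fraction, hub_min_connections = hub_min_connections,
         threshold_sd = threshold_sd, min_duration_s = min_duration_s,
         n_cells = n_cells),
    class = "run_config"
  )
}

stage <- function(name, id, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed for '%s': %s", name, id,
                  conditionMessage(e)))
  })
}

analyze_recording_mea <- function(raster, config) {
  binned <- compute_tsr(raster, config$bin_width_s)
  bursts <- detect_network_bursts(binned, config$min_spikes, config$min_electrodes)
  bsum <- summarize_bursts(bursts)
  conn <- cross_correlation_matrix(raster, config$params)
  edges <- select_edges(conn, config$top_fraction)
  hubs <- hub_analysis(edges, conn$electrode_ids, config$hub_min_connections)
  graph <- build_graph(conn, edges)
  list(binned = binned, bursts = bursts, burst_summary = bsum, connectivity = conn,
       edges = edges, hubs = hubs, graph = graph)
}

#' Run the full analysis pipeline
#'
#' For every group and replicate: simulate (or load) the recording, run burst
#' detection and summary, connectivity inference with edge selection, hub
#' analysis and graph construction, and calcium event detection and summary;
#' write per-recording artifacts (spike table, burst table, graph, JSON
#' summaries) under `out_dir/<group>/rep_<i>/`; aggregate per group as
#' mean +/- SEM and write `group_summary.tsv`, `recordings.tsv` and a
#' `manifest.json` with a checksum per artifact and the exact configuration
#' echoed. Inferential group testing is deliberately left to external tools —
#' the aggregate table is the tidy input for it. Deterministic given
#' `config$seed`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `recordings` (per-recording tibble),
#'   `groups` (per-group mean/SEM tibble) and `manifest` (file table).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must come from run_config().")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rec_rows <- list()
  files <- character(0)
  emit <- function(path) { files[[length(files) + 1]] <<- path; path }
  g_i <- 0L
  for (gname in names(config$groups)) {
    g_i <- g_i + 1L
    gdef <- config$groups[[gname]]
    is_preset <- is.character(gdef) && length(gdef) == 1
    n_rep <- if (is_preset) config$n_replicates else {
      max(length(gdef$spike_tables %||% character(0)),
          length(gdef$trace_matrices %||% character(0)))
    }
    for (r in seq_len(n_rep)) {
      rec_id <- sprintf("%s/rep_%d", gname, r)
      rec_dir <- file.path(config$out_dir, gname, sprintf("rep_%d", r))
      dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
      rec_seed <- sub_seed(config$seed, g_i * 1000 + r)
      row <- tibble(group = gname, replicate = r, seed = rec_seed)

      if ("mea" %in% config$analyses) {
        raster <- stage("input_mea", rec_id, {
          if (is_preset) {
            sim <- generate_mea_recording(condition_preset(gdef)$network,
                                          duration_s = config$duration_s,
                                          seed = rec_seed)
            sim$raster
          } else if (!is.null(gdef$spike_tables)) {
            read_spike_table(gdef$spike_tables[[r]])
          } else {
            NULL
          }
        })
        if (!is.null(raster)) {
          res <- stage("mea_analysis", rec_id, analyze_recording_mea(raster, config))
          write_spike_table(raster, emit(file.path(rec_dir, "raster.tsv")))
          emit(file.path(rec_dir, "raster.tsv.json"))
          readr::write_tsv(as_tibble(res$bursts), emit(file.path(rec_dir, "bursts.tsv")))
          readr::write_tsv(as_tibble(res$hubs), emit(file.path(rec_dir, "hubs.tsv")))
          write_graph(res$graph, emit(file.path(rec_dir, "graph.edgelist")), "edgelist")
          write_graph(res$graph, emit(file.path(rec_dir, "graph.graphml")), "graphml")
          jsonlite::write_json(as.list(res$burst_summary),
                               emit(file.path(rec_dir, "burst_summary.json")),
                               auto_unbox = TRUE, digits = NA)
          row <- dplyr::bind_cols(row, as_tibble(res$burst_summary)[
            , c("n_small_per_5min", "n_large_per_10min", "mean_spikes_per_burst")],
            tibble(mean_hub_connections = mean_hub_connections(res$hubs),
                   n_hubs = sum(res$hubs$is_hub)))
        }
      }

      if ("calcium" %in% config$analyses) {
        traces <- stage("input_calcium", rec_id, {
          if (is_preset) {
            generate_calcium_traces(condition_preset(gdef, n_cells = config$n_cells)$calcium,
                                    duration_s = config$duration_s,
                                    seed = rec_seed)$traces
          } else if (!is.null(gdef$trace_matrices)) {
            read_trace_matrix(gdef$trace_matrices[[r]])
          } else {
            NULL
          }
        })
        if (!is.null(traces)) {
          csum <- stage("calcium_analysis", rec_id, {
            ev <- detect_events(compute_dff(traces),
                                threshold_sd = config$threshold_sd,
                                min_duration_s = config$min_duration_s)
            readr::write_tsv(as_tibble(ev), emit(file.path(rec_dir, "ca_events.tsv")))
            summarize_calcium(ev)
          })
          jsonlite::write_json(as.list(csum),
                               emit(file.path(rec_dir, "ca_summary.json")),
                               auto_unbox = TRUE, digits = NA)
          row <- dplyr::bind_cols(row, as_tibble(csum)[
            , c("pct_active", "mean_rate_per_min", "mean_duration_s")])
        }
      }
      rec_rows[[rec_id]] <- row
    }
  }
  recordings <- dplyr::bind_rows(rec_rows)
  metric_cols <- setdiff(names(recordings), c("group", "replicate", "seed"))
  groups <- recordings |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  readr::write_tsv(recordings, emit(file.path(config$out_dir, "recordings.tsv")))
  readr::write_tsv(groups, emit(file.path(config$out_dir, "group_summary.tsv")))
  manifest <- tibble(
    path = vapply(files, identity, ""),
    md5 = unname(tools::md5sum(vapply(files, identity, "")))
  )
  cfg_echo <- config
  cfg_echo$groups <- lapply(config$groups, function(g) if (is.character(g)) g else "files")
  jsonlite::write_json(
    list(config = cfg_echo, files = manifest),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  invisible(list(recordings = recordings, groups = groups, manifest = manifest))
}

#' Render figures for a completed pipeline run
#'
#' Walks the recording folders of a [run_pipeline()] output directory and
#' writes, per recording, a raster + TSR panel and a functional-graph panel
#' (PNG). Figure layout uses a fixed seed, so regeneration is deterministic.
#'
#' @param out_dir The pipeline output directory.
#' @param layout_seed Seed for graph layouts.
#' @param width,height,dpi Figure geometry passed to [ggplot2::ggsave()].
#' @return Character vector of written figure paths, invisibly.
#' @export
render_figures <- function(out_dir, layout_seed = 42, width = 7, height = 5, dpi = 150) {
  rasters <- list.files(out_dir, pattern = "^raster\\.tsv$", recursive = TRUE,
                        full.names = TRUE)
  written <- character(0)
  for (rp in rasters) {
    rec_dir <- dirname(rp)
    raster <- read_spike_table(rp)
    f1 <- file.path(rec_dir, "raster_tsr.png")
    ggplot2::ggsave(f1, plot_recording(raster), width = width, height = height,
                    dpi = dpi)
    written <- c(written, f1)
    gp <- file.path(rec_dir, "graph.edgelist")
    if (file.exists(gp)) {
      f2 <- file.path(rec_dir, "graph.png")
      ggplot2::ggsave(f2, autoplot(read_graph(gp, "edgelist"), layout_seed = layout_seed),
                      width = width, height = height, dpi = dpi)
      written <- c(written, f2)
    }
  }
  invisible(written)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
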