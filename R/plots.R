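#' Raster and total-spiking-rate panel for one recording
#'
#' The standard view of an MEA recording: spike raster (one row per
#' electrode) above the total spiking rate per 50-ms bin, sharing the time
#' axis. Empty recordings give a valid empty panel.
#'
#' @param raster A [spike_raster()].
#' @param bin_width_s Bin width for the TSR trace.
#' @return A ggplot object with a raster facet and a TSR facet.
#' @export
plot_recording <- function(raster, bin_width_s = 0.05) {
  ids <- electrode_ids(raster)
  binned <- compute_tsr(raster, bin_width_s)
  raster_df <- tibble(
    time_s = raster$spike_time_s,
    y = match(raster$electrode_id, ids),
    panel = "raster"
  )
  tsr_df <- tibble(time_s = binned$t_start, y = binned$tsr, panel = "spikes / bin")
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$time_s, y = .data$y)) +
    ggplot2::geom_point(data = raster_df, shape = "|", size = 1.2) +
    ggplot2::geom_step(data = tsr_df) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%d electrodes, %d spikes", length(ids), nrow(raster))) +
    ggplot2::xlim(0, raster_duration(raster)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_recording TSR trace of pre-binned activity.
#' @param object A `binned_activity` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.binned_activity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_start, y = .data$tsr)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = sprintf("spikes / %g ms bin", 1000 * attr(object, "bin_width_s"))) +
    ggplot2::theme_minimal()
}

#' Functional-graph panel
#'
#' Renders a [functional_graph()] in the style used for cultured-network
#' connectivity figures: vertex size proportional to the number of
#' significant connections, vertices labelled `Cell X [n]` with the
#' connection count in brackets, directed edges shaded by their `C_ij`
#' weight. The layout is Fruchterman-Reingold with a fixed seed so
#' regeneration is deterministic.
#'
#' @param object A [functional_graph()].
#' @param layout_seed Seed for the graph layout.
#' @param label_all Label every vertex (default labels only connected ones).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.functional_graph <- function(object, layout_seed = 42, label_all = FALSE, ...) {
  g <- as_igraph(object)
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  nodes$label <- sprintf("Cell %s [%d]", nodes$electrode_id, nodes$n_connections)
  edges <- object$edges
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    seg <- dplyr::left_join(edges, nodes[, c("electrode_id", "x", "y")],
                            by = c("src" = "electrode_id"))
    seg <- dplyr::left_join(seg, nodes[, c("electrode_id", "x", "y")],
                            by = c("dst" = "electrode_id"), suffix = c("", "_end"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end, yend = .data$y_end,
                   alpha = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")), colour = "grey30"
    )
  }
  lab <- if (label_all) nodes else nodes[nodes$n_connections > 0, ]
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_connections),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1, size = 2.6
    ) +
    ggplot2::scale_size_continuous(range = c(1, 8)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "connections", alpha = "C_ij")
}

#' @describeIn autoplot.functional_graph Overlay of dF/F traces with a
#'   vertical offset per cell; at most `max_cells` cells are shown.
#' @param max_cells Maximum number of traces drawn.
#' @exportS3Method ggplot2::autoplot
autoplot.calcium_traces <- function(object, max_cells = 20, ...) {
  keep <- head(seq_len(nrow(object)), max_cells)
  long <- tidy(object)
  long <- long[long$cell_id %in% rownames(object)[keep], ]
  offset_unit <- max(diff(range(long$value)), 1e-9)
  long$offset <- (match(long$cell_id, rownames(object)) - 1) * offset_unit
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value + .data$offset,
                                     group = .data$cell_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (offset per cell)") +
    ggplot2::theme_minimal()
}
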