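#' Functional graph objects
#'
#' The functional graph of a recording: nodes are all electrodes (isolated
#' ones included), each carrying its number of significant connections
#' (in-degree + out-degree over the selected edge set); directed edges carry
#' the connectivity weight `C_ij` in `[0, 1]` and the best axonal delay
#' `tau_s`. When rendered, vertex size is proportional to the connection
#' count.
#'
#' @param nodes Tibble with columns `electrode_id` and `n_connections`.
#' @param edges Tibble with columns `src`, `dst`, `weight`, `tau_s`.
#' @return A `functional_graph` (list with `nodes` and `edges` tibbles).
#' @seealso [build_graph()], [write_graph()], [as_igraph()]
#' @export
functional_graph <- function(nodes, edges = NULL) {
  nodes <- as_tibble(nodes)
  if (!all(c("electrode_id", "n_connections") %in% names(nodes))) {
    abort("`nodes` needs columns electrode_id, n_connections.")
  }
  nodes$electrode_id <- as.character(nodes$electrode_id)
  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    edges <- tibble(src = character(), dst = character(),
                    weight = numeric(), tau_s = numeric())
  }
  edges <- as_tibble(edges)
  if (!all(c("src", "dst", "weight", "tau_s") %in% names(edges))) {
    abort("`edges` needs columns src, dst, weight, tau_s.")
  }
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  stray <- setdiff(c(edges$src, edges$dst), nodes$electrode_id)
  if (length(stray) > 0) {
    abort(paste0("edges reference unknown node(s): ", paste(head(stray, 5), collapse = ", ")))
  }
  if (any(edges$weight < 0 | edges$weight > 1)) {
    abort("edge weights must lie in [0, 1].")
  }
  deg <- table(factor(c(edges$src, edges$dst), levels = nodes$electrode_id))
  if (!all(nodes$n_connections == as.integer(deg))) {
    abort("node n_connections must equal in+out degree over `edges`.")
  }
  structure(list(nodes = nodes, edges = edges), class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @describeIn functional_graph Convert to an igraph graph (directed; vertex
#'   attribute `n_connections`, edge attributes `weight`, `tau_s`).
#' @param graph A `functional_graph`.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = graph$edges, directed = TRUE,
    vertices = as.data.frame(graph$nodes)
  )
}

#' @describeIn functional_graph Edge table, one row per directed connection.
#' @param x A `functional_graph`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.functional_graph <- function(x, ...) x$edges

#' @describeIn functional_graph One-row graph summary (node, edge and hub
#'   counts, mean weight).
#' @exportS3Method generics::glance
glance.functional_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_connected = sum(x$nodes$n_connections > 0),
    mean_weight = if (nrow(x$edges) > 0) mean(x$edges$weight) else NA_real_,
    max_connections = if (nrow(x$nodes) > 0) max(x$nodes$n_connections) else NA_integer_
  )
}

#' Serialize functional graphs
#'
#' Two plain-text formats: `"edgelist"` is a line-oriented format with a node
#' section (`node <id> <n_connections>`, which keeps isolated electrodes) and
#' an edge section (`edge <src> <dst> <weight> <tau_s>`); `"graphml"` uses
#' igraph's GraphML writer. Both round-trip all node and edge attributes.
#'
#' @param graph A [functional_graph()].
#' @param path Output (input) file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `write_graph()` its input invisibly; `read_graph()` a
#'   [functional_graph()].
#' @export
write_graph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort("`format` must be \"edgelist\" or \"graphml\".")
  })
  if (format == "edgelist") {
    lines <- c(
      "# functional graph: node <id> <n_connections>; edge <src> <dst> <weight> <tau_s>",
      sprintf("node %s %d", graph$nodes$electrode_id, graph$nodes$n_connections),
      if (nrow(graph$edges) > 0) {
        sprintf("edge %s %s %.17g %.17g", graph$edges$src, graph$edges$dst,
                graph$edges$weight, graph$edges$tau_s)
      }
    )
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  }
  invisible(graph)
}

#' @rdname write_graph
#' @export
read_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort("`format` must be \"edgelist\" or \"graphml\".")
  })
  if (format == "edgelist") {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    parts <- strsplit(trimws(lines), "\\s+")
    kind <- vapply(parts, `[[`, "", 1)
    bad <- which(!kind %in% c("node", "edge"))
    if (length(bad) > 0) {
      abort(sprintf("Malformed graph line %d in %s.", bad[1], path))
    }
    nodes <- purrr::map_dfr(parts[kind == "node"], function(p) {
      tibble(electrode_id = p[2], n_connections = as.integer(p[3]))
    })
    edges <- purrr::map_dfr(parts[kind == "edge"], function(p) {
      tibble(src = p[2], dst = p[3], weight = as.numeric(p[4]), tau_s = as.numeric(p[5]))
    })
    if (nrow(nodes) == 0) nodes <- tibble(electrode_id = character(), n_connections = integer())
    functional_graph(nodes, edges)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(
      electrode_id = igraph::vertex_attr(g, "name"),
      n_connections = as.integer(igraph::vertex_attr(g, "n_connections"))
    )
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble(src = ed$from, dst = ed$to,
                    weight = as.numeric(ed$weight), tau_s = as.numeric(ed$tau_s))
    functional_graph(nodes, edges)
  }
}
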