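# Graph readers/writers: edge-list TSV and GraphML. Round trips preserve
# node ids and the edge set exactly; edge correlations are written at full
# precision.

#' Write a cell graph as an edge-list TSV
#'
#' Columns: `cell_i`, `cell_j` and (when present) the edge correlation `r`.
#' Isolated nodes are preserved through a header comment listing all node
#' ids, so a write/read round trip reproduces the full vertex set.
#'
#' @param graph Undirected simple `igraph` graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  graph <- check_cell_graph(graph)
  tab <- as_edge_tibble(graph)
  if ("r" %in% names(tab)) {
    tab$r <- sprintf("%.17g", tab$r)
  }
  header <- paste0("# nodes: ", paste(igraph::V(graph)$name, collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab)) {
    writeLines(do.call(paste, c(unname(as.list(tab)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a cell graph from an edge-list TSV
#'
#' @param path Path written by [write_edge_list()], or any TSV with
#'   `cell_i`/`cell_j` columns (a `# nodes:` comment, if present, fixes the
#'   vertex set).
#' @return An undirected simple `igraph` graph.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("Edge list not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nodes <- NULL
  if (length(lines) && startsWith(lines[1L], "# nodes:")) {
    nodes <- strsplit(sub("^# nodes: ?", "", lines[1L]), "\t")[[1L]]
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) abort(sprintf("Malformed edge list (no header): %s", path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(c("cell_i", "cell_j") %in% header)) {
    abort(sprintf("Malformed edge list header at line 1 of %s", path))
  }
  body <- lines[-1L]
  ei <- character(0); ej <- character(0); rr <- numeric(0)
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header)) {
      abort(sprintf("Malformed edge list line %d in %s", k + 1L, path))
    }
    ei <- c(ei, f[match("cell_i", header)])
    ej <- c(ej, f[match("cell_j", header)])
    if ("r" %in% header) rr <- c(rr, as.numeric(f[match("r", header)]))
  }
  nodes <- nodes %||% unique(c(ei, ej))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(ei)) {
    g <- igraph::add_edges(g, rbind(match(ei, nodes), match(ej, nodes)))
    if ("r" %in% header) igraph::E(g)$r <- rr
  }
  g
}

#' Write / read a cell graph as GraphML
#'
#' Thin wrappers over igraph's GraphML support that enforce the package's
#' graph contract (undirected, simple, named vertices) on the way in and
#' out.
#'
#' @param graph Undirected simple `igraph` graph.
#' @param path File path.
#' @return `write_graphml()` returns `path` invisibly; `read_graphml()` the
#'   graph.
#' @export
write_graphml <- function(graph, path) {
  graph <- check_cell_graph(graph)
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) abort(sprintf("GraphML file not found: %s", path))
  g <- igraph::read_graph(path, format = "graphml")
  check_cell_graph(g)
}
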