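# Compartment-labelled PPI graph construction and primitives.
#
# Graphs are igraph objects: undirected, simple, vertex attribute
# `compartment` (one of COMPARTMENTS), optional edge attribute `confidence`.

#' Build a compartment-labelled interaction graph
#'
#' Edges whose endpoints are not both in the catalog are dropped and counted
#' (closed-world: the catalog defines the node universe, so the network has
#' zero external interactions). Self-loops and duplicate edges are removed.
#'
#' @param edge_table data.frame with columns `protein_a`, `protein_b` and
#'   optionally `confidence` in `[0, 1]`.
#' @param catalog A `protein_catalog`; primary compartments are copied onto
#'   the vertices (assigned with the default policy if missing).
#' @param min_confidence Optional confidence cutoff; edges below it are
#'   dropped. Default `NULL` keeps everything.
#' @return An igraph; `attr(, "n_dropped_external")` and
#'   `attr(, "n_dropped_confidence")` record the filter counts.
#' @export
build_graph <- function(edge_table, catalog, min_confidence = NULL) {
  stopifnot(inherits(catalog, "protein_catalog"))
  if (!all(c("protein_a", "protein_b") %in% names(edge_table))) {
    stop("edge table needs columns protein_a, protein_b")
  }
  a <- as.character(edge_table$protein_a)
  b <- as.character(edge_table$protein_b)
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  conf <- if ("confidence" %in% names(edge_table)) {
    as.numeric(edge_table$confidence)
  } else {
    rep(NA_real_, length(a))
  }
  n_conf <- 0L
  if (!is.null(min_confidence)) {
    keep <- !is.na(conf) & conf >= min_confidence
    n_conf <- sum(!keep)
    a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  }
  if (anyNA(catalog$primary)) catalog <- assign_primary_compartment(catalog)
  known <- a %in% catalog$symbol & b %in% catalog$symbol
  n_ext <- sum(!known)
  a <- a[known]; b <- b[known]; conf <- conf[known]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = a, to = b, confidence = conf,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = catalog$symbol,
                          compartment = catalog$primary,
                          stringsAsFactors = FALSE))
  g <- igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
  message(sprintf(
    "graph: %d nodes / %d edges (%d external edge(s) dropped, %d below confidence cutoff)",
    igraph::vcount(g), igraph::ecount(g), n_ext, n_conf))
  attr(g, "n_dropped_external") <- n_ext
  attr(g, "n_dropped_confidence") <- n_conf
  g
}

#' Density of a simple undirected graph
#'
#' Loopless normalization `2e / (n (n - 1))`; a single-vertex graph has
#' density 0 by convention.
#' @param graph An igraph.
#' @return Fraction in `[0, 1]`.
#' @export
graph_density <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 1L)
  if (n < 2L) return(0)
  2 * igraph::ecount(graph) / (n * (n - 1))
}

#' k-core of a graph
#'
#' Maximal subgraph in which every vertex has degree at least `k`, computed
#' by iterative pruning. May be empty.
#' @param graph An igraph.
#' @param k Non-negative integer.
#' @return The induced k-core subgraph.
#' @export
k_core <- function(graph, k) {
  stopifnot(k >= 0)
  g <- graph
  repeat {
    if (igraph::vcount(g) == 0L) break
    deg <- igraph::degree(g)
    drop <- which(deg < k)
    if (length(drop) == 0L) break
    g <- igraph::delete_vertices(g, drop)
  }
  g
}

# largest k with a non-empty k-core, together with that core
highest_k_core <- function(graph) {
  k <- 0L
  core <- graph
  repeat {
    nxt <- k_core(core, k + 1L)
    if (igraph::vcount(nxt) == 0L) break
    k <- k + 1L
    core <- nxt
  }
  list(k = k, core = core)
}

#' Multi-source BFS hop distances
#'
#' Unweighted shortest hop count from the nearest source to every node;
#' unreachable nodes map to `Inf`.
#' @param graph An igraph.
#' @param sources Character vector of source node names (must exist).
#' @return Named numeric vector over all nodes.
#' @export
bfs_distances <- function(graph, sources) {
  nodes <- igraph::V(graph)$name
  if (!all(sources %in% nodes)) {
    stop(sprintf("unknown source node(s): %s",
                 paste(setdiff(sources, nodes), collapse = ", ")))
  }
  d <- igraph::distances(graph, v = sources, to = igraph::V(graph),
                         weights = NA)
  setNames(apply(d, 2L, min), nodes)
}

# named list: compartment -> member symbols, from the vertex attribute
compartment_sets <- function(graph) {
  comp <- igraph::V(graph)$compartment
  nm <- igraph::V(graph)$name
  lapply(setNames(COMPARTMENTS, COMPARTMENTS), function(cc) nm[comp == cc])
}

#' Read / write edge lists
#'
#' TSV columns `protein_a`, `protein_b`, optional `confidence`; SIF lines
#' `"A pp B"`.
#' @param path File path.
#' @param graph An igraph (for the writers).
#' @return Readers return a data.frame suitable for [build_graph()]; writers
#'   return `path` invisibly.
#' @export
read_edge_tsv <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("protein_a", "protein_b") %in% names(df)))
  df
}

#' @rdname read_edge_tsv
#' @export
write_edge_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(protein_a = el[, 1L], protein_b = el[, 2L],
                   stringsAsFactors = FALSE)
  if ("confidence" %in% igraph::edge_attr_names(graph)) {
    df$confidence <- igraph::E(graph)$confidence
  }
  write_tsv(df, path)
}

#' @rdname read_edge_tsv
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  ok <- vapply(parts, length, integer(1)) == 3L
  if (!all(ok)) {
    stop(sprintf("malformed SIF row(s): %s",
                 paste(head(which(!ok), 5L), collapse = ", ")))
  }
  data.frame(protein_a = vapply(parts, `[[`, character(1), 1L),
             protein_b = vapply(parts, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' @rdname read_edge_tsv
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  writeLines(sprintf("%s pp %s", el[, 1L], el[, 2L]), path)
  invisible(path)
}

#' @rdname read_edge_tsv
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
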