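# Cytosolic linker scoring: shortest-path bridging between ER and
# mitochondrial members inside the selected tri-compartment complex.
#
# The bridge length of a cytosolic node c is
#   min over ER members e, mitochondrial members m of d(e, c) + d(c, m)
# in hops within the cluster's induced subgraph, computed by two
# multi-source BFS sweeps. Ties are broken by the number of minimal witness
# paths through c, then degree, then name, so the ranking is total.

#' Select the tri-compartment disease cluster
#'
#' Among disease-flagged clusters containing at least one ER, one
#' mitochondrial and one cytosolic member (by primary compartment), returns
#' the highest-ranked one together with its compartment composition.
#'
#' @param pd_clusters A `pd_clusters` list from [map_degs_to_clusters()]
#'   (a plain `mcode_result` is accepted: all clusters are then eligible).
#' @param catalog A `protein_catalog` with primary compartments.
#' @return The selected `mcode_complex` with a `composition` field (named
#'   counts over compartments), or `NULL` with a diagnostic message when no
#'   disease cluster spans all three compartments.
#' @export
select_tricompartment_cluster <- function(pd_clusters, catalog) {
  if (length(pd_clusters) == 0L) stop("need at least one cluster")
  if (anyNA(catalog$primary)) catalog <- assign_primary_compartment(catalog)
  prim <- setNames(catalog$primary, catalog$symbol)
  compositions <- lapply(pd_clusters, function(cx) {
    tab <- table(factor(prim[cx$members], levels = COMPARTMENTS))
    setNames(as.integer(tab), COMPARTMENTS)
  })
  eligible <- vapply(seq_along(pd_clusters), function(i) {
    pd <- pd_clusters[[i]]$pd %||% TRUE
    pd && all(compositions[[i]] > 0L)
  }, logical(1))
  if (!any(eligible)) {
    message(sprintf(
      "no tri-compartment disease cluster among %d cluster(s); compositions: %s",
      length(pd_clusters),
      paste(vapply(compositions, function(x) {
        paste(x, collapse = "/")
      }, character(1)), collapse = " | ")))
    return(NULL)
  }
  i <- which(eligible)[1L] # clusters arrive in MCODE rank order
  cx <- pd_clusters[[i]]
  cx$composition <- compositions[[i]]
  cx
}

#' Induced subgraph of a complex, carrying compartment labels
#' @param graph The full interaction igraph.
#' @param cluster An `mcode_complex` (or a character vector of members).
#' @return The induced igraph.
#' @export
cluster_subgraph <- function(graph, cluster) {
  members <- if (is.list(cluster)) cluster$members else cluster
  igraph::induced_subgraph(graph, members)
}

# all shortest paths from `from` to its nearest members of `targets`
# (list of name vectors, each starting at `from`); `dist_from` holds the
# hop distances from `from` to every node
min_paths_to_set <- function(graph, from, targets, dist_from) {
  dmin <- min(dist_from[targets])
  if (!is.finite(dmin)) return(list())
  near <- targets[dist_from[targets] == dmin]
  paths <- list()
  for (tgt in near) {
    sp <- igraph::all_shortest_paths(graph, from = from, to = tgt,
                                     weights = NA)$vpaths
    paths <- c(paths, lapply(sp, function(p) p$name))
  }
  paths
}

# minimal ER -> c -> mito witness concatenations that form simple paths
witness_pairs <- function(graph, cyt, er, mito, d_er, d_mito) {
  dc <- bfs_distances(graph, cyt)
  to_er <- min_paths_to_set(graph, cyt, er, dc)
  to_mito <- min_paths_to_set(graph, cyt, mito, dc)
  out <- list()
  for (p1 in to_er) {
    for (p2 in to_mito) {
      if (length(intersect(p1[-1L], p2[-1L])) > 0L) next # must stay simple
      out[[length(out) + 1L]] <- c(rev(p1), p2[-1L])     # e ... c ... m
    }
  }
  if (length(out) > 1L) {
    out <- out[order(vapply(out, paste, character(1), collapse = ">"))]
  }
  out
}

#' Score cytosolic linker candidates in a cluster
#'
#' For every cytosolic member of the cluster subgraph the bridge length
#' `d(ER set, c) + d(c, mito set)` is computed from two multi-source BFS
#' sweeps. Candidates are ranked ascending by bridge length; ties are broken
#' by more minimal witness paths, then larger degree, then name.
#' Cytosolic nodes that cannot reach both organelle sets get infinite bridge
#' length and rank last.
#'
#' @param cluster_graph igraph of the cluster (vertex attribute
#'   `compartment`), e.g. from [cluster_subgraph()].
#' @return data.frame (class `linker_scores`): `rank`, `symbol`,
#'   `bridge_length`, `d_er`, `d_mito`, `n_paths`, `degree`.
#' @export
score_cytosolic_linkers <- function(cluster_graph) {
  sets <- compartment_sets(cluster_graph)
  if (any(lengths(sets) == 0L)) {
    stop(sprintf(
      "cluster must span all three compartments (ER/mitochondria/cytosol = %d/%d/%d)",
      length(sets$ER), length(sets$mitochondria), length(sets$cytosol)))
  }
  d_er <- bfs_distances(cluster_graph, sets$ER)
  d_mito <- bfs_distances(cluster_graph, sets$mitochondria)
  deg <- igraph::degree(cluster_graph)
  rows <- lapply(sets$cytosol, function(cyt) {
    bl <- d_er[[cyt]] + d_mito[[cyt]]
    n_paths <- if (is.finite(bl)) {
      length(witness_pairs(cluster_graph, cyt, sets$ER, sets$mitochondria,
                           d_er, d_mito))
    } else 0L
    data.frame(symbol = cyt, bridge_length = bl, d_er = d_er[[cyt]],
               d_mito = d_mito[[cyt]], n_paths = n_paths,
               degree = deg[[cyt]], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$bridge_length, -tab$n_paths, -tab$degree, tab$symbol)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  structure(tab, class = c("linker_scores", "data.frame"))
}

#' Extract explicit witness paths for a linker
#'
#' Enumerates minimal-length ER -> linker -> mitochondria concatenations
#' that form simple paths, ordered lexicographically by node sequence.
#'
#' @param cluster_graph igraph of the cluster.
#' @param linker Linker symbol (a cytosolic member with finite bridge
#'   length).
#' @param max_paths Maximum number of witnesses returned.
#' @return List of witness paths; each is a character vector of symbols whose
#'   names give the compartment of every node.
#' @export
extract_witness_paths <- function(cluster_graph, linker, max_paths = 10L) {
  stopifnot(max_paths >= 1L)
  sets <- compartment_sets(cluster_graph)
  d_er <- bfs_distances(cluster_graph, sets$ER)
  d_mito <- bfs_distances(cluster_graph, sets$mitochondria)
  if (!is.finite(d_er[[linker]] + d_mito[[linker]])) {
    stop(sprintf("'%s' has infinite bridge length", linker))
  }
  comp <- setNames(igraph::V(cluster_graph)$compartment,
                   igraph::V(cluster_graph)$name)
  paths <- witness_pairs(cluster_graph, linker, sets$ER, sets$mitochondria,
                         d_er, d_mito)
  paths <- paths[seq_len(min(max_paths, length(paths)))]
  lapply(paths, function(p) setNames(p, comp[p]))
}

#' @export
print.linker_scores <- function(x, ...) {
  cat(sprintf("cytosolic linker candidates: %d\n", nrow(x)))
  print.data.frame(head(x, 10L))
  invisible(x)
}

#' Write the linker ranking (with witness path strings) as TSV
#' @param scores A `linker_scores` table.
#' @param cluster_graph The cluster igraph (for witness extraction).
#' @param path Output path.
#' @param max_paths Witnesses per linker.
#' @export
write_linkers_tsv <- function(scores, cluster_graph, path, max_paths = 5L) {
  wit <- vapply(seq_len(nrow(scores)), function(i) {
    if (!is.finite(scores$bridge_length[i])) return("")
    ps <- extract_witness_paths(cluster_graph, scores$symbol[i], max_paths)
    paste(vapply(ps, paste, character(1), collapse = ">"), collapse = "|")
  }, character(1))
  out <- as.data.frame(scores)
  out$witness_paths <- wit
  write_tsv(out, path)
}

#' Export the cluster as DOT, highlighting witness edges
#'
#' Mirrors a highlighted-edge cluster figure: nodes are colored by
#' compartment and the union of edges on the linker's witness paths is drawn
#' bold red.
#'
#' @param cluster_graph The cluster igraph.
#' @param linker Linker symbol whose witnesses are highlighted.
#' @param path Output `.dot` path.
#' @export
write_cluster_dot <- function(cluster_graph, linker, path) {
  colors <- c(ER = "orange", mitochondria = "green", cytosol = "skyblue")
  comp <- setNames(igraph::V(cluster_graph)$compartment,
                   igraph::V(cluster_graph)$name)
  wit <- tryCatch(extract_witness_paths(cluster_graph, linker, 10L),
                  error = function(e) list())
  hi <- unique(unlist(lapply(wit, function(p) {
    vapply(seq_len(length(p) - 1L), function(i) {
      paste(sort(c(p[i], p[i + 1L])), collapse = "\r")
    }, character(1))
  })))
  el <- igraph::as_edgelist(cluster_graph)
  lines <- c("graph cluster {",
             sprintf("  \"%s\" [style=filled, fillcolor=%s];",
                     names(comp), colors[comp]))
  for (i in seq_len(nrow(el))) {
    key <- paste(sort(c(el[i, 1L], el[i, 2L])), collapse = "\r")
    style <- if (key %in% hi) " [color=red, penwidth=3]" else ""
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\"%s;",
                              el[i, 1L], el[i, 2L], style))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
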