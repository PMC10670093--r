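# MCODE-style molecular complex detection.
#
# From-scratch implementation of the three-stage algorithm: (1) vertex
# weighting by the highest k-core of each closed neighborhood (core number
# times core density, after a degree-cutoff filter), (2) greedy complex
# growth from high-weight seeds under a vertex-weight-percentage admission
# threshold, (3) optional haircut / fluff post-processing. All tie-breaks
# are made total so the ranked output is deterministic.

#' MCODE parameter set
#'
#' Canonical defaults of the original release: `degree_cutoff = 2`,
#' `vwp = 0.2`, `haircut = TRUE`, `fluff = FALSE`,
#' `fluff_density_threshold = 0.1`, `max_depth = 100`.
#'
#' @param degree_cutoff Minimum within-neighborhood degree for a vertex to
#'   contribute to the weighting core (>= 1).
#' @param vwp Vertex weight percentage in `[0, 1)`: growth admits neighbors
#'   with weight at least `(1 - vwp)` times the seed weight.
#' @param haircut Remove singly-connected members (iterated, i.e. the 2-core
#'   of the grown complex).
#' @param fluff Add boundary neighbors whose closed-neighborhood density
#'   exceeds `fluff_density_threshold`; fluffed nodes may overlap between
#'   complexes and the overlap is reported.
#' @param fluff_density_threshold Density threshold used by `fluff`.
#' @param max_depth Maximum BFS depth of complex growth from the seed (>= 1).
#' @return A validated list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, vwp = 0.2, haircut = TRUE,
                         fluff = FALSE, fluff_density_threshold = 0.1,
                         max_depth = 100L) {
  stopifnot(degree_cutoff >= 1L, max_depth >= 1L,
            vwp >= 0, vwp < 1,
            fluff_density_threshold >= 0, fluff_density_threshold <= 1)
  structure(list(degree_cutoff = as.integer(degree_cutoff), vwp = vwp,
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density_threshold = fluff_density_threshold,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

#' MCODE vertex weight
#'
#' The weight of `v` is the highest-core number of its closed neighborhood
#' (after removing neighborhood vertices of within-neighborhood degree below
#' `degree_cutoff`) multiplied by the density of that highest k-core — the
#' core-clustering coefficient scaled by the core number. Isolated vertices
#' (and vertices whose filtered neighborhood is empty) weigh 0.
#'
#' @param graph An igraph.
#' @param v Vertex name.
#' @param degree_cutoff See [mcode_params()].
#' @return Non-negative numeric weight.
#' @export
vertex_weight <- function(graph, v, degree_cutoff = 2L) {
  if (!v %in% igraph::V(graph)$name) stop(sprintf("unknown node '%s'", v))
  nb <- igraph::neighbors(graph, v)$name
  if (length(nb) == 0L) return(0)
  sub <- igraph::induced_subgraph(graph, c(v, nb))
  deg <- igraph::degree(sub)
  keep <- names(deg)[deg >= degree_cutoff]
  if (length(keep) < 2L) return(0)
  sub <- igraph::induced_subgraph(sub, keep)
  hk <- highest_k_core(sub)
  if (hk$k == 0L) return(0)
  hk$k * graph_density(hk$core)
}

# weights for every vertex (named numeric)
mcode_weights <- function(graph, degree_cutoff = 2L) {
  nm <- igraph::V(graph)$name
  setNames(vapply(nm, function(v) vertex_weight(graph, v, degree_cutoff),
                  numeric(1)), nm)
}

# Greedy breadth-first growth from a seed: admit a node on first qualifying
# encounter (weight >= threshold, not globally visited), never revisit.
mcode_grow <- function(adj, weights, seed, threshold, max_depth, visited) {
  members <- seed
  examined <- structure(rep(FALSE, length(weights)), names = names(weights))
  examined[seed] <- TRUE
  frontier <- seed
  depth <- 0L
  while (length(frontier) > 0L && depth < max_depth) {
    nxt <- character(0)
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (examined[[w]]) next
        examined[[w]] <- TRUE
        if (!visited[[w]] && weights[[w]] >= threshold) {
          members <- c(members, w)
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  members
}

# haircut = iterative removal of degree<2 members (2-core of the complex);
# if the pruned complex is disconnected, keep the seed's component (or the
# largest / lexicographically smallest one if the seed itself was pruned).
mcode_haircut <- function(graph, members, seed) {
  sub <- k_core(igraph::induced_subgraph(graph, members), 2L)
  if (igraph::vcount(sub) == 0L) return(character(0))
  comp <- igraph::components(sub)
  keep_id <- if (seed %in% igraph::V(sub)$name) {
    comp$membership[[seed]]
  } else {
    sz <- comp$csize
    cand <- which(sz == max(sz))
    first <- vapply(cand, function(i) {
      min(igraph::V(sub)$name[comp$membership == i])
    }, character(1))
    cand[order(first)][1L]
  }
  sort(igraph::V(sub)$name[comp$membership == keep_id])
}

#' Find dense complexes (MCODE)
#'
#' Seeds are processed in decreasing vertex weight (ties: higher degree,
#' then lexicographic name); each unvisited positive-weight seed grows a
#' complex admitting neighbors with weight `>= (1 - vwp) * seed weight`.
#' Admitted nodes are marked visited and excluded from later complexes, so
#' pre-fluff complexes are disjoint. Complexes are scored
#' `density x member count` and ranked by score (ties: larger size, then
#' lexicographically smallest member).
#'
#' @param graph A non-empty igraph.
#' @param params An [mcode_params()] list.
#' @return List of `mcode_complex` results (class `mcode_result`), each with
#'   `members`, `seed`, `score`, `rank`, `n_edges`, `density`, `n_fluffed`.
#'   `attr(, "overlap")` reports any post-fluff member sharing.
#' @examples
#' g <- igraph::simplify(igraph::graph_from_data_frame(
#'   t(combn(paste0("K", 1:5), 2)), directed = FALSE))
#' find_complexes(g, mcode_params())
#' @export
find_complexes <- function(graph, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  if (igraph::vcount(graph) == 0L) stop("graph is empty")
  nm <- igraph::V(graph)$name
  weights <- mcode_weights(graph, params$degree_cutoff)
  degs <- igraph::degree(graph)
  adj <- lapply(igraph::as_adj_list(graph), function(v) v$name)
  names(adj) <- nm
  seed_order <- nm[order(-weights, -degs, nm)]
  visited <- structure(rep(FALSE, length(nm)), names = nm)
  complexes <- list()
  for (s in seed_order) {
    if (visited[[s]] || weights[[s]] <= 0) next
    members <- mcode_grow(adj, weights, s,
                          threshold = (1 - params$vwp) * weights[[s]],
                          max_depth = params$max_depth, visited = visited)
    visited[members] <- TRUE
    if (params$haircut) members <- mcode_haircut(graph, members, s)
    n_fluffed <- 0L
    if (params$fluff && length(members) > 0L) {
      boundary <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                          members)
      fluffed <- boundary[vapply(boundary, function(u) {
        nbu <- igraph::induced_subgraph(graph, c(u, adj[[u]]))
        graph_density(nbu) > params$fluff_density_threshold
      }, logical(1))]
      n_fluffed <- length(fluffed)
      members <- c(members, fluffed) # fluffed nodes stay available elsewhere
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(graph, members)
    n_edges <- as.integer(igraph::ecount(sub))
    if (n_edges == 0L) next
    dens <- graph_density(sub)
    complexes[[length(complexes) + 1L]] <- structure(
      list(members = sort(members), seed = s, score = dens * length(members),
           rank = NA_integer_, n_edges = n_edges, density = dens,
           n_fluffed = n_fluffed),
      class = "mcode_complex")
  }
  ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
               -vapply(complexes, function(x) length(x$members), integer(1)),
               vapply(complexes, function(x) x$members[1L], character(1)))
  complexes <- complexes[ord]
  for (i in seq_along(complexes)) complexes[[i]]$rank <- i
  overlap <- character(0)
  if (length(complexes) > 1L) {
    for (i in seq_along(complexes)[-1L]) {
      for (j in seq_len(i - 1L)) {
        shared <- intersect(complexes[[i]]$members, complexes[[j]]$members)
        if (length(shared) > 0L) {
          overlap <- c(overlap, sprintf("complex %d & %d share: %s", j, i,
                                        paste(shared, collapse = ",")))
        }
      }
    }
  }
  if (length(overlap) > 0L) {
    message("post-fluff overlap: ", paste(overlap, collapse = "; "))
  }
  structure(complexes, overlap = overlap, class = "mcode_result")
}

#' Keep the top-ranked complexes
#'
#' @param results An `mcode_result` list.
#' @param k Number to keep (>= 1); fewer are returned if fewer exist.
#' @return The first `min(k, length(results))` complexes, ranks `1..k`.
#' @export
top_k <- function(results, k) {
  stopifnot(k >= 1L)
  out <- results[seq_len(min(k, length(results)))]
  structure(out, overlap = attr(results, "overlap"), class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("MCODE complexes: %d\n", length(x)))
  for (cx in x) {
    cat(sprintf("  #%d seed=%s score=%.3f members=%d edges=%d\n",
                cx$rank, cx$seed, cx$score, length(cx$members), cx$n_edges))
  }
  invisible(x)
}

# flat TSV view of a result list
complexes_to_table <- function(results) {
  if (length(results) == 0L) {
    return(data.frame(rank = integer(0), score = numeric(0),
                      n_members = integer(0), n_edges = integer(0),
                      seed = character(0), members = character(0)))
  }
  data.frame(
    rank = vapply(results, `[[`, integer(1), "rank"),
    score = vapply(results, `[[`, numeric(1), "score"),
    n_members = vapply(results, function(x) length(x$members), integer(1)),
    n_edges = vapply(results, `[[`, integer(1), "n_edges"),
    seed = vapply(results, `[[`, character(1), "seed"),
    members = vapply(results, function(x) paste(x$members, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
}

#' Write complexes as TSV or a GMT-like one-line-per-complex file
#' @param results An `mcode_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complexes_tsv <- function(results, path) {
  write_tsv(complexes_to_table(results), path)
}

#' @rdname write_complexes_tsv
#' @export
write_complexes_gmt <- function(results, path) {
  lines <- vapply(results, function(x) {
    paste(c(sprintf("complex_%d", x$rank), sprintf("score=%.6g", x$score),
            x$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
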