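# Brute-force oracles and small graph builders shared across tests.
# The oracles enumerate subsets / triples directly and stay independent of
# the package's pruning-based implementations.

# named adjacency matrix
adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# igraph from an edge list given as a two-column matrix plus isolated nodes
graph_from_edges <- function(edges, nodes = NULL, compartment = NULL) {
  nodes <- nodes %||% sort(unique(as.vector(edges)))
  vert <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(compartment)) vert$compartment <- compartment[nodes]
  igraph::simplify(igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vert))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clique_edges <- function(v) t(combn(v, 2))

# list of all non-empty vertex-index subsets of 1..n (n <= 8)
all_subsets <- function(n) {
  lapply(seq_len(2^n - 1L), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
  })
}

# exhaustive k-core on an adjacency matrix: the union of all vertex subsets
# whose induced minimum degree is >= k (min-degree->=k sets are closed under
# union, so the union is the maximal such set)
oracle_k_core_mat <- function(A, k) {
  n <- nrow(A)
  if (n == 0L) return(character(0))
  hit <- rep(FALSE, n)
  for (idx in all_subsets(n)) {
    if (min(rowSums(A[idx, idx, drop = FALSE])) >= k) hit[idx] <- TRUE
  }
  sort(rownames(A)[hit])
}

oracle_k_core <- function(g, k) {
  oracle_k_core_mat(adj_matrix(g), k)
}

# highest non-empty core by subset enumeration
oracle_highest_core_mat <- function(A) {
  k <- 0L
  members <- sort(rownames(A))
  repeat {
    nxt <- oracle_k_core_mat(A, k + 1L)
    if (length(nxt) == 0L) break
    k <- k + 1L
    members <- nxt
  }
  list(k = k, members = members)
}

# MCODE vertex weight recomputed via the subset-enumeration core oracle
oracle_vertex_weight <- function(A, v, degree_cutoff = 2L) {
  nbrs <- rownames(A)[A[v, ] > 0]
  if (length(nbrs) == 0L) return(0)
  idx <- c(v, nbrs)
  B <- A[idx, idx, drop = FALSE]
  keep <- rownames(B)[rowSums(B) >= degree_cutoff]
  if (length(keep) < 2L) return(0)
  B <- B[keep, keep, drop = FALSE]
  hc <- oracle_highest_core_mat(B)
  if (hc$k == 0L) return(0)
  C <- B[hc$members, hc$members, drop = FALSE]
  n <- nrow(C)
  hc$k * (sum(C) / (n * (n - 1)))
}

# all-pairs hop distances by Floyd-Warshall (vectorized over the inner loops)
oracle_all_pairs <- function(g) {
  nm <- igraph::V(g)$name
  A <- adj_matrix(g)[nm, nm, drop = FALSE]
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_along(nm)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# minimum over (e, c, m) triples of d(e, c) + d(c, m) for a cytosolic node c
oracle_bridge_length <- function(g, cyt) {
  D <- oracle_all_pairs(g)
  comp <- setNames(igraph::V(g)$compartment, igraph::V(g)$name)
  er <- names(comp)[comp == "ER"]
  mito <- names(comp)[comp == "mitochondria"]
  best <- Inf
  for (e in er) for (m in mito) {
    best <- min(best, D[e, cyt] + D[cyt, m])
  }
  best
}

# G(n, p) with compartment labels guaranteeing >=1 member per compartment
random_tri_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  comp <- setNames(c(COMPARTMENTS,
                     sample(COMPARTMENTS, n - 3L, replace = TRUE)),
                   sample(nodes))
  pairs <- t(combn(nodes, 2))
  edges <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  graph_from_edges(edges, nodes = nodes, compartment = comp)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

best_match_jaccard <- function(planted, complexes) {
  if (length(complexes) == 0L) return(0)
  max(vapply(complexes, function(cx) jaccard(planted, cx$members),
             numeric(1)))
}

# connected graphs on 2..7 vertices from the graph atlas
atlas_connected_graphs <- function() {
  graphs <- list()
  for (i in 1:1252) {
    g <- igraph::graph_from_atlas(i)
    if (igraph::vcount(g) < 2L || !igraph::is_connected(g)) next
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    graphs[[length(graphs) + 1L]] <- g
  }
  graphs
}
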