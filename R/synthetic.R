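# Seeded synthetic-data generators.
#
# These emulate the statistical structure the screen assumes: a three-way
# organelle catalog split, dense planted complexes in a sparse interaction
# background, multi-study case/control expression with mean-shift DEGs, a
# planted cytosol-mitochondria-ER linker motif, and qPCR Ct tables with known
# fold changes. Every generator takes an explicit seed and restores the
# caller's RNG state, so identical calls yield byte-identical tables.

#' Generate a synthetic protein catalog
#'
#' Symbols are `"P000001"`-style identifiers. Compartment counts follow
#' `proportions` by largest-remainder apportionment, so rational proportions
#' reproduce exact target counts (e.g. a 243/1399/1299 ER/mitochondria/cytosol
#' split at n = 2941). A `multilocal_rate` fraction of proteins receives a
#' second compartment drawn uniformly from the remaining two.
#'
#' @param n_proteins Positive integer.
#' @param proportions Named fractions over the three compartments, summing
#'   to 1 (within 1e-9).
#' @param multilocal_rate Fraction in `[0, 1)` of proteins given a second
#'   compartment.
#' @param seed Integer seed.
#' @return A `protein_catalog` with `primary` set to the drawn compartment
#'   and source `"synthetic"` (second localizations get source
#'   `"synthetic_multilocal"`).
#' @examples
#' cat3 <- generate_catalog(2941, c(ER = 243, mitochondria = 1399,
#'                                  cytosol = 1299) / 2941, seed = 1)
#' compartment_counts(cat3)
#' @export
generate_catalog <- function(n_proteins,
                             proportions = c(ER = 243, mitochondria = 1399,
                                             cytosol = 1299) / 2941,
                             multilocal_rate = 0,
                             seed = 1L) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 1 ||
      n_proteins != round(n_proteins)) {
    stop("`n_proteins` must be a positive integer")
  }
  names(proportions) <- canon_compartment(names(proportions))
  if (anyNA(names(proportions)) || !setequal(names(proportions), COMPARTMENTS)) {
    stop("`proportions` must be named over ER, mitochondria, cytosol")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("`proportions` must sum to 1")
  }
  if (multilocal_rate < 0 || multilocal_rate >= 1) {
    stop("`multilocal_rate` must be in [0, 1)")
  }
  proportions <- proportions[COMPARTMENTS]
  # largest-remainder apportionment; ties broken in canonical order
  quota <- n_proteins * proportions
  counts <- floor(quota)
  left <- n_proteins - sum(counts)
  if (left > 0) {
    ord <- order(-(quota - counts), seq_along(quota))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1L
  }
  with_seed(seed, {
    symbols <- sprintf("P%06d", seq_len(n_proteins))
    primary <- sample(rep(COMPARTMENTS, times = counts))
    second <- rep(NA_character_, n_proteins)
    n_multi <- round(multilocal_rate * n_proteins)
    if (n_multi > 0) {
      idx <- sample(n_proteins, n_multi)
      second[idx] <- vapply(primary[idx], function(p) {
        sample(setdiff(COMPARTMENTS, p), 1L)
      }, character(1))
    }
    compartments <- vapply(seq_len(n_proteins), function(i) {
      comps <- c(primary[i], second[i])
      comps <- COMPARTMENTS[COMPARTMENTS %in% comps]
      paste(comps, collapse = ";")
    }, character(1))
    support <- data.frame(symbol = symbols, compartment = primary,
                          source = "synthetic", stringsAsFactors = FALSE)
    multi <- !is.na(second)
    if (any(multi)) {
      support <- rbind(support,
                       data.frame(symbol = symbols[multi],
                                  compartment = second[multi],
                                  source = "synthetic_multilocal",
                                  stringsAsFactors = FALSE))
    }
    recs <- data.frame(symbol = symbols, compartments = compartments,
                       sources = ifelse(multi, "synthetic;synthetic_multilocal",
                                        "synthetic"),
                       primary = primary, stringsAsFactors = FALSE)
    new_protein_catalog(recs, support)
  })
}

# all unordered pairs of `ids` as a two-column character matrix
all_pairs <- function(ids) {
  if (length(ids) < 2L) return(matrix(character(0), ncol = 2L))
  t(combn(ids, 2L))
}

#' Generate a planted-complex interaction network
#'
#' Background edges are drawn independently with probability `p_bg` over all
#' pairs not inside the same planted complex; pairs within a planted complex
#' get an edge with that complex's `p_in`. With `linker_motif = TRUE` a
#' four-node bridge motif is injected inside the first planted complex: one
#' cytosolic node attached to two mitochondrial nodes, each attached to one
#' ER node (the geometry of a cytosolic protein reaching the ER through two
#' mitochondrial intermediates).
#'
#' @param catalog A `protein_catalog` with primary compartments.
#' @param complex_specs List of specs `list(size =, mix =, p_in =)`; `mix` is
#'   a named integer vector of per-compartment member counts summing to
#'   `size` (omit for compartment-agnostic sampling).
#' @param p_bg Background edge probability.
#' @param linker_motif Inject the cytosol-mito-ER bridge motif.
#' @param seed Integer seed.
#' @return `list(graph =, truth =)`: an undirected simple igraph with vertex
#'   attribute `compartment`, and a `synthetic_truth` list (planted member
#'   sets, planted linker, motif nodes, probabilities, seed).
#' @export
generate_network <- function(catalog, complex_specs = list(), p_bg = 0.02,
                             linker_motif = FALSE, seed = 1L) {
  stopifnot(inherits(catalog, "protein_catalog"))
  if (anyNA(catalog$primary)) catalog <- assign_primary_compartment(catalog)
  sizes <- vapply(complex_specs, function(s) as.integer(s$size), integer(1))
  if (sum(sizes) > nrow(catalog)) {
    stop("planted complex sizes exceed catalog size")
  }
  probs <- c(p_bg, vapply(complex_specs, function(s) s$p_in, numeric(1)))
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")

  with_seed(seed, {
    syms <- catalog$symbol
    prim <- setNames(catalog$primary, syms)
    free <- syms
    members <- lapply(complex_specs, function(spec) {
      if (!is.null(spec$mix)) {
        mix <- spec$mix
        names(mix) <- canon_compartment(names(mix))
        if (sum(mix) != spec$size) stop("complex mix must sum to size")
        picked <- unlist(lapply(names(mix), function(cc) {
          pool <- free[prim[free] == cc]
          if (length(pool) < mix[[cc]]) {
            stop(sprintf("not enough free %s proteins for complex mix", cc))
          }
          sample(pool, mix[[cc]])
        }), use.names = FALSE)
      } else {
        picked <- sample(free, spec$size)
      }
      free <<- setdiff(free, picked)
      picked
    })

    in_complex <- setNames(rep(0L, length(syms)), syms)
    for (i in seq_along(members)) in_complex[members[[i]]] <- i

    # within a planted complex: p_in; pairs touching the background: p_bg;
    # direct complex-to-complex pairs stay empty (the planted structures are
    # embedded in, not wired to, each other)
    pairs <- all_pairs(syms)
    ca <- in_complex[pairs[, 1L]]
    cb <- in_complex[pairs[, 2L]]
    p_in_by_complex <- c(0, vapply(complex_specs, `[[`, numeric(1), "p_in"))
    p_edge <- ifelse(ca != 0L & ca == cb, p_in_by_complex[ca + 1L],
                     ifelse(ca != 0L & cb != 0L, 0, p_bg))
    keep <- runif(nrow(pairs)) < p_edge
    edges <- pairs[keep, , drop = FALSE]

    motif <- NULL
    if (isTRUE(linker_motif)) {
      if (length(members) == 0L) stop("linker_motif needs a planted complex")
      host <- members[[1L]]
      cyt <- host[prim[host] == "cytosol"]
      mit <- host[prim[host] == "mitochondria"]
      er <- host[prim[host] == "ER"]
      if (length(cyt) < 1L || length(mit) < 2L || length(er) < 1L) {
        stop("first complex needs >=1 cytosol, >=2 mitochondria, >=1 ER members for the motif")
      }
      c0 <- sample(cyt, 1L)
      m2 <- sample(mit, 2L)
      e2 <- if (length(er) >= 2L) sample(er, 2L) else rep(er, 2L)
      motif <- c(cytosol = c0, mito1 = m2[1L], mito2 = m2[2L],
                 er1 = e2[1L], er2 = e2[2L])
      motif_edges <- rbind(c(c0, m2[1L]), c(c0, m2[2L]),
                           c(m2[1L], e2[1L]), c(m2[2L], e2[2L]))
      # the motif must not be short-circuited by a direct cytosol-ER edge
      direct <- (edges[, 1L] == c0 & edges[, 2L] %in% e2) |
        (edges[, 2L] == c0 & edges[, 1L] %in% e2)
      edges <- rbind(edges[!direct, , drop = FALSE], motif_edges)
    }

    g <- igraph::graph_from_data_frame(
      d = as.data.frame(edges, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = syms, compartment = unname(prim[syms]),
                            stringsAsFactors = FALSE))
    g <- igraph::simplify(g)
    truth <- structure(list(
      planted_complexes = lapply(members, sort),
      planted_linker = if (!is.null(motif)) unname(motif[["cytosol"]]),
      motif = motif,
      planted_deg_set = NULL,
      p_bg = p_bg,
      p_in = vapply(complex_specs, `[[`, numeric(1), "p_in"),
      seed = seed), class = "synthetic_truth")
    list(graph = g, truth = truth)
  })
}

#' Generate multi-study case/control expression data
#'
#' Expression is simulated on a log2-like additive scale: per-gene baselines
#' `mu_g ~ N(8, 1.5)` are drawn once and shared across studies; control
#' samples are `N(mu_g, noise_sd)` and case samples are
#' `N(mu_g + delta, noise_sd)` for the planted DEG set (shared across
#' studies), so a mean shift of `delta` equals a log2 fold change of `delta`.
#'
#' @param catalog A `protein_catalog` (its symbols become the gene universe).
#' @param n_studies Number of studies.
#' @param n_per_group Samples per group: a scalar (same case = control size in
#'   every study), a length-2 vector `c(case, control)`, or a list of such
#'   vectors, one per study (the paper-scale 277-sample design uses
#'   `list(c(57, 57), c(47, 47), c(35, 34))`).
#' @param deg_fraction Fraction of genes planted as differentially expressed
#'   (ignored when `deg_set` is given).
#' @param delta Mean shift in log2 units applied to planted DEGs in cases.
#' @param noise_sd Residual standard deviation (> 0).
#' @param seed Integer seed.
#' @param deg_set Optional explicit character vector of planted DEGs.
#' @return `list(studies =, truth =)`; each study is a list with `matrix`
#'   (genes x samples), `groups` (named `"case"`/`"control"` per sample) and
#'   `study_id`, of class `expression_study`.
#' @export
generate_expression <- function(catalog, n_studies = 3L, n_per_group = 10L,
                                deg_fraction = 0.1, delta = 1, noise_sd = 1,
                                seed = 1L, deg_set = NULL) {
  stopifnot(inherits(catalog, "protein_catalog"), n_studies >= 1L,
            noise_sd > 0)
  if (is.null(deg_set) && (deg_fraction < 0 || deg_fraction > 1)) {
    stop("`deg_fraction` must be in [0, 1]")
  }
  sizes <- if (is.list(n_per_group)) n_per_group else
    rep(list(n_per_group), n_studies)
  if (length(sizes) != n_studies) stop("one group-size entry per study")
  sizes <- lapply(sizes, function(s) {
    s <- as.integer(if (length(s) == 1L) c(s, s) else s)
    if (length(s) != 2L || any(s < 2L)) {
      stop("each group needs >=2 samples")
    }
    setNames(s, c("case", "control"))
  })
  genes <- catalog$symbol
  with_seed(seed, {
    mu <- setNames(rnorm(length(genes), mean = 8, sd = 1.5), genes)
    if (is.null(deg_set)) {
      deg_set <- sort(sample(genes, round(deg_fraction * length(genes))))
    } else {
      stopifnot(all(deg_set %in% genes))
      deg_set <- sort(deg_set)
    }
    shift <- ifelse(genes %in% deg_set, delta, 0)
    studies <- lapply(seq_len(n_studies), function(s) {
      n_case <- sizes[[s]][["case"]]; n_ctl <- sizes[[s]][["control"]]
      n <- n_case + n_ctl
      groups <- c(rep("control", n_ctl), rep("case", n_case))
      m <- matrix(rnorm(length(genes) * n, mean = mu, sd = noise_sd),
                  nrow = length(genes))
      m[, groups == "case"] <- m[, groups == "case"] + shift
      colnames(m) <- sprintf("S%d_%s_%02d", s, groups,
                             c(seq_len(n_ctl), seq_len(n_case)))
      rownames(m) <- genes
      structure(list(matrix = m,
                     groups = setNames(groups, colnames(m)),
                     study_id = sprintf("study%d", s)),
                class = "expression_study")
    })
    truth <- structure(list(planted_deg_set = deg_set, delta = delta,
                            noise_sd = noise_sd, seed = seed),
                       class = "synthetic_truth")
    list(studies = studies, truth = truth)
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' The reference gene has expectation 20 cycles in every group; the target
#' gene is `25 - log2(fold)` in expectation, so the delta-delta-Ct method
#' recovers `true_fold_changes` exactly in the noise-free limit.
#'
#' @param group_names Character vector of group labels; must include
#'   `control_group`.
#' @param n_per_group Samples per group (scalar or named per group).
#' @param true_fold_changes Named positive fold changes vs control; groups
#'   not named (and the control) default to fold 1.
#' @param ct_noise_sd Per-measurement Ct noise SD (>= 0).
#' @param seed Integer seed.
#' @param control_group Name of the control group.
#' @return A data.frame (class `ct_table`) with columns `sample`, `group`,
#'   `ct_target`, `ct_reference`.
#' @export
generate_ct_table <- function(group_names, n_per_group = 25L,
                              true_fold_changes = NULL, ct_noise_sd = 0.1,
                              seed = 1L, control_group = "control") {
  if (!control_group %in% group_names) {
    stop(sprintf("control group '%s' missing from group_names", control_group))
  }
  folds <- setNames(rep(1, length(group_names)), group_names)
  if (!is.null(true_fold_changes)) {
    stopifnot(all(names(true_fold_changes) %in% group_names))
    if (any(true_fold_changes <= 0)) stop("fold changes must be positive")
    folds[names(true_fold_changes)] <- true_fold_changes
  }
  n <- if (length(n_per_group) == 1L) {
    setNames(rep(as.integer(n_per_group), length(group_names)), group_names)
  } else {
    stopifnot(setequal(names(n_per_group), group_names))
    n_per_group[group_names]
  }
  with_seed(seed, {
    rows <- do.call(rbind, lapply(group_names, function(gp) {
      k <- n[[gp]]
      data.frame(
        sample = sprintf("%s_%02d", gp, seq_len(k)),
        group = gp,
        ct_target = 25 - log2(folds[[gp]]) + rnorm(k, sd = ct_noise_sd),
        ct_reference = 20 + rnorm(k, sd = ct_noise_sd),
        stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    structure(rows, control_group = control_group,
              class = c("ct_table", "data.frame"))
  })
}
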