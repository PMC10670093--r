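# Packaged end-to-end fixture.
#
# A deterministic, desk-scale data set with the shape of the full screen:
# three planted clique complexes in a sparse background, one of them a
# 44-member tri-compartment complex (37 mitochondrial members carrying the
# IDE/UBA52 intermediates, 6 cytosolic members including the DDO linker,
# and the single ER member SEC61A1), three case/control expression studies
# with planted DEGs in every complex, and a three-group qPCR Ct table. The
# motif geometry is: DDO - IDE, DDO - UBA52, IDE - SEC61A1, UBA52 - SEC61A1,
# i.e. the cytosolic linker reaches the ER in two hops through either
# mitochondrial intermediate.

#' Build the packaged reference fixture
#'
#' @param seed Integer seed driving the background edges, expression noise
#'   and Ct noise; the planted structure itself is deterministic.
#' @return List with `catalog`, `graph`, `studies`, `ct`, `truth` and
#'   `config` (the pipeline settings the fixture is designed for: MCODE with
#'   fluff enabled, `min_hits = 3`, `alpha = 0.05`).
#' @export
make_reference_fixture <- function(seed = 101L) {
  # --- node universe -------------------------------------------------------
  a_mito <- sprintf("AM%02d", 1:25)
  a_cyto <- sprintf("AC%02d", 1:25)
  b_mito <- sprintf("BM%02d", 1:40)
  c_mito <- c(sprintf("CM%02d", 1:35), "IDE", "UBA52")
  c_cyto <- c("DDO", sprintf("CC%02d", 1:5))
  c_er <- "SEC61A1"
  n_bg <- 106L
  bg <- sprintf("BG%03d", seq_len(n_bg))
  bg_comp <- rep(COMPARTMENTS, length.out = n_bg)

  symbols <- c(a_mito, a_cyto, b_mito, c_mito, c_cyto, c_er, bg)
  primary <- c(rep("mitochondria", length(a_mito)),
               rep("cytosol", length(a_cyto)),
               rep("mitochondria", length(b_mito)),
               rep("mitochondria", length(c_mito)),
               rep("cytosol", length(c_cyto)),
               "ER",
               bg_comp)
  support <- data.frame(symbol = symbols, compartment = primary,
                        source = "fixture", stringsAsFactors = FALSE)
  catalog <- new_protein_catalog(
    data.frame(symbol = symbols, compartments = primary, sources = "fixture",
               primary = primary, stringsAsFactors = FALSE),
    support)

  # --- edges ---------------------------------------------------------------
  clique <- function(v) all_pairs(v)
  cluster_a <- c(a_mito, a_cyto)
  cluster_b <- b_mito
  attach_cyto <- do.call(rbind, lapply(1:5, function(i) {
    cbind(sprintf("CC%02d", i), sprintf("CM%02d", (3 * i - 2):(3 * i)))
  }))
  motif <- rbind(c("DDO", "IDE"), c("DDO", "UBA52"),
                 c("SEC61A1", "IDE"), c("SEC61A1", "UBA52"))
  bg_edges <- with_seed(seed, {
    pr <- all_pairs(bg)
    pr[runif(nrow(pr)) < 0.02, , drop = FALSE]
  })
  edges <- rbind(clique(cluster_a), clique(cluster_b), clique(c_mito),
                 attach_cyto, motif, bg_edges)
  g <- igraph::simplify(igraph::graph_from_data_frame(
    d = as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(name = symbols, compartment = primary,
                          stringsAsFactors = FALSE)))

  # --- expression ----------------------------------------------------------
  deg_set <- c(a_mito[1:4], a_cyto[1:2],      # hits in complex A
               b_mito[1:6],                   # hits in complex B
               c_mito[1:4], "DDO", "IDE",     # hits in complex C
               bg[1:12])
  expr <- generate_expression(catalog, n_studies = 3L, n_per_group = 10L,
                              delta = 2, noise_sd = 1, seed = seed + 1L,
                              deg_set = deg_set)

  # --- qPCR ----------------------------------------------------------------
  ct <- generate_ct_table(
    group_names = c("control", "istradefylline", "amantadine"),
    n_per_group = 25L,
    true_fold_changes = c(istradefylline = 0.5, amantadine = 0.9),
    ct_noise_sd = 0.15, seed = seed + 2L)

  truth <- structure(list(
    planted_complexes = list(sort(cluster_a), sort(cluster_b),
                             sort(c(c_mito, c_cyto, c_er))),
    tri_compartment_members = sort(c(c_mito, c_cyto, c_er)),
    tri_compartment_composition = c(ER = 1L, mitochondria = 37L,
                                    cytosol = 6L),
    planted_linker = "DDO",
    motif = c(cytosol = "DDO", mito1 = "IDE", mito2 = "UBA52",
              er1 = "SEC61A1", er2 = "SEC61A1"),
    planted_deg_set = sort(deg_set),
    p_bg = 0.02, seed = seed), class = "synthetic_truth")

  config <- list(
    seed = seed,
    mcode = list(degree_cutoff = 2L, vwp = 0.2, haircut = TRUE, fluff = TRUE,
                 fluff_density_threshold = 0.1, max_depth = 100L),
    top_k = 3L,
    meta = list(alpha = 0.05, adjust = "none", min_hits = 3L),
    catalog_policy = "source_majority",
    ct = list(control_group = "control"))

  list(catalog = catalog, graph = g, studies = expr$studies, ct = ct,
       truth = truth, config = config)
}
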