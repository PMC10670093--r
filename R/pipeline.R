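# Full-screen orchestration: simulate/ingest -> annotate -> build network ->
# cluster -> meta differential expression -> linker scoring -> qPCR stats,
# with per-stage logging, TSV outputs and a JSON run manifest.

default_config <- function() {
  list(
    seed = 1L,
    simulate = list(fixture = "reference"),
    inputs = NULL,
    catalog_policy = "source_majority",
    min_confidence = NULL,
    mcode = list(degree_cutoff = 2L, vwp = 0.2, haircut = TRUE,
                 fluff = FALSE, fluff_density_threshold = 0.1,
                 max_depth = 100L),
    top_k = 3L,
    meta = list(alpha = 0.05, adjust = "none", min_hits = 1L,
                moderated = FALSE, log_transform = FALSE),
    ct = list(control_group = "control", family_alpha = 0.05),
    max_witness_paths = 5L)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

load_run_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    catalog <- read_catalog_tsv(inp$catalog)
    edge_table <- if (grepl("\\.sif$", inp$edges)) read_sif(inp$edges) else
      read_edge_tsv(inp$edges)
    studies <- read_expression_tsv(inp$expression, inp$metadata)
    ct <- if (!is.null(inp$ct)) {
      read_ct_tsv(inp$ct, config$ct$control_group %||% "control")
    }
    return(list(catalog = catalog, edge_table = edge_table, graph = NULL,
                studies = studies, ct = ct, truth = NULL))
  }
  sim <- config$simulate %||% list(fixture = "reference")
  if (identical(sim$fixture, "reference")) {
    fx <- make_reference_fixture(seed = config$seed %||% 101L)
    return(list(catalog = fx$catalog, edge_table = NULL, graph = fx$graph,
                studies = fx$studies, ct = fx$ct, truth = fx$truth))
  }
  stop("config must provide either `inputs` paths or a known `simulate` block")
}

#' Run the full organelle cross-talk screen
#'
#' Executes every stage in order, writes each stage's TSV outputs plus a
#' plain-text report and a JSON manifest into `out_dir`, and returns the
#' report as a list. All randomness is controlled by `config$seed`, so two
#' runs with the same configuration produce byte-identical outputs.
#'
#' @param config A configuration list, or the path to a YAML file with the
#'   same structure. Fields (all optional, with defaults): `seed`;
#'   `simulate` (e.g. `list(fixture = "reference")`) or `inputs` (paths
#'   `catalog`, `edges`, `expression`, `metadata`, optional `ct`);
#'   `catalog_policy`; `min_confidence`; `mcode` (see [mcode_params()]);
#'   `top_k`; `meta` (`alpha`, `adjust`, `min_hits`, `moderated`,
#'   `log_transform`); `ct` (`control_group`, `family_alpha`);
#'   `max_witness_paths`.
#' @param out_dir Output directory (created if needed). `NULL` runs
#'   everything in a temporary directory.
#' @return The run report, invisibly: network summary, ranked complexes,
#'   DEG count, disease clusters, selected tri-compartment composition,
#'   ranked linkers with witness paths, and (when Ct data are present)
#'   delta-delta-Ct, ANOVA and Tukey results.
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(seed = 101), out_dir = tempfile())
#' rep$top_linker
#' }
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  user <- config
  config <- merge_config(default_config(), user)
  # the fixture ships its recommended settings; honour them unless the user
  # overrides them explicitly
  if (is.null(config$inputs) &&
      identical(config$simulate$fixture, "reference")) {
    fxcfg <- make_reference_fixture(seed = config$seed)$config
    config$mcode <- merge_config(merge_config(config$mcode, fxcfg$mcode),
                                 user$mcode %||% list())
    config$meta <- merge_config(merge_config(config$meta, fxcfg$meta),
                                user$meta %||% list())
  }
  out_dir <- out_dir %||% tempfile("cytobridge_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (partial outputs kept in %s)",
                   stage, conditionMessage(e), out_dir), call. = FALSE)
    })
  }

  # -- data -----------------------------------------------------------------
  dat <- run_stage("data", load_run_inputs(config))
  stage_log("data", "catalog of %d proteins, %d studies, ct table: %s",
            nrow(dat$catalog), length(dat$studies),
            if (is.null(dat$ct)) "absent" else "present")

  # -- annotate -------------------------------------------------------------
  catalog <- run_stage("annotate", {
    if (anyNA(dat$catalog$primary)) {
      assign_primary_compartment(dat$catalog, policy = config$catalog_policy)
    } else dat$catalog
  })
  counts <- compartment_counts(catalog)
  stage_log("annotate", "primary compartments: ER=%d mitochondria=%d cytosol=%d",
            counts[["ER"]], counts[["mitochondria"]], counts[["cytosol"]])
  write_catalog_tsv(catalog, file.path(out_dir, "catalog.tsv"))
  report$compartment_counts <- counts

  # -- network --------------------------------------------------------------
  graph <- run_stage("build-net", {
    if (!is.null(dat$graph)) dat$graph else
      suppressMessages(build_graph(dat$edge_table, catalog,
                                   min_confidence = config$min_confidence))
  })
  stage_log("build-net", "%d nodes / %d edges",
            igraph::vcount(graph), igraph::ecount(graph))
  write_edge_tsv(graph, file.path(out_dir, "edges.tsv"))
  report$network <- list(n_nodes = igraph::vcount(graph),
                         n_edges = igraph::ecount(graph))

  # -- cluster --------------------------------------------------------------
  clusters <- run_stage("cluster", {
    params <- do.call(mcode_params, config$mcode)
    suppressMessages(top_k(find_complexes(graph, params), config$top_k))
  })
  stage_log("cluster", "top %d complexes: %s", length(clusters),
            paste(vapply(clusters, function(cx) {
              sprintf("#%d n=%d e=%d score=%.2f", cx$rank,
                      length(cx$members), cx$n_edges, cx$score)
            }, character(1)), collapse = "; "))
  write_complexes_tsv(clusters, file.path(out_dir, "complexes.tsv"))
  report$clusters <- complexes_to_table(clusters)

  # -- meta differential expression ----------------------------------------
  meta <- run_stage("meta-de", {
    suppressWarnings(meta_de(dat$studies, alpha = config$meta$alpha,
                             adjust = config$meta$adjust,
                             moderated = config$meta$moderated,
                             log_transform = config$meta$log_transform))
  })
  degs <- call_degs(meta, alpha = config$meta$alpha,
                    adjust = config$meta$adjust)
  stage_log("meta-de", "%d / %d genes called DEG at alpha %.3g",
            length(degs), nrow(meta), config$meta$alpha)
  write_meta_de_tsv(meta, file.path(out_dir, "meta_de.tsv"))
  report$n_degs <- length(degs)

  # -- disease clusters & linker -------------------------------------------
  pd <- map_degs_to_clusters(clusters, degs, min_hits = config$meta$min_hits)
  pd_tab <- complexes_to_table(pd)
  pd_tab$n_hits <- vapply(pd, function(cx) length(cx$hits), integer(1))
  pd_tab$pd <- vapply(pd, `[[`, logical(1), "pd")
  write_tsv(pd_tab, file.path(out_dir, "pd_clusters.tsv"))
  stage_log("linker", "%d disease cluster(s) (min_hits=%d)",
            sum(pd_tab$pd), config$meta$min_hits)
  report$pd_clusters <- pd_tab

  selected <- run_stage("linker", select_tricompartment_cluster(pd, catalog))
  if (is.null(selected)) {
    stage_log("linker", "no tri-compartment disease cluster; stage skipped")
    report$selected_cluster <- NULL
  } else {
    sub <- cluster_subgraph(graph, selected)
    linkers <- run_stage("linker", score_cytosolic_linkers(sub))
    witnesses <- extract_witness_paths(sub, linkers$symbol[1L],
                                       config$max_witness_paths)
    stage_log("linker",
              "cluster #%d selected (ER/mito/cytosol = %d/%d/%d); top linker %s (bridge %g, %d witness path(s))",
              selected$rank, selected$composition[["ER"]],
              selected$composition[["mitochondria"]],
              selected$composition[["cytosol"]],
              linkers$symbol[1L], linkers$bridge_length[1L],
              length(witnesses))
    write_linkers_tsv(linkers, sub, file.path(out_dir, "linkers.tsv"),
                      config$max_witness_paths)
    write_cluster_dot(sub, linkers$symbol[1L],
                      file.path(out_dir, "selected_cluster.dot"))
    report$selected_cluster <- list(rank = selected$rank,
                                    n_members = length(selected$members),
                                    composition = selected$composition)
    report$linkers <- linkers
    report$top_linker <- linkers$symbol[1L]
    report$witness_paths <- vapply(witnesses, paste, character(1),
                                   collapse = ">")
  }

  # -- qPCR validation ------------------------------------------------------
  if (is.null(dat$ct)) {
    stage_log("ddct", "no Ct table supplied; stage skipped")
    report$ddct <- NULL
  } else {
    val <- run_stage("ddct", {
      dd <- delta_delta_ct(dat$ct, config$ct$control_group)
      folds <- split(dd$samples$fold, dd$samples$group)
      list(ddct = dd, anova = one_way_anova(folds),
           tukey = tukey_hsd(folds, config$ct$family_alpha))
    })
    stage_log("ddct", "group folds: %s; ANOVA F=%.3f p=%.3g",
              paste(sprintf("%s=%.3f", val$ddct$groups$group,
                            val$ddct$groups$mean_fold), collapse = " "),
              val$anova$statistic, val$anova$p)
    write_tsv(val$ddct$samples, file.path(out_dir, "ddct_samples.tsv"))
    write_tsv(val$ddct$groups, file.path(out_dir, "ddct_groups.tsv"))
    anova_tab <- data.frame(F = val$anova$statistic,
                            df_between = val$anova$df_between,
                            df_within = val$anova$df_within,
                            p = val$anova$p)
    write_tsv(anova_tab, file.path(out_dir, "anova.tsv"))
    write_tsv(val$tukey, file.path(out_dir, "tukey.tsv"))
    report$ddct <- val$ddct$groups
    report$anova <- val$anova
    report$tukey <- val$tukey
  }

  # -- report & manifest ----------------------------------------------------
  writeLines(render_report(report), file.path(out_dir, "report.txt"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "CytoBridge",
    version = as.character(utils::packageVersion("CytoBridge")),
    config = config,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$out_dir <- out_dir
  invisible(report)
}

render_report <- function(report) {
  lines <- c("CytoBridge run report",
             sprintf("seed: %s", report$config$seed),
             sprintf("network: %d nodes / %d edges",
                     report$network$n_nodes, report$network$n_edges),
             "clusters:")
  if (nrow(report$clusters) > 0L) {
    lines <- c(lines, sprintf("  #%d size=%d edges=%d score=%.4f",
                              report$clusters$rank, report$clusters$n_members,
                              report$clusters$n_edges, report$clusters$score))
  }
  lines <- c(lines, sprintf("DEGs called: %d", report$n_degs),
             sprintf("disease clusters: %d", sum(report$pd_clusters$pd)))
  if (!is.null(report$selected_cluster)) {
    comp <- report$selected_cluster$composition
    lines <- c(lines,
               sprintf("selected cluster: #%d, %d members (ER/mito/cytosol = %d/%d/%d)",
                       report$selected_cluster$rank,
                       report$selected_cluster$n_members,
                       comp[["ER"]], comp[["mitochondria"]],
                       comp[["cytosol"]]),
               sprintf("top linker: %s", report$top_linker),
               sprintf("  witness: %s", report$witness_paths))
  } else {
    lines <- c(lines, "selected cluster: none")
  }
  if (!is.null(report$ddct)) {
    lines <- c(lines,
               sprintf("ddct fold %s: %.4f (sd %.4f)", report$ddct$group,
                       report$ddct$mean_fold, report$ddct$sd_fold),
               sprintf("ANOVA: F=%.4f df=(%d,%d) p=%.6g",
                       report$anova$statistic, report$anova$df_between,
                       report$anova$df_within, report$anova$p))
  } else {
    lines <- c(lines, "ddct: skipped (no Ct table)")
  }
  lines
}
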