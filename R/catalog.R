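# Organelle catalog harmonization.
#
# A protein catalog is a plain data.frame (class "protein_catalog") with one
# row per harmonized symbol:
#   symbol       character, unique
#   compartments semicolon-joined subset of COMPARTMENTS (canonical order)
#   sources      semicolon-joined, sorted
#   primary      one compartment per protein (NA until assigned)
# The per-(symbol, compartment, source) evidence rows survive in
# attr(catalog, "support"); the primary-compartment policies need them.

new_protein_catalog <- function(records, support) {
  stopifnot(is.data.frame(records),
            all(c("symbol", "compartments", "sources") %in% names(records)))
  if (is.null(records$primary)) records$primary <- NA_character_
  records <- records[order(records$symbol), , drop = FALSE]
  rownames(records) <- NULL
  structure(records, support = support,
            class = c("protein_catalog", "data.frame"))
}

catalog_support <- function(catalog) {
  sup <- attr(catalog, "support")
  if (!is.null(sup)) return(sup)
  # reconstruct a flat evidence table from the joined columns
  do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
    expand.grid(symbol = catalog$symbol[i],
                compartment = strsplit(catalog$compartments[i], ";")[[1]],
                source = strsplit(catalog$sources[i], ";")[[1]],
                stringsAsFactors = FALSE)
  }))
}

#' Harmonize raw organelle protein lists into one catalog
#'
#' Multiple source tables (e.g. dumps from localization databases) are merged
#' into a single compartment-labelled catalog: aliases are mapped to canonical
#' symbols, rows with unrecognised compartment labels are dropped with a
#' warning, and duplicate symbols are merged with the union of their
#' compartments and sources. This replaces manual symbol verification with an
#' explicit, reproducible policy.
#'
#' @param raw_tables A data.frame with columns `symbol`, `compartment`,
#'   `source`, or a list of such data.frames; a `protein_catalog` is also
#'   accepted (its evidence rows are re-harmonized, making the operation
#'   idempotent).
#' @param alias_map Optional named character vector mapping alias symbols to
#'   canonical ones (`c(ddo1 = "DDO")`). Symbols are compared case-sensitively
#'   after alias mapping.
#' @return A `protein_catalog` sorted by symbol. The number of rejected rows
#'   is available as `attr(x, "n_rejected")`.
#' @examples
#' harmonize(data.frame(symbol = c("ddo1", "X", "X"),
#'                      compartment = c("cytosol", "cytosol", "mitochondria"),
#'                      source = c("A", "A", "B")),
#'           alias_map = c(ddo1 = "DDO"))
#' @export
harmonize <- function(raw_tables, alias_map = NULL) {
  if (inherits(raw_tables, "protein_catalog")) {
    raw_tables <- catalog_support(raw_tables)
  }
  if (is.data.frame(raw_tables)) raw_tables <- list(raw_tables)
  stopifnot(length(raw_tables) >= 1L)
  raw <- do.call(rbind, lapply(raw_tables, function(tb) {
    if (!all(c("symbol", "compartment", "source") %in% names(tb))) {
      stop("raw tables need columns symbol, compartment, source")
    }
    tb[, c("symbol", "compartment", "source")]
  }))
  raw$symbol <- as.character(raw$symbol)
  raw$source <- as.character(raw$source)
  comp <- canon_compartment(raw$compartment)
  bad <- is.na(comp)
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with unknown compartment label: %s",
                    sum(bad),
                    paste(unique(raw$compartment[bad]), collapse = ", ")))
  }
  raw <- raw[!bad, , drop = FALSE]
  raw$compartment <- comp[!bad]
  if (!is.null(alias_map)) {
    hit <- raw$symbol %in% names(alias_map)
    raw$symbol[hit] <- unname(alias_map[raw$symbol[hit]])
  }
  support <- unique(raw[, c("symbol", "compartment", "source")])
  rownames(support) <- NULL
  recs <- lapply(split(support, support$symbol), function(g) {
    data.frame(
      symbol = g$symbol[1L],
      compartments = paste(COMPARTMENTS[COMPARTMENTS %in% g$compartment],
                           collapse = ";"),
      sources = paste(sort(unique(g$source)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- new_protein_catalog(do.call(rbind, recs), support)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Assign one primary compartment per protein
#'
#' Multi-localized proteins keep their full label set, but downstream stages
#' (graph labels, linker scoring) need a single compartment per node. Two
#' policies are provided: `source_majority` picks the compartment supported by
#' the most distinct sources, breaking ties with `priority`; `priority_order`
#' simply takes the first compartment in `priority` that the protein carries.
#'
#' @param catalog A `protein_catalog`.
#' @param policy `"source_majority"` (default) or `"priority_order"`.
#' @param priority Total order over compartments used as tie-break (and as
#'   the whole rule under `priority_order`).
#' @return The catalog with its `primary` column filled.
#' @export
assign_primary_compartment <- function(catalog,
                                       policy = c("source_majority",
                                                  "priority_order"),
                                       priority = c("mitochondria", "ER",
                                                    "cytosol")) {
  policy <- match.arg(policy)
  stopifnot(setequal(priority, COMPARTMENTS))
  support <- catalog_support(catalog)
  pick <- function(sym, comps) {
    if (length(comps) == 1L) return(comps)
    if (policy == "priority_order") {
      return(priority[priority %in% comps][1L])
    }
    sup <- support[support$symbol == sym, , drop = FALSE]
    votes <- vapply(comps, function(cc) {
      length(unique(sup$source[sup$compartment == cc]))
    }, integer(1))
    best <- comps[votes == max(votes)]
    priority[priority %in% best][1L]
  }
  comp_list <- strsplit(catalog$compartments, ";", fixed = TRUE)
  catalog$primary <- vapply(seq_len(nrow(catalog)), function(i) {
    pick(catalog$symbol[i], comp_list[[i]])
  }, character(1))
  catalog
}

#' Count proteins per primary compartment
#'
#' @param catalog A `protein_catalog`; if primary compartments have not been
#'   assigned yet the default policy of [assign_primary_compartment()] is
#'   applied first.
#' @return Named integer vector over `ER`, `mitochondria`, `cytosol`; the
#'   counts sum to the number of records.
#' @export
compartment_counts <- function(catalog) {
  if (nrow(catalog) == 0L) {
    return(setNames(integer(length(COMPARTMENTS)), COMPARTMENTS))
  }
  if (anyNA(catalog$primary)) {
    catalog <- assign_primary_compartment(catalog)
  }
  tab <- table(factor(catalog$primary, levels = COMPARTMENTS))
  setNames(as.integer(tab), COMPARTMENTS)
}

#' @export
print.protein_catalog <- function(x, ...) {
  cat(sprintf("protein catalog: %d proteins\n", nrow(x)))
  if (nrow(x) > 0L && !anyNA(x$primary)) {
    cts <- compartment_counts(x)
    cat("  primary compartments:",
        paste(sprintf("%s=%d", names(cts), cts), collapse = ", "), "\n")
  }
  multi <- grepl(";", x$compartments, fixed = TRUE)
  if (any(multi)) cat(sprintf("  multi-localized: %d\n", sum(multi)))
  invisible(x)
}

#' Read / write the catalog TSV dialect
#'
#' Columns: `symbol`, `compartments` (semicolon-joined), `sources`
#' (semicolon-joined), `primary`.
#' @param catalog A `protein_catalog`.
#' @param path File path.
#' @return `read_catalog_tsv` returns a `protein_catalog`;
#'   `write_catalog_tsv` returns `path` invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("symbol", "compartments", "sources") %in% names(df)))
  if (is.null(df$primary)) df$primary <- NA_character_
  df$primary <- as.character(df$primary)
  new_protein_catalog(df, support = NULL)
}
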