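# Expression / metadata / Ct table IO (the TSV dialects the generators
# write and the pipeline reads).

#' Read expression studies from TSV
#'
#' The matrix TSV has genes as rows (first column `gene`) and samples as
#' columns; the metadata TSV has columns `sample`, `group`
#' (`case`/`control`) and `study`. One `expression_study` is returned per
#' distinct `study`.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return List of `expression_study` objects.
#' @export
read_expression_tsv <- function(matrix_path, metadata_path) {
  m <- read_tsv(matrix_path)
  stopifnot(names(m)[1L] == "gene")
  genes <- m$gene
  mat <- as.matrix(m[, -1L, drop = FALSE])
  rownames(mat) <- genes
  meta <- read_tsv(metadata_path)
  stopifnot(all(c("sample", "group", "study") %in% names(meta)))
  if (!all(meta$sample %in% colnames(mat))) {
    stop("metadata lists samples missing from the expression matrix")
  }
  lapply(split(meta, meta$study), function(ms) {
    structure(list(matrix = mat[, ms$sample, drop = FALSE],
                   groups = setNames(ms$group, ms$sample),
                   study_id = as.character(ms$study[1L])),
              class = "expression_study")
  })
}

#' Write expression studies as matrix + metadata TSVs
#' @param studies List of `expression_study` objects (same gene universe).
#' @param matrix_path,metadata_path Output paths.
#' @export
write_expression_tsv <- function(studies, matrix_path, metadata_path) {
  mats <- lapply(studies, `[[`, "matrix")
  genes <- rownames(mats[[1L]])
  stopifnot(all(vapply(mats, function(m) identical(rownames(m), genes),
                       logical(1))))
  full <- do.call(cbind, mats)
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(full, optional = TRUE))
  write_tsv(df, matrix_path)
  meta <- do.call(rbind, lapply(studies, function(s) {
    data.frame(sample = names(s$groups), group = unname(s$groups),
               study = s$study_id, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  write_tsv(meta, metadata_path)
  invisible(c(matrix_path, metadata_path))
}

#' Read / write qPCR Ct tables
#' @param path File path.
#' @param ct A `ct_table`.
#' @param control_group Control group label recorded on the read table.
#' @export
read_ct_tsv <- function(path, control_group = "control") {
  df <- read_tsv(path)
  stopifnot(all(c("sample", "group", "ct_target", "ct_reference") %in%
                  names(df)))
  structure(df, control_group = control_group,
            class = c("ct_table", "data.frame"))
}

#' @rdname read_ct_tsv
#' @export
write_ct_tsv <- function(ct, path) {
  write_tsv(as.data.frame(ct), path)
}
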