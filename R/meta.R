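# Cross-study differential expression with Fisher's combined probability.

#' Two-group differential expression for one study
#'
#' Per gene, a two-group linear-model contrast equivalent to the
#' pooled-variance two-sample t statistic with
#' `df = n_case + n_control - 2` and a two-sided p-value. The statistic is
#' case minus control, so positive values mean up-regulation in cases.
#' Zero pooled variance is guarded by an epsilon, so exact separation yields
#' a p-value at (or underflowing to) the representable floor and is flagged.
#'
#' @param study An `expression_study` (list with `matrix`, `groups`,
#'   `study_id`), e.g. from [generate_expression()] or [read_expression_tsv()].
#' @param moderated Use limma's empirical-Bayes moderated t instead (needs
#'   the limma package); off by default.
#' @param log_transform Apply `log2(x + 1)` first, for raw-intensity input.
#' @return data.frame `gene`, `statistic`, `p`, `df`, `degenerate`.
#' @export
differential_expression <- function(study, moderated = FALSE,
                                    log_transform = FALSE) {
  m <- study$matrix
  groups <- study$groups[colnames(m)]
  if (anyNA(groups) || !all(groups %in% c("case", "control"))) {
    stop("every sample needs a 'case' or 'control' label")
  }
  n1 <- sum(groups == "case")
  n2 <- sum(groups == "control")
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf("study %s rejected: need >=2 samples per group (case=%d, control=%d)",
                 study$study_id %||% "?", n1, n2))
  }
  if (log_transform) m <- log2(m + 1)
  if (moderated) {
    if (!requireNamespace("limma", quietly = TRUE)) {
      stop("moderated = TRUE requires the limma package")
    }
    design <- cbind(Intercept = 1, case = as.integer(groups == "case"))
    fit <- limma::eBayes(limma::lmFit(m, design))
    return(data.frame(gene = rownames(m),
                      statistic = fit$t[, "case"],
                      p = fit$p.value[, "case"],
                      df = fit$df.total,
                      degenerate = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  x1 <- m[, groups == "case", drop = FALSE]
  x2 <- m[, groups == "control", drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, var); v2 <- apply(x2, 1L, var)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  diff <- m1 - m2
  degenerate <- sp2 == 0 & diff != 0
  tied <- sp2 == 0 & diff == 0
  sp2 <- pmax(sp2, .Machine$double.eps) # epsilon guard for exact separation
  tstat <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat[tied] <- 0
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  data.frame(gene = rownames(m), statistic = tstat, p = p, df = df,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fisher's combined-probability method
#'
#' Combines k independent p-values via `X2 = -2 * sum(log(p_i))`, which is
#' chi-square distributed with `2k` degrees of freedom under the joint null.
#' With a single study the combined p equals the input p; the statistic is
#' permutation-invariant and monotone (lowering any p_i never raises the
#' combined p).
#'
#' @param p_list Numeric vector of p-values in `(0, 1]`.
#' @param p_floor Zero p-values are clamped to this floor with a warning
#'   (default `1e-300`); negative values or values above 1 are rejected.
#' @return `list(chisq =, df =, p =)`.
#' @examples
#' fisher_combine(c(0.5, 0.5)) # chisq 2.773, df 4, p 0.5966
#' @export
fisher_combine <- function(p_list, p_floor = 1e-300) {
  if (length(p_list) == 0L) stop("`p_list` must be non-empty")
  if (any(is.na(p_list)) || any(p_list < 0) || any(p_list > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (any(p_list == 0)) {
    warning(sprintf("clamping %d zero p-value(s) to %g",
                    sum(p_list == 0), p_floor))
    p_list <- pmax(p_list, p_floor)
  }
  chisq <- -2 * sum(log(p_list))
  df <- 2L * length(p_list)
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df = df, lower.tail = FALSE))
}

#' Combine per-study differential expression across studies
#'
#' Runs [differential_expression()] on every study and combines the per-gene
#' p-values with Fisher's method. Genes absent from some studies are
#' combined over the studies that measure them (`df = 2 * k_available`).
#'
#' @param studies List of `expression_study` objects.
#' @param alpha DEG-calling level used for the `deg_flag` column.
#' @param adjust `"none"` (default, matching an unadjusted p < alpha call) or
#'   `"bh"` for Benjamini-Hochberg.
#' @param moderated,log_transform Passed to [differential_expression()].
#' @param p_floor Passed to the Fisher combination.
#' @return data.frame (class `meta_de`) with one row per gene: per-study
#'   p columns, `chisq`, `df`, `combined_p`, `adjusted_p`, `deg_flag`.
#' @export
meta_de <- function(studies, alpha = 0.05, adjust = c("none", "bh"),
                    moderated = FALSE, log_transform = FALSE,
                    p_floor = 1e-300) {
  adjust <- match.arg(adjust)
  stopifnot(length(studies) >= 1L, alpha > 0, alpha < 1)
  per_study <- lapply(studies, differential_expression,
                      moderated = moderated, log_transform = log_transform)
  ids <- vapply(seq_along(studies), function(i) {
    studies[[i]]$study_id %||% sprintf("study%d", i)
  }, character(1))
  genes <- sort(unique(unlist(lapply(per_study, `[[`, "gene"))))
  pmat <- matrix(NA_real_, nrow = length(genes), ncol = length(studies),
                 dimnames = list(genes, paste0("p_", ids)))
  for (i in seq_along(per_study)) {
    pmat[per_study[[i]]$gene, i] <- per_study[[i]]$p
  }
  n_zero <- sum(pmat == 0, na.rm = TRUE)
  if (n_zero > 0L) {
    warning(sprintf("clamping %d zero p-value(s) to %g", n_zero, p_floor))
  }
  clamped <- pmax(pmat, p_floor)
  chisq <- -2 * rowSums(log(clamped), na.rm = TRUE)
  k <- rowSums(!is.na(clamped))
  df <- 2L * k
  combined <- pchisq(chisq, df = df, lower.tail = FALSE)
  adjusted <- if (adjust == "bh") p.adjust(combined, method = "BH") else combined
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pmat, optional = TRUE))
  out$chisq <- chisq
  out$df <- df
  out$combined_p <- combined
  out$adjusted_p <- adjusted
  out$deg_flag <- adjusted < alpha
  rownames(out) <- NULL
  structure(out, alpha = alpha, adjust = adjust,
            class = c("meta_de", "data.frame"))
}

#' Call differentially expressed genes
#'
#' Strict inequality: genes with (adjusted) combined p `< alpha`; a gene
#' landing exactly on alpha is not called.
#'
#' @param meta A `meta_de` table.
#' @param alpha Level in `(0, 1)`.
#' @param adjust `"none"` or `"bh"`.
#' @return Character vector of DEG symbols.
#' @export
call_degs <- function(meta, alpha = 0.05, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1)
  p <- if (adjust == "bh") p.adjust(meta$combined_p, method = "BH") else
    meta$combined_p
  meta$gene[p < alpha]
}

#' Map DEGs onto complexes and nominate disease clusters
#'
#' Each complex is annotated with its members' intersection with the DEG
#' set; complexes reaching `min_hits` hits are flagged as disease ("PD")
#' clusters. Input order (MCODE ranking) is preserved.
#'
#' @param clusters An `mcode_result` list.
#' @param degs Character vector of DEG symbols.
#' @param min_hits Minimum DEG hits for the disease flag (>= 1).
#' @return The cluster list with `hits` (character) and `pd` (logical) added
#'   to every complex; class `pd_clusters`.
#' @export
map_degs_to_clusters <- function(clusters, degs, min_hits = 1L) {
  stopifnot(min_hits >= 1L)
  out <- lapply(clusters, function(cx) {
    cx$hits <- sort(intersect(cx$members, degs))
    cx$pd <- length(cx$hits) >= min_hits
    cx
  })
  structure(out, min_hits = as.integer(min_hits),
            overlap = attr(clusters, "overlap"),
            class = c("pd_clusters", "mcode_result"))
}

#' Write the per-gene meta-analysis table
#' @param meta A `meta_de` table.
#' @param path Output path.
#' @export
write_meta_de_tsv <- function(meta, path) {
  write_tsv(as.data.frame(meta), path)
}
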