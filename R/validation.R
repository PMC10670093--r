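# Expression-validation statistics: delta-delta-Ct relative quantification
# and one-way ANOVA with Tukey post-hoc comparisons.

#' Delta-delta-Ct relative quantification
#'
#' Per sample, `dCt = ct_target - ct_reference`; `ddCt` is `dCt` minus the
#' mean `dCt` of the control group (the calibrator); the relative fold
#' change is `2^(-ddCt)`. Group summaries report the mean and SD of the
#' per-sample folds, or of the group-mean `dCt` under the `group_mean`
#' summary variant.
#'
#' @param ct A `ct_table` data.frame (`sample`, `group`, `ct_target`,
#'   `ct_reference`).
#' @param control_group Calibrator group label (must be present).
#' @param summary_method `"per_sample"` (mean/SD of per-sample folds,
#'   default) or `"group_mean"` (fold of the group-mean dCt).
#' @return `list(samples =, groups =)` of class `ddct_result`: per-sample
#'   `dct`, `ddct`, `fold`, and per-group `n`, `mean_ddct`, `mean_fold`,
#'   `sd_fold`.
#' @examples
#' ct <- data.frame(sample = c("t1", "c1"), group = c("treated", "control"),
#'                  ct_target = c(25, 24), ct_reference = c(20, 20))
#' delta_delta_ct(ct)$samples # treated ddct = +1, fold = 0.5
#' @export
delta_delta_ct <- function(ct, control_group = NULL,
                           summary_method = c("per_sample", "group_mean")) {
  summary_method <- match.arg(summary_method)
  stopifnot(all(c("sample", "group", "ct_target", "ct_reference") %in%
                  names(ct)))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)) ||
      any(ct$ct_target <= 0) || any(ct$ct_reference <= 0)) {
    stop("Ct values must be positive and finite")
  }
  control_group <- control_group %||% attr(ct, "control_group") %||% "control"
  ctl <- ct$group == control_group
  if (!any(ctl)) {
    stop(sprintf("control group '%s' is empty or absent", control_group))
  }
  dct <- ct$ct_target - ct$ct_reference
  calibrator <- mean(dct[ctl])
  ddct <- dct - calibrator
  fold <- 2^(-ddct)
  samples <- data.frame(sample = ct$sample, group = ct$group, dct = dct,
                        ddct = ddct, fold = fold, stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(samples, samples$group), function(g) {
    mean_fold <- if (summary_method == "per_sample") mean(g$fold) else
      2^(-(mean(g$dct) - calibrator))
    data.frame(group = g$group[1L], n = nrow(g),
               mean_ddct = mean(g$ddct), mean_fold = mean_fold,
               sd_fold = if (nrow(g) > 1L) sd(g$fold) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  structure(list(samples = samples, groups = groups,
                 control_group = control_group,
                 summary_method = summary_method),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("delta-delta-Ct vs '%s':\n", x$control_group))
  print.data.frame(x$groups)
  invisible(x)
}

as_group_list <- function(values_by_group) {
  if (is.data.frame(values_by_group)) {
    values_by_group <- split(values_by_group$value, values_by_group$group)
  }
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  if (any(lengths(values_by_group) < 2L)) {
    stop("every group needs >=2 values")
  }
  values_by_group
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition,
#' `F = MS_between / MS_within`, with the p-value from the upper tail of the
#' F distribution (fitted via [stats::aov()]). A degenerate design with zero
#' within-group variance but unequal means is reported as `p = 0` with the
#' `degenerate` flag set.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups, each
#'   with >= 2 values), or a data.frame with `value` and `group` columns.
#' @return `list(statistic =, df_between =, df_within =, p =, degenerate =)`.
#' @export
one_way_anova <- function(values_by_group) {
  values_by_group <- as_group_list(values_by_group)
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group), lengths(values_by_group))))
  # a perfect fit triggers a stats warning; that case is detected and
  # reported below through the `degenerate` flag
  tab <- suppressWarnings(anova(aov(value ~ group, data = df)))
  ms_within <- tab["Residuals", "Mean Sq"]
  ms_between <- tab["group", "Mean Sq"]
  # guard against floating-point sums of squares of order 1e-30
  scale2 <- mean(df$value^2) + 1
  if (ms_between < 1e-20 * scale2 && ms_within < 1e-20 * scale2) {
    # all values identical up to rounding
    return(list(statistic = 0, df_between = unname(tab["group", "Df"]),
                df_within = unname(tab["Residuals", "Df"]), p = 1,
                degenerate = FALSE))
  }
  degenerate <- ms_between > 0 && ms_within < 1e-10 * ms_between
  f <- if (degenerate) Inf else unname(tab["group", "F value"])
  p <- if (degenerate) 0 else unname(tab["group", "Pr(>F)"])
  list(statistic = f,
       df_between = unname(tab["group", "Df"]),
       df_within = unname(tab["Residuals", "Df"]),
       p = p, degenerate = degenerate)
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group comparisons via the studentized-range distribution
#' ([stats::TukeyHSD()]), using the Tukey-Kramer adjustment when group sizes
#' differ.
#'
#' @param values_by_group As in [one_way_anova()].
#' @param family_alpha Family-wise error level for the significance flags
#'   (and `1 - family_alpha` confidence intervals).
#' @return data.frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`, `significant`
#'   for all `choose(g, 2)` pairs.
#' @export
tukey_hsd <- function(values_by_group, family_alpha = 0.05) {
  stopifnot(family_alpha > 0, family_alpha < 1)
  values_by_group <- as_group_list(values_by_group)
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group), lengths(values_by_group))))
  hsd <- TukeyHSD(aov(value ~ group, data = df),
                  conf.level = 1 - family_alpha)$group
  out <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                    lwr = hsd[, "lwr"], upr = hsd[, "upr"],
                    p_adj = hsd[, "p adj"],
                    significant = hsd[, "p adj"] < family_alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
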