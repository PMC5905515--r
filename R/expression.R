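#' Mean of technical replicate Ct values
#'
#' @param replicates numeric Ct values; NA replicates are dropped.
#' @return list with `ct` (mean) and `n` (replicates used).
#' @export
replicate_mean <- function(replicates) {
  x <- replicates[is.finite(replicates)]
  if (!length(x)) stop("all replicates missing")
  list(ct = mean(x), n = length(x))
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged first; per sample
#' `delta_ct = Ct_target - Ct_control`; `delta_delta_ct = delta_ct -
#' delta_ct_calibrator` where the calibrator is either a single sample (its
#' own delta Ct; that sample's relative expression is exactly 1) or a group
#' (the group's mean delta Ct); `rel_expr = 2^-delta_delta_ct`. Samples with
#' no control-gene measurement are flagged and skipped with a warning.
#'
#' @param ct long-format Ct table: columns `sample_id`, `group`, `gene`,
#'   `ct` (one row per technical replicate).
#' @param target_gene,control_gene gene names in `ct`.
#' @param calibrator list `list(sample = id)` or `list(group = label)`; a bare
#'   character is interpreted as a group label if it matches one, else as a
#'   sample id.
#' @return data.frame (`ExpressionResult`): sample_id, group, gene, delta_ct,
#'   delta_delta_ct, rel_expr.
#' @export
ddct <- function(ct, target_gene, control_gene, calibrator) {
  if (is.character(calibrator)) {
    calibrator <- if (calibrator %in% ct$group) list(group = calibrator)
    else list(sample = calibrator)
  }
  mean_ct <- function(gene) {
    sub <- ct[ct$gene == gene, , drop = FALSE]
    vapply(split(sub$ct, sub$sample_id),
           function(x) replicate_mean(x)$ct, numeric(1))
  }
  tgt <- mean_ct(target_gene)
  ctl <- mean_ct(control_gene)
  samples <- unique(ct$sample_id[ct$gene == target_gene])
  no_ctl <- setdiff(samples, names(ctl))
  if (length(no_ctl)) {
    warning("no control-gene Ct for sample(s) ", paste(no_ctl, collapse = ", "),
            "; skipped")
    samples <- setdiff(samples, no_ctl)
  }
  grp <- ct$group[match(samples, ct$sample_id)]
  dct <- tgt[samples] - ctl[samples]
  cal_dct <- if (!is.null(calibrator$sample)) {
    if (!calibrator$sample %in% samples)
      stop("calibrator sample not present: ", calibrator$sample)
    dct[[calibrator$sample]]
  } else {
    ing <- grp == calibrator$group
    if (!any(ing)) stop("calibrator group not present: ", calibrator$group)
    mean(dct[ing])
  }
  ddc <- dct - cal_dct
  data.frame(sample_id = samples, group = grp, gene = target_gene,
             delta_ct = unname(dct), delta_delta_ct = unname(ddc),
             rel_expr = 2^(-unname(ddc)))
}

#' Compare relative expression between two groups
#'
#' Welch two-sample t-test on the `2^-ddCt` scale.
#'
#' @param results `ExpressionResult` data.frame from [ddct()].
#' @param groupA,groupB group labels.
#' @param value column compared (default `"rel_expr"`).
#' @return list with `mean_diff` (A - B), `t`, `df`, `p_value`, group sizes.
#' @export
group_compare <- function(results, groupA, groupB, value = "rel_expr") {
  xa <- results[[value]][results$group == groupA]
  xb <- results[[value]][results$group == groupB]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("each group needs at least 2 samples")
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0 && mean(xa) == mean(xb))
    return(list(mean_diff = 0, t = 0, df = length(xa) + length(xb) - 2,
                p_value = 1, nA = length(xa), nB = length(xb)))
  tt <- stats::t.test(xa, xb)
  list(mean_diff = mean(xa) - mean(xb), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value,
       nA = length(xa), nB = length(xb))
}

#' Pearson correlation of expression with a phenotype
#'
#' Pearson r with a two-sided t-test p-value; the slope and intercept of the
#' least-squares trend line are reported for plotting.
#'
#' @param results `ExpressionResult` data.frame.
#' @param phenotype named numeric vector (names are sample ids), e.g. horn
#'   length per sample.
#' @param value expression column used (default `"rel_expr"`).
#' @return list with `r`, `p_value`, `n`, `slope`, `intercept`.
#' @export
expr_phenotype_correlation <- function(results, phenotype, value = "rel_expr") {
  common <- intersect(results$sample_id, names(phenotype))
  x <- results[[value]][match(common, results$sample_id)]
  y <- as.numeric(phenotype[common])
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ctest <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  list(r = unname(ctest$estimate), p_value = ctest$p.value, n = length(x),
       slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
}

#' Read a long-format Ct table TSV
#'
#' Columns: `sample_id`, `group`, `gene`, `replicate`, `ct`.
#' @param path TSV file.
#' @export
read_ct_table <- function(path) {
  df <- read_table_tsv(path)
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  df
}
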