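#' Top-quantile significance thresholds for sweep calling
#'
#' For each statistic independently, the `ceiling((1 - quantile) * N)`
#' highest-ranked non-excluded windows are selected and the cutoff is the
#' smallest selected value; windows tied at the boundary are all included by
#' the downstream `>=` rule.
#'
#' @param stats window statistics from [window_statistics()].
#' @param quantile significance quantile (default 0.95, i.e. top 5%).
#' @return list with `fst_cutoff`, `hp_ratio_cutoff`, `quantile`, `n_windows`.
#' @export
compute_thresholds <- function(stats, quantile = 0.95) {
  use <- stats[!stats$excluded, , drop = FALSE]
  if (nrow(use) < 20L)
    stop("need at least 20 non-excluded windows to set thresholds (have ",
         nrow(use), ")")
  list(fst_cutoff = top_quantile_cutoff(use$fst, quantile),
       hp_ratio_cutoff = top_quantile_cutoff(use$log2_hp_ratio, quantile),
       quantile = quantile, n_windows = nrow(use))
}

top_quantile_cutoff <- function(x, quantile) {
  x <- x[!is.na(x)]
  # round before ceiling: (1 - 0.95) * 100 is 5 + 4e-15 in floating point
  m <- max(1L, ceiling(round((1 - quantile) * length(x), 9)))
  s <- sort(x, decreasing = TRUE)
  cutoff <- s[m]
  if (cutoff == s[length(s)])
    warning("all values tied at the top-quantile boundary; every window selected")
  cutoff
}

#' Call significant sweep windows by the joint criterion
#'
#' A non-excluded window is called when both its F_ST and its heterozygosity
#' log ratio are at or above their respective top-quantile cutoffs.
#'
#' @param stats window statistics.
#' @param thresholds from [compute_thresholds()].
#' @return the subset of `stats` rows that are called.
#' @export
call_sweep_windows <- function(stats, thresholds) {
  hit <- !stats$excluded &
    !is.na(stats$fst) & stats$fst >= thresholds$fst_cutoff &
    !is.na(stats$log2_hp_ratio) &
    stats$log2_hp_ratio >= thresholds$hp_ratio_cutoff
  stats[hit, , drop = FALSE]
}

#' Merge significant windows into sweep regions and add flanks
#'
#' Overlapping or book-ended called windows on one chromosome are merged into
#' maximal regions; the flank is applied to the merged region and clipped to
#' the chromosome.
#'
#' @param windows called windows (rows of the stats table, with `chrom`,
#'   `start`, `end`, `index` and optionally `fst` / `log2_hp_ratio`).
#' @param flank flank size in bp (default 15 kb).
#' @param chrom_lengths optional named lengths used to clip the right flank.
#' @return data.frame of regions with member window indices and peak
#'   statistics.
#' @export
merge_regions <- function(windows, flank = 15000, chrom_lengths = NULL) {
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      flank_start = numeric(0), flank_end = numeric(0),
                      n_windows = integer(0), members = character(0),
                      peak_fst = numeric(0), peak_log2_hp_ratio = numeric(0))
  if (nrow(windows) == 0L) return(empty)
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  out <- list()
  cur <- windows[1, , drop = FALSE]
  members <- list(cur$index)
  cs <- cur$chrom; s <- cur$start; e <- cur$end
  fst <- cur$fst; hp <- cur$log2_hp_ratio
  flush <- function() {
    data.frame(chrom = cs, start = s, end = e,
               flank_start = max(0, s - flank),
               flank_end = if (!is.null(chrom_lengths) && cs %in% names(chrom_lengths))
                 min(chrom_lengths[[cs]], e + flank) else e + flank,
               n_windows = length(unlist(members)),
               members = paste(unlist(members), collapse = ","),
               peak_fst = if (is.null(fst)) NA_real_ else max(fst, na.rm = TRUE),
               peak_log2_hp_ratio = if (is.null(hp)) NA_real_ else
                 suppressWarnings(max(hp, na.rm = TRUE)))
  }
  if (nrow(windows) > 1L) for (i in 2:nrow(windows)) {
    w <- windows[i, ]
    if (w$chrom == cs && w$start <= e) {  # overlap or book-ended
      e <- max(e, w$end)
      members <- c(members, w$index)
      fst <- c(fst, w$fst); hp <- c(hp, w$log2_hp_ratio)
    } else {
      out[[length(out) + 1L]] <- flush()
      cs <- w$chrom; s <- w$start; e <- w$end
      members <- list(w$index); fst <- w$fst; hp <- w$log2_hp_ratio
    }
  }
  out[[length(out) + 1L]] <- flush()
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Candidate genes implicated by sweep regions
#'
#' Genes overlapping a flanked sweep region by at least 1 bp (all coordinates
#' 0-based half-open) are candidates.
#'
#' @param regions from [merge_regions()].
#' @param genes annotation from [read_gene_annotation()] or
#'   [simulate_gene_annotation()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `region` (index
#'   of the first implicating region) — zero rows when nothing overlaps.
#' @export
candidate_genes <- function(regions, genes) {
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), region = integer(0))
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(empty)
  unmatched <- union(setdiff(unique(regions$chrom), unique(genes$chrom)),
                     setdiff(unique(genes$chrom), unique(regions$chrom)))
  if (length(unmatched) == length(union(unique(regions$chrom),
                                        unique(genes$chrom))))
    warning("no shared chromosome names between regions and annotation: ",
            paste(unmatched, collapse = ", "))
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ov <- which(regions$chrom == g$chrom &
                  regions$flank_start < g$end & regions$flank_end > g$start)
    if (!length(ov)) return(NULL)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end, region = ov[1])
  })
  res <- do.call(rbind, hits)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Venn partition of candidate-gene sets across populations
#'
#' Counts, for every non-empty combination of populations, the genes found in
#' exactly that combination; combination labels join population names with
#' `&`.
#'
#' @param sets named list of character vectors of gene ids, one per
#'   population.
#' @return data.frame with `combo`, `count`; the union size equals
#'   `sum(count)`.
#' @export
overlap_candidate_sets <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 candidate sets")
  all_genes <- unique(unlist(sets))
  if (!length(all_genes))
    return(data.frame(combo = character(0), count = integer(0)))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, names(sets)))
  combo <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  tab <- table(combo)
  data.frame(combo = names(tab), count = as.integer(tab), row.names = NULL)
}

#' Run a full selective-sweep scan
#'
#' Computes per-window statistics for a target-vs-reference comparison, sets
#' joint top-quantile thresholds, calls and merges sweep windows, and (when an
#' annotation is given) assigns candidate genes via the flanked regions.
#'
#' @param vt a `VariantTable`.
#' @param popmap population map (data.frame with `sample_id`, `breed`,
#'   `group`), or NULL if `target` / `reference` are sample-id vectors.
#' @param target,reference group labels in `popmap`, or sample-id vectors
#'   when `popmap` is NULL.
#' @param genes optional gene annotation.
#' @param window_size,step,min_variants,quantile,flank scan parameters; the
#'   defaults are the 30-kb/15-kb tiling, the fewer-than-50-variants
#'   exclusion, the top-5% joint threshold and 15-kb flanks.
#' @param chrom_lengths named chromosome lengths (defaults to those carried by
#'   `vt`).
#' @return object of class `sweep_scan`: list with `stats`, `thresholds`,
#'   `called`, `regions`, `candidates`, `params`.
#' @export
sweep_scan <- function(vt, popmap = NULL, target, reference, genes = NULL,
                       window_size = 30000, step = 15000, min_variants = 50,
                       quantile = 0.95, flank = 15000,
                       chrom_lengths = vt_chrom_lengths(vt)) {
  if (!is.null(popmap)) {
    if (identical(target, reference))
      stop("target and reference populations must differ")
    target_s <- pop_samples(popmap, target)
    reference_s <- pop_samples(popmap, reference)
    labels <- c(target, reference)
  } else {
    target_s <- target; reference_s <- reference
    labels <- c("target", "reference")
  }
  stats <- window_statistics(vt, target_s, reference_s,
                             chrom_lengths = chrom_lengths,
                             window_size = window_size, step = step,
                             min_variants = min_variants)
  thr <- compute_thresholds(stats, quantile)
  called <- call_sweep_windows(stats, thr)
  regions <- merge_regions(called, flank = flank, chrom_lengths = chrom_lengths)
  cand <- if (!is.null(genes)) candidate_genes(regions, genes) else NULL
  structure(list(stats = stats, thresholds = thr, called = called,
                 regions = regions, candidates = cand,
                 params = list(target = labels[1], reference = labels[2],
                               window_size = window_size, step = step,
                               min_variants = min_variants,
                               quantile = quantile, flank = flank)),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  p <- x$params
  cat(sprintf("Selective-sweep scan: %s vs %s\n", p$target, p$reference))
  cat(sprintf("  %d windows (%d bp / %d bp), %d excluded (<%d variants)\n",
              nrow(x$stats), p$window_size, p$step, sum(x$stats$excluded),
              p$min_variants))
  cat(sprintf("  thresholds (top %.0f%%): F_ST >= %.4f, log2 Hp ratio >= %.4f\n",
              100 * (1 - p$quantile), x$thresholds$fst_cutoff,
              x$thresholds$hp_ratio_cutoff))
  cat(sprintf("  %d windows called, %d merged regions",
              nrow(x$called), nrow(x$regions)))
  if (!is.null(x$candidates))
    cat(sprintf(", %d candidate genes", nrow(x$candidates)))
  cat("\n")
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  print(object)
  if (nrow(object$regions)) {
    cat("\nRegions:\n")
    print(object$regions[, c("chrom", "start", "end", "n_windows",
                             "peak_fst", "peak_log2_hp_ratio")])
  }
  invisible(object)
}
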