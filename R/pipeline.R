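#' Write a full synthetic cohort to disk
#'
#' Emits the five standard inputs of the pipeline — VCF genotypes (with any
#' configured sweeps injected), population map, BED gene annotation,
#' genotype-phenotype table and Ct table — plus a manifest with the seed and
#' md5 checksums. Identical configurations produce identical bytes.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
pipeline_simulate <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(cfg)
  vt <- sim$vt
  for (k in seq_along(cfg$sweeps)) {
    sw <- cfg$sweeps[[k]]
    vt <- inject_sweep(vt, pop_samples(sim$popmap, sw$pop),
                       list(chrom = sw$chrom, start = sw$start, end = sw$end),
                       target_freq = if (is.null(sw$target_freq)) 0.98
                                     else sw$target_freq,
                       seed = cfg$seed + 100L + k)
  }
  genes <- simulate_gene_annotation(cfg)
  causal <- pick_causal_site(vt, cfg)
  pheno <- simulate_phenotypes(vt, causal, cfg)
  ctab <- simulate_ct_table(cfg)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             popmap = file.path(out_dir, "popmap.tsv"),
             genes = file.path(out_dir, "genes.bed"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             ct = file.path(out_dir, "ct.tsv"))
  write_vcf(vt, paths["vcf"])
  write_popmap(sim$popmap, paths["popmap"])
  write_bed(genes, paths["genes"])
  write_table(pheno, paths["phenotypes"])
  write_table(ctab, paths["ct"])
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         seed = cfg$seed)
  write_table(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(c(paths, manifest = file.path(out_dir, "manifest.tsv")))
}

# default causal SNP: site nearest the middle of the first sweep interval,
# else the site nearest the middle of the first chromosome
pick_causal_site <- function(vt, cfg) {
  if (length(cfg$sweeps)) {
    sw <- cfg$sweeps[[1]]
    idx <- which(vt$chrom == sw$chrom & vt$pos - 1 >= sw$start &
                   vt$pos - 1 < sw$end)
    if (length(idx)) {
      mid <- (sw$start + sw$end) / 2
      return(idx[which.min(abs(vt$pos[idx] - mid))])
    }
  }
  ch <- vt$chrom[1]
  idx <- which(vt$chrom == ch)
  idx[which.min(abs(vt$pos[idx] - stats::median(vt$pos[idx])))]
}

#' Run the sweep scan stage and write its reports
#'
#' Reads the VCF, population map and (optionally) annotation, runs
#' [sweep_scan()], and writes `window_stats.tsv`, `sweep_regions.tsv` and
#' `candidate_genes.tsv`. Reported coordinates are 1-based inclusive;
#' parameters and thresholds are echoed as `#` comment lines.
#'
#' @param vcf,popmap,genes input paths (`genes` may be NULL); alternatively
#'   `vcf` may be a `VariantTable` and `popmap`/`genes` data.frames.
#' @param target,reference analysis-group labels.
#' @param out_dir output directory.
#' @param window_size,step,min_variants,quantile,flank scan parameters.
#' @param min_maf optional MAF filter applied on ingest.
#' @return the `sweep_scan` object, invisibly.
#' @export
pipeline_scan <- function(vcf, popmap, genes = NULL, target, reference,
                          out_dir, window_size = 30000, step = 15000,
                          min_variants = 50, quantile = 0.95, flank = 15000,
                          min_maf = NULL) {
  vt <- if (inherits(vcf, "VariantTable")) vcf else read_vcf(vcf, min_maf = min_maf)
  pm <- if (is.data.frame(popmap)) popmap else read_population_map(popmap)
  ga <- if (is.null(genes) || is.data.frame(genes)) genes
        else read_gene_annotation(genes)
  unmapped <- setdiff(vt$sample_ids, pm$sample_id)
  if (length(unmapped))
    message(length(unmapped), " VCF sample(s) absent from the population map; ",
            "excluded from grouped statistics")
  scan <- sweep_scan(vt, pm, target, reference, genes = ga,
                     window_size = window_size, step = step,
                     min_variants = min_variants, quantile = quantile,
                     flank = flank)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("target=%s reference=%s", target, reference),
           sprintf("window=%d step=%d min_variants=%d quantile=%g flank=%d",
                   window_size, step, min_variants, quantile, flank),
           sprintf("fst_cutoff=%.6g hp_ratio_cutoff=%.6g",
                   scan$thresholds$fst_cutoff, scan$thresholds$hp_ratio_cutoff),
           sprintf("excluded_windows=%d", sum(scan$stats$excluded)))
  st <- scan$stats
  st_out <- data.frame(chrom = st$chrom, start1 = st$start + 1, end = st$end,
                       st[, c("n_variants", "fst", "hp_target", "hp_ref",
                              "log2_hp_ratio", "pi", "theta_w", "tajima_d",
                              "snp_density", "z_fst", "z_hp", "excluded")])
  write_table(st_out, file.path(out_dir, "window_stats.tsv"), comments = hdr)
  rg <- scan$regions
  rg_out <- if (nrow(rg)) data.frame(chrom = rg$chrom, start1 = rg$start + 1,
                                     end = rg$end,
                                     flank_start1 = rg$flank_start + 1,
                                     flank_end = rg$flank_end,
                                     rg[, c("n_windows", "members", "peak_fst",
                                            "peak_log2_hp_ratio")])
           else data.frame(chrom = character(0), start1 = numeric(0),
                           end = numeric(0))
  write_table(rg_out, file.path(out_dir, "sweep_regions.tsv"), comments = hdr)
  if (!is.null(scan$candidates)) {
    cg <- scan$candidates
    cg_out <- if (nrow(cg)) data.frame(gene_id = cg$gene_id, chrom = cg$chrom,
                                       start1 = cg$start + 1, end = cg$end,
                                       region = cg$region)
             else data.frame(gene_id = character(0))
    write_table(cg_out, file.path(out_dir, "candidate_genes.tsv"), comments = hdr)
  }
  invisible(scan)
}

#' Run the association stage and write its report
#'
#' @param phenotypes TSV path or genotype-phenotype data.frame.
#' @param snps SNP column names (default: every non-phenotype column);
#'   monomorphic SNPs are dropped first.
#' @param out_dir output directory.
#' @param covariates covariates for the linear (size) fits.
#' @return the result data.frame, invisibly.
#' @export
pipeline_assoc <- function(phenotypes, snps = NULL, out_dir,
                           covariates = c("age", "sex")) {
  tab <- if (is.data.frame(phenotypes)) phenotypes else read_genopheno(phenotypes)
  if (is.null(snps))
    snps <- setdiff(names(tab), c("animal_id", "horn_length", "horn_shape",
                                  "age", "sex"))
  snps <- drop_monomorphic(tab, snps)
  res <- assoc_scan(tab, snps, covariates = covariates)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(res, file.path(out_dir, "association.tsv"))
  invisible(res)
}

#' Run the expression stage and write its reports
#'
#' @param ct TSV path or long-format Ct data.frame.
#' @param target_gene,control_gene gene names.
#' @param calibrator calibrator sample or group (see [ddct()]).
#' @param out_dir output directory.
#' @return list with `results` and `comparisons`, invisibly.
#' @export
pipeline_expr <- function(ct, target_gene = "RXFP2", control_gene = "ACTB",
                          calibrator = "SHE", out_dir) {
  ctab <- if (is.data.frame(ct)) ct else read_ct_table(ct)
  res <- ddct(ctab, target_gene, control_gene, calibrator)
  groups <- unique(res$group)
  comps <- list()
  if (length(groups) >= 2L)
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      gc <- group_compare(res, groups[i], groups[j])
      comps[[length(comps) + 1L]] <- data.frame(
        groupA = groups[i], groupB = groups[j], mean_diff = gc$mean_diff,
        t = gc$t, df = gc$df, p_value = gc$p_value)
    }
  comps <- if (length(comps)) do.call(rbind, comps) else
    data.frame(groupA = character(0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(res, file.path(out_dir, "relative_expression.tsv"))
  write_table(comps, file.path(out_dir, "group_comparisons.tsv"))
  invisible(list(results = res, comparisons = comps))
}

#' Run the population-structure stage and write its reports
#'
#' Writes the pairwise F_ST matrix, a neighbor-joining Newick tree over the
#' analysis groups, and PCA sample coordinates.
#'
#' @param vcf VCF path or `VariantTable`.
#' @param popmap TSV path or data.frame.
#' @param out_dir output directory.
#' @param n_components PCA components to report.
#' @return list with `fst`, `tree`, `pca`, invisibly.
#' @export
pipeline_popstruct <- function(vcf, popmap, out_dir, n_components = 2) {
  vt <- if (inherits(vcf, "VariantTable")) vcf else read_vcf(vcf)
  pm <- if (is.data.frame(popmap)) popmap else read_population_map(popmap)
  groups <- unique(pm$group)
  pops <- lapply(groups, function(g) intersect(pop_samples(pm, g), vt$sample_ids))
  names(pops) <- groups
  fst <- fst_distance_matrix(vt, pops)
  tree <- if (length(pops) >= 3L) neighbor_joining(fst) else NULL
  pca <- pca_genotypes(vt, intersect(pm$sample_id, vt$sample_ids),
                       n_components = n_components)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(data.frame(pop = rownames(fst), as.data.frame(fst)),
              file.path(out_dir, "fst_matrix.tsv"))
  if (!is.null(tree)) {
    con <- file(file.path(out_dir, "nj_tree.nwk"), open = "wb")
    writeLines(to_newick(tree), con, sep = "\n")
    close(con)
  }
  write_table(data.frame(sample_id = rownames(pca$scores),
                         as.data.frame(pca$scores)),
              file.path(out_dir, "pca.tsv"))
  invisible(list(fst = fst, tree = tree, pca = pca))
}
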