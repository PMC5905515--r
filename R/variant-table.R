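#' Construct a VariantTable
#'
#' The central genotype container of the package: biallelic SNP sites by
#' samples, with genotypes stored as alt-allele dosages (0, 1, 2 or NA for
#' missing). Sites are kept sorted by chromosome and position; positions are
#' 1-based as in VCF, while all interval arithmetic elsewhere in the package
#' is 0-based half-open.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-nucleotide reference / alternate alleles.
#' @param dosage integer matrix, sites x samples, values in \{0,1,2,NA\}.
#' @param sample_ids unique sample identifiers (column order of `dosage`).
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   carried as an attribute and used to clip window tilings and flanks.
#' @return An object of class `VariantTable`.
#' @export
variant_table <- function(chrom, pos, ref, alt, dosage, sample_ids,
                          chrom_lengths = NULL) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  dosage <- as.matrix(dosage)
  if (n == 0L) dosage <- matrix(NA_integer_, 0L, length(sample_ids))
  stopifnot(nrow(dosage) == n, ncol(dosage) == length(sample_ids))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (n > 0L) {
    nonsnp <- nchar(ref) != 1L | nchar(alt) != 1L
    if (any(nonsnp)) stop("ref/alt must be single nucleotides (biallelic SNPs)")
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
    dosage <- dosage[o, , drop = FALSE]
    if (anyDuplicated(cbind(chrom, pos)))
      warning("duplicated (chrom, pos) sites present")
  }
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- sample_ids
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         dosage = dosage, sample_ids = as.character(sample_ids)),
    chrom_lengths = chrom_lengths,
    class = "VariantTable")
}

#' @export
print.VariantTable <- function(x, ...) {
  cat(sprintf("VariantTable: %d biallelic SNP sites x %d samples\n",
              n_sites(x), length(x$sample_ids)))
  for (ch in unique(x$chrom))
    cat(sprintf("  %s: %d sites\n", ch, sum(x$chrom == ch)))
  invisible(x)
}

#' Number of sites in a VariantTable
#' @param vt a `VariantTable`.
#' @export
n_sites <- function(vt) length(vt$pos)

#' Subset a VariantTable by site index and/or samples
#' @param vt a `VariantTable`.
#' @param sites integer or logical site index.
#' @param samples character vector of sample ids (order preserved).
#' @export
vt_subset <- function(vt, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(vt))
  if (is.null(samples)) samples <- vt$sample_ids
  miss <- setdiff(samples, vt$sample_ids)
  if (length(miss)) stop("samples not in table: ", paste(miss, collapse = ", "))
  variant_table(vt$chrom[sites], vt$pos[sites], vt$ref[sites], vt$alt[sites],
                vt$dosage[sites, samples, drop = FALSE], samples,
                chrom_lengths = attr(vt, "chrom_lengths"))
}

#' Chromosome lengths associated with a VariantTable
#'
#' Uses the lengths recorded at construction (VCF `##contig` headers or the
#' simulator configuration) and falls back to the largest observed position
#' per chromosome.
#' @param vt a `VariantTable`.
#' @export
vt_chrom_lengths <- function(vt) {
  cl <- attr(vt, "chrom_lengths")
  chroms <- unique(vt$chrom)
  obs <- vapply(chroms, function(ch) max(vt$pos[vt$chrom == ch]), numeric(1))
  if (is.null(cl)) return(obs)
  out <- obs
  keep <- intersect(names(cl), chroms)
  out[keep] <- pmax(out[keep], as.numeric(cl[keep]))
  out
}

# Frequency summaries used by every statistic: per-site alt-allele count,
# non-missing genotype count and observed heterozygote count in a sample set.
site_counts <- function(vt, samples) {
  d <- vt$dosage[, samples, drop = FALSE]
  notna <- !is.na(d)
  n <- rowSums(notna)
  alt <- rowSums(d, na.rm = TRUE)
  het <- rowSums(d == 1L, na.rm = TRUE)
  list(n = n, alt = alt, het = het, freq = ifelse(n > 0, alt / (2 * n), NA_real_))
}
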