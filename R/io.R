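#' Read a VCF file into a VariantTable
#'
#' Parses genotypes with \pkg{vcfR} and converts GT fields to alt-allele
#' dosages, ignoring phase. Multi-allelic and non-SNP records are dropped when
#' `biallelic_only = TRUE`. Half-called genotypes (e.g. `./1`) are treated as
#' missing. Chromosome lengths are taken from `##contig` header lines when
#' present.
#'
#' @param path VCF file (plain or gzipped), v4.x with GT fields.
#' @param min_maf optional minor-allele-frequency cutoff; computed over all
#'   non-missing alleles across the whole cohort, sites strictly below it are
#'   removed.
#' @param biallelic_only drop multi-allelic and non-SNP records (default TRUE).
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, min_maf = NULL, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  cl <- parse_contig_lengths(meta)
  fix <- vcf@fix
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("empty cohort: VCF has no sample columns")
  samples <- colnames(gt)[-1L]
  if (nrow(fix) == 0L)
    return(variant_table(character(0), integer(0), character(0), character(0),
                         matrix(NA_integer_, 0, length(samples)), samples,
                         chrom_lengths = cl))
  keep <- rep(TRUE, nrow(fix))
  if (biallelic_only) {
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
      nchar(ref) == 1L & nchar(alt) == 1L &
      ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  }
  fix <- fix[keep, , drop = FALSE]
  gtm <- gt[keep, -1L, drop = FALSE]
  dos <- gt_to_dosage(gtm)
  vt <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                      fix[, "REF"], fix[, "ALT"], dos, samples,
                      chrom_lengths = cl)
  if (!is.null(min_maf)) vt <- filter_maf(vt, min_maf)
  vt
}

parse_contig_lengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  id <- sub(".*ID=([^,>]+).*", "\\1", ln)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
  ok <- !is.na(len)
  if (!any(ok)) return(NULL)
  stats::setNames(len[ok], id[ok])
}

# GT strings -> dosage; any missing or half-called allele makes the call NA.
gt_to_dosage <- function(gtm) {
  g <- sub(":.*", "", as.vector(gtm))
  g <- gsub("|", "/", g, fixed = TRUE)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  d <- unname(map[g])
  matrix(d, nrow = nrow(gtm), ncol = ncol(gtm))
}

#' Filter sites by cohort minor-allele frequency
#' @param vt a `VariantTable`.
#' @param min_maf sites with MAF below this are removed.
#' @export
filter_maf <- function(vt, min_maf) {
  if (n_sites(vt) == 0L) return(vt)
  sc <- site_counts(vt, vt$sample_ids)
  maf <- pmin(sc$freq, 1 - sc$freq)
  keep <- !is.na(maf) & maf >= min_maf
  vt_subset(vt, sites = keep)
}

#' Read a sample-to-breed population map
#'
#' Two or three tab-separated columns: `sample<TAB>breed[<TAB>group]`; lines
#' starting with `#` are comments. When the group column is absent the group
#' defaults to the breed, so each breed is its own analysis group.
#'
#' @param path TSV file.
#' @return data.frame with columns `sample_id`, `breed`, `group`.
#' @export
read_population_map <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (!length(ln))
    return(data.frame(sample_id = character(0), breed = character(0),
                      group = character(0)))
  parts <- strsplit(ln, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 2L | nc > 3L))
    stop("population map lines must have 2 or 3 tab-separated fields")
  sample_id <- vapply(parts, `[`, "", 1L)
  breed <- vapply(parts, `[`, "", 2L)
  group <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else p[2L], "")
  if (anyDuplicated(sample_id))
    stop("duplicate sample id in population map: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  data.frame(sample_id = sample_id, breed = breed, group = group)
}

#' Samples belonging to an analysis group (or breed)
#' @param popmap data.frame from [read_population_map()].
#' @param group group or breed label.
#' @export
pop_samples <- function(popmap, group) {
  s <- popmap$sample_id[popmap$group == group | popmap$breed == group]
  unique(s)
}

#' Read gene annotation from BED or GFF3
#'
#' Records are unified to 0-based half-open internal coordinates. For GFF3
#' only `gene`-type features are kept. Dialect is sniffed from the file
#' extension unless given.
#'
#' @param path BED or GFF3 file.
#' @param format one of `"auto"`, `"bed"`, `"gff3"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0))
  ln <- readLines(path)
  if (!any(nzchar(trimws(ln)) & !grepl("^#", ln))) return(empty)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("failed to parse ", format, " annotation: ",
                             conditionMessage(e)))
  if (format == "gff3") {
    type <- as.character(gr$type)
    gr <- gr[type == "gene"]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  } else {
    ids <- gr$name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  }
  out <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)))
  bad <- out$start >= out$end
  if (any(bad))
    stop("annotation record with start >= end: ",
         paste(out$gene_id[bad], collapse = ", "))
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene ids in annotation")
  out
}

#' Write a result table as deterministic TSV
#'
#' Plain tab-separated output with a header row, no quoting and no row names;
#' identical input yields byte-identical files.
#'
#' @param records data.frame (may have zero rows).
#' @param path output file.
#' @param comments optional character vector written first as `#`-prefixed
#'   provenance lines.
#' @export
write_table <- function(records, path, comments = NULL) {
  if (is.null(records)) stop("records must be non-null")
  records <- as.data.frame(records)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", comments), con, sep = "\n")
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path TSV file; `#` comment lines are skipped.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
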