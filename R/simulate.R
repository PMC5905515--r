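#' Simulation configuration for synthetic cohorts
#'
#' One seeded recipe drives every generator, so a full synthetic study —
#' multi-population genotypes with tunable background differentiation,
#' injected sweep regions, gene annotation, horn phenotypes and Ct tables —
#' is reproducible from a single object.
#'
#' @param seed mandatory RNG seed.
#' @param pop_names population (breed) labels.
#' @param samples_per_pop diploid individuals per population (recycled).
#' @param chrom_lengths named chromosome lengths in bp.
#' @param n_sites total SNP count, placed uniformly, split across chromosomes
#'   proportionally to length.
#' @param F Balding-Nichols differentiation parameter per population
#'   (recycled); `F = 0` means all populations share the ancestral frequency.
#' @param ancestral_bounds bounds of the ancestral allele frequency; defaults
#'   to `c(0.001, 0.999)` for the neutral spectrum and `c(0.05, 0.95)` for the
#'   uniform one.
#' @param spectrum shape of the ancestral site-frequency spectrum within the
#'   bounds: `"neutral"` (density proportional to 1/p; combined with binomial
#'   sampling this yields the equilibrium 1/i sample spectrum, so Tajima's D
#'   centers on zero) or `"uniform"`.
#' @param groups optional named vector breed -> analysis group.
#' @param sweeps list of sweep specs: each `list(pop=, chrom=, start=, end=,
#'   target_freq=)` with 0-based half-open interval bounds.
#' @param phenotype list of phenotype-model parameters; see
#'   [simulate_phenotypes()] for defaults mirroring the 182-animal horn
#'   cohort (additive effect 11.75 cm per allele copy, residual sd 8 cm).
#' @param expression list of Ct-model parameters; see [simulate_ct_table()].
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       pop_names = c("PT", "MGS"),
                       samples_per_pop = 25,
                       chrom_lengths = c(chr1 = 3e6),
                       n_sites = 5000,
                       F = 0.1,
                       ancestral_bounds = NULL,
                       spectrum = c("neutral", "uniform"),
                       groups = NULL,
                       sweeps = list(),
                       phenotype = list(),
                       expression = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  F <- rep_len(F, length(pop_names))
  if (any(F < 0 | F >= 1)) stop("F must be in [0, 1)")
  spectrum <- match.arg(spectrum)
  if (is.null(ancestral_bounds))
    ancestral_bounds <- if (spectrum == "neutral") c(0.001, 0.999)
                        else c(0.05, 0.95)
  if (any(ancestral_bounds <= 0 | ancestral_bounds > 1) ||
      ancestral_bounds[1] > ancestral_bounds[2])
    stop("invalid ancestral frequency bounds")
  samples_per_pop <- rep_len(samples_per_pop, length(pop_names))
  for (sw in sweeps) {
    stopifnot(!is.null(sw$pop), !is.null(sw$chrom),
              sw$start >= 0, sw$end > sw$start)
    if (!sw$pop %in% pop_names) stop("sweep population unknown: ", sw$pop)
    if (!sw$chrom %in% names(chrom_lengths))
      stop("sweep chromosome unknown: ", sw$chrom)
  }
  structure(list(seed = as.integer(seed), pop_names = pop_names,
                 samples_per_pop = samples_per_pop,
                 chrom_lengths = chrom_lengths, n_sites = n_sites, F = F,
                 ancestral_bounds = ancestral_bounds, spectrum = spectrum,
                 groups = groups,
                 sweeps = sweeps, phenotype = phenotype,
                 expression = expression),
            class = "sim_config")
}

#' Simulate multi-population genotypes under the Balding-Nichols model
#'
#' Per site an ancestral frequency p0 is drawn within the configured bounds
#' (neutral 1/p spectrum by default); each population's allele frequency is
#' drawn from
#' Beta(p0 (1-F)/F, (1-p0)(1-F)/F) — so the expected Weir-Cockerham F_ST
#' between populations equals F — and genotypes are Binomial(2, freq).
#' Fully reproducible from the seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `vt` (a `VariantTable`, alt = derived allele) and
#'   `popmap` (data.frame `sample_id`, `breed`, `group`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lens <- cfg$chrom_lengths
  n_per <- round(cfg$n_sites * lens / sum(lens))
  lo <- cfg$ancestral_bounds[1]; hi <- cfg$ancestral_bounds[2]
  ids <- lapply(seq_along(cfg$pop_names), function(i)
    sprintf("%s_%02d", cfg$pop_names[i], seq_len(cfg$samples_per_pop[i])))
  sample_ids <- unlist(ids)
  nucs <- c("A", "C", "G", "T")
  # oversample candidate sites, keep only those segregating in the cohort (a
  # variant file holds variants), then thin back to the requested count
  draw_chrom <- function(ch, n_target) {
    if (n_target == 0L) return(NULL)
    cand <- min(lens[[ch]], ceiling(3 * n_target) + 20L)
    pos <- sort(sample.int(lens[[ch]], cand))
    m <- length(pos)
    p0 <- if (identical(cfg$spectrum, "uniform")) stats::runif(m, lo, hi)
          else lo * (hi / lo)^stats::runif(m)  # density proportional to 1/p
    cols <- vector("list", length(cfg$pop_names))
    for (i in seq_along(cfg$pop_names)) {
      Fi <- cfg$F[i]
      freq <- if (Fi == 0) p0 else
        stats::rbeta(m, p0 * (1 - Fi) / Fi, (1 - p0) * (1 - Fi) / Fi)
      ns <- cfg$samples_per_pop[i]
      cols[[i]] <- matrix(stats::rbinom(m * ns, 2, freq), nrow = m, ncol = ns)
    }
    dosage <- do.call(cbind, cols)
    tot <- rowSums(dosage)
    seg <- which(tot > 0L & tot < 2L * ncol(dosage))
    if (length(seg) > n_target)
      seg <- sort(sample(seg, n_target))
    else if (length(seg) < n_target)
      warning("chromosome ", ch, ": only ", length(seg),
              " segregating sites of ", n_target, " requested")
    ref <- sample(nucs, length(seg), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), "")
    list(chrom = rep(ch, length(seg)), pos = pos[seg], ref = ref, alt = alt,
         dosage = dosage[seg, , drop = FALSE])
  }
  parts <- lapply(names(lens), function(ch) draw_chrom(ch, n_per[[ch]]))
  parts <- parts[!vapply(parts, is.null, TRUE)]
  chrom <- unlist(lapply(parts, `[[`, "chrom"))
  pos <- unlist(lapply(parts, `[[`, "pos"))
  ref <- unlist(lapply(parts, `[[`, "ref"))
  alt <- unlist(lapply(parts, `[[`, "alt"))
  dosage <- do.call(rbind, lapply(parts, `[[`, "dosage"))
  vt <- variant_table(chrom, pos, ref, alt, dosage, sample_ids,
                      chrom_lengths = lens)
  breed <- rep(cfg$pop_names, cfg$samples_per_pop)
  group <- if (is.null(cfg$groups)) breed else {
    g <- cfg$groups[breed]
    ifelse(is.na(g), breed, g)
  }
  popmap <- data.frame(sample_id = sample_ids, breed = breed,
                       group = unname(group))
  list(vt = vt, popmap = popmap)
}

#' Inject a selective-sweep signature into one population
#'
#' Within the interval, the target population's derived (alt) allele
#' frequencies are redrawn tightly around `target_freq` — all sites aligned to
#' the same haplotype direction — and its genotypes resampled, producing the
#' sweep signature of excess differentiation and heterozygosity loss. Other
#' populations are untouched.
#'
#' @param vt a `VariantTable`.
#' @param pop sample ids of the swept population.
#' @param interval `list(chrom=, start=, end=)`, 0-based half-open.
#' @param target_freq post-sweep derived-allele frequency (default 0.98).
#' @param seed RNG seed.
#' @param concentration Beta concentration around `target_freq` (default 200).
#' @export
inject_sweep <- function(vt, pop, interval, target_freq = 0.98, seed = 1,
                         concentration = 200) {
  idx <- which(vt$chrom == interval$chrom &
                 vt$pos - 1 >= interval$start & vt$pos - 1 < interval$end)
  if (!length(idx)) stop("empty sweep interval: no sites in ", interval$chrom,
                         ":", interval$start, "-", interval$end)
  miss <- setdiff(pop, vt$sample_ids)
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  set.seed(seed)
  f <- stats::rbeta(length(idx), target_freq * concentration,
                    (1 - target_freq) * concentration)
  g <- matrix(stats::rbinom(length(idx) * length(pop), 2, f),
              nrow = length(idx))
  vt$dosage[idx, pop] <- g
  vt
}

#' Simulate a gene annotation aligned with sweep specs
#'
#' Genes are tiled along every chromosome; additionally, for each sweep spec,
#' three marker genes are placed for recovery tests: one inside the interval,
#' one just downstream (within a 15-kb flank of the interval), and one far
#' downstream (beyond any plausible flank). Deterministic — no RNG.
#'
#' @param cfg a [sim_config()] (uses `chrom_lengths` and `sweeps`).
#' @param gene_length,spacing tiling geometry in bp.
#' @return annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @export
simulate_gene_annotation <- function(cfg, gene_length = 5000, spacing = 1e5) {
  rows <- list()
  for (ch in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - gene_length), by = spacing)
    if (length(starts))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("bg_%s_%03d", ch, seq_along(starts)),
        chrom = ch, start = starts, end = starts + gene_length, strand = "+")
  }
  for (k in seq_along(cfg$sweeps)) {
    sw <- cfg$sweeps[[k]]
    len <- cfg$chrom_lengths[[sw$chrom]]
    mid <- floor((sw$start + sw$end) / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = paste0("sweep", k, c("_inside", "_flank", "_far")),
      chrom = sw$chrom,
      start = c(mid - 1000, sw$end + 1000, min(sw$end + 80000, len - 5000)),
      end = c(mid + 1000, sw$end + 5000, min(sw$end + 85000, len)),
      strand = "+")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Simulate a horn-phenotype cohort from a causal SNP
#'
#' Draws a cohort of `n` animals whose genotype at the causal SNP follows its
#' derived-allele frequency in the chosen samples; horn length is
#' `intercept + beta * (derived-allele dosage) + age and sex terms + noise`,
#' left-censored at 0 (polled); horn shape for long-horned animals is drawn
#' from a logistic model on the recessive (derived-homozygote) indicator,
#' mirroring the overrepresentation of derived homozygotes among spiral
#' (SHE-type) horns. Length bands set the categories: 0 = polled, (0, 12] =
#' scurred, > 12 = SHE / TCF (a small fraction labelled uncertain).
#'
#' @param vt a `VariantTable` containing the causal SNP.
#' @param causal_site site index of the causal SNP in `vt`.
#' @param cfg a [sim_config()]; elements of `cfg$phenotype` override the
#'   defaults: `n` (182), `intercept` (18 cm), `beta` (11.75 cm per derived
#'   allele copy), `sd` (8 cm), `age_range` (1-8 y), `age_beta` (0.8 cm/y),
#'   `sex_ratio` (0.5), `sex_beta` (4 cm for males), `shape_intercept` (-1.2),
#'   `shape_logodds` (3, log-odds of SHE for derived homozygotes),
#'   `uncertain_rate` (0.02), `freq` (derived-allele frequency in the field
#'   cohort, default 0.8; `NA` uses the SNP's frequency in `pop`), `pop`
#'   (samples defining that fallback frequency; default all), `n_null_snps`
#'   (0 extra genotype columns with no effect).
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return `GenotypePhenotypeTable` data.frame with attribute `ref_alleles`.
#' @export
simulate_phenotypes <- function(vt, causal_site, cfg, seed = cfg$seed + 1L) {
  p <- utils::modifyList(list(
    n = 182, intercept = 18, beta = 11.75, sd = 8,
    age_range = c(1, 8), age_beta = 0.8, sex_ratio = 0.5, sex_beta = 4,
    shape_intercept = -1.2, shape_logodds = 3, uncertain_rate = 0.02,
    freq = 0.8, pop = NULL, n_null_snps = 0), cfg$phenotype)
  samples <- if (is.null(p$pop)) vt$sample_ids else p$pop
  sc <- site_counts(vt_subset(vt, causal_site), samples)
  fvt <- sc$freq
  if (is.na(fvt) || fvt == 0 || fvt == 1)
    stop("causal SNP is monomorphic in the chosen samples")
  f <- if (is.na(p$freq)) fvt else p$freq
  set.seed(seed)
  dos <- stats::rbinom(p$n, 2, f)
  age <- stats::runif(p$n, p$age_range[1], p$age_range[2])
  sex <- ifelse(stats::runif(p$n) < p$sex_ratio, "M", "F")
  len <- p$intercept + p$beta * dos + p$age_beta * age +
    p$sex_beta * (sex == "M") + stats::rnorm(p$n, 0, p$sd)
  len <- pmax(len, 0)
  shape <- character(p$n)
  shape[len == 0] <- "polled"
  shape[len > 0 & len <= 12] <- "scurred"
  long <- which(len > 12)
  pr_she <- stats::plogis(p$shape_intercept + p$shape_logodds * (dos[long] == 2))
  shape[long] <- ifelse(stats::runif(length(long)) < pr_she, "SHE", "TCF")
  unc <- long[stats::runif(length(long)) < p$uncertain_rate]
  shape[unc] <- "uncertain"
  ref <- vt$ref[causal_site]; alt <- vt$alt[causal_site]
  gt <- c(paste0(ref, ref), paste0(ref, alt), paste0(alt, alt))[dos + 1L]
  snp_id <- paste0(vt$chrom[causal_site], "_", vt$pos[causal_site])
  tab <- data.frame(animal_id = sprintf("an_%03d", seq_len(p$n)),
                    horn_length = len, horn_shape = shape,
                    age = age, sex = sex)
  tab[[snp_id]] <- gt
  refs <- stats::setNames(ref, snp_id)
  if (p$n_null_snps > 0) for (j in seq_len(p$n_null_snps)) {
    fj <- stats::runif(1, 0.2, 0.8)
    dj <- stats::rbinom(p$n, 2, fj)
    id <- sprintf("null_snp_%02d", j)
    tab[[id]] <- c("AA", "AG", "GG")[dj + 1L]
    refs[id] <- "A"
  }
  attr(tab, "ref_alleles") <- refs
  attr(tab, "causal_snp") <- snp_id
  attr(tab, "causal_alt") <- alt
  tab
}

#' Simulate a grouped Ct table for ddCt analysis
#'
#' Per sample the control-gene Ct is Normal(control_mean, control_sd); the
#' target-gene Ct adds the group's true delta-Ct plus biological noise; each
#' (sample, gene) gets technical replicates with replicate noise. Group sizes
#' default to the 4 SHE / 4 TCF / 5 scurred design.
#'
#' @param cfg a [sim_config()]; elements of `cfg$expression` override:
#'   `group_sizes` (named, default c(SHE=4, TCF=4, scurred=5)),
#'   `group_delta_ct` (true delta Ct per group, default c(4, 2, 2.3)),
#'   `control_mean` (20), `control_sd` (0.2), `bio_sd` (0.3), `rep_sd` (0.1),
#'   `replicates` (3), `target_gene` ("RXFP2"), `control_gene` ("ACTB").
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return long-format `CtTable` data.frame: sample_id, group, gene,
#'   replicate, ct, is_control.
#' @export
simulate_ct_table <- function(cfg, seed = cfg$seed + 2L) {
  e <- utils::modifyList(list(
    group_sizes = c(SHE = 4, TCF = 4, scurred = 5),
    group_delta_ct = c(SHE = 4, TCF = 2, scurred = 2.3),
    control_mean = 20, control_sd = 0.2, bio_sd = 0.3, rep_sd = 0.1,
    replicates = 3, target_gene = "RXFP2", control_gene = "ACTB"),
    cfg$expression)
  set.seed(seed)
  rows <- list()
  for (g in names(e$group_sizes)) {
    for (i in seq_len(e$group_sizes[[g]])) {
      sid <- sprintf("%s_%d", g, i)
      ctl <- stats::rnorm(1, e$control_mean, e$control_sd)
      tgt <- ctl + e$group_delta_ct[[g]] + stats::rnorm(1, 0, e$bio_sd)
      for (r in seq_len(e$replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g,
          gene = c(e$target_gene, e$control_gene),
          replicate = r,
          ct = c(tgt, ctl) + stats::rnorm(2, 0, e$rep_sd),
          is_control = c(FALSE, TRUE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a VariantTable as VCF v4.2
#'
#' Minimal deterministic GT-only emission with `##contig` header lines so a
#' round trip through [read_vcf()] is lossless for dosages, positions and
#' sample order.
#'
#' @param vt a `VariantTable`.
#' @param path output file (plain text).
#' @export
write_vcf <- function(vt, path) {
  cl <- vt_chrom_lengths(vt)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$sample_ids), collapse = "\t"))
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(vt), ncol = length(vt$sample_ids))
  ok <- !is.na(vt$dosage)
  gt[ok] <- gtcode[vt$dosage[ok] + 1L]
  body <- if (n_sites(vt) > 0) {
    fixed <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", ".",
                   "GT", sep = "\t")
    paste(fixed, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Write a population map TSV
#' @param popmap data.frame `sample_id`, `breed`, `group`.
#' @param path output file.
#' @export
write_popmap <- function(popmap, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(popmap$sample_id, popmap$breed, popmap$group, sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' Write a gene annotation as BED
#' @param genes annotation data.frame (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(genes))
    writeLines(paste(genes$chrom, format(genes$start, scientific = FALSE,
                                         trim = TRUE),
                     format(genes$end, scientific = FALSE, trim = TRUE),
                     genes$gene_id, 0, genes$strand, sep = "\t"),
               con, sep = "\n")
  invisible(path)
}
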