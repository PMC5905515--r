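#' Pairwise F_ST distance matrix between populations
#'
#' Genome-wide Weir-Cockerham F_ST (ratio of averages over all sites) for
#' every pair of populations; slightly negative estimates are clamped to 0 so
#' the matrix can be used as a distance.
#'
#' @param vt a `VariantTable`.
#' @param pops named list of sample-id vectors.
#' @return symmetric matrix with zero diagonal.
#' @export
fst_distance_matrix <- function(vt, pops) {
  if (length(pops) < 2L) stop("need at least 2 populations")
  small <- names(pops)[lengths(pops) < 2L]
  if (length(small))
    stop("population with fewer than 2 samples: ", paste(small, collapse = ", "))
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(names(pops), names(pops)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- fst_window(vt, pops[[i]], pops[[j]])
    m[i, j] <- m[j, i] <- max(0, as.numeric(f))
  }
  m
}

#' Allele-sharing distance between samples
#'
#' d(i, j) = sum over sites, non-missing in both samples, of the absolute
#' dosage difference (number of allele differences).
#'
#' @param vt a `VariantTable`.
#' @param samples sample ids (default all).
#' @export
allele_sharing_distance <- function(vt, samples = vt$sample_ids) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  d <- vt$dosage[, samples, drop = FALSE]
  k <- length(samples)
  m <- matrix(0, k, k, dimnames = list(samples, samples))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- abs(d[, i] - d[, j])
    m[i, j] <- m[j, i] <- sum(diff, na.rm = TRUE)
  }
  m
}

#' Mean allele-frequency difference between populations
#'
#' d(A, B) = mean over sites of |alt-freq_A - alt-freq_B| (average delta-AF).
#'
#' @inheritParams fst_distance_matrix
#' @export
allele_freq_distance <- function(vt, pops) {
  if (length(pops) < 2L) stop("need at least 2 populations")
  freqs <- lapply(pops, function(s) site_counts(vt, s)$freq)
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(names(pops), names(pops)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    dd <- abs(freqs[[i]] - freqs[[j]])
    m[i, j] <- m[j, i] <- mean(dd, na.rm = TRUE)
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}), returning a `phylo` object;
#' serialize with [to_newick()].
#'
#' @param dm symmetric distance matrix with labels.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 labels for neighbor joining")
  if (is.null(rownames(dm))) stop("distance matrix must be labelled")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  ape::nj(dm)
}

#' Newick serialization of a tree
#' @param tree a `phylo` object.
#' @export
to_newick <- function(tree) ape::write.tree(tree)

#' Principal component analysis of genotypes
#'
#' Sites are mean-centered and scaled by sqrt(p(1-p)) of their mean allele
#' frequency (EIGENSOFT-style); missing dosages are mean-imputed per site;
#' sample coordinates are the top eigenvectors of the sample covariance. Sign
#' convention: within each component the largest-magnitude coordinate is made
#' positive.
#'
#' @param vt a `VariantTable`.
#' @param samples sample ids (default all).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained` (fraction
#'   of variance per component).
#' @export
pca_genotypes <- function(vt, samples = vt$sample_ids, n_components = 2) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  d <- vt$dosage[, samples, drop = FALSE]
  mu <- rowMeans(d, na.rm = TRUE)
  p <- mu / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites: PCA undefined (zero variance)")
  d <- d[poly, , drop = FALSE]; mu <- mu[poly]; p <- p[poly]
  x <- sweep(d, 1, mu)
  x[is.na(x)] <- 0  # mean imputation after centering
  x <- x / sqrt(p * (1 - p))
  cv <- crossprod(x) / nrow(x)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= 1e-12) stop("zero variance among samples: PCA undefined")
  k <- min(n_components, length(samples))
  scores <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- samples
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       explained = pmax(eg$values, 0)[seq_len(k)] / sum(pmax(eg$values, 0)))
}

#' EM estimate of two-locus haplotype frequencies
#'
#' Maximum-likelihood frequencies of the four haplotypes from a 3x3 table of
#' unphased two-locus genotype counts (rows: alt dosage at locus 1, columns:
#' locus 2, both 0/1/2), resolving the double-heterozygote phase ambiguity by
#' EM. Convergence when the largest frequency change is below `tol` or after
#' `max_iter` iterations. The observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' @param counts 3x3 non-negative matrix of genotype counts.
#' @param tol convergence tolerance on frequencies (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return list with `hap_freqs` (named `h00`, `h01`, `h10`, `h11`; the digit
#'   pair is the alt-allele indicator at locus 1 / locus 2), `loglik`,
#'   `iterations`.
#' @export
em_haplotype_freq <- function(counts, tol = 1e-10, max_iter = 1000) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  N <- sum(counts)
  if (N == 0) stop("total genotype count is zero")
  pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * N)         # alt freq locus 1
  pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  f <- c(h00 = (1 - pA) * (1 - pB), h01 = (1 - pA) * pB,
         h10 = pA * (1 - pB), h11 = pA * pB)
  f <- pmax(f, 1e-12); f <- f / sum(f)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    denom <- f["h11"] * f["h00"] + f["h10"] * f["h01"]
    w <- if (denom > 0) unname(f["h11"] * f["h00"] / denom) else 0.5
    ndh <- counts[2, 2]
    c11 <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3] + w * ndh
    c10 <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1] + (1 - w) * ndh
    c01 <- 2 * counts[1, 3] + counts[2, 3] + counts[1, 2] + (1 - w) * ndh
    c00 <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1] + w * ndh
    fnew <- c(h00 = c00, h01 = c01, h10 = c10, h11 = c11) / (2 * N)
    delta <- max(abs(fnew - f))
    f <- fnew
    ll <- hap_loglik(counts, f)
    if (ll < ll_old - 1e-9)
      stop("EM log-likelihood decreased; this should not happen")
    ll_old <- ll
    if (delta < tol) break
  }
  list(hap_freqs = f, loglik = ll_old, iterations = it)
}

# observed-data log-likelihood of a 3x3 genotype table under given haplotype
# frequencies (HWE random pairing)
hap_loglik <- function(counts, f) {
  P <- hap_genotype_probs(f)
  sel <- counts > 0
  sum(counts[sel] * log(P[sel]))
}

hap_genotype_probs <- function(f) {
  h00 <- f[["h00"]]; h01 <- f[["h01"]]; h10 <- f[["h10"]]; h11 <- f[["h11"]]
  P <- matrix(0, 3, 3)
  P[1, 1] <- h00^2;        P[1, 2] <- 2 * h00 * h01; P[1, 3] <- h01^2
  P[2, 1] <- 2 * h00 * h10; P[2, 2] <- 2 * (h11 * h00 + h10 * h01)
  P[2, 3] <- 2 * h01 * h11
  P[3, 1] <- h10^2;        P[3, 2] <- 2 * h10 * h11; P[3, 3] <- h11^2
  pmax(P, 1e-300)
}

#' Linkage-disequilibrium coefficients from haplotype frequencies
#'
#' D = f(AB) - pA pB; D' = |D| / D_max with D_max = min(pA qB, qA pB) when
#' D > 0 and min(pA pB, qA qB) otherwise; r^2 = D^2 / (pA qA pB qB). A
#' monomorphic locus yields NA sentinels.
#'
#' @param hap_freqs named vector as returned by [em_haplotype_freq()] (element
#'   `hap_freqs`), or the full list.
#' @return list with `D`, `d_prime`, `r2`, `pA`, `pB`.
#' @export
ld_pair <- function(hap_freqs) {
  if (is.list(hap_freqs) && !is.null(hap_freqs$hap_freqs))
    hap_freqs <- hap_freqs$hap_freqs
  pA <- hap_freqs[["h10"]] + hap_freqs[["h11"]]
  pB <- hap_freqs[["h01"]] + hap_freqs[["h11"]]
  qA <- 1 - pA; qB <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(list(D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                pA = pA, pB = pB))
  D <- hap_freqs[["h11"]] - pA * pB
  dmax <- if (D > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  d_prime <- if (D == 0) 0 else abs(D) / dmax
  r2 <- D^2 / (pA * qA * pB * qB)
  list(D = D, d_prime = d_prime, r2 = r2, pA = pA, pB = pB)
}

# r^2 between two dosage columns via EM haplotype frequencies (Haploview
# semantics); complete cases only. Returns NA when either locus is
# monomorphic among complete cases.
r2_em <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) return(NA_real_)
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  em <- em_haplotype_freq(tab)
  ld_pair(em$hap_freqs)$r2
}

#' Mean r^2 by physical distance (LD decay)
#'
#' Intra-chromosomal site pairs within `max_dist`, after per-site MAF and
#' missingness filters, are (optionally) subsampled and their EM-based r^2
#' values averaged within distance bins.
#'
#' @param vt a `VariantTable`.
#' @param pop sample ids.
#' @param max_dist largest pair distance considered, bp.
#' @param bins distance bin edges in bp (default 1-kb bins up to `max_dist`).
#' @param min_maf minor-allele-frequency filter (default 0.1).
#' @param missing_cutoff maximum per-site missing fraction (default 0.2).
#' @param max_pairs subsample cap on the number of pairs.
#' @param seed RNG seed for the subsample.
#' @return data.frame with `bin_start`, `bin_end`, `n_pairs`, `mean_r2`
#'   (NA for empty bins).
#' @export
ld_decay <- function(vt, pop = vt$sample_ids, max_dist = 50000, bins = NULL,
                     min_maf = 0.1, missing_cutoff = 0.2, max_pairs = 10000,
                     seed = 1) {
  if (is.null(bins)) bins <- seq(0, max_dist, by = 1000)
  sc <- site_counts(vt, pop)
  maf <- pmin(sc$freq, 1 - sc$freq)
  missfrac <- 1 - sc$n / length(pop)
  keep <- which(!is.na(maf) & maf >= min_maf & missfrac <= missing_cutoff)
  pr_i <- integer(0); pr_j <- integer(0)
  for (ch in unique(vt$chrom)) {
    ii <- keep[vt$chrom[keep] == ch]
    if (length(ii) < 2L) next
    pos <- vt$pos[ii]
    for (a in seq_len(length(ii) - 1L)) {
      b <- a + 1L
      while (b <= length(ii) && pos[b] - pos[a] <= max_dist) {
        pr_i <- c(pr_i, ii[a]); pr_j <- c(pr_j, ii[b])
        b <- b + 1L
      }
    }
  }
  if (length(pr_i) > max_pairs) {
    set.seed(seed)
    sel <- sort(sample.int(length(pr_i), max_pairs))
    pr_i <- pr_i[sel]; pr_j <- pr_j[sel]
  }
  d <- vt$dosage[, pop, drop = FALSE]
  dist <- vt$pos[pr_j] - vt$pos[pr_i]
  r2 <- vapply(seq_along(pr_i),
               function(k) r2_em(d[pr_i[k], ], d[pr_j[k], ]), numeric(1))
  bin <- cut(dist, breaks = bins, right = TRUE, include.lowest = TRUE)
  out <- data.frame(bin_start = bins[-length(bins)], bin_end = bins[-1])
  out$n_pairs <- as.integer(table(bin))
  means <- tapply(r2, bin, mean, na.rm = TRUE)
  out$mean_r2 <- as.numeric(means)
  out
}

#' LD pruning of SNP sites
#'
#' PLINK-style `indep-pairwise`: a window of `window_snps` sites advances by
#' `step_snps`; within each window, for any surviving pair with r^2 above
#' `r2_max` the later-position site is removed, repeated until no offending
#' pair remains.
#'
#' @param vt a `VariantTable` (sites sorted).
#' @param pop sample ids used for r^2 (default all).
#' @param window_snps,step_snps,r2_max pruning parameters (defaults 50, 5,
#'   0.2).
#' @return integer vector of retained site indices.
#' @export
ld_prune <- function(vt, pop = vt$sample_ids, window_snps = 50, step_snps = 5,
                     r2_max = 0.2) {
  d <- vt$dosage[, pop, drop = FALSE]
  removed <- rep(FALSE, n_sites(vt))
  cache <- new.env(parent = emptyenv())
  pair_r2 <- function(i, j) {
    key <- paste0(i, "_", j)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- r2_em(d[i, ], d[j, ])
    cache[[key]] <- v
    v
  }
  for (ch in unique(vt$chrom)) {
    idx <- which(vt$chrom == ch)
    if (length(idx) < 2L) next
    starts <- seq(1L, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      repeat {
        alive <- win[!removed[win]]
        if (length(alive) < 2L) break
        hit <- FALSE
        for (a in seq_len(length(alive) - 1L)) {
          for (b in (a + 1L):length(alive)) {
            r2 <- pair_r2(alive[a], alive[b])
            if (!is.na(r2) && r2 > r2_max) {
              removed[alive[b]] <- TRUE  # drop the later-position site
              hit <- TRUE
              break
            }
          }
          if (hit) break
        }
        if (!hit) break
      }
    }
  }
  which(!removed)
}
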