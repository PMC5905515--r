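#' Tile chromosomes with sliding windows
#'
#' Windows are 0-based half-open, start at 0 and advance by `step` while the
#' start lies inside the chromosome; the last windows are truncated at the
#' chromosome end.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window_size window width in bp (default 30 kb).
#' @param step stride in bp (default 15 kb).
#' @return data.frame with columns `chrom`, `start`, `end`, `index`.
#' @export
make_windows <- function(chrom_lengths, window_size = 30000, step = 15000) {
  if (step <= 0) stop("step must be positive")
  if (step > window_size) stop("step must not exceed window_size")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len <= 0) {
      warning("chromosome ", ch, " has non-positive length; no windows")
      return(NULL)
    }
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-site allele frequencies within a population
#'
#' Major/minor alleles are assigned per site within the given sample set;
#' sites with no non-missing call are flagged unusable and skipped downstream.
#'
#' @param vt a `VariantTable`.
#' @param pop character vector of sample ids.
#' @return data.frame with columns `p` (major), `q` (minor), `n_chrom`
#'   (non-missing allele count), `alt_freq`, `usable`.
#' @export
site_frequencies <- function(vt, pop) {
  if (!length(pop)) stop("empty population")
  miss <- setdiff(pop, vt$sample_ids)
  if (length(miss)) stop("samples not in table: ", paste(miss, collapse = ", "))
  sc <- site_counts(vt, pop)
  f <- sc$freq
  data.frame(p = pmax(f, 1 - f), q = pmin(f, 1 - f),
             n_chrom = 2L * sc$n, alt_freq = f, usable = sc$n > 0L)
}

#' Pooled heterozygosity of a window
#'
#' \eqn{H_P = 2 \Sigma p \Sigma q / (\Sigma p + \Sigma q)^2} where the sums
#' run over the major (p) and minor (q) allele frequencies of all usable SNP
#' sites in the window. Bounded by 0.5, reached when \eqn{\Sigma p = \Sigma q}.
#'
#' @param freqs data.frame from [site_frequencies()] (or any with `p`, `q`
#'   and optionally `usable` columns).
#' @return scalar `H_P`, or `NA` when no site is usable.
#' @export
pooled_heterozygosity <- function(freqs) {
  if (!is.null(freqs$usable)) freqs <- freqs[freqs$usable, , drop = FALSE]
  if (nrow(freqs) == 0L) return(NA_real_)
  sp <- sum(freqs$p); sq <- sum(freqs$q)
  2 * sp * sq / (sp + sq)^2
}

#' Heterozygosity-loss log ratio
#'
#' `log2(hp_ref / hp_target)`: positive values indicate loss of
#' heterozygosity in the target population relative to the reference. A zero
#' target heterozygosity yields `+Inf`, an infinite-loss sentinel that always
#' exceeds any finite threshold (no pseudocount is applied).
#'
#' @param hp_ref,hp_target pooled heterozygosities.
#' @export
hp_log_ratio <- function(hp_ref, hp_target) {
  log2(hp_ref / hp_target)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for two
# populations, from dosages. Sites with fewer than one genotyped individual
# in either population, or nbar <= 1, are returned as NA and excluded from
# window sums.
wc_site_components <- function(vt, popA, popB) {
  a1 <- site_counts(vt, popA); b1 <- site_counts(vt, popB)
  n1 <- a1$n; n2 <- b1$n
  p1 <- a1$freq; p2 <- b1$freq
  h1 <- ifelse(n1 > 0, a1$het / n1, NA_real_)
  h2 <- ifelse(n2 > 0, b1$het / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 > 0 & n2 > 0 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  # monomorphic across both pops: components are all zero; drop from sums so
  # they contribute nothing to either numerator or denominator
  mono <- ok & (pbar == 0 | pbar == 1)
  a[mono] <- NA_real_; b[mono] <- NA_real_; cc[mono] <- NA_real_
  list(a = a, b = b, c = cc)
}

wc_ratio <- function(comp, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(comp$a)
  a <- comp$a[idx]; b <- comp$b[idx]; cc <- comp$c[idx]
  num <- sum(a, na.rm = TRUE)
  den <- sum(a + b + cc, na.rm = TRUE)
  if (!any(is.finite(a)) || den == 0) return(NA_real_)
  num / den
}

#' Window F_ST between two populations
#'
#' Weir & Cockerham (1984) theta-hat with ratio-of-averages aggregation:
#' per-site variance components a, b, c are accumulated over all usable sites
#' in the window and F_ST = sum(a) / sum(a+b+c). The reported value is clamped
#' to \[0, 1\]; the raw (possibly slightly negative) value is kept in the
#' `"raw"` attribute.
#'
#' @param vt a `VariantTable`.
#' @param popA,popB sample-id vectors for the two populations.
#' @param window a one-row window (list or data.frame with `chrom`, `start`,
#'   `end`; 0-based half-open), or NULL for all sites.
#' @export
fst_window <- function(vt, popA, popB, window = NULL) {
  comp <- wc_site_components(vt, popA, popB)
  idx <- if (is.null(window)) NULL else window_site_index(vt, window)
  raw <- wc_ratio(comp, idx)
  val <- if (is.na(raw)) NA_real_ else min(max(raw, 0), 1)
  structure(val, raw = raw)
}

window_site_index <- function(vt, window) {
  which(vt$chrom == window$chrom &
          vt$pos - 1 >= window$start & vt$pos - 1 < window$end)
}

#' Nucleotide diversity (pi) per bp in a window
#'
#' Per site the unbiased pairwise-difference contribution
#' \eqn{2 \hat p \hat q \, k/(k-1)} over the non-missing allele count k,
#' summed over window sites and divided by the window length in bp.
#'
#' @inheritParams fst_window
#' @param pop sample ids of the population.
#' @export
nucleotide_diversity <- function(vt, pop, window) {
  L <- window$end - window$start
  if (L <= 0) stop("window length must be positive")
  idx <- window_site_index(vt, window)
  if (!length(idx)) return(0)
  sc <- site_counts(vt_subset(vt, idx), pop)
  k <- 2 * sc$n
  f <- sc$freq
  contrib <- ifelse(k >= 2, 2 * f * (1 - f) * k / (k - 1), 0)
  sum(contrib) / L
}

#' Watterson's theta per bp in a window
#'
#' \eqn{S / (a_{k-1} L)} with \eqn{a_{k-1} = \sum_{i=1}^{k-1} 1/i}, S the
#' number of sites segregating within the population and k the number of
#' sampled chromosomes (2 x population size).
#'
#' @inheritParams nucleotide_diversity
#' @export
watterson_theta <- function(vt, pop, window) {
  L <- window$end - window$start
  if (L <= 0) stop("window length must be positive")
  k <- 2L * length(pop)
  if (k < 2L) stop("need at least 2 chromosomes")
  idx <- window_site_index(vt, window)
  if (!length(idx)) return(0)
  sc <- site_counts(vt_subset(vt, idx), pop)
  S <- sum(sc$n > 0 & sc$alt > 0 & sc$alt < 2 * sc$n)
  S / (harmonic(k - 1L) * L)
}

harmonic <- function(m) sum(1 / seq_len(m))

#' Tajima's D in a window
#'
#' Standard Tajima (1989) statistic contrasting the pairwise-difference sum
#' with the segregating-site estimator, using the conventional
#' a1, a2, b1, b2, c1, c2, e1, e2 constants at k sampled chromosomes.
#' Undefined (NA) when the window has no segregating site.
#'
#' @inheritParams nucleotide_diversity
#' @export
tajimas_d <- function(vt, pop, window) {
  idx <- window_site_index(vt, window)
  if (!length(idx)) return(NA_real_)
  sc <- site_counts(vt_subset(vt, idx), pop)
  k <- 2L * length(pop)
  if (k < 2L) stop("need at least 2 chromosomes")
  seg <- sc$n > 0 & sc$alt > 0 & sc$alt < 2 * sc$n
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  ksite <- 2 * sc$n
  f <- sc$freq
  pi_sum <- sum(ifelse(ksite >= 2, 2 * f * (1 - f) * ksite / (ksite - 1), 0))
  tajima_d_from_sums(pi_sum, S, k)
}

tajima_d_from_sums <- function(pi_sum, S, k) {
  n <- k
  a1 <- harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Flag windows with too few variants
#'
#' Windows with fewer than `min_variants` cohort SNP sites are flagged as
#' excluded (they stay in the table; they never enter threshold computation
#' and cannot be called).
#'
#' @param stats data.frame of window statistics with an `n_variants` column.
#' @param min_variants exclusion cutoff (default 50: windows with fewer than
#'   50 variants are excluded).
#' @export
exclude_low_variant_windows <- function(stats, min_variants = 50) {
  stats$excluded <- stats$n_variants < min_variants
  stats
}

#' Genome-wide Z-transform of a window statistic
#'
#' `(x - mean) / sd` using the sample standard deviation (n-1), computed over
#' finite values; non-finite entries propagate as NA.
#'
#' @param values numeric vector.
#' @export
z_transform <- function(values) {
  fin <- is.finite(values)
  if (sum(fin) < 2L) stop("need at least 2 finite values")
  s <- stats::sd(values[fin])
  if (s == 0) stop("zero standard deviation: Z-transform undefined")
  out <- (values - mean(values[fin])) / s
  out[!fin] <- NA_real_
  out
}

#' Per-window statistics for a target-vs-reference scan
#'
#' The vectorized engine behind [sweep_scan()]: computes, for every window of
#' the tiling, the cohort variant count, Weir-Cockerham F_ST (target vs
#' reference), pooled heterozygosity of both populations, the heterozygosity
#' log ratio `log2(Hp_ref / Hp_target)`, and pi / Watterson's theta /
#' Tajima's D / SNP density for the target population. Z-scores of F_ST and
#' the log ratio are taken genome-wide over non-excluded windows.
#'
#' @param vt a `VariantTable`.
#' @param target,reference sample-id vectors.
#' @param chrom_lengths named lengths (default from [vt_chrom_lengths()]).
#' @param window_size,step window tiling in bp.
#' @param min_variants exclusion cutoff for low-variant windows.
#' @return data.frame, one row per window.
#' @export
window_statistics <- function(vt, target, reference,
                              chrom_lengths = vt_chrom_lengths(vt),
                              window_size = 30000, step = 15000,
                              min_variants = 50) {
  if (!length(target) || !length(reference)) stop("empty population")
  if (length(intersect(target, reference)))
    stop("target and reference populations overlap")
  win <- make_windows(chrom_lengths, window_size, step)
  comp <- wc_site_components(vt, target, reference)
  st <- site_counts(vt, target)
  sr <- site_counts(vt, reference)
  ft <- st$freq; fr <- sr$freq
  pt_major <- pmax(ft, 1 - ft); qt <- pmin(ft, 1 - ft)
  pr_major <- pmax(fr, 1 - fr); qr <- pmin(fr, 1 - fr)
  kt <- 2 * st$n
  pi_site <- ifelse(kt >= 2, 2 * ft * (1 - ft) * kt / (kt - 1), 0)
  seg_t <- st$n > 0 & st$alt > 0 & st$alt < 2 * st$n
  k_t <- 2L * length(target)
  pos0 <- vt$pos - 1
  n <- nrow(win)
  res <- data.frame(win,
                    n_variants = integer(n), fst = NA_real_,
                    hp_target = NA_real_, hp_ref = NA_real_,
                    log2_hp_ratio = NA_real_, pi = NA_real_,
                    theta_w = NA_real_, tajima_d = NA_real_,
                    snp_density = NA_real_)
  for (ch in unique(win$chrom)) {
    sidx <- which(vt$chrom == ch)
    p0 <- pos0[sidx]
    widx <- which(win$chrom == ch)
    lo <- findInterval(win$start[widx] - 0.5, p0) + 1L
    hi <- findInterval(win$end[widx] - 0.5, p0)
    for (j in seq_along(widx)) {
      w <- widx[j]
      if (hi[j] < lo[j]) { res$n_variants[w] <- 0L; next }
      ii <- sidx[lo[j]:hi[j]]
      res$n_variants[w] <- length(ii)
      res$fst[w] <- {
        raw <- wc_ratio(comp, ii)
        if (is.na(raw)) NA_real_ else min(max(raw, 0), 1)
      }
      ut <- st$n[ii] > 0; ur <- sr$n[ii] > 0
      hp_t <- if (any(ut)) {
        spv <- sum(pt_major[ii][ut]); sqv <- sum(qt[ii][ut])
        2 * spv * sqv / (spv + sqv)^2
      } else NA_real_
      hp_r <- if (any(ur)) {
        spv <- sum(pr_major[ii][ur]); sqv <- sum(qr[ii][ur])
        2 * spv * sqv / (spv + sqv)^2
      } else NA_real_
      res$hp_target[w] <- hp_t
      res$hp_ref[w] <- hp_r
      res$log2_hp_ratio[w] <- log2(hp_r / hp_t)
      L <- win$end[w] - win$start[w]
      res$pi[w] <- sum(pi_site[ii]) / L
      S <- sum(seg_t[ii])
      res$theta_w[w] <- S / (harmonic(k_t - 1L) * L)
      res$tajima_d[w] <- if (S > 0)
        tajima_d_from_sums(sum(pi_site[ii]), S, k_t) else NA_real_
      res$snp_density[w] <- length(ii) / (L / 1000)
    }
  }
  res <- exclude_low_variant_windows(res, min_variants)
  ok <- !res$excluded
  res$z_fst <- NA_real_
  res$z_hp <- NA_real_
  if (sum(ok & is.finite(res$fst)) >= 2 &&
      stats::sd(res$fst[ok], na.rm = TRUE) > 0) {
    z <- rep(NA_real_, n)
    z[ok] <- suppressWarnings(z_fill(res$fst[ok]))
    res$z_fst <- z
  }
  if (sum(ok & is.finite(res$log2_hp_ratio)) >= 2) {
    z <- rep(NA_real_, n)
    z[ok] <- suppressWarnings(z_fill(res$log2_hp_ratio[ok]))
    res$z_hp <- z
  }
  res
}

z_fill <- function(x) {
  fin <- is.finite(x)
  if (sum(fin) < 2L || stats::sd(x[fin]) == 0) return(rep(NA_real_, length(x)))
  out <- (x - mean(x[fin])) / stats::sd(x[fin])
  out[!fin] <- NA_real_
  out
}
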