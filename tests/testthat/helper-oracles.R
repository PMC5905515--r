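# Independent oracles and small fixture builders, kept deliberately separate
# from the package implementation: plain loops, textbook formulas.

# Build a VariantTable directly from a dosage matrix (sites x samples).
toy_vt <- function(dosage, chrom = NULL, pos = NULL, samples = NULL,
                   chrom_lengths = NULL) {
  dosage <- as.matrix(dosage)
  m <- nrow(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(dosage)))
  variant_table(chrom, pos, rep("A", m), rep("C", m), dosage, samples,
                chrom_lengths = chrom_lengths)
}

# Per-site Weir & Cockerham (1984) variance components, transcribed from the
# published formulas with explicit scalar arithmetic (r = 2 populations).
wc_oracle_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 / (r * nbar) + n2^2 / (r * nbar))) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Window F_ST oracle: ratio of summed components over polymorphic sites.
wc_oracle_window <- function(d1, d2) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(d1))) {
    g1 <- d1[i, ][!is.na(d1[i, ])]; g2 <- d2[i, ][!is.na(d2[i, ])]
    pbar <- (sum(g1) + sum(g2)) / (2 * (length(g1) + length(g2)))
    if (pbar == 0 || pbar == 1) next
    comp <- wc_oracle_site(d1[i, ], d2[i, ])
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  unname(num / den)
}

# Tajima's D oracle straight from the 1989 constants, given the per-site
# dosage matrix of one population (complete data, n = 2 * samples chroms).
tajima_oracle <- function(dosage) {
  nind <- ncol(dosage)
  n <- 2 * nind
  freqs <- rowSums(dosage) / n
  seg <- freqs > 0 & freqs < 1
  S <- sum(seg)
  pi_sum <- 0
  for (i in which(seg)) {
    p <- freqs[i]
    pi_sum <- pi_sum + 2 * p * (1 - p) * n / (n - 1)
  }
  # sites monomorphic in the pop contribute 0 to both
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# 1-D grid-search oracle for the two-locus haplotype likelihood: allele
# frequencies are fixed at their observed values; the free parameter is the
# alt-alt haplotype frequency, scanned on a 0.001 grid.
hap_grid_oracle <- function(counts, grid_step = 0.001) {
  N <- sum(counts)
  pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * N)
  pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  f11_grid <- seq(lo, hi, by = grid_step)
  best <- -Inf
  for (f11 in f11_grid) {
    f10 <- pA - f11; f01 <- pB - f11; f00 <- 1 - pA - pB + f11
    f <- pmax(c(f00, f01, f10, f11), 1e-12)
    P <- matrix(0, 3, 3)
    P[1, 1] <- f[1]^2;      P[1, 2] <- 2 * f[1] * f[2]; P[1, 3] <- f[2]^2
    P[2, 1] <- 2 * f[1] * f[3]
    P[2, 2] <- 2 * (f[4] * f[1] + f[3] * f[2])
    P[2, 3] <- 2 * f[2] * f[4]
    P[3, 1] <- f[3]^2;      P[3, 2] <- 2 * f[3] * f[4]; P[3, 3] <- f[4]^2
    ll <- sum(counts[counts > 0] * log(pmax(P[counts > 0], 1e-300)))
    if (ll > best) best <- ll
  }
  best
}

# random 3x3 genotype table drawn from random haplotype frequencies under
# random pairing
random_hap_table <- function(n = 200) {
  f <- as.numeric(stats::rmultinom(1, 1000, rep(1, 4))) / 1000
  f <- pmax(f, 0.01); f <- f / sum(f)
  names(f) <- c("h00", "h01", "h10", "h11")
  hap_draw <- function(k) sample(0:3, k, replace = TRUE, prob = f)
  h1 <- hap_draw(n); h2 <- hap_draw(n)
  gA <- (h1 >= 2) + (h2 >= 2)           # alt dosage locus 1
  gB <- (h1 %% 2) + (h2 %% 2)           # alt dosage locus 2
  table(factor(gA, levels = 0:2), factor(gB, levels = 0:2))
}

# closed-form OLS via normal equations, no lm()
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * s2)
  list(beta = as.numeric(beta), se = as.numeric(se))
}

# minimal VCF text fixture writer
write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}
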