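test_that("F_ST distance matrix is symmetric and matches the window oracle", {
  cfg <- sim_config(seed = 17, pop_names = c("A", "B", "C"),
                    samples_per_pop = 10, chrom_lengths = c(chr1 = 2e5),
                    n_sites = 400, F = c(0.05, 0.1, 0.2))
  sim <- simulate_genotypes(cfg)
  pops <- split(sim$popmap$sample_id, sim$popmap$breed)
  m <- fst_distance_matrix(sim$vt, pops)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(A = 0, B = 0, C = 0))
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    want <- max(0, attr(fst_window(sim$vt, pops[[pair[1]]], pops[[pair[2]]]),
                        "raw"))
    expect_equal(m[pair[1], pair[2]], want, tolerance = 1e-12)
  }
  vt_fix <- toy_vt(cbind(matrix(2L, 5, 10), matrix(0L, 5, 10)))
  mf <- fst_distance_matrix(vt_fix, list(a = vt_fix$sample_ids[1:10],
                                         b = vt_fix$sample_ids[11:20]))
  expect_equal(mf["a", "b"], 1)
  expect_error(fst_distance_matrix(sim$vt, list(a = pops$A, b = pops$B[1])),
               "fewer than 2")
})

test_that("allele-sharing and delta-AF distances follow their definitions", {
  d <- rbind(c(0L, 2L, 1L), c(0L, 2L, 0L), c(2L, 0L, NA))
  vt <- toy_vt(d)
  m <- allele_sharing_distance(vt)
  expect_equal(m, t(m))
  expect_equal(m["s01", "s02"], 2 + 2 + 2)  # opposite homozygotes at 3 sites
  expect_equal(m["s01", "s03"], 1 + 0)      # NA site skipped
  expect_equal(unname(diag(m)), rep(0, 3))
  vt2 <- toy_vt(cbind(c(2L, 1L, 0L), c(2L, 1L, 0L), c(1L, 2L, 0L),
                      c(1L, 2L, 0L)))
  pops <- list(p1 = c("s01", "s02"), p2 = c("s03", "s04"))
  af <- allele_freq_distance(vt2, pops)
  # per-site |freq diffs|: |1-0.5|, |0.5-1|, |0-0| -> mean 1/3
  expect_equal(af["p1", "p2"], 1 / 3)
  expect_equal(allele_freq_distance(vt2, list(a = c("s01", "s02"),
                                              b = c("s01", "s02")))["a", "b"], 0)
})

test_that("neighbor joining reproduces additive trees exactly", {
  # 3 taxa: closed-form branch lengths x=(dAB+dAC-dBC)/2 etc.
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
  edge_to <- tr$tip.label[tr$edge[, 2][tr$edge[, 2] <= 3]]
  lens <- tr$edge.length[tr$edge[, 2] <= 3]
  expect_equal(sort(lens), sort(c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2,
                                  (4 + 5 - 3) / 2)), tolerance = 1e-9)
  # 4 taxa from tree ((A:1,B:2):1,(C:3,D:4))
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["A", "C"] <- d4["C", "A"] <- 1 + 1 + 3
  d4["A", "D"] <- d4["D", "A"] <- 1 + 1 + 4
  d4["B", "C"] <- d4["C", "B"] <- 2 + 1 + 3
  d4["B", "D"] <- d4["D", "B"] <- 2 + 1 + 4
  d4["C", "D"] <- d4["D", "C"] <- 7
  tr4 <- neighbor_joining(d4)
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-9)
  # split AB|CD present
  parts <- ape::prop.part(ape::unroot(tr4))
  expect_true(is.character(to_newick(tr4)) && nchar(to_newick(tr4)) > 0)
  expect_error(neighbor_joining(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ on random additive matrices recovers the metric", {
  set.seed(5)
  for (rep in 1:10) {
    tr <- ape::rtree(6)
    dm <- ape::cophenetic.phylo(tr)
    tr2 <- neighbor_joining(dm)
    expect_equal(ape::cophenetic.phylo(tr2)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }
})

test_that("PCA separates differentiated populations and handles degenerate input", {
  cfg <- sim_config(seed = 23, pop_names = c("A", "B"), samples_per_pop = 25,
                    chrom_lengths = c(chr1 = 1e6), n_sites = 1000, F = 0.2)
  sim <- simulate_genotypes(cfg)
  pc <- pca_genotypes(sim$vt, n_components = 2)
  a <- pc$scores[pop_samples(sim$popmap, "A"), 1]
  b <- pc$scores[pop_samples(sim$popmap, "B"), 1]
  expect_true(max(a) < min(b) || max(b) < min(a))  # PC1 separates with no overlap
  expect_equal(sum(pc$explained <= 1), 2L)
  # order invariance up to sign
  perm <- rev(sim$vt$sample_ids)
  pc2 <- pca_genotypes(vt_subset(sim$vt, samples = perm), n_components = 1)
  v1 <- pc$scores[perm, 1]; v2 <- pc2$scores[perm, 1]
  expect_true(max(abs(v1 - v2)) < 1e-8 || max(abs(v1 + v2)) < 1e-8)
  ident <- toy_vt(matrix(1L, 5, 4))
  expect_error(pca_genotypes(ident), "PCA undefined")
})

test_that("EM haplotype frequencies solve the unambiguous case in one step", {
  counts <- matrix(0, 3, 3)
  counts[1, 1] <- 10; counts[3, 3] <- 10; counts[2, 1] <- 5
  em <- em_haplotype_freq(counts)
  # direct counting: 2*10 h00 + 5 h00 + 20 h11 + 5 h10 over 50 haplotypes
  expect_equal(unname(em$hap_freqs["h00"]), 25 / 50)
  expect_equal(unname(em$hap_freqs["h11"]), 20 / 50)
  expect_equal(unname(em$hap_freqs["h10"]), 5 / 50)
  expect_error(em_haplotype_freq(matrix(0, 3, 3)), "zero")
})

test_that("EM recovers generative haplotype frequencies at large n", {
  set.seed(61)
  f <- c(h00 = 0.4, h01 = 0.1, h10 = 0.2, h11 = 0.3)
  n <- 1e5
  h1 <- sample(0:3, n, replace = TRUE, prob = f)
  h2 <- sample(0:3, n, replace = TRUE, prob = f)
  gA <- (h1 >= 2) + (h2 >= 2); gB <- (h1 %% 2) + (h2 %% 2)
  tab <- table(factor(gA, levels = 0:2), factor(gB, levels = 0:2))
  em <- em_haplotype_freq(tab)
  expect_lt(max(abs(em$hap_freqs - f)), 0.01)
})

test_that("EM attains the grid-search likelihood maximum on random tables", {
  set.seed(19)
  for (rep in 1:100) {
    tab <- random_hap_table()
    em <- em_haplotype_freq(tab)
    expect_gte(em$loglik, hap_grid_oracle(tab) - 1e-6)
  }
})

test_that("LD coefficients match hand arithmetic and bounds", {
  # pA = pB = 0.5, f(AB) = 0.35 -> D = 0.1, D' = 0.4, r2 = 0.16
  f <- c(h00 = 0.35, h01 = 0.15, h10 = 0.15, h11 = 0.35)
  ld <- ld_pair(f)
  expect_equal(ld$D, 0.1)
  expect_equal(ld$d_prime, 0.4)
  expect_equal(ld$r2, 0.16)
  # independence
  ld0 <- ld_pair(c(h00 = 0.42, h01 = 0.18, h10 = 0.28, h11 = 0.12))
  expect_equal(ld0$D, 0, tolerance = 1e-12)
  expect_equal(ld0$r2, 0, tolerance = 1e-12)
  # complete association at equal frequencies
  ld1 <- ld_pair(c(h00 = 0.5, h01 = 0, h10 = 0, h11 = 0.5))
  expect_equal(ld1$d_prime, 1)
  expect_equal(ld1$r2, 1)
  # monomorphic locus -> sentinel
  expect_true(is.na(ld_pair(c(h00 = 0, h01 = 0, h10 = 0.5, h11 = 0.5))$r2))
})

test_that("LD decay bins duplicated sites at r2 = 1 and is seed-stable", {
  set.seed(3)
  g <- rbinom(30, 2, 0.5)
  d <- rbind(matrix(rep(g, 2), nrow = 2, byrow = TRUE),
             matrix(rbinom(30 * 4, 2, 0.5), nrow = 4))
  vt <- toy_vt(d, pos = c(100L, 500L, 15000L, 30000L, 60000L, 90000L))
  out <- ld_decay(vt, max_dist = 50000, bins = seq(0, 50000, 10000), seed = 4)
  expect_equal(out$mean_r2[1], 1)  # only the duplicated pair sits in bin 1
  out2 <- ld_decay(vt, max_dist = 50000, bins = seq(0, 50000, 10000), seed = 4)
  expect_identical(out, out2)
  # pairs beyond max_dist contribute to no bin
  dmat <- outer(vt$pos, vt$pos, function(a, b) b - a)
  expect_equal(sum(out$n_pairs), sum(dmat > 0 & dmat <= 50000))
  # the (30000, 40000] bin is empty: reported missing, not zero
  expect_equal(out$n_pairs[4], 0L)
  expect_true(is.na(out$mean_r2[4]))
})

test_that("LD pruning removes duplicates, keeps independents, is a fixed point", {
  set.seed(8)
  base <- matrix(rbinom(40 * 6, 2, 0.5), nrow = 6)
  d <- rbind(base[1, ], base[1, ], base[2:6, ])  # exact duplicate column pair
  vt <- toy_vt(d)
  kept <- ld_prune(vt, window_snps = 10, step_snps = 2, r2_max = 0.2)
  expect_false(all(c(1, 2) %in% kept))  # later duplicate removed
  expect_true(1 %in% kept)
  # postcondition: no surviving within-window pair above the cutoff
  sub <- vt_subset(vt, kept)
  for (i in seq_len(n_sites(sub) - 1)) for (j in (i + 1):n_sites(sub)) {
    r2 <- sweepscan:::r2_em(sub$dosage[i, ], sub$dosage[j, ])
    if (!is.na(r2)) expect_lte(r2, 0.2 + 1e-9)
  }
  # fixed point
  expect_equal(ld_prune(sub, window_snps = 10, step_snps = 2, r2_max = 0.2),
               seq_len(n_sites(sub)))
})
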