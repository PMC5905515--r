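test_that("simulation is reproducible and respects the model limits", {
  cfg <- sim_config(seed = 41, samples_per_pop = c(5, 5),
                    chrom_lengths = c(chr1 = 2e5), n_sites = 300)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$vt$dosage, s2$vt$dosage)
  expect_identical(s1$vt$pos, s2$vt$pos)
  # byte-identical VCF emission
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(s1$vt, f1); write_vcf(s2$vt, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(sim_config(seed = 1, F = 1), "F must be")
  expect_error(sim_config(), "seed")
})

test_that("F = 0 gives both populations identical expected frequencies", {
  cfg <- sim_config(seed = 47, pop_names = c("A", "B"), samples_per_pop = 200,
                    chrom_lengths = c(chr1 = 2e5), n_sites = 400, F = 0)
  sim <- simulate_genotypes(cfg)
  fa <- site_frequencies(sim$vt, pop_samples(sim$popmap, "A"))$alt_freq
  fb <- site_frequencies(sim$vt, pop_samples(sim$popmap, "B"))$alt_freq
  # same underlying frequency: differences are pure binomial noise
  expect_lt(mean(abs(fa - fb)), 0.05)
  raw <- attr(fst_window(sim$vt, pop_samples(sim$popmap, "A"),
                         pop_samples(sim$popmap, "B")), "raw")
  expect_lt(abs(raw), 0.01)
})

test_that("Balding-Nichols cohorts recover F as the genome-mean F_ST", {
  cfg <- sim_config(seed = 53, pop_names = c("A", "B"), samples_per_pop = 50,
                    chrom_lengths = c(chr1 = 2e6), n_sites = 2000, F = 0.1)
  sim <- simulate_genotypes(cfg)
  st <- window_statistics(sim$vt, pop_samples(sim$popmap, "A"),
                          pop_samples(sim$popmap, "B"), min_variants = 10)
  mean_fst <- mean(st$fst[!st$excluded], na.rm = TRUE)
  expect_gte(mean_fst, 0.08)
  expect_lte(mean_fst, 0.12)
})

test_that("sweep injection lowers target heterozygosity and raises F_ST", {
  interval <- list(chrom = "chr1", start = 450000, end = 540000)
  cfg <- sim_config(seed = 59, pop_names = c("PT", "MGS"),
                    samples_per_pop = c(10, 25), chrom_lengths = c(chr1 = 2e6),
                    n_sites = 4000, F = 0.05)
  sim <- simulate_genotypes(cfg)
  pt <- pop_samples(sim$popmap, "PT"); mgs <- pop_samples(sim$popmap, "MGS")
  idx <- which(sim$vt$chrom == "chr1" & sim$vt$pos - 1 >= interval$start &
                 sim$vt$pos - 1 < interval$end)
  hp_pre <- pooled_heterozygosity(site_frequencies(vt_subset(sim$vt, idx), pt))
  vt2 <- inject_sweep(sim$vt, pt, interval, target_freq = 0.98, seed = 60)
  hp_post <- pooled_heterozygosity(site_frequencies(vt_subset(vt2, idx), pt))
  expect_lt(hp_post, hp_pre)
  # differentiation of the swept window exceeds the genome background
  st <- window_statistics(vt2, pt, mgs, min_variants = 10)
  bg <- st$fst[!st$excluded & (st$end <= interval$start | st$start >= interval$end)]
  inwin <- st$fst[!st$excluded & st$start >= interval$start &
                    st$end <= interval$end]
  expect_gt(min(inwin), mean(bg, na.rm = TRUE) + 3 * sd(bg, na.rm = TRUE))
  # non-target population untouched
  expect_identical(vt2$dosage[, mgs], sim$vt$dosage[, mgs])
  # sites outside the interval untouched
  out <- setdiff(seq_len(n_sites(sim$vt)), idx)
  expect_identical(vt2$dosage[out, ], sim$vt$dosage[out, ])
  expect_error(inject_sweep(sim$vt, pt, list(chrom = "chr9", start = 0,
                                             end = 100)), "empty")
})

test_that("the simulated annotation plants marker genes around each sweep", {
  cfg <- sim_config(seed = 61, chrom_lengths = c(chr1 = 2e6),
                    sweeps = list(list(pop = "PT", chrom = "chr1",
                                       start = 450000, end = 540000)))
  genes <- simulate_gene_annotation(cfg)
  expect_true(all(c("sweep1_inside", "sweep1_flank", "sweep1_far") %in%
                    genes$gene_id))
  gin <- genes[genes$gene_id == "sweep1_inside", ]
  expect_gte(gin$start, 450000); expect_lte(gin$end, 540000)
  gfl <- genes[genes$gene_id == "sweep1_flank", ]
  expect_gte(gfl$start, 540000); expect_lte(gfl$start, 540000 + 15000)
  gfar <- genes[genes$gene_id == "sweep1_far", ]
  expect_gte(gfar$start, 540000 + 60000)
  expect_identical(genes, simulate_gene_annotation(cfg))  # deterministic
  expect_true(all(genes$start < genes$end))
})

test_that("noise-free phenotypes take three levels spaced beta apart", {
  cfg <- sim_config(seed = 67, chrom_lengths = c(chr1 = 1e5), n_sites = 200,
                    phenotype = list(sd = 0, age_beta = 0, sex_beta = 0,
                                     n = 300))
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$vt, 100, cfg)
  lv <- sort(unique(round(ph$horn_length - min(ph$horn_length), 9)))
  expect_equal(lv, c(0, 11.75, 23.5))
})

test_that("shape log-odds zero makes shape independent of genotype", {
  cfg <- sim_config(seed = 68, chrom_lengths = c(chr1 = 1e5), n_sites = 200,
                    phenotype = list(shape_logodds = 0, n = 400,
                                     uncertain_rate = 0))
  sim <- simulate_genotypes(cfg)
  ps <- replicate(40, {
    seed <- sample.int(1e6, 1)
    ph <- simulate_phenotypes(sim$vt, 100, cfg, seed = seed)
    sel <- ph$horn_shape %in% c("SHE", "TCF")
    hom <- encode_genotype(ph[[attr(ph, "causal_snp")]][sel], "recessive",
                           attr(ph, "causal_alt"))
    suppressWarnings(chisq.test(table(hom, ph$horn_shape[sel]))$p.value)
  })
  # null p-values: roughly uniform, no mass near 0
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("phenotype categories respect the length bands", {
  cfg <- sim_config(seed = 69, chrom_lengths = c(chr1 = 1e5), n_sites = 200,
                    phenotype = list(n = 500, intercept = 8, sd = 10))
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$vt, 100, cfg)
  expect_true(all(ph$horn_length >= 0))
  expect_true(all(ph$horn_length[ph$horn_shape == "polled"] == 0))
  sc <- ph$horn_length[ph$horn_shape == "scurred"]
  expect_true(all(sc > 0 & sc <= 12))
  expect_true(all(ph$horn_length[ph$horn_shape %in%
                                   c("SHE", "TCF", "uncertain")] > 12))
  expect_error(simulate_phenotypes(toy_vt(matrix(0L, 3, 4)), 1, cfg),
               "monomorphic")
})

test_that("the Ct generator is seeded and group-structured", {
  cfg <- sim_config(seed = 70)
  ct1 <- simulate_ct_table(cfg)
  ct2 <- simulate_ct_table(cfg)
  expect_identical(ct1, ct2)
  expect_setequal(unique(ct1$group), c("scurred", "SHE", "TCF"))
  expect_equal(nrow(ct1), (4 + 4 + 5) * 3 * 2)  # 13 samples x 3 reps x 2 genes
  # group dCt difference of 1 -> fold change ~ 0.5
  cfgd <- sim_config(seed = 71, expression = list(
    group_sizes = c(A = 20, B = 20), group_delta_ct = c(A = 1, B = 2),
    bio_sd = 0.05, rep_sd = 0.02))
  res <- ddct(simulate_ct_table(cfgd), "RXFP2", "ACTB", "A")
  fold_b <- mean(res$rel_expr[res$group == "B"])
  expect_equal(fold_b, 0.5, tolerance = 0.1)
})
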