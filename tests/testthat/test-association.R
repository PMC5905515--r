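test_that("genotype codings follow the three genetic models", {
  g <- c("TT", "TC", "CC", NA)
  expect_equal(encode_genotype(g, "additive", "T"), c(2, 1, 0, NA))
  expect_equal(encode_genotype(g, "recessive", "T"), c(1, 0, 0, NA))
  expect_equal(encode_genotype(g, "dominant", "T"), c(1, 1, 0, NA))
  expect_equal(encode_genotype("T/C", "additive", "T"), 1)
  expect_error(encode_genotype(c("TT", "TG", "TC"), "additive", "T",
                               minor_allele = "C"), "allele")
})

test_that("monomorphic SNPs are dropped from the panel", {
  tab <- data.frame(snpA = rep("TT", 6), snpB = c("TT", "TC", rep("TT", 4)),
                    stringsAsFactors = FALSE)
  expect_message(keep <- drop_monomorphic(tab, c("snpA", "snpB")), "snpA")
  expect_equal(keep, "snpB")
  nine <- paste0("s", 1:9)
  tab9 <- as.data.frame(setNames(rep(list(c("AG", "GG", "AA")), 9), nine))
  tab9$s5 <- "AA"
  expect_equal(length(suppressMessages(drop_monomorphic(tab9, nine))), 8L)
})

test_that("linear association recovers exact and oracle fits", {
  code <- c(0, 1, 2, 0, 1, 2)
  tab <- data.frame(animal_id = paste0("a", 1:6),
                    horn_length = 3 + 2 * code,
                    horn_shape = "SHE", age = 1, sex = "F",
                    snp = c("CC", "TC", "TT")[code + 1])
  r <- suppressWarnings(   # lm flags the residual-free exact fit
    linear_assoc(tab, "snp", "additive", covariates = character(0),
                 major_allele = "T"))
  expect_equal(r$beta, 2, tolerance = 1e-10)
  expect_equal(r$n_used, 6L)
  # 6-row toy with covariates against the normal-equation oracle
  set.seed(33)
  tab$horn_length <- 5 + 3 * code + rnorm(6)
  tab$age <- c(2, 4, 6, 3, 5, 7)
  tab$sex <- c("M", "F", "M", "F", "M", "F")
  r2 <- linear_assoc(tab, "snp", "additive", covariates = c("age", "sex"),
                     major_allele = "T")
  X <- cbind(1, code, tab$age, as.integer(tab$sex == "M"))
  want <- ols_oracle(X, tab$horn_length)
  expect_equal(r2$beta, want$beta[2], tolerance = 1e-10)
  expect_equal(r2$se, want$se[2], tolerance = 1e-10)
})

test_that("additive beta flips sign (only) under major/minor label swap", {
  set.seed(44)
  code <- rbinom(40, 2, 0.5)
  tab <- data.frame(animal_id = paste0("a", 1:40),
                    horn_length = 10 + 4 * code + rnorm(40),
                    horn_shape = "SHE", age = 1, sex = "F",
                    snp = c("CC", "TC", "TT")[code + 1])
  rT <- linear_assoc(tab, "snp", "additive", character(0), major_allele = "T")
  rC <- linear_assoc(tab, "snp", "additive", character(0), major_allele = "C")
  expect_equal(rT$beta, -rC$beta, tolerance = 1e-10)
  expect_equal(rT$se, rC$se, tolerance = 1e-10)
  expect_equal(rT$p_value, rC$p_value, tolerance = 1e-10)
})

test_that("singular designs raise informative errors", {
  tab <- data.frame(animal_id = paste0("a", 1:6), horn_length = rnorm(6),
                    horn_shape = "SHE", age = 1, sex = "F",
                    snp = rep("TT", 6))
  expect_error(linear_assoc(tab, "snp", "additive", character(0),
                            major_allele = "T"), "constant")
  tab2 <- tab
  tab2$snp <- c("TT", "TC", "CC", "TT", "TC", "CC")
  expect_error(linear_assoc(tab2[1:3, ], "snp", "additive", c("age", "sex"),
                            major_allele = "T"),
               "too few|singular")
})

test_that("logistic association equals the 2x2 log odds ratio", {
  # recessive code 1: 30 SHE / 10 TCF; code 0: 10 SHE / 30 TCF -> ln(9)
  gt <- c(rep("TT", 40), rep("TC", 40))
  shape <- c(rep("SHE", 30), rep("TCF", 10), rep("SHE", 10), rep("TCF", 30))
  tab <- data.frame(animal_id = paste0("a", 1:80), horn_length = 20,
                    horn_shape = shape, age = 1, sex = "F", snp = gt)
  r <- logistic_assoc(tab, "snp", "recessive", major_allele = "T")
  expect_equal(r$beta, log(9), tolerance = 1e-8)
  # independence -> beta ~ 0
  shape0 <- rep(c(rep("SHE", 20), rep("TCF", 20)), 2)
  tab0 <- transform(tab, horn_shape = shape0)
  r0 <- logistic_assoc(tab0, "snp", "recessive", major_allele = "T")
  expect_equal(r0$beta, 0, tolerance = 1e-6)
  # complete separation is flagged, no estimate
  sep <- data.frame(animal_id = paste0("a", 1:40), horn_length = 20,
                    horn_shape = c(rep("SHE", 20), rep("TCF", 20)),
                    age = 1, sex = "F",
                    snp = c(rep("TT", 20), rep("TC", 20)))
  expect_error(logistic_assoc(sep, "snp", "recessive", major_allele = "T"),
               "separation")
})

test_that("shape fits use only SHE vs TCF animals", {
  tab <- data.frame(animal_id = paste0("a", 1:84), horn_length = 20,
                    horn_shape = c(rep("SHE", 30), rep("TCF", 10),
                                   rep("SHE", 10), rep("TCF", 30),
                                   "polled", "scurred", "uncertain", "polled"),
                    age = 1, sex = "F",
                    snp = c(rep("TT", 40), rep("TC", 40), rep("CC", 4)))
  r <- logistic_assoc(tab, "snp", "recessive", major_allele = "T")
  expect_equal(r$n_used, 80L)
  expect_equal(r$beta, log(9), tolerance = 1e-8)
})

test_that("the association grid enumerates fits and records skips", {
  cfg <- sim_config(seed = 55, chrom_lengths = c(chr1 = 1e5), n_sites = 200,
                    phenotype = list(n = 120, n_null_snps = 7))
  sim <- simulate_genotypes(cfg)
  tab <- simulate_phenotypes(sim$vt, 100, cfg)
  snps <- c(attr(tab, "causal_snp"), sprintf("null_snp_%02d", 1:7))
  res <- assoc_scan(tab, snps)
  expect_equal(nrow(res), 8 * 3 * 2)
  expect_equal(res$snp, rep(snps, each = 6))
  # deterministic order and BH column present
  res2 <- assoc_scan(tab, snps)
  expect_identical(res, res2)
  expect_true(all(res$p_bh >= res$p_value - 1e-12, na.rm = TRUE))
  # empty panel -> empty result
  expect_equal(nrow(assoc_scan(tab, character(0))), 0L)
  # a dominant fit with no aa class is recorded as a skip, not an error
  tab$fixed <- sample(c("TT", "TC"), nrow(tab), replace = TRUE)
  attr(tab, "ref_alleles") <- c(attr(tab, "ref_alleles"), fixed = "T")
  resf <- assoc_scan(tab, "fixed")
  dom <- resf[resf$model == "dominant", ]
  expect_true(all(is.na(dom$beta)))
  expect_true(all(nzchar(dom$note)))
})

test_that("simulated cohorts recover the additive effect and the null is calibrated", {
  cfg <- sim_config(seed = 77, chrom_lengths = c(chr1 = 1e5), n_sites = 200)
  sim <- simulate_genotypes(cfg)
  hits <- 0L
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    ph <- simulate_phenotypes(sim$vt, 100, cfg, seed = 1000 + s)
    r <- linear_assoc(ph, attr(ph, "causal_snp"), "additive")
    # coding counts the cohort-major allele; align the sign to the derived allele
    b <- if (r$major_allele == attr(ph, "causal_alt")) r$beta else -r$beta
    if (abs(b - 11.75) <= 3) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
  # null: no genetic effect
  cfg0 <- sim_config(seed = 78, chrom_lengths = c(chr1 = 1e5), n_sites = 200,
                     phenotype = list(beta = 0))
  rej <- 0L
  n_null <- 400
  for (s in seq_len(n_null)) {
    ph <- simulate_phenotypes(sim$vt, 100, cfg0, seed = 5000 + s)
    r <- linear_assoc(ph, attr(ph, "causal_snp"), "additive")
    if (r$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_null, 0.02)
  expect_lte(rej / n_null, 0.08)
})
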