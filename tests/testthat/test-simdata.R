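test_that("minimal configurations produce the expected family structures", {
  # two founders, one generation, one offspring -> a trio
  trio <- simulate_pedigree(sim_config(n_founders = 2, n_generations = 1,
                                       litter_size = 1, seed = 1))
  expect_equal(n_animals(trio), 3L)
  expect_true(is.na(trio$sire[1]) && is.na(trio$dam[2]))
  expect_equal(trio$sire[3], 1L)
  expect_equal(trio$dam[3], 2L)

  # deep pedigree stays topologically ordered
  ped <- simulate_pedigree(sim_config(n_founders = 50, n_generations = 12,
                                      litter_size = 2, seed = 2))
  idx <- seq_len(n_animals(ped))
  expect_true(all(ped$sire[!is.na(ped$sire)] < idx[!is.na(ped$sire)]))
  expect_true(all(ped$dam[!is.na(ped$dam)] < idx[!is.na(ped$dam)]))

  # impossible mating structure errors out
  expect_error(sim_config(n_founders = 1), "founders")
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_founders = 12, n_generations = 2, litter_size = 2,
                    n_chromosomes = 2, chrom_length_bp = 2e6, n_snps = 60,
                    n_qtl = 2, qtl_var_fractions = c(0.1, 0.1),
                    records_per_animal = 3, genotyped_fraction = 0.5,
                    seed = 1)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes_all$dosage, s2$genotypes_all$dosage)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$tbv, s2$truth$tbv)
})

test_that("gene dropping respects Mendelian and Hardy-Weinberg structure", {
  # fixed founder locus stays fixed; parents (0,0) give offspring 0
  cfg <- sim_config(n_founders = 20, n_generations = 2, litter_size = 2,
                    n_chromosomes = 1, chrom_length_bp = 1e6, n_snps = 5,
                    n_qtl = 0, qtl_var_fractions = numeric(0),
                    founder_freq = c(0, 0.5, 0.2, 0.5, 1), seed = 3)
  ped <- simulate_pedigree(cfg)
  g <- drop_genotypes(ped, cfg)
  expect_true(all(g$dosage[, 1] == 0L))
  expect_true(all(g$dosage[, 5] == 2L))
  # Mendelian constraint at every segregating locus
  for (j in 2:4) {
    off <- which(!is.na(ped$sire))
    hi <- g$dosage[ped$sire[off], j] + g$dosage[ped$dam[off], j]
    expect_true(all(g$dosage[off, j][hi == 0] == 0))
    expect_true(all(g$dosage[off, j][hi == 4] == 2))
  }

  # founder genotypes at p = 0.5 in HW proportions (chi-square GOF),
  # with and without the ancestral-mosaic LD model
  for (ld in c(TRUE, FALSE)) {
    cfg2 <- sim_config(n_founders = 10000, n_generations = 1,
                       litter_size = 1, n_chromosomes = 1,
                       chrom_length_bp = 1e6, n_snps = 3, n_qtl = 0,
                       qtl_var_fractions = numeric(0),
                       founder_freq = rep(0.5, 3), founder_ld = ld,
                       seed = 4)
    ped2 <- simulate_pedigree(cfg2)
    g2 <- drop_genotypes(ped2, cfg2)
    counts <- tabulate(g2$dosage[1:10000, 1] + 1L, 3L)
    gof <- suppressWarnings(
      stats::chisq.test(counts, p = c(0.25, 0.5, 0.25)))
    expect_gt(gof$p.value, 1e-4)
  }
})

test_that("gene-dropped genotype covariance matches the pedigree A matrix", {
  # with LD off and 200+ independently segregating chromosomes, the
  # realised genomic relationships converge on the pedigree expectation
  cfg <- sim_config(n_founders = 14, n_generations = 3, litter_size = 2,
                    n_chromosomes = 250, chrom_length_bp = 1e4,
                    n_snps = 4000, n_qtl = 0, qtl_var_fractions = numeric(0),
                    founder_ld = FALSE, genotyped_fraction = 1, seed = 5)
  ped <- simulate_pedigree(cfg)
  g <- drop_genotypes(ped, cfg)
  p0 <- attr(g, "founder_freq")
  Zc <- sweep(matrix(as.numeric(g$dosage), nrow(g$dosage)), 2, 2 * p0, "-")
  G <- tcrossprod(Zc) / sum(2 * p0 * (1 - p0))
  A <- a_matrix(ped)
  expect_lt(mean(abs(G - A)), 0.1)
  expect_lt(max(abs(G - A)), 0.45)
})

test_that("phenotypes follow the repeatability model", {
  # degenerate noise: no pe, no residual, one record, no fixed effects
  cfg <- sim_config(n_founders = 20, n_generations = 2, litter_size = 2,
                    n_chromosomes = 2, chrom_length_bp = 2e6, n_snps = 100,
                    n_qtl = 1, qtl_var_fractions = 0.3,
                    var_pe = 0, var_e = 0, beta_age = 0, beta_intv = 0,
                    yearseason_sd = 0, trait_mean = 10,
                    records_per_animal = 1, seed = 6)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$phenotypes), n_animals(sim$pedigree))
  expect_equal(sim$phenotypes$y - 10,
               unname(sim$truth$tbv[sim$phenotypes$id]), tolerance = 1e-10)

  # QTL variance request beyond var_a errors
  expect_error(sim_config(n_qtl = 3, qtl_var_fractions = c(0.5, 0.4, 0.2)),
               "exceed")
})

test_that("realized heritability matches the configured components", {
  # ~2000 animals at the log sperm-count variance components
  cfg <- sim_config(n_founders = 400, n_generations = 4, litter_size = 2,
                    n_chromosomes = 5, chrom_length_bp = 10e6,
                    n_snps = 1500, n_qtl = 5,
                    qtl_var_fractions = rep(0.05, 5),
                    records_per_animal = 5, genotyped_fraction = 0,
                    yearseason_sd = 0, seed = 7)
  sim <- simulate_dataset(cfg)
  expect_gt(n_animals(sim$pedigree), 1500)
  expect_lt(abs(sim$truth$realized_h2 - 0.1832), 0.02)

  # ANOVA-style check: variance of animal record means
  ph <- sim$phenotypes
  mns <- tapply(ph$y - 0.01 * ph$age - 0.005 * ph$intv, ph$id, mean)
  n_i <- table(ph$id)
  expected <- cfg$var_a + cfg$var_pe + mean(cfg$var_e / n_i)
  n_an <- length(mns)
  mc_se <- expected * sqrt(2 / n_an)
  expect_lt(abs(stats::var(mns) - expected), 3 * mc_se)
})

test_that("breeding values are inherited additively", {
  cfg <- sim_config(n_founders = 150, n_generations = 3, litter_size = 2,
                    n_chromosomes = 5, chrom_length_bp = 10e6,
                    n_snps = 1000, n_qtl = 2, qtl_var_fractions = c(0.1, 0.1),
                    records_per_animal = 2, genotyped_fraction = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  ped <- sim$pedigree
  tbv <- sim$truth$tbv
  off <- which(!is.na(ped$sire) & !is.na(ped$dam))
  midparent <- (tbv[ped$sire[off]] + tbv[ped$dam[off]]) / 2
  fit <- stats::lm(tbv[off] ~ midparent)
  slope <- stats::coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - 1), 3.5 * se)
})

test_that("PLINK PED/MAP writer and reader round-trip", {
  sim <- tiny_sim(seed = 9, n_founders = 10, n_generations = 1,
                  n_snps = 30, genotyped_fraction = 1)
  g <- sim$genotypes
  prefix <- tempfile()
  write_plink(g, prefix, ped = sim$pedigree)
  g2 <- read_plink(prefix)
  expect_equal(g2$dosage, g$dosage)
  expect_equal(g2$map$chr, g$map$chr)
  expect_equal(g2$map$bp, g$map$bp)
})
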