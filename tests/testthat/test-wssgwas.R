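test_that("weight arithmetic follows the update and normalisation rules", {
  expect_equal(update_weights(0.1, 0.5), 0.005)
  expect_equal(update_weights(c(0.2, 0.2), c(0.3, 0.3)),
               rep(0.2^2 * 2 * 0.3 * 0.7, 2))
  expect_equal(update_weights(-0.3, 0.4), update_weights(0.3, 0.4))

  expect_equal(normalize_weights(rep(1, 7)), rep(1, 7))
  expect_equal(normalize_weights(c(2, 0, 0, 0)), c(4, 0, 0, 0))
  set.seed(1)
  raw <- rexp(100)
  expect_lt(abs(sum(normalize_weights(raw)) - 100), 1e-10)
  expect_error(normalize_weights(rep(0, 5)), "zero")
  expect_error(normalize_weights(c(-1, 2)), "negative")
})

test_that("back-solving reconstructs breeding values with full-rank G", {
  # more SNPs than animals and external frequencies -> full-rank G
  sim <- tiny_sim(seed = 12, n_founders = 8, n_generations = 1,
                  litter_size = 1, n_snps = 60, genotyped_fraction = 1)
  g <- sim$genotypes
  p <- attr(g, "founder_freq")
  n <- nrow(g$dosage)
  set.seed(13)
  a <- rnorm(n)
  gh <- backsolve_snp_effects(a, g, p = p)
  Zc <- centered_dosage(g, p)
  expect_equal(drop(Zc %*% gh), a, tolerance = 1e-8, ignore_attr = TRUE)

  # zero breeding values give zero effects
  expect_equal(unname(backsolve_snp_effects(numeric(n), g, p = p)),
               rep(0, 60))

  # linearity in a-hat
  gh2 <- backsolve_snp_effects(2 * a, g, p = p)
  expect_equal(gh2, 2 * gh, tolerance = 1e-8)

  # weighted reconstruction also holds
  set.seed(14)
  w <- normalize_weights(rexp(60))
  ghw <- backsolve_snp_effects(a, g, weights = w, p = p)
  expect_equal(drop(Zc %*% ghw), a, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("one-SNP toy matches the dense pseudoinverse oracle", {
  dos <- matrix(0:2, 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  g <- genotype_matrix(dos, data.frame(snp = "s1", chr = 1L, bp = 1000L))
  zc <- c(-1, 0, 1)
  a_hat <- zc * 0.3                     # lies in range(G)
  lam <- 2
  G <- lam * outer(zc, zc)
  oracle <- lam * drop(t(zc) %*% pinv(G) %*% a_hat)
  gh <- backsolve_snp_effects(a_hat, g, p = 0.5, ridge = 1e-10)
  expect_equal(unname(gh), oracle, tolerance = 1e-6)
  # and the singular G without ridge errors with advice
  expect_error(backsolve_snp_effects(a_hat, g, p = 0.5), "ridge")
})

test_that("the weighting loop conserves trace and is deterministic", {
  sim <- tiny_sim(seed = 15)
  qc <- apply_qc(sim$genotypes)
  fit1 <- wssgwas(y ~ yearseason + age + intv, sim$phenotypes,
                  sim$pedigree, qc$genotypes,
                  varcomp = c(var_a = 0.05172, var_pe = 0.03682,
                              var_e = 0.19380))
  m <- nrow(fit1$marker_effects)
  expect_equal(fit1$trace$trace_D, rep(m, fit1$n_iter), tolerance = 1e-12)
  expect_lt(abs(sum(fit1$weights) - m), 1e-10)
  expect_equal(nrow(fit1$trace), 3L)

  fit2 <- wssgwas(y ~ yearseason + age + intv, sim$phenotypes,
                  sim$pedigree, qc$genotypes,
                  varcomp = c(var_a = 0.05172, var_pe = 0.03682,
                              var_e = 0.19380))
  expect_identical(fit1$effects_by_iter, fit2$effects_by_iter)
  expect_identical(fit1$gebv, fit2$gebv)

  # n_iter = 1 equals the first column of the 3-iteration trace
  fit_a <- wssgwas(y ~ yearseason + age + intv, sim$phenotypes,
                   sim$pedigree, qc$genotypes, n_iter = 1,
                   varcomp = c(var_a = 0.05172, var_pe = 0.03682,
                               var_e = 0.19380))
  expect_equal(unname(fit_a$effects_by_iter[, 1]),
               unname(fit1$effects_by_iter[, 1]), tolerance = 1e-10)
})

test_that("iteration 1 GEBVs equal a hand-built unweighted ssGBLUP", {
  sim <- tiny_sim(seed = 16)
  qc <- apply_qc(sim$genotypes)
  vc <- c(var_a = 0.05172, var_pe = 0.03682, var_e = 0.19380)
  fit <- wssgwas(y ~ yearseason + age + intv, sim$phenotypes,
                 sim$pedigree, qc$genotypes, n_iter = 1, varcomp = vc)

  ped <- sim$pedigree
  ped$genotyped <- ped$id %in% rownames(qc$genotypes$dosage)
  gorder <- ped$id[ped$genotyped]
  g <- qc$genotypes
  g$dosage <- g$dosage[match(gorder, rownames(g$dosage)), ]
  G <- g_matrix(g)                      # D = I
  A22m <- a22(ped)
  hinv <- h_inverse(a_inverse(ped), A22m, blend_gw(G, A22m), ped)
  sol <- solve_mme(build_mme(y ~ yearseason + age + intv, sim$phenotypes,
                             hinv, vc))
  expect_equal(fit$gebv, sol$a, tolerance = 1e-8)
})

test_that("pedigree-only fits equal pedigree BLUP exactly", {
  sim <- tiny_sim(seed = 17)
  vc <- c(var_a = 0.05172, var_pe = 0.03682, var_e = 0.19380)
  expect_warning(
    fit0 <- wssgwas(y ~ yearseason + age + intv, sim$phenotypes,
                    sim$pedigree, genotypes = NULL, varcomp = vc),
    "pedigree BLUP")
  sol <- solve_mme(build_mme(y ~ yearseason + age + intv, sim$phenotypes,
                             a_inverse(sim$pedigree), vc))
  expect_equal(fit0$gebv, sol$a)
  expect_null(fit0$windows)
})

test_that("weights concentrate on a strong single QTL across iterations", {
  hits <- 0L
  for (s in 1:3) {
    cfg <- sim_config(n_founders = 60, n_generations = 2, litter_size = 4,
                      n_chromosomes = 4, chrom_length_bp = 10e6,
                      n_snps = 800, n_qtl = 1, qtl_var_fractions = 0.3,
                      records_per_animal = 8, genotyped_fraction = 0.8,
                      seed = 20 + s)
    sim <- simulate_dataset(cfg)
    qc <- apply_qc(sim$genotypes)
    fit <- wssgwas(y ~ yearseason + age + intv, sim$phenotypes,
                   sim$pedigree, qc$genotypes,
                   varcomp = c(var_a = 0.05172, var_pe = 0.03682,
                               var_e = 0.19380))
    j <- match(sim$truth$qtl_snp, qc$genotypes$map$snp)
    p <- fit$marker_effects$freq
    widx <- attr(fit$windows, "snp_window")
    share <- sapply(1:3, function(t) {
      w <- normalize_weights(update_weights(fit$effects_by_iter[, t], p))
      sum(w[widx == widx[j]]) / sum(w)
    })
    if (share[3] > share[1]) hits <- hits + 1L
    # the QTL's own |effect| grows as weights concentrate
    expect_gt(abs(fit$effects_by_iter[j, 3]),
              abs(fit$effects_by_iter[j, 1]))
  }
  expect_gte(hits, 2L)
})
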