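# build a small record set over a given pedigree
make_records <- function(ped, recs_per_animal, seed = 1, mu = 5,
                         vc = c(var_a = 1, var_pe = 0.5, var_e = 2)) {
  set.seed(seed)
  n <- n_animals(ped)
  nrec <- rep(recs_per_animal, n)
  idx <- rep(seq_len(n), nrec)
  a <- drop(t(chol(a_matrix(ped) * vc["var_a"])) %*% rnorm(n))
  pe <- rnorm(n, 0, sqrt(vc["var_pe"]))
  y <- mu + a[idx] + pe[idx] + rnorm(length(idx), 0, sqrt(vc["var_e"]))
  data.frame(id = ped$id[idx], y = y)
}

test_that("MME solutions equal the dense GLS/BLUP oracle", {
  ped <- random_pedigree(12, seed = 1)
  dat <- make_records(ped, 3, seed = 2)          # 36 records
  dat$x <- rnorm(nrow(dat))
  vc <- c(var_a = 0.8, var_pe = 0.4, var_e = 1.5)
  sys <- build_mme(y ~ x, dat, a_inverse(ped), vc)
  sol <- solve_mme(sys)

  n <- nrow(dat)
  ai <- match(dat$id, ped$id)
  X <- cbind(1, dat$x)
  Z <- matrix(0, n, 12); Z[cbind(1:n, ai)] <- 1
  ids <- sort(unique(ai))
  W <- matrix(0, n, length(ids)); W[cbind(1:n, match(ai, ids))] <- 1
  oracle <- gls_oracle(dat$y, X, Z, a_matrix(ped), W,
                       va = 0.8, vp = 0.4, ve = 1.5)
  expect_equal(unname(sol$b), oracle$b, tolerance = 1e-6)
  expect_equal(unname(sol$a), unname(oracle$a), tolerance = 1e-6)
  expect_equal(unname(sol$p), unname(oracle$p), tolerance = 1e-6)
})

test_that("ridge-regression special case and scalar shrinkage hold", {
  # independent animals (A = I), k_a = 1, no permanent environment:
  # the animal solutions solve (Z'MZ + I) a = Z'My (ridge on centred data)
  ids <- c("a", "b", "c")
  kinv <- Matrix::Diagonal(3)
  dimnames(kinv) <- list(ids, ids)
  dat <- data.frame(id = ids, y = c(1, 3, 8))
  sol <- solve_mme(build_mme(y ~ 1, dat, kinv,
                             c(var_a = 1, var_e = 1), pe = FALSE))
  oracle <- gls_oracle(dat$y, matrix(1, 3), diag(3), diag(3),
                       va = 1, ve = 1)
  expect_equal(unname(sol$a), unname(oracle$a), tolerance = 1e-8)

  # single animal, single record, no fixed effects: scalar BLUP shrinkage
  k1 <- Matrix::Diagonal(1); dimnames(k1) <- list("a", "a")
  d1 <- data.frame(id = "a", y = 2)
  vc <- c(var_a = 1, var_pe = 0.5, var_e = 2.5)
  s1 <- solve_mme(build_mme(y ~ 0, d1, k1, vc))
  expect_equal(unname(s1$a), 2 * 1 / (1 + 0.5 + 2.5), tolerance = 1e-8)

  # permuting record order leaves solutions unchanged
  ped <- random_pedigree(10, seed = 3)
  dat2 <- make_records(ped, 2, seed = 4)
  vc2 <- c(var_a = 1, var_pe = 0.5, var_e = 2)
  s_a <- solve_mme(build_mme(y ~ 1, dat2, a_inverse(ped), vc2))
  s_b <- solve_mme(build_mme(y ~ 1, dat2[sample(nrow(dat2)), ],
                             a_inverse(ped), vc2))
  expect_equal(s_a$b, s_b$b, tolerance = 1e-8)
  expect_equal(s_a$a, s_b$a, tolerance = 1e-8)
})

test_that("duplicating records strengthens GEBVs as the refit oracle says", {
  ped <- random_pedigree(10, seed = 5)
  dat <- make_records(ped, 2, seed = 6)
  vc <- c(var_a = 1, var_pe = 0.5, var_e = 2)
  base <- solve_mme(build_mme(y ~ 1, dat, a_inverse(ped), vc))
  dup <- rbind(dat, dat)
  redo <- solve_mme(build_mme(y ~ 1, dup, a_inverse(ped), vc))
  # refit oracle on the duplicated data
  n <- nrow(dup)
  ai <- match(dup$id, ped$id)
  Z <- matrix(0, n, 10); Z[cbind(1:n, ai)] <- 1
  ids <- sort(unique(ai))
  W <- matrix(0, n, length(ids)); W[cbind(1:n, match(ai, ids))] <- 1
  oracle <- gls_oracle(dup$y, matrix(1, n), Z, a_matrix(ped), W,
                       va = 1, vp = 0.5, ve = 2)
  expect_equal(unname(redo$a), unname(oracle$a), tolerance = 1e-6)
  # shrinkage decreases: breeding values move outward
  expect_gt(mean(abs(redo$a)), mean(abs(base$a)))
})

test_that("constant phenotypes give zero random effects", {
  ped <- random_pedigree(8, seed = 7)
  dat <- data.frame(id = rep(ped$id, 2), y = 4.2)
  sol <- solve_mme(build_mme(y ~ 1, dat, a_inverse(ped),
                             c(var_a = 1, var_pe = 0.5, var_e = 1)))
  expect_equal(unname(sol$b), 4.2, tolerance = 1e-8)
  expect_lt(max(abs(sol$a)), 1e-8)
  expect_lt(max(abs(sol$p)), 1e-8)
})

test_that("PCG solver agrees with the direct factorisation", {
  ped <- random_pedigree(30, seed = 8)
  dat <- make_records(ped, 3, seed = 9)
  sys <- build_mme(y ~ 1, dat, a_inverse(ped),
                   c(var_a = 1, var_pe = 0.5, var_e = 2))
  s1 <- solve_mme(sys)
  s2 <- solve_mme(sys, method = "pcg", tol = 1e-12)
  expect_equal(s1$a, s2$a, tolerance = 1e-6)
})

test_that("AI-REML recovers simulated components and is scale-equivariant", {
  cfg <- sim_config(n_founders = 150, n_generations = 3, litter_size = 2,
                    n_chromosomes = 3, chrom_length_bp = 5e6, n_snps = 400,
                    n_qtl = 2, qtl_var_fractions = c(0.1, 0.1),
                    records_per_animal = 4, genotyped_fraction = 0,
                    seed = 10)
  sim <- simulate_dataset(cfg)
  ainv <- a_inverse(sim$pedigree)
  fit <- reml_ai(y ~ yearseason + age + intv, sim$phenotypes, ainv)
  expect_true(fit$converged)
  for (k in c("var_a", "var_pe", "var_e"))
    expect_lt(abs(fit$varcomp[[k]] - cfg[[k]]) / max(fit$se[[k]], 1e-8),
              3.5)

  # doubling the phenotypes multiplies all components by 4
  dat4 <- sim$phenotypes
  dat4$y <- 2 * dat4$y
  fit4 <- reml_ai(y ~ yearseason + age + intv, dat4, ainv)
  expect_equal(unname(fit4$varcomp), unname(4 * fit$varcomp),
               tolerance = 1e-4)

  # relabelling the factor levels leaves the fit invariant
  dat_r <- sim$phenotypes
  dat_r$yearseason <- factor(dat_r$yearseason,
                             levels = rev(levels(dat_r$yearseason)))
  fit_r <- reml_ai(y ~ yearseason + age + intv, dat_r, ainv)
  expect_equal(fit_r$varcomp, fit$varcomp, tolerance = 1e-5)
})

test_that("null heritability lands on the boundary", {
  cfg <- sim_config(n_founders = 250, n_generations = 3, litter_size = 2,
                    n_chromosomes = 2, chrom_length_bp = 4e6, n_snps = 200,
                    n_qtl = 0, qtl_var_fractions = numeric(0),
                    var_a = 0, var_pe = 0.04, var_e = 0.2,
                    records_per_animal = 4, genotyped_fraction = 0,
                    seed = 11)
  sim <- simulate_dataset(cfg)
  fit <- reml_ai(y ~ yearseason + age + intv, sim$phenotypes,
                 a_inverse(sim$pedigree))
  # estimate at or near the zero boundary: a small fraction of the
  # phenotypic variance (~0.24)
  expect_lt(fit$varcomp["var_a"], 0.012)

  # permanent environment without repeated records is not identifiable
  one <- sim$phenotypes[!duplicated(sim$phenotypes$id), ]
  expect_error(reml_ai(y ~ 1, one, a_inverse(sim$pedigree)),
               "not identifiable")
})

test_that("heritability arithmetic matches published component ratios", {
  expect_equal(unname(heritability(c(0.00757, 0.00248, 0.03695))["h2"]),
               0.16105, tolerance = 0.0005)
  expect_equal(unname(heritability(c(0.05172, 0.03682, 0.19380))["h2"]),
               0.1832, tolerance = 0.0005)
  expect_equal(unname(heritability(c(1, 0, 0))["h2"]), 1)
  h <- heritability(c(var_a = 2, var_pe = 1, var_e = 1))
  expect_equal(unname(h["repeatability"]), 0.75)
  expect_error(heritability(c(0, 0, 0)), "zero")
})
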