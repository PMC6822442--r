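# Independent oracles and small fixture builders shared across tests.

# Gene-dropping Monte-Carlo estimate of the numerator relationship matrix:
# founder alleles get unique labels, alleles descend by fair Mendelian
# sampling, and A_ij is estimated as twice the coancestry (probability that
# random alleles drawn from i and j are identical by descent).
gene_drop_A <- function(ped, n_drops = 1e5) {
  n <- length(ped$id)
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  next_label <- 1L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s)) {
      a1[, i] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick, a1[, s], a2[, s])
    }
    if (is.na(d)) {
      a2[, i] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a2[, i] <- ifelse(pick, a1[, d], a2[, d])
    }
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    co <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
      (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
    A[i, j] <- A[j, i] <- 2 * mean(co) / 4
  }
  A
}

# Exact HWE probabilities by direct factorial enumeration over all
# heterozygote counts compatible with the allele counts (independent of the
# package's recurrence-free implementation path).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_AA + n_Aa
  nb <- 2 * n_aa + n_Aa
  hets <- seq(na %% 2, min(na, nb), by = 2)
  prob1 <- function(h) {
    nA <- (na - h) / 2; nB <- (nb - h) / 2
    exp(lfactorial(n) - lfactorial(nA) - lfactorial(h) - lfactorial(nB) +
          h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
  }
  pr <- vapply(hets, prob1, numeric(1))
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Dense GLS / BLUP oracle for the repeatability model:
#   V = Z A Z' va + W W' vp + I ve
# Returns GLS fixed effects and BLUP breeding values a_hat = va A Z' P y.
gls_oracle <- function(y, X, Z, A, W = NULL, va, vp = 0, ve) {
  V <- va * Z %*% A %*% t(Z) + ve * diag(length(y))
  if (!is.null(W)) V <- V + vp * tcrossprod(W)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  a <- va * A %*% t(Z) %*% P %*% y
  p <- if (!is.null(W)) vp * t(W) %*% P %*% y else NULL
  list(b = drop(b), a = drop(a), p = if (!is.null(p)) drop(p))
}

# Moore-Penrose pseudoinverse via SVD (oracle for near-singular G solves).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Random valid pedigree: animals pick parents among earlier animals (or
# unknown), guaranteeing topological order; produces inbreeding by chance.
random_pedigree <- function(n, p_known = 0.8, seed = 1) {
  set.seed(seed)
  sire <- dam <- rep(NA_character_, n)
  ids <- sprintf("a%d", seq_len(n))
  for (i in 3:n) {
    if (stats::runif(1) < p_known) {
      sire[i] <- ids[sample.int(i - 1L, 1L)]
      repeat {
        d <- ids[sample.int(i - 1L, 1L)]
        if (d != sire[i]) break
      }
      dam[i] <- d
    }
  }
  pedigree(ids, sire, dam)
}

# Small fully simulated dataset for end-to-end tests.
tiny_sim <- function(seed = 1, n_founders = 40, n_generations = 3,
                     litter_size = 2, n_snps = 300, n_chromosomes = 3,
                     chrom_length_bp = 6e6, n_qtl = 1,
                     qtl_var_fractions = 0.3, records_per_animal = 4,
                     genotyped_fraction = 0.6, ...) {
  simulate_dataset(sim_config(
    n_founders = n_founders, n_generations = n_generations,
    litter_size = litter_size, n_chromosomes = n_chromosomes,
    chrom_length_bp = chrom_length_bp, n_snps = n_snps, n_qtl = n_qtl,
    qtl_var_fractions = qtl_var_fractions,
    records_per_animal = records_per_animal,
    genotyped_fraction = genotyped_fraction, seed = seed, ...))
}
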