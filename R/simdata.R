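#' Simulation configuration
#'
#' Collects the parameters of the synthetic-data generator. Defaults emulate
#' the design of a commercial Duroc boar nucleus herd analysed with a
#' repeatability model: a deep multi-generation pedigree of which only recent
#' generations are genotyped, a medium-density autosomal SNP panel, additive
#' QTL plus a polygenic remainder, and many repeated ejaculate records per
#' boar with year-season, age and collection-interval effects. Default
#' variance components are those of a log sperm-count trait
#' (\eqn{\sigma^2_a = 0.05172}, \eqn{\sigma^2_{pe} = 0.03682},
#' \eqn{\sigma^2_e = 0.19380}, \eqn{h^2 \approx 0.18}).
#'
#' @param n_founders number of founder animals (generation 0).
#' @param n_generations number of descendant generations.
#' @param litter_size offspring per mating.
#' @param n_chromosomes,chrom_length_bp autosome count and length.
#' @param n_snps total SNPs across the genome.
#' @param n_qtl number of causal SNPs.
#' @param qtl_var_fractions per-QTL fraction of \eqn{\sigma^2_a}
#'   (sum \eqn{\le} 1; remainder is polygenic background).
#' @param polygenic how the polygenic remainder of \eqn{\sigma^2_a} is
#'   generated: \code{"marker"} (default) spreads it as small additive
#'   effects over all non-QTL segregating SNPs, so the whole additive
#'   variance is marker-linked, as the single-step model assumes;
#'   \code{"pedigree"} drops an unlinked polygenic term through the
#'   pedigree (Mendelian-sampling recursion), emulating genetic variance
#'   the panel cannot tag.
#' @param var_a,var_pe,var_e additive, permanent-environment and residual
#'   variances.
#' @param beta_age,beta_intv covariate slopes (per month of age, per day of
#'   collection interval).
#' @param trait_mean overall mean of the trait.
#' @param n_yearseason number of year-season classes.
#' @param yearseason_sd spread of the fixed year-season effects.
#' @param records_per_animal mean number of repeated records (Poisson,
#'   minimum 1).
#' @param genotyped_fraction fraction of animals genotyped (most recent
#'   animals first).
#' @param phenotyped_prob per-animal probability of having records at all
#'   (emulates traits recorded on a subset of boars).
#' @param founder_freq optional vector of founder allele frequencies; default
#'   Uniform(0.05, 0.5).
#' @param founder_ld simulate linkage disequilibrium among founder loci by
#'   building each founder haplotype as a mosaic of \code{n_ancestors}
#'   ancestral haplotypes with mean segment length \code{haploblock_bp}
#'   (default \code{TRUE}); \code{FALSE} gives independent loci
#'   (linkage equilibrium) in the founders.
#' @param n_ancestors number of distinct ancestral haplotypes segregating
#'   per region; closed nucleus herds have small effective population
#'   sizes, so few haplotypes per block is realistic.
#' @param haploblock_bp mean ancestral-segment (haploblock) length; 0.4 Mb
#'   is the average haploblock length reported for commercial pig lines.
#' @param seed RNG seed; each generator stage derives its own stream from it,
#'   so a fixed seed gives byte-identical output.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_founders = 400L, n_generations = 12L,
                       litter_size = 2L,
                       n_chromosomes = 18L, chrom_length_bp = 82.4e6,
                       n_snps = 28289L, n_qtl = 10L,
                       qtl_var_fractions = rep(0.03, n_qtl),
                       polygenic = c("marker", "pedigree"),
                       var_a = 0.05172, var_pe = 0.03682, var_e = 0.19380,
                       beta_age = 0.01, beta_intv = 0.005,
                       trait_mean = 27.2,
                       n_yearseason = 16L, yearseason_sd = 0.2,
                       records_per_animal = 53,
                       genotyped_fraction = 0.31,
                       phenotyped_prob = 1,
                       founder_freq = NULL,
                       founder_ld = TRUE, n_ancestors = 10L,
                       haploblock_bp = 400000,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              litter_size = as.integer(litter_size),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
              qtl_var_fractions = qtl_var_fractions,
              polygenic = match.arg(polygenic),
              var_a = var_a, var_pe = var_pe, var_e = var_e,
              beta_age = beta_age, beta_intv = beta_intv,
              trait_mean = trait_mean,
              n_yearseason = as.integer(n_yearseason),
              yearseason_sd = yearseason_sd,
              records_per_animal = records_per_animal,
              genotyped_fraction = genotyped_fraction,
              phenotyped_prob = phenotyped_prob,
              founder_freq = founder_freq,
              founder_ld = isTRUE(founder_ld),
              n_ancestors = as.integer(n_ancestors),
              haploblock_bp = haploblock_bp,
              seed = as.integer(seed))
  if (any(c(cfg$var_a, cfg$var_pe, cfg$var_e) < 0))
    stop("variances must be non-negative")
  if (cfg$n_qtl > 0 && length(cfg$qtl_var_fractions) != cfg$n_qtl)
    stop("qtl_var_fractions must have length n_qtl")
  if (sum(cfg$qtl_var_fractions) > 1 + 1e-12)
    stop("QTL variance fractions exceed the additive variance (sum > 1)")
  if (cfg$n_snps < cfg$n_qtl) stop("need n_snps >= n_qtl")
  if (cfg$n_founders < 2L) stop("need at least 2 founders (one per sex)")
  if (cfg$n_generations < 1L) stop("need at least one descendant generation")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) are assigned alternating sexes so matings always
#' exist. In each later generation every dam of the previous generation is
#' mated to a randomly drawn sire of that generation and produces
#' \code{litter_size} offspring with alternating sexes. The most recent
#' \code{genotyped_fraction} of animals is flagged as genotyped.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{pedigree}} with a \code{generation} attribute.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  nf <- config$n_founders
  id <- sprintf("G0_%d", seq_len(nf))
  sex <- rep(c("M", "F"), length.out = nf)
  sire <- dam <- rep(NA_character_, nf)
  gen <- rep(0L, nf)
  prev_ids <- id; prev_sex <- sex
  for (g in seq_len(config$n_generations)) {
    sires <- prev_ids[prev_sex == "M"]
    dams <- prev_ids[prev_sex == "F"]
    if (length(sires) == 0L || length(dams) == 0L)
      stop("generation ", g - 1L, " has a single sex; no matings possible")
    mate_sire <- sires[sample.int(length(sires), length(dams), replace = TRUE)]
    noff <- length(dams) * config$litter_size
    off_id <- sprintf("G%d_%d", g, seq_len(noff))
    off_sire <- rep(mate_sire, each = config$litter_size)
    off_dam <- rep(dams, each = config$litter_size)
    off_sex <- rep(c("M", "F"), length.out = noff)
    id <- c(id, off_id); sire <- c(sire, off_sire); dam <- c(dam, off_dam)
    sex <- c(sex, off_sex); gen <- c(gen, rep(g, noff))
    prev_ids <- off_id; prev_sex <- off_sex
  }
  n <- length(id)
  n_geno <- round(config$genotyped_fraction * n)
  genotyped <- rep(FALSE, n)
  if (n_geno > 0L) genotyped[(n - n_geno + 1L):n] <- TRUE
  ped <- pedigree(id, sire, dam, genotyped = genotyped, sex = sex)
  attr(ped, "generation") <- gen
  ped
}

# Random SNP map: positions uniform within chromosomes, sorted; SNP counts
# split as evenly as possible across chromosomes.
sim_snp_map <- function(config) {
  m <- config$n_snps
  per <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1L)))
  chr <- rep(seq_len(config$n_chromosomes), per)
  bp <- unlist(lapply(per, function(k)
    sort(sample.int(config$chrom_length_bp, k))))
  data.frame(snp = sprintf("snp%d", seq_len(m)), chr = chr, bp = bp)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn from per-SNP allele frequencies so founder
#' genotypes are in Hardy-Weinberg proportions. By default
#' (\code{founder_ld = TRUE}) each founder haplotype is a mosaic of
#' \code{n_ancestors} ancestral haplotypes with mean segment length
#' \code{haploblock_bp}, which induces haploblock-scale linkage
#' disequilibrium among founder loci (at each SNP, the number of ancestral
#' haplotypes carrying the counted allele is fixed to match the target
#' frequency, so marginal frequencies and Hardy-Weinberg proportions are
#' preserved); with \code{founder_ld = FALSE} loci are independent.
#' Descendant gametes are sampled from the parental haplotypes with
#' recombination between adjacent SNPs at the Haldane rate
#' \eqn{r = \tfrac12(1 - e^{-2d})} for map distance d (1 cM/Mb),
#' resetting to independent segregation at chromosome starts.
#'
#' @param pedigree a \code{\link{pedigree}} (typically from
#'   \code{\link{simulate_pedigree}}).
#' @param config a \code{\link{sim_config}}; \code{founder_freq} overrides the
#'   default Uniform(0.05, 0.5) founder frequencies.
#' @return a \code{\link{genotype_matrix}} over \emph{all} pedigree animals
#'   (downstream code subsets the genotyped ones), with founder allele
#'   frequencies attached as attribute \code{"founder_freq"}.
#' @export
drop_genotypes <- function(pedigree, config) {
  set.seed(config$seed + 1L)
  map <- sim_snp_map(config)
  m <- nrow(map); n <- length(pedigree$id)
  p <- config$founder_freq
  if (is.null(p)) p <- stats::runif(m, 0.05, 0.5)
  stopifnot(length(p) == m)
  # per-gap recombination fractions; chromosome starts segregate freely
  d_morgan <- c(0, diff(map$bp)) * 1e-8
  r <- 0.5 * (1 - exp(-2 * d_morgan))
  r[c(1L, which(diff(map$chr) != 0) + 1L)] <- 0.5
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  gamete <- function(i) {
    phase <- cumsum(stats::rbinom(m, 1L, r)) %% 2L
    ifelse(phase == 0L, H1[i, ], H2[i, ])
  }
  if (config$founder_ld) {
    # ancestral mosaic: K ancestral haplotypes; at each SNP exactly
    # round(K p) of them carry the counted allele, so the marginal founder
    # frequency stays (close to) p while same-segment loci are correlated
    K <- max(2L, config$n_ancestors)
    anc <- vapply(seq_len(m), function(jj) {
      a <- integer(K)
      cnt <- round(K * p[jj])
      if (cnt > 0L) a[sample.int(K, cnt)] <- 1L
      a
    }, integer(K))                      # K x m
    d_gap <- c(Inf, diff(map$bp))
    d_gap[c(1L, which(diff(map$chr) != 0) + 1L)] <- Inf
    switch_prob <- 1 - exp(-d_gap / config$haploblock_bp)
    founder_hap <- function() {
      seg <- cumsum(stats::runif(m) < switch_prob)
      h <- sample.int(K, max(seg), replace = TRUE)[seg]
      anc[cbind(h, seq_len(m))]
    }
  } else {
    founder_hap <- function() stats::rbinom(m, 1L, p)
  }
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    H1[i, ] <- if (is.na(s)) founder_hap() else gamete(s)
    H2[i, ] <- if (is.na(d)) founder_hap() else gamete(d)
  }
  dos <- H1 + H2
  rownames(dos) <- pedigree$id
  g <- genotype_matrix(dos, map)
  attr(g, "founder_freq") <- p
  g
}

#' Simulate repeated-record phenotypes under the repeatability model
#'
#' True breeding values are the sum of a marker part (additive effects at
#' \code{n_qtl} causal SNPs, scaled so QTL j contributes
#' \code{qtl_var_fractions[j]} of \eqn{\sigma^2_a} at its founder frequency)
#' and a pedigree polygenic part that tops the additive variance up to
#' \eqn{\sigma^2_a}. Each phenotyped animal receives a Poisson number of
#' records (mean \code{records_per_animal}, minimum 1); record r of animal i
#' is
#' \deqn{y_{ir} = \mu + ys_{c(r)} + \beta_{age} Age_{ir} + \beta_{intv}
#'   Intv_{ir} + a_i + pe_i + e_{ir}}
#' with \eqn{pe_i \sim N(0, \sigma^2_{pe})} and
#' \eqn{e_{ir} \sim N(0, \sigma^2_e)}.
#'
#' @param pedigree a \code{\link{pedigree}}.
#' @param genotypes genotypes of all pedigree animals
#'   (\code{\link{drop_genotypes}}).
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{phenotypes} (data.frame: \code{id}, \code{record},
#'   \code{yearseason}, \code{age}, \code{intv}, \code{y}) and \code{truth}
#'   (list: \code{tbv}, \code{qtl_idx}, \code{qtl_eff}, \code{realized_h2}).
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config) {
  set.seed(config$seed + 2L)
  n <- length(pedigree$id)
  m <- ncol(genotypes$dosage)
  frac <- config$qtl_var_fractions
  if (sum(frac) * config$var_a > config$var_a + 1e-12)
    stop("requested QTL variance exceeds var_a")
  p0 <- allele_freq(genotypes)       # realized frequencies, all animals
  # QTL: causal SNPs drawn among loci segregating at intermediate realized
  # frequency; effects scaled by the realized dosage variance so each QTL
  # contributes exactly its assigned fraction of var_a
  qtl_idx <- integer(0); qtl_eff <- numeric(0)
  a_qtl <- numeric(n)
  if (config$n_qtl > 0L && sum(frac) > 0) {
    sd_dos <- apply(genotypes$dosage, 2L, stats::sd)
    eligible <- which(p0 >= 0.1 & p0 <= 0.9 & sd_dos > 0)
    if (length(eligible) < config$n_qtl)
      eligible <- order(abs(p0 - 0.5))[seq_len(config$n_qtl)]
    qtl_idx <- sort(sample(eligible, config$n_qtl))
    qtl_eff <- sample(c(-1, 1), config$n_qtl, replace = TRUE) *
      sqrt(frac * config$var_a) / sd_dos[qtl_idx]
    zq <- sweep(matrix(as.numeric(genotypes$dosage[, qtl_idx, drop = FALSE]),
                       n), 2L, 2 * p0[qtl_idx], "-")
    a_qtl <- drop(zq %*% qtl_eff)
  }
  # polygenic remainder: marker-linked background (default) or an unlinked
  # term dropped through the pedigree
  var_poly <- config$var_a * (1 - sum(frac))
  u <- numeric(n)
  if (var_poly > 0 && identical(config$polygenic, "marker")) {
    bg <- setdiff(which(p0 > 0 & p0 < 1), qtl_idx)
    if (length(bg) == 0L)
      stop("no segregating background SNPs for the marker polygenic term")
    beff <- stats::rnorm(length(bg), 0,
                         sqrt(var_poly / (length(bg) * 2 * p0[bg] *
                                            (1 - p0[bg]))))
    zb <- sweep(matrix(as.numeric(genotypes$dosage[, bg, drop = FALSE]), n),
                2L, 2 * p0[bg], "-")
    u <- drop(zb %*% beff)
    if (length(qtl_idx) > 0L && stats::var(a_qtl) > 0) {
      # orthogonalise against the QTL values so the realized additive
      # variance decomposes exactly into the assigned fractions
      u <- stats::residuals(stats::lm(u ~ zq))
    }
    su <- stats::sd(u)
    if (su > 0) u <- u * sqrt(var_poly) / su  # realized variance = var_poly
  } else if (var_poly > 0) {
    f <- inbreeding(pedigree)
    for (i in seq_len(n)) {
      s <- pedigree$sire[i]; d <- pedigree$dam[i]
      if (is.na(s) && is.na(d)) {
        u[i] <- stats::rnorm(1L, 0, sqrt(var_poly))
      } else {
        us <- if (is.na(s)) 0 else u[s]
        ud <- if (is.na(d)) 0 else u[d]
        fs <- if (is.na(s)) 0 else f[s]
        fd <- if (is.na(d)) 0 else f[d]
        vm <- if (!is.na(s) && !is.na(d))
          0.5 * var_poly * (1 - 0.5 * (fs + fd)) else 0.75 * var_poly
        u[i] <- 0.5 * (us + ud) + stats::rnorm(1L, 0, sqrt(vm))
      }
    }
  }
  tbv <- a_qtl + u
  names(tbv) <- pedigree$id
  # repeated records
  phen_animal <- stats::runif(n) < config$phenotyped_prob
  if (!any(phen_animal)) stop("no phenotyped animals (phenotyped_prob too low)")
  nrec <- 1L + stats::rpois(n, max(config$records_per_animal - 1, 0))
  nrec[!phen_animal] <- 0L
  idx <- rep(seq_len(n), nrec)
  nr <- length(idx)
  ys_eff <- stats::rnorm(config$n_yearseason, 0, config$yearseason_sd)
  ys <- sample.int(config$n_yearseason, nr, replace = TRUE)
  age <- stats::runif(nr, 8, 60)
  intv <- stats::runif(nr, 2, 14)
  pe <- stats::rnorm(n, 0, sqrt(config$var_pe))
  e <- stats::rnorm(nr, 0, sqrt(config$var_e))
  y <- config$trait_mean + ys_eff[ys] + config$beta_age * age +
    config$beta_intv * intv + tbv[idx] + pe[idx] + e
  phen <- data.frame(id = pedigree$id[idx],
                     record = sequence(nrec[nrec > 0L]),
                     yearseason = factor(ys),
                     age = age, intv = intv, y = y,
                     stringsAsFactors = FALSE)
  va <- stats::var(tbv)
  truth <- list(tbv = tbv, qtl_idx = qtl_idx, qtl_eff = qtl_eff,
                qtl_snp = genotypes$map$snp[qtl_idx],
                realized_h2 = va / (va + config$var_pe + config$var_e))
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs \code{\link{simulate_pedigree}}, \code{\link{drop_genotypes}} and
#' \code{\link{simulate_phenotypes}} and subsets the genotype matrix to the
#' genotyped animals, mirroring a population where only part of the pedigree
#' is on the SNP array.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{"wssgwas_sim"}: \code{pedigree},
#'   \code{genotypes} (genotyped animals only), \code{phenotypes},
#'   \code{truth}, \code{config}.
#' @examples
#' sim <- simulate_dataset(sim_config(n_founders = 10, n_generations = 2,
#'                                    n_snps = 50, n_qtl = 2,
#'                                    qtl_var_fractions = c(0.2, 0.2),
#'                                    records_per_animal = 3, seed = 42))
#' sim$pedigree
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  geno_all <- drop_genotypes(ped, config)
  sp <- simulate_phenotypes(ped, geno_all, config)
  gidx <- which(ped$genotyped)
  geno <- if (length(gidx) > 0L) {
    g <- genotype_matrix(geno_all$dosage[gidx, , drop = FALSE], geno_all$map)
    attr(g, "founder_freq") <- attr(geno_all, "founder_freq")
    g
  } else NULL
  structure(list(pedigree = ped, genotypes = geno,
                 genotypes_all = geno_all,
                 phenotypes = sp$phenotypes, truth = sp$truth,
                 config = config),
            class = "wssgwas_sim")
}

#' @export
print.wssgwas_sim <- function(x, ...) {
  cat("Simulated dataset:", length(x$pedigree$id), "animals,",
      if (is.null(x$genotypes)) 0L else nrow(x$genotypes$dosage),
      "genotyped,", nrow(x$phenotypes), "records,",
      ncol(x$genotypes_all$dosage), "SNPs; realized h2 =",
      round(x$truth$realized_h2, 3), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits PLINK PED/MAP (genotyped animals), pedigree CSV, phenotype CSV and a
#' truth JSON (requires jsonlite).
#'
#' @param sim a \code{\link{simulate_dataset}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$genotypes))
    write_plink(sim$genotypes, file.path(dir, "genotypes"), ped = sim$pedigree)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  utils::write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- sim$truth
    jsonlite::write_json(list(qtl_snp = tr$qtl_snp, qtl_eff = tr$qtl_eff,
                              realized_h2 = tr$realized_h2,
                              tbv = as.list(tr$tbv)),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
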