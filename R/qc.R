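#' Marker and sample quality-control configuration
#'
#' Thresholds of the standard SNP-array QC chain: individual call rate, SNP
#' call rate, minor allele frequency and exact Hardy-Weinberg test, applied
#' to autosomal, mapped SNPs only.
#'
#' @param min_ind_callrate minimum per-individual call rate (kept if
#'   \eqn{\ge}).
#' @param min_snp_callrate minimum per-SNP call rate (kept if \eqn{\ge}).
#' @param min_maf minimum minor allele frequency (kept if \eqn{\ge}).
#' @param hwe_p_min minimum Hardy-Weinberg p-value (kept if \eqn{\ge}).
#' @param autosomes_only drop unmapped and sex-chromosome SNPs first.
#' @param autosome_max largest autosome number (18 for pig); numeric
#'   chromosome codes above it, and labels X/Y/XY/MT, count as
#'   non-autosomal.
#' @param hwe_method \code{"exact"} (default) or \code{"chisq"}.
#' @return list of class \code{"qc_config"}.
#' @export
qc_config <- function(min_ind_callrate = 0.90, min_snp_callrate = 0.90,
                      min_maf = 0.01, hwe_p_min = 1e-6,
                      autosomes_only = TRUE, autosome_max = 18L,
                      hwe_method = c("exact", "chisq")) {
  thr <- c(min_ind_callrate, min_snp_callrate, min_maf, hwe_p_min)
  if (any(thr < 0 | thr > 1)) stop("QC thresholds must lie in [0, 1]")
  structure(list(min_ind_callrate = min_ind_callrate,
                 min_snp_callrate = min_snp_callrate,
                 min_maf = min_maf, hwe_p_min = hwe_p_min,
                 autosomes_only = autosomes_only,
                 autosome_max = as.integer(autosome_max),
                 hwe_method = match.arg(hwe_method)),
            class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test of Hardy-Weinberg proportions from genotype counts: the
#' conditional distribution of the heterozygote count given the allele
#' counts is enumerated and the p-value is the summed probability of all
#' heterozygote outcomes no more probable than the observed one (no mid-p
#' correction). Symmetric in the allele labels.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return p-value in (0, 1].
#' @examples
#' hwe_pvalue(25, 50, 25)  # perfect proportions -> 1
#' hwe_pvalue(50, 0, 50)   # extreme heterozygote deficit -> ~1e-30
#' @export
hwe_pvalue <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0L) stop("all genotype counts are zero")
  na <- 2 * n_AA + n_Aa          # copies of allele A
  nb <- 2 * n_aa + n_Aa
  nab <- seq(na %% 2, min(na, nb), by = 2)   # feasible heterozygote counts
  # log P(n_Aa = h | allele counts), up to a common constant
  lp <- lgamma(n + 1) - lgamma((na - nab) / 2 + 1) - lgamma(nab + 1) -
    lgamma((nb - nab) / 2 + 1) + nab * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, nab)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# chi-square HWE test (1 df), offered as a faster alternative
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Assemble a QC bookkeeping report
#'
#' Records the per-filter removal counts of the QC chain and enforces the
#' accounting identity: survivors = input minus the sum of removals, each
#' SNP (or individual) attributed to exactly the first filter it fails.
#'
#' @param n_snps_in,removed_unmapped,removed_sex_chrom,removed_snp_callrate,removed_maf,removed_hwe
#'   SNP counts.
#' @param n_ind_in,removed_ind_callrate individual counts.
#' @return list of class \code{"qc_report"} with derived \code{n_snps_out}
#'   and \code{n_ind_out}.
#' @export
qc_report <- function(n_snps_in, removed_unmapped = 0L, removed_sex_chrom = 0L,
                      removed_snp_callrate = 0L, removed_maf = 0L,
                      removed_hwe = 0L, n_ind_in = 0L,
                      removed_ind_callrate = 0L) {
  snp_removed <- removed_unmapped + removed_sex_chrom +
    removed_snp_callrate + removed_maf + removed_hwe
  if (snp_removed > n_snps_in) stop("more SNPs removed than supplied")
  if (removed_ind_callrate > n_ind_in)
    stop("more individuals removed than supplied")
  structure(list(n_snps_in = n_snps_in,
                 removed_unmapped = removed_unmapped,
                 removed_sex_chrom = removed_sex_chrom,
                 removed_snp_callrate = removed_snp_callrate,
                 removed_maf = removed_maf,
                 removed_hwe = removed_hwe,
                 n_snps_out = n_snps_in - snp_removed,
                 n_ind_in = n_ind_in,
                 removed_ind_callrate = removed_ind_callrate,
                 n_ind_out = n_ind_in - removed_ind_callrate),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  individuals: %d in, %d removed (call rate), %d retained\n",
              x$n_ind_in, x$removed_ind_callrate, x$n_ind_out))
  cat(sprintf("  SNPs: %d in\n", x$n_snps_in))
  cat(sprintf("    unmapped:      -%d\n", x$removed_unmapped))
  cat(sprintf("    sex chrom.:    -%d\n", x$removed_sex_chrom))
  cat(sprintf("    call rate:     -%d\n", x$removed_snp_callrate))
  cat(sprintf("    MAF:           -%d\n", x$removed_maf))
  cat(sprintf("    HWE:           -%d\n", x$removed_hwe))
  cat(sprintf("  SNPs retained: %d\n", x$n_snps_out))
  invisible(x)
}

#' Filter individuals by call rate
#'
#' Removes individuals whose fraction of non-missing genotype calls falls
#' below \code{min_ind_callrate}.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param config a \code{\link{qc_config}}.
#' @return list with the filtered \code{genotypes}, the number
#'   \code{removed} and the \code{removed_ids}.
#' @export
filter_samples <- function(genotypes, config = qc_config()) {
  dos <- genotypes$dosage
  if (nrow(dos) == 0L || ncol(dos) == 0L) stop("empty genotype matrix")
  cr <- rowMeans(!is.na(dos))
  keep <- cr >= config$min_ind_callrate
  out <- genotypes
  out$dosage <- dos[keep, , drop = FALSE]
  list(genotypes = out, removed = sum(!keep),
       removed_ids = rownames(dos)[!keep])
}

#' Filter SNPs by map, call rate, MAF and Hardy-Weinberg
#'
#' Applies the marker filters in fixed order -- unmapped, sex chromosome,
#' SNP call rate, minor allele frequency, exact Hardy-Weinberg test -- with
#' each SNP attributed to the first filter it fails. Call rate, MAF and HWE
#' are computed on the non-missing genotypes of the individuals present in
#' the matrix (i.e. after sample filtering).
#'
#' @inheritParams filter_samples
#' @param n_ind_in,removed_ind_callrate optional individual accounting to
#'   embed in the report.
#' @return list with filtered \code{genotypes} and a \code{\link{qc_report}}.
#' @export
filter_snps <- function(genotypes, config = qc_config(),
                        n_ind_in = nrow(genotypes$dosage),
                        removed_ind_callrate = 0L) {
  dos <- genotypes$dosage
  map <- genotypes$map
  if (nrow(dos) == 0L || ncol(dos) == 0L) stop("empty genotype matrix")
  m <- ncol(dos)
  chr_raw <- as.character(map$chr)
  unmapped <- is.na(map$chr) | chr_raw == "0" | is.na(map$bp) | map$bp <= 0
  sex_labels <- c("X", "Y", "XY", "MT", "M")
  chr_num <- suppressWarnings(as.integer(chr_raw))
  is_sex <- !unmapped & (chr_raw %in% sex_labels |
                           (!is.na(chr_num) & chr_num > config$autosome_max))
  unknown <- !unmapped & is.na(chr_num) & !(chr_raw %in% sex_labels)
  if (any(unknown))
    stop("unknown chromosome labels: ",
         paste(unique(chr_raw[unknown]), collapse = ", "))
  if (!config$autosomes_only) unmapped[] <- is_sex[] <- FALSE
  cr <- colMeans(!is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  hwe_fun <- if (config$hwe_method == "exact") hwe_pvalue else hwe_chisq
  fail <- rep(NA_character_, m)
  fail[unmapped] <- "unmapped"
  fail[is.na(fail) & is_sex] <- "sex_chrom"
  fail[is.na(fail) & cr < config$min_snp_callrate] <- "callrate"
  fail[is.na(fail) & maf < config$min_maf] <- "maf"
  todo <- which(is.na(fail))
  hwe_p <- vapply(todo, function(j) {
    x <- dos[, j]
    hwe_fun(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
            sum(x == 2L, na.rm = TRUE))
  }, numeric(1))
  fail[todo[hwe_p < config$hwe_p_min]] <- "hwe"
  keep <- is.na(fail)
  rep_ <- qc_report(n_snps_in = m,
                    removed_unmapped = sum(fail == "unmapped", na.rm = TRUE),
                    removed_sex_chrom = sum(fail == "sex_chrom", na.rm = TRUE),
                    removed_snp_callrate = sum(fail == "callrate", na.rm = TRUE),
                    removed_maf = sum(fail == "maf", na.rm = TRUE),
                    removed_hwe = sum(fail == "hwe", na.rm = TRUE),
                    n_ind_in = n_ind_in,
                    removed_ind_callrate = removed_ind_callrate)
  out <- genotypes
  out$dosage <- dos[, keep, drop = FALSE]
  out$map <- map[keep, , drop = FALSE]
  rownames(out$map) <- NULL
  list(genotypes = out, report = rep_)
}

#' Run the full QC chain
#'
#' Sample call-rate filter followed by the SNP filters, with one combined
#' bookkeeping report.
#'
#' @inheritParams filter_samples
#' @return list with \code{genotypes} and \code{report}.
#' @export
apply_qc <- function(genotypes, config = qc_config()) {
  n_in <- nrow(genotypes$dosage)
  fs <- filter_samples(genotypes, config)
  filter_snps(fs$genotypes, config, n_ind_in = n_in,
              removed_ind_callrate = fs$removed)
}

#' Impute missing genotypes
#'
#' Fills missing calls either by sampling from the per-SNP genotype
#' frequencies of the observed calls (\code{method = "sample"},
#' reproducible given \code{seed}) or deterministically by the mean dosage
#' \eqn{2p} (\code{method = "mean"}; the result then carries fractional
#' dosages). Intended for post-QC matrices; externally imputed files can be
#' supplied instead via \code{\link{read_plink}}.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param method \code{"sample"} or \code{"mean"}.
#' @param seed RNG seed for \code{method = "sample"}.
#' @return the genotype matrix with no missing calls.
#' @export
impute_missing <- function(genotypes, method = c("sample", "mean"),
                           seed = 1L) {
  method <- match.arg(method)
  dos <- genotypes$dosage
  miss <- is.na(dos)
  if (!any(miss)) return(genotypes)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop("SNP(s) with all genotypes missing (should have been filtered): ",
         paste(utils::head(genotypes$map$snp[all_missing], 5L), collapse = ", "))
  if (method == "sample") {
    set.seed(seed)
    for (j in which(colSums(miss) > 0L)) {
      obs <- dos[!miss[, j], j]
      tab <- tabulate(obs + 1L, nbins = 3L)
      dos[miss[, j], j] <- sample(0:2, sum(miss[, j]), replace = TRUE,
                                  prob = tab / sum(tab))
    }
  } else {
    dosd <- matrix(as.numeric(dos), nrow(dos), dimnames = dimnames(dos))
    p2 <- colMeans(dosd, na.rm = TRUE)
    for (j in which(colSums(miss) > 0L))
      dosd[miss[, j], j] <- p2[j]
    out <- genotypes
    out$dosage <- dosd
    return(out)
  }
  out <- genotypes
  out$dosage <- dos
  out
}
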