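#' Construct a genotype matrix with its genome map
#'
#' Container for biallelic SNP dosages (individuals x SNPs, codes 0/1/2,
#' \code{NA} = missing) plus a genome map (chromosome, base-pair position per
#' SNP). Dosages count copies of the "B" allele; all genomic-relationship
#' algebra is invariant to which allele is counted (flipping a column
#' \code{x -> 2 - x} flips \code{p -> 1 - p} and leaves the centred coding,
#' \code{2p(1-p)} and hence G unchanged).
#'
#' @param dosage integer matrix, individuals in rows (rownames = animal ids),
#'   SNPs in columns.
#' @param map data.frame with columns \code{snp}, \code{chr} (integer
#'   chromosome), \code{bp} (position); one row per dosage column. Must be
#'   sorted by (chr, bp).
#' @return object of class \code{"geno_matrix"}.
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) stop("dosage matrix needs rownames (animal ids)")
  stopifnot(is.data.frame(map), all(c("snp", "chr", "bp") %in% names(map)),
            nrow(map) == ncol(dosage))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosage codes must be 0, 1, 2 or NA")
  if (any(order(map$chr, map$bp) != seq_len(nrow(map))))
    stop("map must be sorted by (chr, bp)")
  map$snp <- as.character(map$snp)
  colnames(dosage) <- map$snp
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs on", length(unique(x$map$chr)), "chromosome(s);",
      sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' Allele frequency of the counted allele
#'
#' Frequency of the counted ("B") allele per SNP, computed over non-missing
#' genotypes: \eqn{p_i = \bar{x}_i / 2}.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @return numeric vector of length m.
#' @export
allele_freq <- function(geno) {
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

#' Centred genotype coding
#'
#' Returns the dosage matrix with each column centred by twice its allele
#' frequency (\code{0 - 2p}, \code{1 - 2p}, \code{2 - 2p}), the Z used in the
#' genomic relationship matrix and in window genetic scores.
#'
#' @param geno a \code{\link{genotype_matrix}} with no missing calls.
#' @param p allele frequencies; defaults to the observed \code{\link{allele_freq}}.
#' @return numeric matrix, individuals x SNPs.
#' @export
centered_dosage <- function(geno, p = allele_freq(geno)) {
  if (anyNA(geno$dosage)) stop("missing genotypes: impute before centring")
  sweep(matrix(as.numeric(geno$dosage), nrow(geno$dosage),
               dimnames = dimnames(geno$dosage)), 2L, 2 * p, "-")
}

#' Read and write text PLINK PED/MAP files
#'
#' Minimal reader/writer for the whitespace-delimited text PLINK format.
#' Alleles are written as A/B with \code{0 0} for a missing call; the MAP file
#' carries chromosome, SNP id, genetic distance (written as 0) and bp.
#'
#' @param prefix path prefix; \code{<prefix>.ped} and \code{<prefix>.map} are
#'   read or written.
#' @return \code{read_plink} returns a \code{\link{genotype_matrix}} (dosage =
#'   count of B alleles) with a \code{fam} attribute holding the six leading
#'   PED columns.
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chr", "snp", "cm", "bp"),
                           stringsAsFactors = FALSE)
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop("PED has ", ncol(ped), " columns; expected ", 6L + 2L * m)
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  dos <- (a1 == "B") + (a2 == "B")
  dos[a1 == "0" | a2 == "0"] <- NA
  storage.mode(dos) <- "integer"
  rownames(dos) <- ped[[2L]]
  g <- genotype_matrix(dos, data.frame(snp = map$snp, chr = as.integer(map$chr),
                                       bp = as.integer(map$bp)))
  attr(g, "fam") <- ped[, 1:6]
  g
}

#' @rdname read_plink
#' @param geno a \code{\link{genotype_matrix}} to write.
#' @param ped optional \code{\link{pedigree}} supplying parent and sex codes
#'   for the PED columns.
#' @export
write_plink <- function(geno, prefix, ped = NULL) {
  dos <- geno$dosage
  n <- nrow(dos); m <- ncol(dos)
  a1 <- matrix("A", n, m); a2 <- matrix("A", n, m)
  a1[dos >= 1L] <- "B"
  a2[dos == 2L] <- "B"
  a1[is.na(dos)] <- "0"; a2[is.na(dos)] <- "0"
  inter <- matrix("", n, 2L * m)
  inter[, seq(1L, 2L * m, by = 2L)] <- a1
  inter[, seq(2L, 2L * m, by = 2L)] <- a2
  ids <- rownames(dos)
  sire <- dam <- rep("0", n); sex <- rep("0", n)
  if (!is.null(ped)) {
    j <- match(ids, ped$id)
    code <- function(i) ifelse(is.na(i), "0", ped$id[i])
    sire <- code(ped$sire[j]); dam <- code(ped$dam[j])
    if (!is.null(ped$sex)) sex <- ifelse(ped$sex[j] == "M", "1", "2")
  }
  lead <- cbind("FAM", ids, sire, dam, sex, "-9")
  utils::write.table(cbind(lead, inter), paste0(prefix, ".ped"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(geno$map$chr, geno$map$snp, 0, geno$map$bp),
                     paste0(prefix, ".map"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
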