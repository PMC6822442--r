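#' Pedigree numerator relationship matrix (tabular method)
#'
#' Computes the additive relationship matrix A by the tabular method:
#' processing animals in topological order, each new row is the half-sum of
#' the parental rows and the diagonal is \eqn{1 + F_i}, where the inbreeding
#' coefficient \eqn{F_i} is half the relationship between the parents.
#'
#' @param ped a \code{\link{pedigree}}.
#' @return dense symmetric matrix (animals x animals, dimnames = ids).
#' @export
a_matrix <- function(ped) {
  n <- length(ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + 0.5 * A[j, si]
      if (!is.na(di)) row <- row + 0.5 * A[j, di]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' \eqn{F_i = a_{ii} - 1} from the tabular relationship matrix.
#'
#' @param ped a \code{\link{pedigree}}.
#' @return numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  diag(a_matrix(ped)) - 1
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Builds \eqn{A^{-1}} directly by Henderson's rules with inbreeding
#' accounted for: each animal contributes \eqn{1/d_i} times the outer product
#' of \eqn{(e_i - \tfrac12 e_s - \tfrac12 e_d)}, where the Mendelian-sampling
#' variance is \eqn{d_i = \tfrac12 - \tfrac14 (F_s + F_d)} with both parents
#' known, \eqn{\tfrac34 - \tfrac14 F_k} with one parent known, and 1 for
#' founders.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param use_inbreeding logical; set \code{FALSE} to use the classic
#'   non-inbred rules (exact only for non-inbred pedigrees).
#' @return sparse symmetric \code{\link[Matrix]{Matrix}}.
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  n <- length(ped$id)
  f <- if (use_inbreeding) inbreeding(ped) else numeric(n)
  s <- ped$sire; d <- ped$dam
  fs <- ifelse(is.na(s), NA_real_, f[ifelse(is.na(s), 1L, s)])
  fd <- ifelse(is.na(d), NA_real_, f[ifelse(is.na(d), 1L, d)])
  di <- ifelse(!is.na(s) & !is.na(d), 0.5 - 0.25 * (fs + fd),
        ifelse(!is.na(s), 0.75 - 0.25 * fs,
        ifelse(!is.na(d), 0.75 - 0.25 * fd, 1)))
  alpha <- 1 / di
  ii <- jj <- xx <- vector("list", 4L)
  anim <- seq_len(n)
  # contributions: (i,i) + (parent pairs) - (i,parent) cross terms
  add <- function(i, j, x) {
    keep <- !is.na(i) & !is.na(j)
    list(i = i[keep], j = j[keep], x = x[keep])
  }
  parts <- list(
    add(anim, anim, alpha),
    add(anim, s, -alpha / 2), add(s, anim, -alpha / 2),
    add(anim, d, -alpha / 2), add(d, anim, -alpha / 2),
    add(s, s, alpha / 4), add(d, d, alpha / 4),
    add(s, d, alpha / 4), add(d, s, alpha / 4))
  i <- unlist(lapply(parts, `[[`, "i"))
  j <- unlist(lapply(parts, `[[`, "j"))
  x <- unlist(lapply(parts, `[[`, "x"))
  M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(M)
}

#' Pedigree relationships among genotyped animals
#'
#' Extracts the block of the A matrix corresponding to the genotyped animals
#' (the A22 block of single-step GBLUP).
#'
#' @param ped a \code{\link{pedigree}} with \code{genotyped} flags set.
#' @return dense symmetric matrix over genotyped animals.
#' @export
a22 <- function(ped) {
  idx <- which(ped$genotyped)
  if (length(idx) == 0L) stop("no genotyped animals in pedigree")
  a_matrix(ped)[idx, idx, drop = FALSE]
}

#' Scaling constant of the genomic relationship matrix
#'
#' \eqn{\lambda = 1 / \sum_i 2 p_i (1 - p_i)}, the reciprocal of the expected
#' marker variance under Hardy-Weinberg and linkage equilibrium.
#'
#' @param p per-SNP allele frequencies in (0, 1).
#' @return scalar.
#' @export
lambda_scale <- function(p) {
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNPs (p = 0 or 1) make the G scaling undefined; ",
         "apply the MAF filter first")
  1 / sum(2 * p * (1 - p))
}

#' (Weighted) genomic relationship matrix
#'
#' \deqn{G = \lambda Z D Z',\qquad \lambda = 1/\sum_i 2 p_i (1-p_i),}
#' with Z the centred dosage matrix (\code{0-2p}, \code{1-2p}, \code{2-2p})
#' and D a diagonal matrix of per-SNP weights (identity for the unweighted
#' VanRaden matrix).
#'
#' @param geno a \code{\link{genotype_matrix}} without missing calls.
#' @param weights per-SNP weights \eqn{d_i \ge 0}; \code{NULL} for D = I.
#' @param p allele frequencies used for centring and \eqn{\lambda}; fixed to
#'   the post-QC frequencies across weighting iterations.
#' @return dense symmetric matrix over the genotyped individuals, with the
#'   scaling constant attached as attribute \code{"lambda"}.
#' @export
g_matrix <- function(geno, weights = NULL, p = allele_freq(geno)) {
  lam <- lambda_scale(p)
  Zc <- centered_dosage(geno, p)
  if (is.null(weights)) {
    G <- tcrossprod(Zc) * lam
  } else {
    stopifnot(length(weights) == ncol(Zc))
    if (any(weights < 0)) stop("negative SNP weights")
    G <- tcrossprod(sweep(Zc, 2L, sqrt(weights), "*")) * lam
  }
  attr(G, "lambda") <- lam
  G
}

#' Blend genomic and pedigree relationships
#'
#' \eqn{G_\omega = \omega G + (1-\omega) A_{22}}; the default
#' \eqn{\omega = 0.9} keeps the genomic information dominant while restoring
#' full rank and controlling bias relative to the pedigree base.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships among the same (ordered) animals.
#' @param g_share weight on G, in (0, 1].
#' @return dense symmetric matrix.
#' @export
blend_gw <- function(G, A22, g_share = 0.9) {
  if (!all(dim(G) == dim(A22))) stop("G and A22 are not conformable")
  stopifnot(g_share > 0, g_share <= 1)
  G * g_share + A22 * (1 - g_share)
}

#' Inverse of the single-step H relationship matrix
#'
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G_\omega^{-1} -
#'   A_{22}^{-1}\end{bmatrix},}
#' the pedigree inverse plus a correction on the genotyped block. With no
#' genotyped animals it degenerates to \eqn{A^{-1}} exactly.
#'
#' @param ainv sparse \eqn{A^{-1}} over the full pedigree.
#' @param a22 pedigree relationships among genotyped animals.
#' @param gw blended genomic matrix \eqn{G_\omega} (same ordering as
#'   \code{a22}).
#' @param ped the \code{\link{pedigree}} (supplies the genotyped indices).
#' @return sparse symmetric \code{\link[Matrix]{Matrix}} of order
#'   \code{n_animals(ped)}.
#' @export
h_inverse <- function(ainv, a22, gw, ped) {
  n <- length(ped$id)
  stopifnot(all(dim(ainv) == n))
  idx <- which(ped$genotyped)
  if (length(idx) == 0L) return(ainv)
  q <- length(idx)
  if (!all(dim(gw) == q) || !all(dim(a22) == q))
    stop("G_w / A22 dimension does not match the number of genotyped animals")
  gw_inv <- tryCatch(chol2inv(chol(gw)), error = function(e)
    stop("G_w is singular; blend with A22 (blend_gw) before inverting"))
  a22_inv <- chol2inv(chol(a22))
  corr <- gw_inv - a22_inv
  corrS <- Matrix::sparseMatrix(i = rep(idx, times = q),
                                j = rep(idx, each = q),
                                x = as.numeric(corr), dims = c(n, n))
  out <- ainv + corrS
  Matrix::forceSymmetric((out + Matrix::t(out)) / 2)
}
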