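#' Back-solve SNP effects from genomic breeding values
#'
#' Converts the breeding values of the genotyped animals into per-SNP
#' effects through the equivalence of marker-effect and breeding-value
#' models:
#' \deqn{\hat g = \lambda D Z' G^{-1} \hat a,}
#' where G is the (weighted, unblended) genomic relationship matrix built
#' from the same weights D and scaling \eqn{\lambda}. By construction
#' \eqn{Z \hat g = \hat a} exactly when G is full rank.
#'
#' @param gebv breeding values of the genotyped animals, in the row order of
#'   \code{geno}.
#' @param geno a \code{\link{genotype_matrix}} (no missing calls).
#' @param weights per-SNP weights (diagonal of D); \code{NULL} for D = I.
#' @param p allele frequencies used throughout the weighting loop.
#' @param ridge small diagonal added to G before solving; 0 (default)
#'   requires full-rank G, a documented \code{1e-8} helps when G is
#'   near-singular (more SNPs than animals is the usual full-rank case).
#' @return numeric vector of SNP effects (length m).
#' @export
backsolve_snp_effects <- function(gebv, geno, weights = NULL,
                                  p = allele_freq(geno), ridge = 0) {
  stopifnot(length(gebv) == nrow(geno$dosage))
  Zc <- centered_dosage(geno, p)
  lam <- lambda_scale(p)
  m <- ncol(Zc)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m)
  G <- tcrossprod(sweep(Zc, 2L, sqrt(weights), "*")) * lam
  if (ridge > 0) diag(G) <- diag(G) + ridge
  ginv_a <- tryCatch(solve(G, gebv), error = function(e)
    stop("weighted G is singular; consider the ridge argument ",
         "(e.g. ridge = 1e-8)"))
  lam * weights * drop(crossprod(Zc, ginv_a))
}

#' SNP weights from marker effects
#'
#' \eqn{d_i = \hat g_i^2 \, 2 p_i (1 - p_i)}: each SNP is weighted by the
#' additive variance its estimated effect explains at its allele frequency.
#'
#' @param ghat marker effects.
#' @param p allele frequencies.
#' @return raw (unnormalised) weights, all \eqn{\ge 0}.
#' @export
update_weights <- function(ghat, p) {
  stopifnot(length(ghat) == length(p))
  ghat^2 * 2 * p * (1 - p)
}

#' Normalise SNP weights to constant trace
#'
#' Rescales weights so that \eqn{tr(D) = m} (the trace of the initial
#' identity), keeping the total genetic variance of the weighted G constant
#' across iterations while preserving the proportions among SNPs.
#'
#' @param raw raw weights (non-negative, not all zero).
#' @return weights summing to \code{length(raw)}.
#' @export
normalize_weights <- function(raw) {
  if (any(raw < 0)) stop("negative weights")
  s <- sum(raw)
  if (s <= 0) stop("all SNP weights are zero (degenerate marker effects)")
  raw * length(raw) / s
}

#' Weighted single-step GWAS
#'
#' Fits the repeatability animal model by single-step GBLUP and runs the
#' iterative SNP-weighting procedure:
#' \enumerate{
#'   \item initialise \eqn{t = 1}, \eqn{D = I},
#'     \eqn{G_{(t)} = \lambda Z D Z'} with
#'     \eqn{\lambda = 1/\sum_i 2p_i(1-p_i)};
#'   \item estimate breeding values \eqn{\hat a} by ssGBLUP with
#'     \eqn{H^{-1} = A^{-1} + [0, 0; 0, (0.9 G_{(t)} + 0.1 A_{22})^{-1} -
#'     A_{22}^{-1}]};
#'   \item back-solve marker effects
#'     \eqn{\hat g_{(t)} = \lambda D Z' G_{(t)}^{-1} \hat a};
#'   \item update weights \eqn{d_i = \hat g_i^2 2 p_i (1 - p_i)};
#'   \item rescale the weights to trace m;
#'   \item rebuild the weighted G and iterate.
#' }
#' Variance components are estimated once by pedigree AI-REML (unless
#' supplied) and held fixed across iterations. After the final iteration
#' (default 3) the marker effects are mapped to fixed-width genomic windows
#' and the share of additive variance per window is computed, selected
#' (> \code{select_threshold} %), merged and the top regions extended.
#'
#' Without genotypes the fit degrades to pedigree BLUP (\eqn{H^{-1} =
#' A^{-1}}) and the marker/window stages are skipped with a warning.
#'
#' @param formula model formula for the records, e.g.
#'   \code{y ~ yearseason + age + intv}.
#' @param data data.frame of repeated records with an \code{id} column.
#' @param pedigree a \code{\link{pedigree}} covering every recorded animal.
#' @param genotypes post-QC, fully imputed \code{\link{genotype_matrix}} of
#'   the genotyped animals (rownames must appear in the pedigree), or
#'   \code{NULL}.
#' @param varcomp optional variance components (named vector or
#'   \code{\link{reml_ai}} fit); if \code{NULL} they are estimated by
#'   pedigree AI-REML first.
#' @param n_iter number of weighting iterations.
#' @param blend weight on G in \eqn{G_\omega}.
#' @param window_bp genomic window width in bp.
#' @param select_threshold window selection threshold, percent of
#'   \eqn{\sigma^2_a} (strict >).
#' @param ridge diagonal added to the unblended G before back-solving.
#'   With allele frequencies computed from the analysed animals the centred
#'   dosage columns sum to zero, so G is singular with null vector 1; the
#'   default \code{1e-8} ridge regularises exactly that direction, which the
#'   centred Z' then annihilates, leaving the marker effects equal to the
#'   minimum-norm solution. Set to 0 to require a full-rank G.
#' @param id animal-id column in \code{data}.
#' @param transform optional response transform applied before fitting:
#'   \code{"log"} for count-like traits, or \code{NULL}.
#' @param reml_args list of extra arguments for \code{\link{reml_ai}}.
#' @return object of class \code{"wssgwas"}; see
#'   \code{\link{summary.wssgwas}}, \code{\link{coef.wssgwas}},
#'   \code{\link{predict.wssgwas}}, \code{\link{plot.wssgwas}}.
#' @export
wssgwas <- function(formula, data, pedigree, genotypes = NULL,
                    varcomp = NULL, n_iter = 3L, blend = 0.9,
                    window_bp = 400000L, select_threshold = 1.0,
                    ridge = 1e-8, id = "id", transform = NULL,
                    reml_args = list()) {
  cl <- match.call()
  ped <- pedigree
  if (!is.null(transform)) {
    resp <- all.vars(formula[[2L]])
    if (transform == "log") data[[resp]] <- log(data[[resp]])
    else stop("unknown transform: ", transform)
  }
  ainv <- a_inverse(ped)
  if (is.null(varcomp)) {
    vc_fit <- do.call(reml_ai, c(list(formula = formula, data = data,
                                      kinv = ainv, id = id), reml_args))
  } else {
    vc_fit <- varcomp
  }
  vc <- as_varcomp(vc_fit)
  if (is.null(genotypes)) {
    warning("no genotypes supplied: fitting pedigree BLUP, ",
            "skipping marker back-solving and window analysis")
    sol <- solve_mme(build_mme(formula, data, ainv, vc, id = id))
    return(structure(list(varcomp = vc_fit, solutions = sol, gebv = sol$a,
                          marker_effects = NULL, windows = NULL,
                          regions = NULL, top = NULL, trace = NULL,
                          n_iter = 0L, blend = blend,
                          window_bp = window_bp,
                          select_threshold = select_threshold,
                          formula = formula, pedigree = ped, call = cl),
                     class = "wssgwas"))
  }
  gids <- rownames(genotypes$dosage)
  if (!all(gids %in% ped$id))
    stop("genotyped animals missing from the pedigree: ",
         paste(utils::head(setdiff(gids, ped$id), 5L), collapse = ", "))
  ped$genotyped <- ped$id %in% gids
  gorder <- ped$id[ped$genotyped]
  geno <- genotypes
  geno$dosage <- geno$dosage[match(gorder, gids), , drop = FALSE]
  p <- allele_freq(geno)
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop(sum(mono), " monomorphic SNP(s) present; run apply_qc() first")
  Zc <- centered_dosage(geno, p)
  lam <- lambda_scale(p)
  m <- ncol(Zc)
  A22m <- a22(ped)
  n_iter <- as.integer(n_iter)
  stopifnot(n_iter >= 1L)
  d <- rep(1, m)
  eff <- matrix(NA_real_, m, n_iter,
                dimnames = list(geno$map$snp, paste0("iter", seq_len(n_iter))))
  trace <- data.frame()
  prev_gebv <- NULL
  sol <- NULL
  for (t in seq_len(n_iter)) {
    Gt <- tcrossprod(sweep(Zc, 2L, sqrt(d), "*")) * lam
    Gw <- blend_gw(Gt, A22m, g_share = blend)
    hinv <- h_inverse(ainv, A22m, Gw, ped)
    sol <- solve_mme(build_mme(formula, data, hinv, vc, id = id))
    a_g <- sol$a[gorder]
    Gt_solve <- Gt
    if (ridge > 0) diag(Gt_solve) <- diag(Gt_solve) + ridge
    ghat <- lam * d * drop(crossprod(Zc, solve(Gt_solve, a_g)))
    eff[, t] <- ghat
    raw <- update_weights(ghat, p)
    d_next <- normalize_weights(raw)
    trace <- rbind(trace, data.frame(
      iter = t, trace_D = sum(d), min_w = min(d), max_w = max(d),
      gebv_cor = if (is.null(prev_gebv)) NA_real_
                 else stats::cor(a_g, prev_gebv)))
    prev_gebv <- a_g
    d <- d_next
  }
  ghat <- eff[, n_iter]
  weights_final <- normalize_weights(update_weights(ghat, p))
  me <- data.frame(snp = geno$map$snp, chr = geno$map$chr, bp = geno$map$bp,
                   freq = p, effect = ghat, weight = weights_final,
                   stringsAsFactors = FALSE)
  win <- make_windows(geno$map, size_bp = window_bp)
  wres <- window_variance(win, geno, ghat, vc[["var_a"]], p = p)
  wres <- select_windows(wres, threshold_pct = select_threshold)
  regions <- merge_windows(wres)
  top <- top_regions(wres, k = 3L, flank_bp = window_bp)
  structure(list(varcomp = vc_fit, solutions = sol,
                 gebv = sol$a, gebv_genotyped = sol$a[gorder],
                 marker_effects = me, effects_by_iter = eff,
                 weights = weights_final, lambda = lam,
                 windows = wres, regions = regions, top = top,
                 trace = trace, n_iter = n_iter, blend = blend,
                 window_bp = window_bp, select_threshold = select_threshold,
                 formula = formula, pedigree = ped, call = cl),
            class = "wssgwas")
}

#' @export
print.wssgwas <- function(x, ...) {
  cat("Weighted single-step GWAS fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  vc <- as_varcomp(x$varcomp)
  h <- heritability(vc)
  cat(sprintf("  variance components: var_a=%.5g var_pe=%.5g var_e=%.5g (h2=%.3f)\n",
              vc["var_a"], vc["var_pe"], vc["var_e"], h["h2"]))
  if (is.null(x$windows)) {
    cat("  pedigree BLUP only (no genotypes)\n")
  } else {
    cat(sprintf("  %d weighting iterations over %d SNPs, %d windows (%d selected > %.2g%%)\n",
                x$n_iter, nrow(x$marker_effects), nrow(x$windows),
                sum(x$windows$selected), x$select_threshold))
  }
  invisible(x)
}

#' Summarise a wssGWAS fit
#'
#' Reports heritability, the share of additive variance in the selected
#' windows, and the top QTL regions.
#'
#' @param object a \code{\link{wssgwas}} fit.
#' @param ... unused.
#' @return list of class \code{"summary.wssgwas"} with \code{varcomp},
#'   \code{heritability}, \code{n_windows}, \code{n_selected},
#'   \code{pct_selected_total}, \code{top} and \code{regions}.
#' @export
summary.wssgwas <- function(object, ...) {
  vc <- as_varcomp(object$varcomp)
  out <- list(varcomp = vc, heritability = heritability(vc),
              n_windows = if (is.null(object$windows)) 0L
                          else nrow(object$windows),
              n_selected = if (is.null(object$windows)) 0L
                           else sum(object$windows$selected),
              pct_selected_total = if (is.null(object$windows)) NA_real_
                else sum(object$windows$pct_var[object$windows$selected]),
              top = object$top, regions = object$regions,
              trace = object$trace)
  class(out) <- "summary.wssgwas"
  out
}

#' @export
print.summary.wssgwas <- function(x, ...) {
  cat("wssGWAS summary\n")
  print(round(rbind(estimate = x$varcomp), 6))
  cat(sprintf("h2 = %.5f, repeatability = %.5f\n",
              x$heritability["h2"], x$heritability["repeatability"]))
  if (x$n_windows > 0L) {
    cat(sprintf("%d/%d windows selected; selected windows explain %.2f%% of var_a\n",
                x$n_selected, x$n_windows, x$pct_selected_total))
    if (!is.null(x$top) && nrow(x$top) > 0L) {
      cat("top regions (midpoint +/- flank):\n")
      print(x$top, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Marker effects of a wssGWAS fit
#'
#' @param object a \code{\link{wssgwas}} fit.
#' @param iteration which weighting iteration (default: the final one).
#' @param ... unused.
#' @return data.frame with snp, chr, bp, frequency, effect and weight.
#' @export
coef.wssgwas <- function(object, iteration = object$n_iter, ...) {
  if (is.null(object$marker_effects)) return(NULL)
  me <- object$marker_effects
  if (iteration != object$n_iter)
    me$effect <- object$effects_by_iter[, iteration]
  me
}

#' Breeding values from a wssGWAS fit
#'
#' @param object a \code{\link{wssgwas}} fit.
#' @param ids optional animal ids (default: all pedigree animals).
#' @param ... unused.
#' @return named numeric vector of GEBVs.
#' @export
predict.wssgwas <- function(object, ids = NULL, ...) {
  g <- object$gebv
  if (is.null(ids)) return(g)
  if (!all(ids %in% names(g))) stop("unknown animal id(s)")
  g[ids]
}

#' @export
residuals.wssgwas <- function(object, ...) object$solutions$residuals

#' Window variance Manhattan plot
#'
#' Plots the share of additive variance per genomic window along the
#' genome, with the selection threshold as a horizontal line.
#'
#' @param x a \code{\link{wssgwas}} fit with window results.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.wssgwas <- function(x, ...) {
  w <- x$windows
  if (is.null(w)) stop("no window results (fit had no genotypes)")
  chr_len <- tapply(w$end, w$chr, max)
  offs <- c(0, cumsum(as.numeric(chr_len)))[seq_along(chr_len)]
  names(offs) <- names(chr_len)
  pos <- w$midpoint + offs[as.character(w$chr)]
  graphics::plot(pos / 1e6, w$pct_var,
                 col = ifelse(w$selected, "firebrick",
                              c("grey40", "grey65")[w$chr %% 2 + 1]),
                 pch = 16, cex = 0.6,
                 xlab = "genome position (Mb)",
                 ylab = "% of additive genetic variance", ...)
  graphics::abline(h = x$select_threshold, lty = 2)
  invisible(x)
}
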