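#' Partition a SNP map into fixed-width genomic windows
#'
#' Tiles every chromosome with non-overlapping windows of \code{size_bp}
#' (default 0.4 Mb, about the average haploblock length in commercial pig
#' lines), anchored at position 0. Coordinates are 0-based half-open
#' internally; a terminal window is truncated at the last mapped SNP, and
#' empty bins are dropped so every SNP belongs to exactly one window.
#'
#' @param snp_map data.frame with \code{chr} and \code{bp}, sorted by
#'   (chr, bp).
#' @param size_bp window width in base pairs.
#' @return object of class \code{"genome_windows"}: a data.frame
#'   (\code{chr}, \code{start}, \code{end}, \code{midpoint},
#'   \code{n_snps}) with the per-SNP window assignment attached as
#'   attribute \code{"snp_window"}.
#' @export
make_windows <- function(snp_map, size_bp = 400000L) {
  stopifnot(all(c("chr", "bp") %in% names(snp_map)))
  o <- order(snp_map$chr, snp_map$bp)
  if (any(o != seq_len(nrow(snp_map))))
    stop("snp_map must be sorted by (chr, bp)")
  bin <- floor(snp_map$bp / size_bp)
  key <- paste(snp_map$chr, bin, sep = ":")
  uk <- unique(key)                      # genome order (map is sorted)
  idx <- match(key, uk)
  chr <- snp_map$chr[!duplicated(key)]
  start <- bin[!duplicated(key)] * size_bp
  chrom_max <- tapply(snp_map$bp, snp_map$chr, max)
  end <- pmin(start + size_bp, chrom_max[as.character(chr)] + 1)
  df <- data.frame(window = seq_along(uk), chr = chr, start = start,
                   end = end, midpoint = (start + end) / 2,
                   n_snps = as.integer(table(idx)[as.character(seq_along(uk))]),
                   row.names = NULL)
  structure(df, snp_window = idx, size_bp = size_bp,
            class = c("genome_windows", "data.frame"))
}

#' Expected variance share of one window
#'
#' Under an even spread of genetic variance, each of K windows is expected
#' to explain 100/K percent; used as the reference point for the 1 percent
#' selection threshold.
#'
#' @param n_windows number of windows K.
#' @return percentage (e.g. 3707 windows -> 0.027).
#' @export
expected_window_share <- function(n_windows) {
  stopifnot(n_windows > 0)
  100 / n_windows
}

#' Percentage of additive variance explained per genomic window
#'
#' For each window the genetic score of every genotyped individual is the
#' sum of its centred dosages times the back-solved marker effects,
#' \eqn{a_w = \sum_{j \in w} z_j \hat g_j}; the window's share is
#' \deqn{100 \cdot Var(a_w) / \sigma^2_a,}
#' with the sample variance (n-1 denominator) taken across individuals.
#'
#' @param windows a \code{\link{make_windows}} result.
#' @param geno the \code{\link{genotype_matrix}} of the genotyped animals.
#' @param ghat marker effects from the final weighting iteration.
#' @param var_a additive genetic variance (REML estimate).
#' @param p allele frequencies used for centring.
#' @return data.frame of window results: window coordinates plus
#'   \code{pct_var}, \code{selected} (initialised \code{FALSE}) and
#'   \code{rank} (1 = largest share, ties broken by genome order).
#' @export
window_variance <- function(windows, geno, ghat, var_a,
                            p = allele_freq(geno)) {
  stopifnot(inherits(windows, "genome_windows"),
            length(ghat) == sum(windows$n_snps))
  if (var_a <= 0) stop("var_a must be positive")
  Zc <- centered_dosage(geno, p)
  idx <- attr(windows, "snp_window")
  pct <- vapply(seq_len(nrow(windows)), function(w) {
    j <- which(idx == w)
    aw <- Zc[, j, drop = FALSE] %*% ghat[j]
    100 * stats::var(as.numeric(aw)) / var_a
  }, numeric(1))
  out <- as.data.frame(windows)
  out$pct_var <- pct
  out$selected <- FALSE
  out$rank <- order(order(-pct, out$chr, out$start))
  attr(out, "snp_window") <- idx
  attr(out, "size_bp") <- attr(windows, "size_bp")
  class(out) <- c("window_result", "data.frame")
  out
}

#' Select candidate QTL windows
#'
#' Flags windows explaining strictly more than \code{threshold_pct} percent
#' of the additive variance.
#'
#' @param results a \code{\link{window_variance}} data.frame.
#' @param threshold_pct selection threshold (strict >).
#' @return the same data.frame with \code{selected} updated.
#' @export
select_windows <- function(results, threshold_pct = 1.0) {
  results$selected <- results$pct_var > threshold_pct
  results
}

#' Merge overlapping selected windows into QTL regions
#'
#' Within a chromosome, consecutive selected windows whose midpoints are
#' strictly less than \code{gap_bp} apart are chained into one region
#' spanning the minimum start to the maximum end; the region's percentage
#' is the sum of its windows' percentages (between-window covariances make
#' this a bookkeeping total, not a variance of the merged region).
#'
#' @param results a \code{\link{window_variance}} data.frame (the
#'   \code{selected} flags define the input set).
#' @param gap_bp midpoint-distance threshold (strict <); defaults to the
#'   window width.
#' @return data.frame of merged regions: \code{chr}, \code{start},
#'   \code{end}, \code{n_windows}, \code{n_snps}, \code{pct_var}.
#' @export
merge_windows <- function(results, gap_bp = attr(results, "size_bp")) {
  if (is.null(gap_bp)) gap_bp <- 400000L
  sel <- results[results$selected, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(chr = integer(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      n_snps = integer(0), pct_var = numeric(0)))
  sel <- sel[order(sel$chr, sel$start), , drop = FALSE]
  new_region <- c(TRUE, !(sel$chr[-1L] == sel$chr[-nrow(sel)] &
                            diff(sel$midpoint) < gap_bp))
  grp <- cumsum(new_region)
  do.call(rbind, lapply(split(sel, grp), function(g)
    data.frame(chr = g$chr[1L], start = min(g$start), end = max(g$end),
               n_windows = nrow(g), n_snps = sum(g$n_snps),
               pct_var = sum(g$pct_var))))
}

#' Top QTL regions extended by flanking distance
#'
#' Takes the \code{k} windows with the largest variance share and reports
#' the region from \code{flank_bp} upstream to \code{flank_bp} downstream
#' of each window midpoint (total span 2 x flank), clipped at position 0
#' and at the chromosome end. The window's own percentage is retained for
#' the extended region.
#'
#' @param results a \code{\link{window_variance}} data.frame.
#' @param k number of top windows.
#' @param flank_bp flanking distance on each side of the midpoint.
#' @return data.frame: \code{chr}, \code{midpoint}, \code{region_start},
#'   \code{region_end}, \code{n_snps}, \code{pct_var}.
#' @export
top_regions <- function(results, k = 3L, flank_bp = 400000L) {
  if (k <= 0L)
    return(data.frame(chr = integer(0), midpoint = numeric(0),
                      region_start = numeric(0), region_end = numeric(0),
                      n_snps = integer(0), pct_var = numeric(0)))
  if (k > nrow(results)) {
    warning("k exceeds the number of windows; returning all")
    k <- nrow(results)
  }
  chrom_end <- tapply(results$end, results$chr, max)
  topw <- results[order(results$rank), , drop = FALSE][seq_len(k), ]
  data.frame(chr = topw$chr,
             midpoint = topw$midpoint,
             region_start = pmax(0, topw$midpoint - flank_bp),
             region_end = pmin(chrom_end[as.character(topw$chr)],
                               topw$midpoint + flank_bp),
             n_snps = topw$n_snps,
             pct_var = topw$pct_var,
             row.names = NULL)
}

#' Write window results as TSV / BED
#'
#' Human-readable reports use 1-based inclusive coordinates; the BED file
#' keeps the 0-based half-open convention.
#'
#' @param results a \code{\link{window_variance}} data.frame.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_window_tsv <- function(results, file) {
  out <- as.data.frame(results)
  out$start <- out$start + 1          # 1-based inclusive for reports
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_window_tsv
#' @export
write_selected_bed <- function(results, file) {
  sel <- results[results$selected, , drop = FALSE]
  utils::write.table(data.frame(sel$chr, format(sel$start, scientific = FALSE,
                                                trim = TRUE),
                                format(sel$end, scientific = FALSE,
                                       trim = TRUE),
                                sprintf("pct=%.4f", sel$pct_var)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
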