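#' Run the full wssGWAS pipeline and write its artifacts
#'
#' Orchestrates simulate/ingest -> QC -> imputation -> pedigree AI-REML ->
#' iterative weighting -> window analysis, writing every stage's output
#' under \code{out_dir}: the QC report, variance components, breeding
#' values, per-iteration marker effects, window/region tables and a run
#' manifest (seed, parameters) sufficient to reproduce the run.
#'
#' @param config list with either \code{sim} (a \code{\link{sim_config}})
#'   or input paths \code{plink_prefix}, \code{pedigree_csv},
#'   \code{phenotype_csv}; plus optional \code{trait} (response column,
#'   default \code{"y"}), \code{formula}, \code{qc}
#'   (a \code{\link{qc_config}}), \code{n_iter}, \code{blend},
#'   \code{window_bp}, \code{select_threshold}, \code{transform} and
#'   \code{seed}.
#' @param out_dir output directory (created).
#' @return list of class \code{"wssgwas_run"}: the \code{\link{wssgwas}}
#'   fit, the QC report, file paths and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("wssgwas_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) config$seed else 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_dataset(config$sim))
    ped <- sim$pedigree
    geno <- sim$genotypes
    phen <- sim$phenotypes
  } else {
    ped <- stage("input", read_pedigree(config$pedigree_csv))
    geno <- stage("input", read_plink(config$plink_prefix))
    phen <- stage("input", utils::read.csv(config$phenotype_csv,
                                           stringsAsFactors = FALSE))
    phen$yearseason <- factor(phen$yearseason)
    sim <- NULL
  }
  trait <- if (!is.null(config$trait)) config$trait else "y"
  formula <- if (!is.null(config$formula)) config$formula
             else stats::as.formula(paste(trait, "~ yearseason + age + intv"))
  qc_cfg <- if (!is.null(config$qc)) config$qc else qc_config()
  report <- NULL
  if (!is.null(geno)) {
    qcres <- stage("qc", apply_qc(geno, qc_cfg))
    geno <- stage("impute", impute_missing(qcres$genotypes, seed = seed))
    report <- qcres$report
    utils::write.table(data.frame(metric = names(unclass(report)),
                                  value = unlist(unclass(report))),
                       file.path(out_dir, "qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  fit <- stage("wssgwas", wssgwas(
    formula, phen, ped, genotypes = geno,
    n_iter = if (!is.null(config$n_iter)) config$n_iter else 3L,
    blend = if (!is.null(config$blend)) config$blend else 0.9,
    window_bp = if (!is.null(config$window_bp)) config$window_bp
                else 400000L,
    select_threshold = if (!is.null(config$select_threshold))
      config$select_threshold else 1.0,
    transform = config$transform))
  vc <- as_varcomp(fit$varcomp)
  utils::write.table(data.frame(component = names(vc), estimate = vc),
                     file.path(out_dir, "varcomp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = names(fit$gebv), gebv = fit$gebv),
                     file.path(out_dir, "gebv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fit$marker_effects)) {
    for (t in seq_len(fit$n_iter)) {
      me <- fit$marker_effects
      me$effect <- fit$effects_by_iter[, t]
      utils::write.table(me, file.path(out_dir,
                                       sprintf("marker_effects_iter%d.tsv", t)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_window_tsv(fit$windows, file.path(out_dir, "windows.tsv"))
    utils::write.table(fit$regions, file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$top, file.path(out_dir, "top_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_selected_bed(fit$windows, file.path(out_dir, "selected.bed"))
  }
  manifest <- list(seed = seed, trait = trait,
                   formula = deparse(formula),
                   n_iter = fit$n_iter, blend = fit$blend,
                   window_bp = fit$window_bp,
                   select_threshold = fit$select_threshold,
                   n_records = nrow(phen),
                   n_animals = length(ped$id),
                   n_genotyped = if (is.null(geno)) 0L
                                 else nrow(geno$dosage),
                   n_snps = if (is.null(geno)) 0L else ncol(geno$dosage),
                   package_version = as.character(
                     utils::packageVersion("wssgwas")))
  writeLines(paste(names(manifest), vapply(manifest, paste, ""),
                   sep = "\t"),
             file.path(out_dir, "manifest.tsv"))
  structure(list(fit = fit, qc_report = report, out_dir = out_dir,
                 manifest = manifest, sim = sim),
            class = "wssgwas_run")
}

#' @export
print.wssgwas_run <- function(x, ...) {
  cat("wssGWAS pipeline run ->", x$out_dir, "\n")
  print(x$fit)
  invisible(x)
}

#' One-page report of a pipeline run
#'
#' @param run a \code{\link{run_pipeline}} result.
#' @return list with heritability, top-region percentages and the total
#'   percentage in selected windows; printed as a short text report.
#' @export
summarize <- function(run) {
  stopifnot(inherits(run, "wssgwas_run"))
  s <- summary(run$fit)
  rep_ <- list(heritability = unname(s$heritability["h2"]),
               repeatability = unname(s$heritability["repeatability"]),
               n_windows = s$n_windows,
               n_selected = s$n_selected,
               pct_selected_total = s$pct_selected_total,
               top_pct = if (!is.null(s$top)) s$top$pct_var else numeric(0))
  class(rep_) <- "wssgwas_report"
  rep_
}

#' @export
print.wssgwas_report <- function(x, ...) {
  cat(sprintf("h2 = %.4f (repeatability %.4f)\n", x$heritability,
              x$repeatability))
  if (x$n_windows > 0L) {
    cat(sprintf("windows: %d total, %d selected, %.2f%% of var_a in selected\n",
                x$n_windows, x$n_selected, x$pct_selected_total))
    cat("top-3 window shares (%):",
        paste(sprintf("%.2f", x$top_pct), collapse = ", "), "\n")
  }
  invisible(x)
}
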