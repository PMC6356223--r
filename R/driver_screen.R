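# The main fitting interface: one call from a cohort bundle to candidate
# driver genes, returning a classed object holding every stage output.

#' Screen a tumor cohort for candidate driver genes
#'
#' Runs the integrative procedure end to end: probe filtering
#' ([filter_probes()]), per-gene copy-number status
#' ([aggregate_gene_status()]), representative-probe selection and
#' concordant alteration calling ([call_alterations()]), pathway flags and
#' universal-pathway selection ([select_universal_pathways()]), gene and
#' pathway subgroup enrichment (Fisher exact), and the two-condition
#' candidate-driver call ([select_candidate_drivers()]).
#'
#' @param bundle a [cohort_bundle()].
#' @param gain_cut,loss_cut log-ratio cuts, used only when the CNV table is
#'   numeric.
#' @param sex_chroms chromosomes excluded as sexual.
#' @param tie_rule probe-aggregation tie rule (see
#'   [aggregate_gene_status()]).
#' @param min_controls minimum copy-normal control-group size for the
#'   expression quartiles (default 30).
#' @param boundary quartile comparison, `"strict"` or `"inclusive"`.
#' @param fraction minimum fraction of samples for universal-pathway
#'   selection (default 1.0).
#' @param subgroup clinical column defining the enrichment subgroup.
#' @param alpha significance level for the driver call.
#' @param use_adjusted select candidates on BH-adjusted p.
#' @param with_chi2 also report chi-squared p values in the enrichment
#'   tables.
#' @return An object of class `driver_screen` with components `status`,
#'   `rep_expr`, `control_stats`, `alterations`, `load`, `catalog`
#'   (restricted), `pathway_flags`, `universal_pathways`, `pool`,
#'   `gene_enrichment`, `pathway_enrichment`, `candidates`, `params`,
#'   `bundle`.
#' @seealso [mfs_analysis()] for survival follow-up on a candidate;
#'   [run_pipeline()] for the file-based orchestration.
#' @export
driver_screen <- function(bundle, gain_cut = 0.2, loss_cut = -0.2,
                          sex_chroms = c("chrX", "chrY"),
                          tie_rule = "majority",
                          min_controls = 30L,
                          boundary = "strict",
                          fraction = 1.0,
                          subgroup = "metastasis",
                          alpha = 0.05,
                          use_adjusted = FALSE,
                          with_chi2 = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  cnv <- bundle$cnv
  if (cnv$type == "logratio")
    cnv <- threshold_logratio_probes(cnv, gain_cut, loss_cut)
  filtered <- filter_probes(cnv, constitutional = bundle$constitutional,
                            sex_chroms = sex_chroms)
  status <- aggregate_gene_status(filtered, tie_rule = tie_rule)
  rep_expr <- select_representative_probes(bundle$expr)
  control_stats <- compute_control_stats(rep_expr, status,
                                         min_controls = min_controls)
  alterations <- call_alterations(status, rep_expr, control_stats,
                                  boundary = boundary)
  load <- alteration_load(alterations)
  catalog <- restrict_catalog(bundle$pathways, alterations)
  pathway_flags <- flag_pathways(catalog, alterations)
  universal <- select_universal_pathways(pathway_flags, fraction = fraction)
  pool <- genes_in_universal_pathways(universal, catalog, alterations)
  gene_enrichment <- gene_subgroup_enrichment(alterations, bundle$clinical,
                                              pool = pool, subgroup = subgroup,
                                              with_chi2 = with_chi2)
  pathway_enrichment <- pathway_subgroup_enrichment(pathway_flags,
                                                    bundle$clinical,
                                                    subgroup = subgroup,
                                                    with_chi2 = with_chi2)
  candidates <- select_candidate_drivers(gene_enrichment, pathway_enrichment,
                                         catalog, alpha = alpha,
                                         use_adjusted = use_adjusted)
  structure(list(status = status, rep_expr = rep_expr,
                 control_stats = control_stats, alterations = alterations,
                 load = load, catalog = catalog,
                 pathway_flags = pathway_flags,
                 universal_pathways = universal, pool = pool,
                 gene_enrichment = gene_enrichment,
                 pathway_enrichment = pathway_enrichment,
                 candidates = candidates,
                 removal_counts = attr(filtered, "removal_counts"),
                 params = list(gain_cut = gain_cut, loss_cut = loss_cut,
                               sex_chroms = sex_chroms, tie_rule = tie_rule,
                               min_controls = min_controls,
                               boundary = boundary, fraction = fraction,
                               subgroup = subgroup, alpha = alpha,
                               use_adjusted = use_adjusted,
                               quantile_convention = "linear interpolation at p*(n-1) (type 7)"),
                 bundle = bundle),
            class = "driver_screen")
}

#' @export
print.driver_screen <- function(x, ...) {
  cat("Integrative CNV-expression driver screen\n")
  cat("  samples:", ncol(x$status),
      "| genes with status:", nrow(x$status),
      "| evaluable genes:", sum(x$control_stats$defined), "\n")
  cat("  probe removals:",
      paste(names(x$removal_counts), x$removal_counts, collapse = ", "), "\n")
  cat(sprintf("  mean alteration load: %.1f genes/sample (%.0f%% gains / %.0f%% losses)\n",
              x$load$mean_load, 100 * x$load$gain_fraction,
              100 * x$load$loss_fraction))
  cat("  pathways:", length(x$catalog$sets), "analyzable,",
      length(x$universal_pathways), "altered in every tumor\n")
  cat("  candidate pool:", length(x$pool), "genes |",
      sum(x$gene_enrichment$p_fisher < x$params$alpha &
            x$gene_enrichment$direction == "enriched_in_subgroup"),
      "enriched in subgroup '", x$params$subgroup, "' |",
      nrow(x$candidates), "candidate driver(s)\n")
  if (nrow(x$candidates))
    cat("  top candidate:", x$candidates$gene_id[1L],
        sprintf("(p = %.2e)", x$candidates$p_fisher[1L]), "\n")
  invisible(x)
}

#' @export
summary.driver_screen <- function(object, n = 10L, ...) {
  out <- list(screen = object,
              top_candidates = utils::head(object$candidates, n),
              top_genes = utils::head(object$gene_enrichment, n),
              enriched_set = object$gene_enrichment$unit_id[
                object$gene_enrichment$direction == "enriched_in_subgroup" &
                  object$gene_enrichment$p_fisher < object$params$alpha],
              depleted_set = object$gene_enrichment$unit_id[
                object$gene_enrichment$direction == "depleted_in_subgroup" &
                  object$gene_enrichment$p_fisher < object$params$alpha])
  class(out) <- "summary.driver_screen"
  out
}

#' @export
print.summary.driver_screen <- function(x, ...) {
  print(x$screen)
  cat("\nGenes enriched in subgroup:", length(x$enriched_set),
      "| associated with the complement:", length(x$depleted_set),
      "| union:", length(x$enriched_set) + length(x$depleted_set), "\n")
  if (nrow(x$top_candidates)) {
    cat("\nTop candidate drivers:\n")
    print(x$top_candidates, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a driver screen
#'
#' With `gene` given, draws the kernel density curves of that gene's
#' expression in copy-deleted vs copy-normal tumors with the
#' density-intersection threshold. Otherwise draws the signed alteration
#' frequency (gains up, losses down) of the enriched genes.
#'
#' @param x a `driver_screen`.
#' @param gene optional gene id.
#' @param ... passed on to plotting primitives.
#' @export
plot.driver_screen <- function(x, gene = NULL, ...) {
  if (!is.null(gene)) {
    st <- x$status[gene, ]
    e <- x$rep_expr$values[gene, names(st)]
    thr <- density_intersection_threshold(e[st == "lost"], e[st == "normal"])
    graphics::plot(thr$grid$x, thr$grid$f_a, type = "l", col = "firebrick",
                   lwd = 2, xlab = "log2 expression", ylab = "density",
                   main = paste0(gene, ": deleted vs copy-normal"), ...)
    graphics::lines(thr$grid$x, thr$grid$f_b, col = "navy", lwd = 2)
    graphics::abline(v = thr$threshold, lty = 2)
    graphics::legend("topleft", c("deleted", "copy-normal",
                                  sprintf("threshold = %.2f", thr$threshold)),
                     col = c("firebrick", "navy", "black"),
                     lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
    return(invisible(thr))
  }
  ge <- x$gene_enrichment
  sig <- ge[ge$p_fisher < x$params$alpha, , drop = FALSE]
  if (!nrow(sig)) {
    message("nothing significant to plot")
    return(invisible(x))
  }
  freq <- (sig$a + sig$b) / (sig$a + sig$b + sig$c + sig$d)
  signed <- ifelse(sig$alteration_type == "loss", -freq, freq)
  graphics::barplot(signed, names.arg = sig$unit_id, las = 2,
                    col = ifelse(signed < 0, "steelblue", "tomato"),
                    ylab = "alteration frequency (gain +, loss -)",
                    cex.names = 0.6, ...)
  invisible(x)
}
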