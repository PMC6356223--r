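# File-based orchestration: one config drives load/simulate -> screen ->
# survival -> report, with a manifest that makes reruns verifiable.

#' Default pipeline configuration
#'
#' A plain named list, serializable to YAML. `inputs` holds the file paths
#' (ignored under `simulate = TRUE`), `simulation` any [sim_config()]
#' overrides, `screen` the [driver_screen()] settings, and `survival` the
#' [mfs_analysis()] settings (`gene` defaults to the planted driver for
#' simulated cohorts, else the top candidate).
#'
#' @param ... replacements for any top-level entry.
#' @return list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(seed = 1L,
              inputs = list(cnv = NULL, expression = NULL, clinical = NULL,
                            pathways = NULL, controls = NULL,
                            constitutional = NULL, one_based = FALSE),
              simulation = list(),
              screen = list(gain_cut = 0.2, loss_cut = -0.2,
                            min_controls = 30L, boundary = "strict",
                            tie_rule = "majority", fraction = 1.0,
                            subgroup = "metastasis", alpha = 0.05,
                            use_adjusted = FALSE),
              survival = list(gene = NULL, method = "density_intersection",
                              subset = "all",
                              exclude_metastatic_at_diagnosis = TRUE))
  dots <- list(...)
  for (k in names(dots)) {
    if (is.list(cfg[[k]]) && is.list(dots[[k]]))
      cfg[[k]][names(dots[[k]])] <- dots[[k]]
    else cfg[[k]] <- dots[[k]]
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with any subset of the [default_config()] keys.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}

#' Write the report tables and run manifest for a screen
#'
#' Emits TSVs for every stage (gene status, alterations, pathway flags,
#' universal pathways, enrichment tables, candidates, alteration load),
#' optional survival tables, and a YAML manifest holding the config
#' snapshot, seed, per-stage counts, the quantile convention, package
#' version and md5 digests of every written table. With `results = NULL`
#' only the manifest is written.
#'
#' @param results a `driver_screen` or NULL.
#' @param out_dir output directory (created; must be writable).
#' @param mfs optional `mfs_fit` to include.
#' @param config optional config snapshot for the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_report <- function(results, out_dir, mfs = NULL, config = NULL,
                         seed = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop2("cannot create output directory ", out_dir)
  paths <- character()
  counts <- list()
  if (!is.null(results)) {
    stopifnot(inherits(results, "driver_screen"))
    p <- function(f) file.path(out_dir, f)
    paths <- c(paths,
      matrix_tsv(results$status, p("gene_status.tsv"), "gene_id"),
      matrix_tsv(results$alterations, p("alterations.tsv"), "gene_id"),
      matrix_tsv(1L * results$pathway_flags, p("pathway_flags.tsv"),
                 "pathway_id"),
      write_tsv(results$control_stats, p("control_stats.tsv")),
      write_tsv(data.frame(pathway_id = results$universal_pathways),
                p("universal_pathways.tsv")),
      write_tsv(results$gene_enrichment, p("gene_enrichment.tsv")),
      write_tsv(results$pathway_enrichment, p("pathway_enrichment.tsv")),
      write_tsv(as.data.frame(results$candidates), p("candidates.tsv")),
      write_tsv(data.frame(sample_id = names(results$load$per_sample),
                           n_altered = as.integer(results$load$per_sample)),
                p("alteration_load.tsv")))
    counts <- list(probes_kept = nrow(results$bundle$cnv$probes) -
                     sum(results$removal_counts),
                   probe_removals = as.list(results$removal_counts),
                   genes_with_status = nrow(results$status),
                   evaluable_genes = sum(results$control_stats$defined),
                   mean_alteration_load = round(results$load$mean_load, 2),
                   gain_fraction = round(results$load$gain_fraction, 4),
                   pathways_analyzable = length(results$catalog$sets),
                   universal_pathways = length(results$universal_pathways),
                   pool_genes = length(results$pool),
                   candidates = nrow(results$candidates))
  }
  if (!is.null(mfs)) {
    cv <- do.call(rbind, lapply(names(mfs$curves), function(g)
      cbind(group = g, mfs$curves[[g]])))
    paths <- c(paths,
      write_tsv(cv, file.path(out_dir, "km_curves.tsv")),
      write_tsv(data.frame(gene_id = mfs$gene_id, method = mfs$method,
                           threshold = mfs$threshold, subset = mfs$subset,
                           n = mfs$n,
                           n_low = as.integer(mfs$group_sizes["low"]),
                           n_high = as.integer(mfs$group_sizes["high"]),
                           logrank_chisq = mfs$logrank$statistic,
                           logrank_p = mfs$logrank$p,
                           hr_low_vs_high = mfs$logrank$hazard_ratio,
                           hr_ci_low = mfs$logrank$ci[1L],
                           hr_ci_high = mfs$logrank$ci[2L]),
                file.path(out_dir, "survival_summary.tsv")))
  }
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tf <- tempfile()
    yaml::write_yaml(unclass(config), tf)
    cfg_hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  manifest <- list(
    package = "cnvdrive",
    version = as.character(utils::packageVersion("cnvdrive")),
    seed = seed,
    config = if (!is.null(config)) unclass(config),
    config_md5 = cfg_hash,
    quantile_convention = "linear interpolation at p*(n-1) (stats::quantile type 7)",
    low_stratum_rule = "strict '<' at the threshold",
    counts = counts,
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      basename(paths))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the full analysis from one configuration
#'
#' Stages, in order: load (or simulate) the cohort; probe filtering; gene
#' status; expression integration; pathway flags and universal-pathway
#' selection; gene/pathway enrichment; candidate drivers; expression
#' dichotomization and metastasis-free-survival comparison for the survival
#' gene; report + manifest. A failure aborts with the stage name.
#'
#' @param config a [default_config()]-shaped list or a YAML path.
#' @param out_dir report directory; NULL skips all file output.
#' @param simulate generate the cohort with [simulate_cohort()] instead of
#'   reading the `inputs` paths.
#' @return Invisibly, a list with `screen` (a `driver_screen`), `mfs` (an
#'   `mfs_fit` or NULL), `bundle`, `truth` (simulated runs only) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         simulate = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  truth <- NULL
  if (simulate) {
    bundle <- stage("simulate", {
      sc <- do.call(sim_config, c(list(seed = config$seed),
                                  config$simulation))
      sim <- simulate_cohort(sc)
      truth <- sim$truth
      sim$bundle
    })
  } else {
    ins <- config$inputs
    for (k in c("cnv", "expression", "clinical", "pathways"))
      if (is.null(ins[[k]]))
        stop2("config field inputs$", k, " is required without simulate")
    bundle <- stage("load", load_cohort(
      ins$cnv, ins$expression, ins$clinical, ins$pathways,
      controls_path = ins$controls,
      constitutional_path = ins$constitutional,
      one_based = isTRUE(ins$one_based)))
  }
  screen <- stage("screen", do.call(driver_screen,
                                    c(list(bundle = bundle), config$screen)))
  sv <- config$survival
  gene <- sv$gene %||%
    (if (!is.null(truth)) truth$driver_gene
     else if (nrow(screen$candidates)) screen$candidates$gene_id[1L])
  mfs <- NULL
  if (!is.null(gene))
    mfs <- stage("survival", tryCatch(
      mfs_analysis(screen, gene, method = sv$method %||% "density_intersection",
                   subset = sv$subset %||% "all",
                   threshold = sv$threshold,
                   exclude_metastatic_at_diagnosis =
                     !isFALSE(sv$exclude_metastatic_at_diagnosis)),
      warning = function(w) {
        suppressWarnings(
          mfs_analysis(screen, gene, method = sv$method %||% "density_intersection",
                       subset = sv$subset %||% "all", threshold = sv$threshold,
                       exclude_metastatic_at_diagnosis =
                         !isFALSE(sv$exclude_metastatic_at_diagnosis)))
      }))
  manifest <- NULL
  if (!is.null(out_dir))
    manifest <- stage("report", write_report(screen, out_dir, mfs = mfs,
                                             config = config,
                                             seed = config$seed))
  invisible(list(screen = screen, mfs = mfs, bundle = bundle, truth = truth,
                 manifest = manifest))
}
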