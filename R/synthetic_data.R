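# Synthetic tumor cohorts with planted truth: copy-number states at probe
# level, concordant expression, pathway catalog and censored
# metastasis-free survival, so every pipeline stage can be verified by
# parameter recovery.

#' Simulation configuration
#'
#' Defaults emulate the published cohort this pipeline targets: 106 tumors
#' of which 32 metastatic, ~12,100 genes with an expected 2,960
#' copy-altered genes per sample split 53% gains / 47% losses, a driver
#' gene deleted in 62.5% of metastatic vs 34% of non-metastatic tumors with
#' concordant expression loss, five normal-DNA controls, and censored
#' metastasis-free survival whose hazard is multiplied for driver-low
#' patients.
#'
#' Two survival modes. `"retrospective"` fixes the metastatic subgroup size
#' and plants the conditional driver-loss frequencies, drawing event times
#' for metastatic patients with the driver-low hazard multiplier (the shape
#' of a retrospective cohort study). `"generative"` simulates the hazard
#' model forward — T ~ Exp(h0 * HR^driver_low), uniform censoring,
#' metastasis := event — so the planted hazard ratio is exactly the data's
#' hazard ratio; driver loss then uses `driver_loss_freq` marginally.
#'
#' @param seed integer seed driving all randomness through one stream.
#' @param n_samples,n_metastatic cohort size and metastatic subgroup size.
#' @param n_genes,n_probes_per_gene gene count and per-gene CNV probe count
#'   range.
#' @param n_pathways,pathway_size catalog size and pathway size range.
#' @param passenger_alteration_rate per gene-sample probability of a
#'   passenger copy-number alteration (default 2960 / 12124).
#' @param gain_fraction fraction of passenger alterations that are gains.
#' @param driver_gene planted driver gene id.
#' @param driver_loss_freq_metastatic,driver_loss_freq_nonmetastatic
#'   conditional deletion frequencies (retrospective mode).
#' @param driver_loss_freq marginal deletion frequency (generative mode).
#' @param driver_pathway_size size of the planted driver pathway.
#' @param driver_pathway_rate_factor multiplier shrinking the passenger rate
#'   of the planted pathway's companion genes, keeping the pathway's flag
#'   informative about the driver.
#' @param go_coverage fraction of genes listed in the pathway catalog.
#' @param expr_coverage fraction of genes present on the expression array.
#' @param baseline_mean,baseline_sd gene-level log2 expression baseline.
#' @param loss_shift,gain_shift expression shift added under copy loss /
#'   gain (log2 units).
#' @param noise_sd per-cell expression noise SD.
#' @param probe_noise_rate probability a CNV probe state flips away from its
#'   gene's state.
#' @param baseline_hazard exponential event hazard per month.
#' @param hazard_ratio_driver_low hazard multiplier when the driver is
#'   lost-and-low.
#' @param followup_range censoring window (months, uniform).
#' @param n_controls number of normal-DNA control samples.
#' @param chemo_fraction,chemo_na_fraction chemotherapy prevalence and
#'   unknown-status fraction.
#' @param met_at_dx_fraction fraction of metastatic patients metastatic at
#'   diagnosis.
#' @param n_decoy_probes decoy probes per exclusion rule (constitutional,
#'   sex chromosome, intergenic).
#' @param mode `"retrospective"` or `"generative"` (see above).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 106L, n_metastatic = 32L,
                       n_genes = 12124L, n_probes_per_gene = c(2L, 4L),
                       n_pathways = 200L, pathway_size = c(5L, 60L),
                       passenger_alteration_rate = 2960 / 12124,
                       gain_fraction = 0.53,
                       driver_gene = "RCBTB1",
                       driver_loss_freq_metastatic = 0.625,
                       driver_loss_freq_nonmetastatic = 0.34,
                       driver_loss_freq = 0.42,
                       driver_pathway_size = 5L,
                       driver_pathway_rate_factor = 0.1,
                       go_coverage = 0.70,
                       expr_coverage = 0.94,
                       baseline_mean = 8, baseline_sd = 1,
                       loss_shift = -1.5, gain_shift = 1,
                       noise_sd = 0.5,
                       probe_noise_rate = 0.02,
                       baseline_hazard = 0.01,
                       hazard_ratio_driver_low = 2.5,
                       followup_range = c(24, 120),
                       n_controls = 5L,
                       chemo_fraction = 0.5,
                       chemo_na_fraction = 0,
                       met_at_dx_fraction = 0.05,
                       n_decoy_probes = 100L,
                       mode = c("retrospective", "generative")) {
  cfg <- list(seed = assert_count(seed, "seed"),
              n_samples = assert_count(n_samples, "n_samples", 2L),
              n_metastatic = assert_count(n_metastatic, "n_metastatic", 1L),
              n_genes = assert_count(n_genes, "n_genes", 2L),
              n_probes_per_gene = as.integer(n_probes_per_gene),
              n_pathways = assert_count(n_pathways, "n_pathways", 2L),
              pathway_size = as.integer(pathway_size),
              passenger_alteration_rate =
                assert_prob(passenger_alteration_rate, "passenger_alteration_rate"),
              gain_fraction = assert_prob(gain_fraction, "gain_fraction"),
              driver_gene = as.character(driver_gene),
              driver_loss_freq_metastatic =
                assert_prob(driver_loss_freq_metastatic, "driver_loss_freq_metastatic"),
              driver_loss_freq_nonmetastatic =
                assert_prob(driver_loss_freq_nonmetastatic, "driver_loss_freq_nonmetastatic"),
              driver_loss_freq = assert_prob(driver_loss_freq, "driver_loss_freq"),
              driver_pathway_size =
                assert_count(driver_pathway_size, "driver_pathway_size", 1L),
              driver_pathway_rate_factor =
                assert_prob(driver_pathway_rate_factor, "driver_pathway_rate_factor"),
              go_coverage = assert_prob(go_coverage, "go_coverage"),
              expr_coverage = assert_prob(expr_coverage, "expr_coverage"),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              loss_shift = loss_shift, gain_shift = gain_shift,
              noise_sd = noise_sd,
              probe_noise_rate = assert_prob(probe_noise_rate, "probe_noise_rate"),
              baseline_hazard = baseline_hazard,
              hazard_ratio_driver_low = hazard_ratio_driver_low,
              followup_range = as.numeric(followup_range),
              n_controls = assert_count(n_controls, "n_controls"),
              chemo_fraction = assert_prob(chemo_fraction, "chemo_fraction"),
              chemo_na_fraction = assert_prob(chemo_na_fraction, "chemo_na_fraction"),
              met_at_dx_fraction = assert_prob(met_at_dx_fraction, "met_at_dx_fraction"),
              n_decoy_probes = assert_count(n_decoy_probes, "n_decoy_probes"),
              mode = match.arg(mode))
  if (cfg$n_metastatic > cfg$n_samples)
    stop2("n_metastatic must not exceed n_samples")
  if (length(cfg$n_probes_per_gene) != 2L ||
      cfg$n_probes_per_gene[1L] > cfg$n_probes_per_gene[2L] ||
      cfg$n_probes_per_gene[1L] < 1L)
    stop2("n_probes_per_gene must be an increasing range of positive integers")
  if (length(cfg$pathway_size) != 2L ||
      cfg$pathway_size[1L] > cfg$pathway_size[2L])
    stop2("pathway_size must be an increasing range")
  if (cfg$pathway_size[2L] > cfg$n_genes || cfg$driver_pathway_size > cfg$n_genes)
    stop2("pathways cannot be larger than the gene count")
  if (cfg$hazard_ratio_driver_low <= 0) stop2("hazard ratio must be > 0")
  if (cfg$baseline_hazard <= 0) stop2("baseline hazard must be > 0")
  if (loss_shift >= 0) stop2("loss_shift must be negative")
  if (gain_shift <= 0) stop2("gain_shift must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# sample integers uniformly from lo..hi (safe when lo == hi)
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(lo, n) else sample(seq(lo, hi), n, replace = TRUE)
}

# flip a fraction of probe states to a random *different* state
flip_states <- function(states, rate) {
  if (rate <= 0) return(states)
  idx <- which(stats::runif(length(states)) < rate)
  if (!length(idx)) return(states)
  pool <- c("loss", "normal", "gain")
  cur <- match(states[idx], pool)
  shift <- sample(1:2, length(idx), replace = TRUE)
  states[idx] <- pool[1L + (cur - 1L + shift) %% 3L]
  states
}

#' Simulate a tumor cohort with planted truth
#'
#' Generates the four cohort tables in the package's input dialects plus a
#' truth record. Probe states derive from per-gene states with per-probe
#' flip noise; expression is baseline + status shift + noise;
#' metastasis-free survival is exponential with the hazard multiplied for
#' driver lost-and-low patients, right-censored. Decoy probes exercise each
#' probe-exclusion rule, and the constitutional regions covering the
#' corresponding decoys are emitted alongside. Fully deterministic given
#' the seed.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all input files plus
#'   `truth.tsv` are written there.
#' @return list of class `synthetic_cohort` with elements `bundle` (a
#'   `cohort_bundle`), `truth` (planted driver, pathways, per-sample driver
#'   status, labels, config echo) and, if written, `paths`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  controls <- if (config$n_controls > 0) sprintf("CTRL%02d", seq_len(config$n_controls))
              else character()

  ## gene universe; gene 1 is the driver
  genes <- c(config$driver_gene,
             sprintf("G%05d", seq_len(config$n_genes - 1L)))

  ## metastasis labels and driver deletion
  if (config$mode == "retrospective") {
    metastatic <- rep(FALSE, n)
    metastatic[sample.int(n, config$n_metastatic)] <- TRUE
    p_loss <- ifelse(metastatic, config$driver_loss_freq_metastatic,
                     config$driver_loss_freq_nonmetastatic)
  } else {
    metastatic <- NULL # derived from the survival process below
    p_loss <- rep(config$driver_loss_freq, n)
  }
  driver_lost <- stats::runif(n) < p_loss

  ## per-gene passenger alteration rates; companions of the planted driver
  ## pathway are kept quiet so the pathway flag tracks the driver
  companions <- if (config$driver_pathway_size > 1L)
    genes[1L + seq_len(config$driver_pathway_size - 1L)] else character()
  rate <- rep(config$passenger_alteration_rate, config$n_genes)
  names(rate) <- genes
  rate[config$driver_gene] <- 0
  rate[companions] <- rate[companions] * config$driver_pathway_rate_factor

  ## gene-level states (genes x samples)
  altered <- matrix(stats::runif(config$n_genes * n), config$n_genes, n) < rate
  gain <- altered & (matrix(stats::runif(config$n_genes * n),
                            config$n_genes, n) < config$gain_fraction)
  gstate <- matrix("normal", config$n_genes, n, dimnames = list(genes, samples))
  gstate[altered & !gain] <- "loss"
  gstate[gain] <- "gain"
  gstate[config$driver_gene, driver_lost] <- "loss"

  ## probes: genes tiled along autosomes, k probes per gene
  k <- sample_range(config$n_probes_per_gene[1L], config$n_probes_per_gene[2L],
                    config$n_genes)
  gidx <- rep(seq_len(config$n_genes), k)
  chrom <- paste0("chr", 1L + (gidx - 1L) %% 22L)
  gene_start <- ((gidx - 1L) %/% 22L) * 10000L
  within <- unlist(lapply(k, function(m) seq_len(m)), use.names = FALSE)
  start <- gene_start + (within - 1L) * 1000L
  probe_states <- gstate[gidx, , drop = FALSE]
  if (length(controls)) {
    ctl <- matrix("normal", length(gidx), length(controls))
    probe_states <- cbind(probe_states, ctl)
  }
  colnames(probe_states) <- c(samples, controls)
  probe_states[] <- flip_states(probe_states, config$probe_noise_rate)
  probes <- data.frame(probe_id = sprintf("P%06d", seq_along(gidx)),
                       chrom = chrom, start = start, end = start + 25L,
                       stringsAsFactors = FALSE)
  probes$gene_ids <- as.list(genes[gidx])

  ## decoy probes: constitutional-region, sex-chromosome and intergenic
  nd <- config$n_decoy_probes
  constitutional <- NULL
  if (nd > 0L) {
    mk <- function(prefix, chrom, start, gene_ids, state) {
      d <- data.frame(probe_id = sprintf("%s%04d", prefix, seq_len(nd)),
                      chrom = chrom, start = start, end = start + 25L,
                      stringsAsFactors = FALSE)
      d$gene_ids <- gene_ids
      list(d = d, s = matrix(state, nd, n + length(controls)))
    }
    poly_start <- 90000000L + seq_len(nd) * 1000L
    d1 <- mk("CNVP", "chr1", poly_start,
             as.list(sprintf("POLY%04d", seq_len(nd))), "loss")
    d2 <- mk("SEXP", rep(c("chrX", "chrY"), length.out = nd),
             seq_len(nd) * 1000L, as.list(sprintf("XG%04d", seq_len(nd))),
             "normal")
    d3 <- mk("INTP", "chr2", 95000000L + seq_len(nd) * 1000L,
             replicate(nd, character(), simplify = FALSE), "normal")
    decoys <- rbind(d1$d, d2$d, d3$d)
    dstates <- rbind(d1$s, d2$s, d3$s)
    colnames(dstates) <- c(samples, controls)
    rownames(dstates) <- decoys$probe_id
    probes <- rbind(probes, decoys)
    probe_states <- rbind(probe_states, dstates)
    constitutional <- data.frame(chrom = "chr1",
                                 start = poly_start - 100L,
                                 end = poly_start + 500L,
                                 stringsAsFactors = FALSE)
  }
  rownames(probe_states) <- probes$probe_id
  cnv <- probe_cnv_table(probes, probe_states, type = "state",
                         controls = controls)

  ## expression: representative signal per covered gene, plus an attenuated
  ## second probe for a third of genes (exercises IQRmax selection)
  covered <- sort(sample.int(config$n_genes,
                             round(config$expr_coverage * config$n_genes)))
  covered <- union(1L, covered) # the driver is always on the array
  mu <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  shift <- matrix(0, length(covered), n)
  gs <- gstate[covered, , drop = FALSE]
  shift[gs == "loss"] <- config$loss_shift
  shift[gs == "gain"] <- config$gain_shift
  expr1 <- mu[covered] + shift +
    matrix(stats::rnorm(length(covered) * n, 0, config$noise_sd),
           length(covered), n)
  second <- seq_along(covered) %% 3L == 0L
  expr2 <- mu[covered[second]] + 0.3 * shift[second, , drop = FALSE] +
    matrix(stats::rnorm(sum(second) * n, 0, config$noise_sd * 0.6),
           sum(second), n)
  map <- data.frame(
    probe_id = c(sprintf("EP%05d_1", covered), sprintf("EP%05d_2", covered[second])),
    gene_id = c(genes[covered], genes[covered[second]]),
    stringsAsFactors = FALSE)
  vals <- rbind(expr1, expr2)
  dimnames(vals) <- list(map$probe_id, samples)
  expr <- expression_table(map, vals)

  ## driver lost-and-low: deletion with concordant downregulation
  driver_expr <- expr1[match(1L, covered), ]
  driver_low <- driver_lost & (driver_expr < mu[1L])

  ## survival
  hr <- config$hazard_ratio_driver_low
  hazard <- config$baseline_hazard * hr^driver_low
  t_event <- stats::rexp(n, hazard)
  censor <- stats::runif(n, config$followup_range[1L], config$followup_range[2L])
  if (config$mode == "retrospective") {
    event <- as.integer(metastatic)
    mfs <- ifelse(metastatic, t_event, censor)
  } else {
    event <- as.integer(t_event <= censor)
    mfs <- pmin(t_event, censor)
    metastatic <- event == 1L
  }
  met_at_dx <- rep(FALSE, n)
  if (config$met_at_dx_fraction > 0 && any(metastatic)) {
    pick <- which(metastatic)[stats::runif(sum(metastatic)) <
                                config$met_at_dx_fraction]
    met_at_dx[pick] <- TRUE
    mfs[pick] <- 0
  }
  chemo <- stats::runif(n) < config$chemo_fraction
  if (config$chemo_na_fraction > 0)
    chemo[stats::runif(n) < config$chemo_na_fraction] <- NA
  clinical <- data.frame(
    sample_id = samples, metastasis = metastatic, mfs_time = round(mfs, 2),
    event = event, chemotherapy = chemo,
    histotype = sample(c("LMS", "UPS", "MFS", "DDLPS", "Other"), n,
                       replace = TRUE, prob = c(0.4, 0.3, 0.1, 0.1, 0.1)),
    metastatic_at_diagnosis = met_at_dx, stringsAsFactors = FALSE)

  ## pathway catalog: an anchor pathway large enough to be altered in every
  ## tumor (keeps the driver in the universal-pathway gene pool) and the
  ## quiet planted driver pathway, then random pathways over the GO subset
  go_genes <- union(genes[seq_len(min(config$n_genes,
                                      1L + length(companions)))],
                    sample(genes, round(config$go_coverage * config$n_genes)))
  pw_ids <- sprintf("GO:%07d", seq_len(config$n_pathways))
  anchor_size <- min(config$pathway_size[2L], length(go_genes))
  sets <- vector("list", config$n_pathways)
  sets[[1L]] <- union(config$driver_gene,
                      sample(go_genes, anchor_size - 1L))
  sets[[2L]] <- c(config$driver_gene, companions)
  if (config$n_pathways > 2L)
    for (j in 3:config$n_pathways) {
      sz <- sample_range(config$pathway_size[1L], config$pathway_size[2L], 1L)
      sets[[j]] <- sample(go_genes, min(sz, length(go_genes)))
    }
  names(sets) <- pw_ids
  pw_names <- stats::setNames(c("universal anchor process",
                                "planted driver pathway",
                                sprintf("background process %d",
                                        seq_len(config$n_pathways - 2L))),
                              pw_ids)
  pathways <- pathway_catalog(sets, pw_names)

  bundle <- cohort_bundle(cnv, expr, clinical, pathways,
                          constitutional = constitutional)
  truth <- list(driver_gene = config$driver_gene,
                driver_pathways = pw_ids[1:2],
                driver_lost = stats::setNames(driver_lost, samples),
                driver_low = stats::setNames(driver_low, samples),
                metastatic = stats::setNames(metastatic, samples),
                hazard_ratio = hr,
                config = config)
  out <- structure(list(bundle = bundle, truth = truth),
                   class = "synthetic_cohort")
  if (!is.null(out_dir)) {
    paths <- write_cohort(bundle, out_dir)
    tp <- file.path(out_dir, "truth.tsv")
    utils::write.table(
      data.frame(sample_id = samples, driver_lost = driver_lost,
                 driver_low = driver_low, metastatic = metastatic),
      tp, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- c(paths, truth = tp)
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed", x$truth$config$seed, "):\n  ")
  print(x$bundle)
  cat("  planted driver:", x$truth$driver_gene, "in",
      paste(x$truth$driver_pathways, collapse = " + "), "\n")
  invisible(x)
}

#' Realism report of a (synthetic or loaded) cohort
#'
#' Recomputes, through the pipeline's own stages, the quantities the
#' generator calibrates: per-sample copy-altered gene load, gain/loss split,
#' driver deletion frequency by metastasis subgroup and the censoring
#' fraction — for comparison against the configured targets.
#'
#' @param x a `synthetic_cohort` or a `cohort_bundle`.
#' @param driver_gene gene whose subgroup deletion frequencies are reported
#'   (defaults to the planted driver when `x` carries truth).
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(x, driver_gene = NULL) {
  bundle <- if (inherits(x, "synthetic_cohort")) x$bundle else x
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (is.null(driver_gene) && inherits(x, "synthetic_cohort"))
    driver_gene <- x$truth$driver_gene
  cnv <- bundle$cnv
  if (cnv$type == "logratio") cnv <- threshold_logratio_probes(cnv)
  fp <- filter_probes(cnv, constitutional = bundle$constitutional)
  status <- aggregate_gene_status(fp)
  cn_altered <- status != "normal"
  load <- colSums(cn_altered)
  n_lost <- sum(status == "lost")
  n_gained <- sum(status == "gained")
  drv <- NULL
  if (!is.null(driver_gene) && driver_gene %in% rownames(status)) {
    lost <- status[driver_gene, bundle$clinical$sample_id] == "lost"
    met <- bundle$clinical$metastasis
    drv <- c(loss_freq_metastatic = mean(lost[met]),
             loss_freq_nonmetastatic = mean(lost[!met]))
  }
  structure(list(per_sample_load = load,
                 mean_load = mean(load),
                 gain_fraction = n_gained / (n_gained + n_lost),
                 loss_fraction = n_lost / (n_gained + n_lost),
                 driver = drv,
                 censoring_fraction = mean(bundle$clinical$event == 0L),
                 removal_counts = attr(fp, "removal_counts")),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Mean copy-altered genes per sample: %.1f\n", x$mean_load))
  cat(sprintf("Gain / loss split: %.1f%% / %.1f%%\n",
              100 * x$gain_fraction, 100 * x$loss_fraction))
  if (!is.null(x$driver))
    cat(sprintf("Driver deletion: %.1f%% metastatic vs %.1f%% non-metastatic\n",
                100 * x$driver["loss_freq_metastatic"],
                100 * x$driver["loss_freq_nonmetastatic"]))
  cat(sprintf("Censoring fraction: %.2f\n", x$censoring_fraction))
  invisible(x)
}
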