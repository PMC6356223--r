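# Probe filtering and aggregation of probe states to a per-gene copy-number
# status (normal / lost / gained).

#' Discretize log-ratio probes into loss/normal/gain states
#'
#' Bridge for numeric inputs: state is `gain` when the log2 ratio exceeds
#' `gain_cut`, `loss` when below `loss_cut`, `normal` otherwise.
#'
#' @param table a `probe_cnv_table` holding log-ratios.
#' @param gain_cut positive log2-ratio cut for gains (default 0.2).
#' @param loss_cut negative log2-ratio cut for losses (default -0.2).
#' @return A `probe_cnv_table` with discrete states.
#' @export
threshold_logratio_probes <- function(table, gain_cut = 0.2, loss_cut = -0.2) {
  stopifnot(inherits(table, "probe_cnv_table"))
  if (table$type != "logratio") stop2("table does not hold log-ratios")
  if (!(loss_cut < 0 && 0 < gain_cut))
    stop2("cuts must satisfy loss_cut < 0 < gain_cut")
  st <- matrix("normal", nrow(table$values), ncol(table$values),
               dimnames = dimnames(table$values))
  st[table$values > gain_cut] <- "gain"
  st[table$values < loss_cut] <- "loss"
  probe_cnv_table(table$probes, st, type = "state", controls = table$controls)
}

#' Filter copy-number probes
#'
#' Removes, in order: probes overlapping (by >= 1 bp) any constitutional
#' copy-number-variation region; probes on sex chromosomes; probes not
#' localized in a gene; probes whose state is non-normal in at least one
#' control sample. Per-rule removal counts are attached as the
#' `"removal_counts"` attribute.
#'
#' @param table a `probe_cnv_table` with discrete states.
#' @param constitutional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) or BED path of constitutional-CNV regions; NULL to skip.
#' @param sex_chroms chromosomes excluded as sexual; names are normalized so
#'   `"X"` and `"chrX"` are equivalent.
#' @param controls control sample ids (defaults to the table's own).
#' @return The surviving `probe_cnv_table` (errors if no probe survives).
#' @export
filter_probes <- function(table, constitutional = NULL,
                          sex_chroms = c("chrX", "chrY"),
                          controls = table$controls) {
  stopifnot(inherits(table, "probe_cnv_table"))
  if (table$type != "state")
    stop2("discrete probe states are required; run threshold_logratio_probes() first")
  if (is.character(constitutional) && length(constitutional) == 1L)
    constitutional <- read_bed(constitutional)
  counts <- c(constitutional = 0L, sex_chromosome = 0L,
              intergenic = 0L, control_altered = 0L)
  keep <- rep(TRUE, nrow(table$probes))

  if (!is.null(constitutional) && nrow(constitutional)) {
    pr <- GenomicRanges::GRanges(norm_chrom(table$probes$chrom),
                                 IRanges::IRanges(table$probes$start + 1L,
                                                  table$probes$end))
    cr <- GenomicRanges::GRanges(norm_chrom(constitutional$chrom),
                                 IRanges::IRanges(constitutional$start + 1L,
                                                  constitutional$end))
    hit <- suppressWarnings(IRanges::overlapsAny(pr, cr))
    counts["constitutional"] <- sum(hit & keep)
    keep <- keep & !hit
  }

  sexy <- norm_chrom(table$probes$chrom) %in% norm_chrom(sex_chroms)
  counts["sex_chromosome"] <- sum(sexy & keep)
  keep <- keep & !sexy

  inter <- lengths(table$probes$gene_ids) == 0L
  counts["intergenic"] <- sum(inter & keep)
  keep <- keep & !inter

  if (length(controls)) {
    ctl <- table$values[, controls, drop = FALSE]
    unstable <- rowSums(ctl != "normal") > 0L
    counts["control_altered"] <- sum(unstable & keep)
    keep <- keep & !unstable
  }

  if (!any(keep)) stop2("no probe survives filtering")
  out <- probe_cnv_table(table$probes[keep, , drop = FALSE],
                         table$values[keep, , drop = FALSE],
                         type = "state", controls = table$controls)
  attr(out, "removal_counts") <- counts
  out
}

#' Aggregate probe states into one copy-number status per gene and sample
#'
#' Default rule: the plurality state among the gene's probes wins when it is
#' a strict majority over each other state; any tie for the top count
#' (lost/gained, lost/normal or gained/normal) resolves to `normal`.
#' A probe annotated to several genes counts toward each.
#'
#' Control samples are excluded: status is reported for tumor samples only.
#'
#' @param table a filtered `probe_cnv_table` with discrete states.
#' @param tie_rule `"majority"` (default, above), `"any_nonnormal"` (a gene
#'   is lost/gained as soon as one probe is, the more frequent aberrant
#'   state winning and an exact aberrant tie resolving to normal), or
#'   `"consensus"` (non-normal only when all probes agree).
#' @return A character matrix (genes x samples) with values `"lost"`,
#'   `"normal"`, `"gained"`; attribute `n_probes_by_gene` gives the probe
#'   count per retained gene. Genes with zero probes after filtering are
#'   simply absent.
#' @export
aggregate_gene_status <- function(table,
                                  tie_rule = c("majority", "any_nonnormal",
                                               "consensus")) {
  stopifnot(inherits(table, "probe_cnv_table"))
  tie_rule <- match.arg(tie_rule)
  if (table$type != "state")
    stop2("discrete probe states are required; run threshold_logratio_probes() first")
  ng <- lengths(table$probes$gene_ids)
  if (!any(ng > 0L)) stop2("no probe is annotated to a gene")
  ridx <- rep(which(ng > 0L), ng[ng > 0L])
  gene <- unlist(table$probes$gene_ids[ng > 0L], use.names = FALSE)
  samp <- tumor_samples(table)
  S <- table$values[ridx, samp, drop = FALSE]

  n_loss <- rowsum((S == "loss") + 0L, gene)
  n_gain <- rowsum((S == "gain") + 0L, gene)
  n_norm <- rowsum((S == "normal") + 0L, gene)

  status <- matrix("normal", nrow(n_loss), ncol(n_loss),
                   dimnames = dimnames(n_loss))
  if (tie_rule == "majority") {
    status[n_loss > n_gain & n_loss > n_norm] <- "lost"
    status[n_gain > n_loss & n_gain > n_norm] <- "gained"
  } else if (tie_rule == "any_nonnormal") {
    status[n_loss > 0L & n_loss > n_gain] <- "lost"
    status[n_gain > 0L & n_gain > n_loss] <- "gained"
  } else {
    total <- n_loss + n_gain + n_norm
    status[n_loss == total] <- "lost"
    status[n_gain == total] <- "gained"
  }
  colnames(status) <- samp
  np <- table(gene)
  attr(status, "n_probes_by_gene") <- stats::setNames(as.integer(np), names(np))
  status
}
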