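# Representative-probe selection (IQRmax), copy-normal control-group
# quartiles, and the concordant alteration call that joins copy-number
# status with expression.

#' Select one representative expression probe per gene (IQRmax)
#'
#' For each gene the probe with the maximum interquartile range across all
#' samples is retained; an exact IQR tie resolves to the lexicographically
#' smallest probe id. Quartiles use linear interpolation at p*(n-1)
#' (`stats::quantile` type 7), the convention recorded in the run manifest.
#'
#' @param expr an `expression_table`.
#' @param genes optional character vector restricting the genes considered;
#'   an absent gene is an error.
#' @return An object of class `representative_expression`: `info`
#'   (data.frame `gene_id`, `probe_id`, `iqr`) and `values` (numeric matrix,
#'   genes x samples).
#' @export
select_representative_probes <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  map <- expr$map
  if (!is.null(genes)) {
    missing <- setdiff(genes, map$gene_id)
    if (length(missing))
      stop2("gene(s) absent from expression table: ",
            paste(utils::head(missing, 3), collapse = ", "))
    keep <- map$gene_id %in% genes
    map <- map[keep, , drop = FALSE]
  }
  vals <- expr$values[map$probe_id, , drop = FALSE]
  qs <- apply(vals, 1L, quartiles)
  iqr <- qs[2L, ] - qs[1L, ]
  ord <- order(map$gene_id, -iqr, map$probe_id)
  first <- ord[!duplicated(map$gene_id[ord])]
  info <- data.frame(gene_id = map$gene_id[first],
                     probe_id = map$probe_id[first],
                     iqr = unname(iqr[first]), stringsAsFactors = FALSE)
  out <- vals[info$probe_id, , drop = FALSE]
  rownames(out) <- info$gene_id
  structure(list(info = info, values = out),
            class = "representative_expression")
}

#' @export
print.representative_expression <- function(x, ...) {
  cat("Representative expression:", nrow(x$values), "genes x",
      ncol(x$values), "samples (IQRmax probe per gene)\n")
  invisible(x)
}

#' Copy-normal control-group quartiles per gene
#'
#' For each gene, the control group is the set of tumor samples whose
#' copy-number status for that gene is `normal`. Q1/Q3 of its expression are
#' defined only when the group holds at least `min_controls` samples;
#' otherwise the gene's stats are flagged undefined and downstream calls
#' become `not_evaluable`.
#'
#' @param rep_expr a `representative_expression`.
#' @param status gene-status matrix from [aggregate_gene_status()].
#' @param min_controls minimum copy-normal group size (default 30).
#' @return data.frame `gene_id`, `n_controls`, `q1`, `q3`, `defined`, one
#'   row per gene of `status` (genes without expression get `defined = FALSE`).
#' @export
compute_control_stats <- function(rep_expr, status, min_controls = 30L) {
  stopifnot(inherits(rep_expr, "representative_expression"))
  min_controls <- assert_count(min_controls, "min_controls", min = 1L)
  genes <- rownames(status)
  samp <- intersect(colnames(status), colnames(rep_expr$values))
  out <- data.frame(gene_id = genes, n_controls = 0L,
                    q1 = NA_real_, q3 = NA_real_, defined = FALSE,
                    stringsAsFactors = FALSE)
  have <- intersect(genes, rownames(rep_expr$values))
  if (!length(have) || !length(samp)) return(out)
  E <- rep_expr$values[have, samp, drop = FALSE]
  E[status[have, samp, drop = FALSE] != "normal"] <- NA_real_
  n_ctrl <- rowSums(!is.na(E))
  idx <- match(have, out$gene_id)
  out$n_controls[idx] <- as.integer(n_ctrl)
  ok <- which(n_ctrl >= min_controls)
  if (length(ok)) {
    qs <- apply(E[ok, , drop = FALSE], 1L,
                function(v) quartiles(v[!is.na(v)]))
    out$q1[idx[ok]] <- qs[1L, ]
    out$q3[idx[ok]] <- qs[2L, ]
    out$defined[idx[ok]] <- TRUE
  }
  out
}

#' Call concordant copy-number / expression alterations
#'
#' A gene is `altered_loss` in a sample when its status is `lost` and its
#' expression lies under the control group's first quartile; `altered_gain`
#' when `gained` and above the third quartile; otherwise `not_altered`.
#' Cells are `not_evaluable` when the gene's control stats are undefined or
#' its expression is missing. Comparisons are strict by default ("under" /
#' "above"); `boundary = "inclusive"` makes them `<=` / `>=`.
#'
#' @param status gene-status matrix from [aggregate_gene_status()].
#' @param rep_expr a `representative_expression`.
#' @param stats control stats from [compute_control_stats()].
#' @param boundary `"strict"` (default) or `"inclusive"`.
#' @return Character matrix (genes x samples) in
#'   \{`altered_loss`, `altered_gain`, `not_altered`, `not_evaluable`\}.
#' @export
call_alterations <- function(status, rep_expr, stats,
                             boundary = c("strict", "inclusive")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(rep_expr, "representative_expression"))
  genes <- rownames(status)
  samp <- colnames(status)
  E <- matrix(NA_real_, length(genes), length(samp),
              dimnames = list(genes, samp))
  have <- intersect(genes, rownames(rep_expr$values))
  scommon <- intersect(samp, colnames(rep_expr$values))
  E[have, scommon] <- rep_expr$values[have, scommon]
  q1 <- stats$q1[match(genes, stats$gene_id)]
  q3 <- stats$q3[match(genes, stats$gene_id)]
  defined <- stats$defined[match(genes, stats$gene_id)] %in% TRUE

  alt <- matrix("not_altered", length(genes), length(samp),
                dimnames = list(genes, samp))
  under <- if (boundary == "strict") E < q1 else E <= q1
  over <- if (boundary == "strict") E > q3 else E >= q3
  under[is.na(under)] <- FALSE
  over[is.na(over)] <- FALSE
  alt[status == "lost" & under] <- "altered_loss"
  alt[status == "gained" & over] <- "altered_gain"
  alt[!defined | is.na(E)] <- "not_evaluable"
  alt
}

#' Per-sample alteration load and cohort gain/loss split
#'
#' @param alt alteration matrix from [call_alterations()].
#' @return list with `per_sample` (named integer vector of altered-gene
#'   counts), `mean_load`, and the cohort-wide `gain_fraction` /
#'   `loss_fraction` of altered calls (NA when nothing is altered).
#' @export
alteration_load <- function(alt) {
  is_gain <- alt == "altered_gain"
  is_loss <- alt == "altered_loss"
  counts <- colSums(is_gain | is_loss)
  total <- sum(counts)
  list(per_sample = counts,
       mean_load = mean(counts),
       gain_fraction = if (total > 0) sum(is_gain) / total else NA_real_,
       loss_fraction = if (total > 0) sum(is_loss) / total else NA_real_)
}
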