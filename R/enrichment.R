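# Subgroup enrichment of gene and pathway alterations (Fisher's exact test,
# optional chi-squared) and the two-condition candidate-driver call.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The table is laid out rows = altered / not altered, columns = subgroup /
#' rest: `a` altered in the subgroup, `b` altered in the rest, `c` not
#' altered in the subgroup, `d` not altered in the rest. The two-sided p
#' sums hypergeometric probabilities no larger than the observed table's.
#'
#' The conditional maximum-likelihood odds ratio is returned together with
#' the sample odds ratio `ad/bc` (conventions: `x/0` with `x > 0` is `Inf`,
#' `0/0` is `NaN`).
#'
#' @param a,b,c,d non-negative integer cell counts (not all zero).
#' @return list with `p`, `odds_ratio` (conditional MLE) and
#'   `odds_ratio_sample`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop2("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop2("all-zero 2x2 table")
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE))
  list(p = ft$p.value,
       odds_ratio = unname(ft$estimate),
       odds_ratio_sample = (a * d) / (b * c))
}

#' Pearson chi-squared test of association on a 2x2 table
#'
#' @inheritParams fisher_exact_2x2
#' @param yates apply the continuity correction (default FALSE).
#' @return list with `statistic` and `p` (df = 1).
#' @export
chi2_association <- function(a, b, c, d, yates = FALSE) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop2("cell counts must be non-negative integers")
  m <- matrix(cells, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop2("chi-squared test requires positive margins")
  ct <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

# shared 2x2 engine: X is a logical unit x sample matrix (NA = not
# evaluable), labels a logical vector aligned with colnames(X)
enrich_binary <- function(X, labels, with_chi2 = FALSE) {
  n_units <- nrow(X)
  res <- data.frame(unit_id = rownames(X) %||% character(),
                    a = rep(0L, n_units), b = rep(0L, n_units),
                    c = rep(0L, n_units), d = rep(0L, n_units),
                    direction = rep("neutral", n_units),
                    odds_ratio = rep(NA_real_, n_units),
                    p_fisher = rep(1, n_units),
                    p_chi2 = rep(NA_real_, n_units),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_units)) {
    x <- X[i, ]
    ok <- !is.na(x)
    a <- sum(x[ok] & labels[ok])
    b <- sum(x[ok] & !labels[ok])
    c_ <- sum(!x[ok] & labels[ok])
    d <- sum(!x[ok] & !labels[ok])
    res[i, c("a", "b", "c", "d")] <- c(a, b, c_, d)
    if (a + b + c_ + d == 0L) next
    ft <- fisher_exact_2x2(a, b, c_, d)
    res$p_fisher[i] <- ft$p
    res$odds_ratio[i] <- ft$odds_ratio
    rate_sub <- if (a + c_ > 0L) a / (a + c_) else NA_real_
    rate_rest <- if (b + d > 0L) b / (b + d) else NA_real_
    if (!is.na(rate_sub) && !is.na(rate_rest) && rate_sub != rate_rest)
      res$direction[i] <- if (rate_sub > rate_rest)
        "enriched_in_subgroup" else "depleted_in_subgroup"
    if (with_chi2 && all(rowSums(matrix(c(a, b, c_, d), 2, byrow = TRUE)) > 0) &&
        all(colSums(matrix(c(a, b, c_, d), 2, byrow = TRUE)) > 0))
      res$p_chi2[i] <- chi2_association(a, b, c_, d)$p
  }
  res$p_adjusted <- stats::p.adjust(res$p_fisher, method = "BH")
  res[order(res$p_fisher, res$unit_id), , drop = FALSE]
}

subgroup_labels <- function(clinical, samples, subgroup) {
  if (!subgroup %in% names(clinical))
    stop2("subgroup column '", subgroup, "' absent from clinical table")
  labels <- as.logical(clinical[[subgroup]][match(samples, clinical$sample_id)])
  if (anyNA(labels))
    stop2("subgroup column '", subgroup, "' is missing or NA for some samples")
  if (!any(labels) || all(labels))
    stop2("subgroup '", subgroup, "' does not split the samples (one side empty)")
  labels
}

#' Gene-level subgroup enrichment of alterations
#'
#' For each gene of the candidate pool, builds the 2x2 table of altered vs
#' not altered across subgroup vs rest (samples with a `not_evaluable` call
#' for that gene are excluded from its table), tests it with the two-sided
#' Fisher exact test, and adjusts p across the pool by Benjamini-Hochberg.
#'
#' @param alt alteration matrix from [call_alterations()].
#' @param clinical validated clinical table.
#' @param pool gene ids to test (default: every gene with an evaluable call).
#' @param subgroup name of the logical clinical column defining the subgroup
#'   (default `"metastasis"`).
#' @param with_chi2 also report the uncorrected chi-squared p per gene.
#' @return data.frame of class `enrichment_result`, sorted by `p_fisher`:
#'   `unit_id`, counts `a`,`b`,`c`,`d`, `direction`, `odds_ratio`,
#'   `p_fisher`, `p_chi2`, `p_adjusted`, `alteration_type`.
#' @export
gene_subgroup_enrichment <- function(alt, clinical, pool = NULL,
                                     subgroup = "metastasis",
                                     with_chi2 = FALSE) {
  samples <- intersect(colnames(alt), clinical$sample_id)
  if (!length(samples)) stop2("no clinical sample matches the alteration matrix")
  labels <- subgroup_labels(clinical, samples, subgroup)
  if (is.null(pool))
    pool <- rownames(alt)[rowSums(alt != "not_evaluable") > 0L]
  missing <- setdiff(pool, rownames(alt))
  if (length(missing))
    stop2("pool gene(s) absent from alteration matrix: ",
          paste(utils::head(missing, 3), collapse = ", "))
  A <- alt[pool, samples, drop = FALSE]
  X <- A == "altered_loss" | A == "altered_gain"
  X[A == "not_evaluable"] <- NA
  res <- enrich_binary(X, labels, with_chi2 = with_chi2)
  n_loss <- rowSums(A == "altered_loss")[res$unit_id]
  n_gain <- rowSums(A == "altered_gain")[res$unit_id]
  res$alteration_type <- ifelse(n_loss == 0L & n_gain == 0L, "none",
                         ifelse(n_loss >= n_gain, "loss", "gain"))
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Pathway-level subgroup enrichment of alteration flags
#'
#' Same 2x2 Fisher machinery as [gene_subgroup_enrichment()], applied to the
#' per-sample pathway alteration flags.
#'
#' @param pam pathway flag matrix from [flag_pathways()].
#' @inheritParams gene_subgroup_enrichment
#' @return data.frame of class `enrichment_result`, sorted by `p_fisher`.
#' @export
pathway_subgroup_enrichment <- function(pam, clinical,
                                        subgroup = "metastasis",
                                        with_chi2 = FALSE) {
  samples <- intersect(colnames(pam), clinical$sample_id)
  if (!length(samples)) stop2("no clinical sample matches the pathway flags")
  labels <- subgroup_labels(clinical, samples, subgroup)
  res <- enrich_binary(pam[, samples, drop = FALSE], labels,
                       with_chi2 = with_chi2)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Candidate driver genes: gene and pathway both enriched
#'
#' A gene is a candidate driver when its own alteration is enriched in the
#' subgroup (p below `alpha`, direction `enriched_in_subgroup`) and it
#' belongs to at least one pathway whose alteration flags pass the same
#' test. Each candidate lists its supporting pathways.
#'
#' @param gene_results [gene_subgroup_enrichment()] output.
#' @param pathway_results [pathway_subgroup_enrichment()] output.
#' @param catalog the restricted `pathway_catalog` (gene membership).
#' @param alpha significance level (default 0.05).
#' @param use_adjusted select on BH-adjusted instead of raw p.
#' @return data.frame of class `driver_candidates`: `gene_id`,
#'   `alteration_type`, `p_fisher`, `p_adjusted`, `pathways`
#'   (comma-separated supporting pathway ids).
#' @export
select_candidate_drivers <- function(gene_results, pathway_results, catalog,
                                     alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  alpha <- assert_prob(alpha, "alpha")
  pcol <- if (use_adjusted) "p_adjusted" else "p_fisher"
  gpass <- gene_results[gene_results$direction == "enriched_in_subgroup" &
                          gene_results[[pcol]] < alpha, , drop = FALSE]
  ppass <- pathway_results$unit_id[
    pathway_results$direction == "enriched_in_subgroup" &
      pathway_results[[pcol]] < alpha]
  support <- lapply(gpass$unit_id, function(g)
    ppass[vapply(catalog$sets[ppass], function(s) g %in% s, TRUE)])
  keep <- lengths(support) > 0L
  out <- data.frame(gene_id = gpass$unit_id[keep],
                    alteration_type = if ("alteration_type" %in% names(gpass))
                      gpass$alteration_type[keep] else NA_character_,
                    p_fisher = gpass$p_fisher[keep],
                    p_adjusted = gpass$p_adjusted[keep],
                    pathways = vapply(support[keep], paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("driver_candidates", "data.frame")
  out
}
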