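# Pathway-level alteration flags and selection of pathways altered in
# (a fraction of) all tumors.

#' Restrict a pathway catalog to the evaluable gene universe
#'
#' The universe is the set of genes present in the alteration matrix with at
#' least one evaluable cell. Pathway gene sets are intersected with it;
#' pathways left empty are dropped (count in attribute `"n_dropped"`).
#'
#' @param catalog a `pathway_catalog`.
#' @param alt alteration matrix from [call_alterations()].
#' @return The restricted `pathway_catalog`, with attributes `"universe"`
#'   and `"n_dropped"`.
#' @export
restrict_catalog <- function(catalog, alt) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  universe <- rownames(alt)[rowSums(alt != "not_evaluable") > 0L]
  sets <- lapply(catalog$sets, intersect, y = universe)
  keep <- lengths(sets) > 0L
  if (!any(keep)) stop2("no pathway retains an evaluable gene")
  out <- pathway_catalog(sets[keep], catalog$names)
  attr(out, "universe") <- universe
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Flag pathway alteration per sample
#'
#' A pathway is flagged in a sample when at least one of its (universe)
#' member genes carries an alteration there, loss or gain alike.
#'
#' @param catalog a restricted `pathway_catalog`.
#' @param alt alteration matrix from [call_alterations()].
#' @return Logical matrix, pathways x samples; attribute
#'   `"n_samples_altered"` holds the per-pathway flagged-sample count.
#' @export
flag_pathways <- function(catalog, alt) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  altered <- alt == "altered_loss" | alt == "altered_gain"
  flags <- t(vapply(catalog$sets, function(g) {
    g <- intersect(g, rownames(altered))
    if (!length(g)) return(rep(FALSE, ncol(altered)))
    colSums(altered[g, , drop = FALSE]) > 0L
  }, logical(ncol(altered))))
  dimnames(flags) <- list(names(catalog$sets), colnames(alt))
  attr(flags, "n_samples_altered") <- rowSums(flags)
  flags
}

#' Select pathways altered in (a fraction of) all samples
#'
#' @param pam pathway-alteration flag matrix from [flag_pathways()].
#' @param fraction minimum fraction of samples in which a pathway must be
#'   flagged (default 1.0: altered in every tumor).
#' @return Character vector of selected pathway ids.
#' @export
select_universal_pathways <- function(pam, fraction = 1.0) {
  fraction <- assert_prob(fraction, "fraction")
  rownames(pam)[rowMeans(pam) >= fraction - 1e-12]
}

#' Candidate gene pool: altered members of the selected pathways
#'
#' The union of member genes of the selected pathways that are altered in at
#' least one sample — the pool handed to subgroup enrichment.
#'
#' @param selected pathway ids from [select_universal_pathways()].
#' @param catalog the restricted `pathway_catalog`.
#' @param alt alteration matrix.
#' @return Character vector of gene ids (empty when nothing is selected).
#' @export
genes_in_universal_pathways <- function(selected, catalog, alt) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  members <- unique(as.character(unlist(catalog$sets[selected],
                                        use.names = FALSE)))
  members <- intersect(members, rownames(alt))
  altered_any <- rowSums(alt == "altered_loss" | alt == "altered_gain") > 0L
  members[altered_any[members]]
}
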