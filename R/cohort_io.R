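# Reading, validating and writing the cohort tables shared by all stages.
#
# All genomic coordinates are 0-based half-open internally (BED convention).
# Inputs declared 1-based are converted on load via `one_based = TRUE`.

#' Construct a probe-level copy-number table
#'
#' The container for probe-level copy-number data: probe coordinates, the
#' probe-to-gene annotation, and either discrete per-sample states
#' (`"loss"`, `"normal"`, `"gain"`) or numeric log2 ratios.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `gene_ids` (a list column of character vectors;
#'   empty vectors mark intergenic probes).
#' @param values matrix, probes x samples; character states or numeric
#'   log-ratios, rownames must equal `probes$probe_id`.
#' @param type `"state"` or `"logratio"`; `"auto"` infers from `values`.
#' @param controls character vector of control (normal DNA) sample ids,
#'   a subset of `colnames(values)`.
#' @return An object of class `probe_cnv_table`.
#' @export
probe_cnv_table <- function(probes, values, type = "auto", controls = character()) {
  req <- c("probe_id", "chrom", "start", "end", "gene_ids")
  if (!all(req %in% names(probes)))
    stop2("probes must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stop2("duplicate probe ids: ",
          paste(unique(probes$probe_id[duplicated(probes$probe_id)])[1:3], collapse = ", "))
  if (any(probes$start >= probes$end))
    stop2("malformed coordinates (start >= end) for probe ",
          probes$probe_id[which(probes$start >= probes$end)[1]])
  if (!is.list(probes$gene_ids)) stop2("probes$gene_ids must be a list column")
  if (!is.matrix(values) || nrow(values) != nrow(probes))
    stop2("values must be a probes x samples matrix")
  if (is.null(rownames(values))) rownames(values) <- probes$probe_id
  if (!identical(rownames(values), as.character(probes$probe_id)))
    stop2("rownames(values) must match probes$probe_id")
  if (type == "auto") type <- if (is.numeric(values)) "logratio" else "state"
  if (type == "state") {
    bad <- setdiff(unique(as.vector(values)), c("loss", "normal", "gain"))
    if (length(bad)) stop2("unknown probe state token(s): ", paste(bad, collapse = ", "))
  } else if (type == "logratio") {
    if (!is.numeric(values)) stop2("logratio table requires numeric values")
  } else stop2("type must be 'state' or 'logratio'")
  if (length(controls) && !all(controls %in% colnames(values)))
    stop2("control sample(s) absent from CNV table: ",
          paste(setdiff(controls, colnames(values)), collapse = ", "))
  structure(list(probes = probes, values = values, type = type,
                 controls = as.character(controls)),
            class = "probe_cnv_table")
}

#' @export
print.probe_cnv_table <- function(x, ...) {
  cat("Probe CNV table:", nrow(x$probes), "probes x",
      ncol(x$values), "samples (", length(x$controls), "controls ),",
      x$type, "representation\n")
  invisible(x)
}

#' Tumor sample ids of a probe CNV table (controls excluded)
#' @param x a `probe_cnv_table`
#' @export
tumor_samples <- function(x) setdiff(colnames(x$values), x$controls)

#' Read a probe-level CNV table
#'
#' Tab-delimited, header `probe_id  chrom  start  end  gene_ids` followed by
#' one column per sample. `gene_ids` is comma-separated (empty for
#' intergenic probes). Sample columns hold either state tokens
#' (`loss`/`normal`/`gain`) or numeric log2 ratios, uniformly.
#'
#' @param path TSV file path.
#' @param controls optional path to a control-sample list (one id per line)
#'   or a character vector of control sample ids.
#' @param one_based set TRUE when coordinates are 1-based inclusive; they are
#'   converted to 0-based half-open on load.
#' @return A [probe_cnv_table()].
#' @export
read_probe_cnv <- function(path, controls = NULL, one_based = FALSE) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("probe_id", "chrom", "start", "end", "gene_ids")
  if (!all(req %in% names(raw)))
    stop2("CNV file ", path, " lacks required columns ",
          paste(setdiff(req, names(raw)), collapse = ", "))
  samp <- setdiff(names(raw), req)
  if (!length(samp)) stop2("CNV file ", path, " has no sample columns")
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  if (anyNA(start) || anyNA(end))
    stop2("CNV file ", path, ": non-integer coordinate at row ",
          which(is.na(start) | is.na(end))[1])
  if (one_based) start <- start - 1L
  gene_ids <- strsplit(raw$gene_ids, ",", fixed = TRUE)
  gene_ids <- lapply(gene_ids, function(g) g[nzchar(g)])
  vals <- as.matrix(raw[samp])
  numeric_like <- !anyNA(suppressWarnings(as.numeric(vals)))
  if (numeric_like) {
    vals <- matrix(as.numeric(vals), nrow = nrow(raw),
                   dimnames = list(raw$probe_id, samp))
  } else {
    dimnames(vals) <- list(raw$probe_id, samp)
  }
  if (is.character(controls) && length(controls) == 1L && file.exists(controls))
    controls <- readLines(controls, warn = FALSE)
  controls <- controls %||% character()
  controls <- controls[nzchar(controls)]
  probes <- data.frame(probe_id = raw$probe_id, chrom = raw$chrom,
                       start = start, end = end, stringsAsFactors = FALSE)
  probes$gene_ids <- gene_ids
  probe_cnv_table(probes, vals, type = "auto", controls = controls)
}

#' Write a probe-level CNV table
#' @param x a `probe_cnv_table`
#' @param path output TSV path
#' @param controls_path optional path for the control-sample list file
#' @export
write_probe_cnv <- function(x, path, controls_path = NULL) {
  df <- data.frame(probe_id = x$probes$probe_id, chrom = x$probes$chrom,
                   start = x$probes$start, end = x$probes$end,
                   gene_ids = vapply(x$probes$gene_ids, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$values, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(controls_path)) writeLines(x$controls, controls_path)
  invisible(path)
}

#' Construct / read / write an expression table
#'
#' One row per expression probe with its gene annotation; log2 intensities
#' per sample. A gene may map to several probes.
#'
#' @param map data.frame with columns `probe_id`, `gene_id`.
#' @param values numeric matrix, probes x samples, rownames = probe ids.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(map, values) {
  if (!all(c("probe_id", "gene_id") %in% names(map)))
    stop2("map must have columns probe_id, gene_id")
  if (anyDuplicated(map$probe_id)) stop2("duplicate expression probe ids")
  if (!is.numeric(values)) stop2("expression values must be numeric")
  if (is.null(rownames(values))) rownames(values) <- map$probe_id
  if (!identical(rownames(values), as.character(map$probe_id)))
    stop2("rownames(values) must match map$probe_id")
  if (anyNA(colnames(values)) || is.null(colnames(values)))
    stop2("expression table is missing sample column names")
  structure(list(map = map[c("probe_id", "gene_id")], values = values),
            class = "expression_table")
}

#' @rdname expression_table
#' @param path TSV with header `probe_id  gene_id` then one column per sample.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(raw)))
    stop2("expression file ", path, " lacks probe_id/gene_id columns")
  samp <- setdiff(names(raw), c("probe_id", "gene_id"))
  vals <- as.matrix(raw[samp])
  if (!is.numeric(vals)) stop2("expression file ", path, " has non-numeric values")
  dimnames(vals) <- list(raw$probe_id, samp)
  expression_table(raw[c("probe_id", "gene_id")], vals)
}

#' @rdname expression_table
#' @param x an `expression_table`
#' @export
write_expression <- function(x, path) {
  df <- cbind(x$map, as.data.frame(x$values, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table:", nrow(x$values), "probes,",
      length(unique(x$map$gene_id)), "genes x", ncol(x$values), "samples\n")
  invisible(x)
}

#' Read and validate the clinical table
#'
#' CSV with columns `sample_id`, `metastasis` (TRUE/FALSE), `mfs_time`
#' (months, >= 0), `event` (0/1, 1 = distant recurrence), `chemotherapy`
#' (TRUE/FALSE or empty = unknown; unknown is kept as NA, never coerced),
#' `histotype`, `metastatic_at_diagnosis` (TRUE/FALSE).
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df, where = path)
}

#' @rdname read_clinical
#' @param df clinical data.frame to validate in place
#' @param where label used in error messages
#' @export
validate_clinical <- function(df, where = "clinical table") {
  req <- c("sample_id", "metastasis", "mfs_time", "event")
  if (!all(req %in% names(df)))
    stop2(where, " lacks required column(s): ",
          paste(setdiff(req, names(df)), collapse = ", "))
  if (!"chemotherapy" %in% names(df)) df$chemotherapy <- NA
  if (!"histotype" %in% names(df)) df$histotype <- NA_character_
  if (!"metastatic_at_diagnosis" %in% names(df)) df$metastatic_at_diagnosis <- FALSE
  df$metastasis <- as.logical(df$metastasis)
  df$metastatic_at_diagnosis <- as.logical(df$metastatic_at_diagnosis)
  df$chemotherapy <- as.logical(df$chemotherapy)
  df$mfs_time <- as.numeric(df$mfs_time)
  df$event <- as.integer(df$event)
  if (anyDuplicated(df$sample_id)) stop2(where, ": duplicate sample ids")
  bad <- which(is.na(df$mfs_time) | df$mfs_time < 0)
  if (length(bad))
    stop2(where, ": mfs_time must be >= 0 (row ", bad[1],
          ", sample ", df$sample_id[bad[1]], ")")
  if (!all(df$event %in% c(0L, 1L)))
    stop2(where, ": event must be 0/1 (row ",
          which(!df$event %in% c(0L, 1L))[1], ")")
  bad <- which(df$event == 1L & !df$metastasis)
  if (length(bad))
    stop2(where, ": event = 1 requires metastasis = TRUE (row ", bad[1],
          ", sample ", df$sample_id[bad[1]], ")")
  df
}

#' Read a pathway catalog
#'
#' Two-column TSV (`pathway_id`, `gene_id`), one membership per row; an
#' optional two-column name map (`pathway_id`, `name`).
#'
#' @param path membership TSV path.
#' @param names_path optional pathway-name TSV path.
#' @return An object of class `pathway_catalog`: a named list of gene-id
#'   vectors plus an optional name map.
#' @export
read_pathways <- function(path, names_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "gene_id") %in% names(df)))
    stop2("pathway file ", path, " must have columns pathway_id, gene_id")
  sets <- lapply(split(df$gene_id, df$pathway_id), unique)
  nm <- NULL
  if (!is.null(names_path)) {
    nmdf <- utils::read.delim(names_path, stringsAsFactors = FALSE)
    nm <- stats::setNames(nmdf$name, nmdf$pathway_id)
  }
  pathway_catalog(sets, nm)
}

#' @rdname read_pathways
#' @param sets named list mapping pathway id to a character vector of gene ids
#' @param names optional named character vector of pathway names
#' @export
pathway_catalog <- function(sets, names = NULL) {
  if (is.null(base::names(sets)) || anyDuplicated(base::names(sets)))
    stop2("pathway ids must be unique and non-empty")
  if (any(lengths(sets) == 0L)) stop2("empty pathway gene set(s)")
  structure(list(sets = sets, names = names), class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat("Pathway catalog:", length(x$sets), "pathways,",
      length(unique(unlist(x$sets, use.names = FALSE))), "distinct genes\n")
  invisible(x)
}

#' @rdname read_pathways
#' @param x a `pathway_catalog`
#' @param path output TSV path
#' @export
write_pathways <- function(x, path) {
  df <- data.frame(pathway_id = rep(names(x$sets), lengths(x$sets)),
                   gene_id = unlist(x$sets, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle the four cohort tables, reconciling sample sets
#'
#' Tumor samples are intersected across the CNV, expression and clinical
#' tables; samples missing from any table are dropped with a warning. A zero
#' intersection is a hard error.
#'
#' @param cnv a `probe_cnv_table`.
#' @param expr an `expression_table`.
#' @param clinical a validated clinical data.frame.
#' @param pathways a `pathway_catalog`.
#' @param constitutional optional data.frame of constitutional-CNV regions
#'   (`chrom`, `start`, `end`; 0-based half-open) used by [filter_probes()].
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(cnv, expr, clinical, pathways, constitutional = NULL) {
  stopifnot(inherits(cnv, "probe_cnv_table"), inherits(expr, "expression_table"),
            inherits(pathways, "pathway_catalog"))
  clinical <- validate_clinical(clinical)
  sets <- list(cnv = tumor_samples(cnv), expression = colnames(expr$values),
               clinical = clinical$sample_id)
  common <- Reduce(intersect, sets)
  if (!length(common))
    stop2("no sample id is shared by the CNV, expression and clinical tables")
  dropped <- lapply(sets, setdiff, y = common)
  if (any(lengths(dropped) > 0L)) {
    msg <- vapply(names(dropped)[lengths(dropped) > 0L], function(k)
      paste0(length(dropped[[k]]), " sample(s) only outside the ", k, " table"),
      "")
    warning("dropping samples absent from some table: ",
            paste(unlist(lapply(dropped, utils::head, 3)), collapse = ", "),
            " (", paste(msg, collapse = "; "), ")", call. = FALSE)
  }
  keep <- c(common, intersect(cnv$controls, colnames(cnv$values)))
  cnv$values <- cnv$values[, keep, drop = FALSE]
  expr$values <- expr$values[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(cnv = cnv, expr = expr, clinical = clinical,
                 pathways = pathways, constitutional = constitutional,
                 samples = common, dropped = dropped),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Cohort bundle:", length(x$samples), "samples |",
      nrow(x$cnv$probes), "CNV probes |",
      length(unique(x$expr$map$gene_id)), "expressed genes |",
      length(x$pathways$sets), "pathways\n")
  invisible(x)
}

#' Load a complete cohort from disk
#'
#' @param cnv_path,expr_path,clinical_path,pathway_path input file paths
#'   (dialects in [read_probe_cnv()], [read_expression()], [read_clinical()],
#'   [read_pathways()]).
#' @param controls_path optional control-sample list file.
#' @param constitutional_path optional BED file of constitutional-CNV regions.
#' @param pathway_names_path optional pathway-name TSV.
#' @param one_based TRUE when CNV coordinates are 1-based inclusive.
#' @return A [cohort_bundle()].
#' @export
load_cohort <- function(cnv_path, expr_path, clinical_path, pathway_path,
                        controls_path = NULL, constitutional_path = NULL,
                        pathway_names_path = NULL, one_based = FALSE) {
  cnv <- read_probe_cnv(cnv_path, controls = controls_path, one_based = one_based)
  expr <- read_expression(expr_path)
  clinical <- read_clinical(clinical_path)
  pathways <- read_pathways(pathway_path, pathway_names_path)
  constitutional <- if (!is.null(constitutional_path)) read_bed(constitutional_path)
  b <- cohort_bundle(cnv, expr, clinical, pathways, constitutional)
  message("loaded cohort: ", nrow(cnv$probes), " probes, ",
          length(unique(expr$map$gene_id)), " genes on expression array, ",
          length(b$samples), " samples, ", length(pathways$sets), " pathways")
  b
}

#' Read a BED file of genomic regions
#'
#' Minimal three-column BED (chrom, start, end; 0-based half-open), no header.
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end) | df$start >= df$end))
    stop2("malformed BED interval in ", path)
  df
}

#' Write a cohort bundle back to disk in the package's input dialects
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cnv = file.path(dir, "cnv.tsv"),
             controls = file.path(dir, "controls.txt"),
             expr = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             pathways = file.path(dir, "pathways.tsv"))
  write_probe_cnv(bundle$cnv, paths["cnv"], controls_path = paths["controls"])
  write_expression(bundle$expr, paths["expr"])
  utils::write.csv(bundle$clinical, paths["clinical"], row.names = FALSE, quote = FALSE)
  write_pathways(bundle$pathways, paths["pathways"])
  if (!is.null(bundle$constitutional)) {
    paths <- c(paths, constitutional = file.path(dir, "constitutional.bed"))
    utils::write.table(bundle$constitutional, paths["constitutional"],
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(paths)
}
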