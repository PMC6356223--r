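# Expression dichotomization (density-curve intersection or mean cutoff)
# and metastasis-free-survival comparison: Kaplan-Meier curves, log-rank
# test, observed/expected hazard ratio.

#' Threshold at the intersection of two kernel density curves
#'
#' Gaussian kernel densities of the two groups (typically expression of
#' copy-deleted vs copy-normal tumors) are evaluated on a shared grid
#' spanning the pooled range padded by three pooled bandwidths. Candidate
#' thresholds are the sign changes of the density difference; the crossing
#' lying between the two group medians is returned (the one nearest the
#' midpoint of the medians when several). With no crossing in that window
#' the pooled mean is used with a warning; a zero-variance group falls back
#' to the midpoint of the group means.
#'
#' @param values_a,values_b numeric vectors for the two groups (>= 10 values
#'   each).
#' @param bw bandwidth rule: `"nrd0"` (Silverman, default) or a numeric
#'   bandwidth applied to both groups.
#' @param grid_size number of grid points (default 1024).
#' @return An object of class `threshold_result`: `threshold`, `method`
#'   (`"density_intersection"`, `"pooled_mean"` or `"midpoint_means"`),
#'   `group_sizes`, `crossings` (all in-window candidates) and `grid`
#'   (data.frame `x`, `f_a`, `f_b`).
#' @export
density_intersection_threshold <- function(values_a, values_b, bw = "nrd0",
                                           grid_size = 1024L) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 10L || length(values_b) < 10L)
    stop2("each group needs at least 10 finite values")
  sizes <- c(n_a = length(values_a), n_b = length(values_b))
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    warning("zero-variance group; falling back to the midpoint of group means",
            call. = FALSE)
    return(structure(list(threshold = mean(c(mean(values_a), mean(values_b))),
                          method = "midpoint_means", group_sizes = sizes,
                          crossings = numeric(), grid = NULL),
                     class = "threshold_result"))
  }
  pooled <- c(values_a, values_b)
  bw_a <- if (is.numeric(bw)) bw else stats::bw.nrd0(values_a)
  bw_b <- if (is.numeric(bw)) bw else stats::bw.nrd0(values_b)
  pad <- 3 * stats::bw.nrd0(pooled)
  lo <- min(pooled) - pad
  hi <- max(pooled) + pad
  da <- stats::density(values_a, bw = bw_a, from = lo, to = hi, n = grid_size)
  db <- stats::density(values_b, bw = bw_b, from = lo, to = hi, n = grid_size)
  d <- da$y - db$y
  i <- which(d[-length(d)] * d[-1L] < 0)
  cross <- da$x[i] + d[i] * (da$x[i + 1L] - da$x[i]) / (d[i] - d[i + 1L])
  cross <- c(cross, da$x[d == 0])
  med <- sort(c(stats::median(values_a), stats::median(values_b)))
  inwin <- cross[cross > med[1L] & cross < med[2L]]
  grid <- data.frame(x = da$x, f_a = da$y, f_b = db$y)
  if (!length(inwin)) {
    warning("no density crossing between the group medians; ",
            "falling back to the pooled mean", call. = FALSE)
    return(structure(list(threshold = mean(pooled), method = "pooled_mean",
                          group_sizes = sizes, crossings = numeric(),
                          grid = grid),
                     class = "threshold_result"))
  }
  mid <- mean(med)
  structure(list(threshold = inwin[which.min(abs(inwin - mid))],
                 method = "density_intersection", group_sizes = sizes,
                 crossings = sort(inwin), grid = grid),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("Dichotomization threshold:", format(x$threshold, digits = 4),
      "(", x$method, "; groups", x$group_sizes[1L], "vs",
      x$group_sizes[2L], ")\n")
  invisible(x)
}

#' Dichotomize expression values at a threshold
#'
#' `low` strictly below the threshold, `high` otherwise. For
#' `method = "mean"` the threshold is the mean of `values`; for `"fixed"`
#' and `"density_intersection"` it must be supplied (the latter from
#' [density_intersection_threshold()], which needs the group split).
#'
#' @param values named numeric vector (names = sample ids).
#' @param method `"mean"`, `"fixed"` or `"density_intersection"`.
#' @param threshold cutoff value (ignored for `"mean"`).
#' @return Character vector (`"low"`/`"high"`) named by sample; attribute
#'   `"threshold"` records the cutoff. Warns when all samples fall on one
#'   side.
#' @export
dichotomize <- function(values, method = c("mean", "fixed",
                                           "density_intersection"),
                        threshold = NULL) {
  method <- match.arg(method)
  if (method == "mean") threshold <- mean(values, na.rm = TRUE)
  if (is.null(threshold) || !is.finite(threshold))
    stop2("a finite threshold is required for method '", method, "'")
  lab <- ifelse(values < threshold, "low", "high")
  if (length(unique(lab[!is.na(lab)])) < 2L)
    warning("all samples fall on one side of the threshold", call. = FALSE)
  attr(lab, "threshold") <- threshold
  lab
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator; deaths precede censorings at tied
#' times.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event).
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` at each distinct observed time.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop2("empty survival input")
  if (length(times) != length(events)) stop2("times/events length mismatch")
  if (any(times < 0)) stop2("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop2("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, surv = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test with observed/expected hazard ratio
#'
#' The standard log-rank statistic (hypergeometric variance at each distinct
#' event time), p from chi-squared with one df. The hazard ratio of group 1
#' vs group 2 is estimated as (O1/E1)/(O2/E2) with the log-scale confidence
#' interval from sqrt(1/E1 + 1/E2); group 1 is the first factor level of
#' `groups`.
#'
#' @inheritParams km_estimate
#' @param groups two-level factor/character vector of group labels.
#' @param conf_level confidence level for the hazard-ratio CI.
#' @return An object of class `logrank_result`: `statistic`, `p`,
#'   `observed`, `expected` (named by group), `hazard_ratio`, `ci`,
#'   `levels`.
#' @export
logrank_and_hr <- function(times, events, groups, conf_level = 0.95) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop2("exactly two groups are required")
  if (any(table(g) == 0L)) stop2("each group needs at least one subject")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  obs <- stats::setNames(sd$obs, levels(g))
  exp_ <- stats::setNames(sd$exp, levels(g))
  statistic <- unname(sd$chisq)
  p <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)
  if (sum(obs) == 0) { # no events anywhere: no evidence either way
    hr <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else if (any(exp_ == 0)) {
    hr <- NA_real_
    ci <- c(NA_real_, NA_real_)
    warning("a group has zero expected events; hazard ratio undefined",
            call. = FALSE)
  } else {
    hr <- (obs[1L] / exp_[1L]) / (obs[2L] / exp_[2L])
    se <- sqrt(1 / exp_[1L] + 1 / exp_[2L])
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- unname(exp(log(hr) + c(-1, 1) * z * se))
    hr <- unname(hr)
  }
  structure(list(statistic = statistic, p = p, observed = obs,
                 expected = exp_, hazard_ratio = hr, ci = ci,
                 levels = levels(g), conf_level = conf_level),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank: chisq =", format(x$statistic, digits = 4),
      "(df = 1), p =", format.pval(x$p, digits = 3), "\n")
  cat("  O/E:", paste(sprintf("%s %d/%.2f", x$levels, x$observed, x$expected),
                      collapse = ", "), "\n")
  if (is.finite(x$hazard_ratio))
    cat(sprintf("  HR (%s vs %s) = %.3f [%.3f, %.3f]\n", x$levels[1L],
                x$levels[2L], x$hazard_ratio, x$ci[1L], x$ci[2L]))
  invisible(x)
}

# internal: per-gene status + representative expression, from a screen
# object or recomputed from a bare bundle with default settings
prep_gene <- function(x, gene_id) {
  if (inherits(x, "driver_screen"))
    return(list(status = x$status, rep_expr = x$rep_expr, bundle = x$bundle))
  stopifnot(inherits(x, "cohort_bundle"))
  cnv <- x$cnv
  if (cnv$type == "logratio") cnv <- threshold_logratio_probes(cnv)
  fp <- filter_probes(cnv, constitutional = x$constitutional)
  list(status = aggregate_gene_status(fp),
       rep_expr = select_representative_probes(x$expr), bundle = x)
}

#' Metastasis-free-survival comparison for one gene
#'
#' Dichotomizes the gene's expression (`density_intersection` crosses the
#' kernel densities of copy-deleted vs copy-normal tumors; `mean` cuts at
#' the cohort mean; `fixed` uses a supplied threshold), optionally restricts
#' to patients who did / did not receive chemotherapy, excludes patients
#' metastatic at diagnosis by default, and compares the low vs high strata
#' by Kaplan-Meier, log-rank and the O/E hazard ratio (low vs high).
#'
#' @param x a `driver_screen` object or a `cohort_bundle`.
#' @param gene_id gene to analyse.
#' @param method dichotomization method.
#' @param subset `"all"`, `"chemo"` or `"no_chemo"` (errors when the
#'   chemotherapy column is entirely unknown).
#' @param threshold cutoff for `method = "fixed"`.
#' @param exclude_metastatic_at_diagnosis drop patients already metastatic
#'   at diagnosis (default TRUE).
#' @return An object of class `mfs_fit`: threshold info, per-stratum
#'   Kaplan-Meier curves, the `logrank_result`, group sizes and the number
#'   of patients excluded.
#' @export
mfs_analysis <- function(x, gene_id,
                         method = c("density_intersection", "mean", "fixed"),
                         subset = c("all", "chemo", "no_chemo"),
                         threshold = NULL,
                         exclude_metastatic_at_diagnosis = TRUE) {
  method <- match.arg(method)
  subset <- match.arg(subset)
  pg <- prep_gene(x, gene_id)
  cl <- pg$bundle$clinical
  if (!gene_id %in% rownames(pg$rep_expr$values))
    stop2("gene ", gene_id, " has no expression probe")
  n_flagged <- sum(cl$metastatic_at_diagnosis %in% TRUE)
  if (exclude_metastatic_at_diagnosis)
    cl <- cl[!(cl$metastatic_at_diagnosis %in% TRUE), , drop = FALSE]
  if (subset != "all") {
    if (all(is.na(cl$chemotherapy)))
      stop2("chemotherapy status is unknown for every patient; ",
            "cannot subset on column 'chemotherapy'")
    cl <- cl[!is.na(cl$chemotherapy) &
               cl$chemotherapy == (subset == "chemo"), , drop = FALSE]
  }
  samples <- intersect(cl$sample_id, colnames(pg$rep_expr$values))
  if (!length(samples)) stop2("subset '", subset, "' is empty")
  expr <- pg$rep_expr$values[gene_id, samples]

  thr_info <- NULL
  if (method == "density_intersection") {
    if (!gene_id %in% rownames(pg$status))
      stop2("gene ", gene_id, " has no copy-number status")
    st <- pg$status[gene_id, intersect(samples, colnames(pg$status))]
    del <- expr[names(st)[st == "lost"]]
    nrm <- expr[names(st)[st == "normal"]]
    thr_info <- density_intersection_threshold(del, nrm)
    threshold <- thr_info$threshold
  } else if (method == "mean") {
    threshold <- mean(expr)
  } else if (is.null(threshold)) {
    stop2("method 'fixed' needs a threshold")
  }
  lab <- dichotomize(expr, method = "fixed", threshold = threshold)
  if (length(unique(lab)) < 2L)
    stop2("dichotomization yields a single stratum; survival comparison skipped")
  cl <- cl[match(samples, cl$sample_id), , drop = FALSE]
  lab <- factor(lab, levels = c("low", "high"))
  lr <- logrank_and_hr(cl$mfs_time, cl$event, lab)
  curves <- lapply(split(seq_along(lab), lab), function(i)
    km_estimate(cl$mfs_time[i], cl$event[i]))
  structure(list(gene_id = gene_id, method = method, threshold = threshold,
                 threshold_detail = thr_info, subset = subset,
                 n = length(samples), group_sizes = table(lab),
                 n_excluded_metastatic_at_diagnosis =
                   if (exclude_metastatic_at_diagnosis) n_flagged else 0L,
                 curves = curves, logrank = lr),
            class = "mfs_fit")
}

#' @export
print.mfs_fit <- function(x, ...) {
  cat("Metastasis-free survival for", x$gene_id,
      "| subset:", x$subset, "| n =", x$n, "\n")
  cat("  threshold =", format(x$threshold, digits = 4),
      paste0("(", x$method, ")"),
      "| low:", x$group_sizes["low"], "high:", x$group_sizes["high"], "\n")
  print(x$logrank)
  invisible(x)
}

#' Plot the stratified Kaplan-Meier curves of an `mfs_fit`
#'
#' @param x an `mfs_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mfs_fit <- function(x, ...) {
  cols <- c(low = "firebrick", high = "navy")
  graphics::plot(NA, xlim = c(0, max(unlist(lapply(x$curves, `[[`, "time")))),
                 ylim = c(0, 1), xlab = "Months", ylab = "Metastasis-free survival",
                 main = paste0(x$gene_id, " (", x$subset, ", cut = ",
                               format(x$threshold, digits = 3), ")"), ...)
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), do.points = FALSE,
                    col = cols[[g]], lwd = 2)
  }
  graphics::legend("bottomleft", legend = sprintf("%s (n=%d)", names(x$curves),
                                                  as.integer(x$group_sizes)),
                   col = cols[names(x$curves)], lwd = 2, bty = "n")
  invisible(x)
}
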