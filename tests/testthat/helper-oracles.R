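# Independent oracles used across the suite. These deliberately avoid the
# package's code paths (and where possible the same library routines) so
# that agreement is evidence, not tautology.

# exhaustive two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins; ties in probability use the standard
# relative tolerance for floating-point equality of mathematically equal
# table probabilities
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  xs <- max(0L, k - r2):min(k, r1)
  probs <- dhyper(xs, r1, r2, k)
  p_obs <- dhyper(a, r1, r2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-cell plurality vote with tie -> normal
oracle_gene_status <- function(probe_states, gene_of_probe, samples) {
  genes <- sort(unique(unlist(gene_of_probe)))
  out <- matrix("normal", length(genes), length(samples),
                dimnames = list(genes, samples))
  for (g in genes) {
    rows <- which(vapply(gene_of_probe, function(gs) g %in% gs, TRUE))
    for (s in samples) {
      v <- probe_states[rows, s]
      n <- c(lost = sum(v == "loss"), gained = sum(v == "gain"),
             normal = sum(v == "normal"))
      top <- names(n)[n == max(n)]
      out[g, s] <- if (length(top) == 1L && top != "normal") top else "normal"
    }
  }
  out
}

# hand-coded quartile at position p*(n-1) with linear interpolation
hand_quantile <- function(x, p) {
  x <- sort(x)
  h <- p * (length(x) - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - (lo - 1)) * (x[hi] - x[lo])
}

# double-loop reimplementation of the concordant-alteration rule:
# altered_loss iff status lost and expression strictly under Q1 of the
# copy-normal group (>= min_controls members), altered_gain iff gained and
# strictly above Q3; not_evaluable when the control group is too small or
# expression is missing
oracle_alterations <- function(status, expr, min_controls) {
  out <- matrix(NA_character_, nrow(status), ncol(status),
                dimnames = dimnames(status))
  for (g in rownames(status)) {
    ev <- if (g %in% rownames(expr)) expr[g, colnames(status)] else
      rep(NA_real_, ncol(status))
    ctrl <- ev[status[g, ] == "normal"]
    ctrl <- ctrl[!is.na(ctrl)]
    ok <- length(ctrl) >= min_controls
    q1 <- if (ok) hand_quantile(ctrl, 0.25) else NA
    q3 <- if (ok) hand_quantile(ctrl, 0.75) else NA
    for (j in seq_len(ncol(status))) {
      s <- status[g, j]; e <- ev[j]
      out[g, j] <-
        if (!ok || is.na(e)) "not_evaluable"
        else if (s == "lost" && e < q1) "altered_loss"
        else if (s == "gained" && e > q3) "altered_gain"
        else "not_altered"
    }
  }
  out
}

# nested-loop pathway flagging and universal selection
oracle_flags <- function(sets, alt) {
  out <- matrix(FALSE, length(sets), ncol(alt),
                dimnames = list(names(sets), colnames(alt)))
  for (p in names(sets)) for (s in colnames(alt)) {
    for (g in intersect(sets[[p]], rownames(alt)))
      if (alt[g, s] %in% c("altered_loss", "altered_gain")) {
        out[p, s] <- TRUE
        break
      }
  }
  out
}

# per-event-time O/E/V accumulation for the two-group log-rank statistic
oracle_logrank <- function(times, events, groups) {
  g <- factor(groups)
  o1 <- e1 <- v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n1 <- sum(at_risk & g == levels(g)[1])
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == levels(g)[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(statistic = (o1 - e1)^2 / v, o1 = o1, e1 = e1)
}

# small in-memory cohort pieces used by several files
make_status <- function(genes, samples, values) {
  matrix(values, length(genes), length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

random_status <- function(n_genes, n_samples, p_alt = 0.3) {
  st <- matrix(sample(c("lost", "gained", "normal"), n_genes * n_samples,
                      replace = TRUE, prob = c(p_alt / 2, p_alt / 2, 1 - p_alt)),
               n_genes, n_samples,
               dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                               sprintf("s%03d", seq_len(n_samples))))
  st
}

random_rep_expr <- function(status) {
  vals <- matrix(rnorm(length(status), 8, 1), nrow(status), ncol(status),
                 dimnames = dimnames(status))
  info <- data.frame(gene_id = rownames(status),
                     probe_id = paste0("p_", rownames(status)),
                     iqr = apply(vals, 1, function(v) diff(quantile(v, c(.25, .75)))),
                     stringsAsFactors = FALSE)
  structure(list(info = info, values = vals),
            class = "representative_expression")
}

make_expr_table <- function(probe_id, gene_id, values) {
  expression_table(data.frame(probe_id = probe_id, gene_id = gene_id,
                              stringsAsFactors = FALSE), values)
}
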