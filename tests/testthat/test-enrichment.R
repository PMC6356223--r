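# Fisher exact / chi-squared association, gene and pathway subgroup
# enrichment, and the two-condition candidate-driver call.

test_that("Fisher exact p matches hypergeometric enumeration on hand tables", {
  # margins (3,3,3,3): extreme tables carry 1/20 each, two-sided p = 0.1
  ft <- fisher_exact_2x2(3, 0, 0, 3)
  expect_equal(ft$p, 0.1, tolerance = 1e-12)
  expect_equal(ft$p, oracle_fisher_p(3, 0, 0, 3), tolerance = 1e-12)
  expect_identical(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  expect_identical(ft$odds_ratio_sample, Inf)
  expect_true(is.nan(fisher_exact_2x2(3, 0, 0, 0)$odds_ratio_sample))
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(1.5, 0, 0, 1), "non-negative integers")
})

test_that("Fisher p is invariant under transposition and monotone in |a - E[a]|", {
  set.seed(3)
  for (i in 1:20) {
    t_ <- sample(0:9, 4, replace = TRUE)
    if (sum(t_) == 0) next
    expect_equal(fisher_exact_2x2(t_[1], t_[2], t_[3], t_[4])$p,
                 fisher_exact_2x2(t_[1], t_[3], t_[2], t_[4])$p,
                 tolerance = 1e-12)
  }
  # fixed margins (6,6,6,6): p non-increasing as a moves away from E[a] = 3
  ps <- vapply(3:6, function(a) fisher_exact_2x2(a, 6 - a, 6 - a, a)$p, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("chi-squared equals the hand-computed sum of (O-E)^2/E", {
  expect_equal(chi2_association(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi2_association(10, 10, 10, 10)$p, 1)
  o <- c(20, 12, 25, 49)
  n <- sum(o)
  e <- c((20 + 12) * (20 + 25), (20 + 12) * (12 + 49),
         (25 + 49) * (20 + 25), (25 + 49) * (12 + 49)) / n
  expect_equal(chi2_association(20, 12, 25, 49, yates = FALSE)$statistic,
               sum((o - e)^2 / e))
  # invariant under simultaneous row and column swap
  expect_equal(chi2_association(20, 12, 25, 49)$statistic,
               chi2_association(49, 25, 12, 20)$statistic)
  expect_error(chi2_association(0, 0, 5, 5), "positive margins")
})

test_that("gene enrichment builds the right 2x2, drops unevaluable cells, adjusts by BH", {
  samples <- sprintf("s%02d", 1:20)
  clinical <- validate_clinical(data.frame(
    sample_id = samples, metastasis = rep(c(TRUE, FALSE), each = 10),
    mfs_time = 1, event = 0L))
  alt <- matrix("not_altered", 3, 20, dimnames = list(c("gA", "gB", "gC"), samples))
  alt["gA", 1:8] <- "altered_loss"          # 8/10 metastatic vs 0/10 rest
  alt["gB", c(1, 11)] <- "altered_gain"     # balanced
  alt["gC", 19:20] <- "not_evaluable"       # shrinks its table to 18
  res <- gene_subgroup_enrichment(alt, clinical)
  rA <- res[res$unit_id == "gA", ]
  expect_equal(c(rA$a, rA$b, rA$c, rA$d), c(8, 0, 2, 10))
  expect_identical(rA$direction, "enriched_in_subgroup")
  expect_equal(rA$p_fisher, oracle_fisher_p(8, 0, 2, 10), tolerance = 1e-12)
  expect_identical(rA$alteration_type, "loss")
  rC <- res[res$unit_id == "gC", ]
  expect_equal(rC$a + rC$b + rC$c + rC$d, 18)
  # a gene altered in nobody is neutral with p = 1
  rNobody <- res[res$unit_id == "gC", ]
  expect_identical(rNobody$direction, "neutral")
  expect_identical(rNobody$p_fisher, 1)
  # BH: adjusted >= raw, monotone in rank
  expect_true(all(res$p_adjusted >= res$p_fisher - 1e-15))
  expect_equal(res$p_adjusted, p.adjust(res$p_fisher, "BH"))
  expect_error(gene_subgroup_enrichment(alt, clinical, subgroup = "histotype"),
               "NA for some samples")
})

test_that("candidate drivers need both the gene and one of its pathways to pass", {
  mk_res <- function(ids, p, dir) {
    data.frame(unit_id = ids, p_fisher = p, p_adjusted = pmin(1, p * 2),
               direction = dir, alteration_type = "loss",
               stringsAsFactors = FALSE)
  }
  genes <- mk_res(c("g1", "g2", "g3"), c(0.01, 0.2, 0.03),
                  c("enriched_in_subgroup", "enriched_in_subgroup",
                    "depleted_in_subgroup"))
  paths <- mk_res(c("P1", "P2"), c(0.02, 0.5),
                  c("enriched_in_subgroup", "enriched_in_subgroup"))
  cat_ <- pathway_catalog(list(P1 = c("g1", "g3"), P2 = c("g2"),
                               P3 = c("g1")))
  out <- select_candidate_drivers(genes, paths, cat_)
  # g1: gene passes and P1 passes -> in. g2: gene fails (p). g3: wrong
  # direction despite P1 passing.
  expect_identical(out$gene_id, "g1")
  expect_identical(out$pathways, "P1")
  # gene passing but only in non-passing pathways -> excluded
  cat2 <- pathway_catalog(list(P2 = c("g1", "g2")))
  expect_identical(nrow(select_candidate_drivers(genes, paths, cat2)), 0L)
  # selection on adjusted p is stricter here
  out_adj <- select_candidate_drivers(genes, paths, cat_, alpha = 0.03,
                                      use_adjusted = TRUE)
  expect_identical(nrow(out_adj), 0L)
})

test_that("the planted driver enriches in the metastatic subgroup of a synthetic cohort", {
  hits <- 0L
  for (seed in 1:5) {
    sim <- simulate_cohort(sim_config(
      seed = seed, n_samples = 120, n_metastatic = 36, n_genes = 300,
      n_pathways = 20, driver_loss_freq_metastatic = 0.6,
      driver_loss_freq_nonmetastatic = 0.3, n_decoy_probes = 10))
    scr <- driver_screen(sim$bundle)
    r <- scr$gene_enrichment
    row <- r[r$unit_id == sim$truth$driver_gene, ]
    if (nrow(row) == 1 && row$direction == "enriched_in_subgroup" &&
        row$p_fisher < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
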