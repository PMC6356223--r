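# Probe thresholding, the four exclusion rules, and probe-to-gene
# status aggregation.

mk_table <- function(probes, values, controls = character()) {
  probe_cnv_table(probes, values, type = "auto", controls = controls)
}

ten_probe_fixture <- function() {
  # 2 in a constitutional region, 1 on chrY, 1 intergenic, 1 loss in a
  # control, 5 clean
  probes <- data.frame(
    probe_id = sprintf("p%02d", 1:10),
    chrom = c("chr1", "chr1", "chr2", "chr3", "chrY", "chr4", "chr5",
              "chr6", "chr7", "chr8"),
    start = c(100L, 150L, 10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L),
    end   = c(120L, 170L, 30L, 30L, 30L, 30L, 30L, 30L, 30L, 30L),
    stringsAsFactors = FALSE)
  probes$gene_ids <- c(list("gA"), list("gB"), list("gC"), list("gD"),
                       list("gE"), list(character()), list("gF"),
                       list("gG"), list(c("gH", "gI")), list("gJ"))
  vals <- matrix("normal", 10, 3,
                 dimnames = list(probes$probe_id, c("s1", "s2", "ctrl")))
  vals["p07", "ctrl"] <- "loss"
  vals["p03", "s1"] <- "gain"
  list(table = mk_table(probes, vals, controls = "ctrl"),
       constitutional = data.frame(chrom = "chr1", start = 110L, end = 160L))
}

test_that("log-ratio thresholding matches elementwise re-thresholding", {
  set.seed(11)
  probes <- data.frame(probe_id = sprintf("p%03d", 1:60), chrom = "chr1",
                       start = seq(0L, by = 100L, length.out = 60),
                       end = seq(50L, by = 100L, length.out = 60),
                       stringsAsFactors = FALSE)
  probes$gene_ids <- as.list(sprintf("g%03d", 1:60))
  lr <- matrix(rnorm(60 * 8, 0, 0.4), 60, 8,
               dimnames = list(probes$probe_id, sprintf("s%d", 1:8)))
  tab <- mk_table(probes, lr)
  st <- threshold_logratio_probes(tab, gain_cut = 0.2, loss_cut = -0.2)
  manual <- ifelse(lr > 0.2, "gain", ifelse(lr < -0.2, "loss", "normal"))
  expect_identical(st$values, manual)
  expect_identical(st$values["p001", 1][[1]],
                   if (lr[1, 1] > 0.2) "gain" else if (lr[1, 1] < -0.2) "loss"
                   else "normal")
  expect_error(threshold_logratio_probes(tab, gain_cut = -0.1, loss_cut = -0.2),
               "loss_cut < 0 < gain_cut")
})

test_that("the four exclusion rules remove the expected probes, in order", {
  fx <- ten_probe_fixture()
  out <- filter_probes(fx$table, constitutional = fx$constitutional)
  expect_identical(attr(out, "removal_counts"),
                   c(constitutional = 2L, sex_chromosome = 1L,
                     intergenic = 1L, control_altered = 1L))
  expect_identical(out$probes$probe_id,
                   c("p03", "p04", "p08", "p09", "p10"))
})

test_that("filtering outcome is order-insensitive (rule independence)", {
  # each rule flags probes by an intrinsic property, so applying any single
  # rule after the full filter removes nothing more
  fx <- ten_probe_fixture()
  full <- filter_probes(fx$table, constitutional = fx$constitutional)
  again <- filter_probes(full, constitutional = fx$constitutional)
  expect_identical(full$probes$probe_id, again$probes$probe_id)
  expect_true(all(attr(again, "removal_counts") == 0L))
})

test_that("sex-chromosome naming is normalized and empty survival errors", {
  fx <- ten_probe_fixture()
  out <- filter_probes(fx$table, sex_chroms = c("X", "Y"))
  expect_false("p05" %in% out$probes$probe_id)
  expect_error(
    filter_probes(fx$table,
                  constitutional = data.frame(chrom = paste0("chr", 1:22),
                                              start = 0L, end = 10e6L)),
    "no probe survives")
})

test_that("gene status follows strict plurality with ties to normal", {
  mk_gene <- function(states) {
    n <- length(states)
    probes <- data.frame(probe_id = sprintf("p%d", 1:n), chrom = "chr1",
                         start = seq_len(n) * 10L,
                         end = seq_len(n) * 10L + 5L, stringsAsFactors = FALSE)
    probes$gene_ids <- rep(list("g"), n)
    mk_table(probes, matrix(states, n, 1, dimnames = list(probes$probe_id, "s")))
  }
  expect_identical(aggregate_gene_status(mk_gene(c("normal", "normal", "normal")))["g", "s"],
                   "normal")
  expect_identical(aggregate_gene_status(mk_gene(c("loss", "loss", "normal")))["g", "s"],
                   "lost")
  # ties: aberrant/aberrant, aberrant/normal -> normal
  expect_identical(aggregate_gene_status(mk_gene(c("loss", "gain")))["g", "s"],
                   "normal")
  expect_identical(aggregate_gene_status(mk_gene(c("loss", "normal")))["g", "s"],
                   "normal")
  expect_identical(aggregate_gene_status(mk_gene(c("gain", "gain", "loss")))["g", "s"],
                   "gained")
})

test_that("aggregation equals an independent vote counter on random instances", {
  set.seed(23)
  for (rep in 1:3) {
    n_probes <- 150
    samples <- sprintf("s%02d", 1:10)
    genes <- sprintf("g%02d", 1:50)
    gene_of_probe <- lapply(seq_len(n_probes), function(i) {
      k <- sample(1:2, 1, prob = c(0.9, 0.1)) # some multi-gene probes
      sample(genes, k)
    })
    probes <- data.frame(probe_id = sprintf("p%03d", 1:n_probes),
                         chrom = "chr1", start = (1:n_probes) * 100L,
                         end = (1:n_probes) * 100L + 25L,
                         stringsAsFactors = FALSE)
    probes$gene_ids <- gene_of_probe
    vals <- matrix(sample(c("loss", "normal", "gain"), n_probes * 10,
                          replace = TRUE, prob = c(0.3, 0.5, 0.2)),
                   n_probes, 10, dimnames = list(probes$probe_id, samples))
    tab <- mk_table(probes, vals)
    got <- aggregate_gene_status(tab)
    want <- oracle_gene_status(vals, gene_of_probe, samples)
    expect_identical(got[rownames(want), colnames(want)], want)
  }
})

test_that("aggregation is invariant under probe order and respects consensus", {
  set.seed(31)
  n <- 40
  probes <- data.frame(probe_id = sprintf("p%02d", 1:n), chrom = "chr1",
                       start = (1:n) * 10L, end = (1:n) * 10L + 5L,
                       stringsAsFactors = FALSE)
  probes$gene_ids <- as.list(sample(sprintf("g%d", 1:10), n, replace = TRUE))
  vals <- matrix(sample(c("loss", "normal", "gain"), n * 6, replace = TRUE),
                 n, 6, dimnames = list(probes$probe_id, sprintf("s%d", 1:6)))
  tab <- mk_table(probes, vals)
  perm <- sample(n)
  tab2 <- mk_table(probes[perm, ], vals[perm, ])
  s1 <- aggregate_gene_status(tab)
  s2 <- aggregate_gene_status(tab2)
  expect_identical(s1, s2)
  # consensus consistency: unanimous probes fix the status
  uni <- probes
  uni$gene_ids <- rep(list("gU"), n)
  vuni <- matrix("loss", n, 6, dimnames = dimnames(vals))
  expect_true(all(aggregate_gene_status(mk_table(uni, vuni))["gU", ] == "lost"))
})
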