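# IQRmax probe selection, copy-normal control quartiles and the
# concordant alteration call.

test_that("the representative probe maximizes the IQR, ties to smallest id", {
  vals <- rbind(pA = c(1, 2, 3, 4, 5),
                pB = c(3, 3, 3, 3, 3),
                pC = c(2, 2, 5, 5, 5),  # gene h, IQR 3
                pD = c(10, 10, 13, 13, 13)) # gene h, same IQR, larger id
  colnames(vals) <- sprintf("s%d", 1:5)
  expr <- make_expr_table(rownames(vals), c("g", "g", "h", "h"), vals)
  rep_ <- select_representative_probes(expr)
  # probe A: Q1 = 2, Q3 = 4, IQR = 2 beats probe B's 0
  expect_identical(rep_$info$probe_id[rep_$info$gene_id == "g"], "pA")
  expect_equal(rep_$info$iqr[rep_$info$gene_id == "g"], 2)
  expect_identical(rep_$info$probe_id[rep_$info$gene_id == "h"], "pC")
  # single-probe genes return that probe; absent genes error
  expect_identical(select_representative_probes(expr, genes = "h")$info$probe_id, "pC")
  expect_error(select_representative_probes(expr, genes = "nope"), "absent")
})

test_that("control quartiles follow the p*(n-1) convention and the n>=30 rule", {
  samples <- sprintf("s%02d", 1:40)
  status <- make_status("g1", samples,
                        c(rep("normal", 30), rep("lost", 10)))
  vals <- matrix(NA_real_, 1, 40, dimnames = list("g1", samples))
  vals[1, 1:30] <- 1:30
  vals[1, 31:40] <- 0
  rep_ <- structure(list(info = data.frame(gene_id = "g1", probe_id = "p1",
                                           iqr = 1),
                         values = vals),
                    class = "representative_expression")
  st <- compute_control_stats(rep_, status, min_controls = 30)
  expect_equal(st$q1, 8.25)
  expect_equal(st$q3, 22.75)
  expect_true(st$defined)
  expect_identical(st$n_controls, 30L)
  # one control fewer than the floor -> undefined
  status2 <- status; status2[1, 30] <- "lost"
  st2 <- compute_control_stats(rep_, status2, min_controls = 30)
  expect_false(st2$defined)
  expect_true(is.na(st2$q1))
  # constant control values collapse the quartiles
  vals[1, 1:30] <- 7
  rep_$values <- vals
  st3 <- compute_control_stats(rep_, status, min_controls = 30)
  expect_equal(st3$q1, 7)
  expect_equal(st3$q3, 7)
})

test_that("alteration calls are strict at the quartiles and gated by status", {
  samples <- sprintf("s%02d", 1:36)
  status <- make_status("g1", samples,
                        c(rep("normal", 30), "lost", "lost", "lost",
                          "gained", "gained", "gained"))
  vals <- matrix(0, 1, 36, dimnames = list("g1", samples))
  vals[1, 1:30] <- 1:30           # q1 = 8.25, q3 = 22.75
  vals[1, 31:36] <- c(5, 8.25, 20, 25, 22.75, 10)
  rep_ <- structure(list(info = data.frame(gene_id = "g1", probe_id = "p1",
                                           iqr = 1), values = vals),
                    class = "representative_expression")
  st <- compute_control_stats(rep_, status, min_controls = 30)
  alt <- call_alterations(status, rep_, st)
  expect_identical(unname(alt[1, 31:36]),
                   c("altered_loss",   # lost, 5 < 8.25
                     "not_altered",    # lost, exactly q1: strict
                     "not_altered",    # lost but expression not low
                     "altered_gain",   # gained, 25 > 22.75
                     "not_altered",    # gained, exactly q3: strict
                     "not_altered"))   # gained but expression not high
  # copy-normal samples are never altered, whatever the expression
  expect_true(all(alt[1, 1:30] == "not_altered"))
  # inclusive boundary flips exactly the boundary cells
  alt_inc <- call_alterations(status, rep_, st, boundary = "inclusive")
  expect_identical(unname(alt_inc[1, c(32, 35)]),
                   c("altered_loss", "altered_gain"))
})

test_that("full alteration calling equals the double-loop rule on random instances", {
  set.seed(71)
  for (rep_i in 1:5) {
    status <- random_status(60, 50)
    rep_ <- random_rep_expr(status)
    # drop one gene's expression entirely: must become not_evaluable
    rep_$values <- rep_$values[-5, , drop = FALSE]
    st <- compute_control_stats(rep_, status, min_controls = 15)
    got <- call_alterations(status, rep_, st)
    want <- oracle_alterations(status, rep_$values, min_controls = 15)
    expect_identical(got, want)
  }
})

test_that("control-group leakage cannot occur and quartile moves are monotone", {
  set.seed(97)
  status <- random_status(40, 60, p_alt = 0.4)
  rep_ <- random_rep_expr(status)
  st <- compute_control_stats(rep_, status, min_controls = 10)
  # leakage check: recompute quartiles from copy-normal samples only
  for (g in sample(rownames(status), 10)) {
    ctrl <- rep_$values[g, status[g, ] == "normal"]
    row <- st[st$gene_id == g, ]
    if (row$defined) {
      expect_equal(row$q1, unname(quantile(ctrl, 0.25, type = 7)))
      expect_equal(row$q3, unname(quantile(ctrl, 0.75, type = 7)))
    } else expect_lt(length(ctrl), 10)
  }
  alt <- call_alterations(status, rep_, st)
  # lowering q1 / raising q3 can only shrink the altered sets
  st_tight <- st
  st_tight$q1 <- st$q1 - 0.5
  st_tight$q3 <- st$q3 + 0.5
  alt_tight <- call_alterations(status, rep_, st_tight)
  expect_true(all(alt[alt_tight == "altered_loss"] == "altered_loss"))
  expect_true(all(alt[alt_tight == "altered_gain"] == "altered_gain"))
})

test_that("alteration load counts cells and splits directions", {
  alt <- matrix("not_altered", 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  load0 <- alteration_load(alt)
  expect_equal(unname(load0$per_sample), c(0, 0))
  expect_true(is.na(load0$gain_fraction))
  alt[, "s1"] <- c("altered_loss", "altered_loss", "altered_gain")
  alt["g1", "s2"] <- "altered_loss"
  load1 <- alteration_load(alt)
  expect_equal(unname(load1$per_sample), c(3, 1))
  expect_equal(load1$loss_fraction, 0.75)
  expect_equal(load1$gain_fraction, 0.25)
})
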