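# Density-intersection dichotomization, Kaplan-Meier, log-rank and the
# metastasis-free-survival comparison.

test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(5, 8), c(0, 0))
  expect_true(all(km0$surv == 1))
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(km$n_risk, c(3, 2, 1))
  # ties: deaths counted before censorings at the same time
  kmt <- km_estimate(c(2, 2, 4), c(1, 0, 1))
  expect_equal(kmt$surv[kmt$time == 2], 2 / 3)
  expect_equal(kmt$surv[kmt$time == 4], 2 / 3 * 0)
  # with no censoring the estimator is the empirical survival function
  set.seed(4)
  t_ <- round(rexp(40, 0.1), 3)
  kme <- km_estimate(t_, rep(1, 40))
  for (i in seq_len(nrow(kme)))
    expect_equal(kme$surv[i], mean(t_ > kme$time[i]))
  expect_true(all(diff(kme$surv) <= 0) && kme$surv[1] <= 1)
  expect_error(km_estimate(numeric(), integer()), "empty")
})

test_that("log-rank agrees with per-event-time O/E/V accumulation", {
  # duplicated groups: no difference whatsoever
  t_ <- c(1, 3, 5, 7)
  e <- c(1, 0, 1, 1)
  lr0 <- logrank_and_hr(c(t_, t_), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)
  expect_equal(lr0$hazard_ratio, 1)
  # 6-subject fixture against the independent accumulation
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 0, 1, 1, 0)
  groups <- c("g1", "g1", "g1", "g2", "g2", "g2")
  lr <- logrank_and_hr(times, events, groups)
  want <- oracle_logrank(times, events, groups)
  expect_equal(lr$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(unname(lr$observed["g1"]), want$o1)
  expect_equal(unname(lr$expected["g1"]), want$e1, tolerance = 1e-12)
  o2 <- sum(events) - want$o1
  e2 <- sum(events) - want$e1
  expect_equal(lr$hazard_ratio, (want$o1 / want$e1) / (o2 / e2))
  # relabeling the groups flips the HR but not the test
  lr_sw <- logrank_and_hr(times, events, rev(groups))
  expect_equal(lr_sw$statistic, lr$statistic)
  expect_equal(lr_sw$p, lr$p)
  expect_error(logrank_and_hr(times, events, rep("g1", 6)), "two groups")
})

test_that("density intersection finds the equal-variance midpoint", {
  set.seed(19)
  a <- rnorm(2000, 0, 1)
  b <- rnorm(2000, 2, 1)
  thr <- density_intersection_threshold(a, b)
  expect_identical(thr$method, "density_intersection")
  expect_lt(abs(thr$threshold - 1), 0.05)
  # threshold lies inside the observed range and between the medians
  expect_gt(thr$threshold, median(a))
  expect_lt(thr$threshold, median(b))
  # the density difference changes sign across the chosen crossing
  g <- thr$grid
  i <- findInterval(thr$threshold, g$x)
  expect_lt((g$f_a[i] - g$f_b[i]) * (g$f_a[i + 1] - g$f_b[i + 1]), 0)
})

test_that("with several in-window crossings the one nearest the median midpoint wins", {
  set.seed(29)
  a <- c(rnorm(600, 0, 0.5), rnorm(400, 3, 0.5))
  b <- c(rnorm(400, 1.5, 0.4), rnorm(600, 4, 0.4))
  thr <- density_intersection_threshold(a, b)
  expect_gte(length(thr$crossings), 2)
  # independent 10x-resolution scan with the same bandwidths
  bw_a <- bw.nrd0(a); bw_b <- bw.nrd0(b)
  pad <- 3 * bw.nrd0(c(a, b))
  xs <- seq(min(c(a, b)) - pad, max(c(a, b)) + pad, length.out = 10240)
  fa <- vapply(xs, function(x) mean(dnorm((x - a) / bw_a)) / bw_a, 0)
  fb <- vapply(xs, function(x) mean(dnorm((x - b) / bw_b)) / bw_b, 0)
  d <- fa - fb
  i <- which(d[-length(d)] * d[-1] < 0)
  cross <- xs[i] + d[i] * (xs[i + 1] - xs[i]) / (d[i] - d[i + 1])
  med <- sort(c(median(a), median(b)))
  cross <- cross[cross > med[1] & cross < med[2]]
  want <- cross[which.min(abs(cross - mean(med)))]
  expect_equal(thr$threshold, want, tolerance = 5e-3)
})

test_that("degenerate groups fall back with a warning", {
  expect_warning(thr <- density_intersection_threshold(rep(1, 20), rnorm(20, 3)),
                 "zero-variance")
  expect_identical(thr$method, "midpoint_means")
  set.seed(37)
  x <- rnorm(200)
  expect_warning(thr2 <- density_intersection_threshold(x, x + 1e-9),
                 "pooled mean")
  expect_identical(thr2$method, "pooled_mean")
  expect_equal(thr2$threshold, mean(c(x, x + 1e-9)))
})

test_that("dichotomization is strict below the threshold", {
  v <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 6)
  lab <- dichotomize(v, method = "mean") # mean = 3; the boundary sample is high
  expect_identical(as.vector(lab), c("low", "low", "high", "high"))
  expect_equal(attr(lab, "threshold"), 3)
  expect_warning(lab2 <- dichotomize(v, method = "fixed", threshold = 0.5),
                 "one side")
  expect_true(all(lab2 == "high"))
  set.seed(41)
  x <- rnorm(50)
  lab3 <- dichotomize(x, method = "fixed", threshold = 0.2)
  expect_identical(as.vector(lab3), ifelse(x < 0.2, "low", "high"))
})

test_that("MFS analysis subsets, excludes and stratifies correctly", {
  sim <- simulate_cohort(sim_config(seed = 57, n_samples = 150,
                                    n_metastatic = 50, n_genes = 120,
                                    n_pathways = 10, met_at_dx_fraction = 0.2,
                                    chemo_na_fraction = 0))
  drv <- sim$truth$driver_gene
  fit <- mfs_analysis(sim$bundle, drv)
  n_flagged <- sum(sim$bundle$clinical$metastatic_at_diagnosis)
  expect_gt(n_flagged, 0)
  fit_all <- mfs_analysis(sim$bundle, drv,
                          exclude_metastatic_at_diagnosis = FALSE)
  expect_identical(fit_all$n - fit$n, n_flagged)
  expect_identical(sum(fit$group_sizes), fit$n)
  # chemo subsets partition the (non-flagged) patients
  fit_c <- mfs_analysis(sim$bundle, drv, subset = "chemo")
  fit_nc <- mfs_analysis(sim$bundle, drv, subset = "no_chemo")
  expect_identical(fit_c$n + fit_nc$n, fit$n)
  # all-unknown chemotherapy is a hard error naming the column
  b2 <- sim$bundle
  b2$clinical$chemotherapy <- NA
  expect_error(mfs_analysis(b2, drv, subset = "chemo"), "chemotherapy")
  # driver-low patients do worse by construction
  expect_gt(fit$logrank$hazard_ratio, 1)
})
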