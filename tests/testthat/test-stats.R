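# Group-comparison statistics: factorial ANOVA, Bonferroni, Grubbs,
# Kaplan-Meier / log-rank, the gene-retention filter and qPCR fold changes.

make_2x2 <- function(values) {
  data.frame(value = values,
             genotype = rep(c("WT", "R6/2"), each = 6),
             treatment = rep(rep(c("vehicle", "ACVR2B/Fc"), each = 3), 2))
}

test_that("balanced two-way ANOVA matches the closed form to 1e-10", {
  set.seed(2)
  d <- make_2x2(round(rnorm(12, 20, 4), 2))
  res <- two_way_anova(d)
  oracle <- balanced_anova_oracle(d$value, d$genotype, d$treatment)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$sum_sq, oracle$ss, tolerance = 1e-10)
  expect_identical(res$df1, oracle$df)
  expect_true(all(res$df2 == oracle$df_error))
  # exact SS partition in the balanced case
  expect_equal(sum(res$sum_sq) + oracle$ss_error, oracle$ss_total,
               tolerance = 1e-10)
  # invariance to factor-level relabelling
  d2 <- d
  d2$genotype <- factor(d$genotype, levels = c("WT", "R6/2"),
                        labels = c("B", "A"))
  expect_equal(two_way_anova(d2)$F, res$F, tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs behave: constant data, empty cells", {
  d <- make_2x2(rep(7, 12))
  res <- two_way_anova(d)
  expect_true(all(res$F == 0) && all(res$p == 1))
  d_missing <- subset(make_2x2(rnorm(12)),
                      !(genotype == "WT" & treatment == "vehicle"))
  expect_error(two_way_anova(d_missing), "WT.*vehicle|vehicle.*WT")
})

test_that("ANOVA p-values are uniform under a permutation null", {
  set.seed(99)
  d <- make_2x2(rnorm(12))
  p <- replicate(1000, {
    d$value <- sample(d$value)
    two_way_anova(d)$p[1]
  })
  # permutation p-values are mildly discrete; ties only warn in ks.test
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.03, m = 1), 0.03)
  expect_equal(bonferroni_adjust(0.03, m = 4), 0.12)
  expect_equal(bonferroni_adjust(0.4, m = 5), 1)
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_true(all(diff(bonferroni_adjust(p)) >= 0))  # monotone in p
  set.seed(1)
  d <- make_2x2(rnorm(12, rep(c(10, 30), each = 6)))
  ph <- bonferroni_posthoc(d, list(c("WT:vehicle", "R6/2:vehicle"),
                                   c("WT:vehicle", "WT:ACVR2B/Fc")))
  expect_equal(ph$p_adj, pmin(1, 2 * ph$p))
})

test_that("Grubbs flags a planted outlier via the closed-form critical value", {
  x <- c(1, 1, 1, 1, 100)
  expect_identical(grubbs_test(x, 0.05), 5L)
  # oracle: G statistic against the t-quantile closed form, computed here
  g <- max(abs(x - mean(x))) / sd(x)
  n <- length(x)
  tq <- qt(0.05 / (2 * n), n - 2, lower.tail = FALSE)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  expect_gt(g, crit)
  expect_length(grubbs_test(c(3, 3, 3, 3)), 0L)      # all equal: none
  expect_error(grubbs_test(c(1, 2)), "at least 3")
  # iterative removal returns original indices in removal order; the
  # extreme value is removed first, unmasking the second outlier
  y <- c(10, 10.2, 9.9, 10.1, 9.8, 30, 100)
  flagged <- grubbs_test(y, 0.05)
  expect_identical(flagged, c(7L, 6L))
  # clean Gaussian data: rarely flags (not asserted per-sample), sanity on n
  set.seed(3)
  clean <- rnorm(20)
  expect_lte(length(grubbs_test(clean)), 2L)
})

test_that("log-rank chi-square is 0 for identical groups and matches a hand table", {
  base <- data.frame(time = c(10, 12, 15, 20, 30), event = c(1, 1, 0, 1, 1))
  dup <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  res <- km_logrank(dup)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  # textbook two-group fixture, O - E tabulated by the oracle
  d <- data.frame(
    time = c(6, 6, 6, 7, 10, 13, 16, 22, 23, 6, 9, 10, 11, 17, 19, 20, 25, 32),
    event = c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 0, 1, 0, 0, 0, 1, 1, 1),
    group = rep(c("ctrl", "drug"), c(9, 9)))
  res2 <- km_logrank(d)
  expect_equal(res2$chisq, logrank_oracle(d$time, d$event, d$group),
               tolerance = 1e-10)
  # symmetric under group swap
  d_swap <- d; d_swap$group <- ifelse(d$group == "ctrl", "drug", "ctrl")
  expect_equal(km_logrank(d_swap)$chisq, res2$chisq, tolerance = 1e-12)
  expect_error(km_logrank(data.frame(time = 1:4, event = 0,
                                     group = rep(c("a", "b"), 2))),
               "no events")
})

test_that("Kaplan-Meier estimator equals the product-limit brute force", {
  d <- simulate_survival(30, c(a = 0.05, b = 0.02), censor_time = 60,
                         seed = 8)
  res <- km_logrank(d)
  fit <- res$fit
  for (g in c("a", "b")) {
    sub <- d[d$group == g, ]
    oracle <- km_oracle(sub$time, sub$event)
    idx <- which(rep(names(fit$strata), fit$strata) ==
                   paste0("group=", g))
    surv_g <- fit$surv[idx]; time_g <- fit$time[idx]
    at_events <- match(oracle$time, time_g)
    expect_equal(surv_g[at_events], oracle$surv, tolerance = 1e-12)
  }
  # right-continuous, starts at 1: survival at time 0- is 1
  expect_true(all(fit$surv <= 1))
})

test_that("log-rank detects a hazard ratio of 3 with high power", {
  set.seed(55)
  rej <- replicate(200, {
    d <- simulate_survival(50, c(a = 0.03, b = 0.09), censor_time = Inf)
    km_logrank(d)$p.value < 0.05
  })
  expect_gt(mean(rej), 0.8)
})

test_that("the gene filter applies the boundary rule and is idempotent", {
  m <- matrix(0L, 3, 79,
              dimnames = list(c("boundary", "low", "high"), NULL))
  m["boundary", 1:10] <- 2L          # count 2 in exactly 10 samples: kept
  m["low", ] <- 1L                   # never reaches 2: dropped
  m["high", ] <- 50L
  expect_identical(gene_filter(m), c("boundary", "high"))
  m2 <- m; m2["boundary", 10] <- 0L  # now only 9 qualifying samples
  expect_identical(gene_filter(m2), "high")
  expect_length(gene_filter(matrix(0L, 5, 79)), 0L)
  # idempotent; retained count monotone non-increasing in both parameters
  kept <- gene_filter(m)
  expect_identical(gene_filter(m[kept, , drop = FALSE]), kept)
  set.seed(10)
  mm <- simulate_counts(300, 79, 0.5)
  for (mc in c(2, 5, 20))
    for (msamp in c(5, 10, 40)) {
      n1 <- length(gene_filter(mm, mc, msamp))
      expect_lte(length(gene_filter(mm, mc + 1, msamp)), n1)
      expect_lte(length(gene_filter(mm, mc, msamp + 5)), n1)
    }
})

test_that("qPCR fold changes normalize by the housekeeping geometric mean", {
  hk <- matrix(rep(c(100, 200, 400), each = 8), ncol = 3)
  target <- c(rep(10, 4), rep(20, 4))
  group <- rep(c("WT", "R62"), each = 4)
  fc <- qpcr_fold_change(target, hk, group, reference = "WT")
  expect_equal(unname(fc["R62"]), 2)
  expect_equal(unname(fc["WT"]), 1)
  # doubling target and all housekeeping genes cancels out
  fc2 <- qpcr_fold_change(c(rep(10, 4), rep(20, 4)),
                          rbind(hk[1:4, ], hk[5:8, ] * 2),
                          c(rep("WT", 4), rep("R62", 4)), "WT")
  expect_equal(unname(fc2["R62"]), 1)
  expect_error(qpcr_fold_change(c(0, target[-1]), hk, group, "WT"),
               "positive")
  expect_error(qpcr_fold_change(target, hk[, 1:2], group, "WT"), "three")
})
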