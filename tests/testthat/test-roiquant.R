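# ROI quantification: threshold semantics, labeling, debris filtering,
# signal partition, inclusion classification and the per-ROI summary.

test_that("threshold keeps the boundary intensity and excludes below", {
  img89 <- matrix(89L, 8, 8)
  img90 <- matrix(90L, 8, 8)
  expect_false(any(threshold_channel(img89, 90)))
  expect_true(all(threshold_channel(img90, 90)))
  expect_true(all(threshold_channel(img89, 0)))
  expect_error(threshold_channel(img89, 300), "threshold")
})

test_that("labeling respects the configured connectivity", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(nrow(label_objects(m, 8L)$objects), 1L)
  expect_identical(nrow(label_objects(m, 4L)$objects), 2L)
  empty <- label_objects(matrix(FALSE, 4, 4))
  expect_identical(nrow(empty$objects), 0L)
})

test_that("labeled objects partition the foreground", {
  set.seed(42)
  for (conn in c(4L, 8L)) {
    mask <- matrix(runif(64 * 64) < 0.4, 64, 64)
    obj <- label_objects(mask, conn)
    expect_identical(sum(obj$objects$n_pixels), sum(mask))
    expect_identical(sort(unlist(obj$pixels)), which(mask))
    # every foreground pixel labeled exactly once
    expect_true(all((obj$labels > 0L) == mask))
    # against the flood-fill oracle
    expect_identical(nrow(obj$objects), flood_fill_count(mask, conn))
  }
})

test_that("debris filter applies the strict less-than rule", {
  m <- matrix(FALSE, 20, 40)
  m[2:5, 2:7] <- TRUE                  # 24 px
  m[10:14, 10:14] <- TRUE              # 25 px
  obj <- label_objects(m)
  expect_identical(nrow(obj$objects), 2L)
  kept <- filter_debris(obj, 25L)
  expect_identical(kept$objects$n_pixels, 25L)
  expect_identical(sum(kept$labels > 0L), 25L)
  expect_identical(filter_debris(obj, 1L)$objects$n_pixels,
                   obj$objects$n_pixels)
  expect_error(filter_debris(obj, 0L), "min_pixels")
})

test_that("raising thresholds or the debris minimum is monotone", {
  set.seed(3)
  img <- matrix(as.integer(sample(0:255, 64 * 64, TRUE)), 64, 64)
  fg <- sapply(c(30, 90, 150), function(t) sum(threshold_channel(img, t)))
  expect_true(all(diff(fg) <= 0))
  obj <- label_objects(threshold_channel(img, 120))
  n <- sapply(c(1L, 3L, 8L, 25L), function(k)
    nrow(filter_debris(obj, k)$objects))
  expect_true(all(diff(n) <= 0))
})

test_that("signal partition conserves pixels in edge cases and at random", {
  a <- matrix(FALSE, 10, 10); a[2:4, 2:4] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  p <- partition_signal(a, b)      # disjoint
  expect_identical(p$n_pixels_intra, 0L)
  expect_identical(p$n_pixels_extra, 9L)
  p2 <- partition_signal(a, a | b) # subset
  expect_identical(p2$n_pixels_extra, 0L)
  set.seed(8)
  for (i in 1:10) {
    s <- matrix(runif(400) < 0.3, 20, 20)
    n <- matrix(runif(400) < 0.4, 20, 20)
    pp <- partition_signal(s, n)
    expect_identical(pp$n_pixels_intra + pp$n_pixels_extra, sum(s))
  }
  expect_error(partition_signal(a, matrix(FALSE, 5, 5)), "same shape")
})

test_that("straddling objects split or vote by rule (hand-computed fixture)", {
  # 10 x 10 S830 object; nucleus mask covers its left 6 columns (60 px)
  s830 <- matrix(FALSE, 12, 12); s830[2:11, 2:11] <- TRUE
  nuc <- matrix(FALSE, 12, 12); nuc[, 1:7] <- TRUE
  obj <- label_objects(s830)
  pp <- classify_inclusions(obj, nuc, rule = "pixel-partition")
  expect_identical(nrow(pp), 2L)
  expect_setequal(pp$size_px, c(60L, 40L))
  expect_identical(pp$compartment[pp$size_px == 60L], "nuclear")
  expect_identical(pp$compartment[pp$size_px == 40L], "cytoplasmic")
  mj <- classify_inclusions(obj, nuc, rule = "majority")
  expect_identical(nrow(mj), 1L)
  expect_identical(mj$compartment, "nuclear")
  expect_identical(mj$size_px, 100L)
  # pixel totals are rule-independent
  for (cl in list(pp, mj)) {
    expect_identical(attr(cl, "n_pixels_intra"), 60L)
    expect_identical(attr(cl, "n_pixels_extra"), 40L)
  }
  # object fully inside a nucleus: one nuclear inclusion under both rules
  nuc_all <- matrix(TRUE, 12, 12)
  for (rule in c("pixel-partition", "majority")) {
    cl <- classify_inclusions(obj, nuc_all, rule = rule)
    expect_identical(nrow(cl), 1L)
    expect_identical(cl$compartment, "nuclear")
  }
})

test_that("noiseless simulated ROIs are recovered exactly, both rules", {
  sim <- simulate_roi(fast_roi_config(seed = 31))
  tr <- sim$truth
  for (rule in c("pixel-partition", "majority")) {
    st <- quantify_roi(sim$dapi, sim$s830,
                       quant_config(nuclear_object_rule = rule))
    expect_identical(st$n_nuclei, nrow(tr$nuclei))
    expect_equal(st$mean_nucleus_px, mean(tr$nuclei$n_pixels))
    expect_identical(st$n_inclusions, nrow(tr$inclusions))
    expect_equal(st$mean_inclusion_px, mean(tr$inclusions$n_pixels))
    expect_equal(st$pct_signal_colocalized, tr$true_pct_signal_nuclear)
    nuc <- tr$inclusions$compartment == "nuclear"
    expect_identical(st$n_nuclear_inclusions, sum(nuc))
    expect_equal(st$pct_inclusions_nuclear, 100 * mean(nuc))
    expect_equal(st$mean_nuclear_inclusion_px,
                 mean(tr$inclusions$n_pixels[nuc]))
    expect_equal(st$pct_nuclei_with_inclusions,
                 100 * length(unique(tr$inclusions$host_nucleus[nuc])) /
                   nrow(tr$nuclei))
  }
})

test_that("ROI summary flags undefined fields instead of zeroing them", {
  nuclei <- label_objects(matrix(c(rep(TRUE, 30), rep(FALSE, 70)), 10, 10))
  no_inc <- classify_inclusions(label_objects(matrix(FALSE, 10, 10)),
                                matrix(FALSE, 10, 10))
  st <- summarize_roi(nuclei, no_inc)
  expect_identical(st$n_inclusions, 0L)
  expect_true(is.na(st$mean_inclusion_px))
  expect_true(is.na(st$pct_inclusions_nuclear))
  expect_true(is.na(st$pct_nuclei_with_inclusions))
  expect_true(is.na(st$mean_nuclear_inclusion_px))
  expect_true(is.na(st$pct_signal_colocalized))
  expect_identical(st$n_nuclei, 1L)
})

test_that("mean nucleus size is the arithmetic mean of pixel counts", {
  m <- matrix(FALSE, 30, 60)
  m[2:4, 2:11] <- TRUE     # 30 px
  m[10:12, 20:29] <- TRUE  # 30 px
  m[20:24, 2:11] <- TRUE   # 50 px
  m[20:24, 30:39] <- TRUE  # 50 px
  st <- summarize_roi(label_objects(m),
                      classify_inclusions(label_objects(matrix(FALSE, 30, 60)),
                                          m))
  expect_identical(st$n_nuclei, 4L)
  expect_equal(st$mean_nucleus_px, 40)
})

test_that("the ROI grid tiles the tissue bounding box deterministically", {
  img <- matrix(200L, 900, 900)
  g <- grid_rois(img, 9)
  expect_identical(nrow(g), 9L)
  expect_true(all(g$row1 - g$row0 + 1L == 300L))
  expect_true(all(g$col1 - g$col0 + 1L == 300L))
  # non-overlapping, covering the box
  cover <- matrix(0L, 900, 900)
  for (i in 1:9) cover[g$row0[i]:g$row1[i], g$col0[i]:g$col1[i]] <-
    cover[g$row0[i]:g$row1[i], g$col0[i]:g$col1[i]] + 1L
  expect_true(all(cover <= 1L))
  expect_identical(sum(cover), 810000L)
  expect_identical(grid_rois(img, 9), g)  # deterministic
  expect_error(grid_rois(matrix(200L, 2, 2), 9), "smaller")
  # two sections x nine ROIs = 18 ROIs per mouse
  expect_identical(2L * nrow(g), 18L)
})

test_that("per-mouse aggregation skips undefined entries field-wise", {
  sim <- simulate_roi(fast_roi_config(seed = 77))
  st <- quantify_roi(sim$dapi, sim$s830)
  same <- do.call(rbind, replicate(18, st, simplify = FALSE))
  agg <- aggregate_mouse(same)
  expect_equal(agg$mean[agg$statistic == "n_nuclei"], st$n_nuclei)
  expect_true(all(agg$n_rois == 18L))
  # one ROI with no inclusions changes only the inclusion-field n
  empty_inc <- st
  empty_inc[c("n_inclusions", "n_nuclear_inclusions")] <- 0L
  empty_inc[c("mean_inclusion_px", "pct_signal_colocalized",
              "pct_inclusions_nuclear", "pct_nuclei_with_inclusions",
              "mean_nuclear_inclusion_px")] <- NA_real_
  mixed <- rbind(same[1:17, ], empty_inc)
  agg2 <- aggregate_mouse(mixed)
  expect_identical(agg2$n_rois[agg2$statistic == "mean_inclusion_px"], 17L)
  expect_identical(agg2$n_rois[agg2$statistic == "n_nuclei"], 18L)
  expect_equal(agg2$mean[agg2$statistic == "mean_nuclear_inclusion_px"],
               st$mean_nuclear_inclusion_px)
  # hand-computed means on a small fixture
  fix <- same[1:3, ]
  fix$n_nuclei <- c(10L, 20L, 30L)
  agg3 <- aggregate_mouse(fix)
  expect_equal(agg3$mean[agg3$statistic == "n_nuclei"], 20)
})
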