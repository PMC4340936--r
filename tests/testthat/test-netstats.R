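test_that("group t-map equals the hand-computed one-sample t", {
  # voxel 1: values {1,2,3} -> t = mean/(sd/sqrt(n)) = 2/(1/sqrt(3)) = 3.4641
  # voxel 2: symmetric +-c -> t = 0, p = 1; voxel 3: constant (zero variance)
  maps <- rbind(c(1, -2, 5), c(2, 0, 5), c(3, 2, 5))
  tm <- group_t_map(maps)
  expect_equal(tm$t[1], 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(tm$p[1], 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-10)
  expect_equal(tm$t[2], 0)
  expect_equal(tm$p[2], 1)
  expect_true(tm$zero_variance[3])
  expect_equal(tm$df, 2)
  expect_error(group_t_map(maps[1, , drop = FALSE]),
               class = "fnoverlap_validation")
})

test_that("BH thresholding equals the brute-force oracle on the worked set", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569,
         0.594, 0.696)
  expect_identical(bh_reject(p, 0.05), bh_oracle(p, 0.05))
  # single p-value: BH reduces to p <= q
  expect_true(bh_reject(0.025, 0.05))
  expect_false(bh_reject(0.06, 0.05))
  # all p = 1: nothing rejected
  tm <- group_t_map(rbind(c(-1, -2), c(1, 2)))
  masks <- fdr_threshold(tm, 0.05)
  expect_false(any(masks$positive) || any(masks$negative))
})

test_that("BH equals the oracle across random vectors of many lengths", {
  fnoverlap:::with_seed(123, {
    for (i in 1:50) {
      n <- sample(1:500, 1)
      p <- stats::runif(n)^sample(1:3, 1)
      q <- stats::runif(1, 0.001, 0.2)
      expect_identical(bh_reject(p, q), bh_oracle(p, q))
    }
  })
})

test_that("sub-network masks split by sign and never intersect", {
  fnoverlap:::with_seed(7, {
    maps <- matrix(stats::rnorm(8 * 200), 8, 200)
    maps[, 1:20] <- maps[, 1:20] + 3        # strongly positive voxels
    maps[, 21:40] <- maps[, 21:40] - 3      # strongly negative voxels
  })
  tm <- group_t_map(maps)
  masks <- fdr_threshold(tm, 0.05)
  expect_false(any(masks$positive & masks$negative))
  expect_true(all(tm$t[masks$positive] > 0))
  expect_true(all(tm$t[masks$negative] < 0))
  expect_gt(sum(masks$positive), 0)
  expect_gt(sum(masks$negative), 0)
})

test_that("overlap map is the exact integer mask sum", {
  m1 <- array(0L, c(4, 4, 2)); m1[1, 1, 1] <- 1L
  ov2 <- overlap_map(list(m1, m1))
  expect_equal(ov2$counts[1, 1, 1], 2L)
  expect_equal(ov2$max_overlap, 2L)

  m2 <- array(0L, c(4, 4, 2)); m2[2, 2, 2] <- 1L
  expect_equal(overlap_map(list(m1, m2))$max_overlap, 1L)

  ovk <- overlap_map(rep(list(m1), 5))
  expect_equal(ovk$counts[1, 1, 1], 5L)
  expect_equal(sum(ovk$counts), 5L)

  # integer conservation on random masks
  masks <- fnoverlap:::with_seed(3, lapply(1:6, function(i)
    array(stats::rbinom(32, 1, 0.3), c(4, 4, 2))))
  ov <- overlap_map(masks)
  expect_identical(ov$counts, Reduce(`+`, masks))
  expect_error(overlap_map(list(m1, array(0L, c(3, 3, 2)))),
               class = "fnoverlap_validation")
})

test_that("volume summary reports unions, intersections and percentages", {
  brain <- array(TRUE, c(10, 10, 1))
  pos <- array(FALSE, c(10, 10, 1)); pos[1:10, 1, 1] <- TRUE
  s <- volume_summary(list(positive = list(pos)), brain)
  expect_equal(s$n_voxels[s$class == "positive"], 10)
  expect_equal(s$pct_brain[s$class == "positive"], 10)

  s2 <- volume_summary(list(positive = list(pos), negative = list(pos)), brain)
  expect_equal(s2$n_voxels[s2$class == "positive&negative"], 10)

  a <- array(FALSE, dim(brain)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, dim(brain)); b[2, 1, 1] <- TRUE
  c3 <- array(FALSE, dim(brain)); c3[3, 1, 1] <- TRUE
  s3 <- volume_summary(list(positive = list(a), negative = list(b),
                            neutral = list(c3)), brain)
  expect_equal(s3$n_voxels[s3$class == "all"], 3)
  # union volume is monotone as masks are added to a class
  s4 <- volume_summary(list(positive = list(a, b)), brain)
  expect_gte(s4$n_voxels[s4$class == "positive"],
             s3$n_voxels[s3$class == "positive"])
})

test_that("spectral artifact indicators follow the periodogram oracle", {
  TR <- 1.5
  n <- 200
  tsec <- (0:(n - 1)) * TR
  slow <- sin(2 * pi * 0.05 * tsec)        # below 0.10 Hz: network-like
  fast <- sin(2 * pi * 0.20 * tsec)        # 0.15-0.25 Hz band: artifact-like
  ic <- structure(list(
    group_maps = rbind(1:5, 1:5),
    subject_timecourses = list(cbind(slow, fast), cbind(slow, fast)),
    mask = array(TRUE, c(5, 1, 1)), TR = TR), class = "ic_result")
  flags <- flag_artifact_components(ic)
  expect_gt(flags$power_ratio[1], 10)
  expect_lt(flags$power_ratio[2], 0.1)
  expect_false(flags$flagged[1])
  expect_true(flags$flagged[2])
})

test_that("a WM/CSF peak flags a component regardless of its spectrum", {
  TR <- 1.5
  n <- 120
  slow <- sin(2 * pi * 0.05 * (0:(n - 1)) * TR)
  gm <- rbind(c(0, 0, 9, 0, 0))
  ic <- structure(list(group_maps = gm,
                       subject_timecourses = list(matrix(slow), matrix(slow)),
                       mask = array(TRUE, c(5, 1, 1)), TR = TR),
                  class = "ic_result")
  csf <- array(FALSE, c(5, 1, 1)); csf[3, 1, 1] <- TRUE
  flags <- flag_artifact_components(ic, tissue_masks = list(csf = csf))
  expect_true(flags$peak_in_wm_csf[1])
  expect_true(flags$flagged[1])
})

test_that("too-long TR truncates the artifact band with a warning", {
  n <- 100
  x <- sin(2 * pi * 0.05 * (0:(n - 1)) * 3)
  ic <- structure(list(group_maps = rbind(1:4),
                       subject_timecourses = list(matrix(x), matrix(x)),
                       mask = array(TRUE, c(4, 1, 1)), TR = 3),
                  class = "ic_result")
  expect_warning(flag_artifact_components(ic), "Nyquist")
})
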