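test_that("contrast estimates satisfy exact OLS identities and linearity", {
  d <- make_design("block", 4, TR = 1.5, n_timepoints = 120, seed = 5,
                   conditions = c("A", "B"), block_duration = 12,
                   rest_gap = 15)
  reg <- hrf_convolve(d)
  M <- reg$matrix
  Y <- cbind(M[, "A"], 0, 2 * M[, "A"] + 0.5 * M[, "B"])
  est <- fit_subject_glm(Y, reg, contrast = c(1, 0))
  expect_equal(est[1], 1, tolerance = 1e-10)
  expect_equal(est[2], 0, tolerance = 1e-10)
  expect_equal(est[3], 2, tolerance = 1e-10)

  # linearity in the data
  Y2 <- fnoverlap:::with_seed(6, matrix(stats::rnorm(120 * 3), 120, 3))
  e1 <- fit_subject_glm(Y2, reg, c(1, -1))
  e2 <- fit_subject_glm(3 * Y2 + Y, reg, c(1, -1))
  expect_equal(e2, 3 * e1 + fit_subject_glm(Y, reg, c(1, -1)),
               tolerance = 1e-10)
})

test_that("subject GLM recovers planted effect sizes without noise", {
  fx <- small_cohort(n_networks = 2, noise_sd = 0, jitter = 0, fluct_amp = 0,
                     grid_dims = c(10, 10, 6), n_timepoints = 100)
  v <- simulate_subject(fx$truth, fx$design, subject_seed = 1)
  reg <- hrf_convolve(fx$design)
  est <- fit_subject_glm(v, reg, contrast = c(1, 0))
  est3d <- array(est, c(10, 10, 6))
  # network 1 has beta +1 on condition A: estimate = map value at each voxel
  expect_equal(est3d, fx$networks[[1]] * 1 +
                 fx$networks[[2]] * fx$truth$betas[2, "A"],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("three-subject inference enumerates the exhaustive sign-flip null", {
  mask <- array(TRUE, c(6, 6, 4))
  maps <- fnoverlap:::with_seed(8, matrix(stats::rnorm(3 * 144), 3, 144))
  expect_message(
    res <- group_cluster_inference(maps, mask, n_permutations = 100, seed = 1),
    "exhaustive")
  expect_true(res$exhaustive)
  expect_length(res$null_max_extent, 8)
  res2 <- suppressMessages(
    group_cluster_inference(maps, mask, n_permutations = 100, seed = 99))
  expect_identical(res$null_max_extent, res2$null_max_extent)
})

test_that("a strong planted blob is detected as a significant cluster", {
  grid <- c(12, 12, 6)
  blob <- fnoverlap:::gaussian_blob(grid, c(6, 6, 3), 1.8)
  mask <- array(TRUE, grid)
  maps <- fnoverlap:::with_seed(10, t(vapply(1:8, function(s)
    as.vector(3 * blob) + stats::rnorm(prod(grid)), numeric(prod(grid)))))
  res <- suppressMessages(
    group_cluster_inference(maps, mask, n_permutations = 200, seed = 2))
  expect_true(any(res$clusters$significant))
  expect_true(res$significant[6, 6, 3])
  # every cluster voxel passes the height threshold, clusters are disjoint
  expect_true(all(abs(res$t[res$significant[mask]]) > res$height_threshold_t))
})

test_that("additivity: complete decompositions reproduce the GLM contrast", {
  fx <- small_cohort(n_networks = 3, noise_sd = 0, jitter = 0,
                     grid_dims = c(10, 10, 6), n_timepoints = 100)
  v <- simulate_subject(fx$truth, fx$design, subject_seed = 2)
  mask <- array(TRUE, c(10, 10, 6))
  X <- standardize(v, mask, variance_normalize = FALSE)
  G <- do.call(rbind, lapply(fx$networks, function(m) as.vector(m)[mask]))
  br <- back_reconstruct(X, G)
  reg <- hrf_convolve(fx$design)
  region <- as.vector(fx$networks[[1]] > 0.3)
  full <- additivity_check(X, br$timecourses, br$maps, reg, c(1, 0), region)
  expect_lt(full$relative_discrepancy, 0.01)
  # truncating the component set degrades the reconstruction
  half <- additivity_check(X, br$timecourses[, 1:2], br$maps[1:2, ], reg,
                           c(1, 0), region)
  expect_gt(half$relative_discrepancy, full$relative_discrepancy)
  # empty region: empty report
  none <- additivity_check(X, br$timecourses, br$maps, reg, c(1, 0),
                           rep(FALSE, ncol(X)))
  expect_length(none$estimate_data, 0)
})

test_that("cancellation report identifies opposed-network overlap regions", {
  dims <- c(6, 6, 2)
  m1 <- array(FALSE, dims); m1[1:4, 1:4, 1] <- TRUE
  m2 <- array(FALSE, dims); m2[3:6, 3:6, 1] <- TRUE
  cls <- data.frame(ic = c(1, 2), condition = "A",
                    label = c("positive", "negative"))
  subnets <- list(list(ic = 1, polarity = "positive", values = m1),
                  list(ic = 2, polarity = "positive", values = m2))
  glm <- structure(list(significant = array(FALSE, dims)),
                   class = "cluster_result")
  rep <- cancellation_report(glm, subnets, cls, "A")
  expect_equal(rep$n_region, 4)          # the 2x2 intersection
  expect_equal(rep$fraction_glm_null, 1)
  # single positive network: no cancellation region
  rep2 <- cancellation_report(glm, subnets[1], cls[1, ], "A")
  expect_equal(rep2$n_region, 0)
  expect_true(is.na(rep2$fraction_glm_null))
})
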