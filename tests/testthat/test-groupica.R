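test_that("pca_reduce agrees with a brute-force eigendecomposition", {
  X <- fnoverlap:::with_seed(11, matrix(stats::rnorm(50 * 200), 50, 200))
  res <- pca_reduce(X, 10)
  # oracle: eigendecomposition of the timepoint covariance
  ev <- eigen(X %*% t(X) / (ncol(X) - 1), symmetric = TRUE)$values
  expect_equal(res$explained_variance, (ev / sum(ev))[1:10], tolerance = 1e-10)
  expect_true(all(diff(res$explained_variance) <= 1e-12))

  # full rank: perfect reconstruction
  full <- pca_reduce(X, 50)
  expect_equal(full$basis %*% full$scores, X, tolerance = 1e-8)

  # rank-2 input captured entirely by 2 components
  R2 <- outer(1:20, 1:30) + outer(sin(1:20), cos(1:30))
  expect_equal(sum(pca_reduce(R2, 2)$explained_variance), 1, tolerance = 1e-12)
  expect_error(pca_reduce(R2, 5), class = "fnoverlap_config")
})

test_that("infomax separates independent heavy-tailed sources", {
  S <- laplace_sources(2, 5000, seed = 21)
  wh <- fnoverlap:::whiten_rows(S)
  fit <- infomax(wh$Y, seed = 2)
  r <- abs(stats::cor(t(fit$S), t(S)))
  # each true source recovered exactly once
  best <- apply(r, 2, max)
  expect_true(all(best > 0.99))
  expect_equal(sort(apply(r, 2, which.max)), 1:2)
})

test_that("infomax inverts a random mixing matrix up to permutation and scale", {
  S <- laplace_sources(3, 6000, seed = 33)
  A <- fnoverlap:::with_seed(34, matrix(stats::rnorm(9), 3, 3))
  wh <- fnoverlap:::whiten_rows(A %*% S)
  fit <- infomax(wh$Y, seed = 3)
  G <- fit$W %*% wh$whitener %*% A          # should be permutation x diagonal
  for (i in 1:3) {
    row <- abs(G[i, ])
    expect_gt(max(row), 0)
    expect_lt(sort(row, decreasing = TRUE)[2] / max(row), 0.05)
  }
  expect_equal(sort(apply(abs(G), 1, which.max)), 1:3)
})

test_that("infomax demands whitened input and is seed-deterministic", {
  S <- laplace_sources(2, 2000, seed = 5)
  expect_error(infomax(3 * S, seed = 1), class = "fnoverlap_validation")
  wh <- fnoverlap:::whiten_rows(S)
  f1 <- infomax(wh$Y, seed = 9)
  f2 <- infomax(wh$Y, seed = 9)
  expect_identical(f1$S, f2$S)
})

test_that("one-component infomax returns the input up to sign and scale", {
  x <- laplace_sources(1, 1000, seed = 8)
  wh <- fnoverlap:::whiten_rows(x)
  fit <- infomax(wh$Y, seed = 1)
  expect_equal(abs(stats::cor(fit$S[1, ], x[1, ])), 1, tolerance = 1e-8)
})

test_that("dual regression recovers generating timecourses and additivity", {
  fx <- small_cohort(n_networks = 3, noise_sd = 0, jitter = 0,
                     grid_dims = c(12, 12, 7), n_timepoints = 80)
  v <- simulate_subject(fx$truth, fx$design, subject_seed = 44)
  mask <- array(TRUE, c(12, 12, 7))
  X <- standardize(v, mask, variance_normalize = FALSE)
  G <- do.call(rbind, lapply(fx$networks, function(m) as.vector(m)[mask]))
  br <- back_reconstruct(X, G)
  tc_true <- attr(v, "true_timecourses")
  for (k in 1:3)
    expect_gt(abs(stats::cor(br$timecourses[, k], tc_true[, k])), 0.999)
  # sum over components reproduces >= 99% of the noiseless data variance
  recon <- br$timecourses %*% br$maps
  expect_gt(1 - sum((recon - X)^2) / sum(X^2), 0.99)
})

test_that("dual regression flags collinear components", {
  X <- fnoverlap:::with_seed(1, matrix(stats::rnorm(40 * 100), 40, 100))
  G <- fnoverlap:::with_seed(2, matrix(stats::rnorm(2 * 100), 2, 100))
  G3 <- rbind(G, G[1, ])
  expect_error(back_reconstruct(X, G3), class = "fnoverlap_rank")
})

test_that("constant-in-time data yields constant timecourses", {
  G <- diag(4)[, rep(1:4, each = 5)]          # 4 orthonormal-ish maps, 20 vox
  X <- matrix(rep(G[2, ], each = 10), 10, 20) # data = map 2 at every timepoint
  br <- back_reconstruct(X, G, compute_maps = FALSE)
  expect_equal(apply(br$timecourses, 2, stats::sd), rep(0, 4),
               tolerance = 1e-12)
})

test_that("orientation flip preserves the product and is idempotent", {
  fx <- small_cohort(n_subjects = 3, grid_dims = c(10, 10, 6),
                     n_timepoints = 60)
  mask <- compute_mask(fx$cohort$volumes)
  ica <- run_group_ica(fx$cohort$volumes, mask,
                       ica_config(4, n_icasso_runs = 2, seed = 3))
  flipped <- ica
  flipped$group_maps[1, ] <- -flipped$group_maps[1, ]
  flipped$subject_maps <- lapply(flipped$subject_maps, function(m) {
    m[1, ] <- -m[1, ]; m })
  flipped$subject_timecourses <- lapply(flipped$subject_timecourses,
                                        function(tc) { tc[, 1] <- -tc[, 1]; tc })
  prod_before <- flipped$subject_timecourses[[1]] %*% flipped$subject_maps[[1]]
  re <- orient_components(flipped)
  expect_equal(re$group_maps, ica$group_maps)
  prod_after <- re$subject_timecourses[[1]] %*% re$subject_maps[[1]]
  expect_equal(prod_after, prod_before, tolerance = 1e-10)
  expect_equal(orient_components(re), re)
})

test_that("group ICA is deterministic and validates its configuration", {
  fx <- small_cohort(n_subjects = 3, grid_dims = c(10, 10, 6),
                     n_timepoints = 60)
  mask <- compute_mask(fx$cohort$volumes)
  cfg <- ica_config(3, n_icasso_runs = 2, seed = 12)
  a <- run_group_ica(fx$cohort$volumes, mask, cfg)
  b <- run_group_ica(fx$cohort$volumes, mask, cfg)
  expect_identical(a$group_maps, b$group_maps)
  expect_error(ica_config(8, group_pca_dims = 5), class = "fnoverlap_config")
  expect_error(run_group_ica(fx$cohort$volumes[1], mask, cfg),
               class = "fnoverlap_validation")
})
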