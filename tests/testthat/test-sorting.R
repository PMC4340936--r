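test_that("HRF-convolved regressor peaks 4-6 s after a brief event", {
  d <- design_spec(data.frame(onset = 20, duration = 1, condition = "A"),
                   TR = 0.5, n_timepoints = 120)
  reg <- hrf_convolve(d)
  tpk <- (which.max(reg$matrix[, "A"]) - 1) * 0.5
  expect_gte(tpk - 20, 4)
  expect_lte(tpk - 20, 6)
  # analytic check on the fine grid: the double-gamma mode is near 5 s
  tf <- seq(0, 30, by = 0.01)
  expect_equal(tf[which.max(hrf_double_gamma(tf))], 5.03, tolerance = 0.05)
})

test_that("degenerate designs are rejected at matrix build", {
  ev <- data.frame(onset = c(10, 10), duration = c(2, 2),
                   condition = c("A", "B"))
  d <- design_spec(ev, TR = 1, n_timepoints = 100)
  expect_error(hrf_convolve(d), class = "fnoverlap_rank")  # identical events
  d0 <- design_spec(data.frame(onset = numeric(0), duration = numeric(0),
                               condition = character(0)),
                    TR = 1, n_timepoints = 50)
  expect_error(hrf_convolve(d0), class = "fnoverlap_validation")
})

test_that("temporal sorting recovers exact betas for constructed timecourses", {
  d <- make_design("block", 6, TR = 1.5, n_timepoints = 150, seed = 2,
                   conditions = c("A", "B"), block_duration = 12,
                   rest_gap = 15)
  M0 <- hrf_convolve(d)$matrix
  # design with mutually orthogonal unit-variance condition regressors, so
  # the OLS identity beta = 1 holds exactly for a matching timecourse
  a <- stats::resid(stats::lm(M0[, "A"] ~ M0[, "B"]))
  a <- a / stats::sd(a)
  b <- stats::resid(stats::lm(M0[, "B"] ~ a))
  b <- b / stats::sd(b)
  reg <- structure(list(matrix = cbind(A = a, B = b, intercept = 1),
                        conditions = c("A", "B")),
                   class = "regressor_matrix")
  tcs <- list(cbind(a, -a), cbind(a, -a))
  bt <- sort_timecourses(tcs, reg)
  sb <- bt$subject_betas
  expect_equal(unname(sb[1, 1, "A"]), 1, tolerance = 1e-10)
  expect_equal(unname(sb[1, 1, "B"]), 0, tolerance = 1e-10)
  expect_equal(unname(sb[1, 2, "A"]), -1, tolerance = 1e-10)
})

test_that("white-noise timecourses give betas centred on zero", {
  d <- make_design("block", 4, TR = 1.5, n_timepoints = 200, seed = 3,
                   conditions = "A", block_duration = 15, rest_gap = 20)
  reg <- hrf_convolve(d)
  betas <- fnoverlap:::with_seed(44, vapply(1:500, function(i) {
    tc <- matrix(stats::rnorm(200), 200, 1)
    sort_timecourses(list(tc), reg)$subject_betas[1, 1, "A"]
  }, numeric(1)))
  se <- stats::sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas)), 2 * se + 1e-3)
})

test_that("classification labels planted effects and controls the null", {
  # one IC with a strong positive beta among nine null ICs
  strong <- c(2.0, 2.1, 1.9, 2.05, 1.95)
  sb <- array(0, c(5, 10, 1), dimnames = list(NULL, NULL, "A"))
  sb[, 1, 1] <- strong
  fnoverlap:::with_seed(9, sb[, 2:10, 1] <- stats::rnorm(45, 0, 0.5))
  bt <- structure(list(subject_betas = sb, conditions = "A"),
                  class = "beta_table")
  cls <- classify_fns(bt, alpha = 0.05)
  expect_equal(cls$label[1], "positive")
  expect_true(all(cls$label[-1] == "neutral"))
  # oracle: one-sample t and BH computed directly
  t1 <- mean(strong) / (stats::sd(strong) / sqrt(5))
  expect_equal(cls$t[1], t1, tolerance = 1e-10)
  p_raw <- vapply(1:10, function(k) {
    x <- sb[, k, 1]
    2 * stats::pt(-abs(mean(x) / (stats::sd(x) / sqrt(5))), df = 4)
  }, numeric(1))
  expect_equal(cls$p_fdr, stats::p.adjust(p_raw, "BH"), tolerance = 1e-10)

  # antisymmetry: negating all betas flips the label, t negates exactly
  btn <- bt; btn$subject_betas <- -sb
  clsn <- classify_fns(btn, alpha = 0.05)
  expect_equal(clsn$label[1], "negative")
  expect_equal(clsn$t, -cls$t, tolerance = 1e-12)

  # all-zero betas: everything neutral
  bt0 <- bt; bt0$subject_betas[] <- 0
  expect_true(all(classify_fns(bt0)$label == "neutral"))
})

test_that("paired comparisons handle identity, degeneracy and power", {
  sb <- array(stats::rnorm(5 * 3 * 2), c(5, 3, 2),
              dimnames = list(NULL, NULL, c("A", "B")))
  sb[, , "B"] <- sb[, , "A"]
  bt <- structure(list(subject_betas = sb, conditions = c("A", "B")),
                  class = "beta_table")
  cmp <- compare_conditions(bt, "A", "B")
  expect_true(all(cmp$t == 0))

  sb2 <- sb; sb2[, , "B"] <- sb2[, , "A"] - 1   # zero-variance differences
  bt2 <- structure(list(subject_betas = sb2, conditions = c("A", "B")),
                   class = "beta_table")
  cmp2 <- compare_conditions(bt2, "A", "B")
  expect_true(all(cmp2$degenerate))
  expect_true(all(cmp2$p == 0))

  expect_error(compare_conditions(bt, "A", "C"),
               class = "fnoverlap_validation")

  # power calibration: shift d = 1, sd = 1, n = 20 against the closed-form
  # noncentral-t power of the paired t-test at alpha = .05
  n <- 20; reps <- 500
  rej <- fnoverlap:::with_seed(55, vapply(seq_len(reps), function(i) {
    diffs <- stats::rnorm(n, mean = 1, sd = 1)
    sbp <- array(0, c(n, 1, 2), dimnames = list(NULL, NULL, c("A", "B")))
    sbp[, 1, "A"] <- diffs
    btp <- structure(list(subject_betas = sbp, conditions = c("A", "B")),
                     class = "beta_table")
    compare_conditions(btp, "A", "B")$p[1] < 0.05
  }, logical(1)))
  tcrit <- stats::qt(0.975, n - 1)
  ncp <- 1 / (1 / sqrt(n))
  power <- 1 - stats::pt(tcrit, n - 1, ncp) + stats::pt(-tcrit, n - 1, ncp)
  phat <- mean(rej)
  ci <- 1.96 * sqrt(power * (1 - power) / reps)
  expect_lt(abs(phat - power), ci + 0.01)
})
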