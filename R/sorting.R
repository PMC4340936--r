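# Temporal sorting: regress IC timecourses on HRF-convolved task regressors,
# aggregate beta weights per subject, and classify each component as
# task-positive, task-negative or task-neutral per condition.

#' Canonical double-gamma hemodynamic response function
#'
#' Standard parameterisation: response gamma peaking at 6 s, undershoot gamma
#' at 16 s, undershoot ratio 1/6; unit time integral.
#'
#' @param t Time grid in seconds.
#' @param peak Response gamma shape (default 6).
#' @param undershoot Undershoot gamma shape (default 16).
#' @param ratio Response-to-undershoot amplitude ratio (default 6).
#' @return HRF values on `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Build an HRF-convolved design matrix from task events
#'
#' Each condition's events form a boxcar on a fine 0.1 s grid, are convolved
#' with the canonical double-gamma HRF, and sampled at the TR grid.
#' Overlapping events within one condition are summed (with a message). An
#' intercept column is appended and full column rank is enforced.
#'
#' @param design A [design_spec()].
#' @param dt Fine-grid step in seconds (default 0.1).
#' @param intercept Append an intercept column (default TRUE).
#' @return Object of class `regressor_matrix`: list with `matrix`
#'   (timepoints x conditions [+ intercept]) and `conditions`.
#' @export
hrf_convolve <- function(design, dt = 0.1, intercept = TRUE) {
  conds <- design$conditions
  if (length(conds) == 0)
    stop_fn("design has no conditions", class = "fnoverlap_validation")
  run_len <- design$TR * design$n_timepoints
  n_fine <- ceiling(run_len / dt)
  tfine <- (seq_len(n_fine) - 1) * dt
  h <- hrf_double_gamma(tfine)
  cols <- matrix(0, design$n_timepoints, length(conds))
  colnames(cols) <- conds
  sample_idx <- pmin(n_fine, round((seq_len(design$n_timepoints) - 1) *
                                     design$TR / dt) + 1)
  for (j in seq_along(conds)) {
    ev <- design$events[design$events$condition == conds[j], , drop = FALSE]
    box <- numeric(n_fine)
    for (i in seq_len(nrow(ev))) {
      a <- floor(ev$onset[i] / dt) + 1
      b <- min(n_fine, ceiling((ev$onset[i] + ev$duration[i]) / dt))
      b <- max(b, a)
      if (any(box[a:b] > 0))
        message("overlapping events within condition '", conds[j], "' summed")
      box[a:b] <- box[a:b] + 1
    }
    conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)] * dt
    cols[, j] <- conv[sample_idx]
  }
  M <- if (intercept) cbind(cols, intercept = 1) else cols
  if (qr(M)$rank < ncol(M)) {
    zero_cols <- conds[colSums(abs(cols)) == 0]
    if (length(zero_cols) > 0)
      stop_fn("empty condition(s) give all-zero regressors: ",
              paste(zero_cols, collapse = ", "), class = "fnoverlap_rank")
    stop_fn("design matrix is rank deficient (collinear conditions)",
            class = "fnoverlap_rank")
  }
  structure(list(matrix = M, conditions = conds), class = "regressor_matrix")
}

#' Temporal sorting of IC timecourses against a design matrix
#'
#' Each component timecourse is standardised to zero mean and unit variance
#' and regressed (ordinary least squares) on the HRF-convolved design matrix,
#' yielding one beta weight per condition per run. Betas are then averaged
#' across runs within subject.
#'
#' @param subject_timecourses List over subjects; each element either a
#'   timepoints x n_ics matrix (single run) or a list of such matrices
#'   (multiple runs).
#' @param regressors A [hrf_convolve()] result (or a list of one per run).
#' @return Object of class `beta_table`: list with `runs` (long data frame:
#'   subject, run, ic, condition, beta) and `subject_betas` (3D array:
#'   subjects x ICs x conditions, run-averaged).
#' @export
sort_timecourses <- function(subject_timecourses, regressors) {
  as_runs <- function(x) if (is.matrix(x)) list(x) else x
  first <- as_runs(subject_timecourses[[1]])[[1]]
  n_ics <- ncol(first)
  reg_for <- function(r) if (inherits(regressors, "regressor_matrix"))
    regressors else regressors[[r]]
  conds <- reg_for(1)$conditions
  n_sub <- length(subject_timecourses)
  subject_betas <- array(NA_real_, c(n_sub, n_ics, length(conds)),
                         dimnames = list(NULL, NULL, conds))
  rows <- list()
  for (s in seq_len(n_sub)) {
    runs <- as_runs(subject_timecourses[[s]])
    acc <- array(0, c(n_ics, length(conds)))
    for (r in seq_along(runs)) {
      reg <- reg_for(r)
      M <- reg$matrix
      if (nrow(M) != nrow(runs[[r]]))
        stop_fn("timecourse length does not match the design matrix",
                class = "fnoverlap_validation")
      if (qr(M)$rank < ncol(M))
        stop_fn("rank-deficient regressor matrix", class = "fnoverlap_rank")
      TC <- scale(runs[[r]])        # unit variance so betas compare across ICs
      TC[is.na(TC)] <- 0
      B <- solve(crossprod(M), crossprod(M, TC))   # (conds+1) x n_ics
      bc <- t(B[conds, , drop = FALSE])            # n_ics x conds
      acc <- acc + bc
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, run = r, ic = rep(seq_len(n_ics), times = length(conds)),
        condition = rep(conds, each = n_ics), beta = as.vector(bc))
    }
    subject_betas[s, , ] <- acc / length(runs)
  }
  structure(list(runs = do.call(rbind, rows), subject_betas = subject_betas,
                 conditions = conds),
            class = "beta_table")
}

#' Classify components as task-positive, task-negative or task-neutral
#'
#' Per condition, the group mean of run-averaged beta weights of each
#' component is tested against zero with a one-sample t-test, and
#' Benjamini-Hochberg FDR correction is applied across components within the
#' condition. A component is labelled positive (negative) for a condition
#' when its adjusted p-value falls below `alpha` and the mean beta is
#' positive (negative), and neutral otherwise. The positive sub-network of a
#' positive component is a positive functional network and its negative
#' sub-network a negative one; for a negative component the designations are
#' reversed; both sub-networks of a neutral component are neutral.
#'
#' @param betas A [sort_timecourses()] result.
#' @param alpha Significance level after FDR correction (default 0.05).
#' @return Data frame: `ic`, `condition`, `mean_beta`, `t`, `df`, `p`,
#'   `p_fdr`, `label`.
#' @export
classify_fns <- function(betas, alpha = 0.05) {
  sb <- betas$subject_betas
  n_sub <- dim(sb)[1]
  if (n_sub < 2)
    stop_fn("classification requires >= 2 subjects",
            class = "fnoverlap_validation")
  n_ics <- dim(sb)[2]
  out <- list()
  for (cond in betas$conditions) {
    mu <- apply(sb[, , cond, drop = FALSE], 2, mean)
    sds <- apply(sb[, , cond, drop = FALSE], 2, stats::sd)
    tval <- ifelse(sds == 0, 0, mu / (sds / sqrt(n_sub)))
    p <- ifelse(sds == 0, 1, 2 * stats::pt(-abs(tval), df = n_sub - 1))
    p_fdr <- stats::p.adjust(p, method = "BH")
    label <- ifelse(p_fdr < alpha & mu > 0, "positive",
                    ifelse(p_fdr < alpha & mu < 0, "negative", "neutral"))
    out[[cond]] <- data.frame(ic = seq_len(n_ics), condition = cond,
                              mean_beta = mu, t = tval, df = n_sub - 1,
                              p = p, p_fdr = p_fdr, label = label)
  }
  cls <- do.call(rbind, out)
  rownames(cls) <- NULL
  cls
}

#' Paired comparison of beta weights between two conditions
#'
#' Paired t-test per component on subject-level run-averaged betas, with
#' Benjamini-Hochberg correction across components. Zero-variance difference
#' vectors with a nonzero mean are flagged as degenerate (p set to 0).
#'
#' @param betas A [sort_timecourses()] result.
#' @param condition_a,condition_b Condition names to compare (A - B).
#' @param alpha FDR level (default 0.05).
#' @return Data frame: `ic`, `mean_diff`, `t`, `df`, `p`, `p_fdr`,
#'   `significant`, `degenerate`.
#' @export
compare_conditions <- function(betas, condition_a, condition_b, alpha = 0.05) {
  sb <- betas$subject_betas
  for (cond in c(condition_a, condition_b))
    if (!cond %in% betas$conditions)
      stop_fn("condition not present: ", cond, class = "fnoverlap_validation")
  diffs <- sb[, , condition_a, drop = FALSE] - sb[, , condition_b, drop = FALSE]
  n_sub <- dim(sb)[1]
  if (any(is.na(diffs)))
    stop_fn("missing condition pairs for subjects: ",
            paste(which(apply(is.na(diffs), 1, any)), collapse = ", "),
            class = "fnoverlap_validation")
  n_ics <- dim(sb)[2]
  mu <- apply(diffs, 2, mean)
  sds <- apply(diffs, 2, stats::sd)
  # constant differences leave sd at floating-point dust; treat as zero
  zero_sd <- sds <= 1e-12 * pmax(abs(mu), .Machine$double.eps)
  degen <- zero_sd & mu != 0
  tval <- ifelse(zero_sd, ifelse(mu == 0, 0, sign(mu) * Inf),
                 mu / (sds / sqrt(n_sub)))
  p <- ifelse(degen, 0,
              ifelse(zero_sd, 1, 2 * stats::pt(-abs(tval), df = n_sub - 1)))
  p_fdr <- stats::p.adjust(p, method = "BH")
  data.frame(ic = seq_len(n_ics), mean_diff = mu, t = tval, df = n_sub - 1,
             p = p, p_fdr = p_fdr, significant = p_fdr < alpha,
             degenerate = degen)
}
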