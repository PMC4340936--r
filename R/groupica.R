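# Group spatial ICA: two-stage PCA reduction of temporally concatenated
# subjects, natural-gradient Infomax unmixing with ICASSO-style restarts,
# and dual-regression back-reconstruction of subject maps and timecourses.

#' ICA configuration
#'
#' @param n_ics Number of independent components to extract.
#' @param subject_pca_dims Temporal dimensions retained per subject in the
#'   first reduction stage (default `ceiling(1.5 * n_ics)`).
#' @param group_pca_dims Dimensions retained at the group stage (default
#'   `n_ics`).
#' @param n_icasso_runs Number of Infomax restarts clustered for stability
#'   (default 10).
#' @param seed Integer seed governing all restarts.
#' @param learning_rate Initial Infomax learning rate; default
#'   `0.015 / log(n_ics)` (for `n_ics` > 1).
#' @param block_size Samples per natural-gradient block update; default
#'   `ceiling(sqrt(n_samples / 3))`, resolved at run time.
#' @param max_sweeps Maximum full passes over the data (default 512).
#' @param tol Stop when the Frobenius norm of the weight update falls below
#'   this value (default 1e-6).
#' @param anneal Learning-rate multiplier applied when successive weight
#'   updates oscillate (default 0.9).
#' @return An object of class `ica_config`.
#' @export
ica_config <- function(n_ics, subject_pca_dims = NULL, group_pca_dims = NULL,
                       n_icasso_runs = 10, seed = 1L, learning_rate = NULL,
                       block_size = NULL, max_sweeps = 512, tol = 1e-6,
                       anneal = 0.9) {
  subject_pca_dims <- subject_pca_dims %||% ceiling(1.5 * n_ics)
  group_pca_dims <- group_pca_dims %||% n_ics
  if (n_ics > group_pca_dims)
    stop_fn("n_ics must not exceed group_pca_dims", class = "fnoverlap_config")
  if (group_pca_dims > subject_pca_dims * 2 && is.null(subject_pca_dims))
    stop_fn("group_pca_dims too large for the subject reduction",
            class = "fnoverlap_config")
  if (n_icasso_runs < 1)
    stop_fn("n_icasso_runs must be >= 1", class = "fnoverlap_config")
  structure(list(n_ics = n_ics, subject_pca_dims = subject_pca_dims,
                 group_pca_dims = group_pca_dims,
                 n_icasso_runs = n_icasso_runs, seed = as.integer(seed),
                 learning_rate = learning_rate, block_size = block_size,
                 max_sweeps = max_sweeps, tol = tol, anneal = anneal),
            class = "ica_config")
}

#' PCA reduction of a timepoints x voxels matrix
#'
#' Temporal reduction as used in group ICA: the top `n_components`
#' eigenvectors of the timepoint covariance project the data to
#' `n_components` x voxels.
#'
#' @param X Numeric matrix, timepoints x voxels (rows are variables to
#'   reduce, columns are samples).
#' @param n_components Number of components to retain.
#' @return List with `scores` (n_components x voxels), `basis` (timepoints x
#'   n_components projection basis) and `explained_variance` (non-increasing
#'   fractions of total variance).
#' @export
pca_reduce <- function(X, n_components) {
  if (n_components > min(dim(X)))
    stop_fn("n_components exceeds matrix dimensions", class = "fnoverlap_config")
  sv <- svd(X, nu = min(dim(X)), nv = 0)
  ev <- sv$d^2
  rank <- sum(sv$d > max(dim(X)) * max(sv$d) * .Machine$double.eps)
  if (n_components > rank)
    stop_fn("n_components (", n_components, ") exceeds matrix rank (", rank, ")",
            class = "fnoverlap_config")
  basis <- sv$u[, seq_len(n_components), drop = FALSE]
  list(scores = t(basis) %*% X,
       basis = basis,
       explained_variance = ev[seq_len(n_components)] / sum(ev))
}

# Whiten the rows of Y so the sample covariance across columns is identity.
whiten_rows <- function(Y) {
  C <- Y %*% t(Y) / (ncol(Y) - 1)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  if (!all(keep)) stop_fn("rank-deficient input to whitening")
  Wt <- diag(1 / sqrt(e$values), nrow(Y)) %*% t(e$vectors)
  list(Y = Wt %*% Y, whitener = Wt, dewhitener = e$vectors %*% diag(sqrt(e$values), nrow(Y)))
}

orient_rows <- function(S) {
  # flip each row so the entry of largest magnitude is positive
  flips <- vapply(seq_len(nrow(S)), function(i) {
    r <- S[i, ]
    if (r[which.max(abs(r))] < 0) -1 else 1
  }, numeric(1))
  list(S = S * flips, flips = flips)
}

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with the logistic nonlinearity, block updates,
#' learning-rate annealing on oscillation, and divergence restarts with a
#' halved rate. The input must be whitened (sample covariance approximately
#' identity); this is asserted.
#'
#' @param Y Whitened matrix, components x samples.
#' @param seed Integer seed for the random initial rotation and sample order.
#' @param learning_rate Initial learning rate (default `0.015 / log(n)` for
#'   n > 1 components, 0.01 otherwise).
#' @param block_size Block size (default `ceiling(sqrt(ncol(Y) / 3))`).
#' @param max_sweeps Maximum sweeps (default 512).
#' @param tol Convergence tolerance on the weight update norm (default 1e-6).
#' @param anneal Annealing factor applied on oscillation (default 0.9).
#' @param max_retries Divergence restarts before giving up (default 5).
#' @return List with `W` (unmixing matrix) and `S = W %*% Y`, rows of `S`
#'   scaled to unit variance and oriented so each row's largest-magnitude
#'   entry is positive.
#' @export
infomax <- function(Y, seed = 1L, learning_rate = NULL, block_size = NULL,
                    max_sweeps = 512, tol = 1e-6, anneal = 0.9,
                    max_retries = 5) {
  n <- nrow(Y); N <- ncol(Y)
  C <- Y %*% t(Y) / (N - 1)
  if (max(abs(C - diag(n))) > 0.01)
    stop_fn("infomax input is not whitened (sample covariance != identity)",
            class = "fnoverlap_validation")
  lr0 <- learning_rate %||% (if (n > 1) 0.015 / log(n) else 0.01)
  B <- block_size %||% ceiling(sqrt(N / 3))
  I_n <- diag(n)
  for (attempt in 0:max_retries) {
    lr <- lr0 / 2^attempt
    W <- with_seed(derive_seed(seed, 7000L + attempt), {
      M <- matrix(stats::rnorm(n * n), n, n)
      qr.Q(qr(M))
    })
    diverged <- FALSE
    prev_delta <- NULL
    rng_seed <- derive_seed(seed, 8000L + attempt)
    converged <- with_seed(rng_seed, {
      done <- FALSE
      for (sweep in seq_len(max_sweeps)) {
        perm <- sample.int(N)
        W_old <- W
        for (b0 in seq(1, N, by = B)) {
          idx <- perm[b0:min(b0 + B - 1, N)]
          u <- W %*% Y[, idx, drop = FALSE]
          y <- 1 / (1 + exp(-u))
          W <- W + lr * (I_n + ((1 - 2 * y) %*% t(u)) / length(idx)) %*% W
          if (!all(is.finite(W)) || max(abs(W)) > 1e8) { diverged <- TRUE; break }
        }
        if (diverged) break
        delta <- W - W_old
        change <- sqrt(sum(delta^2))
        if (!is.null(prev_delta) && sum(delta * prev_delta) < 0)
          lr <- lr * anneal
        prev_delta <- delta
        if (change < tol) { done <- TRUE; break }
      }
      done
    })
    if (!diverged) {
      S <- W %*% Y
      scales <- apply(S, 1, stats::sd)
      S <- S / scales
      W <- W / scales
      o <- orient_rows(S)
      return(list(W = o$flips * W, S = o$S, converged = converged))
    }
  }
  stop_fn("infomax diverged after ", max_retries, " restarts",
          class = "fnoverlap_divergence")
}

#' Dual-regression back-reconstruction of subject maps and timecourses
#'
#' Stage 1 regresses the subject's data on the group spatial maps across
#' voxels, yielding subject timecourses; stage 2 regresses the data on those
#' timecourses across time, yielding subject maps.
#'
#' @param X Standardised subject data, timepoints x in-mask voxels.
#' @param group_maps Group spatial sources, n_ics x in-mask voxels.
#' @param compute_maps Also run stage 2 (default TRUE); stage 2 requires the
#'   stage-1 timecourses to be non-collinear.
#' @return List with `timecourses` (timepoints x n_ics) and `maps`
#'   (n_ics x voxels, `NULL` when `compute_maps` is FALSE).
#' @export
back_reconstruct <- function(X, group_maps, compute_maps = TRUE) {
  G <- group_maps
  if (ncol(X) != ncol(G))
    stop_fn("subject data and group maps are on different masks",
            class = "fnoverlap_validation")
  GGt <- G %*% t(G)
  qrG <- qr(GGt)
  if (qrG$rank < nrow(G)) {
    dep <- setdiff(seq_len(nrow(G)), qrG$pivot[seq_len(qrG$rank)])
    stop_fn("collinear group components: ", paste(dep, collapse = ", "),
            class = "fnoverlap_rank")
  }
  TC <- X %*% t(G) %*% solve(GGt)               # timepoints x n_ics
  if (!compute_maps) return(list(timecourses = TC, maps = NULL))
  TtT <- crossprod(TC)
  qrT <- qr(TtT)
  if (qrT$rank < ncol(TC)) {
    dep <- setdiff(seq_len(ncol(TC)), qrT$pivot[seq_len(qrT$rank)])
    stop_fn("collinear subject timecourses for components: ",
            paste(dep, collapse = ", "), class = "fnoverlap_rank")
  }
  maps <- solve(TtT, t(TC) %*% X)               # n_ics x voxels
  list(timecourses = TC, maps = maps)
}

#' Run group spatial ICA on a cohort
#'
#' Pipeline: per-subject standardisation, subject-level temporal PCA,
#' temporal concatenation, group PCA, whitening, Infomax repeated over
#' ICASSO restarts with cluster-representative selection, component
#' orientation, and dual-regression back-reconstruction.
#'
#' @param cohort List of [volume4d()] runs (>= 2 subjects, one grid).
#' @param mask Logical 3D brain mask.
#' @param config An [ica_config()].
#' @param variance_normalize Passed to [standardize()].
#' @return An object of class `ic_result` with fields `group_maps`
#'   (n_ics x in-mask voxels), `subject_maps`, `subject_timecourses`,
#'   `stability` (see [icasso_cluster()]), `mask`, and `config`.
#' @export
run_group_ica <- function(cohort, mask, config, variance_normalize = TRUE) {
  if (length(cohort) < 2)
    stop_fn("group ICA requires at least 2 subjects",
            class = "fnoverlap_validation")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fn("[", name, "] ", conditionMessage(e)))
  }
  Xs <- stage("standardize", lapply(cohort, standardize, mask = mask,
                                    variance_normalize = variance_normalize))
  red <- stage("subject-pca", lapply(Xs, function(X)
    pca_reduce(X, config$subject_pca_dims)$scores))
  Ycat <- stage("concatenate", do.call(rbind, red))
  grp <- stage("group-pca", pca_reduce(Ycat, config$group_pca_dims))
  wh <- stage("whiten", whiten_rows(grp$scores))
  runs <- stage("infomax", lapply(seq_len(config$n_icasso_runs), function(r) {
    infomax(wh$Y, seed = derive_seed(config$seed, r),
            learning_rate = config$learning_rate,
            block_size = config$block_size, max_sweeps = config$max_sweeps,
            tol = config$tol, anneal = config$anneal)$S
  }))
  stab <- stage("icasso", icasso_cluster(runs, config$n_ics))
  group_maps <- orient_rows(stab$representatives)$S
  br <- stage("back-reconstruct", lapply(Xs, back_reconstruct,
                                         group_maps = group_maps))
  structure(list(group_maps = group_maps,
                 subject_maps = lapply(br, `[[`, "maps"),
                 subject_timecourses = lapply(br, `[[`, "timecourses"),
                 stability = stab, mask = mask, config = config,
                 TR = cohort[[1]]$TR),
            class = "ic_result")
}

#' Orient components so the peak-magnitude voxel of each map is positive
#'
#' Resolves the ICA sign ambiguity consistently across maps, subject maps and
#' timecourses, so that "positive sub-network" is well defined. Idempotent.
#'
#' @param ic An `ic_result`.
#' @return The oriented `ic_result`.
#' @export
orient_components <- function(ic) {
  o <- orient_rows(ic$group_maps)
  ic$group_maps <- o$S
  if (any(o$flips < 0)) {
    ic$subject_maps <- lapply(ic$subject_maps, function(m) o$flips * m)
    ic$subject_timecourses <- lapply(ic$subject_timecourses, function(tc)
      sweep(tc, 2, o$flips, "*"))
  }
  ic
}
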