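# Voxelwise GLM comparison arm: subject-level contrast maps, group
# inference by sign-flip permutation on cluster extent, and the
# cancellation / additivity checks against the ICA decomposition.

#' Fit a voxelwise GLM and form a contrast map for one subject
#'
#' @param v A [volume4d()] (or a timepoints x voxels matrix).
#' @param regressors A [hrf_convolve()] result (intercept included).
#' @param contrast Numeric contrast vector over the modeled conditions (the
#'   intercept is padded with 0 automatically).
#' @param mask Optional logical 3D mask when `v` is a volume; the returned
#'   map is then an in-mask vector.
#' @return Numeric vector (in-mask voxels) of contrast estimates `c' beta`.
#' @export
fit_subject_glm <- function(v, regressors, contrast, mask = NULL) {
  M <- regressors$matrix
  if (length(contrast) != length(regressors$conditions))
    stop_fn("contrast length must equal the number of conditions",
            class = "fnoverlap_validation")
  if (qr(M)$rank < ncol(M))
    stop_fn("rank-deficient design matrix", class = "fnoverlap_rank")
  if (inherits(v, "volume4d")) {
    d <- dim(v$data)
    Y <- t(matrix(v$data, prod(d[1:3]), d[4]))
    if (!is.null(mask)) Y <- Y[, as.vector(mask), drop = FALSE]
  } else {
    Y <- v
  }
  if (nrow(Y) != nrow(M))
    stop_fn("timepoints do not match the design matrix",
            class = "fnoverlap_validation")
  cvec <- c(contrast, rep(0, ncol(M) - length(contrast)))
  B <- solve(crossprod(M), crossprod(M, Y))
  as.vector(cvec %*% B)
}

one_sample_t <- function(maps) {
  n <- nrow(maps)
  mu <- colMeans(maps)
  v <- (colSums(maps^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  out <- numeric(length(mu))
  nz <- v > 0
  out[nz] <- mu[nz] / sqrt(v[nz] / n)
  out
}

max_cluster_extent <- function(tval, thr, mask) {
  mx <- 0
  for (sgn in c(1, -1)) {
    flag <- unmask(sgn * tval > thr, mask) & mask
    sizes <- connected_components_26(flag)$sizes
    if (length(sizes)) mx <- max(mx, sizes)
  }
  mx
}

#' Group cluster inference by sign-flip permutation
#'
#' Computes the one-sample group t-map over subject contrast maps, forms
#' supra-threshold 26-connected clusters separately for positive and
#' negative effects at the voxel-height threshold, and keeps a cluster when
#' its extent exceeds the (1 - `cluster_alpha`) quantile of the null
#' distribution of the maximum cluster extent obtained by randomly
#' sign-flipping subject maps. When `n_permutations` is at least the number
#' of distinct sign patterns, the null is enumerated exhaustively.
#'
#' @param contrast_maps Matrix, subjects x in-mask voxels.
#' @param mask Logical 3D array defining the grid.
#' @param height_p Two-sided voxel-height p threshold (default 0.01).
#' @param cluster_alpha Family-wise cluster error level (default 0.05).
#' @param n_permutations Number of sign-flip permutations (>= 100;
#'   default 1000).
#' @param seed Integer seed for the permutations.
#' @return Object of class `cluster_result`: list with `t` (in-mask vector),
#'   `clusters` (data frame: id, sign, extent, peak_t, p_corrected),
#'   `significant` (logical 3D array of voxels in surviving clusters),
#'   `extent_threshold`, `null_max_extent`, `exhaustive`.
#' @export
group_cluster_inference <- function(contrast_maps, mask, height_p = 0.01,
                                    cluster_alpha = 0.05,
                                    n_permutations = 1000, seed = 1L) {
  n <- nrow(contrast_maps)
  if (n < 2) stop_fn("need >= 2 subjects", class = "fnoverlap_validation")
  if (n_permutations < 100)
    stop_fn("n_permutations must be >= 100", class = "fnoverlap_validation")
  df <- n - 1
  thr <- stats::qt(1 - height_p / 2, df)
  tval <- one_sample_t(contrast_maps)

  exhaustive <- n_permutations >= 2^n
  if (exhaustive) {
    message("permutations capped to exhaustive enumeration of 2^", n,
            " sign patterns")
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    signs <- with_seed(derive_seed(seed, 3L),
                       matrix(sample(c(1, -1), n * n_permutations,
                                     replace = TRUE), ncol = n))
  }
  null_max <- apply(signs, 1, function(s)
    max_cluster_extent(one_sample_t(contrast_maps * s), thr, mask))
  extent_thr <- stats::quantile(null_max, 1 - cluster_alpha, type = 1)

  sig <- array(FALSE, dim(mask))
  rows <- list()
  cid <- 0
  for (sgn in c(1, -1)) {
    flag <- unmask(sgn * tval > thr, mask) & mask
    cc <- connected_components_26(flag)
    for (j in seq_along(cc$sizes)) {
      cid <- cid + 1
      vox <- cc$labels == j
      extent <- cc$sizes[j]
      keep <- extent > extent_thr
      p_corr <- (1 + sum(null_max >= extent)) / (length(null_max) + 1)
      rows[[cid]] <- data.frame(id = cid, sign = sgn, extent = extent,
                                peak_t = sgn * max(sgn * tval[vox[mask]]),
                                p_corrected = p_corr, significant = keep)
      if (keep) sig <- sig | vox
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), sign = numeric(0), extent = integer(0),
               peak_t = numeric(0), p_corrected = numeric(0),
               significant = logical(0))
  structure(list(t = tval, clusters = clusters, significant = sig,
                 extent_threshold = as.numeric(extent_thr),
                 null_max_extent = null_max, exhaustive = exhaustive,
                 height_threshold_t = thr, df = df),
            class = "cluster_result")
}

#' Report GLM significance inside positive/negative network-overlap regions
#'
#' Identifies the voxels covered by at least one positive and at least one
#' negative functional network (where opposite task modulations coexist) and
#' reports what fraction of them the voxelwise GLM arm leaves without
#' significant task-related change — the cancellation signature.
#'
#' @param glm A [group_cluster_inference()] result.
#' @param subnet_masks List of sub-network masks; each element a list with
#'   `ic`, `polarity` (`"positive"`/`"negative"` sub-network of the t-map)
#'   and `values` (logical 3D array).
#' @param classification A [classify_fns()] result.
#' @param condition Condition whose labels are used.
#' @return List with `region` (logical 3D array of pos/neg FN co-overlap),
#'   `n_region`, `n_glm_significant`, `fraction_glm_null`, and
#'   `fn_labels` (the functional-network label assigned to each mask).
#' @export
cancellation_report <- function(glm, subnet_masks, classification, condition) {
  cls <- classification[classification$condition == condition, ]
  fn_label <- function(ic, polarity) {
    lab <- cls$label[cls$ic == ic]
    if (length(lab) != 1) stop_fn("no classification for component ", ic)
    if (lab == "neutral") return("neutral")
    if (polarity == "positive") lab else
      ifelse(lab == "positive", "negative", "positive")
  }
  labels <- vapply(subnet_masks, function(m) fn_label(m$ic, m$polarity),
                   character(1))
  dims <- dim(subnet_masks[[1]]$values)
  pos_cov <- array(FALSE, dims); neg_cov <- array(FALSE, dims)
  for (i in seq_along(subnet_masks)) {
    if (labels[i] == "positive") pos_cov <- pos_cov | subnet_masks[[i]]$values
    if (labels[i] == "negative") neg_cov <- neg_cov | subnet_masks[[i]]$values
  }
  region <- pos_cov & neg_cov
  if (!identical(dim(glm$significant), dims))
    stop_fn("GLM result and masks are on different grids",
            class = "fnoverlap_validation")
  n_region <- sum(region)
  n_sig <- sum(region & glm$significant)
  list(region = region, n_region = n_region, n_glm_significant = n_sig,
       fraction_glm_null = if (n_region > 0) 1 - n_sig / n_region else NA_real_,
       fn_labels = labels)
}

#' Check additivity of component contributions to the GLM contrast
#'
#' Reconstructs the data from the component decomposition as
#' `sum_k timecourse_k (x) map_k`, fits the same GLM contrast to the
#' reconstruction and to the data, and reports the relative discrepancy of
#' the two contrast estimates within a region. For a complete decomposition
#' of noiseless data the discrepancy vanishes; truncating the component set
#' increases it.
#'
#' @param X Standardised subject data, timepoints x in-mask voxels.
#' @param timecourses Subject timecourses, timepoints x n_ics.
#' @param maps Subject maps, n_ics x in-mask voxels.
#' @param regressors A [hrf_convolve()] result.
#' @param contrast Contrast vector over conditions.
#' @param region_mask Logical vector over in-mask voxels (default all).
#' @return List with `estimate_data`, `estimate_reconstruction` (in-region
#'   vectors) and `relative_discrepancy` (L2 norm of the difference over the
#'   L2 norm of the data estimate).
#' @export
additivity_check <- function(X, timecourses, maps, regressors, contrast,
                             region_mask = NULL) {
  region_mask <- region_mask %||% rep(TRUE, ncol(X))
  if (!any(region_mask))
    return(list(estimate_data = numeric(0),
                estimate_reconstruction = numeric(0),
                relative_discrepancy = NA_real_))
  recon <- timecourses %*% maps
  est_data <- fit_subject_glm(X, regressors, contrast)[region_mask]
  est_recon <- fit_subject_glm(recon, regressors, contrast)[region_mask]
  denom <- sqrt(sum(est_data^2))
  list(estimate_data = est_data, estimate_reconstruction = est_recon,
       relative_discrepancy = if (denom > 0)
         sqrt(sum((est_recon - est_data)^2)) / denom else NA_real_)
}
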