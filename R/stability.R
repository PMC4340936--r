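# ICASSO-style stability: cluster components across random restarts and
# score cluster compactness with a stability index.

#' Cluster components across ICA restarts and score stability
#'
#' Pools the spatial sources of all restarts, measures similarity as the
#' absolute Pearson correlation between source maps, clusters by
#' average-linkage agglomeration cut at `n_ics` clusters, and scores each
#' cluster with the stability index
#' `Iq = mean intra-cluster similarity - mean similarity to all
#' out-of-cluster components`. The representative of a cluster is the member
#' nearest its centroid (maximal mean intra-cluster similarity); singleton
#' clusters take intra-similarity 1 by convention.
#'
#' @param runs List (length >= 2) of source matrices, each n_ics x voxels.
#' @param n_ics Number of components per run (and of final clusters).
#' @return List with `report` (data frame: `ic_id`, `iq`, `n_members`,
#'   `rep_run`, `rep_component`), `representatives` (n_ics x voxels matrix,
#'   ordered by decreasing Iq), and `membership` (data frame: run, component,
#'   cluster).
#' @export
icasso_cluster <- function(runs, n_ics) {
  if (length(runs) < 2)
    stop_fn("icasso_cluster needs >= 2 runs", class = "fnoverlap_validation")
  for (S in runs)
    if (nrow(S) != n_ics)
      stop_fn("all runs must contain exactly n_ics components",
              class = "fnoverlap_validation")
  all_S <- do.call(rbind, runs)
  R <- length(runs)
  run_of <- rep(seq_len(R), each = n_ics)
  comp_of <- rep(seq_len(n_ics), times = R)
  sim <- abs(stats::cor(t(all_S)))
  sim[!is.finite(sim)] <- 0
  d <- stats::as.dist(1 - sim)
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = n_ics)
  iq <- numeric(n_ics)
  rep_idx <- integer(n_ics)
  for (c in seq_len(n_ics)) {
    inside <- which(cl == c)
    outside <- which(cl != c)
    if (length(inside) > 1) {
      block <- sim[inside, inside, drop = FALSE]
      intra <- mean(block[upper.tri(block)])
      member_intra <- (rowSums(block) - 1) / (length(inside) - 1)
    } else {
      intra <- 1
      member_intra <- 1
    }
    extra <- if (length(outside) > 0)
      mean(sim[inside, outside, drop = FALSE]) else 0
    iq[c] <- intra - extra
    rep_idx[c] <- inside[which.max(member_intra)]
  }
  ord <- order(iq, decreasing = TRUE)
  report <- data.frame(ic_id = seq_len(n_ics),
                       iq = iq[ord],
                       n_members = as.integer(table(cl)[ord]),
                       rep_run = run_of[rep_idx[ord]],
                       rep_component = comp_of[rep_idx[ord]])
  list(report = report,
       representatives = all_S[rep_idx[ord], , drop = FALSE],
       membership = data.frame(run = run_of, component = comp_of,
                               cluster = match(cl, ord)))
}

#' Write an ICASSO stability report as TSV
#'
#' Adds a `stable` flag at Iq > 0.8, the band conventionally read as a highly
#' stable component.
#'
#' @param stability Result of [icasso_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(stability, path) {
  rep <- stability$report
  rep$stable <- rep$iq > 0.8
  write_table(rep, path)
}
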