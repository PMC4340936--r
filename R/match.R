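# Cross-dataset component matching by spatial correlation ("goodness of
# fit"): pairwise Pearson correlation of component maps with orientation
# resolution, optimal one-to-one assignment, and the r >= 0.5 criterion.

#' Pairwise spatial correlation between two component map sets
#'
#' Pearson correlation over in-mask voxels for every pair of maps. Because
#' ICA component signs are arbitrary, orientation is resolved per pair by
#' taking the sign that maximises the correlation; the chosen sign is
#' recorded. Zero-variance maps yield zero correlations and are flagged.
#'
#' @param setA,setB Matrices, components x in-mask voxels, on one mask.
#' @return List with `r` (orientation-resolved, = |Pearson r|), `sign` (the
#'   sign applied), `raw` (signed correlations) and `zero_variance` flags.
#' @export
correlate_maps <- function(setA, setB) {
  if (ncol(setA) != ncol(setB))
    stop_fn("map sets are on different masks", class = "fnoverlap_validation")
  zvA <- apply(setA, 1, stats::sd) == 0
  zvB <- apply(setB, 1, stats::sd) == 0
  raw <- matrix(0, nrow(setA), nrow(setB))
  ok_a <- which(!zvA); ok_b <- which(!zvB)
  if (length(ok_a) && length(ok_b))
    raw[ok_a, ok_b] <- stats::cor(t(setA[ok_a, , drop = FALSE]),
                                  t(setB[ok_b, , drop = FALSE]))
  sgn <- sign(raw)
  sgn[sgn == 0] <- 1
  list(r = abs(raw), sign = sgn, raw = raw,
       zero_variance = list(A = zvA, B = zvB))
}

#' Match components across decompositions by optimal assignment
#'
#' One-to-one assignment maximising the total orientation-resolved
#' correlation (Hungarian algorithm), or a greedy fallback for parity with
#' ad-hoc practice. Pairs at or above `threshold` are flagged as highly
#' correlated.
#'
#' @param correlation A [correlate_maps()] result (or a plain non-negative
#'   matrix).
#' @param threshold Flagging criterion (default 0.5).
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return Object of class `match_table`: list with `pairs` (data frame:
#'   `icA`, `icB`, `r`, `sign`, `highly_correlated`),
#'   `fraction_highly_correlated`, and `unmatched` (leftover component ids of
#'   the larger set).
#' @export
match_components <- function(correlation, threshold = 0.5,
                             method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (is.matrix(correlation))
    correlation <- list(r = correlation,
                        sign = matrix(1, nrow(correlation), ncol(correlation)))
  R <- correlation$r
  if (any(!is.finite(R)))
    stop_fn("correlation matrix must be finite", class = "fnoverlap_validation")
  nA <- nrow(R); nB <- ncol(R)
  transposed <- nA > nB
  M <- if (transposed) t(R) else R
  if (method == "optimal") {
    sol <- clue::solve_LSAP(M, maximum = TRUE)
    a_idx <- seq_len(nrow(M)); b_idx <- as.integer(sol)
  } else {
    a_idx <- integer(0); b_idx <- integer(0)
    Mw <- M
    for (k in seq_len(nrow(M))) {
      best <- which(Mw == max(Mw), arr.ind = TRUE)[1, ]
      a_idx <- c(a_idx, best[1]); b_idx <- c(b_idx, best[2])
      Mw[best[1], ] <- -Inf; Mw[, best[2]] <- -Inf
    }
  }
  if (transposed) { tmp <- a_idx; a_idx <- b_idx; b_idx <- tmp }
  r <- R[cbind(a_idx, b_idx)]
  pairs <- data.frame(icA = a_idx, icB = b_idx, r = r,
                      sign = correlation$sign[cbind(a_idx, b_idx)],
                      highly_correlated = r >= threshold)
  pairs <- pairs[order(pairs$icA), ]
  rownames(pairs) <- NULL
  unmatched <- if (nA > nB) setdiff(seq_len(nA), pairs$icA) else
    setdiff(seq_len(nB), pairs$icB)
  structure(list(pairs = pairs,
                 fraction_highly_correlated = mean(pairs$highly_correlated),
                 unmatched = unmatched, threshold = threshold),
            class = "match_table")
}

#' Write a match table and the full correlation matrix as TSV
#' @param match A [match_components()] result.
#' @param correlation The [correlate_maps()] result it was built from.
#' @param path Output path for the pair table; the full matrix is written
#'   alongside with suffix `_matrix.tsv`.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(match, correlation, path) {
  write_table(match$pairs, path)
  mat_path <- sub("\\.tsv$", "_matrix.tsv", path)
  write_table(as.data.frame(correlation$r), mat_path)
  invisible(path)
}
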