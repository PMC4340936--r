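# Per-IC group t-maps, FDR thresholding into positive/negative sub-network
# masks, voxelwise overlap maps, volume summaries, and spectral artifact
# indicators.

#' Voxelwise one-sample group t-map for one component
#'
#' @param subject_maps Matrix, subjects x in-mask voxels, of one component's
#'   back-reconstructed subject map values.
#' @return Object of class `t_map`: list with `t`, `p` (two-sided), `df`
#'   (subjects - 1) and `zero_variance` (logical flag per voxel; such voxels
#'   get t = 0, p = 1 and are excluded from FDR pools).
#' @export
group_t_map <- function(subject_maps) {
  n <- nrow(subject_maps)
  if (n < 2)
    stop_fn("group t-map requires >= 2 subjects", class = "fnoverlap_validation")
  mu <- colMeans(subject_maps)
  sds <- apply(subject_maps, 2, stats::sd)
  zero <- sds == 0
  tval <- ifelse(zero, 0, mu / (sds / sqrt(n)))
  p <- ifelse(zero, 1, 2 * stats::pt(-abs(tval), df = n - 1))
  structure(list(t = tval, p = p, df = n - 1, zero_variance = zero),
            class = "t_map")
}

#' Benjamini-Hochberg rejection set
#'
#' Step-up BH over a p-value vector at level `q`; returns the logical
#' rejection indicator.
#'
#' @param p Numeric vector of p-values.
#' @param q FDR level in (0, 1).
#' @return Logical vector, TRUE where rejected.
#' @export
bh_reject <- function(p, q) {
  if (length(p) == 0) return(logical(0))
  stats::p.adjust(p, method = "BH") <= q
}

#' Threshold a t-map into positive and negative sub-network masks
#'
#' Applies Benjamini-Hochberg FDR across the in-mask voxel p-values (zero
#' variance voxels excluded from the pool) and splits surviving voxels by the
#' sign of t into a positive and a negative binary mask.
#'
#' @param tmap A [group_t_map()] result.
#' @param level FDR level (default 0.001).
#' @return List with logical vectors `positive` and `negative` (same length
#'   as the in-mask t vector; always disjoint).
#' @export
fdr_threshold <- function(tmap, level = 0.001) {
  if (level <= 0 || level >= 1) stop_fn("level must be in (0,1)")
  sig <- logical(length(tmap$p))
  pool <- !tmap$zero_variance
  sig[pool] <- bh_reject(tmap$p[pool], level)
  list(positive = sig & tmap$t > 0,
       negative = sig & tmap$t < 0)
}

#' Voxelwise overlap map of binary sub-network masks
#'
#' @param masks List of binary masks (logical/integer arrays or vectors on a
#'   common grid).
#' @param ids Optional identifiers of the contributing masks.
#' @return Object of class `overlap_map`: list with `counts` (integer array
#'   or vector: exact voxelwise sum of the masks), `max_overlap` and `ids`.
#' @export
overlap_map <- function(masks, ids = NULL) {
  if (length(masks) == 0) stop_fn("no masks supplied")
  dims <- dim(masks[[1]]) %||% length(masks[[1]])
  counts <- masks[[1]] * 0L
  for (m in masks) {
    if (!identical(dim(m) %||% length(m), dims))
      stop_fn("masks are on different grids", class = "fnoverlap_validation")
    counts <- counts + as.integer(m)
  }
  structure(list(counts = counts,
                 max_overlap = max(counts),
                 ids = ids %||% seq_along(masks)),
            class = "overlap_map")
}

#' Union-volume summary of sub-network masks by class
#'
#' For each class (positive / negative / neutral), reports the number of
#' voxels covered by the union of its masks and the percentage of the brain
#' mask, plus pairwise class-union intersections and the union over all
#' classes.
#'
#' @param masks_by_class Named list of lists of binary masks, names among
#'   `positive`, `negative`, `neutral`.
#' @param brain_mask Logical array/vector: the whole-brain denominator.
#' @return Data frame with columns `class`, `n_voxels`, `pct_brain`.
#' @export
volume_summary <- function(masks_by_class, brain_mask) {
  stopifnot(all(names(masks_by_class) %in% c("positive", "negative", "neutral")))
  nb <- sum(brain_mask)
  unions <- lapply(masks_by_class, function(ms) {
    if (length(ms) == 0) return(brain_mask & FALSE)
    u <- as.logical(ms[[1]])
    for (m in ms[-1]) u <- u | as.logical(m)
    u
  })
  rows <- data.frame(class = names(unions),
                     n_voxels = vapply(unions, sum, numeric(1)),
                     stringsAsFactors = FALSE)
  cls <- names(unions)
  if (length(cls) >= 2) {
    for (i in seq_len(length(cls) - 1)) for (j in (i + 1):length(cls)) {
      rows <- rbind(rows, data.frame(
        class = paste(cls[i], cls[j], sep = "&"),
        n_voxels = sum(unions[[i]] & unions[[j]])))
    }
  }
  all_u <- Reduce(`|`, unions)
  rows <- rbind(rows, data.frame(class = "all", n_voxels = sum(all_u)))
  rows$pct_brain <- 100 * rows$n_voxels / nb
  rownames(rows) <- NULL
  rows
}

# Hann-windowed periodogram of a single timecourse; returns freq (Hz), power.
periodogram_hann <- function(x, TR) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  X <- stats::fft(x * w)
  nf <- floor(n / 2)
  freq <- (1:nf) / (n * TR)
  power <- Mod(X[2:(nf + 1)])^2 / n
  list(freq = freq, power = power)
}

#' Spectral and tissue-based artifact indicators per component
#'
#' For each component, computes (a) the ratio of integrated spectral power
#' below 0.10 Hz to integrated power between 0.15 and 0.25 Hz, from the mean
#' Hann-windowed periodogram over subject timecourses; (b) the dynamic range
#' of the smoothed spectrum (max - min); and (c), if tissue masks are
#' supplied, whether the peak-|t| voxel lies in white matter or CSF. Flags
#' are advisory: components are reported, never removed.
#'
#' @param ic An `ic_result` from [run_group_ica()].
#' @param TR Repetition time in seconds (default taken from `ic`).
#' @param tissue_masks Optional list with logical arrays `wm` and/or `csf`
#'   on the analysis grid.
#' @param ratio_cutoff Flag components with power ratio below this value
#'   (default 2).
#' @param dynrange_cutoff Flag components whose normalised spectral dynamic
#'   range falls below this value (default 0.1).
#' @return Data frame: `ic_id`, `power_ratio`, `dynamic_range`,
#'   `peak_in_wm_csf`, `flagged`.
#' @export
flag_artifact_components <- function(ic, TR = NULL, tissue_masks = NULL,
                                     ratio_cutoff = 2, dynrange_cutoff = 0.1) {
  TR <- TR %||% ic$TR
  n_ics <- nrow(ic$group_maps)
  nyquist <- 1 / (2 * TR)
  hi_band <- c(0.15, 0.25)
  if (nyquist < hi_band[2]) {
    warning("Nyquist frequency ", round(nyquist, 3),
            " Hz below 0.25 Hz; truncating the artifact band")
    hi_band[2] <- nyquist
    if (hi_band[1] >= hi_band[2]) hi_band[1] <- hi_band[2] / 2
  }
  out <- data.frame(ic_id = seq_len(n_ics), power_ratio = NA_real_,
                    dynamic_range = NA_real_, peak_in_wm_csf = FALSE,
                    flagged = FALSE)
  for (k in seq_len(n_ics)) {
    spectra <- lapply(ic$subject_timecourses, function(tc)
      periodogram_hann(tc[, k], TR))
    power <- rowMeans(do.call(cbind, lapply(spectra, `[[`, "power")))
    freq <- spectra[[1]]$freq
    lo <- sum(power[freq < 0.10])
    hi <- sum(power[freq >= hi_band[1] & freq <= hi_band[2]])
    out$power_ratio[k] <- if (hi > 0) lo / hi else Inf
    sm <- stats::filter(power, rep(1 / 3, 3), sides = 2)
    sm <- sm[!is.na(sm)]
    out$dynamic_range[k] <- (max(sm) - min(sm)) / sum(power)
    if (!is.null(tissue_masks)) {
      peak <- which.max(abs(ic$group_maps[k, ]))
      inmask_idx <- which(ic$mask)[peak]
      in_bad <- FALSE
      for (tm in tissue_masks)
        if (as.logical(tm[inmask_idx])) in_bad <- TRUE
      out$peak_in_wm_csf[k] <- in_bad
    }
  }
  out$flagged <- out$power_ratio < ratio_cutoff |
    out$dynamic_range < dynrange_cutoff | out$peak_in_wm_csf
  out
}
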