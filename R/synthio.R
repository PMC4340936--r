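# Synthetic multi-subject 4D BOLD generator with planted overlapping networks.
#
# The generative model mirrors the spatial-ICA assumption that the signal in
# each voxel is a linear mixture of network source signals:
#   data(v, t) = sum_k map_k(v) * c_k(t) + noise,
# where each network timecourse c_k is a weighted sum of HRF-convolved task
# regressors (the planted condition betas) plus a slow network-specific
# fluctuation that gives task-neutral networks variance for ICA to find.

#' Construct a design specification
#'
#' @param events Data frame with columns `onset`, `duration` (seconds) and
#'   `condition`.
#' @param TR Repetition time in seconds.
#' @param n_timepoints Number of volumes in the run.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(events, TR, n_timepoints) {
  events <- as.data.frame(events)
  required <- c("onset", "duration", "condition")
  if (!all(required %in% names(events)))
    stop_fn("events must have columns onset, duration, condition",
            class = "fnoverlap_validation")
  events$condition <- as.character(events$condition)
  if (nrow(events) > 0) {
    if (any(events$onset < 0))
      stop_fn("event onsets must be non-negative", class = "fnoverlap_validation")
    if (any(events$duration < 0))
      stop_fn("event durations must be non-negative", class = "fnoverlap_validation")
    if (any(events$onset + events$duration > TR * n_timepoints))
      stop_fn("events extend beyond the end of the run",
              class = "fnoverlap_validation")
  }
  structure(list(conditions = unique(events$condition),
                 events = events, TR = TR, n_timepoints = n_timepoints),
            class = "design_spec")
}

#' Construct a 4D BOLD-like volume
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_size_mm Per-axis voxel size in mm (length 3).
#' @param TR Repetition time in seconds.
#' @param affine Optional 4x4 voxel-to-world transform; defaults to a scaled
#'   identity built from the voxel size.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, voxel_size_mm = c(3, 3, 3), TR = 1.5, affine = NULL) {
  if (length(dim(data)) != 4L)
    stop_fn("volume4d requires a 4D array", class = "fnoverlap_dimension")
  assert_finite(data, "volume4d data")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm, TR = TR,
                 affine = affine),
            class = "volume4d")
}

#' @export
dim.volume4d <- function(x) dim(x$data)

#' Bundle planted ground truth for a synthetic cohort
#'
#' @param networks List of 3D spatial maps on a common grid, each normalised
#'   to maximum absolute value 1.
#' @param betas Numeric matrix (networks x conditions) of task modulation
#'   amplitudes; `dimnames` column names must name the conditions.
#' @param noise_sd Standard deviation of the iid Gaussian voxel noise.
#' @param subject_map_jitter_sd Standard deviation of the smooth spatial
#'   perturbation applied to each subject's copy of every network map.
#' @param fluct_amp Amplitude of the slow sinusoidal fluctuation added to each
#'   network timecourse (default 0.4, in the same arbitrary units as the
#'   HRF-convolved regressors).
#' @param fluct_period_s Base period of the slow fluctuation in seconds
#'   (default 60); each network is assigned its own period near this value so
#'   networks remain temporally distinguishable.
#' @param seed Integer seed controlling the network-specific periods.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(networks, betas, noise_sd = 1,
                         subject_map_jitter_sd = 0.05,
                         fluct_amp = 0.4, fluct_period_s = 60, seed = 1L) {
  betas <- as.matrix(betas)
  if (nrow(betas) != length(networks))
    stop_fn("betas must have one row per network", class = "fnoverlap_validation")
  if (is.null(colnames(betas)))
    stop_fn("betas must carry condition names as column names",
            class = "fnoverlap_validation")
  if (any(!is.finite(betas)))
    stop_fn("betas table must be complete and finite",
            class = "fnoverlap_validation")
  if (noise_sd < 0)
    stop_fn("noise_sd must be non-negative", class = "fnoverlap_validation")
  # network-specific fluctuation periods/phases, fixed by the truth seed
  periods <- with_seed(derive_seed(seed, 0L),
                       fluct_period_s * stats::runif(length(networks), 0.7, 1.3))
  structure(list(networks = networks, betas = betas, noise_sd = noise_sd,
                 subject_map_jitter_sd = subject_map_jitter_sd,
                 fluct_amp = fluct_amp, fluct_periods_s = periods,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

place_centers <- function(n, grid_dims, margin, min_sep, seed) {
  # rejection-sample blob centres away from edges and from each other;
  # if the grid cannot honour the separation, relax it stepwise (the looser
  # packing is still asserted against the overlap postcondition downstream)
  try_once <- function(sep, attempt) {
    with_seed(derive_seed(seed, attempt), {
      centers <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in 1:500) {
          cand <- vapply(1:3, function(a)
            stats::runif(1, 1 + margin, grid_dims[a] - margin), numeric(1))
          if (i == 1 ||
              all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                     2, cand)^2)) >= sep)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) return(NULL)
        centers[i, ] <- cand
      }
      centers
    })
  }
  for (attempt in 0:5) {
    centers <- try_once(min_sep * 0.8^attempt, attempt)
    if (!is.null(centers)) return(centers)
  }
  stop_fn("grid too small to place the requested blobs",
          class = "fnoverlap_sizing")
}

#' Build a single Gaussian blob map at an explicit location
#'
#' Utility for constructing custom ground-truth networks (for instance,
#' amplitude-matched pairs sharing one region) when the randomised
#' [make_network_library()] geometry is not wanted.
#'
#' @param grid_dims Voxel counts per axis.
#' @param center Blob centre in voxel coordinates (length 3).
#' @param hwhm Half-width at half maximum in voxels.
#' @return 3D array with maximum value 1 at the centre.
#' @export
blob_map <- function(grid_dims, center, hwhm) {
  gaussian_blob(grid_dims, center, hwhm / sqrt(2 * log(2)))
}

gaussian_blob <- function(grid_dims, center, sigma) {
  dx2 <- outer(seq_len(grid_dims[1]) - center[1], rep(1, grid_dims[2]))^2
  g2 <- dx2 + outer(rep(1, grid_dims[1]), (seq_len(grid_dims[2]) - center[2])^2)
  z2 <- (seq_len(grid_dims[3]) - center[3])^2
  arr <- array(0, grid_dims)
  for (k in seq_len(grid_dims[3]))
    arr[, , k] <- exp(-(g2 + z2[k]) / (2 * sigma^2))
  arr
}

#' Generate a library of overlapping smooth spatial networks
#'
#' Each network map is a sum of 3D Gaussian blobs, unit-normalised to maximum
#' absolute value 1. Pairs named in `overlap_spec` share a blob centre, which
#' guarantees a non-empty intersection of their half-maximum supports. Shared
#' blobs are compact (narrow end of the width range, amplitude 0.8), so an
#' overlap region is a focal zone within two distributed networks rather
#' than the bulk of either.
#'
#' @param n_networks Number of networks (>= 1).
#' @param grid_dims Voxel counts per axis (default 20 x 20 x 12).
#' @param overlap_spec List of length-2 integer vectors naming network pairs
#'   (1-based) that must overlap.
#' @param seed Integer seed.
#' @param sigma_range Range of Gaussian blob widths, as half-widths at half
#'   maximum in voxels (default 2 to 4).
#' @param blobs_per_network Number of private blobs per network (default 2),
#'   emulating distributed networks whose overlap regions are a minority of
#'   their volume.
#' @return List of 3D arrays, one per network.
#' @export
make_network_library <- function(n_networks, grid_dims = c(20, 20, 12),
                                 overlap_spec = list(), seed = 1L,
                                 sigma_range = c(2, 4),
                                 blobs_per_network = 2) {
  if (n_networks < 1) stop_fn("n_networks must be >= 1")
  for (pr in overlap_spec) {
    if (length(pr) != 2 || any(pr < 1) || any(pr > n_networks))
      stop_fn("overlap_spec references invalid network indices",
              class = "fnoverlap_validation")
  }
  # HWHM -> Gaussian sd: sd = HWHM / sqrt(2 ln 2)
  sd_range <- sigma_range / sqrt(2 * log(2))
  margin <- ceiling(min(sd_range))
  if (any(grid_dims <= 2 * margin + 1))
    stop_fn("grid too small to place the requested blobs",
            class = "fnoverlap_sizing")
  n_private <- n_networks * blobs_per_network
  n_centers <- n_private + length(overlap_spec)
  centers <- place_centers(n_centers, grid_dims, margin,
                           min_sep = 1.5 * max(sd_range),
                           seed = derive_seed(seed, 1L))
  sigmas <- with_seed(derive_seed(seed, 2L),
                      stats::runif(n_centers, sd_range[1], sd_range[2]))
  if (length(overlap_spec) > 0)
    sigmas[(n_private + 1):n_centers] <- sd_range[1]
  maps <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    idx <- (k - 1) * blobs_per_network + seq_len(blobs_per_network)
    m <- 0
    for (i in idx) m <- m + gaussian_blob(grid_dims, centers[i, ], sigmas[i])
    maps[[k]] <- m
  }
  # shared blobs realise the requested overlaps
  for (j in seq_along(overlap_spec)) {
    pr <- overlap_spec[[j]]
    shared <- 0.8 * gaussian_blob(grid_dims, centers[n_private + j, ],
                                  sigmas[n_private + j])
    maps[[pr[1]]] <- maps[[pr[1]]] + shared
    maps[[pr[2]]] <- maps[[pr[2]]] + shared
  }
  maps <- lapply(maps, function(m) m / max(abs(m)))
  for (pr in overlap_spec) {
    both <- maps[[pr[1]]] > 0.5 & maps[[pr[2]]] > 0.5
    if (!any(both))
      stop_fn("failed to realise requested overlap; enlarge the grid",
              class = "fnoverlap_sizing")
  }
  maps
}

#' Generate task event timing
#'
#' Event-related designs draw jittered inter-trial intervals; block designs
#' place fixed-duration blocks separated by rest gaps. Events are assigned to
#' conditions round-robin.
#'
#' @param template `"event"` or `"block"`.
#' @param n_events Total number of trials or blocks.
#' @param TR Repetition time (s).
#' @param n_timepoints Volumes per run.
#' @param seed Integer seed for the jitter.
#' @param conditions Character vector of condition names.
#' @param event_duration Trial duration for the event template (s).
#' @param iti_range Inter-trial interval range for the event template (s).
#' @param block_duration Block length for the block template (s).
#' @param rest_gap Rest between blocks for the block template (s).
#' @return A [design_spec()].
#' @export
make_design <- function(template = c("event", "block"), n_events, TR,
                        n_timepoints, seed = 1L, conditions = "task",
                        event_duration = 1, iti_range = c(8, 14),
                        block_duration = 19.2, rest_gap = 12) {
  template <- match.arg(template)
  run_len <- TR * n_timepoints
  if (n_events == 0) {
    ev <- data.frame(onset = numeric(0), duration = numeric(0),
                     condition = character(0))
    return(design_spec(ev, TR, n_timepoints))
  }
  if (template == "event") {
    itis <- with_seed(seed, stats::runif(n_events, iti_range[1], iti_range[2]))
    onsets <- cumsum(itis)
    durs <- rep(event_duration, n_events)
  } else {
    onsets <- rest_gap + (seq_len(n_events) - 1) * (block_duration + rest_gap)
    durs <- rep(block_duration, n_events)
  }
  if (any(onsets + durs > run_len))
    stop_fn("run too short for the requested events",
            class = "fnoverlap_sizing")
  cond <- rep(conditions, length.out = n_events)
  ev <- data.frame(onset = onsets, duration = durs, condition = cond,
                   stringsAsFactors = FALSE)
  design_spec(ev, TR, n_timepoints)
}

# Network timecourses implied by the truth for one subject:
# HRF-convolved condition regressors weighted by the planted betas, plus the
# slow network-specific sinusoid. Returns timepoints x networks.
truth_timecourses <- function(truth, design, subject_seed) {
  n_t <- design$n_timepoints
  K <- length(truth$networks)
  tc <- matrix(0, n_t, K)
  if (length(design$conditions) > 0) {
    regs <- hrf_convolve(design, intercept = FALSE)
    for (cond in colnames(truth$betas)) {
      if (!cond %in% colnames(regs$matrix)) next
      tc <- tc + outer(regs$matrix[, cond], truth$betas[, cond])
    }
  }
  if (truth$fluct_amp > 0) {
    phases <- with_seed(derive_seed(subject_seed, 17L),
                        stats::runif(K, 0, 2 * pi))
    tsec <- (seq_len(n_t) - 1) * design$TR
    for (k in seq_len(K))
      tc[, k] <- tc[, k] + truth$fluct_amp *
        sin(2 * pi * tsec / truth$fluct_periods_s[k] + phases[k])
  }
  tc
}

#' Simulate one subject-run from planted ground truth
#'
#' @param truth A [ground_truth()].
#' @param design A [design_spec()].
#' @param subject_seed Integer seed for this subject's noise, spatial jitter
#'   and fluctuation phases.
#' @param voxel_size_mm Voxel size of the output volume.
#' @return A [volume4d()] plus, as attribute `subject_maps`, the jittered
#'   per-subject network maps actually used.
#' @export
simulate_subject <- function(truth, design, subject_seed,
                             voxel_size_mm = c(3, 3, 3)) {
  grid_dims <- dim(truth$networks[[1]])
  for (m in truth$networks)
    if (!identical(dim(m), grid_dims))
      stop_fn("all networks must share one grid", class = "fnoverlap_validation")
  K <- length(truth$networks)
  n_t <- design$n_timepoints
  V <- prod(grid_dims)
  maps <- matrix(0, V, K)
  for (k in seq_len(K)) {
    m <- truth$networks[[k]]
    if (truth$subject_map_jitter_sd > 0) {
      field <- with_seed(derive_seed(subject_seed, 100L + k),
                         array(stats::rnorm(V), grid_dims))
      field <- smooth_3d(field, sigma_vox = rep(1, 3))
      field <- field / stats::sd(field) * truth$subject_map_jitter_sd
      m <- m + field
    }
    maps[, k] <- as.vector(m)
  }
  tc <- truth_timecourses(truth, design, subject_seed)
  dat <- maps %*% t(tc)                       # V x T
  if (truth$noise_sd > 0)
    dat <- dat + with_seed(derive_seed(subject_seed, 999L),
                           matrix(stats::rnorm(V * n_t, sd = truth$noise_sd),
                                  V, n_t))
  vol <- volume4d(array(dat, c(grid_dims, n_t)),
                  voxel_size_mm = voxel_size_mm, TR = design$TR)
  attr(vol, "subject_maps") <- maps
  attr(vol, "true_timecourses") <- tc
  vol
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the cohort seed, so a
#' cohort is bitwise reproducible. If `dir` is given, each run is written as
#' NIfTI-1, the design as a BIDS-style events TSV, and the ground truth as a
#' JSON sidecar plus NIfTI network maps.
#'
#' @param truth A [ground_truth()].
#' @param design A [design_spec()].
#' @param n_subjects Number of subjects (>= 2; group t-tests are undefined
#'   otherwise).
#' @param seed Cohort seed.
#' @param dir Optional output directory.
#' @return List with elements `volumes` (list of [volume4d()]), `truth`,
#'   `design`, `subject_seeds`, and `manifest` (path, when written).
#' @export
simulate_cohort <- function(truth, design, n_subjects, seed = 1L, dir = NULL) {
  if (n_subjects < 2)
    stop_fn("n_subjects must be >= 2 (group t-tests undefined)",
            class = "fnoverlap_validation")
  subject_seeds <- vapply(seq_len(n_subjects),
                          function(i) derive_seed(seed, i), integer(1))
  volumes <- lapply(subject_seeds, function(s)
    simulate_subject(truth, design, s))
  out <- list(volumes = volumes, truth = truth, design = design,
              subject_seeds = subject_seeds)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    run_paths <- character(n_subjects)
    ev_path <- file.path(dir, "events.tsv")
    write_events(design, ev_path)
    for (i in seq_len(n_subjects)) {
      run_paths[i] <- file.path(dir, sprintf("sub-%02d_bold.nii.gz", i))
      write_volume4d(volumes[[i]], run_paths[i])
    }
    for (k in seq_along(truth$networks))
      write_map(truth$networks[[k]],
                file.path(dir, sprintf("truth_network-%02d.nii.gz", k)))
    truth_json <- list(
      n_networks = length(truth$networks),
      betas = truth$betas, conditions = colnames(truth$betas),
      noise_sd = truth$noise_sd,
      subject_map_jitter_sd = truth$subject_map_jitter_sd,
      fluct_amp = truth$fluct_amp, fluct_periods_s = truth$fluct_periods_s,
      seed = truth$seed)
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      subjects = sprintf("sub-%02d", seq_len(n_subjects)),
      runs = run_paths, events = rep(ev_path, n_subjects), TR = design$TR)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- file.path(dir, "manifest.json")
  }
  out
}
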