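# End-to-end driver: compose simulation, ICA, temporal sorting, overlap
# mapping, the GLM comparison arm and cross-cohort matching, writing every
# report to disk with a machine-readable log of all seeds and thresholds.

#' Desk-scale preset configurations
#'
#' Presets encode the shapes of common task designs at desk scale:
#' `"flanker-mini"` is event-related with two trial types and jittered
#' inter-trial intervals; `"attention-mini"` is a block design with
#' load-graded betas; `"midt-mini"` has two-phase trials (anticipation
#' blocks and outcome events).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A configuration list accepted by [run_pipeline()].
#' @export
preset_config <- function(name = c("flanker-mini", "attention-mini",
                                   "midt-mini"), seed = 1L) {
  name <- match.arg(name)
  base <- list(
    preset = name, seed = as.integer(seed),
    grid_dims = c(20, 20, 12), voxel_size_mm = c(3, 3, 3),
    TR = 1.5, n_timepoints = 150, n_subjects = 8,
    n_networks = 6, overlap_pairs = list(c(1, 2), c(3, 4), c(5, 6)),
    noise_sd = 1, subject_map_jitter_sd = 0.05, smooth_fwhm_mm = 8,
    n_ics = 10, n_icasso_runs = 10,
    fdr_level = 0.001, sort_alpha = 0.05,
    glm_height_p = 0.01, glm_cluster_alpha = 0.05, glm_permutations = 500,
    match_threshold = 0.5, beta_amplitude = 1)
  base$design <- switch(
    name,
    "flanker-mini" = list(template = "event", n_events = 16,
                          conditions = c("congruent", "incongruent"),
                          event_duration = 1),
    "attention-mini" = list(template = "block", n_events = 6,
                            conditions = c("low", "high"),
                            block_duration = 19.2, rest_gap = 12),
    "midt-mini" = list(template = "event", n_events = 16,
                       conditions = c("anticipation", "outcome"),
                       event_duration = 2))
  # planted betas: pairs of opposite-modulation networks plus neutral ones
  b <- base$beta_amplitude
  betas <- matrix(0, base$n_networks, length(base$design$conditions),
                  dimnames = list(NULL, base$design$conditions))
  betas[1, 1] <- b; betas[2, 1] <- -b
  betas[3, 2] <- b; betas[4, 2] <- -b
  base$betas <- betas
  base
}

log_line <- function(con, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full functional-network-overlap pipeline on synthetic data
#'
#' Simulates a cohort from the configuration, runs group ICA with stability
#' assessment, temporally sorts and classifies components, builds
#' sub-network masks, overlap maps and volume summaries, runs the voxelwise
#' GLM arm with permutation cluster inference and the cancellation report,
#' and (optionally) simulates a second cohort sharing the same ground truth
#' to report cross-cohort component matching. All artifacts and a JSON-lines
#' run log (recording every seed and threshold) are written under `out_dir`.
#'
#' @param config Configuration list (see [preset_config()]) or path to a
#'   JSON file with the same fields.
#' @param out_dir Output directory.
#' @param second_cohort Simulate a second cohort for cross-dataset matching
#'   (default TRUE).
#' @return Invisibly, a list with all in-memory results (`cohort`, `ica`,
#'   `classification`, `overlap`, `volume_summary`, `glm`, `cancellation`,
#'   `match`).
#' @export
run_pipeline <- function(config, out_dir, second_cohort = TRUE) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  required <- c("seed", "grid_dims", "TR", "n_timepoints", "n_subjects",
                "n_networks", "betas", "n_ics", "design")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop_fn("config is missing fields: ", paste(missing, collapse = ", "),
            class = "fnoverlap_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run_log.jsonl"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "start", seed = config$seed,
           smooth_fwhm_mm = config$smooth_fwhm_mm %||% 0,
           fdr_level = config$fdr_level, sort_alpha = config$sort_alpha,
           glm_height_p = config$glm_height_p,
           glm_cluster_alpha = config$glm_cluster_alpha)

  # --- simulate -------------------------------------------------------------
  networks <- make_network_library(config$n_networks, config$grid_dims,
                                   config$overlap_pairs,
                                   seed = derive_seed(config$seed, 11L))
  des <- config$design
  design <- make_design(des$template, des$n_events, config$TR,
                        config$n_timepoints,
                        seed = derive_seed(config$seed, 12L),
                        conditions = des$conditions,
                        event_duration = des$event_duration %||% 1,
                        block_duration = des$block_duration %||% 19.2,
                        rest_gap = des$rest_gap %||% 12)
  truth <- ground_truth(networks, as.matrix(config$betas),
                        noise_sd = config$noise_sd,
                        subject_map_jitter_sd = config$subject_map_jitter_sd,
                        seed = derive_seed(config$seed, 13L))
  cohort <- simulate_cohort(truth, design, config$n_subjects,
                            seed = derive_seed(config$seed, 14L),
                            dir = file.path(out_dir, "cohort1"))
  log_line(logf, "simulated", n_subjects = config$n_subjects,
           cohort_seed = derive_seed(config$seed, 14L))

  # --- preprocess and group ICA ---------------------------------------------
  fwhm <- config$smooth_fwhm_mm %||% 0
  smoothed <- lapply(cohort$volumes, gaussian_smooth, fwhm_mm = fwhm)
  mask <- compute_mask(smoothed)
  cfg <- ica_config(config$n_ics, n_icasso_runs = config$n_icasso_runs,
                    seed = derive_seed(config$seed, 15L))
  ica <- run_group_ica(smoothed, mask, cfg)
  write_stability_report(ica$stability, file.path(out_dir, "stability.tsv"))
  log_line(logf, "ica", n_ics = config$n_ics,
           icasso_runs = config$n_icasso_runs,
           ica_seed = cfg$seed, min_iq = min(ica$stability$report$iq))

  # --- temporal sorting and classification ----------------------------------
  regs <- hrf_convolve(design)
  betas <- sort_timecourses(ica$subject_timecourses, regs)
  cls <- classify_fns(betas, alpha = config$sort_alpha)
  write_table(cls, file.path(out_dir, "classification.tsv"))

  # --- sub-network masks, overlap, volumes ----------------------------------
  subnet_masks <- list()
  for (k in seq_len(config$n_ics)) {
    sm <- do.call(rbind, lapply(ica$subject_maps, function(m) m[k, ]))
    masks <- fdr_threshold(group_t_map(sm), level = config$fdr_level)
    for (pol in c("positive", "negative"))
      subnet_masks[[length(subnet_masks) + 1]] <-
        list(ic = k, polarity = pol, values = unmask(masks[[pol]], mask) > 0)
  }
  ov <- overlap_map(lapply(subnet_masks, `[[`, "values"))
  write_map(array(as.integer(ov$counts), dim(mask)),
            file.path(out_dir, "overlap_map.nii.gz"))
  cond1 <- design$conditions[1]
  by_class <- list(positive = list(), negative = list(), neutral = list())
  for (m in subnet_masks) {
    lab <- cls$label[cls$ic == m$ic & cls$condition == cond1]
    fn_lab <- if (lab == "neutral") "neutral" else if (m$polarity == "positive")
      lab else setdiff(c("positive", "negative"), lab)
    by_class[[fn_lab]][[length(by_class[[fn_lab]]) + 1]] <- m$values
  }
  vols <- volume_summary(by_class, mask)
  write_table(vols, file.path(out_dir, "volume_summary.tsv"))
  log_line(logf, "overlap", max_overlap = ov$max_overlap,
           fdr_level = config$fdr_level)

  # --- GLM arm and cancellation ---------------------------------------------
  cmaps <- do.call(rbind, lapply(smoothed, function(v)
    fit_subject_glm(v, regs, contrast = as.numeric(
      design$conditions == cond1), mask = mask)))
  glm <- group_cluster_inference(cmaps, mask,
                                 height_p = config$glm_height_p,
                                 cluster_alpha = config$glm_cluster_alpha,
                                 n_permutations = config$glm_permutations,
                                 seed = derive_seed(config$seed, 16L))
  write_table(glm$clusters, file.path(out_dir, "glm_clusters.tsv"))
  canc <- cancellation_report(glm, subnet_masks, cls, cond1)
  write_table(data.frame(n_region = canc$n_region,
                         n_glm_significant = canc$n_glm_significant,
                         fraction_glm_null = canc$fraction_glm_null),
              file.path(out_dir, "cancellation.tsv"))
  log_line(logf, "glm", height_p = config$glm_height_p,
           cluster_alpha = config$glm_cluster_alpha,
           permutations = config$glm_permutations,
           glm_seed = derive_seed(config$seed, 16L))

  # --- cross-cohort matching ------------------------------------------------
  match_res <- NULL
  if (isTRUE(second_cohort)) {
    cohort2 <- simulate_cohort(truth, design, config$n_subjects,
                               seed = derive_seed(config$seed, 24L),
                               dir = file.path(out_dir, "cohort2"))
    smoothed2 <- lapply(cohort2$volumes, gaussian_smooth, fwhm_mm = fwhm)
    ica2 <- run_group_ica(smoothed2, mask,
                          ica_config(config$n_ics,
                                     n_icasso_runs = config$n_icasso_runs,
                                     seed = derive_seed(config$seed, 25L)))
    corr <- correlate_maps(ica$group_maps, ica2$group_maps)
    match_res <- match_components(corr, threshold = config$match_threshold)
    write_match_table(match_res, corr, file.path(out_dir, "match.tsv"))
    log_line(logf, "match",
             fraction_highly_correlated = match_res$fraction_highly_correlated,
             threshold = config$match_threshold)
  }
  log_line(logf, "done")
  invisible(list(cohort = cohort, mask = mask, ica = ica, betas = betas,
                 classification = cls, subnet_masks = subnet_masks,
                 overlap = ov, volume_summary = vols, glm = glm,
                 cancellation = canc, match = match_res, design = design,
                 truth = truth))
}
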