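# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs in minutes.

# A small two-condition block-design cohort with planted networks.
small_cohort <- function(n_networks = 4, grid_dims = c(14, 14, 8),
                         n_subjects = 6, n_timepoints = 100, TR = 1.5,
                         noise_sd = 0.5, jitter = 0.05, fluct_amp = 0.4,
                         betas = NULL, seed = 101) {
  nets <- make_network_library(n_networks, grid_dims,
                               overlap_spec = list(c(1, 2)), seed = seed,
                               sigma_range = c(1.5, 2.5),
                               blobs_per_network = 1)
  n_events <- max(2, min(4, floor(TR * n_timepoints / 27) - 1))
  design <- make_design("block", n_events = n_events, TR = TR,
                        n_timepoints = n_timepoints, seed = seed + 1,
                        conditions = c("A", "B"),
                        block_duration = 15, rest_gap = 12)
  if (is.null(betas)) {
    betas <- matrix(0, n_networks, 2, dimnames = list(NULL, c("A", "B")))
    betas[1, "A"] <- 1
    if (n_networks >= 2) betas[2, "A"] <- -1
    if (n_networks >= 3) betas[3, "B"] <- 1
  }
  truth <- ground_truth(nets, betas, noise_sd = noise_sd,
                        subject_map_jitter_sd = jitter,
                        fluct_amp = fluct_amp, seed = seed + 2)
  cohort <- simulate_cohort(truth, design, n_subjects, seed = seed + 3)
  list(networks = nets, design = design, truth = truth, cohort = cohort)
}

# Heavy-tailed (Laplace) independent sources for ICA recovery checks.
laplace_sources <- function(n_sources, n_samples, seed) {
  fnoverlap:::with_seed(seed, {
    S <- matrix(stats::rexp(n_sources * n_samples) *
                  sample(c(-1, 1), n_sources * n_samples, replace = TRUE),
                n_sources, n_samples)
    S / apply(S, 1, stats::sd)
  })
}

# Brute-force Benjamini-Hochberg: largest k with p_(k) <= k q / m, reject
# the k smallest p-values. Independent of stats::p.adjust.
bh_oracle <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  out <- logical(m)
  if (length(below) > 0) out[ord[seq_len(max(below))]] <- TRUE
  out
}

# best |correlation| one-to-one matching by exhaustive permutation (<= 6)
brute_force_match <- function(R) {
  n <- nrow(R)
  perms <- gtools_permutations(n)
  best <- NULL; best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    v <- sum(R[cbind(seq_len(n), perms[i, ])])
    if (v > best_val) { best_val <- v; best <- perms[i, ] }
  }
  list(assignment = best, total = best_val)
}

withr_local_tempdir <- function() {
  d <- tempfile("fx")
  dir.create(d)
  d
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
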