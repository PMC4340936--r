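# On-disk formats: NIfTI-1 volumes and maps, BIDS-style events TSV, JSON
# manifests, TSV reports. All computation elsewhere is in voxel space; the
# NIfTI affine is carried through untouched.

#' Write a 4D volume as NIfTI-1
#'
#' The repetition time is stored in the fourth `pixdim` slot, the NIfTI
#' convention for the time step.
#'
#' @param v A [volume4d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume4d <- function(v, path) {
  stopifnot(inherits(v, "volume4d"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- c(v$voxel_size_mm, v$TR)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI-1 volume
#'
#' @param path Path to a 4D NIfTI file.
#' @return A [volume4d()]; TR is taken from the time-step header field.
#' @export
read_volume4d <- function(path) {
  if (!file.exists(path))
    stop_fn("file not found: ", path, class = "fnoverlap_io")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop_fn("expected a 4D NIfTI file, got ", length(dim(img)),
            " dimensions: ", path, class = "fnoverlap_dimension")
  pd <- RNifti::pixdim(img)
  dat <- array(as.numeric(img), dim(img))
  if (!all(is.finite(dat)))
    stop_fn("non-finite voxels in ", path, class = "fnoverlap_validation")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  volume4d(dat, voxel_size_mm = pd[1:3], TR = if (length(pd) >= 4) pd[4] else 1,
           affine = affine)
}

#' Write a 3D map or mask as NIfTI-1
#' @param values 3D numeric array.
#' @param path Output path.
#' @param voxel_size_mm Voxel size (default 3 mm isotropic).
#' @return `path`, invisibly.
#' @export
write_map <- function(values, path, voxel_size_mm = c(3, 3, 3)) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D map or mask from NIfTI-1
#' @param path Path to a 3D NIfTI file.
#' @return 3D numeric array with attribute `voxel_size_mm`.
#' @export
read_map <- function(path) {
  if (!file.exists(path))
    stop_fn("file not found: ", path, class = "fnoverlap_io")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop_fn("expected a 3D NIfTI file: ", path, class = "fnoverlap_dimension")
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1:3]
  out
}

#' Write task events as a BIDS-style TSV
#' @param design A [design_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(design, path) {
  utils::write.table(design$events[, c("onset", "duration", "condition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read task events from a tab-separated file
#'
#' Expects a header with columns `onset`, `duration`, `condition`; conditions
#' are discovered from the file and timing is validated against the run
#' length.
#'
#' @param path Path to the events TSV.
#' @param TR Repetition time of the associated run (s).
#' @param n_timepoints Number of volumes in the associated run.
#' @return A [design_spec()].
#' @export
read_events <- function(path, TR, n_timepoints) {
  if (!file.exists(path))
    stop_fn("file not found: ", path, class = "fnoverlap_io")
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "condition") %in% names(ev)))
    stop_fn("events file must have columns onset, duration, condition: ", path,
            class = "fnoverlap_validation")
  if (nrow(ev) == 0)
    stop_fn("events file has no events (no conditions): ", path,
            class = "fnoverlap_validation")
  design_spec(ev, TR, n_timepoints)
}

#' Write a report table as TSV with fixed numeric precision
#' @param rows Data frame of report rows.
#' @param path Output path.
#' @param digits Decimal places for numeric columns (default 4).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, digits = 4) {
  rows <- as.data.frame(rows)
  for (j in seq_along(rows))
    if (is.numeric(rows[[j]]) && !is.integer(rows[[j]]))
      rows[[j]] <- round(rows[[j]], digits)
  ok <- tryCatch({
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop_fn("cannot write table to ", path, class = "fnoverlap_io")
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a JSON file listing subject ids, run paths, events paths and
#' the cohort TR (plus optionally a mask path). All referenced paths must
#' exist; relative paths are resolved against the manifest's directory.
#'
#' @param path Path to `manifest.json`.
#' @return List with `subjects`, `runs`, `events`, `TR` and optionally `mask`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_fn("file not found: ", path, class = "fnoverlap_io")
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  man$runs <- resolve(man$runs)
  man$events <- resolve(man$events)
  for (p in c(man$runs, man$events, man$mask))
    if (!is.null(p) && !file.exists(p))
      stop_fn("manifest references missing file: ", p, class = "fnoverlap_io")
  if (length(unique(man$TR)) != 1)
    stop_fn("manifest must declare exactly one TR for the cohort",
            class = "fnoverlap_validation")
  man
}
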