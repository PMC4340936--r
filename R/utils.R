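# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_fn <- function(..., class = "fnoverlap_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so no
#' function in the package leaks changes to the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a stream-specific seed from a base seed
#'
#' Deterministic integer hash so that each subject, restart or permutation
#' gets its own reproducible stream. Result stays below 2^31.
#'
#' @param seed Base integer seed.
#' @param index Non-negative stream index.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 + 1) %%
               2147483647)
}

assert_finite <- function(x, what = "array") {
  if (!all(is.finite(x)))
    stop_fn(what, " contains non-finite values", class = "fnoverlap_validation")
  invisible(x)
}

# Connected components of a logical 3D array under 26-neighbour connectivity.
# Returns an integer array of labels (0 = background) and a vector of sizes.
connected_components_26 <- function(flag) {
  dims <- dim(flag)
  stopifnot(length(dims) == 3L)
  idx <- which(flag)
  labels <- array(0L, dims)
  sizes <- integer(0)
  if (length(idx) == 0L)
    return(list(labels = labels, sizes = sizes))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  coords <- arrayInd(idx, dims)
  # map from linear voxel index to position in `idx`, 0 if not supra-threshold
  member <- integer(prod(dims))
  member[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  comp <- integer(length(idx))
  ncomp <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    size <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      cc <- coords[cur, ]
      for (k in seq_len(nrow(offs))) {
        x <- cc[1] + offs[k, 1]; y <- cc[2] + offs[k, 2]; z <- cc[3] + offs[k, 3]
        if (x < 1 || x > nx || y < 1 || y > ny || z < 1 || z > nz) next
        lin <- x + (y - 1L) * nx + (z - 1L) * nx * ny
        m <- member[lin]
        if (m != 0L && comp[m] == 0L) {
          comp[m] <- ncomp
          queue <- c(queue, m)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  labels[idx] <- comp
  list(labels = labels, sizes = sizes)
}
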