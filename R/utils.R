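# Internal helpers shared across modules.

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# n x 3 voxel coordinate matrix -> linear indices for a given grid.
coordToIndex <- function(coords, dims) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  (coords[, 3L] - 1L) * dims[1L] * dims[2L] +
    (coords[, 2L] - 1L) * dims[1L] + coords[, 1L]
}

# Linear indices -> n x 3 voxel coordinate matrix (1-based).
indexToCoord <- function(idx, dims) {
  idx0 <- as.integer(idx) - 1L
  cbind(idx0 %% dims[1L] + 1L,
        (idx0 %/% dims[1L]) %% dims[2L] + 1L,
        idx0 %/% (dims[1L] * dims[2L]) + 1L)
}

# Standardize rows of a V x T matrix so that tcrossprod gives Pearson r.
standardizeRows <- function(X) {
  X <- X - rowMeans(X)
  ss <- sqrt(rowSums(X^2))
  if (any(ss == 0)) {
    bad <- which(ss == 0)
    stop("constant time series at mask voxel(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ...")
  }
  X / ss
}

stopifnotDimsMatch <- function(vol, mask) {
  if (!identical(dim(vol@data)[1:3], dim(mask@grid)))
    stop("volume grid ", paste(dim(vol@data)[1:3], collapse = "x"),
         " does not match mask grid ",
         paste(dim(mask@grid), collapse = "x"))
  invisible(TRUE)
}
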