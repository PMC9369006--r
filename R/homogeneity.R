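#' Fisher r-to-z transform
#'
#' `z = atanh(r)` with |r| clamped to `1 - 1e-7` so that perfect correlations
#' stay finite; the clamp exceeds any empirically attainable correlation.
#' Odd function; an error for |r| > 1.
#'
#' @param r correlation value(s) in [-1, 1].
#' @return Fisher z value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Compute a subject's network homogeneity map
#'
#' For every voxel i of the mask, NH is the mean Pearson correlation of its
#' time series with each of the other N-1 mask voxels (self-correlation
#' excluded), Fisher r-to-z transformed. The default computes the mean
#' correlation first and transforms the mean ("average-then-transform");
#' `transformFirst = TRUE` averages the individually transformed
#' correlations instead (O(N^2) memory, off by default).
#'
#' The efficient path standardizes each series once and accumulates the
#' correlation row-sums via a single inner product with the column sums of
#' the standardized data, so the cost is O(N T) rather than O(N^2 T).
#'
#' @param vol a [Volume4D-class].
#' @param mask a [NetworkMask-class] with at least 2 voxels; every masked
#'   series must have nonzero variance (constant series are an error naming
#'   the voxel).
#' @param transformFirst average Fisher-transformed correlations instead of
#'   transforming the average.
#' @param subjectId label stored in the result.
#' @return An [NHMap-class] (unsmoothed).
#' @export
computeNHMap <- function(vol, mask, transformFirst = FALSE,
                         subjectId = "subject") {
  stopifnot(is(vol, "Volume4D"), is(mask, "NetworkMask"))
  stopifnotDimsMatch(vol, mask)
  d <- dim(vol@data)
  idx <- which(mask@grid)
  N <- length(idx)
  X <- matrix(vol@data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  Xs <- standardizeRows(X)
  if (transformFirst) {
    R <- tcrossprod(Xs)
    Z <- fisherZ(pmin(pmax(R, -1), 1))
    meanR <- tanh((rowSums(Z) - diag(Z)) / (N - 1))
  } else {
    s <- colSums(Xs)
    meanR <- (as.numeric(Xs %*% s) - 1) / (N - 1)
    meanR <- pmin(pmax(meanR, -1), 1)
  }
  mr <- array(0, d[1:3])
  zz <- array(0, d[1:3])
  mr[idx] <- meanR
  zz[idx] <- fisherZ(meanR)
  new("NHMap", meanR = mr, z = zz, mask = mask, subjectId = subjectId,
      smoothedFWHM = NA_real_)
}

# Separable Gaussian convolution of a 3D array; sigma per axis in voxels.
# Kernels are truncated at 4 sigma and normalized to sum 1.
gaussianSmooth3D <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      lo <- max(1L, j - half)
      hi <- min(n, j + half)
      K[lo:hi, j] <- k[(lo:hi) - j + half + 1L]
    }
    arr <- if (ax == 1L) {
      array(K %*% matrix(arr, d[1], d[2] * d[3]), d)
    } else if (ax == 2L) {
      p <- aperm(arr, c(2, 1, 3))
      aperm(array(K %*% matrix(p, d[2], d[1] * d[3]), d[c(2, 1, 3)]),
            c(2, 1, 3))
    } else {
      p <- aperm(arr, c(3, 1, 2))
      aperm(array(K %*% matrix(p, d[3], d[1] * d[2]), d[c(3, 1, 2)]),
            c(2, 3, 1))
    }
  }
  arr
}

#' Smooth an NH map within its mask
#'
#' Gaussian smoothing of the Fisher-z map with
#' `sigma = FWHM / (2 sqrt(2 log 2))` per axis, renormalized within the mask:
#' the smoothed map is `smooth(z * mask) / smooth(mask)` on mask voxels, so
#' out-of-mask voxels contribute neither signal nor dilution and a constant
#' map is unchanged. The mean-correlation slot is smoothed the same way.
#'
#' @param nh an [NHMap-class].
#' @param fwhmMM kernel full-width at half-maximum in mm (default 8).
#' @return A smoothed [NHMap-class].
#' @export
smoothNHMap <- function(nh, fwhmMM = 8) {
  stopifnot(is(nh, "NHMap"))
  if (fwhmMM <= 0) stop("fwhm must be positive")
  vs <- nh@mask@voxelSize
  if (fwhmMM < min(vs))
    warning("smoothing FWHM (", fwhmMM, " mm) is smaller than one voxel")
  sigmaVox <- (fwhmMM / (2 * sqrt(2 * log(2)))) / vs
  m <- nh@mask@grid
  w <- gaussianSmooth3D(array(as.numeric(m), dim(m)), sigmaVox)
  sm <- function(a) {
    out <- gaussianSmooth3D(a * m, sigmaVox)
    out[m] <- out[m] / w[m]
    out[!m] <- 0
    out
  }
  new("NHMap", meanR = sm(nh@meanR), z = sm(nh@z), mask = nh@mask,
      subjectId = nh@subjectId, smoothedFWHM = fwhmMM)
}

#' Mean NH over a region of interest
#'
#' Arithmetic mean of the Fisher-z NH values over the region's voxels — the
#' scalar fed into the brain-behavior regressions and the ROC/SVM
#' classifiers.
#'
#' @param nh an [NHMap-class].
#' @param region a [NetworkMask-class] (or logical array / n x 3 coordinate
#'   matrix) that must lie entirely inside the NH map's mask.
#' @return numeric(1).
#' @export
regionMeanNH <- function(nh, region) {
  stopifnot(is(nh, "NHMap"))
  g <- if (is(region, "NetworkMask")) region@grid else
    if (is.array(region) && length(dim(region)) == 3L) region else {
      a <- array(FALSE, dim(nh@z))
      a[coordToIndex(region, dim(nh@z))] <- TRUE
      a
    }
  if (!identical(dim(g), dim(nh@z)))
    stop("region dims do not match the NH map")
  if (!any(g)) stop("region is empty")
  if (any(g & !nh@mask@grid))
    stop("region contains voxels outside the NH mask")
  mean(nh@z[g])
}

#' Per-subject regional NH feature matrix
#'
#' @param nhMaps list of [NHMap-class], one per subject.
#' @param regions named list of regions (any form accepted by
#'   [regionMeanNH()]); [RegionSpec-class] objects are accepted too.
#' @return subjects x regions numeric matrix.
#' @export
regionFeatureMatrix <- function(nhMaps, regions) {
  regs <- lapply(regions, function(r)
    if (is(r, "RegionSpec")) r@voxels else r)
  nms <- names(regions)
  if (is.null(nms))
    nms <- vapply(seq_along(regions), function(i)
      if (is(regions[[i]], "RegionSpec")) regions[[i]]@name else
        paste0("region", i), character(1))
  out <- vapply(regs, function(r)
    vapply(nhMaps, regionMeanNH, numeric(1), region = r),
    numeric(length(nhMaps)))
  out <- matrix(out, nrow = length(nhMaps),
                dimnames = list(vapply(nhMaps, function(x) x@subjectId,
                                       character(1)), nms))
  out
}
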