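#' Voxel-wise group comparison with covariates
#'
#' Per mask voxel, ordinary least squares of the NH value on
#' `[intercept, group, covariates...]`; the reported statistic is the
#' two-sided t for the group coefficient (patient minus control). With no
#' covariates this equals the pooled two-sample t statistic. The residuals
#' are kept for random-field smoothness estimation.
#'
#' @param nhMaps list of [NHMap-class] (one per subject, identical masks).
#' @param group vector coding patients as 1/`"patient"` and controls as
#'   0/`"control"`.
#' @param covariates optional data.frame/matrix of subject-level covariates
#'   (e.g. age, sex code, education), entered untransformed.
#' @return A [GLMResult-class].
#' @export
fitVoxelwiseGLM <- function(nhMaps, group, covariates = NULL) {
  n <- length(nhMaps)
  if (is.character(group) || is.factor(group))
    group <- as.integer(as.character(group) == "patient")
  group <- as.numeric(group)
  if (length(group) != n)
    stop("group length does not match the number of NH maps")
  if (length(unique(group)) != 2L || min(table(group)) < 2L)
    stop("need at least 2 subjects in each of two groups")
  mask <- nhMaps[[1]]@mask
  idx <- which(mask@grid)
  Y <- t(vapply(nhMaps, function(m) m@z[idx], numeric(length(idx))))
  X <- cbind(intercept = 1, group = group)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject")
    X <- cbind(X, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- n - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom")
  B <- qr.coef(qx, Y)
  R <- Y - X %*% B
  sigma2 <- colSums(R^2) / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tvals <- ifelse(se > 0, B[2, ] / se, 0)
  tm <- array(0, dim(mask@grid))
  tm[idx] <- tvals
  new("GLMResult", tMap = tm, df = as.numeric(df), residuals = R,
      mask = mask, design = X)
}

#' Estimate random-field smoothness from GLM residuals
#'
#' Standard residual-based estimator: residuals are normalized per voxel to
#' unit sum of squares across subjects, spatial first differences are taken
#' along each axis within the mask, and the per-axis variance of those
#' derivatives gives `FWHM_i = sqrt(4 log 2 / lambda_i)` voxels. Resels are
#' the mask voxel count divided by the product of the per-axis FWHMs (in
#' voxels).
#'
#' @param glm a [GLMResult-class] (>= 3 subjects of residuals), or a
#'   subjects x voxels residual matrix with `mask` supplied.
#' @param mask a [NetworkMask-class] (taken from `glm` when omitted).
#' @return A [SmoothnessEstimate-class].
#' @export
estimateSmoothness <- function(glm, mask = NULL) {
  if (is(glm, "GLMResult")) {
    R <- glm@residuals
    mask <- glm@mask
  } else R <- glm
  if (nrow(R) < 3L) stop("need at least 3 subjects of residuals")
  g <- mask@grid
  dims <- dim(g)
  if (any(dims < 2L)) stop("mask must span at least 2 voxels along each axis")
  idx <- which(g)
  ss <- sqrt(colSums(R^2))
  if (any(ss == 0)) stop("zero residual variance at some voxel")
  U <- sweep(R, 2L, ss, "/")  # subjects x voxels, unit SS per voxel
  lambda <- numeric(3)
  lin <- array(NA_integer_, dims)
  lin[idx] <- seq_along(idx)
  offsets <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  coords <- indexToCoord(idx, dims)
  for (ax in 1:3) {
    nb <- sweep(coords, 2L, offsets[[ax]], "+")
    ok <- nb[, ax] <= dims[ax]
    nbIdx <- rep(NA_integer_, nrow(nb))
    nbIdx[ok] <- lin[cbind(nb[ok, 1], nb[ok, 2], nb[ok, 3])]
    pair <- which(!is.na(nbIdx))
    if (!length(pair))
      stop("mask has no adjacent voxel pairs along axis ", ax)
    D <- U[, nbIdx[pair], drop = FALSE] - U[, pair, drop = FALSE]
    lambda[ax] <- mean(colSums(D^2))
  }
  fwhmVox <- sqrt(4 * log(2) / pmax(lambda, .Machine$double.eps))
  vs <- mask@voxelSize
  new("SmoothnessEstimate", fwhm = fwhmVox * vs, fwhmVoxels = fwhmVox,
      resels = length(idx) / prod(fwhmVox), voxelSize = vs)
}

#' Label connected components of a binary 3D array
#'
#' @param bin logical 3D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces, edges,
#'   corners; the default, matching the DPABI/REST convention).
#' @return Integer 3D array; 0 outside clusters, labels 1..k inside.
#' @export
labelClusters <- function(bin, connectivity = 26) {
  dims <- dim(bin)
  stopifnot(length(dims) == 3L)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nl <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[nl == 1, , drop = FALSE],
                "18" = off[nl >= 1 & nl <= 2, , drop = FALSE],
                "26" = off[nl >= 1, , drop = FALSE],
                stop("connectivity must be 6, 18 or 26"))
  labels <- array(0L, dims)
  idx <- which(bin)
  if (!length(idx)) return(labels)
  coords <- indexToCoord(idx, dims)
  inBin <- array(FALSE, dims)
  inBin[idx] <- TRUE
  nextLab <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    labels[start] <- nextLab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- indexToCoord(cur, dims)
      nb <- sweep(off, 2L, as.integer(cc), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nbl <- coordToIndex(nb[ok, , drop = FALSE], dims)
      nbl <- nbl[inBin[nbl] & labels[nbl] == 0L]
      if (length(nbl)) {
        labels[nbl] <- nextLab
        queue <- c(queue, nbl)
      }
    }
  }
  labels
}

# Expected number of clusters (3D resel term of the expected Euler
# characteristic) for a unit-variance Gaussian field above z threshold u.
.expectedClusters <- function(resels, u) {
  resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (u^2 - 1) * exp(-u^2 / 2)
}

# Cluster-extent exceedance probability P(n >= k voxels) given the expected
# cluster count Em and expected suprathreshold voxel count En (both one
# sign), using the classic exponentiated 2/3-power extent law.
.clusterSizeP <- function(k, Em, En) {
  if (Em <= 0 || En <= 0) return(0)
  beta <- (gamma(2.5) * Em / En)^(2 / 3)
  exp(-beta * k^(2 / 3))
}

#' Gaussian-random-field cluster-level inference
#'
#' Converts the group-contrast t map to z-equivalents, thresholds it at the
#' two-sided `voxelP` quantile, labels positive and negative suprathreshold
#' clusters separately (signed cluster formation), and assigns each cluster
#' a family-wise-corrected p from the expected-Euler-characteristic cluster
#' count and the standard cluster-extent distribution. Clusters with
#' corrected p below `clusterP` survive. No suprathreshold voxels yields an
#' empty table (not an error).
#'
#' @param glm a [GLMResult-class].
#' @param smoothness a [SmoothnessEstimate-class] (default: estimated from
#'   the GLM residuals).
#' @param voxelP voxel-level threshold (two-sided; default 0.001).
#' @param clusterP cluster-level corrected threshold (default 0.05).
#' @param connectivity cluster connectivity (default 26).
#' @return list with `clusters` (data.frame: cluster, direction, nVoxels,
#'   peakT, peak voxel coordinates, peak world coordinates, pCorrected —
#'   surviving clusters only) and `labelMap` (integer array labelling the
#'   surviving clusters).
#' @export
grfClusterInference <- function(glm, smoothness = NULL, voxelP = 0.001,
                                clusterP = 0.05, connectivity = 26) {
  stopifnot(is(glm, "GLMResult"))
  if (!(voxelP > 0 && voxelP < 0.5)) stop("voxelP must lie in (0, 0.5)")
  if (is.null(smoothness)) smoothness <- estimateSmoothness(glm)
  mask <- glm@mask
  u <- stats::qnorm(1 - voxelP / 2)
  tv <- glm@tMap
  # t -> z equivalents, numerically stable in the tails
  zmap <- array(0, dim(tv))
  m <- mask@grid
  zmap[m] <- sign(tv[m]) * stats::qnorm(
    stats::pt(abs(tv[m]), glm@df, lower.tail = FALSE, log.p = TRUE),
    lower.tail = FALSE, log.p = TRUE)
  En <- sum(m) * stats::pnorm(u, lower.tail = FALSE)
  Em1 <- .expectedClusters(smoothness@resels, u)
  EmBoth <- 2 * Em1  # two-sided search doubles the expected cluster count
  rows <- list()
  labOut <- array(0L, dim(m))
  outLab <- 0L
  for (dirSign in c(1, -1)) {
    supra <- m & (dirSign * zmap > u)
    if (!any(supra)) next
    labs <- labelClusters(supra, connectivity)
    for (k in seq_len(max(labs))) {
      vox <- which(labs == k)
      size <- length(vox)
      pk <- .clusterSizeP(size, Em1, En)
      pCorr <- 1 - exp(-EmBoth * pk)
      if (pCorr >= clusterP) next
      tvox <- tv[vox]
      peak <- vox[which.max(abs(tvox))]
      pc <- indexToCoord(peak, dim(m))
      world <- voxelToWorld(mask, pc)
      outLab <- outLab + 1L
      labOut[vox] <- outLab
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = outLab,
        direction = if (dirSign > 0) "patients>controls" else
          "patients<controls",
        nVoxels = size, peakT = tv[peak],
        peakX = pc[1], peakY = pc[2], peakZ = pc[3],
        peakWorldX = world[1], peakWorldY = world[2], peakWorldZ = world[3],
        pCorrected = pCorr, stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), direction = character(),
               nVoxels = integer(), peakT = numeric(), peakX = integer(),
               peakY = integer(), peakZ = integer(), peakWorldX = numeric(),
               peakWorldY = numeric(), peakWorldZ = numeric(),
               pCorrected = numeric(), stringsAsFactors = FALSE)
  list(clusters = clusters, labelMap = labOut)
}
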