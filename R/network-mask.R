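# Symmetric fixed-point ICA (logcosh contrast) on whitened data Z (k x V,
# rows unit variance). Returns the orthogonal unmixing matrix W.
.fastICACore <- function(Z, maxit = 500L, tol = 1e-8) {
  k <- nrow(Z)
  V <- ncol(Z)
  symOrth <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                       k, k) %*% t(e$vectors) %*% W
  }
  W <- symOrth(matrix(stats::rnorm(k * k), k, k))
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- G %*% t(Z) / V - diag(rowMeans(1 - G^2), k, k) %*% W
    W1 <- symOrth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Simplified temporal-concatenation group ICA
#'
#' The three classic steps: (1) per-subject temporal reduction by PCA;
#' (2) concatenation of the reduced data and a second PCA reduction to
#' `nComponents`, followed by fixed-point (FastICA-style, logcosh contrast,
#' symmetric decorrelation) estimation of independent spatial components;
#' (3) spatial maps z-scored across voxels. The aggregate mixing matrix
#' (reduced timepoints x components) allows back-reconstruction of the
#' reduced data as `mixing %*% maps-before-z-scoring`; since maps are
#' z-scored against their own mean/SD the reconstruction identity holds up
#' to that per-map affine factor.
#'
#' @param volumes list of [Volume4D-class] (>= 2 subjects), identical dims.
#' @param analyzableMask optional [NetworkMask-class] restricting the voxels
#'   entered into the ICA; default: voxels with nonzero variance in every
#'   subject.
#' @param nComponents number of components (default 20, the fixed model
#'   order used for resting-state decompositions of this kind).
#' @param seed RNG seed for the ICA initialization (decomposition is
#'   deterministic given the seed).
#' @param subjectPCs per-subject retained principal components before
#'   concatenation (default `nComponents`, capped at T - 1).
#' @return An [ICADecomposition-class].
#' @export
groupICA <- function(volumes, analyzableMask = NULL, nComponents = 20L,
                     seed = 1L, subjectPCs = NULL) {
  if (length(volumes) < 2L) stop("group ICA needs at least 2 subjects")
  d <- dim(volumes[[1]]@data)
  for (v in volumes)
    if (!identical(dim(v@data)[1:3], d[1:3]))
      stop("all volumes must share the same grid")
  dims <- d[1:3]
  if (is.null(analyzableMask)) {
    ok <- rep(TRUE, prod(dims))
    for (v in volumes) {
      M <- matrix(v@data, prod(dims), dim(v@data)[4])
      ok <- ok & (matrixStatsRowVar(M) > 0)
    }
    if (sum(ok) < 2L) stop("fewer than 2 analyzable (non-constant) voxels")
    analyzable <- array(ok, dims)
  } else {
    stopifnot(is(analyzableMask, "NetworkMask"))
    if (!identical(dim(analyzableMask@grid), dims))
      stop("analyzable mask dims do not match the volumes")
    analyzable <- analyzableMask@grid
    for (v in volumes) {
      M <- matrix(v@data, prod(dims), dim(v@data)[4])[analyzable, ,
                                                      drop = FALSE]
      if (any(matrixStatsRowVar(M) == 0))
        stop("constant voxel time series inside the analyzable mask")
    }
  }
  idx <- which(analyzable)
  nComponents <- as.integer(nComponents)
  totalT <- sum(vapply(volumes, function(v) dim(v@data)[4], integer(1)))
  if (nComponents >= totalT)
    stop("nComponents must be smaller than the total number of timepoints")

  withSeed(seed, {
    p1 <- if (is.null(subjectPCs)) nComponents else as.integer(subjectPCs)
    reduced <- lapply(volumes, function(v) {
      Tn <- dim(v@data)[4]
      Y <- t(matrix(v@data, prod(dims), Tn)[idx, , drop = FALSE])  # T x V
      Y <- sweep(Y, 2L, colMeans(Y))  # demean voxel series
      p <- min(p1, Tn - 1L, nrow(Y), ncol(Y))
      sv <- svd(Y, nu = p, nv = 0)
      # rows = leading temporal modes: t(U_p) Y = D_p V_p'
      t(sv$u[, seq_len(p), drop = FALSE]) %*% Y / sqrt(max(Tn - 1, 1))
    })
    X2 <- do.call(rbind, reduced)                 # (sum p) x V
    X2 <- X2 - rowMeans(X2)                       # center each row spatially
    if (nComponents > min(dim(X2)))
      stop("nComponents (", nComponents, ") exceeds the data rank (",
           min(dim(X2)), ")")
    sv2 <- svd(X2, nu = nComponents, nv = nComponents)
    if (sv2$d[nComponents] < 1e-10 * sv2$d[1])
      stop("nComponents exceeds the numerical rank of the data")
    V <- length(idx)
    Z <- t(sv2$v[, seq_len(nComponents), drop = FALSE]) * sqrt(V)  # k x V
    W <- .fastICACore(Z)
    S <- W %*% Z                                   # k x V component maps
    mixing <- sv2$u[, seq_len(nComponents), drop = FALSE] %*%
      diag(sv2$d[seq_len(nComponents)] / sqrt(V), nComponents, nComponents) %*%
      t(W)
    maps <- array(0, c(dims, nComponents))
    flat <- matrix(maps, prod(dims), nComponents)
    for (kk in seq_len(nComponents))
      flat[idx, kk] <- (S[kk, ] - mean(S[kk, ])) / stats::sd(S[kk, ])
    new("ICADecomposition", maps = array(flat, c(dims, nComponents)),
        mixing = mixing, analyzableMask = analyzable,
        nComponents = nComponents,
        voxelSize = volumes[[1]]@voxelSize, origin = volumes[[1]]@origin)
  })
}

#' Select the component best matching a network template
#'
#' Returns the component whose z-scored spatial map has the largest absolute
#' Pearson correlation with the template indicator over the analyzable
#' voxels; ties are broken toward the lowest index. Degenerate case: if the
#' template covers every analyzable voxel (constant indicator) the
#' correlation is undefined and the component with the largest map mean is
#' returned instead.
#'
#' @param dec an [ICADecomposition-class].
#' @param template a [NetworkMask-class] with the same grid.
#' @return list with `index`, `score` (the matched |correlation| or map
#'   mean), `flipped` (TRUE when the matching correlation was negative) and
#'   `correlations` (per-component values).
#' @export
selectNetworkComponent <- function(dec, template) {
  stopifnot(is(dec, "ICADecomposition"), is(template, "NetworkMask"))
  if (!identical(dim(template@grid), dim(dec@maps)[1:3]))
    stop("template dims do not match the component maps")
  idx <- which(dec@analyzableMask)
  tvec <- as.numeric(template@grid[idx])
  if (!any(tvec > 0)) stop("template is empty")
  flat <- matrix(dec@maps, prod(dim(dec@maps)[1:3]), dec@nComponents)
  M <- flat[idx, , drop = FALSE]
  if (stats::sd(tvec) == 0) {
    means <- colMeans(M)
    i <- which.max(means)
    return(list(index = i, score = means[i], flipped = FALSE,
                correlations = means))
  }
  cors <- as.numeric(stats::cor(M, tvec))
  i <- which.max(abs(cors))
  list(index = i, score = abs(cors[i]), flipped = cors[i] < 0,
       correlations = cors)
}

#' Threshold a component map into a network mask
#'
#' @param dec an [ICADecomposition-class].
#' @param index component to binarize (e.g. from
#'   [selectNetworkComponent()]).
#' @param zThreshold mask = analyzable voxels with map z above this value
#'   (default 1).
#' @param flip negate the map first (for components matched with a negative
#'   template correlation).
#' @return A [NetworkMask-class]; an error if fewer than 2 voxels survive.
#' @export
componentToMask <- function(dec, index, zThreshold = 1, flip = FALSE) {
  stopifnot(is(dec, "ICADecomposition"))
  m <- dec@maps[, , , index]
  if (flip) m <- -m
  g <- dec@analyzableMask & (m > zThreshold)
  if (sum(g) < 2L)
    stop("mask is empty (fewer than 2 voxels) at z threshold ", zThreshold)
  NetworkMask(g, voxelSize = dec@voxelSize, origin = dec@origin)
}

# Row variances of a matrix without matrixStats.
matrixStatsRowVar <- function(M) {
  n <- ncol(M)
  rowSums((M - rowMeans(M))^2) / max(n - 1L, 1L)
}
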