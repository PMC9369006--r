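#' Read a motion-parameter file
#'
#' Six-column whitespace-delimited text (translations in mm, rotations in
#' degrees), one row per timepoint — the rigid-body convention.
#'
#' @param path file path.
#' @return T x 6 numeric matrix with columns trans_x/y/z, rot_x/y/z.
#' @export
readMotionParams <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  mp <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(mp) != 6L)
    stop("motion parameter file must have 6 columns, found ", ncol(mp))
  colnames(mp) <- c("trans_x", "trans_y", "trans_z",
                    "rot_x", "rot_y", "rot_z")
  mp
}

#' Motion screening gate
#'
#' A subject is excluded if any translation exceeds `maxTransMM` millimetres
#' or any rotation exceeds `maxRotDeg` degrees on any axis, strictly
#' ("over 3 mm / over 3 degrees"); values exactly at the threshold are kept.
#'
#' @param mp T x 6 motion-parameter matrix (see [readMotionParams()]).
#' @param maxTransMM,maxRotDeg exclusion thresholds (default 3 mm / 3 deg).
#' @param nTimepoints optional expected row count; mismatch is an error.
#' @return A list with `keep` (logical) and, when excluded, `offences`
#'   (data.frame with axis, timepoint, value and type of each violation).
#' @export
screenMotion <- function(mp, maxTransMM = 3, maxRotDeg = 3,
                         nTimepoints = NULL) {
  if (ncol(mp) != 6L) stop("motion parameters must have 6 columns")
  if (!is.null(nTimepoints) && nrow(mp) != nTimepoints)
    stop("motion parameters have ", nrow(mp), " rows but the volume has ",
         nTimepoints, " timepoints")
  lim <- rep(c(maxTransMM, maxRotDeg), each = 3L)
  bad <- which(abs(mp) > rep(lim, each = nrow(mp)), arr.ind = TRUE)
  if (nrow(bad) == 0L) return(list(keep = TRUE, offences = NULL))
  axes <- colnames(mp)[bad[, 2L]]
  list(keep = FALSE,
       offences = data.frame(
         axis = axes, timepoint = bad[, 1L],
         value = mp[bad],
         type = ifelse(bad[, 2L] <= 3L, "translation", "rotation"),
         stringsAsFactors = FALSE))
}

# Ideal FFT band-pass of the columns of a T x V matrix; frequencies strictly
# below low or above high (two-sided, DC included) are zeroed.
.fftBandpass <- function(M, trSeconds, lowHz, highHz) {
  Tn <- nrow(M)
  f <- (seq_len(Tn) - 1) / (Tn * trSeconds)
  f <- pmin(f, 1 / trSeconds - f)  # fold to [0, Nyquist]
  keep <- f >= lowHz & f <= highHz
  Fm <- stats::mvfft(M)
  Fm[!keep, ] <- 0
  Re(stats::mvfft(Fm, inverse = TRUE)) / Tn
}

#' Linear detrend and ideal band-pass filter
#'
#' Removes each voxel's least-squares linear trend, then applies an ideal
#' frequency-domain filter retaining only components inside
#' `[lowHz, highHz]` (default 0.01-0.08 Hz), the convention of the
#' DPARSF/REST preprocessing lineage. The filter is linear and the output
#' has the input's dimensions.
#'
#' @param vol a [Volume4D-class].
#' @param trSeconds repetition time in seconds; NULL uses 2 s.
#' @param lowHz,highHz pass-band edges in Hz; must satisfy
#'   `0 < lowHz < highHz < 1/(2 TR)` (Nyquist).
#' @return A filtered [Volume4D-class].
#' @export
detrendAndFilter <- function(vol, trSeconds = 2, lowHz = 0.01,
                             highHz = 0.08) {
  stopifnot(is(vol, "Volume4D"))
  d <- dim(vol@data)
  Tn <- d[4]
  if (Tn < 8L) stop("at least 8 timepoints are required for filtering")
  nyq <- 1 / (2 * trSeconds)
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyq))
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz",
                 lowHz, highHz, nyq))
  if (!all(is.finite(vol@data))) stop("non-finite values in input volume")
  M <- t(matrix(vol@data, prod(d[1:3]), Tn))  # T x V
  tt <- seq_len(Tn)
  X <- cbind(1, tt - mean(tt))
  M <- M - X %*% qr.solve(X, M)  # linear detrend
  M <- .fftBandpass(M, trSeconds, lowHz, highHz)
  Volume4D(array(t(M), d), voxelSize = vol@voxelSize, origin = vol@origin)
}

#' Friston 24-parameter motion expansion
#'
#' Expands 6 rigid-body parameters p to `[p, p^2, p(t-1), p(t-1)^2]`, the
#' 24-regressor autoregressive model; the first row of the lagged terms is
#' zero-padded.
#'
#' @param mp T x 6 motion-parameter matrix.
#' @return T x 24 matrix.
#' @export
friston24 <- function(mp) {
  if (ncol(mp) != 6L) stop("motion parameters must have 6 columns")
  lag1 <- rbind(0, mp[-nrow(mp), , drop = FALSE])
  out <- cbind(mp, mp^2, lag1, lag1^2)
  colnames(out) <- c(colnames(mp), paste0(colnames(mp), "_sq"),
                     paste0(colnames(mp), "_lag"),
                     paste0(colnames(mp), "_lagsq"))
  out
}

#' Nuisance regression
#'
#' Per voxel, returns the residuals of a least-squares projection onto an
#' intercept plus the confound columns (e.g. the Friston-24 motion
#' expansion, ventricle-ROI and white-matter-ROI mean signals). The global
#' (whole-brain) mean is deliberately not included as a confound. Residuals
#' are orthogonal to every confound column.
#'
#' @param vol a [Volume4D-class].
#' @param nuisance T x K numeric matrix of confound regressors.
#' @return A [Volume4D-class] of residuals.
#' @export
regressNuisance <- function(vol, nuisance) {
  stopifnot(is(vol, "Volume4D"))
  nuisance <- as.matrix(nuisance)
  d <- dim(vol@data)
  if (nrow(nuisance) != d[4])
    stop("nuisance matrix has ", nrow(nuisance), " rows but the volume has ",
         d[4], " timepoints")
  # drop all-zero columns (no-ops for the projection)
  zero <- apply(nuisance, 2L, function(x) all(x == 0))
  ns <- nuisance[, !zero, drop = FALSE]
  X <- cbind(intercept = 1, ns)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    if (is.null(dropped)) dropped <- "<unnamed>"
    stop("confound matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  M <- t(matrix(vol@data, prod(d[1:3]), d[4]))  # T x V
  R <- M - X %*% qr.coef(qx, M)
  Volume4D(array(t(R), d), voxelSize = vol@voxelSize, origin = vol@origin)
}

#' Full temporal preprocessing of one subject
#'
#' Fixed order: linear detrend, band-pass, nuisance regression.
#'
#' @inheritParams detrendAndFilter
#' @param nuisance optional T x K confound matrix (skipped when NULL).
#' @return A preprocessed [Volume4D-class].
#' @export
preprocessVolume <- function(vol, trSeconds = 2, lowHz = 0.01, highHz = 0.08,
                             nuisance = NULL) {
  out <- detrendAndFilter(vol, trSeconds, lowHz, highHz)
  if (!is.null(nuisance)) out <- regressNuisance(out, nuisance)
  out
}
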