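#' @import methods
NULL

#' Volume4D: a single subject's 4D resting-state time series
#'
#' Container for an X x Y x Z x T voxel grid with a diagonal voxel-to-world
#' geometry (voxel size in mm per axis plus the world coordinate of voxel
#' (1,1,1)). Data are held as double precision; on disk volumes are stored
#' as float32 NIfTI-1 (see [writeVolume()]).
#'
#' @slot data 4D numeric array, all values finite, T >= 2.
#' @slot voxelSize numeric(3), positive voxel edge lengths in mm.
#' @slot origin numeric(3), world coordinates (mm) of the first voxel.
#'
#' @seealso [readVolume()], [writeVolume()], [NetworkMask-class]
#' @export
setClass("Volume4D",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a 4D array (X x Y x Z x T)")
    else if (dim(object@data)[4] < 2L)
      msg <- c(msg, "at least 2 timepoints are required")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "data must be finite everywhere")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive reals (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite reals (mm)")
    if (length(msg)) msg else TRUE
  })

#' NetworkMask: boolean 3D grid marking in-network voxels
#'
#' @slot grid logical 3D array; at least 2 voxels must be TRUE.
#' @slot voxelSize numeric(3), mm.
#' @slot origin numeric(3), mm.
#'
#' @export
setClass("NetworkMask",
  representation(grid = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@grid)) != 3L || !is.logical(object@grid))
      msg <- c(msg, "grid must be a logical 3D array")
    else if (sum(object@grid) < 2L)
      msg <- c(msg, "mask must contain at least 2 voxels")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive reals (mm)")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must be 3 reals")
    if (length(msg)) msg else TRUE
  })

#' NHMap: per-voxel network homogeneity of one subject
#'
#' NH of a voxel is its mean Pearson correlation with every other voxel of
#' the network mask; `z` holds the Fisher r-to-z transform of that mean
#' (after clamping |r| to 1 - 1e-7). Values are zero outside the mask.
#'
#' @slot meanR 3D numeric array of mean correlations (0 outside mask).
#' @slot z 3D numeric array of Fisher-transformed values (0 outside mask).
#' @slot mask the [NetworkMask-class] the map is defined on.
#' @slot subjectId character(1).
#' @slot smoothedFWHM numeric(1); mm FWHM applied to `z`, or NA if unsmoothed.
#'
#' @export
setClass("NHMap",
  representation(meanR = "array", z = "array", mask = "NetworkMask",
                 subjectId = "character", smoothedFWHM = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@mask@grid)
    if (!identical(dim(object@meanR), d) || !identical(dim(object@z), d))
      msg <- c(msg, "meanR/z dims must match the mask grid")
    m <- object@mask@grid
    if (any(!is.finite(object@z[m])) || any(!is.finite(object@meanR[m])))
      msg <- c(msg, "NH values must be finite on the mask")
    if (any(abs(object@meanR[m]) > 1))
      msg <- c(msg, "meanR must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' RegionSpec: one planted coupled region of the synthetic network
#'
#' In-region voxel time series are generated from a shared latent factor
#' with group-specific loading lambda: x = lambda * s + sqrt(1 - lambda^2) * e,
#' so that the expected pairwise correlation within the region equals
#' lambda^2.
#'
#' @slot name character(1) region label.
#' @slot voxels integer matrix (n x 3) of 1-based voxel coordinates.
#' @slot loadingPatients,loadingControls shared-factor loading per group,
#'   each in [0, 1).
#'
#' @export
setClass("RegionSpec",
  representation(name = "character", voxels = "matrix",
                 loadingPatients = "numeric", loadingControls = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@voxels) || ncol(object@voxels) != 3L ||
        nrow(object@voxels) < 1L)
      msg <- c(msg, "voxels must be a nonempty n x 3 coordinate matrix")
    for (lam in c(object@loadingPatients, object@loadingControls))
      if (!is.finite(lam) || lam < 0 || lam >= 1)
        msg <- c(msg, "loadings must lie in [0, 1)")
    if (length(msg)) unique(msg) else TRUE
  })

#' SimulationConfig: full description of a synthetic cohort
#'
#' Defaults emulate a desk-scale two-group resting-state study: a 20^3 grid
#' of 3 mm voxels, 240 timepoints at TR = 2 s, 20 patients + 20 controls,
#' four disjoint coupled regions (~300 network voxels), and clinical scores
#' linearly linked to regional NH (see [defaultCovariateModel()]).
#'
#' @slot gridDims integer(3) grid size in voxels.
#' @slot nTimepoints integer(1), >= 3.
#' @slot trSeconds numeric(1), repetition time in seconds.
#' @slot nPatients,nControls integer(1), each >= 2.
#' @slot regions list of [RegionSpec-class]; voxel sets must be disjoint.
#' @slot noiseSD numeric(1) marginal SD of every voxel series.
#' @slot voxelSize numeric(3) mm.
#' @slot covariateModel named list of per-score linear models
#'   (intercept, beta over region names / "age" / "education", residualSD).
#' @slot seed integer(1) RNG seed.
#'
#' @export
setClass("SimulationConfig",
  representation(gridDims = "integer", nTimepoints = "integer",
                 trSeconds = "numeric", nPatients = "integer",
                 nControls = "integer", regions = "list",
                 noiseSD = "numeric", voxelSize = "numeric",
                 covariateModel = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@gridDims) != 3L || any(object@gridDims < 1L))
      msg <- c(msg, "gridDims must be 3 positive integers")
    if (object@nTimepoints < 3L)
      msg <- c(msg, "nTimepoints must be >= 3")
    if (object@trSeconds <= 0)
      msg <- c(msg, "trSeconds must be positive")
    if (object@nPatients < 2L || object@nControls < 2L)
      msg <- c(msg, "both group sizes must be >= 2")
    if (object@noiseSD <= 0)
      msg <- c(msg, "noiseSD must be positive")
    if (length(object@regions)) {
      if (!all(vapply(object@regions, is, logical(1), "RegionSpec")))
        msg <- c(msg, "regions must be a list of RegionSpec")
      else {
        idx <- lapply(object@regions, function(r)
          coordToIndex(r@voxels, object@gridDims))
        if (any(unlist(idx) < 1) || any(unlist(idx) > prod(object@gridDims)))
          msg <- c(msg, "region voxels fall outside the grid")
        if (anyDuplicated(unlist(idx)))
          msg <- c(msg, "region voxel sets must be disjoint")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' ICADecomposition: simplified temporal-concatenation group ICA result
#'
#' @slot maps 4D array (X x Y x Z x k) of z-scored component spatial maps.
#' @slot mixing matrix (reduced timepoints x k) of aggregate temporal modes.
#' @slot analyzableMask logical 3D array of voxels entered into the ICA.
#' @slot nComponents integer(1).
#' @slot voxelSize,origin geometry carried from the input volumes.
#'
#' @export
setClass("ICADecomposition",
  representation(maps = "array", mixing = "matrix",
                 analyzableMask = "array", nComponents = "integer",
                 voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@maps)) != 4L)
      msg <- c(msg, "maps must be a 4D array")
    else if (dim(object@maps)[4] != object@nComponents)
      msg <- c(msg, "4th dim of maps must equal nComponents")
    if (!identical(dim(object@analyzableMask), dim(object@maps)[1:3]))
      msg <- c(msg, "analyzableMask dims must match maps")
    if (length(msg)) msg else TRUE
  })

#' GLMResult: voxel-wise group-contrast fit over a mask
#'
#' @slot tMap 3D array of group-contrast t statistics (0 outside mask).
#' @slot df numeric(1) residual degrees of freedom.
#' @slot residuals matrix (subjects x mask voxels), column order follows
#'   `which(mask@grid)`.
#' @slot mask the analysis [NetworkMask-class].
#' @slot design the design matrix used.
#'
#' @export
setClass("GLMResult",
  representation(tMap = "array", df = "numeric", residuals = "matrix",
                 mask = "NetworkMask", design = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@df <= 0)
      msg <- c(msg, "residual df must be positive")
    if (ncol(object@residuals) != sum(object@mask@grid))
      msg <- c(msg, "residual columns must match mask voxel count")
    if (length(msg)) msg else TRUE
  })

#' SmoothnessEstimate: random-field smoothness of a residual field
#'
#' @slot fwhm numeric(3), per-axis FWHM in mm.
#' @slot fwhmVoxels numeric(3), per-axis FWHM in voxel units.
#' @slot resels numeric(1), mask volume in resolution elements.
#' @slot voxelSize numeric(3), mm.
#'
#' @export
setClass("SmoothnessEstimate",
  representation(fwhm = "numeric", fwhmVoxels = "numeric",
                 resels = "numeric", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@fwhm)) || any(object@fwhm <= 0))
      msg <- c(msg, "FWHM must be positive")
    if (!is.finite(object@resels) || object@resels <= 0)
      msg <- c(msg, "resels must be positive")
    if (length(msg)) msg else TRUE
  })
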