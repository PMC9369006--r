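#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `volData` returns
#' the raw 4D array of a [Volume4D-class]; `voxelSize` and `origin` return
#' the geometry; `maskArray` the logical grid of a [NetworkMask-class];
#' `nMaskVoxels` its voxel count; `zMap` / `meanRMap` the value arrays of an
#' [NHMap-class]; `tMap` the t-statistic array of a [GLMResult-class].
#'
#' @param x an object of the documented class.
#' @return The slot contents described above.
#' @name accessors
#' @aliases volData voxelSize origin maskArray nMaskVoxels zMap meanRMap tMap
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("nMaskVoxels", function(x) standardGeneric("nMaskVoxels"))
#' @rdname accessors
#' @export
setGeneric("zMap", function(x) standardGeneric("zMap"))
#' @rdname accessors
#' @export
setGeneric("meanRMap", function(x) standardGeneric("meanRMap"))
#' @rdname accessors
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))

#' @rdname accessors
setMethod("volData", "Volume4D", function(x) x@data)
#' @rdname accessors
setMethod("voxelSize", "Volume4D", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "NetworkMask", function(x) x@voxelSize)
#' @rdname accessors
setMethod("origin", "Volume4D", function(x) x@origin)
#' @rdname accessors
setMethod("origin", "NetworkMask", function(x) x@origin)
#' @rdname accessors
setMethod("maskArray", "NetworkMask", function(x) x@grid)
#' @rdname accessors
setMethod("nMaskVoxels", "NetworkMask", function(x) sum(x@grid))
#' @rdname accessors
setMethod("zMap", "NHMap", function(x) x@z)
#' @rdname accessors
setMethod("meanRMap", "NHMap", function(x) x@meanR)
#' @rdname accessors
setMethod("tMap", "GLMResult", function(x) x@tMap)

setMethod("show", "Volume4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume4D: %d x %d x %d voxels, %d timepoints\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm; origin: %s mm\n",
              paste(object@voxelSize, collapse = " x "),
              paste(round(object@origin, 2), collapse = ", ")))
})

setMethod("show", "NetworkMask", function(object) {
  d <- dim(object@grid)
  cat(sprintf("NetworkMask: %d of %d voxels in-network (%d x %d x %d grid)\n",
              sum(object@grid), prod(d), d[1], d[2], d[3]))
})

setMethod("show", "NHMap", function(object) {
  m <- object@mask@grid
  cat(sprintf("NHMap [%s]: %d mask voxels; mean z = %.4f%s\n",
              object@subjectId, sum(m), mean(object@z[m]),
              if (is.na(object@smoothedFWHM)) " (unsmoothed)"
              else sprintf(" (smoothed %.1f mm FWHM)", object@smoothedFWHM)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %s grid, T = %d (TR = %g s), ",
                     "%d patients + %d controls, %d regions, seed = %d\n"),
              paste(object@gridDims, collapse = "x"), object@nTimepoints,
              object@trSeconds, object@nPatients, object@nControls,
              length(object@regions), object@seed))
})

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf("ICADecomposition: %d components over %d analyzable voxels\n",
              object@nComponents, sum(object@analyzableMask)))
})

setMethod("show", "GLMResult", function(object) {
  m <- object@mask@grid
  cat(sprintf("GLMResult: group-contrast t over %d voxels, df = %g, t range [%.3f, %.3f]\n",
              sum(m), object@df, min(object@tMap[m]), max(object@tMap[m])))
})

setMethod("show", "SmoothnessEstimate", function(object) {
  cat(sprintf("SmoothnessEstimate: FWHM = %s mm (%s voxels), %.2f resels\n",
              paste(round(object@fwhm, 2), collapse = " x "),
              paste(round(object@fwhmVoxels, 2), collapse = " x "),
              object@resels))
})
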