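#' Construct a Volume4D
#'
#' @param data 4D numeric array (X x Y x Z x T).
#' @param voxelSize numeric(3) voxel edge lengths in mm (default 3 mm
#'   isotropic, the common resampling resolution of resting-state pipelines).
#' @param origin numeric(3) world coordinates (mm) of voxel (1,1,1).
#' @return A [Volume4D-class] object.
#' @export
Volume4D <- function(data, voxelSize = c(3, 3, 3), origin = c(0, 0, 0)) {
  new("Volume4D", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Construct a NetworkMask
#'
#' @param grid logical 3D array (TRUE marks in-network voxels).
#' @param voxelSize,origin geometry, as for [Volume4D()].
#' @return A [NetworkMask-class] object.
#' @export
NetworkMask <- function(grid, voxelSize = c(3, 3, 3), origin = c(0, 0, 0)) {
  new("NetworkMask", grid = grid, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

.xformFrom <- function(voxelSize, origin) {
  structure(rbind(cbind(diag(voxelSize), origin), c(0, 0, 0, 1)), code = 2L)
}

.geometryOf <- function(img) {
  xf <- RNifti::xform(img)
  list(voxelSize = sqrt(colSums(xf[1:3, 1:3]^2)), origin = xf[1:3, 4])
}

#' Read and write 4D NIfTI volumes
#'
#' Volumes are stored as float32 NIfTI-1 with a diagonal affine; reading a
#' file that is not 4D is an error. A write-then-read roundtrip preserves
#' the data to float32 precision and the geometry exactly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [Volume4D-class].
#' @return `readVolume` returns a [Volume4D-class]; `writeVolume` returns
#'   `path` invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D volume but '", path, "' has ", length(d),
         " dimension(s)")
  g <- .geometryOf(img)
  Volume4D(array(as.numeric(img), d), voxelSize = g$voxelSize,
           origin = g$origin)
}

#' @rdname readVolume
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume4D"))
  img <- RNifti::asNifti(vol@data, datatype = "float")
  RNifti::sform(img) <- .xformFrom(vol@voxelSize, vol@origin)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write binary network masks
#'
#' Masks are 3D NIfTI-1 volumes; on read, voxels with intensity > 0.5 are
#' taken as in-network.
#'
#' @param path file path.
#' @param mask a [NetworkMask-class].
#' @return `readMask` returns a [NetworkMask-class]; `writeMask` returns
#'   `path` invisibly.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D mask but '", path, "' has ", length(d),
         " dimension(s)")
  g <- .geometryOf(img)
  NetworkMask(array(as.numeric(img) > 0.5, d), voxelSize = g$voxelSize,
              origin = g$origin)
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "NetworkMask"))
  img <- RNifti::asNifti(array(as.numeric(mask@grid), dim(mask@grid)),
                         datatype = "uint8")
  RNifti::sform(img) <- .xformFrom(mask@voxelSize, mask@origin)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write and read 3D statistic maps
#'
#' `writeStatMap` stores any 3D numeric array (an NH z-map, a t-map, a
#' cluster label map) as a float32 NIfTI-1 volume with the geometry of the
#' supplied mask or volume; `readStatMap` returns the array with its
#' geometry attached as attributes `voxelSize` and `origin`.
#'
#' @param arr 3D numeric array.
#' @param geom a [NetworkMask-class] or [Volume4D-class] supplying geometry.
#' @param path file path.
#' @return `writeStatMap` returns `path` invisibly; `readStatMap` the array.
#' @export
writeStatMap <- function(arr, geom, path) {
  stopifnot(length(dim(arr)) == 3L)
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::sform(img) <- .xformFrom(voxelSize(geom), origin(geom))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeStatMap
#' @export
readStatMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D map but '", path, "' has ", length(d),
         " dimension(s)")
  g <- .geometryOf(img)
  structure(array(as.numeric(img), d), voxelSize = g$voxelSize,
            origin = g$origin)
}

#' Map voxel coordinates to world (scanner/MNI-style) coordinates
#'
#' @param x a [Volume4D-class] or [NetworkMask-class] supplying the geometry.
#' @param coords n x 3 matrix of 1-based voxel coordinates.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxelToWorld <- function(x, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  sweep(sweep(coords - 1, 2L, voxelSize(x), "*"), 2L, origin(x), "+")
}

.requiredCohortColumns <- c("subject_id", "group", "age", "sex", "education")

#' Read a cohort table
#'
#' Reads the per-subject CSV (columns `subject_id`, `group`, `age`, `sex`,
#' `education`, and optionally `duration`, PANSS subscales and cognition
#' scores). Group labels must be `patient`/`control` (a numeric column coded
#' 1 = patient, 0 = control is also accepted); sex is normalized to
#' `male`/`female` from either labels or 0/1 codes (1 = male). The returned
#' frame carries `group_code` (patient = 1, control = 0) and `sex_code`
#' (male = 1).
#'
#' @param path CSV file path.
#' @param required extra column names that must be present (e.g. the
#'   covariates a downstream stage needs); missing ones are named in the
#'   error.
#' @return A data.frame, one row per subject.
#' @export
readCohortTable <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateCohortTable(tab, required = required)
}

#' Validate (and normalize) a cohort data.frame
#'
#' @param tab data.frame with the columns described in [readCohortTable()].
#' @inheritParams readCohortTable
#' @return The normalized data.frame.
#' @export
validateCohortTable <- function(tab, required = character()) {
  need <- unique(c(.requiredCohortColumns, required))
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject ids: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  grp <- tab$group
  if (is.numeric(grp)) {
    if (!all(grp %in% c(0, 1))) stop("numeric group codes must be 0/1")
    grp <- ifelse(grp == 1, "patient", "control")
  }
  grp <- tolower(as.character(grp))
  if (!all(grp %in% c("patient", "control")))
    stop("unknown group label(s): ",
         paste(setdiff(unique(grp), c("patient", "control")), collapse = ", "))
  tab$group <- grp
  tab$group_code <- as.integer(grp == "patient")
  sx <- tab$sex
  if (is.numeric(sx)) {
    if (!all(sx %in% c(0, 1))) stop("numeric sex codes must be 0/1")
    sx <- ifelse(sx == 1, "male", "female")
  }
  sx <- tolower(as.character(sx))
  if (!all(sx %in% c("male", "female")))
    stop("unknown sex label(s): ",
         paste(setdiff(unique(sx), c("male", "female")), collapse = ", "))
  tab$sex <- sx
  tab$sex_code <- as.integer(sx == "male")
  numCols <- intersect(c("age", "education", "duration"), names(tab))
  for (cc in numCols)
    if (!is.numeric(tab[[cc]])) stop("column '", cc, "' must be numeric")
  tab
}

#' @rdname readCohortTable
#' @param tab data.frame to write.
#' @export
writeCohortTable <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
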