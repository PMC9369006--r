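#' End-to-end NH group analysis
#'
#' Convenience driver chaining the pipeline stages on an in-memory cohort:
#' (optional) temporal preprocessing, per-subject NH maps over the network
#' mask, Fisher z + Gaussian smoothing, voxel-wise group GLM with
#' age/sex/education covariates, residual smoothness estimation and GRF
#' cluster-level inference. Regional NH features are extracted for any
#' regions supplied (e.g. the generator's truth regions or the surviving
#' clusters).
#'
#' @param volumes named list of [Volume4D-class], aligned with `cohort`
#'   rows.
#' @param cohort cohort data.frame (see [readCohortTable()]).
#' @param mask analysis [NetworkMask-class].
#' @param regions optional named list of regions for [regionFeatureMatrix()].
#' @param preprocess apply [detrendAndFilter()] first (default FALSE: the
#'   synthetic generator emits white series whose analytic NH targets hold
#'   pre-filter).
#' @param trSeconds,lowHz,highHz band-pass settings when `preprocess = TRUE`.
#' @param fwhmMM smoothing kernel FWHM in mm (default 8).
#' @param covariateColumns cohort columns entered as confounders (default
#'   age, sex_code, education; NULL for none).
#' @param voxelP,clusterP,connectivity see [grfClusterInference()].
#' @return list with `nhMaps`, `glm`, `smoothness`, `clusters` (the
#'   [grfClusterInference()] result), and `features` (NULL when no regions
#'   given).
#' @export
nhGroupAnalysis <- function(volumes, cohort, mask, regions = NULL,
                            preprocess = FALSE, trSeconds = 2, lowHz = 0.01,
                            highHz = 0.08, fwhmMM = 8,
                            covariateColumns = c("age", "sex_code",
                                                 "education"),
                            voxelP = 0.001, clusterP = 0.05,
                            connectivity = 26) {
  stopifnot(length(volumes) == nrow(cohort))
  nhMaps <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (preprocess) v <- detrendAndFilter(v, trSeconds, lowHz, highHz)
    nh <- computeNHMap(v, mask, subjectId = cohort$subject_id[i])
    nhMaps[[i]] <- smoothNHMap(nh, fwhmMM = fwhmMM)
  }
  covs <- if (is.null(covariateColumns)) NULL else
    cohort[, covariateColumns, drop = FALSE]
  glm <- fitVoxelwiseGLM(nhMaps, cohort$group, covariates = covs)
  sm <- estimateSmoothness(glm)
  cl <- grfClusterInference(glm, sm, voxelP = voxelP, clusterP = clusterP,
                            connectivity = connectivity)
  features <- if (is.null(regions)) NULL else
    regionFeatureMatrix(nhMaps, regions)
  list(nhMaps = nhMaps, glm = glm, smoothness = sm, clusters = cl,
       features = features)
}

#' Write a cluster table as TSV
#'
#' @param clusters the `clusters` data.frame from [grfClusterInference()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClusterTable <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
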