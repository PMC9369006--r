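#' Construct a RegionSpec
#'
#' @param name region label.
#' @param voxels n x 3 matrix of 1-based voxel coordinates.
#' @param loadingPatients,loadingControls shared-factor loadings in [0, 1).
#'   The expected within-region pairwise correlation is the squared loading.
#' @return A [RegionSpec-class].
#' @export
RegionSpec <- function(name, voxels, loadingPatients, loadingControls) {
  new("RegionSpec", name = name,
      voxels = matrix(as.integer(voxels), ncol = 3L),
      loadingPatients = loadingPatients, loadingControls = loadingControls)
}

#' Cuboid region helper
#'
#' @param name region label.
#' @param x,y,z integer ranges of voxel coordinates spanned by the cuboid.
#' @inheritParams RegionSpec
#' @return A [RegionSpec-class].
#' @export
boxRegion <- function(name, x, y, z, loadingPatients, loadingControls) {
  g <- as.matrix(expand.grid(x = x, y = y, z = z))
  RegionSpec(name, g, loadingPatients, loadingControls)
}

#' Default planted regions
#'
#' Four disjoint cuboid regions (~300 voxels total on the default 20^3 grid),
#' named after the default-mode-network nodes they emulate. Two regions
#' couple more strongly in patients (superior medial frontal gyrus,
#' cerebellum Crus I/II analogues) and two more strongly in controls
#' (posterior cingulate, inferior temporal analogues), mirroring the mixed
#' direction of group effects such studies report. Regions are separated by
#' well over the default 8-mm smoothing kernel so planted effects stay
#' within their region.
#'
#' @return A list of four [RegionSpec-class] objects.
#' @export
defaultRegions <- function() {
  list(
    boxRegion("smfg",       3:6,   3:7,   4:7,   0.65, 0.45),
    boxRegion("cerebellum", 14:17, 3:7,   13:16, 0.65, 0.45),
    boxRegion("pcc",        3:6,   13:17, 13:16, 0.45, 0.65),
    boxRegion("itg",        14:17, 14:17, 4:7,   0.45, 0.65))
}

#' Default clinical-score model
#'
#' Linear links from regional NH (Fisher-z units), age and education to the
#' PANSS subscales and the eight cognition scores. Couplings follow the
#' pattern typical of first-episode psychosis cohorts: negative-symptom and
#' general-psychopathology severity fall with frontal/cerebellar network
#' coupling, processing speed and social cognition track temporal/cerebellar
#' coupling, attention rises with age and reasoning varies with education.
#' PANSS scores are generated for patients only; the PANSS total is the sum
#' of its three subscales.
#'
#' @return Named list of per-score models, each with `intercept`, `beta`
#'   (named coefficients over region names, `age`, `education`, `duration`),
#'   `residualSD` and `group` (`"patients"` or `"all"`).
#' @export
defaultCovariateModel <- function() {
  sc <- function(intercept, beta = numeric(), residualSD, group = "all")
    list(intercept = intercept, beta = beta, residualSD = residualSD,
         group = group)
  list(
    panss_positive   = sc(26.4, residualSD = 4.8, group = "patients"),
    panss_negative   = sc(30,   c(smfg = -20),        6.0, "patients"),
    panss_general    = sc(58,   c(cerebellum = -30),  6.5, "patients"),
    speed_of_processing      = sc(50, c(itg = -25),  10.0),
    attention_vigilance      = sc(30, c(age = 0.35), 12.0),
    verbal_learning          = sc(41, residualSD = 11.0),
    visual_learning          = sc(45, residualSD = 10.5),
    reasoning_problem_solving = sc(55, c(education = -0.9), 10.0),
    working_memory           = sc(33, residualSD = 12.0),
    social_cognition = sc(30, c(age = 0.25, cerebellum = -10, itg = -10), 5.0),
    overall_composite        = sc(45, c(itg = -20), 10.0))
}

#' Construct a SimulationConfig
#'
#' @param gridDims integer(3); default 20 x 20 x 20.
#' @param nTimepoints number of timepoints (default 240).
#' @param trSeconds repetition time in seconds (default 2).
#' @param nPatients,nControls group sizes (default 20 each).
#' @param regions list of [RegionSpec-class] (default [defaultRegions()]).
#' @param noiseSD marginal SD of every voxel series (default 1).
#' @param voxelSize numeric(3) mm (default 3 mm isotropic).
#' @param covariateModel see [defaultCovariateModel()].
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class].
#' @export
SimulationConfig <- function(gridDims = c(20L, 20L, 20L), nTimepoints = 240L,
                             trSeconds = 2, nPatients = 20L, nControls = 20L,
                             regions = defaultRegions(), noiseSD = 1,
                             voxelSize = c(3, 3, 3),
                             covariateModel = defaultCovariateModel(),
                             seed = 1L) {
  new("SimulationConfig", gridDims = as.integer(gridDims),
      nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
      nPatients = as.integer(nPatients), nControls = as.integer(nControls),
      regions = regions, noiseSD = noiseSD,
      voxelSize = as.numeric(voxelSize), covariateModel = covariateModel,
      seed = as.integer(seed))
}

.truthMask <- function(config) {
  dims <- config@gridDims
  if (!length(config@regions)) return(NULL)
  g <- array(FALSE, dims)
  for (r in config@regions) g[coordToIndex(r@voxels, dims)] <- TRUE
  NetworkMask(g, voxelSize = config@voxelSize)
}

# Mean pairwise correlation of the rows of a V x T matrix (off-diagonal).
.meanPairwiseR <- function(X) {
  Xs <- standardizeRows(X)
  u <- colSums(Xs)
  n <- nrow(X)
  (sum(u * u) - n) / (n * (n - 1))
}

#' Generate a synthetic two-group resting-state cohort
#'
#' Each subject's volume is white Gaussian noise except inside the planted
#' regions, where every voxel series is
#' `lambda * s + sqrt(1 - lambda^2) * e` for a shared latent series `s` and
#' independent noise `e` (all unit variance, scaled by `noiseSD`). The
#' loading `lambda` is group-specific, so the expected within-region pairwise
#' correlation is `lambda^2` per group. Demographics are drawn from
#' distributions typical of a first-episode, drug-naive cohort with matched
#' controls; clinical scores are appended via [generateClinicalScores()].
#' The generation is bit-reproducible under a fixed `seed`.
#'
#' @param config a [SimulationConfig-class].
#' @param scores logical; append clinical scores (default TRUE).
#' @return A list:
#' \describe{
#'   \item{volumes}{named list of [Volume4D-class], patients first.}
#'   \item{cohort}{data.frame with demographics and clinical scores.}
#'   \item{truth}{list with `mask` ([NetworkMask-class] of all region voxels),
#'     `regions` (the [RegionSpec-class] list), `regionNH` (subjects x regions
#'     matrix of realized within-region mean pairwise r), `regionNHz` (its
#'     Fisher transform), and `covariateModel`.}
#' }
#' @export
generateCohort <- function(config, scores = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  dims <- config@gridDims
  nvox <- prod(dims)
  Tn <- config@nTimepoints
  nP <- config@nPatients
  nC <- config@nControls
  n <- nP + nC
  group <- c(rep("patient", nP), rep("control", nC))
  ids <- sprintf("sub-%03d", seq_len(n))
  regIdx <- lapply(config@regions, function(r) coordToIndex(r@voxels, dims))
  regNames <- vapply(config@regions, function(r) r@name, character(1))

  withSeed(config@seed, {
    age <- round(c(pmin(pmax(stats::rnorm(nP, 31.6, 11.4), 16), 60),
                   pmin(pmax(stats::rnorm(nC, 28.4, 6.9), 16), 60)), 1)
    sex <- c(ifelse(stats::rbinom(nP, 1, 20 / 57) == 1, "male", "female"),
             ifelse(stats::rbinom(nC, 1, 23 / 50) == 1, "male", "female"))
    education <- round(c(pmin(pmax(stats::rnorm(nP, 12.9, 3.4), 6), 22),
                         pmin(pmax(stats::rnorm(nC, 15.6, 2.3), 6), 22)), 1)
    duration <- c(round(pmax(stats::rnorm(nP, 2.4, 2.7), 0.1), 1), rep(0, nC))

    volumes <- vector("list", n)
    regionNH <- matrix(NA_real_, n, length(regIdx),
                       dimnames = list(ids, regNames))
    for (i in seq_len(n)) {
      X <- matrix(stats::rnorm(nvox * Tn), nvox, Tn)
      for (k in seq_along(regIdx)) {
        r <- config@regions[[k]]
        lam <- if (group[i] == "patient") r@loadingPatients else
          r@loadingControls
        s <- stats::rnorm(Tn)
        X[regIdx[[k]], ] <- lam * matrix(s, length(regIdx[[k]]), Tn,
                                         byrow = TRUE) +
          sqrt(1 - lam^2) * X[regIdx[[k]], ]
        regionNH[i, k] <- .meanPairwiseR(X[regIdx[[k]], , drop = FALSE])
      }
      volumes[[i]] <- Volume4D(array(config@noiseSD * X, c(dims, Tn)),
                               voxelSize = config@voxelSize)
    }
    names(volumes) <- ids

    cohort <- data.frame(subject_id = ids, group = group, age = age,
                         sex = sex, education = education,
                         duration = duration, stringsAsFactors = FALSE)
    cohort <- validateCohortTable(cohort)
    truth <- list(mask = .truthMask(config), regions = config@regions,
                  regionNH = regionNH, regionNHz = fisherZ(regionNH),
                  covariateModel = config@covariateModel)
    if (scores && length(config@covariateModel))
      cohort <- generateClinicalScores(truth$regionNHz, cohort,
                                       config@covariateModel)
    list(volumes = volumes, cohort = cohort, truth = truth)
  })
}

#' Append model-generated clinical scores to a cohort table
#'
#' Each score is `intercept + sum(beta_k * x_k) + Normal(0, residualSD)`,
#' where regressors are regional NH values (Fisher-z units) or the cohort
#' columns `age`, `education`, `duration`. Scores with `group = "patients"`
#' are NA for controls. If all three PANSS subscales are generated, a
#' `panss_total` column (their sum) is added.
#'
#' Called inside [generateCohort()]; call it directly (with `seed`) to
#' regenerate scores for an existing cohort.
#'
#' @param regionNHz subjects x regions matrix of NH values (Fisher z), with
#'   column names matching the region names used in `covariateModel`.
#' @param cohort cohort data.frame (see [readCohortTable()]).
#' @param covariateModel see [defaultCovariateModel()].
#' @param seed optional seed; if NULL, draws from the current RNG stream.
#' @return The cohort with score columns appended.
#' @export
generateClinicalScores <- function(regionNHz, cohort, covariateModel,
                                   seed = NULL) {
  run <- function() {
    n <- nrow(cohort)
    known <- c(colnames(regionNHz), "age", "education", "duration")
    for (score in names(covariateModel)) {
      m <- covariateModel[[score]]
      y <- rep(m$intercept, n)
      for (nm in names(m$beta)) {
        if (!nm %in% known)
          stop("covariate model for '", score,
               "' refers to unknown regressor '", nm, "'")
        x <- if (nm %in% colnames(regionNHz)) regionNHz[, nm] else
          cohort[[nm]]
        y <- y + m$beta[[nm]] * x
      }
      if (m$residualSD > 0) y <- y + stats::rnorm(n, 0, m$residualSD)
      if (identical(m$group, "patients")) y[cohort$group != "patient"] <- NA
      cohort[[score]] <- round(y, 2)
    }
    pan <- c("panss_positive", "panss_negative", "panss_general")
    if (all(pan %in% names(cohort)))
      cohort$panss_total <- cohort$panss_positive + cohort$panss_negative +
        cohort$panss_general
    cohort
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Generate a null cohort (no group effect)
#'
#' Identical to [generateCohort()] except that every region's patient
#' loading is replaced by its control loading, so the two groups have
#' identical distributions and group labels are exchangeable.
#'
#' @inheritParams generateCohort
#' @return As [generateCohort()].
#' @export
generateNullCohort <- function(config, scores = FALSE) {
  cfg <- config
  cfg@regions <- lapply(config@regions, function(r) {
    r@loadingPatients <- r@loadingControls
    r
  })
  generateCohort(cfg, scores = scores)
}

#' Simulate a rigid-body motion-parameter table
#'
#' Random-walk translations (mm) and rotations (degrees) for the motion
#' screening gate; optionally inject a spike exceeding the exclusion
#' threshold.
#'
#' @param nTimepoints number of rows.
#' @param stepSD random-walk step SD (same value for mm and degrees).
#' @param spikeAt optional timepoint index receiving a 5 mm / 5 degree spike
#'   on the first axis.
#' @param seed optional RNG seed.
#' @return T x 6 matrix with columns trans_x/y/z, rot_x/y/z.
#' @export
simulateMotionParams <- function(nTimepoints, stepSD = 0.02, spikeAt = NULL,
                                 seed = NULL) {
  run <- function() {
    mp <- vapply(1:6, function(j) cumsum(stats::rnorm(nTimepoints, 0, stepSD)),
                 numeric(nTimepoints))
    colnames(mp) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
    if (!is.null(spikeAt)) {
      mp[spikeAt, "trans_x"] <- 5
      mp[spikeAt, "rot_x"] <- 5
    }
    mp
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}
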