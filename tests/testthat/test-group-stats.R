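makeMaps <- function(Y, mask) {
  # subjects x voxels matrix -> list of NHMap over the mask
  idx <- which(maskArray(mask))
  lapply(seq_len(nrow(Y)), function(i) {
    z <- array(0, dim(maskArray(mask)))
    z[idx] <- Y[i, ]
    new("NHMap", meanR = z * 0, z = z, mask = mask,
        subjectId = sprintf("s%02d", i), smoothedFWHM = NA_real_)
  })
}

test_that("the covariate-free GLM t equals the pooled two-sample t", {
  set.seed(14)
  dims <- c(4, 4, 3)
  mask <- NetworkMask(array(TRUE, dims))
  n1 <- 9; n2 <- 7
  Y <- matrix(rnorm((n1 + n2) * prod(dims)), n1 + n2)
  grp <- rep(c(1, 0), c(n1, n2))
  glm <- fitVoxelwiseGLM(makeMaps(Y, mask), grp)
  direct <- apply(Y, 2, function(col)
    t.test(col[grp == 1], col[grp == 0], var.equal = TRUE)$statistic)
  expect_lt(max(abs(tMap(glm)[maskArray(mask)] - direct)), 1e-10)
  expect_equal(glm@df, n1 + n2 - 2)
})

test_that("planted mean differences produce t of the expected size", {
  set.seed(15)
  dims <- c(5, 5, 4)
  mask <- NetworkMask(array(TRUE, dims))
  d <- 1.2; s <- 1; n <- 20
  expectT <- d / (s * sqrt(2 / n))
  tbar <- replicate(8, {
    Y <- matrix(rnorm(2 * n * prod(dims), sd = s), 2 * n)
    Y[1:n, ] <- Y[1:n, ] + d
    glm <- fitVoxelwiseGLM(makeMaps(Y, mask), rep(c(1, 0), each = n))
    mean(tMap(glm)[maskArray(mask)])
  })
  expect_lt(abs(mean(tbar) - expectT), 0.15 * expectT)
})

test_that("rank-deficient designs are rejected with the offending column", {
  set.seed(16)
  mask <- NetworkMask(array(TRUE, c(3, 2, 2)))
  Y <- matrix(rnorm(10 * 12), 10)
  grp <- rep(c(1, 0), each = 5)
  expect_error(fitVoxelwiseGLM(makeMaps(Y, mask), grp,
                               covariates = data.frame(dup = grp)),
               "dup")
})

test_that("null covariates change df but keep the mean t near zero", {
  set.seed(17)
  dims <- c(5, 5, 4)
  mask <- NetworkMask(array(TRUE, dims))
  n <- 24
  Y <- matrix(rnorm(n * prod(dims)), n)
  grp <- rep(c(1, 0), each = n / 2)
  covs <- data.frame(age = rnorm(n, 30, 8), sexc = rbinom(n, 1, 0.5))
  g0 <- fitVoxelwiseGLM(makeMaps(Y, mask), grp)
  g1 <- fitVoxelwiseGLM(makeMaps(Y, mask), grp, covariates = covs)
  expect_equal(g1@df, g0@df - 2)
  expect_lt(abs(mean(tMap(g1)[maskArray(mask)])), 0.15)
})

test_that("smoothness estimation recovers known kernel widths", {
  dims <- c(18, 18, 18)
  mask <- NetworkMask(array(TRUE, dims), voxelSize = c(3, 3, 3))
  gs <- NHfmri:::gaussianSmooth3D
  set.seed(18)
  # white noise smoothed at 6 mm (sigma = 6/2.3548/3 voxels)
  R6 <- do.call(rbind, lapply(1:8, function(i)
    c(gs(array(rnorm(prod(dims)), dims), rep(6 / (2 * sqrt(2 * log(2))) / 3, 3)))))
  est6 <- estimateSmoothness(R6, mask = mask)
  expect_lt(max(abs(est6@fwhm - 6)), 6 * 0.2)
  # unsmoothed noise: about one voxel width (3 mm)
  R0 <- matrix(rnorm(8 * prod(dims)), 8)
  est0 <- estimateSmoothness(R0, mask = mask)
  expect_lt(max(abs(est0@fwhm - 3)), 3 * 0.3)
  # resels scale as mask volume over the FWHM product (voxel units)
  expect_equal(est0@resels,
               prod(dims) / prod(est0@fwhmVoxels), tolerance = 1e-12)
})

test_that("doubling the voxel size doubles the FWHM in mm", {
  dims <- c(14, 14, 14)
  set.seed(19)
  R <- matrix(rnorm(6 * prod(dims)), 6)
  m3 <- NetworkMask(array(TRUE, dims), voxelSize = c(3, 3, 3))
  m6 <- NetworkMask(array(TRUE, dims), voxelSize = c(6, 6, 6))
  expect_equal(estimateSmoothness(R, mask = m6)@fwhm,
               2 * estimateSmoothness(R, mask = m3)@fwhm, tolerance = 1e-12)
})

test_that("cluster labelling matches a brute-force flood fill", {
  set.seed(20)
  for (conn in c(6, 26)) {
    for (rep in 1:4) {
      bin <- array(runif(10 * 9 * 8) < 0.18, c(10, 9, 8))
      fast <- labelClusters(bin, connectivity = conn)
      slow <- floodFillLabels(bin, connectivity = conn)
      # same partition: one-to-one label correspondence
      expect_equal(max(fast), max(slow))
      expect_true(all((fast > 0) == bin))
      for (k in seq_len(max(fast))) {
        members <- which(fast == k)
        expect_equal(length(unique(slow[members])), 1L)
        expect_equal(sum(slow == slow[members[1]]), length(members))
      }
    }
  }
})

test_that("GRF inference on an all-zero map returns an empty table", {
  dims <- c(8, 8, 8)
  mask <- NetworkMask(array(TRUE, dims), voxelSize = c(3, 3, 3))
  set.seed(23)
  Y <- matrix(rnorm(12 * prod(dims), sd = 0.01), 12)
  glm <- fitVoxelwiseGLM(makeMaps(Y, mask), rep(c(1, 0), each = 6))
  glm@tMap[] <- 0
  sm <- estimateSmoothness(glm)
  out <- grfClusterInference(glm, sm)
  expect_equal(nrow(out$clusters), 0L)
  expect_true(all(out$labelMap == 0L))
})

test_that("a planted high-t blob yields exactly one matching cluster", {
  dims <- c(12, 12, 12)
  mask <- NetworkMask(array(TRUE, dims), voxelSize = c(3, 3, 3))
  blob <- array(FALSE, dims)
  blob[5:8, 5:8, 5:8] <- TRUE  # 64 voxels
  set.seed(24)
  n <- 20
  Y <- matrix(rnorm(n * prod(dims)), n)
  Y[1:(n / 2), which(blob)] <- Y[1:(n / 2), which(blob)] + 4
  glm <- fitVoxelwiseGLM(makeMaps(Y, mask), rep(c(1, 0), each = n / 2))
  out <- grfClusterInference(glm)
  expect_equal(nrow(out$clusters), 1L)
  expect_equal(out$clusters$direction, "patients>controls")
  expect_gt(diceCoef(out$labelMap == 1, blob), 0.5)
})

test_that("stricter voxel thresholds never grow clusters", {
  dims <- c(12, 12, 12)
  mask <- NetworkMask(array(TRUE, dims), voxelSize = c(3, 3, 3))
  blob <- array(FALSE, dims)
  blob[4:9, 4:9, 4:9] <- TRUE
  set.seed(25)
  n <- 16
  Y <- matrix(rnorm(n * prod(dims)), n)
  Y[1:(n / 2), which(blob)] <- Y[1:(n / 2), which(blob)] + 3
  glm <- fitVoxelwiseGLM(makeMaps(Y, mask), rep(c(1, 0), each = n / 2))
  loose <- grfClusterInference(glm, voxelP = 0.005)
  strict <- grfClusterInference(glm, voxelP = 0.0005)
  expect_lte(sum(strict$labelMap > 0), sum(loose$labelMap > 0))
  expect_true(all((strict$labelMap > 0) <= (loose$labelMap > 0) |
                    !(strict$labelMap > 0)))
})
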