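# Build subject volumes from known spatial sources: each subject's data is
# mixing (T x q) %*% sources (q x V) + noise, reshaped to a 4D grid.
# Sparse positive sources on small disjoint supports are near-uncorrelated
# and super-Gaussian, the regime spatial ICA assumes; `dense = TRUE` swaps
# in heavy-tailed dense sources for noiseless subspace tests.
sourcesFixture <- function(dims = c(12L, 12L, 8L), nSources = 3,
                           nSubjects = 4, Tn = 40, noise = 0.1, seed = 1,
                           dense = FALSE, supportSize = 60) {
  set.seed(seed)
  nvox <- prod(dims)
  supports <- list()
  S <- matrix(0, nSources, nvox)
  if (dense) {
    S <- matrix(rt(nSources * nvox, df = 3), nSources)
    supports <- NULL
  } else {
    pool <- sample(nvox)
    for (k in seq_len(nSources)) {
      sel <- pool[((k - 1) * supportSize + 1):(k * supportSize)]
      S[k, sel] <- runif(supportSize, 0.5, 1.5)
      supports[[k]] <- sort(sel)
    }
  }
  vols <- lapply(seq_len(nSubjects), function(i) {
    A <- matrix(rnorm(Tn * nSources), Tn, nSources)
    Y <- A %*% S + noise * matrix(rnorm(Tn * nvox), Tn, nvox)
    Volume4D(array(t(Y), c(dims, Tn)))
  })
  list(volumes = vols, sources = S, supports = supports, dims = dims)
}

test_that("group ICA recovers planted spatial sources", {
  fx <- sourcesFixture(seed = 2)
  dec <- groupICA(fx$volumes, nComponents = 3, seed = 7)
  flat <- matrix(dec@maps, prod(fx$dims), 3)
  cors <- abs(cor(t(fx$sources), flat))
  # every source matched by some component with |spatial correlation| > 0.9
  expect_true(all(apply(cors, 1, max) > 0.9))
  # components match distinct sources
  expect_equal(length(unique(apply(cors, 1, which.max))), 3L)
})

test_that("a single source is identified up to sign and scale", {
  fx <- sourcesFixture(nSources = 1, noise = 0, seed = 3, dense = TRUE)
  dec <- groupICA(fx$volumes, nComponents = 1, seed = 7)
  flat <- as.numeric(dec@maps)
  expect_gt(abs(cor(flat, fx$sources[1, ])), 0.999)
})

test_that("the decomposition is deterministic under a fixed seed", {
  fx <- sourcesFixture(seed = 4)
  d1 <- groupICA(fx$volumes, nComponents = 3, seed = 11)
  d2 <- groupICA(fx$volumes, nComponents = 3, seed = 11)
  expect_identical(d1@maps, d2@maps)
  expect_identical(d1@mixing, d2@mixing)
})

test_that("reduced data are reconstructed from mixing and maps", {
  fx <- sourcesFixture(noise = 0, seed = 5, dense = TRUE)
  dec <- groupICA(fx$volumes, nComponents = 3, seed = 7)
  idx <- which(dec@analyzableMask)
  flat <- matrix(dec@maps, prod(fx$dims), 3)[idx, ]
  # undo the per-map z-scoring: reconstruction uses raw component rows
  recon <- dec@mixing %*% t(flat)
  # compare against the concatenated reduced data rebuilt the same way
  vols <- fx$volumes
  reduced <- lapply(vols, function(v) {
    Tn <- dim(v@data)[4]
    Y <- t(matrix(v@data, prod(fx$dims), Tn)[idx, , drop = FALSE])
    Y <- sweep(Y, 2L, colMeans(Y))
    sv <- svd(Y, nu = 3, nv = 0)
    t(sv$u[, 1:3, drop = FALSE]) %*% Y / sqrt(Tn - 1)
  })
  X2 <- do.call(rbind, reduced)
  X2 <- X2 - rowMeans(X2)
  relErr <- norm(X2 - recon, "F") / norm(X2, "F")
  expect_lt(relErr, 0.05)
})

test_that("invalid component counts and degenerate voxels are rejected", {
  fx <- sourcesFixture(seed = 6, nSubjects = 2, Tn = 10)
  expect_error(groupICA(fx$volumes, nComponents = 60, seed = 1), "rank|timepoints")
  vols <- fx$volumes
  d <- dim(vols[[1]]@data)
  arr <- vols[[1]]@data
  arr[1, 1, 1, ] <- 7  # constant voxel
  vols[[1]] <- Volume4D(arr)
  m <- NetworkMask(array(TRUE, d[1:3]))
  expect_error(groupICA(vols, analyzableMask = m, nComponents = 2, seed = 1),
               "constant")
})

test_that("template matching selects the planted component", {
  fx <- sourcesFixture(seed = 8)
  dec <- groupICA(fx$volumes, nComponents = 3, seed = 7)
  tpl <- array(FALSE, fx$dims)
  tpl[fx$supports[[2]]] <- TRUE
  sel <- selectNetworkComponent(dec, NetworkMask(tpl))
  flat <- matrix(dec@maps, prod(fx$dims), 3)
  expect_gt(abs(cor(flat[, sel$index], fx$sources[2, ])), 0.9)
  expect_gt(sel$score, 0.8)

  # all-true template degenerates to the map-mean rule
  allt <- NetworkMask(array(TRUE, fx$dims))
  degen <- selectNetworkComponent(dec, allt)
  means <- colMeans(flat)
  expect_equal(degen$index, which.max(means))

  # identical components tie toward the lowest index
  dup <- dec
  dup@maps[, , , 3] <- dup@maps[, , , 1]
  tpl1 <- array(FALSE, fx$dims)
  tpl1[fx$supports[[1]]] <- TRUE
  tie <- selectNetworkComponent(dup, NetworkMask(tpl1))
  expect_equal(tie$index, 1L)
})

test_that("component thresholding recovers the planted support", {
  fx <- sourcesFixture(seed = 9)
  dec <- groupICA(fx$volumes, nComponents = 3, seed = 7)
  tpl <- array(FALSE, fx$dims)
  tpl[fx$supports[[1]]] <- TRUE
  sel <- selectNetworkComponent(dec, NetworkMask(tpl))
  mask <- componentToMask(dec, sel$index, zThreshold = 1, flip = sel$flipped)
  expect_gt(diceCoef(maskArray(mask), tpl), 0.8)

  # threshold above the map maximum: empty-mask error
  expect_error(componentToMask(dec, sel$index,
                               zThreshold = max(dec@maps) + 1), "empty")
  # threshold -> -Inf: all analyzable voxels
  all <- componentToMask(dec, sel$index, zThreshold = -Inf)
  expect_equal(sum(maskArray(all)), sum(dec@analyzableMask))
})

test_that("ICA-derived masks recover the generator's truth mask", {
  dice <- vapply(1:3, function(s) {
    cfg <- SimulationConfig(gridDims = c(10L, 10L, 10L), nTimepoints = 60,
                            nPatients = 3, nControls = 3,
                            regions = list(boxRegion("net", 3:6, 3:6, 3:6,
                                                     0.8, 0.8)),
                            covariateModel = list(), seed = 100 + s)
    sim <- generateCohort(cfg, scores = FALSE)
    dec <- groupICA(sim$volumes, nComponents = 5, seed = s)
    sel <- selectNetworkComponent(dec, sim$truth$mask)
    mask <- componentToMask(dec, sel$index, zThreshold = 1,
                            flip = sel$flipped)
    diceCoef(maskArray(mask), maskArray(sim$truth$mask))
  }, numeric(1))
  expect_true(all(dice >= 0.5))
})
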