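# Shared fixtures and independent oracles used across test files.

# Small random volume with fixed seed.
randomVolume <- function(dims = c(6, 5, 4), Tn = 20, seed = 1,
                         voxelSize = c(3, 3, 3), origin = c(0, 0, 0)) {
  set.seed(seed)
  Volume4D(array(rnorm(prod(dims) * Tn), c(dims, Tn)),
           voxelSize = voxelSize, origin = origin)
}

# Brute-force NH oracle: explicit double loop over voxel pairs.
bruteForceNH <- function(X) {
  N <- nrow(X)
  meanR <- numeric(N)
  for (i in seq_len(N)) {
    acc <- 0
    for (j in seq_len(N)) if (j != i) acc <- acc + cor(X[i, ], X[j, ])
    meanR[i] <- acc / (N - 1)
  }
  meanR
}

# Brute-force connected-component labelling by iterative region growing.
floodFillLabels <- function(bin, connectivity = 26) {
  dims <- dim(bin)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nl <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[nl == 1, , drop = FALSE],
                "18" = off[nl >= 1 & nl <= 2, , drop = FALSE],
                off[nl >= 1, , drop = FALSE])
  labels <- array(0L, dims)
  lab <- 0L
  repeat {
    seedIdx <- which(bin & labels == 0L)
    if (!length(seedIdx)) break
    lab <- lab + 1L
    comp <- array(FALSE, dims)
    comp[seedIdx[1]] <- TRUE
    repeat {
      grew <- FALSE
      for (v in which(comp)) {
        z <- (v - 1) %/% (dims[1] * dims[2]) + 1
        y <- ((v - 1) %/% dims[1]) %% dims[2] + 1
        x <- (v - 1) %% dims[1] + 1
        for (o in seq_len(nrow(off))) {
          nx <- x + off[o, 1]; ny <- y + off[o, 2]; nz <- z + off[o, 3]
          if (nx < 1 || nx > dims[1] || ny < 1 || ny > dims[2] ||
              nz < 1 || nz > dims[3]) next
          if (bin[nx, ny, nz] && !comp[nx, ny, nz]) {
            comp[nx, ny, nz] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    labels[comp] <- lab
  }
  labels
}

# Exhaustive concordant-pair AUC oracle (ties count 1/2).
pairCountAUC <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == "patient"]
  neg <- scores[labels == 0 | labels == "control"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Dice coefficient of two logical arrays.
diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Compact two-region config for fast pipeline tests.
tinyConfig <- function(seed = 1, lamP = 0.7, lamC = 0.4, Tn = 100,
                       nPer = 10) {
  SimulationConfig(gridDims = c(12L, 12L, 12L), nTimepoints = Tn,
                   nPatients = nPer, nControls = nPer,
                   regions = list(
                     boxRegion("target", 3:5, 3:5, 3:5, lamP, lamC),
                     boxRegion("stable", 8:11, 8:11, 8:11, 0.5, 0.5)),
                   covariateModel = list(), seed = seed)
}
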