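#' ROC analysis with the Youden index
#'
#' Builds the full ROC curve over all distinct score thresholds (decision
#' rule: score >= threshold predicts patient), with tied scores moving
#' sensitivity and specificity together so the trapezoidal AUC equals the
#' Mann-Whitney concordance probability (ties counted 1/2). Patients are the
#' positive class; when the raw AUC falls below 0.5 the score is negated
#' (recorded in `flipped`) so the reported AUC is >= 0.5 — NH scores can run
#' in either direction depending on the region's group effect. The optimal
#' cut-off maximizes the Youden index J = sensitivity + specificity - 1;
#' ties are broken toward higher sensitivity.
#'
#' @param scores numeric score per subject (e.g. regional mean NH).
#' @param labels patient/control labels (`"patient"`/1 is positive).
#' @return list with `auc`, `cutoff` (threshold on the possibly flipped
#'   score), `sensitivity`, `specificity`, `youden`, `accuracy` (fraction
#'   correct at the cut-off), `flipped`, and `curve` (data.frame threshold /
#'   fpr / tpr).
#' @export
rocWithYouden <- function(scores, labels) {
  pos <- .asPatientIndicator(labels)
  if (length(unique(pos)) < 2L) stop("both classes must be present")
  if (length(scores) != length(pos))
    stop("scores and labels differ in length")
  buildCurve <- function(sc) {
    thr <- sort(unique(sc), decreasing = TRUE)
    tpr <- vapply(thr, function(th) mean(sc[pos == 1] >= th), numeric(1))
    fpr <- vapply(thr, function(th) mean(sc[pos == 0] >= th), numeric(1))
    data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  }
  aucOf <- function(curve) {
    x <- c(0, curve$fpr, 1)
    y <- c(0, curve$tpr, 1)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  curve <- buildCurve(scores)
  auc <- aucOf(curve)
  flipped <- FALSE
  if (auc < 0.5) {
    flipped <- TRUE
    scores <- -scores
    curve <- buildCurve(scores)
    auc <- aucOf(curve)
  }
  J <- curve$tpr - curve$fpr
  tied <- which(J >= max(J) - 1e-9)  # numerically tied J: higher sensitivity
  best <- tied[which.max(curve$tpr[tied])]
  nPos <- sum(pos == 1)
  nNeg <- sum(pos == 0)
  acc <- (curve$tpr[best] * nPos + (1 - curve$fpr[best]) * nNeg) /
    (nPos + nNeg)
  list(auc = auc, cutoff = curve$threshold[best],
       sensitivity = curve$tpr[best], specificity = 1 - curve$fpr[best],
       youden = J[best], accuracy = acc, flipped = flipped, curve = curve)
}

.asPatientIndicator <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "patient")
  else as.integer(labels == 1)
}

.defaultCGrid <- function() 2^seq(-5, 15, by = 2)
.defaultGammaGrid <- function() 2^seq(-15, 3, by = 2)

# Center/scale with train statistics; zero-SD columns get scale 1.
.foldScale <- function(train, test) {
  mu <- colMeans(train)
  sg <- apply(train, 2L, stats::sd)
  sg[sg == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sg, "/"),
       test = sweep(sweep(test, 2L, mu, check.margin = FALSE), 2L, sg, "/"))
}

#' Leave-one-out SVM accuracy with grid search
#'
#' Radial-basis-kernel soft-margin SVM (libsvm via e1071). For every (C,
#' gamma) pair on the grid the leave-one-out accuracy is computed, with
#' feature standardization refit inside each training fold (no leakage from
#' the held-out subject); the reported result is the grid maximum, ties
#' resolved toward the smallest C and then the smallest gamma. By default
#' the (C, gamma) pair is selected by the same LOO estimate that is
#' reported; `nested = TRUE` instead picks the pair inside every fold by an
#' inner LOO on that fold's training set, which removes the selection
#' optimism at substantially higher cost.
#'
#' @param features n x p numeric matrix; constant features are dropped with
#'   a warning (if none remain, the majority-class LOO accuracy is
#'   returned).
#' @param labels patient/control labels.
#' @param cGrid,gammaGrid parameter grids (defaults 2^-5..2^15 and
#'   2^-15..2^3 in powers of 4).
#' @param nested use nested (per-fold) parameter selection.
#' @return list with `accuracy` (percent), `bestC`, `bestGamma`, `confusion`
#'   (2 x 2 table), `grid` (per-combination LOO accuracies; NULL when
#'   nested), `nFeatures`, `droppedFeatures`.
#' @export
svmLooAccuracy <- function(features, labels, cGrid = .defaultCGrid(),
                           gammaGrid = .defaultGammaGrid(), nested = FALSE) {
  features <- as.matrix(features)
  pos <- .asPatientIndicator(labels)
  n <- nrow(features)
  if (n < 4L) stop("need at least 4 subjects")
  if (length(unique(pos)) < 2L) stop("both classes must be present")
  const <- apply(features, 2L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(features)[const], collapse = ", "))
    features <- features[, !const, drop = FALSE]
  }
  y <- factor(ifelse(pos == 1, "patient", "control"),
              levels = c("control", "patient"))
  if (ncol(features) == 0L) {
    pred <- vapply(seq_len(n), function(i) {
      tt <- table(y[-i])
      names(tt)[which.max(tt)]  # ties -> first level
    }, character(1))
    conf <- table(truth = y, predicted = factor(pred, levels = levels(y)))
    return(list(accuracy = 100 * mean(pred == as.character(y)),
                bestC = NA_real_, bestGamma = NA_real_, confusion = conf,
                grid = NULL, nFeatures = 0L,
                droppedFeatures = colnames(features)))
  }
  combos <- expand.grid(gamma = gammaGrid, C = cGrid)[, c("C", "gamma")]
  combos <- combos[order(combos$C, combos$gamma), ]
  looPredictions <- function(feat, yy, C, gamma) {
    vapply(seq_len(nrow(feat)), function(i) {
      sc <- .foldScale(feat[-i, , drop = FALSE], feat[i, , drop = FALSE])
      fit <- e1071::svm(sc$train, yy[-i], kernel = "radial", cost = C,
                        gamma = gamma, scale = FALSE)
      as.character(stats::predict(fit, sc$test))
    }, character(1))
  }
  if (!nested) {
    preds <- matrix(NA_character_, n, nrow(combos))
    for (j in seq_len(nrow(combos)))
      preds[, j] <- looPredictions(features, y, combos$C[j], combos$gamma[j])
    accs <- colMeans(preds == as.character(y))
    best <- which.max(accs)  # combos ordered by C then gamma: ties -> smallest
    bestPred <- preds[, best]
    grid <- cbind(combos, accuracy = 100 * accs)
  } else {
    bestPred <- vapply(seq_len(n), function(i) {
      innerAcc <- vapply(seq_len(nrow(combos)), function(j) {
        p <- looPredictions(features[-i, , drop = FALSE], y[-i],
                            combos$C[j], combos$gamma[j])
        mean(p == as.character(y[-i]))
      }, numeric(1))
      j <- which.max(innerAcc)
      sc <- .foldScale(features[-i, , drop = FALSE],
                       features[i, , drop = FALSE])
      fit <- e1071::svm(sc$train, y[-i], kernel = "radial",
                        cost = combos$C[j], gamma = combos$gamma[j],
                        scale = FALSE)
      as.character(stats::predict(fit, sc$test))
    }, character(1))
    grid <- NULL
    best <- NA_integer_
  }
  conf <- table(truth = y, predicted = factor(bestPred, levels = levels(y)))
  list(accuracy = 100 * mean(bestPred == as.character(y)),
       bestC = if (is.na(best[1])) NA_real_ else combos$C[best],
       bestGamma = if (is.na(best[1])) NA_real_ else combos$gamma[best],
       confusion = conf, grid = grid, nFeatures = ncol(features),
       droppedFeatures = if (any(const)) colnames(features)[const] else
         character())
}

#' Exhaustive feature-subset SVM accuracy table
#'
#' Runs [svmLooAccuracy()] independently for every nonempty subset of the
#' feature columns (2^k - 1 rows); rows are keyed by concatenated 1-based
#' feature indices ("1", "12", "134", ...), and the best-accuracy subset is
#' flagged (ties toward the smallest subset key).
#'
#' @inheritParams svmLooAccuracy
#' @return data.frame with columns `subset`, `features`, `nFeatures`,
#'   `accuracy`, `bestC`, `bestGamma`, `best`.
#' @export
subsetSearch <- function(features, labels, cGrid = .defaultCGrid(),
                         gammaGrid = .defaultGammaGrid()) {
  features <- as.matrix(features)
  k <- ncol(features)
  if (k < 1L || k > 10L) stop("subset search supports 1 to 10 features")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(k))
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(ss) {
    res <- svmLooAccuracy(features[, ss, drop = FALSE], labels,
                          cGrid = cGrid, gammaGrid = gammaGrid)
    data.frame(subset = paste(ss, collapse = ""),
               features = paste(colnames(features)[ss], collapse = ","),
               nFeatures = length(ss), accuracy = res$accuracy,
               bestC = res$bestC, bestGamma = res$bestGamma,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$best <- FALSE
  out$best[which.max(out$accuracy)] <- TRUE
  out
}
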