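#' Two-sample t test from raw samples or summary statistics
#'
#' Pooled-variance or Welch t statistic, computable either from raw samples
#' (`x`, `y`) or directly from the printed `n`/mean/SD summaries; both
#' routes reduce to the same closed-form expressions, so raw and summary
#' input agree to machine precision.
#'
#' @param x,y raw samples (alternative to the summary interface).
#' @param n1,mean1,sd1,n2,mean2,sd2 summary statistics (alternative to
#'   `x`/`y`).
#' @param variant `"pooled"` (df-weighted pooled variance, df = n1+n2-2) or
#'   `"welch"` (Welch-Satterthwaite df).
#' @return list with `t`, `df`, `p` (two-tailed), `variant`,
#'   `meanDifference`.
#' @export
twoSampleT <- function(x = NULL, y = NULL, n1 = NULL, mean1 = NULL,
                       sd1 = NULL, n2 = NULL, mean2 = NULL, sd2 = NULL,
                       variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!is.null(x) && !is.null(y)) {
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    n1 <- length(x); mean1 <- mean(x); sd1 <- stats::sd(x)
    n2 <- length(y); mean2 <- mean(y); sd2 <- stats::sd(y)
  }
  if (is.null(n1) || is.null(mean1) || is.null(sd1) ||
      is.null(n2) || is.null(mean2) || is.null(sd2))
    stop("supply either raw samples x/y or all six summary statistics")
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1,
                                    variant = variant,
                                    meanDifference = 0))
    stop("zero variance in both groups with unequal means")
  }
  diff <- mean1 - mean2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- diff / se
  list(t = tval, df = df, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       variant = variant, meanDifference = diff)
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), as used
#' for group-by-sex contingency tables. Cells are
#' `rbind(c(a, b), c(c, d))`.
#'
#' @param a,b,c,d nonnegative integer cell counts; all four marginals must
#'   be positive.
#' @return list with `chi2`, `df` (= 1) and `p`.
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all marginals must be positive")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Variance-equality gate for the pooled-vs-Welch choice
#'
#' Variance-ratio F test (two-sided); when its p-value falls below
#' `alpha`, the Welch variant is recommended, otherwise the pooled one.
#'
#' @param n1,sd1,n2,sd2 group sizes and SDs.
#' @param alpha gate level (default 0.05).
#' @return list with `variant` (`"pooled"` or `"welch"`) and `p` of the
#'   variance-ratio test.
#' @export
varianceGate <- function(n1, sd1, n2, sd2, alpha = 0.05) {
  f <- (sd1 / sd2)^2
  p <- 2 * min(stats::pf(f, n1 - 1, n2 - 1),
               stats::pf(f, n1 - 1, n2 - 1, lower.tail = FALSE))
  p <- min(p, 1)
  list(variant = if (p < alpha) "welch" else "pooled", p = p)
}

#' Group comparison table for demographics and scores
#'
#' One row per continuous variable: group means/SDs and the two-sample t
#' (variant chosen per row by [varianceGate()] unless forced), mirroring the
#' usual "characteristics of the subjects" table.
#'
#' @param cohort cohort data.frame (see [readCohortTable()]).
#' @param variables character vector of numeric column names.
#' @param variant `"auto"` (gate per row), `"pooled"` or `"welch"`.
#' @return data.frame with one row per variable.
#' @export
cohortComparisonTable <- function(cohort, variables, variant = "auto") {
  pat <- cohort[cohort$group == "patient", , drop = FALSE]
  ctl <- cohort[cohort$group == "control", , drop = FALSE]
  rows <- lapply(variables, function(v) {
    if (!v %in% names(cohort)) stop("unknown cohort column: ", v)
    x <- pat[[v]][is.finite(pat[[v]])]
    y <- ctl[[v]][is.finite(ctl[[v]])]
    vr <- if (variant == "auto")
      varianceGate(length(x), stats::sd(x), length(y), stats::sd(y))$variant
    else variant
    tt <- twoSampleT(x = x, y = y, variant = vr)
    data.frame(variable = v, nPatients = length(x), meanPatients = mean(x),
               sdPatients = stats::sd(x), nControls = length(y),
               meanControls = mean(y), sdControls = stats::sd(y),
               t = tt$t, df = tt$df, p = tt$p, variant = vr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stepwise multiple regression (p-value entry/removal)
#'
#' Classic forward-entry / backward-removal stepwise OLS: at each step the
#' candidate with the smallest partial p enters if it is at or below
#' `entryP`, then any retained predictor whose p reaches `removalP` or more
#' is removed (largest first), until the model is stable. A cycle guard
#' returns the last stable model with a warning. An empty model is allowed.
#'
#' @param y numeric response.
#' @param candidates data.frame or matrix of candidate predictors (no
#'   constant columns).
#' @param entryP entry threshold (default 0.05).
#' @param removalP removal threshold (default 0.10); must be >= `entryP`.
#' @return list with `selected` (names), `coefficients` (unstandardized b),
#'   `standardizedBeta` (b * sd(x) / sd(y)), `predictorP`, `intercept`,
#'   `adjR2`, `r2`, `F`, `modelP`, `n`, and `model` (the final `lm` fit or
#'   NULL for the empty model).
#' @export
stepwiseRegression <- function(y, candidates, entryP = 0.05,
                               removalP = 0.10) {
  X <- as.data.frame(candidates)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    names(X) <- paste0("x", seq_along(X))
  keep <- stats::complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n <= ncol(X) + 2) stop("need n > number of candidates + 2")
  if (any(vapply(X, function(col) stats::sd(col) == 0, logical(1))))
    stop("constant candidate predictor")
  if (removalP < entryP)
    stop("removalP must be at least entryP")
  dat <- cbind(.y = y, X)
  partialP <- function(sel, cand) {
    f <- stats::as.formula(paste(".y ~", paste(c(sel, cand), collapse = "+")))
    fit <- stats::lm(f, data = dat)
    cf <- summary(fit)$coefficients
    if (!cand %in% rownames(cf)) return(1)  # aliased
    cf[cand, 4]
  }
  selected <- character()
  seen <- character()
  stable <- FALSE
  while (!stable) {
    stable <- TRUE
    avail <- setdiff(names(X), selected)
    if (length(avail)) {
      ps <- vapply(avail, function(cand) partialP(selected, cand), numeric(1))
      if (min(ps) <= entryP) {
        selected <- c(selected, avail[which.min(ps)])
        stable <- FALSE
      }
    }
    repeat {
      if (!length(selected)) break
      f <- stats::as.formula(paste(".y ~", paste(selected, collapse = "+")))
      cf <- summary(stats::lm(f, data = dat))$coefficients
      ps <- cf[selected, 4]
      if (max(ps) >= removalP) {
        selected <- setdiff(selected, selected[which.max(ps)])
        stable <- FALSE
      } else break
    }
    key <- paste(sort(selected), collapse = ",")
    if (!stable && key %in% seen) {
      warning("stepwise selection cycled; returning last stable model")
      break
    }
    seen <- c(seen, key)
  }
  if (!length(selected))
    return(list(selected = character(), coefficients = numeric(),
                standardizedBeta = numeric(), predictorP = numeric(),
                intercept = mean(y), adjR2 = 0, r2 = 0, F = NA_real_,
                modelP = NA_real_, n = n, model = NULL))
  f <- stats::as.formula(paste(".y ~", paste(selected, collapse = "+")))
  fit <- stats::lm(f, data = dat)
  sm <- summary(fit)
  b <- stats::coef(fit)[selected]
  sdy <- stats::sd(y)
  beta <- vapply(selected, function(v) b[[v]] * stats::sd(dat[[v]]) / sdy,
                 numeric(1))
  fstat <- sm$fstatistic
  list(selected = selected, coefficients = b, standardizedBeta = beta,
       predictorP = stats::setNames(sm$coefficients[selected, 4], selected),
       intercept = unname(stats::coef(fit)[1]),
       adjR2 = sm$adj.r.squared, r2 = sm$r.squared,
       F = unname(fstat[1]),
       modelP = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                 lower.tail = FALSE)),
       n = n, model = fit)
}

#' Stepwise brain-behavior association table
#'
#' For each outcome (PANSS subscales, cognition scores) runs one stepwise
#' regression over the same candidate set — the regional NH features plus
#' age, education and illness duration — in the patient group, mirroring the
#' one-row-per-outcome layout of such association tables. No cross-outcome
#' multiplicity correction is applied.
#'
#' @param cohort cohort data.frame.
#' @param features subjects x regions NH feature matrix (rows aligned with
#'   `cohort`).
#' @param outcomes character vector of outcome column names.
#' @param extraCandidates cohort columns added to the candidate set
#'   (default age, education, duration).
#' @param patientsOnly restrict to the patient group (default TRUE).
#' @inheritParams stepwiseRegression
#' @return data.frame with one row per (outcome, selected predictor):
#'   outcome, adjR2, intercept B, F, model p, variable, standardized beta,
#'   predictor p. Outcomes with an empty model get a single row of NAs.
#' @export
associationTable <- function(cohort, features, outcomes,
                             extraCandidates = c("age", "education",
                                                 "duration"),
                             patientsOnly = TRUE, entryP = 0.05,
                             removalP = 0.10) {
  stopifnot(nrow(features) == nrow(cohort))
  sel <- if (patientsOnly) cohort$group == "patient" else
    rep(TRUE, nrow(cohort))
  cands <- as.data.frame(features[sel, , drop = FALSE])
  for (v in extraCandidates) cands[[v]] <- cohort[[v]][sel]
  rows <- list()
  for (oc in outcomes) {
    if (!oc %in% names(cohort)) stop("unknown outcome column: ", oc)
    res <- stepwiseRegression(cohort[[oc]][sel], cands, entryP, removalP)
    if (!length(res$selected)) {
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, adjR2 = NA_real_, B = NA_real_, F = NA_real_,
        modelP = NA_real_, variable = NA_character_,
        standardizedBeta = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    } else {
      for (v in res$selected)
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = oc, adjR2 = res$adjR2, B = res$intercept, F = res$F,
          modelP = res$modelP, variable = v,
          standardizedBeta = unname(res$standardizedBeta[v]),
          p = unname(res$predictorP[v]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
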