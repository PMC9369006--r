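test_that("group statistics recomputed from printed summaries match", {
  # cognitive battery and demographics of a 57-patient / 50-control cohort
  sop <- twoSampleT(n1 = 57, mean1 = 34.70, sd1 = 12.12,
                    n2 = 50, mean2 = 44.28, sd2 = 9.10, variant = "pooled")
  expect_equal(sop$t, -4.57, tolerance = 0.01 / 4.57 * 4.57)
  att <- twoSampleT(n1 = 57, mean1 = 38.19, sd1 = 13.61,
                    n2 = 50, mean2 = 45.56, sd2 = 9.69, variant = "welch")
  expect_equal(att$t, -3.25, tolerance = 0.01)
  age <- twoSampleT(n1 = 57, mean1 = 31.63, sd1 = 11.43,
                    n2 = 50, mean2 = 28.38, sd2 = 6.87, variant = "welch")
  expect_equal(age$t, 1.81, tolerance = 0.01)
  gender <- chiSquare2x2(20, 37, 23, 27)
  expect_equal(gender$chi2, 1.320, tolerance = 0.001)
  expect_equal(gender$df, 1)
  expect_equal(gender$p, 0.251, tolerance = 0.01)
})

test_that("degenerate and identity cases of the t test hold", {
  same <- twoSampleT(n1 = 10, mean1 = 5, sd1 = 2, n2 = 12, mean2 = 5,
                     sd2 = 2, variant = "pooled")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # welch equals pooled when n1 = n2 and sd1 = sd2
  a <- twoSampleT(n1 = 15, mean1 = 3, sd1 = 1.7, n2 = 15, mean2 = 2.2,
                  sd2 = 1.7, variant = "pooled")
  b <- twoSampleT(n1 = 15, mean1 = 3, sd1 = 1.7, n2 = 15, mean2 = 2.2,
                  sd2 = 1.7, variant = "welch")
  expect_lt(abs(a$t - b$t), 1e-12)
  expect_lt(abs(a$df - b$df), 1e-9)
  expect_error(twoSampleT(n1 = 5, mean1 = 1, sd1 = 0, n2 = 5, mean2 = 2,
                          sd2 = 0), "zero variance")
})

test_that("raw samples and their summaries give identical t statistics", {
  set.seed(33)
  for (variant in c("pooled", "welch")) {
    x <- rnorm(14, 10, 3)
    y <- rnorm(19, 8, 2)
    raw <- twoSampleT(x = x, y = y, variant = variant)
    summ <- twoSampleT(n1 = 14, mean1 = mean(x), sd1 = sd(x),
                       n2 = 19, mean2 = mean(y), sd2 = sd(y),
                       variant = variant)
    expect_lt(abs(raw$t - summ$t), 1e-12)
    expect_lt(abs(raw$df - summ$df), 1e-9)
    # cross-check against the standard implementation
    ht <- t.test(x, y, var.equal = variant == "pooled")
    expect_equal(raw$t, unname(ht$statistic), tolerance = 1e-12)
    expect_equal(raw$df, unname(ht$parameter), tolerance = 1e-9)
  }
})

test_that("chi-square handles homogeneous and strongly split tables", {
  expect_equal(chiSquare2x2(10, 10, 10, 10)$chi2, 0)
  # expected counts all 20 -> chi2 = 4 * 100/20 = 20
  expect_equal(chiSquare2x2(30, 10, 10, 30)$chi2, 20)
  expect_error(chiSquare2x2(0, 0, 5, 5), "marginals")
  expect_error(chiSquare2x2(1.5, 2, 3, 4), "integers")
})

test_that("the variance gate selects welch only under unequal variances", {
  expect_equal(varianceGate(57, 12.12, 50, 9.10)$variant, "welch")
  expect_equal(varianceGate(30, 2.0, 30, 2.1)$variant, "pooled")
})

test_that("stepwise regression recovers exact and planted predictors", {
  set.seed(41)
  n <- 57
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  # y exactly equal to a candidate: beta = 1, adjusted R^2 = 1
  res <- suppressWarnings(stepwiseRegression(X$x2, X))  # perfect-fit warnings
  expect_equal(res$selected, "x2")
  expect_equal(unname(res$standardizedBeta), 1, tolerance = 1e-10)
  expect_equal(res$adjR2, 1, tolerance = 1e-10)

  # single-predictor standardized beta equals the sample correlation
  y <- 0.4 * X$x1 + rnorm(n)
  res2 <- stepwiseRegression(y, X["x1"], entryP = 1, removalP = 1)
  expect_equal(unname(res2$standardizedBeta), cor(y, X$x1),
               tolerance = 1e-12)
})

test_that("entry/removal thresholds of 1 reproduce the full OLS model", {
  set.seed(42)
  n <- 40
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 0.5 * X$a - 0.2 * X$b + rnorm(n)
  res <- stepwiseRegression(y, X, entryP = 1, removalP = 1)
  expect_setequal(res$selected, c("a", "b", "c"))
  full <- lm(y ~ a + b + c, data = X)
  expect_equal(sort(res$coefficients),
               sort(coef(full)[c("a", "b", "c")]), tolerance = 1e-10)
  expect_equal(res$adjR2, summary(full)$adj.r.squared, tolerance = 1e-12)
})

test_that("a strong single predictor is selected with a negative sign", {
  hits <- 0
  signOK <- TRUE
  for (s in 1:40) {
    set.seed(300 + s)
    n <- 57
    X <- data.frame(x1 = rnorm(n), d1 = rnorm(n), d2 = rnorm(n),
                    d3 = rnorm(n))
    y <- -0.5 * X$x1 + rnorm(n, sd = sqrt(1 - 0.25))
    res <- stepwiseRegression(y, X)
    if ("x1" %in% res$selected) {
      if (res$standardizedBeta[["x1"]] >= 0) signOK <- FALSE
      if (identical(res$selected, "x1")) hits <- hits + 1
    }
  }
  expect_true(signOK)
  expect_gt(hits, 40 * 0.6)  # mostly selected alone
})

test_that("a null response mostly yields the empty model", {
  empties <- vapply(1:40, function(s) {
    set.seed(400 + s)
    n <- 57
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
    length(stepwiseRegression(rnorm(n), X)$selected) == 0
  }, logical(1))
  # per-step alpha 0.05 with 4 candidates: about 0.95^4 = 81% empty
  expect_gt(mean(empties), 0.6)
})

test_that("cohort comparison tables gate the variant per row", {
  sim <- generateCohort(tinyConfig(seed = 13, Tn = 40, nPer = 12))
  tab <- cohortComparisonTable(sim$cohort, c("age", "education"))
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$variant %in% c("pooled", "welch")))
  forced <- cohortComparisonTable(sim$cohort, "age", variant = "welch")
  ref <- t.test(age ~ group, data = sim$cohort)
  # t.test orders groups alphabetically (control - patient): sign flips
  expect_equal(forced$t, -unname(ref$statistic), tolerance = 1e-10)
})

test_that("association tables run one stepwise model per outcome", {
  set.seed(55)
  n <- 60
  cohort <- data.frame(subject_id = sprintf("s%d", 1:n),
                       group = rep(c("patient", "control"), each = n / 2),
                       age = rnorm(n, 30, 8), sex = "male",
                       education = rnorm(n, 13, 3),
                       duration = c(runif(n / 2, 0.5, 8), rep(0, n / 2)))
  cohort <- validateCohortTable(cohort)
  feats <- cbind(regA = rnorm(n), regB = rnorm(n))
  cohort$score1 <- -8 * feats[, "regA"] + rnorm(n, sd = 0.5)
  cohort$score2 <- rnorm(n)
  out <- associationTable(cohort, feats, c("score1", "score2"))
  s1 <- out[out$outcome == "score1", ]
  expect_true("regA" %in% s1$variable)
  expect_lt(s1$standardizedBeta[s1$variable == "regA"], -0.9)
  expect_lt(s1$p[s1$variable == "regA"], 0.001)  # per-predictor p is carried
  expect_equal(length(unique(out$outcome)), 2L)
})
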