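test_that("C-statistic equals all-pairs concordance, exhaustively for n <= 50", {
  expect_equal(cStatistic(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1)), 1.0)
  expect_equal(cStatistic(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)), 0.75)
  expect_error(cStatistic(c(0.1, 0.9), c(1, 1)), "one outcome class")
  withr::with_seed(24, {
    for (r in 1:40) {
      n <- sample(4:50, 1)
      p <- round(runif(n), 2)  # rounding forces ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(cStatistic(p, y), bruteForceC(p, y), tolerance = 1e-12)
    }
  })
})

test_that("label-permuted outcomes give chance concordance", {
  withr::with_seed(25, {
    p <- runif(200)
    y <- rbinom(200, 1, 0.3)
    cs <- replicate(300, cStatistic(p, sample(y)))
    expect_equal(mean(cs), 0.5, tolerance = 0.01)
  })
})

test_that("C-statistic agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(26, {
    p <- runif(150); y <- rbinom(150, 1, 0.4)
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
    expect_equal(cStatistic(p, y), ref, tolerance = 1e-10)
  })
})

test_that("Hosmer-Lemeshow reproduces chi-square tail arithmetic", {
  # the p-value is exactly the upper chi-square tail of its own statistic
  withr::with_seed(27, {
    p <- runif(500, 0.05, 0.9)
    y <- rbinom(500, 1, p)
    hl <- hosmerLemeshow(p, y)
    expect_equal(hl$df, 8L)
    expect_equal(hl$p, pchisq(hl$chi2, hl$df, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(sum(hl$table$n), 500)
  })
  # tied risks collapse groups with adjusted df
  pt <- rep(c(0.1, 0.2, 0.3), each = 30)
  yt <- rbinom(90, 1, pt)
  expect_warning(hlt <- hosmerLemeshow(pt, yt), "collapsed")
  expect_equal(hlt$df, length(unique(pt)) - 2L)
  expect_equal(nrow(hlt$table), 3L)
})

test_that("Hosmer-Lemeshow is calibrated on well-specified fitted models", {
  withr::with_seed(28, {
    rej <- replicate(300, {
      x <- matrix(rnorm(2000 * 2), ncol = 2)
      y <- rbinom(2000, 1, plogis(-2 + x %*% c(0.8, -0.5)))
      f <- babymotion:::.fitLogistic(x, y)
      hosmerLemeshow(f$fitted, y)$p < 0.05
    })
    expect_lt(abs(mean(rej) - 0.05), 0.025)
  })
})

test_that("bootstrap optimism is seed-reproducible and leaves the RNG alone", {
  co <- simulateCohort(cohortSpec(n = 300, seed = 29L))
  vars <- c("V_my", "Q_med", "Q_sd", "Q_min")
  withr::with_seed(1, before <- runif(1))
  withr::with_seed(1, {
    runif(1)
    a <- bootstrapOptimism(co, vars, B = 100, seed = 7)
    after <- runif(1)
  })
  b <- bootstrapOptimism(co, vars, B = 100, seed = 7)
  expect_identical(a[c("c_apparent", "optimism", "c_corrected")],
                   b[c("c_apparent", "optimism", "c_corrected")])
  # the bootstrap's internal seeding must not disturb the caller's stream
  withr::with_seed(1, { runif(1); expect_identical(runif(1), after) })
})

test_that("optimism is small for well-specified fits, large for overfits", {
  big <- simulateCohort(cohortSpec(n = 5000, seed = 30L))
  vars <- c("V_my", "Q_med", "Q_sd", "Q_min")
  ob <- bootstrapOptimism(big, vars, B = 100, seed = 8)
  expect_lt(ob$optimism, 0.01)
  # 20 pure-noise predictors on 100 subjects overfit badly
  withr::with_seed(31, {
    noisy <- data.frame(matrix(rnorm(100 * 20), 100,
                               dimnames = list(NULL, paste0("z", 1:20))))
    noisy$outcome <- rbinom(100, 1, 0.3)
  })
  on <- bootstrapOptimism(noisy, paste0("z", 1:20), B = 200, seed = 9)
  expect_gt(on$optimism, 0.05)
})

test_that("the ROC threshold maximizes Youden's J with low-threshold ties", {
  # perfectly separated: every threshold in the gap attains J = 1; the
  # tie-break returns the lowest observed such threshold
  p <- c(0.1, 0.2, 0.7, 0.9)
  y <- c(0, 0, 1, 1)
  roc <- rocCurve(p, y)
  expect_equal(optimalThreshold(roc), 0.7)
  # agreement with exhaustive search on the 4-point mixed example
  p2 <- c(0.2, 0.4, 0.6, 0.8); y2 <- c(0, 1, 0, 1)
  roc2 <- rocCurve(p2, y2)
  js <- vapply(roc2$threshold, function(th) {
    sens <- sum(p2 >= th & y2 == 1) / sum(y2)
    spec <- sum(p2 < th & y2 == 0) / sum(y2 == 0)
    sens + spec - 1
  }, numeric(1))
  expect_equal(optimalThreshold(roc2),
               min(roc2$threshold[js == max(js)]))
  # degenerate: all scores equal -> single candidate with J = 0
  roc3 <- rocCurve(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(nrow(roc3), 1L)
  expect_equal(roc3$sens + roc3$spec - 1, 0)
})

test_that("sensitivity falls and specificity rises along the threshold sweep", {
  withr::with_seed(32, {
    p <- runif(300); y <- rbinom(300, 1, p)
    roc <- rocCurve(p, y)
    expect_true(all(diff(roc$sens) <= 0))
    expect_true(all(diff(roc$spec) >= 0))
  })
})

test_that("confusion metrics use exact arithmetic and exact intervals", {
  m <- confusionMetrics(16, 13, 45, 176)
  est <- setNames(m$estimate, m$metric)
  expect_equal(round(est[["sensitivity"]], 2), 55.17)
  expect_equal(round(est[["specificity"]], 2), 79.64)
  expect_equal(round(est[["ppv"]], 2), 26.23)
  expect_equal(round(est[["npv"]], 2), 93.12)
  # Clopper-Pearson for 16/29 against the binom.test oracle
  sens <- m[m$metric == "sensitivity", ]
  ref <- binom.test(16, 29)$conf.int
  expect_equal(sens$lower, 100 * ref[1], tolerance = 1e-8)
  expect_equal(sens$upper, 100 * ref[2], tolerance = 1e-8)
  # all-correct predictions: every metric 100 with upper bound 100
  all100 <- confusionMetrics(10, 0, 0, 20)
  expect_true(all(all100$estimate == 100))
  expect_true(all(all100$upper == 100))
  expect_true(all(all100$lower < 100))
  # zero denominators are NA, not zero
  na1 <- confusionMetrics(0, 0, 3, 7)  # no true cases
  expect_true(is.na(na1$estimate[na1$metric == "sensitivity"]))
  na2 <- confusionMetrics(0, 5, 0, 7)  # no positive predictions
  expect_true(is.na(na2$estimate[na2$metric == "ppv"]))
  expect_equal(na2$estimate[na2$metric == "sensitivity"], 0)
})

test_that("classificationMetrics dichotomizes at the threshold exactly", {
  p <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  y <- c(0, 0, 1, 0, 1)
  cm <- classificationMetrics(p, y, threshold = 0.5)
  expect_equal(cm$confusion, c(TP = 2, FN = 0, FP = 1, TN = 2))
  expect_equal(sum(cm$confusion), length(y))
})

test_that("evaluateModel assembles a coherent report", {
  co <- simulateCohort(cohortSpec(n = 500, seed = 33L))
  ev <- evaluateModel(co, c("V_my", "Q_med", "Q_sd", "Q_min"),
                      B = 100, seed = 10)
  expect_s4_class(ev, "EvaluationReport")
  expect_true(ev@cApparent >= 0 && ev@cApparent <= 1)
  expect_equal(ev@cCorrected, ev@cApparent - ev@optimism)
  expect_equal(sum(ev@confusion), nrow(co))
  expect_equal(ev@hl$p, pchisq(ev@hl$chi2, ev@hl$df, lower.tail = FALSE))
  p <- withr::local_tempfile(fileext = ".json")
  writeEvaluationReport(ev, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$c_apparent, ev@cApparent)
  expect_equal(unlist(j$confusion), c(TP = ev@confusion[["TP"]],
    FN = ev@confusion[["FN"]], FP = ev@confusion[["FP"]],
    TN = ev@confusion[["TN"]]))
})
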