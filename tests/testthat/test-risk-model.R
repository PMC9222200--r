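fourVars <- c("V_my", "Q_med", "Q_sd", "Q_min")

test_that("univariate screening recovers a known log-odds ratio", {
  withr::with_seed(15, {
    x <- rnorm(500)
    y <- rbinom(500, 1, plogis(-1.5 + 0.78 * x))
    scr <- univariateScreen(data.frame(x = x, outcome = y), "x")
    row <- scr$table[scr$table$variable == "x", ]
    expect_lt(abs(row$beta - 0.78) / row$se, 2)
    expect_true("x" %in% scr$retained)
  })
})

test_that("null features are retained at close to the screening level", {
  withr::with_seed(16, {
    hits <- replicate(1000, {
      d <- data.frame(x = rnorm(300), outcome = rbinom(300, 1, 0.3))
      univariateScreen(d, "x", alpha = 0.20)$table$p < 0.20
    })
    expect_equal(mean(hits), 0.20, tolerance = 0.04)
  })
})

test_that("degenerate predictors are excluded or flagged", {
  withr::with_seed(17, {
    d <- data.frame(flat = rep(1, 60), x = rnorm(60),
                    outcome = rbinom(60, 1, 0.4))
    expect_warning(scr <- univariateScreen(d, c("flat", "x")),
                   "zero-variance")
    expect_false("flat" %in% scr$retained)
    expect_true(scr$table$excluded[scr$table$variable == "flat"])
  })
  # complete separation falls back to a penalized fit and is flagged
  sep <- data.frame(x = c(seq(-3, -1, length.out = 20),
                          seq(1, 3, length.out = 20)),
                    outcome = rep(0:1, each = 20))
  scr2 <- univariateScreen(sep, "x")
  expect_true(scr2$table$flagged)
  expect_true(is.finite(scr2$table$beta))
  expect_lt(abs(scr2$table$beta), 15)
})

test_that("VIF matches the 1/(1-R^2) definition and prunes deterministically", {
  withr::with_seed(18, {
    n <- 400
    x1 <- rnorm(n); x2 <- rnorm(n)
    x3 <- x1 + x2 + rnorm(n, 0, 0.3)
    d <- data.frame(x1 = x1, x2 = x2, x3 = x3)
    v <- computeVIF(d, c("x1", "x2", "x3"))
    # independent oracle: lm R^2
    for (nm in names(v)) {
      others <- setdiff(c("x1", "x2", "x3"), nm)
      r2 <- summary(lm(reformulate(others, nm), data = d))$r.squared
      expect_equal(unname(v[nm]), 1 / (1 - r2), tolerance = 1e-10)
    }
    expect_gt(v["x3"], 4)
    pr <- vifPrune(d, c("x1", "x2", "x3"))
    expect_equal(pr$trace$dropped[1], "x3")
    expect_equal(pr$retained, c("x1", "x2"))

    # orthogonal standardized variables: VIF 1, nothing dropped
    o <- data.frame(a = scale(rnorm(n))[, 1], b = scale(rnorm(n))[, 1])
    expect_equal(unname(computeVIF(o, c("a", "b"))), c(1, 1),
                 tolerance = 0.05)
    expect_equal(vifPrune(o, c("a", "b"))$retained, c("a", "b"))

    # exact duplicate: infinite VIF, later registry name dropped
    dd <- data.frame(a = x1, b = x1)
    expect_equal(unname(computeVIF(dd, c("a", "b"))), c(Inf, Inf))
    expect_equal(vifPrune(dd, c("a", "b"))$retained, "a")
  })
})

test_that("backward selection keeps true effects and sheds noise", {
  co <- simulateCohort(cohortSpec(n = 2000, seed = 19L))
  withr::with_seed(20, {
    for (k in 1:4) co[[paste0("noise", k)]] <- rnorm(nrow(co))
  })
  spec <- backwardSelect(co, c(fourVars, paste0("noise", 1:4)))
  expect_true(all(fourVars %in% variables(spec)))
  # every dropped variable left with p >= 0.20
  expect_true(all(spec@selectionTrace$p >= 0.20))
  # the final model has no variable at or above the stay level
  dat <- babymotion:::.cohortMatrix(co, variables(spec))
  f <- babymotion:::.fitLogistic(dat$X, dat$y)
  pv <- pchisq((f$beta[-1] / f$se[-1])^2, 1, lower.tail = FALSE)
  expect_true(all(pv < 0.20))
  # a single already-significant variable is a fixed point
  one <- backwardSelect(co, "Q_sd")
  expect_equal(variables(one), "Q_sd")
})

test_that("odds ratios are exp(beta) with Wald intervals", {
  spec <- ModelSpec(c("a", "b", "c"), c(0.78, 0, 1.54),
                    se = c(0.31, 0.2, 0.47))
  tab <- oddsRatios(spec)
  expect_equal(tab$or, exp(c(0.78, 0, 1.54)))
  expect_equal(round(tab$or, 2), c(2.18, 1.00, 4.66))
  expect_equal(tab$lower, exp(tab$beta - 1.96 * spec@se))
  expect_equal(tab$upper, exp(tab$beta + 1.96 * spec@se))
})

test_that("risk scoring matches a brute-force dot product", {
  withr::with_seed(21, {
    spec <- ModelSpec(paste0("f", 1:5), rnorm(5), intercept = -1.2)
    X <- as.data.frame(matrix(rnorm(100 * 5), 100,
                              dimnames = list(NULL, paste0("f", 1:5))))
    got <- predictRisk(X, spec)
    oracle <- apply(X, 1, function(r) -1.2 + sum(r * spec@beta))
    expect_equal(got$lp, unname(oracle))
    expect_equal(got$prob, plogis(unname(oracle)))
  })
  # logistic fixed points
  p0 <- predictRisk(data.frame(a = 0), ModelSpec("a", 1, intercept = 0))
  expect_equal(p0$prob, 0.5)
  pc <- predictRisk(data.frame(a = c(-5, 7)),
                    ModelSpec("a", 0, intercept = 1))
  expect_equal(pc$prob, rep(plogis(1), 2))
  # missing feature errors by name; no intercept -> NA probability
  expect_error(predictRisk(data.frame(a = 1),
                           ModelSpec(c("a", "zz"), c(1, 1))), "zz")
  pn <- predictRisk(data.frame(a = 1), ModelSpec("a", 2))
  expect_equal(pn$lp, 2)
  expect_true(is.na(pn$prob))
})

test_that("rescaling a predictor rescales beta and leaves C unchanged", {
  co <- simulateCohort(cohortSpec(n = 800, seed = 22L))
  f1 <- backwardSelect(co, fourVars, alphaStay = 1)  # plain fit, no drops
  co2 <- co; co2$Q_sd <- co2$Q_sd * 10
  f2 <- backwardSelect(co2, fourVars, alphaStay = 1)
  i <- match("Q_sd", variables(f1))
  expect_equal(f2@beta[match("Q_sd", variables(f2))], f1@beta[i] / 10,
               tolerance = 1e-6)
  c1 <- cStatistic(predictRisk(co, f1)$lp, co$outcome)
  c2 <- cStatistic(predictRisk(co2, f2)$lp, co2$outcome)
  expect_equal(c1, c2, tolerance = 1e-8)
})

test_that("the full selection pipeline reproduces its stages", {
  co <- simulateCohort(cohortSpec(n = 2000, seed = 23L))
  co$dup <- co$Q_sd  # exact collinear twin must be VIF-pruned
  spec <- fitRiskModel(co, c(fourVars, "dup"))
  expect_setequal(variables(spec), fourVars)
  expect_true("vif-drop" %in% spec@selectionTrace$action)
  # ModelSpec JSON round trip
  p <- withr::local_tempfile(fileext = ".json")
  writeModelSpec(spec, p)
  back <- readModelSpec(p)
  expect_equal(back@beta, spec@beta)
  expect_equal(back@variables, spec@variables)
})
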