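# Internal validation and classification metrics: concordance, bootstrap
# optimism (Harrell), Hosmer-Lemeshow fit, ROC/Youden threshold, and
# exact-CI confusion metrics.

#' Concordance (C) statistic
#'
#' Probability that a random case receives a higher predicted risk than a
#' random non-case, counting ties as 1/2:
#' `C = (concordant + 0.5 * tied) / (n1 * n0)` over all case-control
#' pairs. Computed via midranks, which is algebraically identical to the
#' all-pairs count.
#'
#' @param probs predicted risks (any monotone score works).
#' @param outcomes 0/1 outcomes; both classes must be present.
#' @return C in `[0, 1]`.
#' @export
cStatistic <- function(probs, outcomes) {
  y <- as.numeric(outcomes)
  stopifnot(length(probs) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("C-statistic undefined: only one outcome class present")
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One point per candidate threshold (the sorted unique scores), with the
#' classification rule "positive if `prob >= threshold`". As the
#' threshold rises, sensitivity is non-increasing and specificity
#' non-decreasing.
#'
#' @inheritParams cStatistic
#' @return data.frame `(threshold, sens, spec)` in increasing threshold
#'   order.
#' @export
rocCurve <- function(probs, outcomes) {
  y <- as.numeric(outcomes)
  thr <- sort(unique(probs))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(probs >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(probs < t & y == 0) / n0, numeric(1))
  data.frame(threshold = thr, sens = sens, spec = spec)
}

#' Threshold maximizing Youden's J
#'
#' `J = sens + spec - 1`; ties are broken toward the LOWER threshold
#' (higher sensitivity).
#'
#' @param roc data.frame of `(threshold, sens, spec)` points, e.g. from
#'   [rocCurve()].
#' @return the chosen threshold.
#' @export
optimalThreshold <- function(roc) {
  stopifnot(nrow(roc) >= 1L)
  j <- roc$sens + roc$spec - 1
  best <- j >= max(j) - 1e-12
  min(roc$threshold[best])
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping (quantile breaks of the predicted risks; tied
#' breaks are collapsed with a warning and the degrees of freedom
#' adjusted). The statistic sums `(O - E)^2 / E` over both outcome levels
#' in every group and is referred to the upper tail of
#' `chi-square(groups - 2)`.
#'
#' @inheritParams cStatistic
#' @param groups number of risk groups (default 10).
#' @return list `(chi2, df, p, table)`; `table` holds per-group n,
#'   observed and expected events.
#' @export
hosmerLemeshow <- function(probs, outcomes, groups = 10L) {
  y <- as.numeric(outcomes)
  n <- length(y)
  stopifnot(n >= groups)
  if (length(unique(probs)) <= groups) {
    # heavy ties: group by distinct risk value directly
    g <- factor(probs)
    warning("tied risk deciles collapsed: ", nlevels(g),
            " groups used, df adjusted")
  } else {
    br <- stats::quantile(probs, seq(0, 1, length.out = groups + 1L),
                          type = 2, names = FALSE)
    br <- unique(br)
    if (length(br) < groups + 1L)
      warning("tied risk deciles collapsed: ", length(br) - 1L,
              " groups used, df adjusted")
    if (length(br) < 3L) stop("fewer than 2 distinct risk groups")
    g <- cut(probs, br, include.lowest = TRUE)
  }
  ng <- as.vector(table(g))
  o1 <- as.vector(tapply(y, g, sum)); o1[is.na(o1)] <- 0
  e1 <- as.vector(tapply(probs, g, sum)); e1[is.na(e1)] <- 0
  o0 <- ng - o1; e0 <- ng - e1
  keep <- ng > 0
  chi2 <- sum((o1[keep] - e1[keep])^2 / pmax(e1[keep], 1e-12) +
              (o0[keep] - e0[keep])^2 / pmax(e0[keep], 1e-12))
  df <- sum(keep) - 2L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = data.frame(n = ng[keep], observed = o1[keep],
                          expected = e1[keep]))
}

#' Bootstrap optimism correction of the C-statistic (Harrell)
#'
#' For each of `B` bootstrap resamples of size `sampleSize`, the FIXED
#' final variable set is refitted; the optimism contribution is the
#' fitted model's C on the resample minus its C on the original data.
#' `c_corrected = c_apparent - mean(optimism)`. Resamples containing a
#' single outcome class are redrawn (count reported). Deterministic for a
#' fixed seed; the caller's RNG state is untouched.
#'
#' @param cohort data.frame with predictors and 0/1 outcome.
#' @param variables the final model's variable set (refit as-is, not
#'   re-selected; set `reselect = TRUE` to bootstrap the whole backward
#'   selection path instead, for sensitivity analysis).
#' @param B number of resamples (>= 100; default 1000).
#' @param sampleSize resample size (default `nrow(cohort)`).
#' @param seed RNG seed (default 20220607).
#' @param reselect bootstrap the selection path too (default FALSE).
#' @param alphaStay stay-level used when `reselect = TRUE`.
#' @param outcome outcome column name.
#' @return list `(c_apparent, optimism, c_corrected, B, sample_size,
#'   seed, redrawn)`.
#' @export
bootstrapOptimism <- function(cohort, variables, B = 1000L,
                              sampleSize = nrow(cohort), seed = 20220607,
                              reselect = FALSE, alphaStay = 0.20,
                              outcome = "outcome") {
  stopifnot(B >= 100L)
  dat <- .cohortMatrix(cohort, variables, outcome)
  n <- length(dat$y)
  fullFit <- .fitLogistic(dat$X, dat$y)
  cApp <- cStatistic(fullFit$fitted, dat$y)
  Xd <- cbind(1, dat$X)
  redrawn <- 0L
  opts <- numeric(B)
  .withSeed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, sampleSize, replace = TRUE)
        if (length(unique(dat$y[idx])) == 2L) break
        redrawn <- redrawn + 1L
      }
      bx <- dat$X[idx, , drop = FALSE]
      by <- dat$y[idx]
      if (reselect) {
        bs <- backwardSelect(cbind(as.data.frame(bx),
                                   outcome = by),
                             variables, alphaStay = alphaStay)
        lpBoot <- predictRisk(as.data.frame(bx), bs)$lp
        lpOrig <- predictRisk(as.data.frame(dat$X), bs)$lp
        if (!length(bs@variables)) { opts[b] <- 0; next }
      } else {
        f <- .fitLogistic(bx, by)
        lpBoot <- drop(cbind(1, bx) %*% f$beta)
        lpOrig <- drop(Xd %*% f$beta)
      }
      opts[b] <- cStatistic(lpBoot, by) - cStatistic(lpOrig, dat$y)
    }
  })
  optimism <- mean(opts)
  list(c_apparent = cApp, optimism = optimism,
       c_corrected = cApp - optimism, B = B, sample_size = sampleSize,
       seed = seed, redrawn = redrawn)
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)` and accuracy, each with an exact 95% Clopper-Pearson
#' interval, on the percent scale. A metric with a zero denominator is
#' reported as `NA` (not 0).
#'
#' @param tp,fn,fp,tn confusion-matrix cells (non-negative counts).
#' @return data.frame `(metric, estimate, lower, upper, x, n)` in percent.
#' @examples
#' confusionMetrics(16, 13, 45, 176)
#' @export
confusionMetrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  cells <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv = c(tp, tp + fp),
    npv = c(tn, tn + fn),
    accuracy = c(tp + tn, tp + fn + fp + tn))
  rows <- lapply(names(cells), function(m) {
    x <- cells[[m]][1L]; n <- cells[[m]][2L]
    if (n == 0)
      return(data.frame(metric = m, estimate = NA_real_, lower = NA_real_,
        upper = NA_real_, x = x, n = n, stringsAsFactors = FALSE))
    ci <- clopperPearson(x, n)
    data.frame(metric = m, estimate = 100 * x / n, lower = 100 * ci[1L],
      upper = 100 * ci[2L], x = x, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classification metrics at a probability threshold
#'
#' Dichotomizes `probs >= threshold` against the outcomes and reports the
#' confusion matrix and [confusionMetrics()].
#'
#' @inheritParams cStatistic
#' @param threshold probability (or linear-predictor) cutoff; predictions
#'   at or above it are called positive.
#' @return list `(confusion, metrics)` with `confusion` named
#'   `(TP, FN, FP, TN)`.
#' @export
classificationMetrics <- function(probs, outcomes, threshold) {
  y <- as.numeric(outcomes)
  pred <- as.numeric(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  fp <- sum(pred == 1 & y == 0); tn <- sum(pred == 0 & y == 0)
  list(confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
       metrics = confusionMetrics(tp, fn, fp, tn))
}

#' Fit and internally validate a risk model on a cohort
#'
#' Fits the logistic model on the given variable set, then produces the
#' full validation report: apparent/optimism-corrected C-statistic
#' (bootstrap, [bootstrapOptimism()]), Hosmer-Lemeshow fit, the ROC
#' curve, the Youden-optimal threshold and the confusion-matrix metrics
#' at that threshold with exact CIs.
#'
#' @inheritParams bootstrapOptimism
#' @param groups Hosmer-Lemeshow risk groups (default 10).
#' @return an [EvaluationReport-class].
#' @export
evaluateModel <- function(cohort, variables, B = 1000L,
                          sampleSize = nrow(cohort), seed = 20220607,
                          groups = 10L, outcome = "outcome") {
  dat <- .cohortMatrix(cohort, variables, outcome)
  fit <- .fitLogistic(dat$X, dat$y)
  probs <- fit$fitted
  boot <- bootstrapOptimism(cohort, variables, B = B,
    sampleSize = sampleSize, seed = seed, outcome = outcome)
  hl <- hosmerLemeshow(probs, dat$y, groups = groups)
  roc <- rocCurve(probs, dat$y)
  thr <- optimalThreshold(roc)
  cm <- classificationMetrics(probs, dat$y, thr)
  new("EvaluationReport", cApparent = boot$c_apparent,
      optimism = boot$optimism, cCorrected = boot$c_corrected,
      hl = hl[c("chi2", "df", "p")], roc = roc, threshold = thr,
      confusion = cm$confusion, metrics = cm$metrics,
      B = as.numeric(B), sampleSize = as.numeric(sampleSize),
      seed = as.numeric(seed))
}

#' Serialize an EvaluationReport as JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path JSON file path.
#' @param rocCsv optional CSV path for the ROC points.
#' @export
writeEvaluationReport <- function(report, path, rocCsv = NULL) {
  jsonlite::write_json(list(
    c_apparent = report@cApparent, optimism = report@optimism,
    c_corrected = report@cCorrected, hl = report@hl,
    threshold = report@threshold, confusion = as.list(report@confusion),
    metrics = report@metrics, B = report@B,
    sample_size = report@sampleSize, seed = report@seed),
    path, digits = NA, auto_unbox = TRUE, na = "null")
  if (!is.null(rocCsv))
    utils::write.csv(report@roc, rocCsv, row.names = FALSE)
  invisible(path)
}
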