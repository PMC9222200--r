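# Logistic model development: univariate screening, VIF pruning and
# backward selection, mirroring a prognostic-model building protocol
# (retain at p < 0.20, prune VIF > 4, backward-eliminate at 0.20).

# Maximum-likelihood logistic fit on a design without intercept column;
# returns coefficients (incl. intercept), Wald SEs and separation flag.
.fitLogistic <- function(X, y) {
  X <- as.matrix(X)
  Xd <- cbind("(Intercept)" = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  p <- ncol(Xd)
  beta <- fit$coefficients
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  covm <- matrix(NA_real_, p, p)
  Rm <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  covm[piv, piv] <- tryCatch(chol2inv(Rm), error = function(e)
    matrix(NA_real_, fit$rank, fit$rank))
  se <- sqrt(diag(covm))
  mu <- fit$fitted.values
  sep <- !fit$converged || any(abs(beta[-1L]) > 15, na.rm = TRUE) ||
    all(mu > 1 - 1e-8 | mu < 1e-8)
  list(beta = beta, se = se, fitted = mu, separation = sep,
       converged = fit$converged, cov = covm)
}

# Firth-penalized logistic (adjusted-score IRLS); fallback under separation
.firthLogistic <- function(X, y, maxit = 200L, tol = 1e-9) {
  Xd <- cbind("(Intercept)" = 1, as.matrix(X))
  p <- ncol(Xd)
  beta <- numeric(p)
  Fm <- diag(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    Fm <- crossprod(Xd, Xd * w)
    Fi <- tryCatch(solve(Fm), error = function(e) NULL)
    if (is.null(Fi)) break
    h <- w * rowSums((Xd %*% Fi) * Xd)
    U <- crossprod(Xd, (y - mu) + h * (0.5 - mu))
    delta <- drop(Fi %*% U)
    delta <- pmin(pmax(delta, -5), 5)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  covm <- tryCatch(solve(Fm), error = function(e) matrix(NA_real_, p, p))
  list(beta = stats::setNames(beta, colnames(Xd)), se = sqrt(diag(covm)),
       fitted = stats::plogis(drop(Xd %*% beta)), separation = TRUE,
       converged = TRUE, cov = covm)
}

.cohortMatrix <- function(cohort, variables, outcome = "outcome") {
  miss <- setdiff(c(variables, outcome), names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(cohort[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  y <- cohort[[outcome]]
  cc <- stats::complete.cases(X) & !is.na(y)
  if (any(!cc))
    message(sum(!cc), " rows dropped (complete-case analysis)")
  list(X = X[cc, , drop = FALSE], y = as.numeric(y[cc]))
}

#' Univariate (unadjusted) logistic screening
#'
#' Fits one single-predictor logistic model per candidate variable and
#' retains those with Wald p below `alpha`. Zero-variance predictors are
#' excluded with a warning; fits showing separation fall back to a
#' Firth-penalized fit and are flagged.
#'
#' @param cohort data.frame with the candidate columns and a 0/1 outcome.
#' @param variables candidate column names (default: all numeric columns
#'   other than the outcome and identifiers).
#' @param alpha retention level (default 0.20).
#' @param outcome outcome column name.
#' @return list with `retained` (names) and `table` (per-variable beta,
#'   se, OR with Wald 95% CI, Wald chi-square statistic, p, flags).
#' @export
univariateScreen <- function(cohort, variables = NULL, alpha = 0.20,
                             outcome = "outcome") {
  if (is.null(variables)) {
    variables <- setdiff(names(cohort)[vapply(cohort, is.numeric,
                                              logical(1))],
                         c(outcome, "patient_id", "video_id"))
  }
  dat <- .cohortMatrix(cohort, variables, outcome)
  if (length(unique(dat$y)) < 2L) stop("both outcome classes required")
  rows <- lapply(variables, function(v) {
    x <- dat$X[, v]
    if (stats::var(x) == 0) {
      warning("excluding zero-variance predictor: ", v)
      return(data.frame(variable = v, beta = NA_real_, se = NA_real_,
        or = NA_real_, or_low = NA_real_, or_high = NA_real_,
        wald = NA_real_, p = NA_real_, flagged = FALSE, excluded = TRUE,
        stringsAsFactors = FALSE))
    }
    f <- .fitLogistic(matrix(x, dimnames = list(NULL, v)), dat$y)
    if (f$separation) f <- .firthLogistic(matrix(x, dimnames = list(NULL, v)),
                                          dat$y)
    b <- f$beta[2L]; s <- f$se[2L]
    w <- (b / s)^2
    data.frame(variable = v, beta = b, se = s, or = exp(b),
      or_low = exp(b - 1.96 * s), or_high = exp(b + 1.96 * s),
      wald = w, p = stats::pchisq(w, 1L, lower.tail = FALSE),
      flagged = f$separation, excluded = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  retained <- tab$variable[!tab$excluded & !is.na(tab$p) & tab$p < alpha]
  list(retained = retained, table = tab)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from the linear regression
#' of predictor `j` on the remaining predictors. Exact collinearity gives
#' `Inf`.
#'
#' @param cohort data.frame holding the predictor columns.
#' @param variables predictor names (>= 2).
#' @return named numeric vector of VIFs.
#' @export
computeVIF <- function(cohort, variables) {
  stopifnot(length(variables) >= 2L)
  X <- as.matrix(cohort[, variables, drop = FALSE])
  vapply(seq_along(variables), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, variables)
}

#' Prune multicollinear variables by VIF
#'
#' While any VIF exceeds `cutoff`, drops the variable with the highest
#' VIF; ties are broken by dropping the name that comes later in the
#' supplied (registry) order. Deterministic.
#'
#' @param cohort data.frame holding the predictor columns.
#' @param variables candidate names in registry order.
#' @param cutoff VIF threshold (default 4.0).
#' @return list with `retained` (in original order) and `trace`
#'   data.frame of drops.
#' @export
vifPrune <- function(cohort, variables, cutoff = 4.0) {
  keep <- variables
  trace <- data.frame(step = integer(), dropped = character(),
                      vif = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  while (length(keep) >= 2L) {
    v <- computeVIF(cohort, keep)
    if (all(v <= cutoff)) break
    worst <- max(v)
    # ties: drop the later name in registry order
    cand <- names(v)[v >= worst - 1e-12]
    drop <- cand[length(cand)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = drop,
      vif = unname(v[drop]), stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop)
  }
  list(retained = keep, trace = trace)
}

#' Backward elimination at a stay-level
#'
#' Repeatedly refits the multivariable logistic model and removes the
#' single variable with the largest Wald p at or above `alphaStay`, until
#' every remaining variable meets the stay-level. An empty final model is
#' allowed; the trace records every step.
#'
#' @param cohort data.frame with predictors and 0/1 outcome.
#' @param variables starting variable set.
#' @param alphaStay significance level to remain (default 0.20).
#' @param outcome outcome column name.
#' @return a [ModelSpec-class] for the final model (fitted intercept
#'   included), with the elimination trace in `selectionTrace`.
#' @export
backwardSelect <- function(cohort, variables, alphaStay = 0.20,
                           outcome = "outcome") {
  dat <- .cohortMatrix(cohort, variables, outcome)
  keep <- variables
  trace <- data.frame(step = integer(), action = character(),
    variable = character(), p = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(keep)) {
      f <- .fitLogistic(matrix(numeric(0), nrow = length(dat$y), ncol = 0),
                        dat$y)
      break
    }
    f <- .fitLogistic(dat$X[, keep, drop = FALSE], dat$y)
    pv <- stats::pchisq((f$beta[-1L] / f$se[-1L])^2, 1L, lower.tail = FALSE)
    if (all(pv < alphaStay, na.rm = TRUE) && !anyNA(pv)) break
    worst <- which.max(ifelse(is.na(pv), Inf, pv))
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, action = "drop",
      variable = keep[worst], p = pv[worst], stringsAsFactors = FALSE))
    keep <- keep[-worst]
  }
  beta <- if (length(keep)) stats::setNames(f$beta[-1L], keep) else numeric(0)
  se <- if (length(keep)) stats::setNames(f$se[-1L], keep) else numeric(0)
  new("ModelSpec", variables = keep, beta = unname(beta),
      se = unname(se), intercept = unname(f$beta[1L]),
      selectionTrace = trace)
}

#' Full model-development pipeline
#'
#' Univariate screening (retain p < `alphaScreen`), VIF pruning
#' (`vifCutoff`), then backward selection (`alphaStay`), returning the
#' final [ModelSpec-class] whose `selectionTrace` records all three
#' stages.
#'
#' @inheritParams backwardSelect
#' @param alphaScreen univariate retention level (default 0.20).
#' @param vifCutoff collinearity threshold (default 4.0).
#' @export
fitRiskModel <- function(cohort, variables = NULL, alphaScreen = 0.20,
                         vifCutoff = 4.0, alphaStay = 0.20,
                         outcome = "outcome") {
  scr <- univariateScreen(cohort, variables, alpha = alphaScreen,
                          outcome = outcome)
  kept <- scr$retained
  tr <- data.frame(step = 0L, action = "screen",
    variable = paste(kept, collapse = ","), p = NA_real_,
    stringsAsFactors = FALSE)
  if (length(kept) >= 2L) {
    vp <- vifPrune(cohort, kept, cutoff = vifCutoff)
    if (nrow(vp$trace))
      tr <- rbind(tr, data.frame(step = vp$trace$step, action = "vif-drop",
        variable = vp$trace$dropped, p = NA_real_, stringsAsFactors = FALSE))
    kept <- vp$retained
  }
  if (!length(kept)) {
    return(new("ModelSpec", variables = character(0), beta = numeric(0),
      se = numeric(0), intercept = NA_real_, selectionTrace = tr))
  }
  spec <- backwardSelect(cohort, kept, alphaStay = alphaStay,
                         outcome = outcome)
  spec@selectionTrace <- rbind(tr, spec@selectionTrace)
  spec
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(beta)`, `CI = exp(beta +/- 1.96 se)`.
#'
#' @param spec a [ModelSpec-class].
#' @return data.frame `(variable, beta, or, lower, upper)`; CI columns are
#'   `NA` where the SE is unknown.
#' @export
oddsRatios <- function(spec) {
  data.frame(variable = spec@variables, beta = spec@beta,
    or = exp(spec@beta),
    lower = exp(spec@beta - 1.96 * spec@se),
    upper = exp(spec@beta + 1.96 * spec@se),
    stringsAsFactors = FALSE)
}

#' Score feature vectors with a risk model
#'
#' Linear predictor `lp = intercept + sum(beta * x)`; when the model has
#' no intercept (`NA`), `lp` omits it and the probability is `NA` --
#' ranking by `lp` is intercept-invariant either way.
#'
#' @param features data.frame (or named vector) holding every model
#'   variable.
#' @param spec a [ModelSpec-class].
#' @return data.frame with `lp` and `prob` per row.
#' @export
predictRisk <- function(features, spec) {
  if (is.numeric(features) && !is.matrix(features))
    features <- as.data.frame(as.list(features))
  miss <- setdiff(spec@variables, names(features))
  if (length(miss))
    stop("missing model variable(s) in features: ",
         paste(miss, collapse = ", "))
  X <- as.matrix(features[, spec@variables, drop = FALSE])
  lp <- drop(X %*% spec@beta)
  if (!is.na(spec@intercept)) lp <- lp + spec@intercept
  data.frame(lp = lp,
             prob = if (is.na(spec@intercept)) NA_real_
                    else stats::plogis(lp))
}

#' Construct a ModelSpec directly
#'
#' @param variables predictor names.
#' @param beta log-odds coefficients per unit.
#' @param se Wald standard errors (NA when unknown).
#' @param intercept log-odds intercept (`NA` if unavailable).
#' @return a [ModelSpec-class].
#' @export
ModelSpec <- function(variables, beta, se = rep(NA_real_, length(beta)),
                      intercept = NA_real_) {
  new("ModelSpec", variables = as.character(variables),
      beta = as.numeric(beta), se = as.numeric(se),
      intercept = as.numeric(intercept),
      selectionTrace = data.frame())
}

#' Serialize / restore a ModelSpec as JSON
#'
#' @param spec a [ModelSpec-class].
#' @param path JSON file path.
#' @export
writeModelSpec <- function(spec, path) {
  jsonlite::write_json(list(variables = spec@variables, beta = spec@beta,
    se = spec@se, intercept = spec@intercept), path,
    digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeModelSpec
#' @export
readModelSpec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  itc <- if (is.null(j$intercept) || is.na(j$intercept)) NA_real_
         else as.numeric(j$intercept)
  ModelSpec(j$variables, as.numeric(j$beta), as.numeric(j$se),
            intercept = itc)
}

#' The published cerebral-palsy risk model coefficients
#'
#' Log-odds coefficients of the published logistic models relating the
#' kinematic features to cerebral palsy at 18--24 months in very preterm
#' infants: mean absolute vertical velocity (`V_my`, px/s) and the
#' median, standard deviation and minimum of the quantity of motion
#' (`Q_med`, `Q_sd`, `Q_min`, percentage points). No intercept was
#' published, so the packaged models support ranking by linear predictor
#' only; supply an intercept (e.g. recalibrated on local data) to obtain
#' absolute risks. Standard errors are back-calculated from the published
#' Wald test statistics (`se = |beta| / sqrt(W)`).
#'
#' Note: the published multivariable `Q_sd` odds-ratio entry (2.12)
#' duplicates the `V_my` row and is inconsistent with its own coefficient
#' (`exp(1.13) = 3.10`); the coefficient is taken as authoritative here.
#'
#' @param type `"multivariable"` (default) or `"univariate"` (one row per
#'   single-predictor model, packaged for reference).
#' @return a [ModelSpec-class] with `intercept = NA`.
#' @examples
#' oddsRatios(publishedModel())
#' @export
publishedModel <- function(type = c("multivariable", "univariate")) {
  type <- match.arg(type)
  path <- system.file("extdata", "published_cp_model.json",
                      package = "babymotion", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- j[[type]]
  ModelSpec(m$variables, as.numeric(m$beta), as.numeric(m$se),
            intercept = NA_real_)
}
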