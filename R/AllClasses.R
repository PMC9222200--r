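#' @import methods
NULL

#' FrameSequence: decoded color video frames
#'
#' Ordered color frames plus the frame rate, the raw input of the motion
#' pipeline. Frames are numeric `H x W x 3` arrays with values in `[0, 1]`
#' (8-bit sources land on the `k/255` grid). Row index increases downward
#' (+y), column index rightward (+x).
#'
#' @slot frames list of `H x W x 3` numeric arrays, all the same size.
#' @slot fps frames per second, `> 0`.
#' @slot sourceId free-text identifier of the source video.
#'
#' @seealso [loadFrames()], [preprocess()], [screenQuality()]
#' @export
setClass("FrameSequence",
  representation(frames = "list", fps = "numeric", sourceId = "character"))

setValidity("FrameSequence", function(object) {
  if (length(object@frames) < 2L)
    return("a FrameSequence needs at least 2 frames")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  d <- dim(object@frames[[1L]])
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    return("frames must be H x W x 3 arrays")
  for (f in object@frames) {
    if (!identical(dim(f), d)) return("all frames must share identical H x W")
  }
  TRUE
})

#' QualityReport: automated video screening result
#'
#' @slot passed `TRUE` iff every individual check passed.
#' @slot checks data.frame with columns `check`, `value`, `threshold`, `pass`.
#' @export
setClass("QualityReport",
  representation(passed = "logical", checks = "data.frame"))

setValidity("QualityReport", function(object) {
  need <- c("check", "value", "threshold", "pass")
  if (!all(need %in% names(object@checks)))
    return("checks must have columns check, value, threshold, pass")
  if (!identical(object@passed, all(object@checks$pass)))
    return("passed must equal all(checks$pass)")
  TRUE
})

#' SkinModel: Gaussian chrominance skin-color model
#'
#' A single 2D Gaussian over the chroma plane (Cb, Cr of BT.601 YCbCr, on
#' the 0--255 scale) with a Mahalanobis-distance acceptance threshold.
#' Discarding luma makes classification robust to moderate brightness
#' changes when the training pixels span a range of exposures.
#'
#' @slot colorSpace chroma plane label, `"CbCr"`.
#' @slot center mean chroma 2-vector.
#' @slot covariance symmetric positive-definite 2 x 2 chroma covariance.
#' @slot threshold Mahalanobis distance cutoff (> 0); pixels with distance
#'   `<= threshold` are classified skin.
#' @slot nTrain number of training pixels (>= 100).
#' @seealso [fitSkinModel()], [segmentSkin()], [defaultSkinModel()]
#' @export
setClass("SkinModel",
  representation(colorSpace = "character", center = "numeric",
    covariance = "matrix", threshold = "numeric", nTrain = "integer"))

setValidity("SkinModel", function(object) {
  if (length(object@center) != 2L) return("center must be a 2-vector")
  S <- object@covariance
  if (!identical(dim(S), c(2L, 2L))) return("covariance must be 2 x 2")
  if (max(abs(S - t(S))) > 1e-8) return("covariance must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return("covariance must be positive-definite")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    return("threshold must be a single positive number")
  if (object@nTrain < 100L) return("nTrain must be >= 100")
  TRUE
})

#' SkinMask: per-frame skin classification
#'
#' @slot masks list of logical `H x W` matrices, one per frame.
#' @slot skinFraction numeric vector, exact fraction of TRUE pixels per frame.
#' @export
setClass("SkinMask",
  representation(masks = "list", skinFraction = "numeric"))

setValidity("SkinMask", function(object) {
  if (length(object@masks) != length(object@skinFraction))
    return("one skinFraction per mask required")
  for (i in seq_along(object@masks)) {
    m <- object@masks[[i]]
    if (!is.logical(m) || is.null(dim(m)))
      return("masks must be logical matrices")
    if (abs(object@skinFraction[i] - mean(m)) > 1e-12)
      return("skinFraction must equal the exact fraction of TRUE pixels")
  }
  TRUE
})

#' FlowField: dense inter-frame displacement
#'
#' One displacement raster per consecutive frame pair, in pixels/frame.
#' `flows[[t]][, , 1]` is dx (+x rightward), `[, , 2]` is dy (+y downward).
#' Pixels within `margin` of the border are estimator-invalid and excluded
#' from all downstream statistics.
#'
#' @slot flows list of `H x W x 2` numeric arrays, length `n_frames - 1`.
#' @slot margin integer border width (pixels) to exclude from statistics.
#' @slot method label of the estimator used.
#' @seealso [estimateFlow()], [pixelVelocities()]
#' @export
setClass("FlowField",
  representation(flows = "list", margin = "integer", method = "character"))

setValidity("FlowField", function(object) {
  if (length(object@flows) < 1L) return("need at least one flow raster")
  d <- dim(object@flows[[1L]])
  if (length(d) != 3L || d[3L] != 2L) return("flows must be H x W x 2 arrays")
  for (f in object@flows)
    if (!identical(dim(f), d)) return("flow rasters must share dimensions")
  if (object@margin < 0L) return("margin must be >= 0")
  TRUE
})

#' VelocityField: skin-restricted pixel velocities
#'
#' Velocities in pixels/second on the skin support (`vx = dx * fps`,
#' `vy = dy * fps`; +y is downward). Frame pair `t` uses the skin mask of
#' the earlier frame `t`. Entries off the support are `NA`. Pairs whose
#' support is empty are flagged invalid rather than silently zeroed.
#'
#' @slot vx,vy lists of `H x W` numeric matrices (px/s), `NA` off support.
#' @slot support list of logical matrices: skin mask AND valid interior.
#' @slot fps frames per second used for the conversion.
#' @slot valid logical per frame pair; `FALSE` when the support is empty.
#' @export
setClass("VelocityField",
  representation(vx = "list", vy = "list", support = "list",
    fps = "numeric", valid = "logical"))

setValidity("VelocityField", function(object) {
  n <- length(object@vx)
  if (length(object@vy) != n || length(object@support) != n ||
      length(object@valid) != n)
    return("vx, vy, support, valid must have equal length")
  if (object@fps <= 0) return("fps must be positive")
  TRUE
})

#' ModelSpec: a fitted or published logistic risk model
#'
#' Variable names with log-odds coefficients, their standard errors, an
#' optional intercept, and the variable-selection trace. When `intercept`
#' is `NA` only the linear predictor (and hence risk ranking) is defined,
#' not absolute probability.
#'
#' @slot variables ordered predictor names.
#' @slot beta log-odds coefficients per unit of each variable.
#' @slot se Wald standard errors (NA when unknown).
#' @slot intercept log-odds intercept, `NA` when not available.
#' @slot selectionTrace data.frame recording screening/VIF/backward steps.
#' @seealso [fitRiskModel()], [oddsRatios()], [predictRisk()],
#'   [publishedModel()]
#' @export
setClass("ModelSpec",
  representation(variables = "character", beta = "numeric", se = "numeric",
    intercept = "numeric", selectionTrace = "data.frame"))

setValidity("ModelSpec", function(object) {
  k <- length(object@variables)
  if (length(object@beta) != k || length(object@se) != k)
    return("beta and se must match variables in length")
  if (length(object@intercept) != 1L)
    return("intercept must be a single number (possibly NA)")
  TRUE
})

#' EvaluationReport: internal validation and classification summary
#'
#' @slot cApparent apparent C-statistic of the fitted model.
#' @slot optimism bootstrap (Harrell) optimism estimate.
#' @slot cCorrected `cApparent - optimism`.
#' @slot hl list with `chi2`, `df`, `p` of the Hosmer-Lemeshow test.
#' @slot roc data.frame of `(threshold, sens, spec)` points.
#' @slot threshold probability cutoff maximizing Youden's J.
#' @slot confusion named numeric `(TP, FN, FP, TN)` at the threshold.
#' @slot metrics data.frame of sens/spec/PPV/NPV/accuracy with exact
#'   95% Clopper-Pearson intervals (percent scale).
#' @slot B,sampleSize,seed bootstrap settings used.
#' @export
setClass("EvaluationReport",
  representation(cApparent = "numeric", optimism = "numeric",
    cCorrected = "numeric", hl = "list", roc = "data.frame",
    threshold = "numeric", confusion = "numeric", metrics = "data.frame",
    B = "numeric", sampleSize = "numeric", seed = "numeric"))

setValidity("EvaluationReport", function(object) {
  if (length(object@confusion) == 4L) {
    if (any(object@confusion < 0)) return("confusion cells must be >= 0")
    if (!all(c("TP", "FN", "FP", "TN") %in% names(object@confusion)))
      return("confusion must be named TP, FN, FP, TN")
  }
  TRUE
})
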