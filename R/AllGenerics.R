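#' @rdname FrameSequence-class
#' @param object,x a babymotion S4 object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname FrameSequence-class
#' @export
setGeneric("nframes", function(x) standardGeneric("nframes"))

#' @rdname FrameSequence-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname FrameSequence-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname SkinMask-class
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname SkinMask-class
#' @export
setGeneric("skinFraction", function(x) standardGeneric("skinFraction"))

#' @rdname FlowField-class
#' @export
setGeneric("flows", function(x) standardGeneric("flows"))

#' @rdname FlowField-class
#' @export
setGeneric("flowMargin", function(x) standardGeneric("flowMargin"))

#' @rdname ModelSpec-class
#' @export
setGeneric("variables", function(x) standardGeneric("variables"))

# --- accessors -------------------------------------------------------------

#' @rdname FrameSequence-class
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @rdname FrameSequence-class
#' @export
setMethod("fps", "FrameSequence", function(x) x@fps)

#' @rdname FrameSequence-class
#' @export
setMethod("nframes", "FrameSequence", function(x) length(x@frames))

#' @rdname FrameSequence-class
#' @export
setMethod("duration", "FrameSequence",
  function(x) (length(x@frames) - 1L) / x@fps)

#' @rdname FrameSequence-class
#' @export
setMethod("sourceId", "FrameSequence", function(x) x@sourceId)

#' @rdname SkinMask-class
#' @export
setMethod("masks", "SkinMask", function(x) x@masks)

#' @rdname SkinMask-class
#' @export
setMethod("skinFraction", "SkinMask", function(x) x@skinFraction)

#' @rdname FlowField-class
#' @export
setMethod("flows", "FlowField", function(x) x@flows)

#' @rdname FlowField-class
#' @export
setMethod("flowMargin", "FlowField", function(x) x@margin)

#' @rdname ModelSpec-class
#' @export
setMethod("variables", "ModelSpec", function(x) x@variables)

#' @rdname ModelSpec-class
#' @param ... unused.
#' @export
setMethod("coef", "ModelSpec", function(object, ...) {
  c("(Intercept)" = object@intercept,
    stats::setNames(object@beta, object@variables))
})

# --- show ------------------------------------------------------------------

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FrameSequence '%s': %d frames of %dx%d @ %.3g fps (%.2f s)\n",
    object@sourceId, length(object@frames), d[1L], d[2L], object@fps,
    duration(object)))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: %s\n",
    if (object@passed) "PASSED" else "FAILED"))
  print(object@checks, row.names = FALSE)
})

setMethod("show", "SkinModel", function(object) {
  cat(sprintf(
    "SkinModel (%s): center (%.1f, %.1f), threshold %.2f, n_train %d\n",
    object@colorSpace, object@center[1L], object@center[2L],
    object@threshold, object@nTrain))
})

setMethod("show", "SkinMask", function(object) {
  cat(sprintf("SkinMask: %d frames, mean skin fraction %.3f\n",
    length(object@masks), mean(object@skinFraction)))
})

setMethod("show", "FlowField", function(object) {
  d <- dim(object@flows[[1L]])
  cat(sprintf("FlowField (%s): %d frame pairs of %dx%d, margin %d px\n",
    object@method, length(object@flows), d[1L], d[2L], object@margin))
})

setMethod("show", "VelocityField", function(object) {
  cat(sprintf("VelocityField: %d frame pairs @ %.3g fps, %d valid\n",
    length(object@vx), object@fps, sum(object@valid)))
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", paste(object@variables, collapse = " + "), "\n")
  print(oddsRatios(object), row.names = FALSE, digits = 4)
  if (is.na(object@intercept))
    cat("(no intercept: linear predictor / ranking only)\n")
  else cat(sprintf("intercept: %.4f\n", object@intercept))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport: C apparent %.3f, optimism %.3f, corrected %.3f\n",
    object@cApparent, object@optimism, object@cCorrected))
  cat(sprintf("Hosmer-Lemeshow: chi2 %.2f, df %d, p %.3f\n",
    object@hl$chi2, object@hl$df, object@hl$p))
  cat(sprintf("Threshold %.4f; confusion TP %.0f FN %.0f FP %.0f TN %.0f\n",
    object@threshold, object@confusion["TP"], object@confusion["FN"],
    object@confusion["FP"], object@confusion["TN"]))
  print(object@metrics, row.names = FALSE, digits = 4)
})
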