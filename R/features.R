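#' Feature registry
#'
#' The named kinematic summary features produced by [summarizeVideo()],
#' in canonical order. Q features are on the percentage scale 0--100,
#' velocities in pixels/second, accelerations in pixels/second^2, and
#' centroid SDs in pixels.
#'
#' @return character vector of feature names.
#' @export
featureRegistry <- function() {
  c("Q_med", "Q_min", "Q_max", "Q_mean", "Q_sd",
    "V_my", "V_mx", "V_my_signed", "V_mx_signed",
    "A_my", "A_mx", "C_sd_x", "C_sd_y")
}

#' Per-frame quantity of motion
#'
#' The percentage of skin pixels whose inter-frame displacement exceeds
#' the motion threshold, among all skin pixels supported in that frame:
#' `q(t) = 100 * |{skin px : |flow| > thr}| / |{skin px}|`.
#'
#' @param vel a [VelocityField-class].
#' @param motionThreshold "moving" cutoff in pixels/frame, `> 0`
#'   (default 0.5, above typical estimator noise on static scenes).
#' @return numeric q series in `[0, 100]`, `NA` for invalid frame pairs.
#' @export
quantityOfMotion <- function(vel, motionThreshold = 0.5) {
  stopifnot(motionThreshold > 0)
  if (!any(vel@valid)) stop("all frame pairs invalid: no skin support")
  n <- length(vel@vx)
  q <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (!vel@valid[t]) next
    s <- vel@support[[t]]
    disp <- sqrt(vel@vx[[t]][s]^2 + vel@vy[[t]][s]^2) / vel@fps  # px/frame
    q[t] <- 100 * sum(disp > motionThreshold) / sum(s)
  }
  q
}

#' Per-frame motion series
#'
#' Assembles the per-frame-pair indices the summary features are built
#' from: quantity of motion, mean signed and mean absolute skin-pixel
#' velocities (px/s), their first differences scaled by fps (px/s^2), and
#' the centroid of the moving skin pixels.
#'
#' @inheritParams quantityOfMotion
#' @return data.frame (class `MotionSeries`) with one row per frame pair:
#'   `q`, `vx_mean`, `vy_mean`, `vabs_x`, `vabs_y`, `accel_x`, `accel_y`,
#'   `cx`, `cy`, `valid`. Acceleration is `NA` on the last row; centroids
#'   are `NA` when no pixel moves.
#' @export
motionSeries <- function(vel, motionThreshold = 0.5) {
  q <- quantityOfMotion(vel, motionThreshold)
  n <- length(q)
  out <- data.frame(q = q, vx_mean = NA_real_, vy_mean = NA_real_,
                    vabs_x = NA_real_, vabs_y = NA_real_,
                    accel_x = NA_real_, accel_y = NA_real_,
                    cx = NA_real_, cy = NA_real_, valid = vel@valid)
  for (t in seq_len(n)) {
    if (!vel@valid[t]) next
    s <- vel@support[[t]]
    vx <- vel@vx[[t]][s]; vy <- vel@vy[[t]][s]
    out$vx_mean[t] <- mean(vx)
    out$vy_mean[t] <- mean(vy)
    out$vabs_x[t] <- mean(abs(vx))
    out$vabs_y[t] <- mean(abs(vy))
    disp <- sqrt(vx^2 + vy^2) / vel@fps
    moving <- disp > motionThreshold
    if (any(moving)) {
      rows <- row(s)[s][moving]
      cols <- col(s)[s][moving]
      out$cy[t] <- mean(rows)
      out$cx[t] <- mean(cols)
    }
  }
  if (n >= 2L) {
    out$accel_x[-n] <- diff(out$vx_mean) * vel@fps
    out$accel_y[-n] <- diff(out$vy_mean) * vel@fps
  }
  attr(out, "fps") <- vel@fps
  attr(out, "motionThreshold") <- motionThreshold
  class(out) <- c("MotionSeries", "data.frame")
  out
}

#' Summarize a motion series into a feature vector
#'
#' Order statistics of q are over valid frames; `Q_sd` is the sample SD
#' (n-1 denominator). `V_my`/`V_mx` are means of the per-frame mean
#' ABSOLUTE velocities: under oscillatory movement signed means cancel to
#' about zero for any symmetric motion, so the absolute value is the
#' interpretation under which a "mean velocity" feature carries magnitude
#' information; the signed variants are also emitted (`V_my_signed`,
#' `V_mx_signed`) for sensitivity analyses. `A_my`/`A_mx` are means of
#' absolute frame-to-frame acceleration; `C_sd_x`/`C_sd_y` are sample SDs
#' of the moving-pixel centroid.
#'
#' @param series a `MotionSeries` from [motionSeries()].
#' @param videoId,patientId identifiers carried into the output row.
#' @return one-row data.frame: [featureRegistry()] columns plus
#'   `n_valid_frames`, `video_id`, `patient_id`.
#' @export
summarizeVideo <- function(series, videoId = "video1",
                           patientId = videoId) {
  v <- series$valid & !is.na(series$q)
  if (sum(v) < 2L) stop("need at least 2 valid frame pairs")
  q <- series$q[v]
  acx <- series$accel_x[v]; acy <- series$accel_y[v]
  out <- data.frame(
    Q_med = stats::median(q), Q_min = min(q), Q_max = max(q),
    Q_mean = mean(q), Q_sd = stats::sd(q),
    V_my = mean(series$vabs_y[v]), V_mx = mean(series$vabs_x[v]),
    V_my_signed = mean(series$vy_mean[v]),
    V_mx_signed = mean(series$vx_mean[v]),
    A_my = mean(abs(acy), na.rm = TRUE),
    A_mx = mean(abs(acx), na.rm = TRUE),
    C_sd_x = stats::sd(series$cx[v], na.rm = TRUE),
    C_sd_y = stats::sd(series$cy[v], na.rm = TRUE),
    n_valid_frames = sum(v),
    video_id = videoId, patient_id = patientId,
    stringsAsFactors = FALSE)
  out
}

#' Average feature vectors of one patient
#'
#' When a patient has several videos, the per-patient value of each
#' feature is the unweighted arithmetic mean over videos.
#'
#' @param vectors data.frame of feature rows sharing one `patient_id`.
#' @return a single averaged feature row (`video_id` lists the inputs).
#' @export
averagePerPatient <- function(vectors) {
  stopifnot(nrow(vectors) >= 1L)
  if (length(unique(vectors$patient_id)) != 1L)
    stop("mixed patient_ids: average one patient at a time")
  if (nrow(vectors) == 1L) return(vectors)
  num <- vapply(vectors, is.numeric, logical(1))
  out <- vectors[1L, , drop = FALSE]
  out[num] <- lapply(vectors[num], mean)
  out$video_id <- paste(vectors$video_id, collapse = "+")
  rownames(out) <- NULL
  out
}

#' Collapse a per-video feature table to one row per patient
#'
#' @param featureTable data.frame of [summarizeVideo()] rows.
#' @return data.frame with one averaged row per `patient_id`.
#' @export
patientFeatures <- function(featureTable) {
  parts <- split(featureTable, featureTable$patient_id)
  out <- do.call(rbind, lapply(parts, averagePerPatient))
  rownames(out) <- NULL
  out
}

#' Run the full vision pipeline on a frame sequence
#'
#' Skin segmentation, dense optical flow, velocities, motion series and
#' the per-video feature summary in one call.
#'
#' @param seq a [FrameSequence-class].
#' @param model a [SkinModel-class] (default [defaultSkinModel()]).
#' @param motionThreshold moving cutoff in px/frame (default 0.5).
#' @param videoId,patientId identifiers for the output row.
#' @param ... passed to [estimateFlow()].
#' @return one-row feature data.frame, see [summarizeVideo()].
#' @export
extractFeatures <- function(seq, model = defaultSkinModel(),
                            motionThreshold = 0.5, videoId = sourceId(seq),
                            patientId = videoId, ...) {
  mask <- segmentSkin(seq, model)
  flow <- estimateFlow(seq, ...)
  vel <- pixelVelocities(flow, mask, fps(seq))
  summarizeVideo(motionSeries(vel, motionThreshold),
                 videoId = videoId, patientId = patientId)
}
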