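#' Construct a FrameSequence
#'
#' @param frames list of `H x W x 3` numeric arrays with values in `[0, 1]`.
#' @param fps frames per second.
#' @param sourceId free-text identifier.
#' @return a [FrameSequence-class] object.
#' @export
FrameSequence <- function(frames, fps, sourceId = "unnamed") {
  new("FrameSequence", frames = frames, fps = as.numeric(fps),
      sourceId = as.character(sourceId))
}

#' Load a frame sequence from an image-sequence directory
#'
#' Reads a directory of equally sized PNG/JPEG/TIFF images in
#' lexicographic filename order. The frame rate comes from `fpsOverride`
#' or, failing that, from a plain-text sidecar file `fps.txt` in the
#' directory holding a single number. Video containers (MP4/AVI/MOV) are
#' not decoded by this package: extract frames first, e.g.
#' `ffmpeg -i in.mp4 dir/frame%05d.png`, and record the frame rate in the
#' sidecar.
#'
#' @param path directory containing at least two ordered image frames.
#' @param fpsOverride frames per second; overrides any sidecar value.
#' @return a [FrameSequence-class].
#' @examples
#' spec <- phantomSpec(duration = 0.5)
#' ph <- generatePhantomVideo(spec)
#' d <- tempfile(); writeFrames(ph$seq, d)
#' seq2 <- loadFrames(d, fpsOverride = fps(ph$seq))
#' @export
loadFrames <- function(path, fpsOverride = NULL) {
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (!dir.exists(path)) {
    stop("cannot decode video container '", path,
         "': no decoder available; extract frames to a directory of ",
         "images and pass that directory (see ?loadFrames)")
  }
  files <- list.files(path, pattern = "\\.(png|jpe?g|tiff?)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  if (length(files) < 2L)
    stop("need at least 2 image frames, found ", length(files))
  frames <- lapply(files, .readImageFrame)
  d <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop("inconsistent image sizes across frames")
  rate <- fpsOverride
  if (is.null(rate)) {
    sidecar <- file.path(path, "fps.txt")
    if (file.exists(sidecar))
      rate <- as.numeric(readLines(sidecar, n = 1L, warn = FALSE))
  }
  if (is.null(rate) || !is.finite(rate) || rate <= 0)
    stop("frame rate unknown: supply fpsOverride or an fps.txt sidecar")
  FrameSequence(frames, rate, sourceId = basename(path))
}

# one image file -> H x W x 3 array in [0,1]
.readImageFrame <- function(file) {
  img <- EBImage::readImage(file)
  a <- EBImage::imageData(img)  # x, y (, c) order
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  aperm(a, c(2L, 1L, 3L))
}

#' Write frames as numbered PNG images
#'
#' The inverse of [loadFrames()]: frames are written 8-bit, together with
#' an `fps.txt` sidecar, so a round trip reproduces an 8-bit-quantized
#' sequence exactly.
#'
#' @param seq a [FrameSequence-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return `dir`, invisibly.
#' @export
writeFrames <- function(seq, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nframes(seq)
  fmt <- paste0(prefix, "%0", max(5L, nchar(n)), "d.png")
  for (i in seq_len(n))
    png::writePNG(frames(seq)[[i]], file.path(dir, sprintf(fmt, i)))
  writeLines(format(fps(seq), digits = 17), file.path(dir, "fps.txt"))
  invisible(dir)
}

#' Spatially and temporally standardize a frame sequence
#'
#' All steps are opt-in; the identity call returns the input unchanged.
#' Order of operations: crop, then resize, then temporal resampling.
#' Temporal resampling only drops frames (no interpolation), so every
#' output frame is bit-identical to some input frame.
#'
#' @param seq a [FrameSequence-class].
#' @param crop optional `c(x, y, w, h)` rectangle (1-based, x = column,
#'   y = row) that must lie within the frame.
#' @param targetSize optional `c(H, W)` to resize to (bilinear).
#' @param targetFps optional target frame rate `<= fps(seq)`; frames are
#'   dropped so the retained frames are as evenly spaced as possible.
#' @return a [FrameSequence-class].
#' @export
preprocess <- function(seq, crop = NULL, targetSize = NULL,
                       targetFps = NULL) {
  fr <- frames(seq)
  d <- dim(fr[[1L]])
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4L)
    x <- crop[1L]; y <- crop[2L]; w <- crop[3L]; h <- crop[4L]
    if (x < 1 || y < 1 || w < 1 || h < 1 ||
        y + h - 1 > d[1L] || x + w - 1 > d[2L])
      stop("crop rectangle outside frame bounds")
    fr <- lapply(fr, function(f) f[y:(y + h - 1), x:(x + w - 1), , drop = FALSE])
  }
  if (!is.null(targetSize)) {
    stopifnot(length(targetSize) == 2L, all(targetSize >= 1))
    fr <- lapply(fr, function(f) {
      img <- EBImage::Image(aperm(f, c(2L, 1L, 3L)), colormode = "Color")
      out <- EBImage::resize(img, w = targetSize[2L], h = targetSize[1L])
      aperm(EBImage::imageData(out), c(2L, 1L, 3L))
    })
  }
  rate <- fps(seq)
  if (!is.null(targetFps)) {
    if (targetFps > rate) stop("targetFps must be <= fps")
    idx <- seq_along(fr) - 1L
    keep <- !duplicated(floor(idx * targetFps / rate))
    fr <- fr[keep]
    rate <- targetFps
  }
  FrameSequence(fr, rate, sourceId = sourceId(seq))
}

#' Default automated screening thresholds
#'
#' Automatable stand-ins for a human video-quality screen: a minimum
#' duration, a well-exposed mean luminance band, a cap on the fraction of
#' clipped (near-0 or near-255 luma) pixels, and a cap on a global
#' inter-frame jitter proxy (median mean absolute luma difference between
#' consecutive frames, which stays small for a static camera even when
#' the subject moves).
#'
#' @return named list: `min_duration` (s), `luminance_range` (0--255),
#'   `max_clip_fraction`, `max_jitter` (0--255).
#' @export
screeningDefaults <- function() {
  list(min_duration = 60, luminance_range = c(40, 220),
       max_clip_fraction = 0.10, max_jitter = 20)
}

#' Read a screening config file
#'
#' Reads the `screening` section (thresholds, see [screeningDefaults()])
#' from a YAML or JSON config file; missing entries keep their defaults.
#'
#' @param path config file (`.yml`/`.yaml` or `.json`).
#' @return a complete screening config list.
#' @export
readScreeningConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  sec <- if (!is.null(cfg$screening)) cfg$screening else cfg
  utils::modifyList(screeningDefaults(), sec)
}

#' Screen a frame sequence for basic quality
#'
#' Deterministic: the same sequence and config always yield the same
#' report. Always returns a report; nothing is thrown on failure.
#'
#' @param seq a [FrameSequence-class].
#' @param config list of thresholds, see [screeningDefaults()]; partial
#'   lists are completed with the defaults.
#' @return a [QualityReport-class].
#' @export
screenQuality <- function(seq, config = screeningDefaults()) {
  cfg <- utils::modifyList(screeningDefaults(), config)
  lum <- vapply(frames(seq), function(f) mean(.frameLuma(f)), numeric(1))
  clip <- vapply(frames(seq), function(f) {
    y <- .frameLuma(f); mean(y <= 2 | y >= 253)
  }, numeric(1))
  prev <- NULL
  jit <- numeric(nframes(seq) - 1L)
  for (i in seq_len(nframes(seq))) {
    y <- .frameLuma(frames(seq)[[i]])
    if (i > 1L) jit[i - 1L] <- mean(abs(y - prev))
    prev <- y
  }
  checks <- data.frame(
    check = c("duration_s", "mean_luminance", "clip_fraction", "jitter"),
    value = c(duration(seq), mean(lum), mean(clip), stats::median(jit)),
    threshold = c(sprintf(">= %g", cfg$min_duration),
                  sprintf("[%g, %g]", cfg$luminance_range[1L],
                          cfg$luminance_range[2L]),
                  sprintf("<= %g", cfg$max_clip_fraction),
                  sprintf("<= %g", cfg$max_jitter)),
    pass = c(duration(seq) >= cfg$min_duration,
             mean(lum) >= cfg$luminance_range[1L] &&
               mean(lum) <= cfg$luminance_range[2L],
             mean(clip) <= cfg$max_clip_fraction,
             stats::median(jit) <= cfg$max_jitter),
    stringsAsFactors = FALSE)
  new("QualityReport", passed = all(checks$pass), checks = checks)
}
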