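# Phantom videos: skin-colored textured ellipse "limbs" oscillating on a
# contrasting background, with analytic ground truth for moving-pixel
# fraction and vertical speed. Stands in for clinic videos, which are not
# distributable.

#' Describe one phantom limb
#'
#' @param center `c(x, y)` rest position in pixels.
#' @param axes `c(a, b)` ellipse semi-axes (x, y) in pixels.
#' @param amplitude oscillation amplitude in pixels.
#' @param frequency oscillation frequency in Hz.
#' @param phase phase offset in radians.
#' @param direction unit-ish direction of oscillation, default vertical.
#' @param color RGB in `[0,1]`; default drawn from [skinPalette()].
#' @return list describing the limb.
#' @export
phantomLimb <- function(center, axes, amplitude = 3, frequency = 1.2,
                        phase = 0, direction = c(0, 1), color = NULL) {
  list(center = center, axes = axes, amplitude = amplitude,
       frequency = frequency, phase = phase,
       direction = direction / sqrt(sum(direction^2)), color = color)
}

#' Phantom video specification
#'
#' Defaults emulate a clinic recording of a supine infant: four limbs of
#' skin-toned texture oscillating at fidgety-range amplitude and rate on
#' a contrasting (green) background, 64 x 64 px at 15 fps for 60 s, with
#' mild amplitude jitter (movement variability) and 8-bit sensor noise.
#'
#' @param width,height canvas size in pixels.
#' @param fps frames per second.
#' @param duration seconds; the sequence has `round(fps * duration) + 1`
#'   frames so its duration is exact.
#' @param background RGB background color.
#' @param limbs list of [phantomLimb()]s; `NULL` for the default four.
#' @param amplitude,frequency defaults applied to the default limbs.
#' @param amplitudeJitterSD per-frame SD of the amplitude jitter (px).
#' @param noiseSD per-pixel Gaussian noise SD (on the `[0,1]` scale).
#' @param seed RNG seed; same seed gives bit-identical videos.
#' @return a `PhantomSpec` list; limbs are checked to stay on canvas at
#'   motion extremes (spec error otherwise).
#' @export
phantomSpec <- function(width = 64L, height = 64L, fps = 15, duration = 60,
                        background = c(0.10, 0.45, 0.15), limbs = NULL,
                        amplitude = 3, frequency = 1.2,
                        amplitudeJitterSD = 1.0, noiseSD = 0.01,
                        seed = 1L) {
  if (is.null(limbs)) {
    pal <- skinPalette()
    limbs <- list(
      phantomLimb(c(width * 0.27, height * 0.30), c(7, 5), amplitude,
                  frequency, phase = 0, color = pal[1L, ]),
      phantomLimb(c(width * 0.73, height * 0.30), c(7, 5), amplitude,
                  frequency, phase = pi / 2, color = pal[2L, ]),
      phantomLimb(c(width * 0.27, height * 0.72), c(7, 5), amplitude,
                  frequency, phase = pi, color = pal[3L, ]),
      phantomLimb(c(width * 0.73, height * 0.72), c(7, 5), amplitude,
                  frequency, phase = 3 * pi / 2, color = pal[4L, ]))
  }
  for (i in seq_along(limbs)) {
    if (is.null(limbs[[i]]$color))
      limbs[[i]]$color <- skinPalette()[1L + (i - 1L) %% 4L, ]
  }
  nFrames <- round(fps * duration) + 1L
  if (nFrames < 2L) stop("fps * duration must give at least 2 frames")
  # reach at motion extremes, with jitter headroom
  for (l in limbs) {
    reach <- abs(l$amplitude) + 4 * amplitudeJitterSD
    lo <- l$center - abs(l$direction) * reach - l$axes
    hi <- l$center + abs(l$direction) * reach + l$axes
    if (lo[1L] < 1 || lo[2L] < 1 || hi[1L] > width || hi[2L] > height)
      stop("limb leaves the canvas at motion extremes")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
    fps = fps, duration = duration, nFrames = nFrames,
    background = background, limbs = limbs,
    amplitudeJitterSD = amplitudeJitterSD, noiseSD = noiseSD,
    seed = as.integer(seed)), class = "PhantomSpec")
}

# per-frame limb centers: nFrames x 2 (x, y) for one limb
.limbTrack <- function(limb, times, jitter) {
  a <- limb$amplitude + jitter
  s <- a * sin(2 * pi * limb$frequency * times + limb$phase)
  cbind(limb$center[1L] + limb$direction[1L] * s,
        limb$center[2L] + limb$direction[2L] * s)
}

#' Generate a phantom video with analytic ground truth
#'
#' Deterministic under the spec's seed. The ground-truth sidecar is
#' computed from the limb trajectories alone (never from the vision
#' pipeline): per frame pair, the fraction of skin area belonging to
#' limbs whose center displacement exceeds `motionThreshold`, and the
#' area-weighted mean absolute vertical speed in px/s.
#'
#' @param spec a [phantomSpec()].
#' @param motionThreshold px/frame cutoff used for the ground-truth
#'   moving fraction (default 0.5, matching [quantityOfMotion()]).
#' @return list with `seq` (a [FrameSequence-class]), `truth` (data.frame
#'   `pair`, `moving_fraction`, `mean_abs_vy`) and `tracks` (per-limb
#'   center positions).
#' @export
generatePhantomVideo <- function(spec, motionThreshold = 0.5) {
  stopifnot(inherits(spec, "PhantomSpec"))
  h <- spec$height; w <- spec$width; n <- spec$nFrames
  times <- (seq_len(n) - 1L) / spec$fps
  nl <- length(spec$limbs)
  .withSeed(spec$seed, {
    jit <- matrix(stats::rnorm(n * nl, 0, spec$amplitudeJitterSD), n, nl)
    tracks <- lapply(seq_len(nl), function(i)
      .limbTrack(spec$limbs[[i]], times, jit[, i]))
    X <- matrix(seq_len(w), h, w, byrow = TRUE)
    Y <- matrix(seq_len(h), h, w)
    fr <- vector("list", n)
    for (t in seq_len(n)) {
      frame <- array(rep(spec$background, each = h * w), c(h, w, 3L))
      for (i in seq_len(nl)) {
        l <- spec$limbs[[i]]
        cx <- tracks[[i]][t, 1L]; cy <- tracks[[i]][t, 2L]
        inside <- ((X - cx) / l$axes[1L])^2 + ((Y - cy) / l$axes[2L])^2 <= 1
        if (!any(inside)) next
        # rigid texture: moves with the limb so flow has gradients to track
        tex <- 1 + 0.12 * sin(0.8 * (X - cx)) * cos(1.1 * (Y - cy))
        for (ch in 1:3) {
          plane <- frame[, , ch]
          plane[inside] <- l$color[ch] * tex[inside]
          frame[, , ch] <- plane
        }
      }
      if (spec$noiseSD > 0)
        frame <- frame + array(stats::rnorm(h * w * 3L, 0, spec$noiseSD),
                               c(h, w, 3L))
      fr[[t]] <- .quantize8(frame)
    }
    areas <- vapply(spec$limbs, function(l) pi * l$axes[1L] * l$axes[2L],
                    numeric(1))
    mf <- vy <- numeric(n - 1L)
    for (t in seq_len(n - 1L)) {
      d <- vapply(seq_len(nl), function(i)
        sqrt(sum((tracks[[i]][t + 1L, ] - tracks[[i]][t, ])^2)), numeric(1))
      dy <- vapply(seq_len(nl), function(i)
        abs(tracks[[i]][t + 1L, 2L] - tracks[[i]][t, 2L]), numeric(1))
      mf[t] <- sum(areas[d > motionThreshold]) / sum(areas)
      vy[t] <- sum(areas * dy * spec$fps) / sum(areas)
    }
    list(seq = FrameSequence(fr, spec$fps,
           sourceId = sprintf("phantom-seed%d", spec$seed)),
         truth = data.frame(pair = seq_len(n - 1L), moving_fraction = mf,
                            mean_abs_vy = vy),
         tracks = tracks)
  })
}
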