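#' Fit a Gaussian chrominance skin model
#'
#' Training pixels are mapped to the (Cb, Cr) chroma plane; the model is
#' their mean and covariance with a Mahalanobis acceptance threshold set
#' at the requested quantile of the training pixels' own distances, so
#' `thresholdQuantile` of the training pixels fall inside by construction.
#'
#' @param trainingPixels `n x 3` matrix of skin RGB triples in `[0, 1]`,
#'   `n >= 100`.
#' @param thresholdQuantile fraction of training pixels inside the
#'   threshold (default 0.95).
#' @return a [SkinModel-class].
#' @details A degenerate covariance (e.g. all-identical training pixels)
#'   is regularized with a small diagonal (0.25 squared-chroma units) and
#'   a warning; the model then accepts that color plus a small ball.
#' @export
fitSkinModel <- function(trainingPixels, thresholdQuantile = 0.95) {
  px <- as.matrix(trainingPixels)
  stopifnot(ncol(px) == 3L)
  if (nrow(px) < 100L) stop("need at least 100 training pixels")
  stopifnot(thresholdQuantile > 0, thresholdQuantile <= 1)
  ch <- .chroma(px[, 1L], px[, 2L], px[, 3L])
  mu <- colMeans(ch)
  S <- stats::cov(ch)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 1e-6)) {
    warning("degenerate training covariance; regularizing with small diagonal")
    S <- S + diag(0.25, 2L)
  }
  S <- (S + t(S)) / 2
  d2 <- stats::mahalanobis(ch, mu, S)
  thr <- sqrt(stats::quantile(d2, thresholdQuantile, names = FALSE, type = 2))
  thr <- max(thr, 1e-3) * (1 + 1e-9)  # keep the quantile point inside
  new("SkinModel", colorSpace = "CbCr", center = mu, covariance = S,
      threshold = thr, nTrain = nrow(px))
}

#' Classify RGB pixels against a skin model
#'
#' @param model a [SkinModel-class].
#' @param pixels `n x 3` RGB matrix in `[0, 1]`.
#' @return logical vector: Mahalanobis chroma distance `<= threshold`.
#' @export
classifyPixels <- function(model, pixels) {
  px <- as.matrix(pixels)
  ch <- .chroma(px[, 1L], px[, 2L], px[, 3L])
  stats::mahalanobis(ch, model@center, model@covariance) <= model@threshold^2
}

#' Segment skin pixels in every frame
#'
#' Per-pixel Mahalanobis test in the chroma plane, optionally followed by
#' one morphological opening then one closing with a 3 x 3 box structuring
#' element, which suppresses salt-and-pepper misclassifications that would
#' otherwise corrupt pixel counts. Deterministic.
#'
#' @param seq a [FrameSequence-class].
#' @param model a [SkinModel-class].
#' @param morphCleanup apply the open/close cleanup (default TRUE).
#' @return a [SkinMask-class] with exact per-frame skin fractions.
#' @export
segmentSkin <- function(seq, model, morphCleanup = TRUE) {
  d <- dim(frames(seq)[[1L]])
  brush <- matrix(1L, 3L, 3L)
  ms <- lapply(frames(seq), function(f) {
    keep <- classifyPixels(model, cbind(as.vector(f[, , 1L]),
                                        as.vector(f[, , 2L]),
                                        as.vector(f[, , 3L])))
    m <- matrix(keep, d[1L], d[2L])
    if (morphCleanup) {
      img <- EBImage::Image(t(m) * 1)
      img <- EBImage::closing(EBImage::opening(img, brush), brush)
      m <- t(EBImage::imageData(img)) > 0.5
    }
    m
  })
  new("SkinMask", masks = ms,
      skinFraction = vapply(ms, mean, numeric(1)))
}

#' Skin palette used by the phantom generator
#'
#' @return `4 x 3` matrix of RGB rows in `[0, 1]`, light-to-deep tones.
#' @export
skinPalette <- function() {
  rbind(c(0.92, 0.72, 0.61),
        c(0.85, 0.63, 0.52),
        c(0.78, 0.55, 0.44),
        c(0.66, 0.45, 0.35))
}

#' Packaged default skin model
#'
#' Fitted deterministically on the phantom generator's skin palette,
#' jittered in chroma and spanning a 0.7--1.3x brightness range so that
#' classification tolerates moderate exposure differences. Suitable for
#' phantom videos and as a starting point for real footage; for a specific
#' camera, fit from a user-drawn seed rectangle instead ([fitSkinModel()]).
#'
#' @param thresholdQuantile passed to [fitSkinModel()] (default 0.99 so
#'   the whole jittered palette is comfortably inside).
#' @return a [SkinModel-class].
#' @export
defaultSkinModel <- function(thresholdQuantile = 0.99) {
  .withSeed(190551, {
    pal <- skinPalette()
    gains <- seq(0.70, 1.30, length.out = 13L)
    px <- do.call(rbind, lapply(seq_len(nrow(pal)), function(i) {
      base <- matrix(rep(pal[i, ], each = 65L), ncol = 3L)
      g <- rep(gains, times = 5L)
      pmin(pmax(base * g + matrix(stats::rnorm(65L * 3L, 0, 0.015),
                                  ncol = 3L), 0), 1)
    }))
    fitSkinModel(px, thresholdQuantile = thresholdQuantile)
  })
}

#' Serialize / restore a skin model as JSON
#'
#' @param model a [SkinModel-class].
#' @param path JSON file path.
#' @return `writeSkinModel`: `path` invisibly; `readSkinModel`: the model.
#' @export
writeSkinModel <- function(model, path) {
  jsonlite::write_json(list(
    color_space = model@colorSpace,
    mean = model@center,
    covariance = model@covariance,
    threshold = model@threshold,
    n_train = model@nTrain), path, digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeSkinModel
#' @export
readSkinModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- matrix(as.numeric(j$covariance), 2L, 2L, byrow = TRUE,
              dimnames = list(c("Cb", "Cr"), c("Cb", "Cr")))
  new("SkinModel", colorSpace = j$color_space,
      center = stats::setNames(as.numeric(j$mean), c("Cb", "Cr")),
      covariance = S,
      threshold = as.numeric(j$threshold), nTrain = as.integer(j$n_train))
}
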