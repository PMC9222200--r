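# Dense pyramidal Lucas-Kanade optical flow, pure R (vectorized).
# Frames are H x W luma matrices in [0,1]; flow is (dx, dy) in px/frame
# with +x rightward (columns) and +y downward (rows).

# 2x downsample by 2x2 block averaging
.pyrDown <- function(m) {
  h2 <- nrow(m) %/% 2L; w2 <- ncol(m) %/% 2L
  m <- m[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
  (m[seq(1L, 2L * h2, 2L), seq(1L, 2L * w2, 2L), drop = FALSE] +
   m[seq(2L, 2L * h2, 2L), seq(1L, 2L * w2, 2L), drop = FALSE] +
   m[seq(1L, 2L * h2, 2L), seq(2L, 2L * w2, 2L), drop = FALSE] +
   m[seq(2L, 2L * h2, 2L), seq(2L, 2L * w2, 2L), drop = FALSE]) / 4
}

# bilinear sample of matrix m at fractional (ys, xs), clamped to borders
.bilinear <- function(m, ys, xs) {
  h <- nrow(m); w <- ncol(m)
  ys <- pmin(pmax(ys, 1), h); xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  fy <- ys - y0; fx <- xs - x0
  i00 <- (x0 - 1) * h + y0
  m00 <- m[i00]; m10 <- m[i00 + 1]; m01 <- m[i00 + h]; m11 <- m[i00 + h + 1]
  (1 - fy) * (1 - fx) * m00 + fy * (1 - fx) * m10 +
    (1 - fy) * fx * m01 + fy * fx * m11
}

# (2r+1)-box windowed sums via an integral image (truncated at borders)
.boxSum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  I <- matrix(0, h + 1L, w + 1L)
  I[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  y1 <- pmax(seq_len(h) - 1L - r, 0L); y2 <- pmin(seq_len(h) + r, h)
  x1 <- pmax(seq_len(w) - 1L - r, 0L); x2 <- pmin(seq_len(w) + r, w)
  I[y2 + 1L, x2 + 1L] - I[y1 + 1L, x2 + 1L] -
    I[y2 + 1L, x1 + 1L] + I[y1 + 1L, x1 + 1L]
}

.boxMean <- function(m, r) {
  cnt <- .boxSum(matrix(1, nrow(m), ncol(m)), r)
  .boxSum(m, r) / cnt
}

.gradX <- function(m) {
  w <- ncol(m)
  (m[, pmin(seq_len(w) + 1L, w), drop = FALSE] -
   m[, pmax(seq_len(w) - 1L, 1L), drop = FALSE]) / 2
}

.gradY <- function(m) {
  h <- nrow(m)
  (m[pmin(seq_len(h) + 1L, h), , drop = FALSE] -
   m[pmax(seq_len(h) - 1L, 1L), , drop = FALSE]) / 2
}

# dense LK flow for one luma pair; returns list(u = dx, v = dy)
# minEig: smallest structure-tensor eigenvalue (per window) required for
# a pixel's system to be solved; below it the update is 0. This gates
# flat/ambiguous regions where the 2x2 system is noise-driven.
.lkPair <- function(f1, f2, win = 9L, iters = 3L, levels = NULL,
                    minEig = 5e-3) {
  # keep the coarsest level at >= 32 px: structures a few pixels wide
  # alias away below that and corrupt the initialization
  if (is.null(levels))
    levels <- max(1L, floor(log2(min(dim(f1)) / 32)) + 1L)
  # presmooth (two 3x3 box passes ~ Gaussian sigma 1.1) to stabilize
  # gradients on noisy input
  f1 <- .boxMean(.boxMean(f1, 1L), 1L)
  f2 <- .boxMean(.boxMean(f2, 1L), 1L)
  p1 <- list(f1); p2 <- list(f2)
  for (l in seq_len(levels - 1L)) {
    p1[[l + 1L]] <- .pyrDown(p1[[l]])
    p2[[l + 1L]] <- .pyrDown(p2[[l]])
  }
  r <- (win - 1L) %/% 2L
  u <- v <- matrix(0, nrow(p1[[levels]]), ncol(p1[[levels]]))
  for (l in rev(seq_len(levels))) {
    g1 <- p1[[l]]; g2 <- p2[[l]]
    h <- nrow(g1); w <- ncol(g1)
    if (!identical(dim(u), dim(g1))) {
      ys <- matrix(seq(1, nrow(u), length.out = h), h, w)
      xs <- matrix(seq(1, ncol(u), length.out = w), h, w, byrow = TRUE)
      u <- 2 * .bilinear(u, ys, xs)
      v <- 2 * .bilinear(v, ys, xs)
    }
    Y <- matrix(seq_len(h), h, w)
    X <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (it in seq_len(iters)) {
      g2w <- .bilinear(g2, Y + v, X + u)
      It <- g2w - g1
      # symmetric gradients (average of both images) reduce warp bias
      gm <- (g1 + g2w) / 2
      Ix <- .gradX(gm); Iy <- .gradY(gm)
      Sxx <- .boxSum(Ix * Ix, r)
      Sxy <- .boxSum(Ix * Iy, r)
      Syy <- .boxSum(Iy * Iy, r)
      det <- Sxx * Syy - Sxy * Sxy
      lmin <- (Sxx + Syy -
               sqrt(pmax((Sxx - Syy)^2 + 4 * Sxy * Sxy, 0))) / 2
      ok <- lmin > minEig & det > 0
      det[!ok] <- 1  # avoid 0/0; updates are zeroed below
      bx <- .boxSum(Ix * It, r)
      by <- .boxSum(Iy * It, r)
      du <- -(Syy * bx - Sxy * by) / det
      dv <- -(Sxx * by - Sxy * bx) / det
      du[!ok] <- 0; dv[!ok] <- 0
      du <- pmin(pmax(du, -1), 1)
      dv <- pmin(pmax(dv, -1), 1)
      u <- u + du; v <- v + dv
      if (max(abs(du), abs(dv)) < 1e-3) break
    }
  }
  list(u = u, v = v)
}

#' Estimate dense inter-frame displacement
#'
#' Computes one dense displacement raster per consecutive frame pair using
#' a coarse-to-fine (pyramidal) iterative Lucas-Kanade estimator on the
#' luma channel, which handles displacements well beyond the window size.
#' Deterministic for a fixed method and input. Pixels within
#' [flowMargin()] of the border are estimator-invalid and are excluded
#' from downstream statistics.
#'
#' @param seq a [FrameSequence-class] with at least 2 frames.
#' @param method estimator label; only `"lucas-kanade"` is built in.
#' @param win odd LK window size in pixels (default 9).
#' @param iters warping iterations per pyramid level (default 3; more
#'   iterations let window noise random-walk on weakly textured regions).
#' @return a [FlowField-class]; displacements in pixels/frame.
#' @export
estimateFlow <- function(seq, method = "lucas-kanade", win = 9L,
                         iters = 3L) {
  method <- as.character(method)
  if (!identical(method, "lucas-kanade"))
    stop("unknown flow method: ", method)
  stopifnot(win >= 3L, win %% 2L == 1L)
  lum <- lapply(frames(seq), function(f) .frameLuma(f) / 255)
  n <- length(lum)
  fl <- vector("list", n - 1L)
  for (t in seq_len(n - 1L)) {
    uv <- .lkPair(lum[[t]], lum[[t + 1L]], win = win, iters = iters)
    a <- array(0, c(dim(uv$u), 2L))
    a[, , 1L] <- uv$u
    a[, , 2L] <- uv$v
    fl[[t]] <- a
  }
  new("FlowField", flows = fl,
      margin = as.integer((win - 1L) %/% 2L + 2L), method = method)
}

#' Convert flow to skin-restricted velocities
#'
#' Displacements become velocities in pixels/second (`v = flow * fps`).
#' Frame pair `t` is supported on the skin mask of the earlier frame `t`,
#' intersected with the estimator-valid interior. A pair whose support is
#' empty is flagged invalid (not silently zero) and excluded downstream.
#'
#' @param flow a [FlowField-class].
#' @param mask a [SkinMask-class] whose dimensions match the flow.
#' @param fps frames per second, `> 0`.
#' @return a [VelocityField-class].
#' @export
pixelVelocities <- function(flow, mask, fps) {
  stopifnot(fps > 0)
  fl <- flows(flow)
  ms <- masks(mask)
  if (length(ms) < length(fl) + 1L)
    stop("mask must cover every frame (one more than flow pairs)")
  d <- dim(fl[[1L]])
  if (!identical(dim(ms[[1L]]), d[1:2]))
    stop("flow and mask dimensions disagree")
  interior <- .interior(d[1L], d[2L], flowMargin(flow))
  n <- length(fl)
  vx <- vy <- sup <- vector("list", n)
  valid <- logical(n)
  for (t in seq_len(n)) {
    s <- ms[[t]] & interior
    valid[t] <- any(s)
    mx <- fl[[t]][, , 1L] * fps
    my <- fl[[t]][, , 2L] * fps
    mx[!s] <- NA_real_
    my[!s] <- NA_real_
    vx[[t]] <- mx; vy[[t]] <- my; sup[[t]] <- s
  }
  new("VelocityField", vx = vx, vy = vy, support = sup,
      fps = fps, valid = valid)
}
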