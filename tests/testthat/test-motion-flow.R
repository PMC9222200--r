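interiorIdx <- function(flow, h = 64L) {
  m <- flowMargin(flow)
  (m + 1L):(h - m)
}

test_that("identical consecutive frames give zero flow", {
  tp <- translationPair(0, 0)
  fl <- estimateFlow(FrameSequence(list(tp$f1, tp$f1), 30))
  expect_lt(max(abs(flows(fl)[[1]])), 0.1)
})

test_that("rigid translations are recovered within half a pixel", {
  cases <- list(c(3, 0), c(0, 2), c(-2, 1))
  for (d in cases) {
    tp <- translationPair(d[1], d[2])
    fl <- estimateFlow(FrameSequence(list(tp$f1, tp$f2), 30))
    int <- interiorIdx(fl)
    u <- flows(fl)[[1]][int, int, 1]
    v <- flows(fl)[[1]][int, int, 2]
    expect_equal(median(u), d[1], tolerance = 0.5)
    expect_equal(median(v), d[2], tolerance = 0.5)
  }
  expect_error(estimateFlow(
    FrameSequence(list(tp$f1, tp$f2), 30), method = "farneback"),
    "unknown flow method")
})

test_that("flow is equivariant under a common translation of both frames", {
  # shifting the whole scene of a moving pair by a constant offset leaves
  # interior flow unchanged within 0.2 px
  withr::with_seed(10, {
    big <- matrix(runif(84 * 84), 84)
    sm <- function(m) (m + m[c(1, seq_len(nrow(m) - 1L)), ] +
                         m[, c(1, seq_len(ncol(m) - 1L))]) / 3
    big <- sm(sm(big))
  })
  at <- function(y, x) big[y + seq_len(64) - 1L, x + seq_len(64) - 1L]
  fA <- estimateFlow(FrameSequence(list(toRGB(at(6, 6)),
                                        toRGB(at(6, 8))), 30))
  fB <- estimateFlow(FrameSequence(list(toRGB(at(9, 11)),
                                        toRGB(at(9, 13))), 30))
  int <- interiorIdx(fA)
  dif <- flows(fA)[[1]][int, int, ] - flows(fB)[[1]][int, int, ]
  expect_lt(median(abs(dif)), 0.2)
})

test_that("velocities are displacements scaled by fps on the mask support", {
  h <- 32L; w <- 32L
  fl <- new("FlowField",
            flows = list(array(1, c(h, w, 2))), margin = 4L,
            method = "lucas-kanade")
  mask <- matrix(TRUE, h, w)
  sm <- new("SkinMask", masks = list(mask, mask),
            skinFraction = c(1, 1))
  vel <- pixelVelocities(fl, sm, fps = 30)
  s <- vel@support[[1]]
  expect_true(all(abs(sqrt(vel@vx[[1]][s]^2 + vel@vy[[1]][s]^2) -
                        30 * sqrt(2)) < 1e-12))
  expect_true(all(is.na(vel@vx[[1]][!s])))
})

test_that("an empty skin mask flags the frame instead of zeroing it", {
  ph <- shortPhantom(0.5, seed = 6L)
  mask <- segmentSkin(ph$seq, defaultSkinModel())
  # blank out one frame's mask
  ms <- masks(mask)
  ms[[3]][] <- FALSE
  mask2 <- new("SkinMask", masks = ms,
               skinFraction = vapply(ms, mean, numeric(1)))
  fl <- estimateFlow(ph$seq)
  vel <- pixelVelocities(fl, mask2, fps(ph$seq))
  expect_false(vel@valid[3])
  expect_true(all(vel@valid[-3]))
  ser <- motionSeries(vel)
  expect_true(is.na(ser$q[3]))
  # and the summary uses only the valid frames
  expect_equal(summarizeVideo(ser)$n_valid_frames,
               length(vel@valid) - 1L)
})

test_that("phantom peak speed is recovered by the 95th-percentile velocity", {
  # jitter-free phantom so the analytic peak speed A*2*pi*f is exact
  ph <- generatePhantomVideo(phantomSpec(duration = 4, fps = 15,
    amplitude = 3, frequency = 1.2, amplitudeJitterSD = 0, seed = 9L))
  mask <- segmentSkin(ph$seq, defaultSkinModel())
  vel <- pixelVelocities(estimateFlow(ph$seq), mask, 15)
  speeds <- unlist(lapply(seq_along(vel@vx), function(t) {
    s <- vel@support[[t]]
    sqrt(vel@vx[[t]][s]^2 + vel@vy[[t]][s]^2)
  }))
  peak <- 3 * 2 * pi * 1.2
  expect_equal(unname(quantile(speeds, 0.95)), peak, tolerance = 0.2)
})

test_that("pixels/second velocities are fps-coherent under frame dropping", {
  ph <- generatePhantomVideo(phantomSpec(duration = 4, fps = 30,
    amplitude = 3, frequency = 1.0, amplitudeJitterSD = 0, seed = 12L))
  half <- preprocess(ph$seq, targetFps = 15)
  vmy <- function(s) {
    mask <- segmentSkin(s, defaultSkinModel())
    vel <- pixelVelocities(estimateFlow(s), mask, fps(s))
    summarizeVideo(motionSeries(vel))$V_my
  }
  v30 <- vmy(ph$seq)
  v15 <- vmy(half)
  expect_equal(v15 / v30, 1, tolerance = 0.25)
})
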