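# Shared fixtures, all generated in code.

# grayscale matrix -> H x W x 3 array
toRGB <- function(m) {
  a <- array(0, c(dim(m), 3L))
  a[, , 1L] <- m; a[, , 2L] <- m; a[, , 3L] <- m
  a
}

# smooth random texture with room to shift by (dx, dy); returns the two
# frames of a rigid translation with known displacement
translationPair <- function(dx, dy, h = 64L, w = 64L, seed = 42L,
                            pad = 10L) {
  withr::with_seed(seed, {
    base <- matrix(runif((h + 2 * pad) * (w + 2 * pad)), h + 2 * pad)
    sm <- function(m) (m + m[c(1, seq_len(nrow(m) - 1L)), ] +
                         m[, c(1, seq_len(ncol(m) - 1L))]) / 3
    base <- sm(sm(base))
    rows <- pad + seq_len(h); cols <- pad + seq_len(w)
    # content at (y, x) in frame2 was at (y - dy, x - dx) in frame1
    f1 <- base[rows, cols]
    f2 <- base[rows - dy, cols - dx]
    list(f1 = toRGB(f1), f2 = toRGB(f2))
  })
}

# short default-style phantom for pipeline tests
shortPhantom <- function(seconds = 2, seed = 11L, ...) {
  generatePhantomVideo(phantomSpec(duration = seconds, fps = 15,
                                   seed = seed, ...))
}

# uniform-color frame sequence
flatSequence <- function(color, n = 3L, h = 32L, w = 32L, fps = 10) {
  f <- array(rep(color, each = h * w), c(h, w, 3L))
  FrameSequence(rep(list(f), n), fps)
}

# brute-force all-pairs concordance, the independent C-statistic oracle
bruteForceC <- function(probs, outcomes) {
  i1 <- which(outcomes == 1); i0 <- which(outcomes == 0)
  s <- 0
  for (i in i1) for (j in i0)
    s <- s + (probs[i] > probs[j]) + 0.5 * (probs[i] == probs[j])
  s / (length(i1) * length(i0))
}
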