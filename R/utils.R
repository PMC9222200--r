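# Color conversions (BT.601, full range, 0-255 scale) and small numerics
# shared across the pipeline.

# RGB in [0,1] (vector/matrix n x 3) -> luma Y on 0..255
.luma <- function(r, g, b) 255 * (0.299 * r + 0.587 * g + 0.114 * b)

# RGB in [0,1] -> chroma (Cb, Cr) on 0..255
.chroma <- function(r, g, b) {
  cb <- 128 + 255 * (-0.168736 * r - 0.331264 * g + 0.5 * b)
  cr <- 128 + 255 * (0.5 * r - 0.418688 * g - 0.081312 * b)
  cbind(Cb = cb, Cr = cr)
}

.frameLuma <- function(frame)
  .luma(frame[, , 1L], frame[, , 2L], frame[, , 3L])

.frameChroma <- function(frame)
  .chroma(as.vector(frame[, , 1L]), as.vector(frame[, , 2L]),
          as.vector(frame[, , 3L]))

# quantize to the 8-bit k/255 grid, as written/read through PNG
.quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

# logical interior matrix excluding a border of `margin` pixels
.interior <- function(h, w, margin) {
  m <- matrix(FALSE, h, w)
  if (h > 2 * margin && w > 2 * margin)
    m[(margin + 1L):(h - margin), (margin + 1L):(w - margin)] <- TRUE
  m
}

# run code under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric `(lower, upper)` on the proportion scale. For `x = 0`
#'   the lower bound is 0; for `x = n` the upper bound is 1.
#' @examples
#' clopperPearson(16, 29)
#' @export
clopperPearson <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}
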