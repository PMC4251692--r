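# Shared fixtures, built in code.

# small noise-free spec for geometry-level checks
quietSpec <- function(rows = 96, cols = 128, ...) {
  PhantomSpec(imageSize = c(rows, cols), noiseSigma = 0, ...)
}

# straight horizontal vein through the middle of a spec's field
midVein <- function(spec, depth, radius = 1.5) {
  fov <- fieldOfView(spec)
  y <- fov[["height"]] / 2
  VeinSegment(cbind(c(0.15 * fov[["width"]], 0.85 * fov[["width"]]), c(y, y)),
              radius = radius, depth = depth)
}

rampImage <- function(n = 64, lo = 0, hi = 1, pitch = 0.1) {
  NIRImage(matrix(seq(lo, hi, length.out = n * n), n, n), pixelPitch = pitch)
}

constImage <- function(value = 0.5, n = 32, pitch = 0.1) {
  NIRImage(matrix(value, n, n), pixelPitch = pitch)
}

# impulse image whose kernels fit well inside the frame
impulseImage <- function(n = 65, pitch = 0.5) {
  m <- matrix(0, n, n)
  m[(n + 1) / 2, (n + 1) / 2] <- 1
  NIRImage(m, pixelPitch = pitch)
}

# independently evaluated, truncated + renormalized Gaussian taps
oracleGaussTaps <- function(sigmaPx) {
  r <- max(1L, ceiling(4 * sigmaPx))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigmaPx^2))
  list(taps = g / sum(g), radius = r)
}

# Michelson contrast of a straight mid vein, measured on its centerline
# against the same render without the vein
veinContrastOf <- function(spec, depth, radius = 1.5) {
  v <- midVein(spec, depth, radius)
  withV <- renderPhantom(spec, list(v))
  noV <- renderPhantom(spec, list())
  clPx <- truthCenterlinePixels(spec, list(v))
  iv <- mean(pixels(phantomImage(withV))[clPx])
  ib <- mean(pixels(phantomImage(noV))[clPx])
  (ib - iv) / (ib + iv)
}

# one shared synthetic study bundle per test run (fixture generation is
# the expensive step; every consumer reads the same seed-1 bundle)
.fixtureCache <- new.env(parent = emptyenv())
fixtureBundle <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.fixtureCache[[key]])) {
    dir <- file.path(tempdir(), paste0("veinviz-fixtures-", seed))
    .fixtureCache[[key]] <- makeFixtures(seed, dir, writeImages = FALSE)
    .fixtureCache[[key]]$dir <- dir
  }
  .fixtureCache[[key]]
}
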