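test_that("contrast stretch maps the requested percentiles to 0 and 1", {
  cst <- constImage(0.42)
  expect_identical(pixels(contrastEnhance(cst, c(0, 100))), pixels(cst))

  two <- NIRImage(matrix(rep(c(0.4, 0.6), 50), 10, 10))
  expect_setequal(unique(as.vector(pixels(contrastEnhance(two, c(0, 100))))),
                  c(0, 1))

  ramp <- rampImage(100)
  out <- pixels(contrastEnhance(ramp, c(1, 99)))
  # oracle: recompute the percentiles on the output
  q <- quantile(out, c(0.01, 0.99), names = FALSE)
  expect_lt(abs(q[1] - 0), 1 / 255)
  expect_lt(abs(q[2] - 1), 1 / 255)

  expect_error(contrastEnhance(ramp, c(40, 40)), "percentiles")
  expect_error(contrastEnhance(ramp, c(90, 10)), "percentiles")
})

test_that("DoG rejects DC, matches the sampled kernel difference, is linear", {
  expect_true(all(pixels(differenceOfGaussians(constImage(0.37), 0.4, 2)) == 0.5))

  # impulse response vs an independently evaluated kernel-difference grid
  img <- impulseImage(65, pitch = 0.5)       # sigmas 0.8 px and 4 px
  resp <- differenceOfGaussians(img, 0.4, 2.0, normalize = FALSE)
  gn <- oracleGaussTaps(0.4 / 0.5)
  gw <- oracleGaussTaps(2.0 / 0.5)
  n <- 65; ctr <- 33
  oracle <- matrix(0, n, n)
  addSep <- function(M, taps, r, sgn) {
    for (dr in -r:r) for (dc in -r:r) {
      M[ctr + dr, ctr + dc] <- M[ctr + dr, ctr + dc] +
        sgn * taps[dr + r + 1] * taps[dc + r + 1]
    }
    M
  }
  oracle <- addSep(oracle, gn$taps, gn$radius, +1)
  oracle <- addSep(oracle, gw$taps, gw$radius, -1)
  expect_lt(max(abs(resp - oracle)), 1e-6)

  # linearity before renormalization
  base <- NIRImage(matrix(runif(32 * 32, 0, 0.5), 32, 32), pixelPitch = 0.5)
  doubled <- NIRImage(2 * pixels(base), pixelPitch = 0.5)
  r1 <- differenceOfGaussians(base, 0.4, 2, normalize = FALSE)
  r2 <- differenceOfGaussians(doubled, 0.4, 2, normalize = FALSE)
  expect_equal(r2, 2 * r1, tolerance = 1e-10)

  expect_error(differenceOfGaussians(constImage(), 2, 0.4), "sigmaNarrow")
})

test_that("Laplacian annihilates planar ramps and matches its kernels", {
  # planar ramp: zero response on the interior
  n <- 32
  plane <- NIRImage(outer(seq_len(n) * 0.01, seq_len(n) * 0.012, "+"),
                    pixelPitch = 0.5)
  r <- laplacianFilter(plane, 0, normalize = FALSE)
  expect_lt(max(abs(r[2:(n - 1), 2:(n - 1)])), 1e-12)

  # impulse, sigma 0: the bare 4-neighbour kernel
  img <- impulseImage(33, pitch = 0.5)
  r0 <- laplacianFilter(img, 0, normalize = FALSE)
  expect_equal(r0[16:18, 16:18],
               matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3),
               tolerance = 1e-12)
  expect_equal(sum(abs(r0)) - sum(abs(r0[16:18, 16:18])), 0, tolerance = 1e-12)

  # impulse, sigma 1 mm (2 px): discrete Laplacian of the sampled Gaussian
  img2 <- impulseImage(65, pitch = 0.5)
  rL <- laplacianFilter(img2, 1.0, normalize = FALSE)
  g <- oracleGaussTaps(2)
  G <- matrix(0, 65, 65)
  idx <- 33 + seq(-g$radius, g$radius)
  G[idx, idx] <- outer(g$taps, g$taps)
  oracle <- matrix(0, 65, 65)
  for (r_ in 2:64) for (c_ in 2:64)
    oracle[r_, c_] <- G[r_ - 1, c_] + G[r_ + 1, c_] + G[r_, c_ - 1] +
      G[r_, c_ + 1] - 4 * G[r_, c_]
  expect_lt(max(abs(rL[2:64, 2:64] - oracle[2:64, 2:64])), 1e-6)

  expect_error(laplacianFilter(img, -0.5), "non-negative")
})

test_that("ROI processing is local and matches crop-process-paste", {
  img <- NIRImage(matrix(runif(128 * 128), 128, 128))
  stage <- function(x) differenceOfGaussians(x, 0.4, 2)

  expect_identical(pixels(applyROI(img, c(0, 0, 128, 128), stage)),
                   pixels(stage(img)))

  roi <- c(40, 56, 72, 88)                   # 32 x 32, 0-based half-open
  out <- applyROI(img, roi, stage)
  inside <- matrix(FALSE, 128, 128)
  inside[41:72, 57:88] <- TRUE
  expect_identical(pixels(out)[!inside], pixels(img)[!inside])

  # independent crop -> process -> paste
  crop <- NIRImage(pixels(img)[41:72, 57:88], pixelPitch = pixelPitch(img))
  expected <- pixels(img)
  expected[41:72, 57:88] <- pixels(stage(crop))
  expect_identical(pixels(out), expected)

  expect_error(applyROI(img, c(0, 0, 200, 10), stage), "outside")
})

test_that("frame pipeline composes, finds ridges on veins, is deterministic", {
  ramp <- rampImage(64)
  cfg <- EnhanceConfig("raw-contrast", stretchPercentiles = c(1, 99))
  expect_identical(pixels(processFrame(ramp, CameraSettings(), cfg)),
                   pixels(contrastEnhance(ramp, c(1, 99))))

  # identity end to end: full-range image, (0, 100) stretch, no operator
  full <- rampImage(64, 0, 1)
  cfg0 <- EnhanceConfig("raw-contrast", stretchPercentiles = c(0, 100))
  expect_equal(pixels(processFrame(full, CameraSettings(), cfg0)),
               pixels(full), tolerance = 1e-12)

  # ridge-profile oracle: on a straight-vein phantom the dog1 response is
  # minimal at the centerline along the perpendicular direction
  spec <- quietSpec(128, 192)
  v <- midVein(spec, 2)
  out <- renderPhantom(spec, list(v))
  enh <- processFrame(phantomImage(out), CameraSettings(), EnhanceConfig("dog1"))
  r0 <- round(fieldOfView(spec)[["height"]] / 2 / spec@pixelPitch)
  for (c0 in seq(40, 150, by = 10)) {
    prof <- pixels(enh)[(r0 - 25):(r0 + 25), c0]
    expect_lte(abs(which.min(prof) - 26), 2)
  }

  a <- processFrame(phantomImage(out), CameraSettings(), EnhanceConfig("dog1"))
  expect_identical(pixels(a), pixels(enh))
})

test_that("operators preserve dimensions and range", {
  img <- NIRImage(matrix(runif(40 * 56), 40, 56), pixelPitch = 0.2)
  for (f in list(function(x) contrastEnhance(x, c(2, 98)),
                 function(x) differenceOfGaussians(x, 0.4, 2),
                 function(x) laplacianFilter(x, 1),
                 function(x) laplacianFilter(x, 0))) {
    out <- f(img)
    expect_identical(dim(pixels(out)), c(40L, 56L))
    expect_true(all(pixels(out) >= 0 & pixels(out) <= 1))
  }
})

test_that("stream processing is stateless and reports its throughput", {
  img <- NIRImage(matrix(runif(64 * 64), 64, 64))
  cfg <- EnhanceConfig("dog1")
  single <- processStream(list(img), config = cfg)
  expect_identical(pixels(single$frames[[1]]),
                   pixels(processFrame(img, CameraSettings(), cfg)))

  res <- processStream(rep(list(img), 4), config = cfg)
  for (k in 2:4)
    expect_identical(pixels(res$frames[[k]]), pixels(res$frames[[1]]))

  frames <- lapply(1:10, function(i) {
    spec <- PhantomSpec(imageSize = c(64, 96), rngSeed = i)
    phantomImage(renderPhantom(spec, list()))
  })
  rep10 <- processStream(frames, config = cfg)
  expect_identical(rep10$report$frameCount, 10L)

  expect_error(processStream(list()), "empty")
})
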