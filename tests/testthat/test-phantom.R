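test_that("vein network generation respects count, bounds and determinism", {
  spec <- PhantomSpec(imageSize = c(400, 600), pixelPitch = 0.1)  # 40 x 60 mm
  expect_identical(generateVeinNetwork(spec, 0), list())
  expect_error(generateVeinNetwork(spec, -1), "non-negative")

  vs <- generateVeinNetwork(spec, 3, rngSeed = 7)
  expect_length(vs, 3)
  for (v in vs) {
    cl <- v@centerline
    expect_gte(nrow(cl), 2)
    # exhaustive bounds check over every emitted point (x = cols, y = rows)
    expect_true(all(cl[, 1] >= 0 & cl[, 1] <= 60))
    expect_true(all(cl[, 2] >= 0 & cl[, 2] <= 40))
  }

  expect_identical(generateVeinNetwork(spec, 3, rngSeed = 7),
                   generateVeinNetwork(spec, 3, rngSeed = 7))
})

test_that("illumination field is radial, symmetric and matches closed form", {
  # single LED exactly on a pixel centre: global maximum there
  spec1 <- quietSpec(64, 96, ledPositions = cbind(4.75, 3.25), ledFalloff = 3)
  L1 <- pixels(illuminationField(spec1))
  expect_equal(arrayInd(which.max(L1), dim(L1)),
               matrix(c(33L, 48L), 1))  # row: 3.25/0.1+0.5, col: 4.75/0.1+0.5

  # closed form: r = 10 mm from a single LED with sigma_L = 10 mm
  spec2 <- PhantomSpec(imageSize = c(64, 256), pixelPitch = 0.1,
                       ledPositions = cbind(2.05, 3.25), ledFalloff = 10,
                       noiseSigma = 0)
  L2 <- pixels(illuminationField(spec2))
  peak <- L2[33, 21]          # pixel centred on the LED
  at10 <- L2[33, 121]         # same row, 100 px = 10 mm away
  expect_equal(at10 / peak, exp(-0.5), tolerance = 1e-10)

  # 4 LEDs at rectangle corners centred on the field: mirror symmetries
  spec4 <- quietSpec(64, 96,
                     ledPositions = cbind(4.8 + c(-3, 3, 3, -3),
                                          3.2 + c(-2, -2, 2, 2)),
                     ledFalloff = 2)
  L4 <- pixels(illuminationField(spec4))
  expect_equal(L4, L4[nrow(L4):1, ], tolerance = 1e-12)   # up-down flip
  expect_equal(L4, L4[, ncol(L4):1], tolerance = 1e-12)   # left-right flip

  expect_error(PhantomSpec(ledFalloff = -1), "ledFalloff")
})

test_that("render with no absorbers is exactly I0 * L * R_bg", {
  spec <- quietSpec(64, 96)
  out <- renderPhantom(spec, list())
  expect_identical(pixels(phantomImage(out)),
                   spec@baseIntensity * pixels(illuminationField(spec)) *
                     spec@backgroundReflectance)
  expect_true(all(is.infinite(depthMap(out))))
  expect_false(any(truthMask(out)))
})

test_that("centerline intensity matches a dense numerical convolution", {
  spec <- quietSpec(128, 128)
  depth <- 2; radius <- 1.5
  v <- midVein(spec, depth, radius)
  out <- renderPhantom(spec, list(v))

  # oracle: 1-D convolution of the rect tube profile with the Gaussian on
  # a fine grid (for a straight horizontal vein the 2-D convolution
  # separates; the along-vein direction integrates to 1)
  sigma <- spec@blurBase + spec@blurSlope * depth
  amp <- spec@maxAbsorption * exp(-depth / spec@depthDecay)
  y <- fieldOfView(spec)[["height"]] / 2
  r0 <- round(y / spec@pixelPitch)      # nearest row; centre may be offset
  offset <- abs((r0 - 0.5) * spec@pixelPitch - y)
  du <- 0.001
  u <- seq(-radius - 6 * sigma, radius + 6 * sigma, by = du)
  rect <- as.numeric(abs(u - offset) <= radius)
  gauss <- exp(-u^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  aOracle <- amp * sum(rect * gauss) * du

  c0 <- 64
  bg <- pixels(phantomImage(renderPhantom(spec, list())))[r0, c0]
  got <- pixels(phantomImage(out))[r0, c0]
  expect_equal(got, bg * (1 - aOracle), tolerance = 2e-3)
})

test_that("a vein 50 decay lengths deep is invisible", {
  spec <- quietSpec(64, 96, depthDecay = 0.3)
  v <- midVein(spec, depth = 15, radius = 1)   # 50 * delta
  withV <- renderPhantom(spec, list(v))
  noV <- renderPhantom(spec, list())
  expect_lt(max(abs(pixels(phantomImage(withV)) - pixels(phantomImage(noV)))),
            1e-6)
})

test_that("vein contrast is non-increasing in depth and adipose thickness", {
  spec <- quietSpec(96, 128)
  depths <- seq(0.5, 5.5, length.out = 11)
  contrasts <- vapply(depths, function(d) veinContrastOf(spec, d), numeric(1))
  expect_true(all(diff(contrasts) <= 1e-12))

  adiposes <- seq(0, 4, length.out = 10)
  cA <- vapply(adiposes, function(a)
    veinContrastOf(quietSpec(96, 128, adiposeThickness = a), 2), numeric(1))
  expect_true(all(diff(cA) <= 1e-12))
})

test_that("rendering is deterministic and stays in range", {
  spec <- PhantomSpec(imageSize = c(64, 96), noiseSigma = 0.05,
                      hairDensity = 0.05, rngSeed = 11)
  vs <- generateVeinNetwork(spec, 2, rngSeed = 3)
  a <- renderPhantom(spec, vs)
  b <- renderPhantom(spec, vs)
  expect_identical(pixels(phantomImage(a)), pixels(phantomImage(b)))
  expect_identical(truthMask(a), truthMask(b))
  expect_true(all(pixels(phantomImage(a)) >= 0 & pixels(phantomImage(a)) <= 1))
})

test_that("truth mask equals a brute-force point-in-capsule test", {
  spec <- quietSpec(48, 64)
  vs <- generateVeinNetwork(spec, 2, rngSeed = 5)
  out <- renderPhantom(spec, vs)
  tm <- truthMask(out)
  segDist <- function(px, py, p, q) {
    t <- ((px - p[1]) * (q[1] - p[1]) + (py - p[2]) * (q[2] - p[2])) /
      sum((q - p)^2)
    t <- min(1, max(0, t))
    sqrt((px - (p[1] + t * (q[1] - p[1])))^2 +
         (py - (p[2] + t * (q[2] - p[2])))^2)
  }
  for (r in seq_len(nrow(tm))) for (cc in seq_len(ncol(tm))) {
    px <- (cc - 0.5) * spec@pixelPitch
    py <- (r - 0.5) * spec@pixelPitch
    inside <- FALSE
    for (v in vs) {
      cl <- v@centerline
      for (i in seq_len(nrow(cl) - 1))
        if (segDist(px, py, cl[i, ], cl[i + 1, ]) <= v@radius) inside <- TRUE
    }
    if (inside != tm[r, cc])
      fail(sprintf("truth mask mismatch at (%d, %d)", r, cc))
  }
  succeed()
})

test_that("render rejects out-of-field veins", {
  spec <- quietSpec(64, 96)
  bad <- VeinSegment(cbind(c(-5, 5), c(3, 3)), radius = 1, depth = 1)
  expect_error(renderPhantom(spec, list(bad)), "outside the field")
})

test_that("hair occlusion darkens roughly the requested pixel fraction", {
  spec <- PhantomSpec(imageSize = c(96, 128), noiseSigma = 0,
                      hairDensity = 0.08, rngSeed = 4)
  out <- renderPhantom(spec, list())
  base <- renderPhantom(quietSpec(96, 128, rngSeed = 4), list())
  darker <- pixels(phantomImage(out)) < pixels(phantomImage(base)) - 1e-9
  expect_gt(mean(darker), 0.04)
  expect_lt(mean(darker), 0.20)
})
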