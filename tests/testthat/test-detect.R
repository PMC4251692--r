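test_that("segmentation returns an empty mask on signal-free frames", {
  vm <- segmentVeins(constImage(0.5, 64), DetectConfig())
  expect_false(any(veinMask(vm)))
  expect_length(centerlines(vm), 0)
})

test_that("segmentation recovers a default single-vein phantom", {
  spec <- PhantomSpec()                       # 256 x 384, noise 0.01
  v <- midVein(spec, 2)
  out <- renderPhantom(spec, list(v))
  enh <- processFrame(phantomImage(out), CameraSettings(), EnhanceConfig("dog1"))
  vm <- segmentVeins(enh, DetectConfig())
  det <- do.call(rbind, centerlines(vm))
  expect_gt(nrow(det), 50)

  # brute-force nearest-distance matching of detected centerline pixels
  # against the ground-truth footprint
  tolPx <- DetectConfig()@hitTolerance / spec@pixelPitch
  tmPx <- which(truthMask(out), arr.ind = TRUE)
  inTruth <- vapply(seq_len(nrow(det)), function(i)
    min((tmPx[, 1] - det[i, 1])^2 + (tmPx[, 2] - det[i, 2])^2) <= tolPx^2,
    logical(1))
  expect_gte(mean(inTruth), 0.90)

  # structural invariants
  expect_identical(dim(veinMask(vm)), dim(pixels(enh)))
  for (cl in centerlines(vm)) expect_true(all(veinMask(vm)[cl]))
})

test_that("marker-hit decision matches a brute-force distance scan", {
  img <- constImage(0.5, 32)
  empty <- VeinMask(matrix(FALSE, 32, 32), list(), img)
  expect_false(isVeinAt(empty, c(10, 10), 5))

  m <- matrix(FALSE, 32, 32); m[16, 16] <- TRUE
  vm <- VeinMask(m, list(), img)
  expect_true(isVeinAt(vm, c(16, 16), 0))
  # point 3 px away, tolerance worth 2 px (0.2 mm at 0.1 mm pitch)
  expect_false(isVeinAt(vm, c(16, 19), 0.2))
  expect_true(isVeinAt(vm, c(16, 19), 0.3))
  # oracle: exhaustive scan over every mask pixel
  pt <- c(12, 25)
  fg <- which(m, arr.ind = TRUE)
  dmin <- sqrt(min((fg[, 1] - pt[1])^2 + (fg[, 2] - pt[2])^2))
  expect_identical(isVeinAt(vm, pt, dmin * 0.1), TRUE)
  expect_identical(isVeinAt(vm, pt, dmin * 0.1 - 0.05), FALSE)

  expect_error(isVeinAt(vm, c(0, 5), 1), "outside")
})

test_that("distinct veins are counted via centerline length", {
  img <- constImage(0.5, 64)
  expect_identical(countVisibleVeins(VeinMask(matrix(FALSE, 32, 32), list(),
                                              constImage(0.5, 32))), 0L)

  # three disjoint parallel veins on one phantom
  spec <- quietSpec(192, 256)
  veins <- lapply(c(5, 10, 15), function(y)
    VeinSegment(cbind(c(3, 22), c(y, y)), radius = 1, depth = 1.5))
  out <- renderPhantom(spec, veins)
  enh <- processFrame(phantomImage(out), CameraSettings(), EnhanceConfig("dog1"))
  vm <- segmentVeins(enh, DetectConfig(thresholdQuantile = 0.3))
  expect_identical(countVisibleVeins(vm, 5), 3L)
})

test_that("morphological closing bridges sub-radius gaps before counting", {
  # synthetic ridge frame: one dark 3-px-thick line with a 1-px gap
  px <- matrix(0.6, 64, 64)
  px[30:32, 5:30] <- 0.2
  px[30:32, 32:60] <- 0.2                     # column 31 missing
  frame <- NIRImage(px)
  vmClosed <- segmentVeins(frame, DetectConfig(thresholdQuantile = 0.45,
                                               morphRadius = 1,
                                               minComponentArea = 10))
  expect_identical(countVisibleVeins(vmClosed, 3), 1L)
  vmOpen <- segmentVeins(frame, DetectConfig(thresholdQuantile = 0.45,
                                             morphRadius = 0,
                                             minComponentArea = 10))
  expect_identical(countVisibleVeins(vmOpen, 1), 2L)
})

test_that("marker hit rates separate on-vein from far-field points", {
  spec <- PhantomSpec()
  v <- midVein(spec, 2)
  out <- renderPhantom(spec, list(v))
  enh <- processFrame(phantomImage(out), CameraSettings(), EnhanceConfig("dog1"))
  vm <- segmentVeins(enh, DetectConfig())
  clPx <- truthCenterlinePixels(spec, list(v))
  d <- dim(truthMask(out))

  set.seed(99)
  onVein <- clPx[sample(nrow(clPx), 200, replace = TRUE), ]
  hitsOn <- vapply(seq_len(200), function(k)
    isVeinAt(vm, onVein[k, ], 2), logical(1))
  expect_gte(mean(hitsOn), 0.9)

  # far field: >= 5 mm (50 px) from the truth footprint
  tmPx <- which(truthMask(out), arr.ind = TRUE)
  far <- matrix(NA_integer_, 0, 2)
  while (nrow(far) < 200) {
    cand <- cbind(sample(d[1], 200, TRUE), sample(d[2], 200, TRUE))
    ok <- vapply(seq_len(200), function(k)
      min((tmPx[, 1] - cand[k, 1])^2 + (tmPx[, 2] - cand[k, 2])^2) >= 50^2,
      logical(1))
    far <- rbind(far, cand[ok, , drop = FALSE])
  }
  far <- far[seq_len(200), ]
  hitsFar <- vapply(seq_len(200), function(k)
    isVeinAt(vm, far[k, ], 2), logical(1))
  expect_lte(mean(hitsFar), 0.1)
})

test_that("raising the threshold quantile never shrinks the mask", {
  spec <- PhantomSpec(imageSize = c(128, 192), rngSeed = 3)
  vs <- generateVeinNetwork(spec, 2, rngSeed = 3)
  out <- renderPhantom(spec, vs)
  enh <- processFrame(phantomImage(out), CameraSettings(), EnhanceConfig("dog1"))
  prev <- NULL
  for (q in c(0.05, 0.1, 0.2, 0.3)) {
    m <- veinMask(segmentVeins(enh, DetectConfig(thresholdQuantile = q)))
    if (!is.null(prev)) expect_true(all(m[prev]))
    prev <- m
  }
})

test_that("vein counting is invariant to pre-enhancement gain", {
  spec <- quietSpec(128, 192, rngSeed = 8)
  vs <- generateVeinNetwork(spec, 2, rngSeed = 8)
  img <- phantomImage(renderPhantom(spec, vs))
  cfg <- EnhanceConfig("dog1")
  det <- DetectConfig()
  n1 <- countVisibleVeins(segmentVeins(processFrame(img, CameraSettings(), cfg), det))
  n2 <- countVisibleVeins(segmentVeins(processFrame(
    img, CameraSettings(gain = 0.8), cfg), det))  # non-clipping regime
  expect_identical(n1, n2)
})

test_that("depth sweep handles invisibility and adipose monotonically", {
  grid <- c(1, 2, 3)
  clear <- PhantomSpec(imageSize = c(128, 192), maxAbsorption = 0)
  expect_identical(maxVisibleDepth(clear, DetectConfig(), grid), 0)

  lean <- PhantomSpec(imageSize = c(128, 192))
  obese <- PhantomSpec(imageSize = c(128, 192), adiposeThickness = 2.5)
  gridC <- seq(1, 7, by = 1)
  expect_lte(maxVisibleDepth(obese, DetectConfig(), gridC),
             maxVisibleDepth(lean, DetectConfig(), gridC))

  expect_error(maxVisibleDepth(lean, DetectConfig(), numeric(0)), "empty")
})
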