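## Vein segmentation, marker-hit decision, vein counting, depth sweep.

#' Segment veins from a ridge-response frame
#'
#' The enhanced frame encodes vein-like (dark, below-0.5) ridge response.
#' Pixels below the `thresholdQuantile` quantile of the response are kept,
#' morphologically opened and closed with a disc of `morphRadius` pixels,
#' components smaller than `minComponentArea` pixels are dropped, and the
#' survivors are skeletonized into centerline polylines (8-connectivity
#' throughout). A constant (signal-free) frame yields an empty mask.
#'
#' @param enhanced an [NIRImage-class] ridge response (e.g. from
#'   [processFrame()] with a DoG mode).
#' @param config a [DetectConfig-class].
#' @return A [VeinMask-class].
#' @examples
#' out <- renderPhantom(PhantomSpec(imageSize = c(96, 128), noiseSigma = 0),
#'                      list(VeinSegment(cbind(c(2, 10), c(5, 5)), 1, 2)))
#' enh <- processFrame(phantomImage(out), config = EnhanceConfig("dog1"))
#' m <- segmentVeins(enh, DetectConfig())
#' @export
segmentVeins <- function(enhanced, config = DetectConfig()) {
  stopifnot(is(enhanced, "NIRImage"), is(config, "DetectConfig"))
  validObject(config)
  px <- pixels(enhanced)
  empty <- function() VeinMask(matrix(FALSE, nrow(px), ncol(px)),
                               list(), enhanced)
  if (diff(range(px)) < .Machine$double.eps) return(empty())
  thr <- stats::quantile(px, config@thresholdQuantile, names = FALSE)
  mask <- px < thr
  if (config@morphRadius >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(config@morphRadius) + 1L,
                                shape = "disc")
    m <- EBImage::closing(EBImage::opening(matrix(as.numeric(mask),
                                                  nrow(mask), ncol(mask)),
                                           brush), brush)
    mask <- m > 0.5
  }
  if (!any(mask)) return(empty())
  lab <- .label8(mask)
  keep <- which(tabulate(lab[lab > 0]) >= config@minComponentArea)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  if (!any(mask)) return(empty())
  VeinMask(mask, .maskCenterlines(mask), enhanced)
}

#' Is there a vein under a marked point?
#'
#' TRUE iff some segmented vein pixel lies within `tolerance` mm (converted
#' to pixels through the mask's pixel pitch) of the marked point. This
#' distance rule stands in for the visual check a supervising clinician
#' performs when adjudicating a marked venipuncture site.
#'
#' @param mask a [VeinMask-class].
#' @param point numeric (row, col) pixel coordinate, 1-based.
#' @param tolerance distance tolerance in mm (default: the config default
#'   of 2 mm is a typical antecubital vein radius).
#' @return Logical scalar.
#' @examples
#' img <- NIRImage(matrix(0.5, 32, 32))
#' m <- VeinMask(matrix(FALSE, 32, 32), list(), img)
#' isVeinAt(m, c(10, 10), 2)  # FALSE: empty mask
#' @export
isVeinAt <- function(mask, point, tolerance = 2) {
  stopifnot(is(mask, "VeinMask"))
  d <- dim(veinMask(mask))
  if (length(point) != 2 || point[1] < 1 || point[1] > d[1] ||
      point[2] < 1 || point[2] > d[2])
    .fail("point (%s) outside %d x %d frame",
          paste(point, collapse = ", "), d[1], d[2])
  fg <- which(veinMask(mask), arr.ind = TRUE)
  if (!nrow(fg)) return(FALSE)
  tolPx <- tolerance / pixelPitch(mask)
  # epsilon shields exact-boundary distances from mm/pixel roundoff
  min((fg[, 1] - point[1])^2 + (fg[, 2] - point[2])^2) <= tolPx^2 + 1e-9
}

#' Count distinct visible veins
#'
#' Number of 8-connected mask components whose skeleton arc length (pixel
#' count times pixel pitch) reaches `minLength` mm.
#'
#' @param mask a [VeinMask-class].
#' @param minLength minimum centerline length in mm (default 5).
#' @return Integer count.
#' @export
countVisibleVeins <- function(mask, minLength = 5) {
  stopifnot(is(mask, "VeinMask"))
  cls <- centerlines(mask)
  if (!length(cls)) return(0L)
  lens <- vapply(cls, nrow, integer(1)) * pixelPitch(mask)
  sum(lens >= minLength)
}

## One straight test vein across the field at a given depth.
.straightVein <- function(spec, depth, radius = 1.5) {
  fov <- fieldOfView(spec)
  y <- fov[["height"]] / 2
  VeinSegment(cbind(c(0.15 * fov[["width"]], 0.85 * fov[["width"]]),
                    c(y, y)),
              radius = radius, depth = depth)
}

## Centerline recall: fraction of truth centerline pixels lying within
## tolPx of a detected centerline pixel.
.centerlineRecall <- function(truthPx, detectedPx, tolPx) {
  if (!nrow(truthPx)) return(NA_real_)
  if (!nrow(detectedPx)) return(0)
  hit <- vapply(seq_len(nrow(truthPx)), function(i) {
    min((detectedPx[, 1] - truthPx[i, 1])^2 +
        (detectedPx[, 2] - truthPx[i, 2])^2) <= tolPx^2
  }, logical(1))
  mean(hit)
}

## Michelson contrast of a vein, measured on centerline pixels against a
## vein-free render of the same spec and seed.
.veinContrast <- function(spec, vein, withV = NULL) {
  if (is.null(withV)) withV <- renderPhantom(spec, list(vein))
  noV <- renderPhantom(spec, list())
  clPx <- truthCenterlinePixels(spec, list(vein))
  iv <- mean(pixels(phantomImage(withV))[clPx])
  ib <- mean(pixels(phantomImage(noV))[clPx])
  if (ib + iv <= 0) return(0)
  (ib - iv) / (ib + iv)
}

#' Maximum visible vein depth by phantom sweep
#'
#' Renders one straight vein per depth in `depthGrid` under `spec`, runs
#' the default dog1 enhancement and [segmentVeins()], and declares the vein
#' at a depth "visible" when (i) the fraction of truth-centerline pixels
#' within the hit tolerance of a detected centerline reaches `recallFloor`
#' and (ii) the vein's Michelson contrast against a vein-free render is at
#' least the config's `contrastFloor`. Returns the largest visible depth,
#' or 0 if none is.
#'
#' This sweep is the desk-scale counterpart of validating a device's
#' penetration depth against ultrasound: handheld NIR vein finders lose
#' veins at around 5 mm of tissue, and the default calibration of
#' [PhantomSpec()] places the sweep's answer in that range.
#'
#' @param spec a [PhantomSpec-class].
#' @param config a [DetectConfig-class].
#' @param depthGrid ascending depths in mm to test.
#' @param recallFloor minimum centerline recall, default 0.5.
#' @param veinRadius radius of the test vein in mm, default 1.5.
#' @return Largest visible depth in mm (0 if no depth qualifies).
#' @examples
#' \donttest{
#' maxVisibleDepth(PhantomSpec(), DetectConfig(), seq(2, 7, by = 0.5))
#' }
#' @export
maxVisibleDepth <- function(spec, config = DetectConfig(),
                            depthGrid = seq(0.5, 8, by = 0.1),
                            recallFloor = 0.5, veinRadius = 1.5) {
  stopifnot(is(spec, "PhantomSpec"), is(config, "DetectConfig"))
  if (length(depthGrid) == 0) .fail("depthGrid is empty")
  if (is.unsorted(depthGrid)) .fail("depthGrid must be ascending")
  tolPx <- config@hitTolerance / spec@pixelPitch
  best <- 0
  for (i in seq_along(depthGrid)) {
    d <- depthGrid[i]
    specD <- spec
    specD@rngSeed <- spec@rngSeed + i   # fresh noise per depth
    vein <- .straightVein(specD, d, veinRadius)
    out <- renderPhantom(specD, list(vein))
    enh <- processFrame(phantomImage(out), CameraSettings(),
                        EnhanceConfig("dog1"))
    vm <- segmentVeins(enh, config)
    det <- do.call(rbind, centerlines(vm))
    if (is.null(det)) det <- matrix(integer(0), 0, 2)
    recall <- .centerlineRecall(truthCenterlinePixels(specD, list(vein)),
                                det, tolPx)
    if (is.na(recall) || recall < recallFloor) next
    if (.veinContrast(specD, vein, out) < config@contrastFloor) next
    best <- d
  }
  best
}
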