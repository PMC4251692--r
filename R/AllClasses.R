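#' @import methods
NULL

## Central value classes. All physical quantities are in millimetres; pixel
## coordinates are 1-based (row, col) as usual in R; the mapping between the
## two is fixed by the pixel pitch, with pixel (r, c) centred at
## x = (c - 0.5) * pitch, y = (r - 0.5) * pitch (x runs along columns).

#' NIRImage: a single-channel near-infrared intensity frame
#'
#' The unit of currency of the pipeline: a 2-D array of reflectance
#' intensities in \[0, 1\] plus the physical pixel pitch that anchors all
#' millimetre-denominated parameters (Gaussian scales, tolerances, vein
#' radii) to the pixel grid.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\], at least 8 x 8.
#' @slot pixelPitch physical size of one pixel in mm (> 0).
#' @slot frameIndex optional integer frame number within a stream (NA if
#'   the image is not part of a stream).
#'
#' @seealso [NIRImage()] for the constructor, [pixels()], [pixelPitch()].
#' @export
setClass("NIRImage",
  representation(pixels = "matrix", pixelPitch = "numeric",
                 frameIndex = "integer"),
  prototype(pixels = matrix(0, 8, 8), pixelPitch = 0.1,
            frameIndex = NA_integer_))

setValidity("NIRImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 8 || ncol(p) < 8) return("image must be at least 8 x 8 pixels")
  if (any(!is.finite(p))) return("pixel intensities must be finite")
  if (min(p) < 0 || max(p) > 1) return("pixel intensities must lie in [0, 1]")
  if (length(object@pixelPitch) != 1 || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    return("pixelPitch must be a single positive number")
  TRUE
})

#' Construct an NIRImage
#'
#' @param pixels numeric matrix of intensities in \[0, 1\].
#' @param pixelPitch pixel size in mm/pixel (default 0.1 mm).
#' @param frameIndex optional integer frame index.
#' @return An [NIRImage-class] object.
#' @examples
#' img <- NIRImage(matrix(runif(64 * 64), 64, 64), pixelPitch = 0.1)
#' dim(pixels(img))
#' @export
NIRImage <- function(pixels, pixelPitch = 0.1, frameIndex = NA_integer_) {
  new("NIRImage", pixels = pixels, pixelPitch = as.numeric(pixelPitch),
      frameIndex = as.integer(frameIndex))
}

#' VeinSegment: ground-truth geometry of one subcutaneous vein
#'
#' A vein is modelled as a tube of constant radius following a polyline
#' centerline in the image plane, lying at a constant depth below the skin
#' surface. Depths of clinical interest are a few millimetres; NIR devices
#' lose veins beyond roughly half a centimetre of tissue.
#'
#' @slot centerline n x 2 numeric matrix of (x, y) points in mm, n >= 2,
#'   consecutive points distinct.
#' @slot radius tube radius in mm (0 < radius <= 3).
#' @slot depth distance from skin surface to the top of the vessel in mm
#'   (0 <= depth <= 20).
#' @export
setClass("VeinSegment",
  representation(centerline = "matrix", radius = "numeric", depth = "numeric"))

setValidity("VeinSegment", function(object) {
  cl <- object@centerline
  if (!is.numeric(cl) || ncol(cl) != 2) return("centerline must be an n x 2 matrix")
  if (nrow(cl) < 2) return("centerline needs at least 2 points")
  if (any(!is.finite(cl))) return("centerline points must be finite")
  d <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  if (any(d == 0)) return("consecutive centerline points must be distinct")
  if (object@radius <= 0 || object@radius > 3)
    return("radius must be in (0, 3] mm")
  if (object@depth < 0 || object@depth > 20)
    return("depth must be in [0, 20] mm")
  TRUE
})

#' Construct a VeinSegment
#'
#' @param centerline n x 2 matrix of (x, y) mm points.
#' @param radius vein radius in mm.
#' @param depth depth of the vessel top below the skin in mm.
#' @return A [VeinSegment-class] object.
#' @examples
#' v <- VeinSegment(cbind(c(5, 30), c(10, 12)), radius = 1.5, depth = 2)
#' @export
VeinSegment <- function(centerline, radius, depth) {
  new("VeinSegment", centerline = centerline, radius = as.numeric(radius),
      depth = as.numeric(depth))
}

#' PhantomSpec: tissue, illumination and sensor parameters of a phantom
#'
#' Parameters of the forearm phantom renderer. The optical model is a
#' single-scatter Beer-Lambert surrogate: a vein at depth d attenuates the
#' backscattered signal by `maxAbsorption * exp(-(d + adiposeThickness) /
#' depthDecay)` over its projected footprint, and tissue scattering widens
#' the footprint with a Gaussian blur of sigma `blurBase + blurSlope * (d +
#' adiposeThickness)`. Illumination is the superposition of radial Gaussian
#' falloffs from four LEDs in a rectangular layout.
#'
#' @slot imageSize integer (rows, cols) in pixels.
#' @slot pixelPitch mm per pixel.
#' @slot baseIntensity source intensity I0 in \[0, 1\].
#' @slot backgroundReflectance tissue reflectance in \[0, 1\].
#' @slot maxAbsorption absorption contrast of a surface-contact vein, \[0, 1\].
#' @slot depthDecay exponential attenuation scale in mm (> 0).
#' @slot blurBase scatter blur at zero depth, mm (>= 0).
#' @slot blurSlope increase of scatter blur per mm of depth (>= 0).
#' @slot adiposeThickness extra tissue added to every vein's effective
#'   depth, mm (models subcutaneous fat).
#' @slot noiseSigma standard deviation of additive Gaussian sensor noise.
#' @slot ledPositions 4 x 2 matrix of LED (x, y) positions in mm.
#' @slot ledFalloff Gaussian radius of one LED's illumination, mm.
#' @slot hairDensity target fraction of pixels occluded by hair strokes.
#' @slot rngSeed integer seed controlling noise and hair placement.
#' @export
setClass("PhantomSpec",
  representation(imageSize = "integer", pixelPitch = "numeric",
                 baseIntensity = "numeric", backgroundReflectance = "numeric",
                 maxAbsorption = "numeric", depthDecay = "numeric",
                 blurBase = "numeric", blurSlope = "numeric",
                 adiposeThickness = "numeric", noiseSigma = "numeric",
                 ledPositions = "matrix", ledFalloff = "numeric",
                 hairDensity = "numeric", rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
  num1 <- function(x) length(x) == 1 && is.finite(x)
  if (length(object@imageSize) != 2 || any(object@imageSize < 8))
    return("imageSize must be two integers >= 8")
  if (!num1(object@pixelPitch) || object@pixelPitch <= 0)
    return("pixelPitch must be positive")
  for (s in c("baseIntensity", "backgroundReflectance", "maxAbsorption")) {
    v <- slot(object, s)
    if (!num1(v) || v < 0 || v > 1) return(paste(s, "must be in [0, 1]"))
  }
  if (!num1(object@depthDecay) || object@depthDecay <= 0)
    return("depthDecay must be > 0")
  if (!num1(object@blurBase) || object@blurBase < 0)
    return("blurBase must be >= 0")
  if (!num1(object@blurSlope) || object@blurSlope < 0)
    return("blurSlope must be >= 0")
  if (!num1(object@adiposeThickness) || object@adiposeThickness < 0)
    return("adiposeThickness must be >= 0")
  if (!num1(object@noiseSigma) || object@noiseSigma < 0)
    return("noiseSigma must be >= 0")
  if (!is.numeric(object@ledPositions) || ncol(object@ledPositions) != 2 ||
      nrow(object@ledPositions) < 1 || any(!is.finite(object@ledPositions)))
    return("ledPositions must be a finite n x 2 matrix (n >= 1)")
  if (!num1(object@ledFalloff) || object@ledFalloff <= 0)
    return("ledFalloff must be > 0")
  if (!num1(object@hairDensity) || object@hairDensity < 0 ||
      object@hairDensity > 1)
    return("hairDensity must be in [0, 1]")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults render a 256 x 384 pixel (25.6 x 38.4 mm) forearm patch at
#' 0.1 mm pitch, calibrated so that the maximum visible vein depth of the
#' default detection pipeline falls near 5 mm, the working range reported
#' for handheld NIR vein finders. The four LEDs sit at the corners of a
#' 50 x 35 mm rectangle centred on the field of view.
#'
#' @param imageSize integer (rows, cols), default c(256, 384).
#' @param pixelPitch mm per pixel, default 0.1.
#' @param baseIntensity source intensity I0, default 1.0.
#' @param backgroundReflectance tissue reflectance, default 0.6.
#' @param maxAbsorption surface-contact vein contrast, default 0.85.
#' @param depthDecay Beer-Lambert attenuation scale in mm, default 2.5.
#' @param blurBase scatter blur at zero depth in mm, default 0.3.
#' @param blurSlope scatter blur slope (mm blur per mm depth), default 0.35.
#' @param adiposeThickness extra effective depth in mm, default 0.
#' @param noiseSigma sensor noise sd, default 0.01.
#' @param ledPositions 4 x 2 matrix of LED positions in mm; default a
#'   50 x 35 mm rectangle centred on the field.
#' @param ledFalloff LED Gaussian radius in mm, default 30.
#' @param hairDensity fraction of pixels occluded by hair, default 0.
#' @param rngSeed integer seed, default 1.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(imageSize = c(128, 192))
#' fieldOfView(spec)  # mm
#' @export
PhantomSpec <- function(imageSize = c(256L, 384L), pixelPitch = 0.1,
                        baseIntensity = 1.0, backgroundReflectance = 0.6,
                        maxAbsorption = 0.85, depthDecay = 2.5,
                        blurBase = 0.3, blurSlope = 0.35,
                        adiposeThickness = 0, noiseSigma = 0.01,
                        ledPositions = NULL, ledFalloff = 30,
                        hairDensity = 0, rngSeed = 1L) {
  imageSize <- as.integer(imageSize)
  if (is.null(ledPositions)) {
    cx <- imageSize[2] * pixelPitch / 2
    cy <- imageSize[1] * pixelPitch / 2
    ledPositions <- cbind(cx + c(-25, 25, 25, -25), cy + c(-17.5, -17.5, 17.5, 17.5))
  }
  new("PhantomSpec", imageSize = imageSize, pixelPitch = pixelPitch,
      baseIntensity = baseIntensity,
      backgroundReflectance = backgroundReflectance,
      maxAbsorption = maxAbsorption, depthDecay = depthDecay,
      blurBase = blurBase, blurSlope = blurSlope,
      adiposeThickness = adiposeThickness, noiseSigma = noiseSigma,
      ledPositions = ledPositions, ledFalloff = ledFalloff,
      hairDensity = hairDensity, rngSeed = as.integer(rngSeed))
}

#' PhantomOutput: a rendered phantom with its ground truth
#'
#' @slot image the rendered [NIRImage-class].
#' @slot truthMask logical matrix, TRUE exactly on the union of projected
#'   vein footprints (unblurred).
#' @slot depthMap per-pixel vein depth in mm; `Inf` where no vein projects.
#' @slot veins list of [VeinSegment-class] used in the render.
#' @export
setClass("PhantomOutput",
  representation(image = "NIRImage", truthMask = "matrix",
                 depthMap = "matrix", veins = "list"))

setValidity("PhantomOutput", function(object) {
  d <- dim(object@image@pixels)
  if (!identical(dim(object@truthMask), d)) return("truthMask dims differ from image")
  if (!identical(dim(object@depthMap), d)) return("depthMap dims differ from image")
  if (!is.logical(object@truthMask)) return("truthMask must be logical")
  if (!all(is.infinite(object@depthMap[!object@truthMask])))
    return("depthMap must be Inf outside the truth mask")
  TRUE
})

#' CameraSettings: multiplicative capture-layer transform
#'
#' Gain and exposure act multiplicatively on intensity; contrast is a
#' linear slope about the mid-gray pivot 0.5:
#' `out = clip01((in * exposure * gain - 0.5) * contrast + 0.5)`.
#'
#' @slot gain multiplicative gain (> 0).
#' @slot exposure multiplicative exposure factor (> 0).
#' @slot contrast linear contrast slope about 0.5 (> 0).
#' @export
setClass("CameraSettings",
  representation(gain = "numeric", exposure = "numeric", contrast = "numeric"),
  prototype(gain = 1, exposure = 1, contrast = 1))

setValidity("CameraSettings", function(object) {
  for (s in c("gain", "exposure", "contrast")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      return(paste(s, "must be a single finite positive number"))
  }
  TRUE
})

#' Construct CameraSettings
#'
#' @param gain,exposure,contrast positive finite factors; (1, 1, 1) is the
#'   identity transform.
#' @return A [CameraSettings-class] object.
#' @examples
#' identitySettings <- CameraSettings()
#' bright <- CameraSettings(gain = 2)
#' @export
CameraSettings <- function(gain = 1, exposure = 1, contrast = 1) {
  new("CameraSettings", gain = as.numeric(gain), exposure = as.numeric(exposure),
      contrast = as.numeric(contrast))
}

#' EnhanceConfig: enhancement-stage configuration
#'
#' Selects the visualization mode and its scales. Scales are given in mm
#' and converted to pixels through the image's pixel pitch, so results are
#' resolution invariant. Modes:
#' \describe{
#'   \item{raw-contrast}{percentile contrast stretch only.}
#'   \item{dog1, dog2}{difference of Gaussians at a fine (0.4/2.0 mm) or
#'     coarse (0.8/4.0 mm) scale pair.}
#'   \item{log1}{Laplacian of Gaussian, sigma 1.0 mm.}
#'   \item{log2}{raw 4-neighbour Laplacian (sigma 0).}
#' }
#'
#' @slot mode one of "raw-contrast", "dog1", "dog2", "log1", "log2".
#' @slot sigmaNarrow,sigmaWide DoG scales in mm (0 < narrow < wide).
#' @slot logSigma Laplacian pre-smoothing sigma in mm (>= 0; 0 = raw).
#' @slot stretchPercentiles length-2 numeric (low, high) percentiles for
#'   the contrast stretch, 0 <= low < high <= 100.
#' @slot roi optional integer rectangle (row0, col0, row1, col1), 0-based
#'   half-open in pixels; length 0 means whole frame.
#' @export
setClass("EnhanceConfig",
  representation(mode = "character", sigmaNarrow = "numeric",
                 sigmaWide = "numeric", logSigma = "numeric",
                 stretchPercentiles = "numeric", roi = "integer"))

.enhanceModes <- c("raw-contrast", "dog1", "dog2", "log1", "log2")

setValidity("EnhanceConfig", function(object) {
  if (!object@mode %in% .enhanceModes)
    return(paste("mode must be one of:", paste(.enhanceModes, collapse = ", ")))
  if (!(object@sigmaNarrow > 0 && object@sigmaNarrow < object@sigmaWide))
    return("require 0 < sigmaNarrow < sigmaWide")
  if (object@logSigma < 0) return("logSigma must be >= 0")
  p <- object@stretchPercentiles
  if (length(p) != 2 || p[1] < 0 || p[2] > 100 || p[1] >= p[2])
    return("stretchPercentiles must satisfy 0 <= low < high <= 100")
  if (!length(object@roi) %in% c(0L, 4L))
    return("roi must be empty or (row0, col0, row1, col1)")
  if (length(object@roi) == 4L && (any(object@roi < 0) ||
      object@roi[3] <= object@roi[1] || object@roi[4] <= object@roi[2]))
    return("roi must be a nonempty half-open rectangle")
  TRUE
})

#' Construct an EnhanceConfig
#'
#' Unset scales are filled from the mode's preset: dog1 = (0.4, 2.0) mm,
#' tuned to 1-2 mm vein radii; dog2 = (0.8, 4.0) mm; log1 sigma = 1.0 mm;
#' log2 sigma = 0 (raw 4-neighbour Laplacian).
#'
#' @param mode visualization mode (see [EnhanceConfig-class]).
#' @param sigmaNarrow,sigmaWide DoG scales in mm; defaults per mode.
#' @param logSigma Laplacian smoothing sigma in mm; default per mode.
#' @param stretchPercentiles contrast-stretch percentiles, default c(1, 99).
#' @param roi optional 0-based half-open rectangle (row0, col0, row1, col1).
#' @return An [EnhanceConfig-class] object.
#' @examples
#' EnhanceConfig("dog1")
#' EnhanceConfig("dog2", roi = c(0, 0, 64, 64))
#' @export
EnhanceConfig <- function(mode = "dog1", sigmaNarrow = NULL, sigmaWide = NULL,
                          logSigma = NULL, stretchPercentiles = c(1, 99),
                          roi = integer(0)) {
  mode <- match.arg(tolower(mode), .enhanceModes)
  if (is.null(sigmaNarrow)) sigmaNarrow <- if (mode == "dog2") 0.8 else 0.4
  if (is.null(sigmaWide))   sigmaWide   <- if (mode == "dog2") 4.0 else 2.0
  if (is.null(logSigma))    logSigma    <- if (mode == "log2") 0.0 else 1.0
  new("EnhanceConfig", mode = mode, sigmaNarrow = as.numeric(sigmaNarrow),
      sigmaWide = as.numeric(sigmaWide), logSigma = as.numeric(logSigma),
      stretchPercentiles = as.numeric(stretchPercentiles),
      roi = as.integer(roi))
}

#' DetectConfig: segmentation and marker-hit parameters
#'
#' @slot thresholdQuantile fraction of the darkest ridge response kept as
#'   candidate vein pixels (in \[0, 0.5)).
#' @slot minComponentArea connected components smaller than this many
#'   pixels are discarded.
#' @slot morphRadius radius (pixels) of the disc used for morphological
#'   opening and closing; 0 disables morphology.
#' @slot hitTolerance marker-hit distance tolerance in mm.
#' @slot minCenterlineLength minimum skeleton arc length in mm for a
#'   component to count as a distinct vein.
#' @slot contrastFloor minimum Michelson contrast for a vein to count as
#'   visible in the depth sweep.
#' @export
setClass("DetectConfig",
  representation(thresholdQuantile = "numeric", minComponentArea = "numeric",
                 morphRadius = "numeric", hitTolerance = "numeric",
                 minCenterlineLength = "numeric", contrastFloor = "numeric"))

setValidity("DetectConfig", function(object) {
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      return(paste(s, "must be a single finite non-negative number"))
  }
  if (object@thresholdQuantile >= 0.5)
    return("thresholdQuantile must be < 0.5")
  TRUE
})

#' Construct a DetectConfig
#'
#' The hit tolerance defaults to 2 mm, about the radius of a typical
#' antecubital vein: a marked point within 2 mm of segmented vein tissue
#' counts as lying over the vein. This distance rule is a computational
#' proxy for the visual adjudication a supervising clinician would perform.
#'
#' The contrast floor is the calibration knob of the depth-visibility
#' sweep: 0.033 places [maxVisibleDepth()]'s answer near 4.8 mm under the
#' default phantom optics, the penetration depth reported for handheld NIR
#' vein finders validated against ultrasound.
#'
#' @param thresholdQuantile darkest-fraction threshold, default 0.10.
#' @param minComponentArea minimum component area in pixels, default 40.
#' @param morphRadius disc radius for open/close in pixels, default 1.
#' @param hitTolerance marker-hit tolerance in mm, default 2.
#' @param minCenterlineLength minimum centerline length in mm, default 5.
#' @param contrastFloor Michelson-contrast floor, default 0.033.
#' @return A [DetectConfig-class] object.
#' @examples
#' DetectConfig()
#' @export
DetectConfig <- function(thresholdQuantile = 0.10, minComponentArea = 40,
                         morphRadius = 1, hitTolerance = 2,
                         minCenterlineLength = 5, contrastFloor = 0.033) {
  new("DetectConfig", thresholdQuantile = thresholdQuantile,
      minComponentArea = as.numeric(minComponentArea),
      morphRadius = as.numeric(morphRadius),
      hitTolerance = as.numeric(hitTolerance),
      minCenterlineLength = as.numeric(minCenterlineLength),
      contrastFloor = as.numeric(contrastFloor))
}

#' VeinMask: binary segmentation with centerlines
#'
#' @slot mask logical matrix, TRUE on segmented vein pixels.
#' @slot centerlines list of m x 2 integer matrices of (row, col) skeleton
#'   pixel polylines, one per connected component; every centerline pixel
#'   lies inside the mask.
#' @slot sourceFrame the [NIRImage-class] the mask was derived from.
#' @export
setClass("VeinMask",
  representation(mask = "matrix", centerlines = "list",
                 sourceFrame = "NIRImage"))

setValidity("VeinMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!identical(dim(object@mask), dim(object@sourceFrame@pixels)))
    return("mask dims must match the source frame")
  for (cl in object@centerlines) {
    if (!is.matrix(cl) || ncol(cl) != 2) return("centerlines must be m x 2 matrices")
    if (nrow(cl) && !all(object@mask[cl])) return("centerline pixels must lie in mask")
  }
  TRUE
})

#' Construct a VeinMask
#'
#' @param mask logical matrix.
#' @param centerlines list of m x 2 integer (row, col) matrices.
#' @param sourceFrame the [NIRImage-class] the mask belongs to.
#' @return A [VeinMask-class] object.
#' @export
VeinMask <- function(mask, centerlines = list(), sourceFrame) {
  new("VeinMask", mask = mask, centerlines = centerlines,
      sourceFrame = sourceFrame)
}
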