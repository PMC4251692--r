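## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' Accessors for pipeline objects
#'
#' @param object an object of one of the package's S4 classes.
#' @return The requested component: `pixels()` the intensity matrix,
#'   `pixelPitch()` the mm/pixel scale, `frameIndex()` the frame number,
#'   `phantomImage()` the rendered [NIRImage-class], `truthMask()` the
#'   ground-truth footprint mask, `depthMap()` the per-pixel depth map (mm,
#'   `Inf` off-vein), `veins()` the list of [VeinSegment-class],
#'   `veinMask()` the logical segmentation mask, `centerlines()` the list
#'   of (row, col) skeleton polylines, `fieldOfView()` the (width, height)
#'   of the field in mm.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setGeneric("frameIndex", function(object) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))
#' @rdname accessors
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))
#' @rdname accessors
#' @export
setGeneric("depthMap", function(object) standardGeneric("depthMap"))
#' @rdname accessors
#' @export
setGeneric("veins", function(object) standardGeneric("veins"))
#' @rdname accessors
#' @export
setGeneric("veinMask", function(object) standardGeneric("veinMask"))
#' @rdname accessors
#' @export
setGeneric("centerlines", function(object) standardGeneric("centerlines"))
#' @rdname accessors
#' @export
setGeneric("fieldOfView", function(object) standardGeneric("fieldOfView"))

#' @rdname accessors
setMethod("pixels", "NIRImage", function(object) object@pixels)
#' @rdname accessors
setMethod("pixelPitch", "NIRImage", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("frameIndex", "NIRImage", function(object) object@frameIndex)
#' @rdname accessors
setMethod("pixelPitch", "PhantomSpec", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("phantomImage", "PhantomOutput", function(object) object@image)
#' @rdname accessors
setMethod("truthMask", "PhantomOutput", function(object) object@truthMask)
#' @rdname accessors
setMethod("depthMap", "PhantomOutput", function(object) object@depthMap)
#' @rdname accessors
setMethod("veins", "PhantomOutput", function(object) object@veins)
#' @rdname accessors
setMethod("veinMask", "VeinMask", function(object) object@mask)
#' @rdname accessors
setMethod("centerlines", "VeinMask", function(object) object@centerlines)
#' @rdname accessors
setMethod("pixelPitch", "VeinMask",
          function(object) object@sourceFrame@pixelPitch)

#' @rdname accessors
setMethod("fieldOfView", "PhantomSpec", function(object)
  c(width = object@imageSize[2] * object@pixelPitch,
    height = object@imageSize[1] * object@pixelPitch))

setMethod("show", "NIRImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("NIRImage %d x %d px (%.1f x %.1f mm), range [%.3f, %.3f]%s\n",
              d[1], d[2], d[1] * object@pixelPitch, d[2] * object@pixelPitch,
              min(object@pixels), max(object@pixels),
              if (is.na(object@frameIndex)) ""
              else sprintf(", frame %d", object@frameIndex)))
})

setMethod("show", "VeinSegment", function(object) {
  cat(sprintf("VeinSegment: %d points, radius %.2f mm, depth %.2f mm\n",
              nrow(object@centerline), object@radius, object@depth))
})

setMethod("show", "PhantomSpec", function(object) {
  fov <- fieldOfView(object)
  cat(sprintf(paste0(
    "PhantomSpec %d x %d px @ %.3f mm/px (%.1f x %.1f mm)\n",
    "  I0 %.2f, R_bg %.2f, A_max %.2f, decay %.2f mm\n",
    "  blur %.2f + %.2f*d mm, adipose %.2f mm, noise sd %.3f\n",
    "  %d LEDs, falloff %.1f mm, hair %.2f, seed %d\n"),
    object@imageSize[1], object@imageSize[2], object@pixelPitch,
    fov["width"], fov["height"],
    object@baseIntensity, object@backgroundReflectance, object@maxAbsorption,
    object@depthDecay, object@blurBase, object@blurSlope,
    object@adiposeThickness, object@noiseSigma,
    nrow(object@ledPositions), object@ledFalloff, object@hairDensity,
    object@rngSeed))
})

setMethod("show", "PhantomOutput", function(object) {
  cat(sprintf("PhantomOutput: %d veins, %.1f%% of pixels in truth mask\n",
              length(object@veins), 100 * mean(object@truthMask)))
  show(object@image)
})

setMethod("show", "CameraSettings", function(object) {
  cat(sprintf("CameraSettings: gain %.2f, exposure %.2f, contrast %.2f\n",
              object@gain, object@exposure, object@contrast))
})

setMethod("show", "EnhanceConfig", function(object) {
  cat(sprintf("EnhanceConfig: mode %s, DoG (%.2f, %.2f) mm, LoG %.2f mm, stretch (%g, %g)%%%s\n",
              object@mode, object@sigmaNarrow, object@sigmaWide,
              object@logSigma, object@stretchPercentiles[1],
              object@stretchPercentiles[2],
              if (length(object@roi)) sprintf(", roi [%d,%d)x[%d,%d)",
                object@roi[1], object@roi[3], object@roi[2], object@roi[4])
              else ""))
})

setMethod("show", "DetectConfig", function(object) {
  cat(sprintf(paste0("DetectConfig: quantile %.2f, min area %g px, morph %g px,\n",
                     "  hit tol %.1f mm, min centerline %.1f mm, contrast floor %.3f\n"),
              object@thresholdQuantile, object@minComponentArea,
              object@morphRadius, object@hitTolerance,
              object@minCenterlineLength, object@contrastFloor))
})

setMethod("show", "VeinMask", function(object) {
  cat(sprintf("VeinMask: %.1f%% foreground, %d centerline(s)\n",
              100 * mean(object@mask), length(object@centerlines)))
})
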