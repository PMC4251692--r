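## Enhancement operators: contrast stretch, DoG, Laplacian, ROI, pipeline.

## Symmetric renormalization of a signed, zero-centred response: 0 maps to
## 0.5 and the largest absolute response to 0 or 1, preserving sign
## structure (dark, vein-like responses land below 0.5).
.signedNormalize <- function(resp) {
  m <- max(abs(resp))
  # responses below 1e-12 are FFT roundoff, not signal
  if (m < 1e-12) return(matrix(0.5, nrow(resp), ncol(resp)))
  .clip01(0.5 + 0.5 * resp / m)
}

#' Percentile contrast stretch
#'
#' Linearly rescales intensities so the `low`-th percentile maps to 0 and
#' the `high`-th to 1, clipping the tails. NIR capture under strong LED
#' illumination concentrates tissue intensities in a narrow band; the
#' stretch restores usable dynamic range before ridge operators run.
#' Constant (degenerate) frames are returned unchanged.
#'
#' @param image an [NIRImage-class].
#' @param percentiles length-2 numeric (low, high), 0 <= low < high <= 100.
#' @return An [NIRImage-class].
#' @examples
#' img <- NIRImage(matrix(seq(0.4, 0.6, length.out = 256), 16, 16))
#' range(pixels(contrastEnhance(img, c(0, 100))))
#' @export
contrastEnhance <- function(image, percentiles = c(1, 99)) {
  stopifnot(is(image, "NIRImage"))
  if (length(percentiles) != 2 || percentiles[1] >= percentiles[2] ||
      percentiles[1] < 0 || percentiles[2] > 100)
    .fail("percentiles must satisfy 0 <= low < high <= 100")
  px <- pixels(image)
  q <- stats::quantile(px, percentiles / 100, names = FALSE)
  if (diff(q) < .Machine$double.eps) return(image)
  NIRImage(.clip01((px - q[1]) / (q[2] - q[1])),
           pixelPitch = pixelPitch(image), frameIndex = frameIndex(image))
}

#' Difference of Gaussians
#'
#' Band-pass ridge operator: `G(sigmaNarrow) * I - G(sigmaWide) * I`
#' (convolutions with reflect padding), then symmetric renormalization to
#' \[0, 1\] about 0.5. Dark curvilinear structures between the two scales
#' — subcutaneous veins — come out below 0.5; the smooth illumination
#' gradient and constant offsets are rejected.
#'
#' Sigmas are in mm and converted to pixels via the image's pixel pitch.
#'
#' @param image an [NIRImage-class].
#' @param sigmaNarrow,sigmaWide Gaussian scales in mm, 0 < narrow < wide.
#' @param normalize if FALSE, return the raw signed response matrix
#'   (linear in the input) instead of a renormalized image.
#' @return An [NIRImage-class], or a numeric matrix if `normalize = FALSE`.
#' @examples
#' img <- NIRImage(matrix(0.5, 32, 32))
#' unique(as.vector(pixels(differenceOfGaussians(img, 0.4, 2))))  # 0.5
#' @export
differenceOfGaussians <- function(image, sigmaNarrow = 0.4, sigmaWide = 2.0,
                                  normalize = TRUE) {
  stopifnot(is(image, "NIRImage"))
  if (!(sigmaNarrow > 0 && sigmaNarrow < sigmaWide))
    .fail("require 0 < sigmaNarrow < sigmaWide (mm)")
  px <- pixels(image)
  pitch <- pixelPitch(image)
  resp <- .gaussBlurReflect(px, sigmaNarrow / pitch) -
    .gaussBlurReflect(px, sigmaWide / pitch)
  if (!normalize) return(resp)
  NIRImage(.signedNormalize(resp), pixelPitch = pitch,
           frameIndex = frameIndex(image))
}

#' Laplacian / Laplacian of Gaussian
#'
#' Second-derivative ridge operator. With `logSigma = 0` the raw
#' 4-neighbour discrete Laplacian `[[0,1,0],[1,-4,1],[0,1,0]]` is applied;
#' with `logSigma > 0` the image is first Gaussian-smoothed at that scale
#' (mm), giving a Laplacian-of-Gaussian response. Constant and planar-ramp
#' images are annihilated (interior response 0). Renormalization as in
#' [differenceOfGaussians()].
#'
#' @param image an [NIRImage-class].
#' @param logSigma smoothing sigma in mm; >= 0.
#' @param normalize if FALSE, return the raw signed response matrix.
#' @return An [NIRImage-class], or a numeric matrix if `normalize = FALSE`.
#' @examples
#' ramp <- NIRImage(outer(seq(0, 0.5, length.out = 16),
#'                        seq(0, 0.5, length.out = 16), "+"))
#' r <- laplacianFilter(ramp, 0, normalize = FALSE)
#' max(abs(r[2:15, 2:15]))  # ~0 on the interior
#' @export
laplacianFilter <- function(image, logSigma = 1.0, normalize = TRUE) {
  stopifnot(is(image, "NIRImage"))
  if (length(logSigma) != 1 || !is.finite(logSigma) || logSigma < 0)
    .fail("logSigma must be a single non-negative number (mm)")
  px <- pixels(image)
  pitch <- pixelPitch(image)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  sm <- .gaussBlurReflect(px, logSigma / pitch)
  resp <- .convolveReflect(sm, lap)
  if (!normalize) return(resp)
  NIRImage(.signedNormalize(resp), pixelPitch = pitch,
           frameIndex = frameIndex(image))
}

#' Apply an operator inside a region of interest
#'
#' Crops the ROI, runs `stage` on the crop (whose own reflect padding then
#' acts at the ROI borders) and pastes the result back; pixels outside the
#' ROI are returned bit-identical to the input.
#'
#' @param image an [NIRImage-class].
#' @param roi integer (row0, col0, row1, col1), 0-based half-open in
#'   pixels; NULL or empty means whole frame.
#' @param stage a function mapping [NIRImage-class] to [NIRImage-class].
#' @return An [NIRImage-class].
#' @examples
#' img <- NIRImage(matrix(runif(128 * 128), 128, 128))
#' out <- applyROI(img, c(10, 10, 60, 60),
#'                 function(x) differenceOfGaussians(x, 0.4, 2))
#' identical(pixels(out)[100, ], pixels(img)[100, ])
#' @export
applyROI <- function(image, roi, stage) {
  stopifnot(is(image, "NIRImage"), is.function(stage))
  if (is.null(roi) || length(roi) == 0) return(stage(image))
  if (length(roi) != 4) .fail("roi must be (row0, col0, row1, col1)")
  d <- dim(pixels(image))
  roi <- as.integer(roi)
  if (any(roi < 0) || roi[3] > d[1] || roi[4] > d[2] ||
      roi[3] <= roi[1] || roi[4] <= roi[2])
    .fail("roi [%d,%d)x[%d,%d) outside %d x %d image",
          roi[1], roi[3], roi[2], roi[4], d[1], d[2])
  rows <- (roi[1] + 1L):roi[3]
  cols <- (roi[2] + 1L):roi[4]
  crop <- NIRImage(pixels(image)[rows, cols, drop = FALSE],
                   pixelPitch = pixelPitch(image))
  proc <- stage(crop)
  out <- pixels(image)
  out[rows, cols] <- pixels(proc)
  NIRImage(out, pixelPitch = pixelPitch(image), frameIndex = frameIndex(image))
}

.modeStage <- function(config) {
  switch(config@mode,
    "raw-contrast" = NULL,
    "dog1" = ,
    "dog2" = function(x) differenceOfGaussians(x, config@sigmaNarrow,
                                               config@sigmaWide),
    "log1" = ,
    "log2" = function(x) laplacianFilter(x, config@logSigma))
}

#' Process one frame through the capture-and-enhancement pipeline
#'
#' Composition: [applySettings()] (capture emulation), then global
#' [contrastEnhance()] at the config's stretch percentiles, then the
#' config's mode operator restricted to the ROI (if any). Deterministic.
#'
#' @param image an [NIRImage-class].
#' @param settings a [CameraSettings-class] (default identity).
#' @param config an [EnhanceConfig-class].
#' @return The enhanced [NIRImage-class].
#' @examples
#' img <- NIRImage(matrix(runif(64 * 64), 64, 64))
#' out <- processFrame(img, CameraSettings(), EnhanceConfig("dog1"))
#' @export
processFrame <- function(image, settings = CameraSettings(),
                         config = EnhanceConfig()) {
  stopifnot(is(image, "NIRImage"), is(config, "EnhanceConfig"))
  validObject(config)
  x <- applySettings(image, settings)
  x <- contrastEnhance(x, config@stretchPercentiles)
  stage <- .modeStage(config)
  if (is.null(stage)) return(x)
  applyROI(x, if (length(config@roi)) config@roi else NULL, stage)
}

#' Process a stream of frames
#'
#' Applies [processFrame()] to each frame independently (the pipeline is
#' stateless) and reports the measured throughput. The frame rate is
#' informational: it characterizes this machine, not any capture device.
#'
#' @param frames nonempty list of [NIRImage-class].
#' @param settings a [CameraSettings-class].
#' @param config an [EnhanceConfig-class].
#' @return A list with `frames` (the processed list) and `report`
#'   (`frameCount`, `elapsedSeconds`, `framesPerSecond`).
#' @examples
#' fr <- replicate(3, NIRImage(matrix(runif(64^2), 64, 64)))
#' res <- processStream(fr, config = EnhanceConfig("raw-contrast"))
#' res$report$frameCount
#' @export
processStream <- function(frames, settings = CameraSettings(),
                          config = EnhanceConfig()) {
  if (length(frames) == 0) .fail("frame stream is empty")
  t0 <- proc.time()[["elapsed"]]
  out <- lapply(frames, processFrame, settings = settings, config = config)
  dt <- proc.time()[["elapsed"]] - t0
  list(frames = out,
       report = list(frameCount = length(out), elapsedSeconds = dt,
                     framesPerSecond = if (dt > 0) length(out) / dt else NA_real_))
}
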