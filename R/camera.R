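## Capture-settings layer: gain/exposure/contrast and named profiles.

#' Apply capture settings to a frame
#'
#' Gain and exposure multiply the intensity; contrast is a linear slope
#' about mid-gray: `out = clip01((in * exposure * gain - 0.5) * contrast +
#' 0.5)`. With identity settings (1, 1, 1) the frame is returned pixelwise
#' unchanged.
#'
#' @param image an [NIRImage-class].
#' @param settings a [CameraSettings-class].
#' @return An [NIRImage-class] of the same dimensions.
#' @examples
#' img <- NIRImage(matrix(0.25, 16, 16))
#' max(pixels(applySettings(img, CameraSettings(gain = 2))))  # 0.5
#' @export
applySettings <- function(image, settings) {
  stopifnot(is(image, "NIRImage"), is(settings, "CameraSettings"))
  validObject(settings)
  out <- pixels(image) * (settings@exposure * settings@gain)
  # skip the pivot arithmetic at unit contrast so identity settings are
  # exact to the bit
  if (settings@contrast != 1)
    out <- (out - 0.5) * settings@contrast + 0.5
  NIRImage(.clip01(out), pixelPitch = pixelPitch(image),
           frameIndex = frameIndex(image))
}

.profileNames <- c("Low light", "Medium light", "Very bright", "LED profile",
                   "Custom")

#' Packaged capture profiles
#'
#' Reads the named capture presets shipped with the package (or a
#' user-supplied JSON file with the same structure). The numeric values
#' are uncalibrated placeholders: the field devices these presets emulate
#' derive theirs from bench measurements under each lighting condition,
#' which a desk toolkit cannot repeat.
#'
#' @param file optional path to a profiles JSON (named objects with gain,
#'   exposure, contrast); defaults to the packaged presets.
#' @return Named list of [CameraSettings-class], one per profile.
#' @examples
#' names(cameraProfiles())
#' @export
cameraProfiles <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "camera_profiles.json", package = "veinviz",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(file)
  lapply(raw, function(p)
    CameraSettings(gain = p$gain %||% 1, exposure = p$exposure %||% 1,
                   contrast = p$contrast %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a capture profile by name
#'
#' The five named profiles are "Low light", "Medium light", "Very bright",
#' "LED profile" and "Custom" (case-insensitive). "Custom" carries no
#' preset and requires explicit `custom` settings.
#'
#' @param name profile name (case-insensitive).
#' @param custom a [CameraSettings-class], required when `name` is
#'   "Custom".
#' @param file optional profiles JSON passed to [cameraProfiles()].
#' @return The profile's [CameraSettings-class].
#' @examples
#' profileSettings("Low light")
#' profileSettings("custom", custom = CameraSettings(gain = 1.5))
#' @export
profileSettings <- function(name, custom = NULL, file = NULL) {
  if (length(name) != 1 || !is.character(name))
    .fail("profile name must be a single string")
  idx <- match(tolower(name), tolower(.profileNames))
  if (is.na(idx))
    .fail("unknown profile \"%s\"; valid profiles: %s", name,
          paste(.profileNames, collapse = ", "))
  canonical <- .profileNames[idx]
  if (canonical == "Custom") {
    if (is.null(custom))
      .fail("profile \"Custom\" requires explicit CameraSettings")
    stopifnot(is(custom, "CameraSettings"))
    return(custom)
  }
  profiles <- cameraProfiles(file)
  p <- profiles[[canonical]]
  if (is.null(p)) .fail("profile \"%s\" missing from profiles file", canonical)
  p
}
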