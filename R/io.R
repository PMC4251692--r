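## File I/O: images (PNG/TIFF), vein geometry and config JSON, study CSVs.

#' Read a grayscale image as an NIRImage
#'
#' PNG and TIFF are supported; multi-channel images are averaged to one
#' channel. Intensities are returned in \[0, 1\] regardless of source bit
#' depth.
#'
#' @param path image path (.png, .tif/.tiff).
#' @param pixelPitch mm/pixel to attach (not stored in either format).
#' @return An [NIRImage-class].
#' @export
readNIRImage <- function(path, pixelPitch = 0.1) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .fail("unsupported image format: .%s", ext))
  if (length(dim(arr)) == 3) arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])),
                                              drop = FALSE], c(1, 2), mean)
  NIRImage(.clip01(arr), pixelPitch = pixelPitch)
}

#' Write an NIRImage (or matrix) to disk
#'
#' PNG output is 8-bit; TIFF output is 16-bit for intensity images and
#' 32-bit float for depth maps (`float = TRUE`). Float TIFF storage is
#' only defined on \[0, 1\], so depth values (mm) are stored divided by
#' 64, with non-finite (off-vein) pixels stored as exactly 1.0 — i.e. a
#' nominal 64 mm, far beyond any renderable vein depth; [readDepthMap()]
#' reverses both.
#'
#' @param image an [NIRImage-class] or numeric matrix.
#' @param path destination (.png or .tif/.tiff).
#' @param float write a 32-bit float depth TIFF (mm / 64 encoding).
#' @return The path, invisibly.
#' @export
writeNIRImage <- function(image, path, float = FALSE) {
  m <- if (is(image, "NIRImage")) pixels(image) else image
  ext <- tolower(tools::file_ext(path))
  if (float) {
    if (!ext %in% c("tif", "tiff")) .fail("float output requires TIFF")
    mf <- m / 64
    mf[!is.finite(mf) | mf > 1] <- 1
    tiff::writeTIFF(mf, path, bits.per.sample = 32L, reduce = FALSE)
  } else if (ext == "png") {
    png::writePNG(.clip01(m), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(.clip01(m), path, bits.per.sample = 16L)
  } else .fail("unsupported image format: .%s", ext)
  invisible(path)
}

#' Read a depth-map TIFF written by [writeNIRImage()]
#'
#' @param path 32-bit float TIFF path.
#' @return Numeric matrix of depths in mm, `Inf` off-vein.
#' @export
readDepthMap <- function(path) {
  m <- tiff::readTIFF(path) * 64
  m[m >= 63.9] <- Inf   # float32 roundoff guard on the sentinel
  m
}

#' Serialize / restore vein segments as JSON
#'
#' @param veins list of [VeinSegment-class].
#' @param path JSON path.
#' @return `writeVeins`: the path, invisibly. `readVeins`: a list of
#'   [VeinSegment-class].
#' @export
writeVeins <- function(veins, path) {
  jsonlite::write_json(lapply(veins, function(v)
    list(centerline = unname(v@centerline), radius = v@radius,
         depth = v@depth)), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeVeins
#' @export
readVeins <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(v) {
    cl <- v$centerline
    if (is.list(cl)) cl <- do.call(rbind, cl)
    VeinSegment(matrix(as.numeric(cl), ncol = 2), radius = v$radius,
                depth = v$depth)
  })
}

#' Build a PhantomSpec from a JSON config
#'
#' The JSON keys mirror the [PhantomSpec()] argument names; absent keys
#' keep their defaults.
#'
#' @param path JSON path (or a parsed named list).
#' @return A [PhantomSpec-class].
#' @export
phantomSpecFromJSON <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  args <- cfg[intersect(names(cfg), names(formals(PhantomSpec)))]
  if (!is.null(args$ledPositions))
    args$ledPositions <- matrix(as.numeric(unlist(args$ledPositions)),
                                ncol = 2, byrow = FALSE)
  do.call(PhantomSpec, args)
}

#' Read study CSV inputs
#'
#' `readAttempts`: venipuncture attempt records
#' (`clinician_id,subject_id,bmi_class,row,col,hit`). `readLikert`: Likert
#' responses (`id` plus one column per item). `readSUS`: SUS responses
#' (`id,q1..q10`). `readVeinCounts`: per-patient additional-vein counts
#' (`patient_id,difficult_flag,additional_veins`).
#'
#' @param path CSV path.
#' @return A data.frame with typed columns.
#' @name studyIO
NULL

#' @rdname studyIO
#' @export
readAttempts <- function(path) {
  df <- utils::read.csv(path, colClasses = c(bmi_class = "character"))
  df$hit <- as.logical(df$hit)
  df
}

#' @rdname studyIO
#' @export
readLikert <- function(path) utils::read.csv(path)

#' @rdname studyIO
#' @export
readSUS <- function(path) utils::read.csv(path)

#' @rdname studyIO
#' @export
readVeinCounts <- function(path) {
  df <- utils::read.csv(path)
  df$difficult_flag <- as.logical(df$difficult_flag)
  df
}
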