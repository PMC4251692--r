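## End-to-end pipeline driver and the synthetic-study fixture generator.

.md5 <- function(path) unname(tools::md5sum(path))

#' Run the full phantom-to-detection pipeline
#'
#' Executes phantom rendering, capture emulation, enhancement and
#' segmentation as configured, writing every artifact plus a manifest JSON
#' listing each output with its MD5 content hash. With a fixed seed the
#' manifest hashes are stable across runs.
#'
#' @param config a named list: `outDir` (required), `seed` (default 1),
#'   `phantom` (argument list for [PhantomSpec()]), `nVeins` (default 3),
#'   `profile` (capture profile name, default "LED profile"),
#'   `camera` (argument list for [CameraSettings()], overrides `profile`),
#'   `enhance` (argument list for [EnhanceConfig()]),
#'   `detect` (argument list for [DetectConfig()]).
#' @return Invisibly, the manifest as a list.
#' @examples
#' \donttest{
#' d <- tempfile(); dir.create(d)
#' runPipeline(list(outDir = d, seed = 7,
#'                  phantom = list(imageSize = c(96, 128))))
#' }
#' @export
runPipeline <- function(config) {
  if (is.null(config$outDir)) .fail("config$outDir is required")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stageName <- "configure"
  withCallingHandlers({
    stage <- function(name, expr) {
      stageName <<- name
      force(expr)
    }
    phArgs <- config$phantom %||% list()
    phArgs$rngSeed <- seed
    spec <- stage("phantom", do.call(PhantomSpec, phArgs))
    veins <- stage("phantom",
                   generateVeinNetwork(spec, config$nVeins %||% 3L,
                                       rngSeed = seed))
    out <- stage("phantom", renderPhantom(spec, veins))
    settings <- stage("capture",
      if (!is.null(config$camera)) do.call(CameraSettings, config$camera)
      else profileSettings(config$profile %||% "LED profile"))
    enhCfg <- stage("enhance", do.call(EnhanceConfig, config$enhance %||% list()))
    enhanced <- stage("enhance", processFrame(phantomImage(out), settings, enhCfg))
    detCfg <- stage("detect", do.call(DetectConfig, config$detect %||% list()))
    vm <- stage("detect", segmentVeins(enhanced, detCfg))

    stageName <- "write"
    paths <- c(image = file.path(config$outDir, "image.tiff"),
               enhanced = file.path(config$outDir, "enhanced.tiff"),
               mask = file.path(config$outDir, "mask.png"),
               truth_mask = file.path(config$outDir, "truth_mask.png"),
               depth = file.path(config$outDir, "depth.tiff"),
               veins = file.path(config$outDir, "veins.json"),
               centerlines = file.path(config$outDir, "centerlines.json"))
    writeNIRImage(phantomImage(out), paths[["image"]])
    writeNIRImage(enhanced, paths[["enhanced"]])
    writeNIRImage(veinMask(vm) * 1, paths[["mask"]])
    writeNIRImage(truthMask(out) * 1, paths[["truth_mask"]])
    writeNIRImage(depthMap(out), paths[["depth"]], float = TRUE)
    writeVeins(veins, paths[["veins"]])
    jsonlite::write_json(lapply(centerlines(vm), unname),
                         paths[["centerlines"]], digits = NA)
    manifest <- list(
      seed = seed,
      nVeinsDetected = countVisibleVeins(vm, detCfg@minCenterlineLength),
      outputs = lapply(seq_along(paths), function(i)
        list(name = names(paths)[i], path = unname(paths[i]),
             md5 = .md5(paths[i]))))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stageName,
                 conditionMessage(e)), call. = FALSE)
  })
}

## BMI-class presets used ONLY by the fixture generator (the optics core
## never sees a BMI label). Marker placement follows a two-component
## model: with probability pVis the student perceived a vein (palpation or
## faint visibility) and marks near it with Gaussian jitter; otherwise the
## site is an uninformed uniform guess. Thicker adipose lowers pVis and
## widens the jitter, so failure rates rise from class 1 to class 3.
.bmiPresets <- data.frame(
  bmi_class = c("1", "2", "3"),
  nSubjects = c(4L, 18L, 3L),
  adipose = c(0, 1.5, 3.5),
  pVis = c(0.65, 0.45, 0.0),
  markerJitter = c(2.0, 2.5, 3.0))

#' Generate a complete synthetic study bundle
#'
#' Emulates the structure of an educational venipuncture study: 25 subject
#' phantoms across 3 BMI presets, 500 attempt records (20 clinicians each
#' marking every subject, hits adjudicated with [isVeinAt()] against the
#' ground-truth masks), a 20 x 4 Likert table, 4 SUS responses, a
#' per-patient additional-veins table (64 patients, 27 difficult) and a
#' JSONL usage-event log with 497 sessions. Everything is derived from
#' `seed`; the bundle is documented as synthetic throughout.
#'
#' Marker placement uses a two-component model: with a per-class
#' probability the student perceived a vein and marks near it (Gaussian
#' jitter); otherwise the mark is an uninformed uniform guess. Both the
#' perception probability and the jitter worsen with the BMI preset, so
#' failure rates increase from class 1 to class 3.
#'
#' @param seed integer master seed.
#' @param outDir output directory (created if needed).
#' @param imageSize phantom size in pixels, default c(192, 256)
#'   (19.2 x 25.6 mm at the default pitch) — a field in which two veins
#'   leave most of the skin vein-free, as on a real inner elbow.
#' @param writeImages write per-subject TIFF/PNG renders (default TRUE);
#'   FALSE keeps only the CSV/JSONL tables.
#' @return Invisibly, a list with the attempt records, Likert, SUS and
#'   vein-count tables, the usage events and the manifest path.
#' @examples
#' \donttest{
#' d <- tempfile(); dir.create(d)
#' fx <- makeFixtures(1, d, writeImages = FALSE)
#' nrow(fx$attempts)  # 500
#' }
#' @export
makeFixtures <- function(seed, outDir, imageSize = c(192L, 256L),
                         writeImages = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outDir, 2) != 0) .fail("output directory not writable: %s", outDir)
  seed <- as.integer(seed)
  detCfg <- DetectConfig()

  subjects <- .bmiPresets[rep(seq_len(nrow(.bmiPresets)),
                              .bmiPresets$nSubjects),
                          c("bmi_class", "adipose", "pVis", "markerJitter")]
  names(subjects)[4] <- "jitter"
  rownames(subjects) <- NULL
  nSub <- nrow(subjects)

  attempts <- vector("list", nSub)
  for (s in seq_len(nSub)) {
    subSeed <- seed + 97L * s
    spec <- PhantomSpec(imageSize = imageSize,
                        adiposeThickness = subjects$adipose[s],
                        rngSeed = subSeed)
    veins <- generateVeinNetwork(spec, 2L, rngSeed = subSeed + 1L)
    out <- renderPhantom(spec, veins)
    truthVM <- VeinMask(truthMask(out), list(), phantomImage(out))
    clPx <- truthCenterlinePixels(spec, veins)
    d <- dim(truthMask(out))
    marks <- .withSeed(subSeed + 2L, {
      guided <- runif(20) < subjects$pVis[s]
      anchor <- clPx[sample(nrow(clPx), 20, replace = TRUE), , drop = FALSE]
      jitterPx <- subjects$jitter[s] / spec@pixelPitch
      r <- round(anchor[, 1] + rnorm(20, 0, jitterPx))
      c <- round(anchor[, 2] + rnorm(20, 0, jitterPx))
      r[!guided] <- sample(d[1], sum(!guided), replace = TRUE)
      c[!guided] <- sample(d[2], sum(!guided), replace = TRUE)
      cbind(pmax(1, pmin(d[1], r)), pmax(1, pmin(d[2], c)))
    })
    hits <- vapply(seq_len(20), function(k)
      isVeinAt(truthVM, marks[k, ], detCfg@hitTolerance), logical(1))
    attempts[[s]] <- data.frame(
      clinician_id = sprintf("C%02d", seq_len(20)),
      subject_id = sprintf("S%02d", s),
      bmi_class = subjects$bmi_class[s],
      row = marks[, 1], col = marks[, 2], hit = hits)
    if (writeImages) {
      subDir <- file.path(outDir, "phantoms", sprintf("S%02d", s))
      dir.create(subDir, recursive = TRUE, showWarnings = FALSE)
      writeNIRImage(phantomImage(out), file.path(subDir, "image.tiff"))
      writeNIRImage(truthMask(out) * 1, file.path(subDir, "mask.png"))
      writeVeins(veins, file.path(subDir, "veins.json"))
    }
  }
  attempts <- do.call(rbind, attempts)

  likert <- .withSeed(seed + 11L, data.frame(
    id = seq_len(20),
    A = sample(2:5, 20, TRUE, prob = c(0.05, 0.1, 0.35, 0.5)),
    B = sample(2:5, 20, TRUE, prob = c(0.05, 0.1, 0.45, 0.4)),
    C = sample(2:5, 20, TRUE, prob = c(0.05, 0.1, 0.5, 0.35)),
    D = sample(1:4, 20, TRUE, prob = c(0.5, 0.3, 0.15, 0.05))))

  sus <- .withSeed(seed + 13L, {
    m <- t(vapply(seq_len(4), function(i) {
      odd <- sample(4:5, 5, TRUE, prob = c(0.45, 0.55))
      even <- sample(1:2, 5, TRUE, prob = c(0.55, 0.45))
      as.integer(rbind(odd, even))
    }, integer(10)))
    colnames(m) <- paste0("q", seq_len(10))
    data.frame(id = sprintf("P%d", seq_len(4)), m)
  })

  veinCounts <- .withSeed(seed + 17L, {
    difficult <- c(rep(TRUE, 27), rep(FALSE, 37))
    n <- length(difficult)
    data.frame(patient_id = sprintf("PT%02d", seq_len(n)),
               difficult_flag = difficult,
               additional_veins = ifelse(difficult, stats::rpois(n, 2.4),
                                         stats::rpois(n, 1.0)))
  })

  events <- .generateUsageLog(seed + 19L, nSessions = 497L, nUsers = 20L)

  utils::write.csv(attempts, file.path(outDir, "attempts.csv"), row.names = FALSE)
  utils::write.csv(likert, file.path(outDir, "likert.csv"), row.names = FALSE)
  utils::write.csv(sus, file.path(outDir, "sus.csv"), row.names = FALSE)
  utils::write.csv(veinCounts, file.path(outDir, "counts.csv"), row.names = FALSE)
  .writeUsageLog(events, file.path(outDir, "usage.jsonl"))

  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(seed = seed,
                   outputs = lapply(files, function(f)
                     list(path = f, md5 = .md5(f))))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)

  invisible(list(attempts = attempts, likert = likert, sus = sus,
                 veinCounts = veinCounts, events = events,
                 manifest = manifestPath))
}

## Synthetic two-week usage log: sessions dominated by the visual-detection
## screen, with camera adjustments (exposure > contrast > gain), profile
## selections led by "Low light" and the fine DoG as the most-used mode.
.generateUsageLog <- function(seed, nSessions = 497L, nUsers = 20L) {
  .withSeed(seed, {
    rows <- vector("list", nSessions)
    for (i in seq_len(nSessions)) {
      user <- sample(nUsers, 1)
      day <- sample(0:13, 1)
      t0 <- day * 86400 + stats::runif(1, 8 * 3600, 20 * 3600)
      dur <- pmin(2400, stats::rlnorm(1, log(420), 0.7))
      sid <- sprintf("U%02d-%04d", user, i)
      ev <- list(list(t = 0, kind = "session_start"))
      nScreen <- sample(1:3, 1)
      for (k in seq_len(nScreen))
        ev <- c(ev, list(list(t = stats::runif(1, 0.02, 0.2) * dur,
                              kind = "screen_view",
                              screen = sample(c("Visual detection",
                                                "Camera settings", "Help"),
                                              1, prob = c(0.7, 0.25, 0.05)))))
      for (k in seq_len(stats::rpois(1, 24)))
        ev <- c(ev, list(list(t = stats::runif(1, 0.1, 0.95) * dur,
                              kind = "camera_adjust",
                              setting = sample(c("exposure", "contrast", "gain"),
                                               1, prob = c(0.45, 0.35, 0.2)))))
      for (k in seq_len(stats::rpois(1, 0.8)))
        ev <- c(ev, list(list(t = stats::runif(1, 0.05, 0.5) * dur,
                              kind = "profile_select",
                              profile = sample(c("Low light", "LED profile",
                                                 "Medium light", "Very bright"),
                                               1, prob = c(0.45, 0.3, 0.15, 0.1)))))
      for (k in seq_len(stats::rpois(1, 0.6)))
        ev <- c(ev, list(list(t = stats::runif(1, 0.2, 0.9) * dur,
                              kind = "mode_select",
                              mode = sample(c("Difference of Gaussians I",
                                              "Difference of Gaussians II",
                                              "Laplacian I", "Laplacian II"),
                                            1, prob = c(0.5, 0.2, 0.2, 0.1)))))
      for (k in seq_len(stats::rpois(1, 0.6)))
        ev <- c(ev, list(list(t = stats::runif(1, 0.3, 0.95) * dur,
                              kind = "snapshot",
                              has_veins = stats::runif(1) < 0.75)))
      ev <- c(ev, list(list(t = dur, kind = "session_end")))
      ord <- order(vapply(ev, `[[`, numeric(1), "t"))
      rows[[i]] <- do.call(rbind, lapply(ev[ord], function(e)
        data.frame(timestamp = t0 + e$t, session_id = sid, kind = e$kind,
                   setting = e$setting %||% NA_character_,
                   profile = e$profile %||% NA_character_,
                   mode = e$mode %||% NA_character_,
                   screen = e$screen %||% NA_character_,
                   has_veins = e$has_veins %||% NA)))
    }
    do.call(rbind, rows)
  })
}

.writeUsageLog <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    payload <- Filter(Negate(is.na),
                      list(setting = e$setting, profile = e$profile,
                           mode = e$mode, screen = e$screen,
                           has_veins = e$has_veins))
    rec <- list(timestamp = e$timestamp, session_id = e$session_id,
                kind = e$kind)
    if (length(payload)) rec$payload <- payload
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
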