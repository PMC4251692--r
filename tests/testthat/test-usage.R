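emptyEventFrame <- function() {
  data.frame(timestamp = numeric(0), session_id = character(0),
             kind = character(0), setting = character(0),
             profile = character(0), mode = character(0),
             screen = character(0), has_veins = logical(0))
}

sessionEvents <- function(sid, t0, dur, extra = NULL) {
  base <- data.frame(timestamp = c(t0, t0 + dur), session_id = sid,
                     kind = c("session_start", "session_end"),
                     setting = NA_character_, profile = NA_character_,
                     mode = NA_character_, screen = NA_character_,
                     has_veins = NA)
  if (!is.null(extra)) {
    out <- rbind(base[1, ], extra, base[2, ])
    out[order(out$timestamp), ]
  } else base
}

test_that("an empty log yields zero counts and zero durations", {
  s <- usageSummary(emptyEventFrame())
  expect_identical(s$totalSessions, 0L)
  expect_identical(s$averageSessionDuration, "00:00:00")
  expect_identical(s$longestSessionDuration, "00:00:00")
  expect_true(all(s$eventCounts == 0))
  expect_identical(s$snapshots, 0L)
})

test_that("session durations aggregate to average and longest", {
  ev <- rbind(sessionEvents("a", 0, 600), sessionEvents("b", 5000, 1200))
  s <- usageSummary(ev)
  expect_identical(s$totalSessions, 2L)
  expect_identical(s$averageSessionDuration, "00:15:00")
  expect_identical(s$longestSessionDuration, "00:20:00")
})

test_that("malformed logs are rejected with the offending session named", {
  lone <- data.frame(timestamp = 10, session_id = "ghost",
                     kind = "session_end", setting = NA, profile = NA,
                     mode = NA, screen = NA, has_veins = NA)
  expect_error(usageSummary(lone), "ghost")

  disordered <- sessionEvents("s9", 100, 50)
  disordered$timestamp <- rev(disordered$timestamp)
  expect_error(usageSummary(disordered), "s9")

  odd <- data.frame(timestamp = 1, session_id = "x", kind = "reboot",
                    setting = NA, profile = NA, mode = NA, screen = NA,
                    has_veins = NA)
  expect_error(usageSummary(odd), "unknown event kind")
})

test_that("rankings sort by count with alphabetical tie-break", {
  extra <- data.frame(
    timestamp = 1:7,
    session_id = "s",
    kind = c(rep("camera_adjust", 5), "screen_view", "snapshot"),
    setting = c("gain", "exposure", "exposure", "contrast", "contrast",
                NA, NA),
    profile = NA_character_, mode = NA_character_,
    screen = c(rep(NA, 5), "Visual detection", NA),
    has_veins = c(rep(NA, 6), TRUE))
  ev <- sessionEvents("s", 0, 10, extra)
  s <- usageSummary(ev)
  # contrast and exposure tie at 2: alphabetical order decides
  expect_identical(names(s$cameraAdjustCounts), c("contrast", "exposure", "gain"))
  expect_identical(unname(s$cameraAdjustCounts), c(2L, 2L, 1L))
  expect_identical(s$mostUsedScreen, "Visual detection")
  expect_identical(s$snapshots, 1L)
  expect_identical(s$snapshotsWithVeins, 1L)
})

test_that("usage logs round-trip through JSONL", {
  ev <- rbind(sessionEvents("u1", 0, 120),
              sessionEvents("u2", 1000, 60,
                            data.frame(timestamp = 1030, session_id = "u2",
                                       kind = "profile_select",
                                       setting = NA_character_,
                                       profile = "Low light",
                                       mode = NA_character_,
                                       screen = NA_character_,
                                       has_veins = NA)))
  path <- tempfile(fileext = ".jsonl")
  veinviz:::.writeUsageLog(ev, path)
  back <- readUsageLog(path)
  expect_identical(nrow(back), nrow(ev))
  expect_identical(usageSummary(back)$totalSessions, 2L)
  expect_identical(usageSummary(back)$profileCounts,
                   c("Low light" = 1L))
})
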