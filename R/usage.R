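## Usage-log analytics: JSONL event logs -> session/event report.

.usageKinds <- c("session_start", "session_end", "screen_view",
                 "camera_adjust", "profile_select", "mode_select", "snapshot")

#' Read a JSONL usage-event log
#'
#' One JSON object per line with fields `timestamp` (seconds or ISO-8601
#' string), `session_id`, `kind` and an optional `payload` object with
#' `setting`, `profile`, `mode`, `screen` and `has_veins` entries.
#'
#' @param path path to the JSONL file.
#' @return data.frame of events (one row per line) with flattened payload
#'   columns, ordered as in the file.
#' @export
readUsageLog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    e <- jsonlite::fromJSON(l)
    p <- e$payload
    data.frame(timestamp = as.numeric(e$timestamp),
               session_id = as.character(e$session_id),
               kind = as.character(e$kind),
               setting = as.character(p$setting %||% NA),
               profile = as.character(p$profile %||% NA),
               mode = as.character(p$mode %||% NA),
               screen = as.character(p$screen %||% NA),
               has_veins = as.logical(p$has_veins %||% NA))
  })
  do.call(rbind, rows)
}

.fmtDuration <- function(seconds) {
  s <- max(0, floor(seconds + 0.5))
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

## Ranked tally: counts descending, alphabetical tie-break.
.rankedCounts <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(integer(0))
  tab <- table(x)
  tab <- tab[order(-as.integer(tab), names(tab))]
  stats::setNames(as.integer(tab), names(tab))
}

#' Summarize a usage-event log
#'
#' Computes the session and event analytics a pilot deployment would
#' report: matched session count, average and longest session duration
#' (hh:mm:ss), most-viewed screen, exact event tallies by kind, per-setting
#' camera-adjustment counts, profile and visualization-mode rankings
#' (descending, alphabetical tie-break) and snapshot totals.
#'
#' @param events data.frame of events as returned by [readUsageLog()].
#'   Each `session_end` must follow a `session_start` with the same
#'   `session_id`, and timestamps must be monotone within a session.
#' @return A list: `totalSessions`, `averageSessionDuration`,
#'   `longestSessionDuration`, `mostUsedScreen`, `eventCounts`,
#'   `cameraAdjustCounts`, `profileCounts`, `modeCounts`, `snapshots`,
#'   `snapshotsWithVeins`.
#' @examples
#' ev <- data.frame(timestamp = c(0, 600, 1000, 2200),
#'                  session_id = c("s1", "s1", "s2", "s2"),
#'                  kind = rep(c("session_start", "session_end"), 2),
#'                  setting = NA, profile = NA, mode = NA, screen = NA,
#'                  has_veins = NA)
#' usageSummary(ev)$averageSessionDuration  # "00:15:00"
#' @export
usageSummary <- function(events) {
  empty <- list(totalSessions = 0L,
                averageSessionDuration = "00:00:00",
                longestSessionDuration = "00:00:00",
                mostUsedScreen = NA_character_,
                eventCounts = stats::setNames(integer(length(.usageKinds)),
                                              .usageKinds),
                cameraAdjustCounts = integer(0), profileCounts = integer(0),
                modeCounts = integer(0), snapshots = 0L,
                snapshotsWithVeins = 0L)
  if (is.null(events) || nrow(events) == 0) return(empty)
  stopifnot(all(c("timestamp", "session_id", "kind") %in% names(events)))
  bad <- setdiff(unique(events$kind), .usageKinds)
  if (length(bad)) .fail("unknown event kind(s): %s", paste(bad, collapse = ", "))

  durations <- numeric(0)
  for (sid in unique(events$session_id)) {
    ev <- events[events$session_id == sid, ]
    if (is.unsorted(ev$timestamp))
      .fail("malformed log: timestamps not monotone in session %s", sid)
    nStart <- sum(ev$kind == "session_start")
    nEnd <- sum(ev$kind == "session_end")
    if (nEnd > nStart)
      .fail("malformed log: unmatched session_end in session %s", sid)
    if (nStart >= 1 && nEnd >= 1) {
      t0 <- ev$timestamp[ev$kind == "session_start"][1]
      t1 <- ev$timestamp[ev$kind == "session_end"][nEnd]
      if (t1 < t0)
        .fail("malformed log: session_end precedes session_start in %s", sid)
      durations <- c(durations, t1 - t0)
    }
  }

  counts <- stats::setNames(integer(length(.usageKinds)), .usageKinds)
  tab <- table(events$kind)
  counts[names(tab)] <- as.integer(tab)

  screens <- .rankedCounts(events$screen[events$kind == "screen_view"])
  snaps <- events[events$kind == "snapshot", , drop = FALSE]

  list(totalSessions = length(durations),
       averageSessionDuration = if (length(durations))
         .fmtDuration(mean(durations)) else "00:00:00",
       longestSessionDuration = if (length(durations))
         .fmtDuration(max(durations)) else "00:00:00",
       mostUsedScreen = if (length(screens)) names(screens)[1] else NA_character_,
       eventCounts = counts,
       cameraAdjustCounts =
         .rankedCounts(events$setting[events$kind == "camera_adjust"]),
       profileCounts =
         .rankedCounts(events$profile[events$kind == "profile_select"]),
       modeCounts = .rankedCounts(events$mode[events$kind == "mode_select"]),
       snapshots = nrow(snaps),
       snapshotsWithVeins = sum(snaps$has_veins %in% TRUE))
}
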