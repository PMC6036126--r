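## Epoch labels -> timed events -> REI -> severity grade.

#' Convert smoothed epoch labels into timed apnea events
#'
#' Builds a 0.5-s frame timeline over the recording, marking each frame
#' APN when the epoch whose center is nearest to the frame is APN
#' (\code{timeline = "nearest"}, default) or when more than half of the
#' epochs covering the frame are APN (\code{"majority"}). Maximal APN runs
#' become events; runs shorter than 10 s are discarded and runs longer
#' than 120 s are split into ceiling(len/120) consecutive events of equal
#' length (splitting rather than truncating preserves total apnea burden).
#'
#' @param labels data.frame with \code{epoch_start} and \code{label}
#'   columns on the 0.5-s epoch grid.
#' @param win epoch length, seconds (default 10).
#' @param hop epoch hop, seconds (default 0.5).
#' @param minEvent,maxEvent admissible event duration bounds, seconds.
#' @param timeline \code{"nearest"} or \code{"majority"}.
#' @return event table (\code{etype = "APN"}, \code{start},
#'   \code{duration}).
#' @export
epochsToEvents <- function(labels, win = 10, hop = 0.5, minEvent = 10,
                           maxEvent = 120,
                           timeline = c("nearest", "majority")) {
  timeline <- match.arg(timeline)
  n <- nrow(labels)
  if (n == 0) return(makeEventTable())
  apn <- labels$label == "APN"
  dur <- labels$epoch_start[n] + win
  frameT <- seq(0, dur - hop, by = hop)
  if (timeline == "nearest") {
    centers0 <- labels$epoch_start[1] + win / 2
    nearest <- round((frameT - centers0) / hop) + 1
    nearest[nearest < 1L] <- 1L
    nearest[nearest > n] <- n
    frameApn <- apn[nearest]
  } else {
    # majority over covering epochs: epoch i covers frames in
    # [start_i, start_i + win)
    cnt <- numeric(length(frameT))
    tot <- numeric(length(frameT))
    fIdx <- function(t) pmin(length(frameT), pmax(1, round(t / hop) + 1))
    for (i in seq_len(n)) {
      a <- fIdx(labels$epoch_start[i])
      b <- fIdx(labels$epoch_start[i] + win - hop)
      tot[a:b] <- tot[a:b] + 1
      if (apn[i]) cnt[a:b] <- cnt[a:b] + 1
    }
    frameApn <- cnt > tot / 2
  }
  r <- rle(frameApn)
  ends <- cumsum(r$lengths)
  startsF <- ends - r$lengths + 1
  out <- makeEventTable()
  for (j in which(r$values)) {
    s <- frameT[startsF[j]]
    len <- r$lengths[j] * hop
    if (len < minEvent) next
    if (len > maxEvent) {
      m <- ceiling(len / maxEvent)
      piece <- len / m
      out <- rbind(out, makeEventTable("APN", s + (seq_len(m) - 1) * piece,
                                       rep(piece, m)))
    } else {
      out <- rbind(out, makeEventTable("APN", s, len))
    }
  }
  rownames(out) <- NULL
  out
}

#' Respiratory event index
#'
#' REI = number of events overlapping the light-off..light-on analysis
#' period, divided by the period length in hours. The AHI surrogate when
#' sleep staging is unavailable: events per hour of recording rather than
#' per hour of sleep.
#'
#' @param events event table.
#' @param lightOff,lightOn analysis period bounds, seconds.
#' @return events per hour.
#' @export
computeREI <- function(events, lightOff, lightOn) {
  if (!(lightOn > lightOff)) stopf("light_on must be greater than light_off")
  hours <- (lightOn - lightOff) / 3600
  if (nrow(events) == 0) return(0)
  nIn <- sum(events$start < lightOn & events$start + events$duration > lightOff)
  nIn / hours
}

#' Severity grade from an apnea index
#'
#' Boundary-inclusive clinical buckets: Normal (AHI <= 5),
#' Mild (5 < AHI <= 15), Moderate (15 < AHI <= 30), Severe (AHI > 30).
#'
#' @param rei nonnegative events-per-hour index (vectorized).
#' @return factor with levels [severityLevels()].
#' @export
classifySeverity <- function(rei) {
  if (any(rei < 0)) stopf("severity is undefined for a negative index")
  cut(rei, breaks = c(-Inf, 5, 15, 30, Inf), labels = severityLevels(),
      right = TRUE)
}
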