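## Windowing and the two feature families: apnea-related features from the
## fused effort channels and desaturation features from SpO2.

# zero-phase band-pass by FFT masking: exact band edges, no filter
# instability at very low normalized cutoffs
bandpassFFT <- function(x, rate, low, high) {
  n <- length(x)
  if (n < 4) return(rep(0, n))
  x <- x - mean(x)
  nf <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, rep(0, nf - n))
  fr <- seq_len(nf) - 1
  fr <- pmin(fr, nf - fr) * rate / nf
  mask <- fr >= low & fr <= high
  Re(fft(fft(xp) * mask, inverse = TRUE))[seq_len(n)] / nf
}

#' Fuse a tri-axial effort channel into one respiratory waveform
#'
#' Removes the per-axis mean (gravity/orientation offset), projects the
#' three axes onto their first principal direction, band-passes to the
#' respiratory band and resamples to a common analysis rate. The sign of
#' the principal direction is fixed so its largest-magnitude loading is
#' positive. A constant channel yields an all-zero waveform with a warning.
#'
#' @param channel 3-axis \linkS4class{ChannelSignal}.
#' @param band respiratory band in Hz (default 0.05-1).
#' @param targetRate output rate in Hz (default 10).
#' @return 1-axis \linkS4class{ChannelSignal} at \code{targetRate}.
#' @export
fuseTriaxial <- function(channel, band = c(0.05, 1), targetRate = 10) {
  stopifnot(is(channel, "ChannelSignal"), ncol(channel@samples) == 3L)
  X <- channel@samples
  X <- sweep(X, 2, colMeans(X))
  cv <- crossprod(X) / max(1, nrow(X) - 1)
  if (all(abs(cv) < 1e-12)) {
    warnf("constant tri-axial channel: fused waveform is zero")
    n <- max(1L, floor(nrow(X) / channel@rate * targetRate))
    return(ChannelSignal(rep(0, n), rate = targetRate, units = "a.u.",
                         startOffset = channel@startOffset))
  }
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (ev[which.max(abs(ev))] < 0) ev <- -ev
  w <- drop(X %*% ev)
  wf <- bandpassFFT(w, channel@rate, band[1], band[2])
  if (abs(channel@rate - targetRate) < 1e-9) {
    out <- wf
  } else {
    n <- length(wf)
    tIn <- (seq_len(n) - 1) / channel@rate
    nOut <- floor(n / channel@rate * targetRate)
    tOut <- (seq_len(nOut) - 1) / targetRate
    out <- approx(tIn, wf, xout = tOut, rule = 2)$y
  }
  ChannelSignal(out, rate = targetRate, units = "a.u.",
                startOffset = channel@startOffset)
}

#' Epoch grid over a recording
#'
#' Epoch start times for 10-s windows advanced by 0.5 s (9.5 s overlap):
#' 0, 0.5, 1, ... with the last start no later than duration - win. The
#' number of epochs is floor((duration - win)/hop) + 1; a recording shorter
#' than one window yields no epochs.
#'
#' @param duration recording duration, seconds.
#' @param win window length, seconds (default 10).
#' @param hop hop between window starts, seconds (default 0.5).
#' @return numeric vector of epoch start times.
#' @export
segmentWindows <- function(duration, win = 10, hop = 0.5) {
  if (duration < win) return(numeric(0))
  n <- floor((duration - win) / hop + 1e-9) + 1
  (seq_len(n) - 1) * hop
}

#' Breathing-envelope amplitude of an effort segment
#'
#' Robust amplitude of the band-passed respiratory oscillation:
#' sqrt(2) times the unscaled median absolute deviation of the segment,
#' calibrated so a pure sinusoid of amplitude A maps to A. Homogeneous of
#' degree 1; zero for a flat segment.
#'
#' @param x numeric segment (band-passed effort samples).
#' @return amplitude in the units of \code{x}.
#' @export
amplitudeFeature <- function(x) {
  if (!length(x)) return(0)
  sqrt(2) * median(abs(x - median(x)))
}

#' Dominant breathing frequency of an effort segment
#'
#' Frequency of the periodogram peak restricted to the physiological
#' breathing band (default 0.1-0.6 Hz). The segment is mean-removed and
#' zero-padded for finer bin spacing. A flat segment returns 0 with
#' attribute \code{flagged = TRUE}.
#'
#' @param x numeric segment.
#' @param rate sampling rate, Hz.
#' @param band search band in Hz.
#' @param nfft FFT length after zero-padding.
#' @return peak frequency in Hz.
#' @export
frequencyFeature <- function(x, rate, band = c(0.1, 0.6), nfft = 256) {
  x <- x - mean(x)
  if (all(abs(x) < 1e-12))
    return(structure(0, flagged = TRUE))
  nfft <- max(nfft, length(x))
  xp <- c(x, rep(0, nfft - length(x)))
  P <- Mod(fft(xp))^2
  fr <- (seq_len(nfft) - 1) * rate / nfft
  inband <- which(fr >= band[1] & fr <= band[2])
  if (!length(inband) || max(P[inband]) < 1e-20)
    return(structure(0, flagged = TRUE))
  fr[inband[which.max(P[inband])]]
}

#' Thoraco-abdominal paradox of an epoch
#'
#' Zero-lag normalized cross-correlation (Pearson correlation at lag 0) of
#' the band-passed thoracic and abdominal segments of one epoch. Values
#' near +1 indicate synchronous effort, values near -1 thoraco-abdominal
#' paradox (out-of-phase motion typical of obstructive events). Either
#' segment constant returns 0 with attribute \code{flagged = TRUE}.
#'
#' @param tho,abd numeric segments of equal length, same epoch and rate.
#' @return correlation in [-1, 1].
#' @export
paradoxFeature <- function(tho, abd) {
  stopifnot(length(tho) == length(abd))
  tho <- tho - mean(tho); abd <- abd - mean(abd)
  den <- sqrt(sum(tho^2) * sum(abd^2))
  if (den < 1e-20) return(structure(0, flagged = TRUE))
  max(-1, min(1, sum(tho * abd) / den))
}

spo2Index <- function(ch, from, n) {
  # index of n consecutive 1-per-sample points starting at time >= from
  k0 <- ceiling((from - ch@startOffset) * ch@rate - 1e-9) + 1
  k0 + seq_len(n) - 1
}

#' Desaturation features of one epoch
#'
#' Six SpO2 statistics per 10-s epoch: minimum, maximum, median and mean of
#' the epoch samples; the variance of the 1-s first difference within the
#' epoch; and the maximum, over sliding 20-s context windows covering the
#' epoch, of (window median - window minimum).
#'
#' @param spo2 1-axis 1-Hz \linkS4class{ChannelSignal}, percent.
#' @param epochStart epoch start time, seconds.
#' @param win epoch length, seconds (default 10).
#' @param context context window length for the median-minus-min term,
#'   seconds (default 20).
#' @param align \code{"centered"} (default) or \code{"trailing"} context
#'   windows.
#' @return named numeric vector: \code{spo2_min}, \code{spo2_max},
#'   \code{spo2_median}, \code{spo2_mean}, \code{spo2_d1_var},
#'   \code{spo2_med_min_20s}.
#' @export
desaturationFeatures <- function(spo2, epochStart, win = 10, context = 20,
                                 align = c("centered", "trailing")) {
  align <- match.arg(align)
  stopifnot(is(spo2, "ChannelSignal"))
  v <- spo2@samples[, 1]
  nWin <- round(win * spo2@rate)
  idx <- spo2Index(spo2, epochStart, nWin)
  if (idx[1] < 1 || idx[length(idx)] > length(v))
    stopf("SpO2 does not cover epoch [%g, %g) s", epochStart, epochStart + win)
  seg <- v[idx]
  d1 <- diff(seg)
  half <- round(context / 2 * spo2@rate)
  centers <- seq(floor(epochStart), ceiling(epochStart + win))
  mm <- vapply(centers, function(ct) {
    kc <- spo2Index(spo2, ct, 1L)
    rng <- if (align == "centered") (kc - half):(kc + half) else (kc - 2 * half):kc
    rng <- rng[rng >= 1 & rng <= length(v)]
    if (!length(rng)) return(0)
    median(v[rng]) - min(v[rng])
  }, numeric(1))
  c(spo2_min = min(seg), spo2_max = max(seg), spo2_median = median(seg),
    spo2_mean = mean(seg), spo2_d1_var = if (length(d1) > 1) var(d1) else 0,
    spo2_med_min_20s = max(mm))
}

#' Detect an oxygen desaturation against a preceding baseline
#'
#' TRUE when the SpO2 minimum of the 10-s segment falls at least
#' \code{threshold} percentage points (default 3, the scoring criterion)
#' below the median of the immediately preceding baseline window.
#'
#' @param spo2 1-axis 1-Hz \linkS4class{ChannelSignal}.
#' @param segmentStart segment start time, seconds.
#' @param win segment length, seconds (default 10).
#' @param baseline baseline window length preceding the segment, seconds
#'   (default 20).
#' @param threshold desaturation depth, percentage points (default 3).
#' @return logical.
#' @export
detectDesaturation <- function(spo2, segmentStart, win = 10, baseline = 20,
                               threshold = 3) {
  stopifnot(is(spo2, "ChannelSignal"))
  v <- spo2@samples[, 1]
  segIdx <- spo2Index(spo2, segmentStart, round(win * spo2@rate))
  basIdx <- spo2Index(spo2, segmentStart - baseline,
                      round(baseline * spo2@rate))
  if (basIdx[1] < 1)
    stopf("no %g-s baseline window available before %g s", baseline,
          segmentStart)
  if (segIdx[length(segIdx)] > length(v))
    stopf("SpO2 does not cover segment [%g, %g) s", segmentStart,
          segmentStart + win)
  (median(v[basIdx]) - min(v[segIdx])) >= threshold
}

## ---- vectorized per-subject extraction ------------------------------------

rowMins <- function(M) do.call(pmin, as.data.frame(M))
rowMaxs <- function(M) do.call(pmax, as.data.frame(M))

# spectral peak per row, chunked to bound memory
rowPeakFreq <- function(X, rate, band, nfft = 256, chunk = 8192L) {
  n <- nrow(X); p <- ncol(X)
  nfft <- max(nfft, p)
  fr <- (seq_len(nfft) - 1) * rate / nfft
  inband <- which(fr >= band[1] & fr <= band[2])
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    B <- X[i:j, , drop = FALSE]
    B <- B - rowMeans(B)
    Bp <- matrix(0, nfft, j - i + 1L)
    Bp[seq_len(p), ] <- t(B)
    P <- Mod(stats::mvfft(Bp))^2
    Pb <- P[inband, , drop = FALSE]
    pk <- max.col(t(Pb), ties.method = "first")
    f <- fr[inband[pk]]
    f[apply(Pb, 2, max) < 1e-20] <- 0
    out[i:j] <- f
    i <- j + 1L
  }
  out
}

# window-index matrix: one row per epoch start, win samples at `rate`
windowIndexMatrix <- function(starts, rate, winS) {
  w <- round(winS * rate)
  outer(round(starts * rate), seq_len(w) - 1L, "+") + 1L
}

# epoch ground-truth labels: APN iff the epoch center lies inside an event
labelEpochs <- function(starts, events, win = 10) {
  lab <- rep("NOR", length(starts))
  if (!is.null(events) && nrow(events)) {
    centers <- starts + win / 2
    ev <- events[order(events$start), , drop = FALSE]
    i <- findInterval(centers, ev$start)
    hit <- i > 0 & centers < (ev$start[pmax(i, 1)] + ev$duration[pmax(i, 1)])
    lab[hit] <- "APN"
  }
  lab
}

# vectorized 3%-drop rule over all epochs; epochs without a full preceding
# baseline window are never flagged
desatFlags <- function(spo2, starts, fc) {
  v <- spo2@samples[, 1]
  spRate <- spo2@rate
  n10 <- round(fc$win_s * spRate)
  k0 <- ceiling((starts - spo2@startOffset) * spRate - 1e-9) + 1
  idx10 <- outer(k0, seq_len(n10) - 1L, "+")
  idx10[idx10 > length(v)] <- length(v)
  segMin <- rowMins(matrix(v[idx10], nrow(idx10), ncol(idx10)))
  nBase <- round(fc$baseline_s * spRate)
  kb <- k0 - nBase
  hasBase <- kb >= 1
  desat <- rep(FALSE, length(starts))
  if (any(hasBase)) {
    idxB <- outer(kb[hasBase], seq_len(nBase) - 1L, "+")
    B <- matrix(v[idxB], nrow(idxB), ncol(idxB))
    desat[hasBase] <- (row_medians(B) - segMin[hasBase]) >= fc$desat_threshold
  }
  desat
}

#' Extract the epoch feature matrix of a subject
#'
#' Runs the whole feature stage: tri-axial fusion of both effort channels,
#' the 10-s / 0.5-s-hop epoch grid, the three apnea-related features
#' (envelope amplitude averaged over the two channels, dominant breathing
#' frequency of the thoracic channel, thoraco-abdominal paradox) and the
#' six desaturation features, plus a per-epoch desaturation flag (3%-drop
#' rule against the preceding 20-s baseline) and, when the subject is
#' annotated, ground-truth epoch labels (an epoch is APN when its center
#' falls inside an annotated event, all types merged).
#'
#' @param subject a \linkS4class{Subject}.
#' @param config pipeline configuration, see [apneaConfig()].
#' @return list with \code{epoch_start}, \code{features} (epochs x 9 named
#'   matrix), \code{paradox}, \code{desat} (logical), and \code{labels}
#'   (\code{NOR}/\code{APN}, or NULL when unannotated).
#' @export
extractFeatures <- function(subject, config = apneaConfig()) {
  stopifnot(is(subject, "Subject"))
  fc <- config$features
  rec <- subject@recording
  wt <- fuseTriaxial(rec@thoracic, band = c(fc$band_low_hz, fc$band_high_hz),
                     targetRate = fc$target_rate)
  wa <- fuseTriaxial(rec@abdominal, band = c(fc$band_low_hz, fc$band_high_hz),
                     targetRate = fc$target_rate)
  rate <- fc$target_rate
  nW <- min(nrow(wt@samples), nrow(wa@samples))
  spo2 <- rec@spo2
  dur <- min(nW / rate, signalDuration(spo2))
  starts <- segmentWindows(dur, fc$win_s, fc$hop_s)
  if (!length(starts)) stopf("recording shorter than one %g-s epoch", fc$win_s)
  idx <- windowIndexMatrix(starts, rate, fc$win_s)
  Xt <- matrix(wt@samples[idx, 1], nrow(idx), ncol(idx))
  Xa <- matrix(wa@samples[idx, 1], nrow(idx), ncol(idx))
  amp <- sqrt(2) / 2 * (row_mads(Xt) + row_mads(Xa))
  freq <- rowPeakFreq(Xt, rate, fc$breath_band)
  Ct <- Xt - rowMeans(Xt); Ca <- Xa - rowMeans(Xa)
  den <- sqrt(rowSums(Ct^2) * rowSums(Ca^2))
  par <- ifelse(den < 1e-20, 0, pmax(-1, pmin(1, rowSums(Ct * Ca) / den)))

  v <- spo2@samples[, 1]
  spRate <- spo2@rate
  n10 <- round(fc$win_s * spRate)
  k0 <- ceiling((starts - spo2@startOffset) * spRate - 1e-9) + 1
  idx10 <- outer(k0, seq_len(n10) - 1L, "+")
  S <- matrix(v[idx10], nrow(idx10), ncol(idx10))
  spMin <- rowMins(S); spMax <- rowMaxs(S)
  spMed <- row_medians(S); spMean <- rowMeans(S)
  D <- S[, -1, drop = FALSE] - S[, -ncol(S), drop = FALSE]
  m <- ncol(D)
  d1var <- (rowSums(D^2) - rowSums(D)^2 / m) / (m - 1)
  # per-integer-second context windows: median - min, then max over the
  # centers spanning each epoch
  half <- round(fc$context_s / 2 * spRate)
  nSp <- length(v)
  ctrIdx <- outer(seq_len(nSp), -half:half, "+")
  ctrIdx[ctrIdx < 1L] <- 1L
  ctrIdx[ctrIdx > nSp] <- nSp
  W <- matrix(v[ctrIdx], nSp, ncol(ctrIdx))
  wmm <- row_medians(W) - rowMins(W)
  ctrs <- outer(floor(k0), 0:n10, "+")
  ctrs[ctrs < 1L] <- 1L
  ctrs[ctrs > nSp] <- nSp
  medMin20 <- rowMaxs(matrix(wmm[ctrs], nrow(ctrs), ncol(ctrs)))

  desat <- desatFlags(spo2, starts, fc)

  feat <- cbind(amplitude = amp, frequency = freq, paradox = par,
                spo2_min = spMin, spo2_max = spMax, spo2_median = spMed,
                spo2_mean = spMean, spo2_d1_var = d1var,
                spo2_med_min_20s = medMin20)
  labels <- if (nrow(subject@annotations))
    labelEpochs(starts, mergeEventTypes(subject@annotations), fc$win_s)
  else NULL
  list(epoch_start = starts, features = feat, paradox = par, desat = desat,
       labels = labels)
}
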