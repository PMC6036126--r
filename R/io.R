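#' Save a subject to a directory-of-CSV container
#'
#' Writes the canonical on-disk container: \code{profile.json} (identity,
#' phenotype, light markers, channel metadata), one CSV per channel
#' (\code{time_s,x[,y,z]}), and \code{annotations.csv}
#' (\code{etype,start_s,duration_s}) when the subject is annotated.
#' Sample values are written verbatim, so quantized (integer-count) effort
#' signals round-trip bit-exactly; the time column is derived from the
#' channel metadata and regenerated on load.
#'
#' @param subject a \linkS4class{Subject}.
#' @param path directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @seealso [loadSubject()]
#' @export
saveSubject <- function(subject, path) {
  stopifnot(is(subject, "Subject"))
  validObject(subject)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stopf("cannot create directory '%s'", path)
  rec <- subject@recording
  chanMeta <- function(ch) list(rate_hz = ch@rate, units = ch@units,
                                start_offset_s = ch@startOffset,
                                n_samples = nrow(ch@samples))
  meta <- list(
    id = subject@id,
    gender = subject@profile@gender,
    age = subject@profile@age,
    bmi = subject@profile@bmi,
    comorbidities = as.list(subject@profile@comorbidities),
    light_off_s = rec@lightOff,
    light_on_s = rec@lightOn,
    channels = list(thoracic = chanMeta(rec@thoracic),
                    abdominal = chanMeta(rec@abdominal),
                    spo2 = chanMeta(rec@spo2)))
  jsonlite::write_json(meta, file.path(path, "profile.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeChannel <- function(ch, file) {
    n <- nrow(ch@samples)
    t <- ch@startOffset + (seq_len(n) - 1) / ch@rate
    df <- if (ncol(ch@samples) == 3L)
      data.table::data.table(time_s = t, x = ch@samples[, 1],
                             y = ch@samples[, 2], z = ch@samples[, 3])
    else data.table::data.table(time_s = t, x = ch@samples[, 1])
    data.table::fwrite(df, file.path(path, file))
  }
  writeChannel(rec@thoracic, "thoracic.csv")
  writeChannel(rec@abdominal, "abdominal.csv")
  writeChannel(rec@spo2, "spo2.csv")
  if (nrow(subject@annotations) > 0) {
    ann <- data.table::data.table(etype = subject@annotations$etype,
                                  start_s = subject@annotations$start,
                                  duration_s = subject@annotations$duration)
    data.table::fwrite(ann, file.path(path, "annotations.csv"))
  } else {
    unlink(file.path(path, "annotations.csv"))
  }
  invisible(path)
}

readChannelCSV <- function(path, file, meta, axes) {
  f <- file.path(path, file)
  if (!file.exists(f)) stopf("missing channel file '%s'", f)
  df <- data.table::fread(f, data.table = FALSE)
  cols <- if (axes == 3L) c("x", "y", "z") else "x"
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("channel file '%s': missing column(s) %s", f,
          paste(miss, collapse = ", "))
  if (!is.null(meta$n_samples) && nrow(df) != meta$n_samples)
    stopf("channel file '%s': %d samples but metadata declares %d", f,
          nrow(df), meta$n_samples)
  ChannelSignal(as.matrix(df[, cols, drop = FALSE]), rate = meta$rate_hz,
                units = meta$units %||% "",
                startOffset = meta$start_offset_s %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a subject from its on-disk container
#'
#' Reads the container written by [saveSubject()]: \code{profile.json} plus
#' per-channel CSVs, or \code{signals.edf} holding channels labelled
#' \code{THOx/THOy/THOz}, \code{ABDx/ABDy/ABDz} and \code{SpO2}. The
#' returned subject is validated (SpO2 range, channel coverage, annotation
#' durations); validation failures name the offending file and field.
#'
#' @param path directory containing the container.
#' @return a validated \linkS4class{Subject}.
#' @export
loadSubject <- function(path) {
  pf <- file.path(path, "profile.json")
  if (!file.exists(pf)) stopf("missing metadata file '%s'", pf)
  meta <- jsonlite::read_json(pf, simplifyVector = TRUE)
  for (field in c("id", "gender", "age", "bmi", "comorbidities",
                  "light_off_s", "light_on_s"))
    if (is.null(meta[[field]]))
      stopf("metadata file '%s': missing field '%s'", pf, field)
  cm <- meta$comorbidities
  prof <- PhenotypeProfile(meta$gender, meta$age, meta$bmi,
                           hypertension = isTRUE(cm$hypertension),
                           diabetes = isTRUE(cm$diabetes),
                           hypothyroidism = isTRUE(cm$hypothyroidism))
  edf <- file.path(path, "signals.edf")
  if (file.exists(edf)) {
    sig <- readEDFSignals(edf)
    need <- c("THOx", "THOy", "THOz", "ABDx", "ABDy", "ABDz", "SpO2")
    miss <- setdiff(need, names(sig))
    if (length(miss))
      stopf("EDF file '%s': missing channel(s) %s", edf,
            paste(miss, collapse = ", "))
    tri <- function(lbls, units) {
      rates <- vapply(sig[lbls], sampleRate, numeric(1))
      if (length(unique(rates)) != 1L)
        stopf("EDF file '%s': rate mismatch across axes %s", edf,
              paste(lbls, collapse = ", "))
      ChannelSignal(do.call(cbind, lapply(sig[lbls], samples)),
                    rate = rates[[1]], units = units)
    }
    tho <- tri(c("THOx", "THOy", "THOz"), "counts")
    abd <- tri(c("ABDx", "ABDy", "ABDz"), "counts")
    sp <- sig[["SpO2"]]
  } else {
    chm <- meta$channels
    if (is.null(chm))
      stopf("metadata file '%s': missing field 'channels'", pf)
    tho <- readChannelCSV(path, "thoracic.csv", chm$thoracic, 3L)
    abd <- readChannelCSV(path, "abdominal.csv", chm$abdominal, 3L)
    sp <- readChannelCSV(path, "spo2.csv", chm$spo2, 1L)
  }
  if (nrow(sp@samples) &&
      (min(sp@samples) < 0 || max(sp@samples) > 100))
    stopf("file '%s': SpO2 out of [0,100]", file.path(path, "spo2.csv"))
  rec <- Recording(tho, abd, sp, meta$light_off_s, meta$light_on_s)
  af <- file.path(path, "annotations.csv")
  ann <- makeEventTable()
  if (file.exists(af)) {
    adf <- data.table::fread(af, data.table = FALSE)
    miss <- setdiff(c("etype", "start_s", "duration_s"), names(adf))
    if (length(miss))
      stopf("annotation file '%s': missing column(s) %s", af,
            paste(miss, collapse = ", "))
    ann <- makeEventTable(adf$etype, adf$start_s, adf$duration_s)
    validateEventTable(ann, where = sprintf("annotation file '%s'", af))
  }
  sub <- Subject(meta$id, prof, rec, ann)
  validObject(sub)
  sub
}

#' Read signal channels from an EDF file
#'
#' A minimal reader for the European Data Format (EDF): parses the fixed
#' ASCII header and signal headers, decodes the 16-bit little-endian data
#' records, and applies the physical calibration of each channel. Intended
#' for pulling effort and oximetry channels out of device exports; EDF
#' writing is not supported.
#'
#' @param path EDF file.
#' @return named list of 1-axis \linkS4class{ChannelSignal}, one per EDF
#'   channel, named by the (trimmed) channel label.
#' @export
readEDFSignals <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    trimws(rawToChar(readBin(con, "raw", nchars)))
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  rd(8); rd(44)                           # header bytes, reserved
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("EDF file '%s': unparseable header", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)           # reserved
  store <- lapply(nsamp, function(k) numeric(k * nrec))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < nsamp[i])
        stopf("EDF file '%s': truncated data record %d", path, r)
      store[[i]][(r - 1) * nsamp[i] + seq_len(nsamp[i])] <- v
    }
  }
  out <- lapply(seq_len(ns), function(i) {
    gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    phys <- (store[[i]] - digMin[i]) * gain + physMin[i]
    ChannelSignal(phys, rate = nsamp[i] / recdur)
  })
  names(out) <- labels
  out
}

#' Merge all apnea subtypes into one event class
#'
#' Obstructive, central and mixed apneas and hypopneas are not
#' distinguished downstream: every event type is relabelled \code{APN}.
#' Times and event count are unchanged; the operation is idempotent.
#'
#' @param events event table (\code{etype}, \code{start}, \code{duration}).
#' @return the same table with every \code{etype} set to \code{"APN"}.
#' @export
mergeEventTypes <- function(events) {
  validateEventTable(events)
  if (nrow(events)) events$etype <- "APN"
  events
}

#' Trim a recording to its analysis period
#'
#' Restricts every channel to the light-off..light-on interval and shifts
#' the time origin so the trimmed recording starts at light-off. The
#' trimmed duration equals light_on - light_off within one sample of the
#' slowest (SpO2) channel.
#'
#' @param rec a \linkS4class{Recording}.
#' @return a trimmed \linkS4class{Recording}.
#' @export
trimToLights <- function(rec) {
  off <- rec@lightOff; on <- rec@lightOn
  trim <- function(ch) {
    n <- nrow(ch@samples)
    t <- ch@startOffset + (seq_len(n) - 1) / ch@rate
    keep <- t >= off - 1e-9 & t < on - 1e-9
    ChannelSignal(ch@samples[keep, , drop = FALSE], rate = ch@rate,
                  units = ch@units, startOffset = max(0, t[keep][1] - off))
  }
  Recording(trim(rec@thoracic), trim(rec@abdominal), trim(rec@spo2),
            lightOff = 0, lightOn = on - off)
}
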