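# shared fixture builders: all synthetic, generated in code at test time

# run expr under a fixed seed without disturbing the session RNG
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# TRUE if any two intervals of one event table overlap
selfOverlaps <- function(ev) {
  if (nrow(ev) < 2) return(FALSE)
  o <- order(ev$start)
  s <- ev$start[o]; e <- ev$start[o] + ev$duration[o]
  any(s[-1] < e[-length(e)] - 1e-9)
}

# deterministic random phenotype with continuous age/BMI (ties a.s. absent)
randomProfile <- function() {
  PhenotypeProfile(
    gender = sample(c("male", "female"), 1),
    age = runif(1, 22, 80),
    bmi = runif(1, 17, 40),
    hypertension = runif(1) < 0.35,
    diabetes = runif(1) < 0.2,
    hypothyroidism = runif(1) < 0.1)
}

randomProfileDB <- function(n) {
  profs <- replicate(n, randomProfile(), simplify = FALSE)
  names(profs) <- sprintf("p%02d", seq_len(n))
  profs
}

# a small fully synthetic subject: short recording, a few planted events
smallSubject <- function(id = "s1", hours = 0.25, ahi = 24, seed = 42,
                         group = "Mild") {
  cfg <- simulationConfig(recording_hours = hours, effort_rate = 10,
                          seed = seed)
  withSeed(seed, {
    prof <- simulatePhenotype(group)
    gt <- plantEvents(hours * 3600, ahi, cfg)
    resp <- synthesizeRespiration(gt, cfg)
    sp <- synthesizeSpO2(gt, cfg)
    rec <- Recording(resp$thoracic, resp$abdominal, sp, lightOff = 0,
                     lightOn = hours * 3600)
    Subject(id, prof, rec, annotations = gt$events)
  })
}

# literal re-statement of the neighbor-selection procedure, kept naive on
# purpose: plain loops, no shared code with the implementation
bruteForceKNN <- function(query, profs, K, Kp, sa, sb, wg = 1) {
  ids <- names(profs)
  d <- numeric(length(profs))
  cd <- numeric(length(profs))
  for (i in seq_along(profs)) {
    p <- profs[[i]]
    d[i] <- abs(query@age - p@age) / sa + abs(query@bmi - p@bmi) / sb +
      wg * (query@gender != p@gender)
    cd[i] <- sum(query@comorbidities != p@comorbidities)
  }
  ord <- order(d, ids)
  cand <- ord[seq_len(K + Kp)]
  if (Kp > 0) {
    m <- sum(cd[cand] > 0)
    if (m >= Kp) {
      rord <- cand[order(-cd[cand], -d[cand], ids[cand],
                         decreasing = c(FALSE, FALSE, TRUE),
                         method = "radix")]
      removed <- rord[seq_len(Kp)]
    } else {
      removed <- cand[cd[cand] > 0]
      rest <- setdiff(cand, removed)
      rord <- rest[order(-d[rest], ids[rest], decreasing = c(FALSE, TRUE),
                         method = "radix")]
      removed <- c(removed, rord[seq_len(Kp - m)])
    }
    cand <- setdiff(cand, removed)
  }
  ids[cand[order(d[cand], ids[cand])]]
}

# minimal EDF writer (16-bit little-endian) for reader tests
writeMiniEDF <- function(path, channels, recdurS = 1) {
  nrec <- max(vapply(channels, function(ch)
    ceiling(length(ch$samples) / (ch$rate * recdurS)), numeric(1)))
  ns <- length(channels)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- sprintf("%-*s", w, as.character(x))
    writeChar(substr(s, 1, w), con, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 * (ns + 1), 8); pad("", 44); pad(nrec, 8); pad(recdurS, 8)
  pad(ns, 4)
  for (ch in channels) pad(ch$label, 16)
  for (ch in channels) pad("", 80)
  for (ch in channels) pad(ch$units %||% "", 8)
  physMin <- vapply(channels, function(ch) min(ch$samples), numeric(1))
  physMax <- vapply(channels, function(ch) max(ch$samples) + 1e-6, numeric(1))
  for (p in physMin) pad(format(p, digits = 6), 8)
  for (p in physMax) pad(format(p, digits = 6), 8)
  for (ch in channels) pad(-32768, 8)
  for (ch in channels) pad(32767, 8)
  for (ch in channels) pad("", 80)
  nsamp <- vapply(channels, function(ch) ch$rate * recdurS, numeric(1))
  for (k in nsamp) pad(k, 8)
  for (ch in channels) pad("", 32)
  dig <- lapply(seq_along(channels), function(i) {
    x <- channels[[i]]$samples
    need <- nrec * nsamp[i]
    x <- c(x, rep(x[length(x)], need - length(x)))
    as.integer(round((x - physMin[i]) / (physMax[i] - physMin[i]) * 65535 -
                       32768))
  })
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      idx <- (r - 1) * nsamp[i] + seq_len(nsamp[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
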