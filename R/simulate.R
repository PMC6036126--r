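## Synthetic cohort simulator: phenotypes, planted events, effort and SpO2
## signals with the statistical structure the pipeline assumes.

# group-level demographics (mean/sd age, BMI, AHI; male fraction) of the
# four severity groups, and default comorbidity prevalences increasing
# with severity
.simGroups <- list(
  Normal   = list(n = 10, ahi = c(2.2, 1.4),  bmi = c(22.4, 2.8),
                  age = c(34.8, 16.3), male = 4 / 10,
                  htn = 0.10, dm = 0.05, hypo = 0.02,
                  interval = c(0, 5)),
  Mild     = list(n = 11, ahi = c(9.9, 2.7),  bmi = c(25.0, 4.5),
                  age = c(38.6, 15.5), male = 7 / 11,
                  htn = 0.20, dm = 0.10, hypo = 0.02,
                  interval = c(5, 15)),
  Moderate = list(n = 4,  ahi = c(24.9, 5.3), bmi = c(27.0, 1.6),
                  age = c(49.8, 13.1), male = 1.0,
                  htn = 0.30, dm = 0.15, hypo = 0.02,
                  interval = c(15, 30)),
  Severe   = list(n = 37, ahi = c(63.8, 23.4), bmi = c(27.8, 3.7),
                  age = c(52.3, 13.8), male = 34 / 37,
                  htn = 0.40, dm = 0.25, hypo = 0.02,
                  interval = c(30, Inf)))

rnormTrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulation configuration
#'
#' Conditions of the synthetic cohort. Group sizes and the per-group
#' age/BMI/AHI distributions and male fractions follow the demographic
#' table of the reference cohort (10/11/4/37 subjects over the four
#' severity groups, 6.3-h recordings).
#'
#' @param n_subjects named integer vector, subjects per severity group.
#' @param recording_hours recording (light-off to light-on) length, hours.
#' @param breathing_freq_mean,breathing_freq_sd breathing rate, Hz.
#' @param baseline_amplitude effort oscillation amplitude in 8-bit counts.
#' @param apnea_residual_fraction residual effort amplitude during an
#'   apnea (must be <= 0.10: a ">90% decrease").
#' @param hypopnea_reduction_range amplitude reduction during hypopneas
#'   (lower bound must be >= 0.30).
#' @param desat_depth mean desaturation depth, percent (>= 3).
#' @param desat_lag circulatory lag from event end to desaturation nadir,
#'   seconds.
#' @param resat_tau resaturation time constant after the nadir, seconds.
#' @param event_duration_range admissible planted event durations,
#'   seconds; events are kept within the 10-120 s scoring range.
#' @param obstructive_fraction probability an event is obstructive
#'   (paradoxical); the remainder split central/hypopnea.
#' @param noise_sd additive accelerometer noise, counts.
#' @param effort_rate effort channel sampling rate, Hz (226 for the
#'   device; analyses may simulate directly at the 10-Hz analysis rate).
#' @param seed base seed; every simulator output is a deterministic
#'   function of the configuration.
#' @return a validated \code{SimulationConfig} list.
#' @export
simulationConfig <- function(n_subjects = c(Normal = 10, Mild = 11,
                                            Moderate = 4, Severe = 37),
                             recording_hours = 6.3,
                             breathing_freq_mean = 0.25,
                             breathing_freq_sd = 0.05,
                             baseline_amplitude = 50,
                             apnea_residual_fraction = 0.05,
                             hypopnea_reduction_range = c(0.30, 0.90),
                             desat_depth = 4, desat_lag = 10, resat_tau = 6,
                             event_duration_range = c(10, 40),
                             obstructive_fraction = 0.7, noise_sd = 2,
                             effort_rate = 226, seed = 1) {
  cfg <- list(n_subjects = n_subjects, recording_hours = recording_hours,
              breathing_freq_mean = breathing_freq_mean,
              breathing_freq_sd = breathing_freq_sd,
              baseline_amplitude = baseline_amplitude,
              apnea_residual_fraction = apnea_residual_fraction,
              hypopnea_reduction_range = hypopnea_reduction_range,
              desat_depth = desat_depth, desat_lag = desat_lag,
              resat_tau = resat_tau,
              event_duration_range = event_duration_range,
              obstructive_fraction = obstructive_fraction,
              noise_sd = noise_sd, effort_rate = effort_rate,
              seed = as.integer(seed))
  if (cfg$apnea_residual_fraction > 0.10)
    stopf("apnea_residual_fraction must be <= 0.10 (a '>90%% decrease')")
  if (cfg$hypopnea_reduction_range[1] < 0.30)
    stopf("hypopnea reductions must be >= 0.30")
  if (cfg$desat_depth < 3)
    stopf("desat_depth must be >= 3 percent")
  if (cfg$event_duration_range[1] < 10 || cfg$event_duration_range[2] > 120)
    stopf("event_duration_range must lie within [10, 120] s")
  miss <- setdiff(names(cfg$n_subjects), severityLevels())
  if (length(miss))
    stopf("unknown severity group(s) in n_subjects: %s",
          paste(miss, collapse = ", "))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Draw a phenotype profile for a severity group
#'
#' Age and BMI come from truncated normals with the group's reference
#' mean/sd (age >= 20 per the enrollment criterion, BMI >= 15); gender
#' follows the group's male fraction; comorbidity flags are Bernoulli with
#' prevalences increasing with severity. Uses the current RNG state unless
#' \code{seed} is given.
#'
#' @param group severity group name.
#' @param seed optional seed.
#' @return a \linkS4class{PhenotypeProfile}.
#' @export
simulatePhenotype <- function(group, seed = NULL) {
  g <- .simGroups[[match.arg(group, severityLevels())]]
  draw <- function() {
    PhenotypeProfile(
      gender = if (runif(1) < g$male) "male" else "female",
      age = rnormTrunc(1, g$age[1], g$age[2], lower = 20),
      bmi = rnormTrunc(1, g$bmi[1], g$bmi[2], lower = 15),
      hypertension = runif(1) < g$htn,
      diabetes = runif(1) < g$dm,
      hypothyroidism = runif(1) < g$hypo)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Plant non-overlapping apnea events on a recording
#'
#' Places n = round(target_ahi * duration/3600) events with durations
#' uniform in \code{event_duration_range}, uniformly over the recording
#' with at least 10 s between consecutive events. Each event is
#' obstructive (OSA) with probability \code{obstructive_fraction},
#' otherwise central (CSA) or hypopnea (HYP) with equal probability. An
#' event density that cannot fit (total event time plus minimum gaps
#' exceeding the recording) raises an error reporting the occupancy.
#'
#' @param durationS recording length, seconds.
#' @param targetAhi target event rate, events per hour.
#' @param cfg a [simulationConfig()].
#' @param seed optional seed.
#' @return a \code{GroundTruth} list: \code{events} (typed, timed),
#'   \code{true_ahi} (count per recorded hour), \code{duration}.
#' @export
plantEvents <- function(durationS, targetAhi, cfg = simulationConfig(),
                        seed = NULL) {
  if (targetAhi < 0) stopf("target_ahi must be nonnegative")
  if (!is.null(seed)) return(withSeed(seed, plantEvents(durationS, targetAhi, cfg)))
  n <- round(targetAhi * durationS / 3600)
  if (n == 0) {
    return(structure(list(events = makeEventTable(), true_ahi = 0,
                          duration = durationS), class = "GroundTruth"))
  }
  rng <- cfg$event_duration_range
  if (n * mean(rng) >= 0.7 * durationS)
    stopf("infeasible event density: expected occupancy %.0f%% of recording",
          100 * n * mean(rng) / durationS)
  durs <- runif(n, rng[1], rng[2])
  gap <- 10
  free <- durationS - sum(durs) - gap * (n - 1)
  if (free < 0)
    stopf("infeasible event density: %.0f s of events + gaps in %.0f s",
          sum(durs) + gap * (n - 1), durationS)
  u <- sort(runif(n, 0, free))
  starts <- u + cumsum(c(0, durs[-n] + gap))
  types <- ifelse(runif(n) < cfg$obstructive_fraction, "OSA",
                  ifelse(runif(n) < 0.5, "CSA", "HYP"))
  ev <- makeEventTable(types, starts, durs)
  structure(list(events = ev, true_ahi = n / (durationS / 3600),
                 duration = durationS),
            class = "GroundTruth")
}

# piecewise-linear envelope from control points every `step` seconds
.controlEnvelope <- function(n, rate, step, mean, sd, lower = -Inf) {
  tEnd <- (n - 1) / rate
  cpt <- seq(0, tEnd + step, by = step)
  val <- pmax(lower, rnorm(length(cpt), mean, sd))
  approx(cpt, val, xout = (seq_len(n) - 1) / rate, rule = 2)$y
}

#' Synthesize tri-axial thoracic and abdominal effort channels
#'
#' Baseline breathing is an amplitude- and frequency-jittered sinusoid.
#' During apnea events (OSA/CSA) the oscillation amplitude drops to
#' \code{apnea_residual_fraction} of baseline; hypopneas are attenuated by
#' their drawn reduction. Obstructive events flip the abdominal phase by
#' pi relative to the thorax (thoraco-abdominal paradox); central events
#' attenuate both channels coherently. Each waveform is projected onto a
#' random 3-axis orientation, given per-axis DC offsets and white noise,
#' and quantized to the integer 8-bit grid.
#'
#' @param gt a [plantEvents()] ground truth.
#' @param cfg a [simulationConfig()].
#' @param seed optional seed.
#' @return list with 3-axis \code{thoracic} and \code{abdominal}
#'   \linkS4class{ChannelSignal}s at \code{cfg$effort_rate}.
#' @export
synthesizeRespiration <- function(gt, cfg = simulationConfig(), seed = NULL) {
  if (!is.null(seed)) return(withSeed(seed, synthesizeRespiration(gt, cfg)))
  rate <- cfg$effort_rate
  n <- round(gt$duration * rate)
  f <- .controlEnvelope(n, rate, 30, cfg$breathing_freq_mean,
                        cfg$breathing_freq_sd, lower = 0.05)
  phase <- cumsum(2 * pi * f / rate)
  amp <- cfg$baseline_amplitude * .controlEnvelope(n, rate, 30, 1, 0.1,
                                                   lower = 0.3)
  gain <- rep(1, n)
  osa <- rep(FALSE, n)
  ev <- gt$events
  for (i in seq_len(nrow(ev))) {
    a <- max(1L, floor(ev$start[i] * rate) + 1L)
    b <- min(n, ceiling((ev$start[i] + ev$duration[i]) * rate))
    if (a > b) next
    if (ev$etype[i] == "HYP") {
      gain[a:b] <- 1 - runif(1, cfg$hypopnea_reduction_range[1],
                             cfg$hypopnea_reduction_range[2])
    } else {
      gain[a:b] <- cfg$apnea_residual_fraction
      if (ev$etype[i] == "OSA") osa[a:b] <- TRUE
    }
  }
  core <- amp * gain * sin(phase)
  abdCore <- core * ifelse(osa, -1, 1)
  project <- function(w) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    # consistent sensor mounting: dominant axis points with the motion, so
    # the principal-direction sign convention recovers the same polarity
    # on both channels
    if (u[which.max(abs(u))] < 0) u <- -u
    off <- round(runif(3, -20, 20))
    M <- outer(w, u) + matrix(rnorm(3 * n, 0, cfg$noise_sd), n, 3)
    M <- sweep(M, 2, off, "+")
    M <- round(M)
    M[M > 127] <- 127
    M[M < -128] <- -128
    M
  }
  list(thoracic = ChannelSignal(project(core), rate = rate, units = "counts"),
       abdominal = ChannelSignal(project(abdCore), rate = rate,
                                 units = "counts"))
}

#' Synthesize the 1-Hz SpO2 trace
#'
#' Baseline ~97% with a slow sub-percent drift. Each planted event is
#' followed by a desaturation: SpO2 falls from the event end to a nadir
#' \code{desat_lag} seconds later (depth at least 3 points, around
#' \code{desat_depth}) and recovers exponentially with time constant
#' \code{resat_tau}. Overlapping dips take the deeper value. Samples are
#' rounded to integer percent and clamped to [80, 100].
#'
#' @param gt a [plantEvents()] ground truth.
#' @param cfg a [simulationConfig()].
#' @param seed optional seed.
#' @return 1-axis \linkS4class{ChannelSignal} at 1 Hz, percent.
#' @export
synthesizeSpO2 <- function(gt, cfg = simulationConfig(), seed = NULL) {
  if (!is.null(seed)) return(withSeed(seed, synthesizeSpO2(gt, cfg)))
  n <- round(gt$duration)
  t <- seq_len(n) - 1
  base <- 97 + 0.7 * sin(2 * pi * t / 3600 + runif(1, 0, 2 * pi))
  dip <- numeric(n)
  ev <- gt$events
  for (i in seq_len(nrow(ev))) {
    depth <- max(3, rnorm(1, cfg$desat_depth, 0.5))
    # saturation falls through the event with a circulatory lag: onset at
    # event start + lag, nadir at event end + lag, then fast resaturation
    fallStart <- ev$start[i] + cfg$desat_lag
    nadir <- ev$start[i] + ev$duration[i] + cfg$desat_lag
    idx <- which(t >= fallStart & t <= nadir + 6 * cfg$resat_tau)
    if (!length(idx)) next
    shape <- ifelse(t[idx] <= nadir,
                    depth * (t[idx] - fallStart) / (nadir - fallStart),
                    depth * exp(-(t[idx] - nadir) / cfg$resat_tau))
    dip[idx] <- pmax(dip[idx], shape)
  }
  v <- pmin(100, pmax(80, round(base - dip)))
  ChannelSignal(v, rate = 1, units = "percent")
}

#' Simulate an annotated cohort
#'
#' Generates the full synthetic database: for each severity group,
#' phenotypes from [simulatePhenotype()], a target AHI from the group's
#' truncated-normal AHI distribution (redrawn until the realized
#' event-count rate falls in the group's severity interval, and capped at
#' the event density the recording can hold), planted events, effort and
#' SpO2 signals, and the planted events attached as expert annotations.
#' Fully determined by \code{cfg$seed}.
#'
#' @param cfg a [simulationConfig()].
#' @return an \linkS4class{ApneaCohort}; each subject's \code{annotations}
#'   are its planted ground-truth events.
#' @export
simulateCohort <- function(cfg = simulationConfig()) {
  durationS <- cfg$recording_hours * 3600
  hours <- cfg$recording_hours
  capN <- floor(0.65 * durationS / (mean(cfg$event_duration_range) + 10))
  capAhi <- capN / hours
  withSeed(cfg$seed, {
    subjectsList <- list()
    k <- 0L
    for (group in severityLevels()) {
      ng <- cfg$n_subjects[[group]]
      if (is.null(ng) || ng == 0) next
      g <- .simGroups[[group]]
      for (j in seq_len(ng)) {
        k <- k + 1L
        prof <- simulatePhenotype(group)
        # floor guarantees every subject at least one annotated event
        lo <- max(g$interval[1], 0.2, 0.51 / hours)
        hi <- min(g$interval[2], capAhi)
        repeat {
          ahi <- rnormTrunc(1, g$ahi[1], g$ahi[2], lower = lo, upper = hi)
          nEv <- round(ahi * hours)
          if (as.character(classifySeverity(nEv / hours)) == group) break
        }
        gt <- plantEvents(durationS, ahi, cfg)
        resp <- synthesizeRespiration(gt, cfg)
        sp <- synthesizeSpO2(gt, cfg)
        rec <- Recording(resp$thoracic, resp$abdominal, sp,
                         lightOff = 0, lightOn = durationS)
        subjectsList[[k]] <- Subject(sprintf("sim%02d", k), prof, rec,
                                     annotations = gt$events)
      }
    }
    ApneaCohort(subjectsList,
                provenance = sprintf("synthetic cohort (seed %d)", cfg$seed))
  })
}
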