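mkSine <- function(freq, dur, rate, amp = 1, phase = 0)
  amp * sin(2 * pi * freq * (seq_len(dur * rate) - 1) / rate + phase)

test_that("tri-axial fusion recovers a single-axis oscillation", {
  rate <- 10
  s <- mkSine(0.25, 60, rate, amp = 20)
  ch <- ChannelSignal(cbind(s, 0, 0), rate = rate)
  w <- fuseTriaxial(ch, targetRate = rate)
  # recovered up to sign and gain; interior samples to dodge edge effects
  got <- samples(w)[100:500, 1]
  expect_gt(abs(cor(got, s[100:500])), 0.99)
  expect_equal(sd(got), sd(s[100:500]), tolerance = 0.05)

  # identical oscillation on all three axes: same frequency, not tripled
  ch3 <- ChannelSignal(cbind(s, s, s), rate = rate)
  w3 <- fuseTriaxial(ch3, targetRate = rate)
  expect_lt(abs(frequencyFeature(samples(w3)[101:200, 1], rate) - 0.25),
            10 / 256 + 1e-9)

  # constant channel: zero waveform with a warning
  expect_warning(w0 <- fuseTriaxial(ChannelSignal(matrix(5, 600, 3), 10)),
                 "constant")
  expect_true(all(samples(w0) == 0))
})

test_that("band-pass keeps under 5% of out-of-band energy", {
  rate <- 10
  withSeed(8, {
    # broadband noise through the fusion path: whatever leaves the filter
    # carries (almost) no energy outside [0.05, 1] Hz
    noise <- matrix(rnorm(3 * 6000), ncol = 3)
    ch <- ChannelSignal(noise, rate = rate)
    w <- drop(samples(fuseTriaxial(ch, targetRate = rate)))
    n <- length(w)
    P <- Mod(fft(w - mean(w)))^2
    fr <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * rate / n
    inband <- fr >= 0.04 & fr <= 1.01
    expect_lt(sum(P[!inband]) / sum(P), 0.05)
  })
  # an input living entirely outside the band is annihilated: < 5% of its
  # energy survives the filter
  t <- (seq_len(6000) - 1) / rate
  hf <- sin(2 * pi * 2 * t) + sin(2 * pi * 4.3 * t)
  ch2 <- ChannelSignal(cbind(hf, 0.5 * hf, 0), rate = rate)
  w2 <- drop(samples(fuseTriaxial(ch2, targetRate = rate)))
  expect_lt(sum(w2^2) / sum((hf - mean(hf))^2), 0.05)
})

test_that("the epoch grid matches the overlap specification", {
  expect_equal(length(segmentWindows(60)), 101)
  expect_equal(segmentWindows(10), 0)
  expect_equal(length(segmentWindows(9)), 0)
  # count formula on random durations
  withSeed(3, {
    for (d in runif(300, 10, 30000)) {
      s <- segmentWindows(d)
      expect_equal(length(s), floor((d - 10) / 0.5 + 1e-9) + 1)
      expect_lte(s[length(s)], d - 10 + 1e-9)
    }
  })
})

test_that("amplitude feature is sinusoid-calibrated and degree-1 homogeneous", {
  rate <- 10
  x <- mkSine(0.2, 10, rate, amp = 3.7)     # whole cycles in the window
  expect_equal(amplitudeFeature(x), 3.7, tolerance = 0.05)
  expect_equal(amplitudeFeature(numeric(100)), 0)
  expect_equal(amplitudeFeature(0.5 * x), 0.5 * amplitudeFeature(x))
  expect_equal(amplitudeFeature(10 * x), 10 * amplitudeFeature(x))
})

test_that("frequency feature finds the dominant breathing peak", {
  rate <- 10
  x <- mkSine(0.25, 10, rate)
  expect_lt(abs(frequencyFeature(x, rate) - 0.25), 10 / 256 + 1e-9)
  two <- mkSine(0.2, 10, rate, amp = 3) + mkSine(0.5, 10, rate, amp = 0.5)
  expect_lt(abs(frequencyFeature(two, rate) - 0.2), 10 / 256 + 1e-9)
  z <- frequencyFeature(numeric(100), rate)
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "flagged")))
})

test_that("paradox feature is the zero-lag normalized cross-correlation", {
  x <- mkSine(0.2, 10, 10)     # whole cycles in the window
  expect_equal(paradoxFeature(x, x), 1)
  expect_equal(paradoxFeature(x, -x), -1)
  q <- mkSine(0.2, 10, 10, phase = pi / 2)      # quadrature
  expect_equal(paradoxFeature(x, q), 0, tolerance = 1e-6)
  expect_equal(paradoxFeature(3 * x, 0.1 * x), 1)   # scale-invariant
  flat <- paradoxFeature(x, numeric(100))
  expect_equal(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "flagged")))
})

test_that("desaturation features reproduce closed-form traces", {
  # constant 97%
  sp <- ChannelSignal(rep(97, 120), rate = 1)
  f <- desaturationFeatures(sp, 50)
  expect_equal(unname(f), c(97, 97, 97, 97, 0, 0))

  # linear ramp 98 -> 94 over the epoch: mean 96, constant slope
  v <- rep(98, 120); v[51:60] <- seq(98, 94, length.out = 10)
  f2 <- desaturationFeatures(ChannelSignal(v, 1), 50)
  expect_equal(unname(f2["spo2_mean"]), 96)
  expect_equal(unname(f2["spo2_d1_var"]), 0)
  expect_equal(unname(f2["spo2_min"]), 94)

  # step 97 -> 93 mid-epoch: the 21-sample context sees median 97, min 93
  v3 <- c(rep(97, 55), rep(93, 65))
  f3 <- desaturationFeatures(ChannelSignal(v3, 1), 50)
  expect_equal(unname(f3["spo2_med_min_20s"]), 4)
  expect_equal(unname(f3["spo2_median"]), 95)

  # missing coverage fails loudly
  expect_error(desaturationFeatures(sp, 115), "cover")
})

test_that("the desaturation detector applies the 3% baseline rule", {
  v <- c(rep(97, 40), rep(93, 10), rep(97, 30))
  sp <- ChannelSignal(v, 1)
  expect_true(detectDesaturation(sp, 40))     # 97 - 93 = 4 >= 3
  v2 <- c(rep(97, 40), rep(95, 10), rep(97, 30))
  expect_false(detectDesaturation(ChannelSignal(v2, 1), 40))  # 2 < 3
  expect_false(detectDesaturation(ChannelSignal(rep(96, 80), 1), 40))
  expect_error(detectDesaturation(sp, 10), "baseline")
})

test_that("amplitude collapses by >= 85% inside a planted apnea", {
  cfg <- simulationConfig(recording_hours = 600 / 3600, effort_rate = 10,
                          seed = 4)
  gt <- structure(list(events = makeEventTable("CSA", 250, 100),
                       true_ahi = 6, duration = 600), class = "GroundTruth")
  resp <- synthesizeRespiration(gt, cfg, seed = 4)
  w <- fuseTriaxial(resp$thoracic)
  x <- drop(samples(w))
  inside <- amplitudeFeature(x[2750:2850])        # deep inside the event
  base <- amplitudeFeature(x[1000:1100])          # far from it
  expect_lt(inside, 0.15 * base)
})

test_that("per-epoch extraction agrees with the scalar feature functions", {
  s <- smallSubject("fx", hours = 0.1, ahi = 20, seed = 21)
  f <- extractFeatures(s)
  expect_equal(nrow(f$features), length(f$epoch_start))
  expect_equal(ncol(f$features), 9)
  expect_true(all(f$features[, "spo2_min"] <= f$features[, "spo2_median"] +
                    1e-12))
  expect_true(all(f$features[, "spo2_median"] <= f$features[, "spo2_max"] +
                    1e-12))
  expect_true(all(f$features[, "paradox"] >= -1 & f$features[, "paradox"] <= 1))
  # spot-check a handful of epochs against the scalar implementations
  sp <- spo2(recording(s))
  for (i in c(1, 57, 120)) {
    st <- f$epoch_start[i]
    expect_equal(unname(f$features[i, 4:9]),
                 unname(desaturationFeatures(sp, st)), tolerance = 1e-12)
  }
  # SpO2 features are exactly shift-equivariant: dropping the first
  # second of all signals shifts epochs by two hops
  rec <- recording(s)
  shift <- function(ch, secs) {
    k <- round(secs * sampleRate(ch))
    ChannelSignal(samples(ch)[-seq_len(k), , drop = FALSE],
                  rate = sampleRate(ch), units = ch@units)
  }
  rec2 <- Recording(shift(thoracic(rec), 1), shift(abdominal(rec), 1),
                    shift(spo2(rec), 1), lightOff = 0,
                    lightOn = lightOn(rec) - 1)
  s2 <- Subject("fx2", phenotype(s), rec2)
  f2 <- extractFeatures(s2)
  rows <- 80:150
  expect_equal(f2$features[rows, 4:9], f$features[rows + 2, 4:9],
               tolerance = 1e-12, ignore_attr = TRUE)
})
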