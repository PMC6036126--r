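mkTrain <- function(nApn, nNor, sep = 6, seed = 1) {
  withSeed(seed, {
    X <- rbind(matrix(rnorm(nApn * 3, sep), ncol = 3),
               matrix(rnorm(nNor * 3, 0), ncol = 3))
    colnames(X) <- c("f1", "f2", "f3")
    trainingSet(X, c(rep("APN", nApn), rep("NOR", nNor)),
                rep("s", nApn + nNor))
  })
}

test_that("upsampling duplicates the minority class to parity", {
  tr <- mkTrain(100, 300)
  up <- upsampleBalance(tr, seed = 7)
  tab <- table(up$labels)
  expect_equal(unname(tab[["APN"]]), 300)
  expect_equal(unname(tab[["NOR"]]), 300)
  # each original APN epoch appears 3x +/- 1 (100 into 300)
  key <- apply(up$features[up$labels == "APN", ], 1, paste, collapse = ",")
  counts <- table(key)
  expect_true(all(counts %in% c(3, 4)))   # 3x, remainder none here
  expect_equal(length(counts), 100)

  # balanced input is a fixed point
  bal <- mkTrain(50, 50)
  expect_identical(upsampleBalance(bal, 1), bal)

  # an empty class is an explicit failure
  none <- trainingSet(matrix(rnorm(30), ncol = 3,
                             dimnames = list(NULL, c("f1", "f2", "f3"))),
                      rep("NOR", 10), rep("s", 10))
  expect_error(upsampleBalance(none), "unusable")
})

test_that("upsampling remainder draw is seeded and majority untouched", {
  tr <- mkTrain(70, 200)     # 200/70: 2x full + 60 drawn
  a <- upsampleBalance(tr, seed = 3)
  b <- upsampleBalance(tr, seed = 3)
  expect_identical(a, b)
  expect_identical(a$features[a$labels == "NOR", ],
                   tr$features[tr$labels == "NOR", ])
  expect_equal(sum(a$labels == "APN"), 200)
})

test_that("the RBF SVM separates a separable toy problem exactly", {
  tr <- mkTrain(80, 80)
  clf <- trainEpochClassifier(tr)
  pred <- predictEpochs(clf, tr$features)
  expect_equal(pred$label, tr$labels)
  expect_true(all(pred$score[pred$label == "APN"] > 0))
  expect_true(all(pred$score[pred$label == "NOR"] < 0))
})

test_that("label-free features give chance-level accuracy", {
  withSeed(99, {
    X <- matrix(rnorm(400 * 3), ncol = 3,
                dimnames = list(NULL, c("f1", "f2", "f3")))
    y <- sample(c("NOR", "APN"), 400, replace = TRUE)
    tr <- trainingSet(X[1:200, ], y[1:200], rep("s", 200))
    clf <- trainEpochClassifier(tr)
    pred <- predictEpochs(clf, X[201:400, ])
    acc <- mean(pred$label == y[201:400])
    expect_gt(acc, 0.35)
    expect_lt(acc, 0.65)
  })
})

test_that("zero-variance features are dropped with a warning", {
  tr <- mkTrain(50, 50)
  tr$features[, "f3"] <- 1
  expect_warning(clf <- trainEpochClassifier(tr), "zero-variance")
  expect_equal(clf@featureNames, c("f1", "f2"))
  pred <- predictEpochs(clf, tr$features)   # extra column tolerated
  expect_equal(nrow(pred), 100)
})

test_that("prediction is deterministic and schema-checked", {
  tr <- mkTrain(60, 60)
  clf <- trainEpochClassifier(tr)
  X <- tr$features[c(1, 1, 5), ]
  p1 <- predictEpochs(clf, X)
  p2 <- predictEpochs(clf, X)
  expect_identical(p1, p2)
  expect_identical(p1$label[1], p1$label[2])  # duplicated row, same label
  bad <- tr$features[, 1:2]
  colnames(bad) <- c("f1", "zz")
  expect_error(predictEpochs(clf, bad), "schema")
})

smLabels <- function(lab, paradox = rep(0, length(lab)),
                     cfg = stateMachineConfig()) {
  pred <- data.frame(epoch_start = (seq_along(lab) - 1) * 0.5, label = lab,
                     score = 0)
  applyStateMachine(pred, paradox, cfg)$label
}

test_that("the state machine debounces, gates on paradox and bridges gaps", {
  # a long APN run is retained in full
  expect_equal(smLabels(rep("APN", 40)), rep("APN", 40))

  # a single isolated APN epoch is debounced to NOR
  lab <- rep("NOR", 20); lab[10] <- "APN"
  expect_equal(smLabels(lab), rep("NOR", 20))

  # 3 consecutive APN (< enter 4) are debounced without the paradox gate...
  lab3 <- c(rep("NOR", 5), rep("APN", 3), rep("NOR", 8))
  expect_equal(smLabels(lab3), rep("NOR", 16))

  # ...but 2 consecutive APN with paradox -0.8 pass the fast-entry gate
  lab2 <- c(rep("NOR", 5), rep("APN", 2), rep("NOR", 8))
  par2 <- rep(0, 15); par2[6:7] <- -0.8
  got <- smLabels(lab2, par2)
  expect_equal(got[6:7], c("APN", "APN"))
  expect_equal(got[-(6:7)], rep("NOR", 13))

  # a NOR gap shorter than the exit requirement is bridged inside an event
  labG <- c(rep("APN", 6), rep("NOR", 2), rep("APN", 6), rep("NOR", 6))
  expect_equal(smLabels(labG), c(rep("APN", 14), rep("NOR", 6)))

  # a gap reaching the exit threshold closes the event
  labC <- c(rep("APN", 6), rep("NOR", 4), rep("APN", 6), rep("NOR", 6))
  gotC <- smLabels(labC)
  expect_equal(gotC[7:10], rep("NOR", 4))
  expect_equal(gotC[1:6], rep("APN", 6))
  expect_equal(gotC[11:16], rep("APN", 6))

  expect_error(smLabels(rep("APN", 5), paradox = numeric(3)), "match")
})

test_that("smoothed output never contains APN runs below the entry requirement", {
  cfg <- stateMachineConfig(enter_threshold = 4, exit_threshold = 4)
  withSeed(12, {
    for (rep in 1:40) {
      lab <- sample(c("NOR", "APN"), 200, replace = TRUE, prob = c(0.7, 0.3))
      out <- smLabels(lab, cfg = cfg)   # paradox 0: no gating
      r <- rle(out == "APN")
      if (any(r$values)) expect_gte(min(r$lengths[r$values]), 4)
    }
  })
})

test_that("desaturation correction converts only NOR epochs", {
  v <- c(rep(97, 40), rep(93, 10), rep(97, 70))
  sp <- ChannelSignal(v, 1)
  pred <- data.frame(epoch_start = c(25, 40, 60), label = c("NOR", "NOR", "NOR"),
                     score = 0)
  out <- desaturationCorrection(pred, spo2 = sp)
  expect_equal(out$label, c("NOR", "APN", "NOR"))   # only the dip epoch flips

  # APN epochs never change, whatever the SpO2 does
  pred2 <- data.frame(epoch_start = c(25, 40), label = c("APN", "APN"),
                      score = 0)
  expect_equal(desaturationCorrection(pred2, spo2 = sp)$label, c("APN", "APN"))

  # monotonicity on random labels/flags: APN set only grows
  withSeed(6, {
    for (rep in 1:20) {
      lab <- sample(c("NOR", "APN"), 50, replace = TRUE)
      fl <- sample(c(TRUE, FALSE), 50, replace = TRUE)
      p <- data.frame(epoch_start = seq_len(50), label = lab, score = 0)
      o <- desaturationCorrection(p, desat = fl)
      expect_true(all(o$label[lab == "APN"] == "APN"))
      expect_gte(sum(o$label == "APN"), sum(lab == "APN"))
    }
  })
})
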