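table3 <- matrix(c(6, 1, 0, 0,
                   4, 7, 1, 0,
                   0, 3, 3, 9,
                   0, 0, 0, 28), nrow = 4, byrow = TRUE,
                 dimnames = list(Prediction = severityLevels(),
                                 Expert = severityLevels()))

test_that("event matching follows the overlap rule one-to-one", {
  det <- makeEventTable("APN", 10, 20)      # [10, 30)
  ann <- makeEventTable("APN", 20, 20)      # [20, 40)
  m <- matchEvents(det, ann)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  # annotated but nothing detected: false negative
  m2 <- matchEvents(makeEventTable(), ann)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 0, 1))

  # disjoint: one FP and one FN
  m3 <- matchEvents(makeEventTable("APN", 0, 15),
                    makeEventTable("APN", 100, 20))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 1, 1))

  # half-open intervals: touching events do not overlap
  m4 <- matchEvents(makeEventTable("APN", 10, 20),
                    makeEventTable("APN", 30, 20))
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 1, 1))

  # one long detection absorbs only one annotation in one-to-one mode
  det5 <- makeEventTable("APN", 0, 100)
  ann5 <- makeEventTable(c("APN", "APN"), c(10, 60), c(20, 20))
  m5 <- matchEvents(det5, ann5)
  expect_equal(c(m5$tp, m5$fp, m5$fn), c(1, 0, 1))
  m5b <- matchEvents(det5, ann5, mode = "many_to_one")
  expect_equal(c(m5b$tp, m5b$fp, m5b$fn), c(1, 0, 0))

  # self-overlapping lists are rejected
  expect_error(matchEvents(makeEventTable(c("APN", "APN"), c(0, 5), c(20, 20)),
                           ann), "overlap")
})

test_that("match counts partition both event lists", {
  withSeed(42, {
    for (rep in 1:25) {
      mk <- function(n) {
        starts <- cumsum(runif(n, 15, 80))
        makeEventTable(rep("APN", n), starts, runif(n, 10, 14))
      }
      det <- mk(sample(3:12, 1)); ann <- mk(sample(3:12, 1))
      m <- matchEvents(det, ann)
      expect_equal(m$tp + m$fp, nrow(det))
      expect_equal(m$tp + m$fn, nrow(ann))
    }
  })
})

test_that("PPV/recall/F1 formulas and 0/0 conventions hold", {
  expect_equal(unlist(ppvF1(8, 2, 2)), c(ppv = 0.8, recall = 0.8, f1 = 0.8))
  expect_equal(unlist(ppvF1(0, 0, 5)), c(ppv = 0, recall = 0, f1 = 0))
  expect_equal(unlist(ppvF1(3, 1, 0)), c(ppv = 0.75, recall = 1, f1 = 6 / 7))
  expect_equal(unlist(ppvF1(0, 0, 0)), c(ppv = 1, recall = 1, f1 = 1))
})

test_that("median +/- MAD is the unscaled robust summary", {
  expect_equal(medianMAD(c(1, 2, 3)), c(median = 2, mad = 1))
  expect_equal(medianMAD(5), c(median = 5, mad = 0))
  expect_equal(medianMAD(c(1, 1, 1, 9)), c(median = 1, mad = 0))
  expect_error(medianMAD(numeric(0)), "empty")
})

test_that("the severity confusion matrix accumulates in fixed class order", {
  pred <- c("Severe", "Normal", "Severe")
  truth <- c("Moderate", "Normal", "Severe")
  m <- confusionMatrix4(pred, truth)
  expect_equal(sum(m), 3)
  expect_equal(m["Severe", "Moderate"], 1L)
  expect_equal(m["Normal", "Normal"], 1L)
  expect_equal(sum(confusionMatrix4(character(), character())), 0)
  expect_error(confusionMatrix4("Severe", c("Mild", "Mild")), "length")
  expect_error(confusionMatrix4("severeX", "Mild"), "severity labels")
})

test_that("four-class metrics reproduce the reference confusion matrix", {
  fc <- fourClassMetrics(table3)
  expect_equal(fc$accuracy, 44 / 62, tolerance = 1e-12)
  expect_equal(round(100 * fc$accuracy, 2), 70.97)
  expect_equal(unname(round(100 * fc$sensitivity, 1)),
               c(60, 63.6, 75, 75.7))
  expect_equal(unname(round(100 * fc$ppv, 1)), c(85.7, 58.3, 20, 100))

  # a perfect diagonal matrix gives 100% everywhere
  eye <- diag(c(5, 5, 5, 5))
  fcI <- fourClassMetrics(eye)
  expect_equal(unname(fcI$sensitivity), rep(1, 4))
  expect_equal(unname(fcI$ppv), rep(1, 4))
  expect_equal(fcI$accuracy, 1)

  # empty classes are flagged undefined, not scored 0
  m0 <- table3; m0[, 1] <- 0; m0[1, ] <- 0
  expect_true(is.na(fourClassMetrics(m0)$sensitivity[["Normal"]]))
})

test_that("screening metrics with likelihood ratios match the reference matrix", {
  sc <- screeningMetrics(table3)
  expect_equal(sc$sensitivity, 40 / 41)
  expect_equal(sc$specificity, 18 / 21)
  expect_equal(sc$accuracy, 58 / 62)
  expect_equal(round(100 * sc$sensitivity, 1), 97.6)
  expect_equal(round(100 * sc$specificity, 1), 85.7)
  expect_equal(round(100 * sc$accuracy, 1), 93.5, tolerance = 0.11)
  expect_equal(sc$lr_pos, (40 / 41) / (1 - 18 / 21))
  expect_equal(round(sc$lr_pos, 1), 6.8)
  expect_equal(round(sc$lr_neg, 2), 0.03)

  # perfect binary split
  perfect <- diag(c(10, 10, 10, 10))
  sp <- screeningMetrics(perfect)
  expect_equal(sp$sensitivity, 1)
  expect_equal(sp$specificity, 1)
  expect_equal(sp$accuracy, 1)
  expect_equal(sp$lr_neg, 0)
  expect_true(is.na(sp$lr_pos))   # undefined at specificity 1

  # collapsing can only help accuracy
  expect_gte(screeningMetrics(table3)$accuracy,
             fourClassMetrics(table3)$accuracy)
})

test_that("LOSOCV runs the protocol without leaking the held-out subject", {
  cfg <- simulationConfig(n_subjects = c(Normal = 2, Mild = 1, Moderate = 1,
                                         Severe = 4),
                          recording_hours = 0.5, effort_rate = 10, seed = 19)
  coh <- simulateCohort(cfg)
  pc <- apneaConfig(knn = list(K = 3, K_prime = 1), seed = 19)
  rep1 <- losoCV(coh, pc)
  expect_equal(nrow(rep1$per_subject), 8)
  expect_equal(sum(rep1$confusion), 8)
  expect_setequal(rep1$per_subject$id, subjectIds(coh))

  # the held-out subject is never its own neighbor
  for (i in seq_len(nSubjects(coh))) {
    s <- subjects(coh)[[i]]
    db <- ApneaCohort(subjects(coh)[-i])
    res <- screenSubject(s, db, pc)
    expect_false(subjectId(s) %in% res$neighbors$neighbors)
  }

  # fixed seed: identical aggregate report across runs
  rep2 <- losoCV(coh, pc)
  expect_identical(rep1$per_subject, rep2$per_subject)
  expect_identical(rep1$confusion, rep2$confusion)
  expect_identical(formatReport(rep1), formatReport(rep2))

  # an unannotated subject is rejected
  bad <- subjects(coh)
  bad[[2]] <- Subject(subjectId(bad[[2]]), phenotype(bad[[2]]),
                      recording(bad[[2]]))
  expect_error(losoCV(ApneaCohort(bad), pc), "unannotated")
})
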