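## Leave-one-subject-out evaluation protocol and report assembly.

#' Leave-one-subject-out cross-validation of the screening pipeline
#'
#' Each subject in turn is held out as the new-arriving query; the
#' remaining subjects form the database from which [screenSubject()]
#' builds its neighbor-specific model (the held-out subject's epochs never
#' enter training). Per subject the detected events are matched one-to-one
#' against the expert annotations (all apnea types merged) and the REI-
#' based severity is compared with the annotation-derived severity.
#' Aggregates: per-subject PPV/recall/F1 summarized by median +/- MAD,
#' overall and per expert-severity stratum; the 4x4 severity confusion
#' matrix with its per-class metrics; and the moderate-or-worse screening
#' metrics with likelihood ratios.
#'
#' @param cohort an annotated \linkS4class{ApneaCohort} with at least
#'   K + K' + 1 subjects.
#' @param config an [apneaConfig()].
#' @param verbose print per-fold progress.
#' @return a \code{LOSOCVReport} list: \code{per_subject} (data.frame),
#'   \code{confusion}, \code{four_class}, \code{screening},
#'   \code{event_summary} (median/MAD of PPV and F1, overall and per
#'   stratum), plus the \code{config} and \code{seed} used.
#' @export
losoCV <- function(cohort, config = apneaConfig(), verbose = FALSE) {
  stopifnot(is(cohort, "ApneaCohort"))
  ids <- subjectIds(cohort)
  n <- length(ids)
  if (n < config$knn$K + config$knn$K_prime + 1)
    stopf("LOSOCV needs at least K + K' + 1 = %d subjects, got %d",
          config$knn$K + config$knn$K_prime + 1, n)
  unann <- vapply(cohort@subjects, function(s) nrow(s@annotations) == 0,
                  logical(1))
  if (any(unann))
    stopf("unannotated subject(s) in cohort: %s",
          paste(ids[unann], collapse = ", "))
  cache <- lapply(cohort@subjects, extractFeatures, config = config)
  names(cache) <- ids
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (verbose) message(sprintf("fold %d/%d: %s", i, n, ids[i]))
    query <- cohort@subjects[[i]]
    db <- ApneaCohort(cohort@subjects[-i], provenance = cohort@provenance)
    res <- screenSubject(query, db, config, featureCache = cache,
                         seed = subSeed(config$seed, i))
    ann <- mergeEventTypes(query@annotations)
    mt <- matchEvents(res$events, ann, mode = config$evaluation$matching)
    rec <- query@recording
    trueRei <- computeREI(ann, rec@lightOff, rec@lightOn)
    rows[[i]] <- data.frame(
      id = ids[i], true_rei = trueRei,
      true_severity = as.character(classifySeverity(trueRei)),
      rei = res$rei, severity = res$severity,
      tp = mt$tp, fp = mt$fp, fn = mt$fn,
      ppv = mt$ppv, recall = mt$recall, f1 = mt$f1,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  cm <- confusionMatrix4(per$severity, per$true_severity)
  strata <- c(list(All = per),
              split(per, factor(per$true_severity, levels = severityLevels())))
  evSummary <- lapply(strata, function(d) {
    if (!nrow(d)) return(NULL)
    list(n = nrow(d), ppv = medianMAD(d$ppv), f1 = medianMAD(d$f1))
  })
  structure(list(per_subject = per, confusion = cm,
                 four_class = fourClassMetrics(cm),
                 screening = screeningMetrics(cm),
                 event_summary = evSummary,
                 config = config, seed = config$seed, n_subjects = n),
            class = "LOSOCVReport")
}

#' Render a LOSOCV report as text
#'
#' @param report a [losoCV()] result.
#' @return character vector of report lines.
#' @export
formatReport <- function(report) {
  stopifnot(inherits(report, "LOSOCVReport"))
  fmtMM <- function(mm) sprintf("%.2f +/- %.2f", mm[["median"]], mm[["mad"]])
  lines <- c(
    sprintf("LOSOCV report: %d subjects (seed %d)", report$n_subjects,
            report$seed),
    "",
    "Event-by-event detection (median +/- MAD over subjects):")
  for (nm in names(report$event_summary)) {
    s <- report$event_summary[[nm]]
    if (is.null(s)) next
    lines <- c(lines, sprintf("  %-8s (n=%2d)  PPV %s   F1 %s", nm, s$n,
                              fmtMM(s$ppv), fmtMM(s$f1)))
  }
  cm <- report$confusion
  lines <- c(lines, "", "Severity confusion matrix (rows = prediction):",
             sprintf("  %-9s %s", "", paste(sprintf("%9s", colnames(cm)),
                                            collapse = "")))
  for (r in seq_len(4))
    lines <- c(lines, sprintf("  %-9s %s", rownames(cm)[r],
                              paste(sprintf("%9d", cm[r, ]), collapse = "")))
  fc <- report$four_class
  pct <- function(x) ifelse(is.na(x), "  NA", sprintf("%.1f", 100 * x))
  lines <- c(lines,
    sprintf("  accuracy %.2f%%", 100 * fc$accuracy),
    sprintf("  sensitivity (%%): %s", paste(pct(fc$sensitivity), collapse = " / ")),
    sprintf("  PPV (%%):         %s", paste(pct(fc$ppv), collapse = " / ")),
    "",
    "Screening (positive = Moderate or Severe):")
  sc <- report$screening
  lines <- c(lines,
    sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%",
            100 * sc$sensitivity, 100 * sc$specificity, 100 * sc$accuracy),
    sprintf("  LR+ %.2f  LR- %.3f", sc$lr_pos, sc$lr_neg))
  lines
}

#' @export
print.LOSOCVReport <- function(x, ...) {
  cat(formatReport(x), sep = "\n")
  invisible(x)
}
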