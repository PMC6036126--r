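## Event-by-event matching, summary statistics, severity confusion matrix,
## screening metrics.

#' Match detected against annotated events
#'
#' Greedy one-to-one matching in start-time order: each detected event that
#' overlaps at least one still-unmatched annotated event is a true
#' positive, paired with the earliest-starting such event; unmatched
#' detected events are false positives and unmatched annotated events false
#' negatives. Intervals are half-open. With \code{mode = "many_to_one"}
#' a detected event is a TP whenever it overlaps any annotated event
#' (sensitivity-analysis variant: one long detection can absorb several
#' annotations).
#'
#' @param detected,annotated event tables; each must be free of internal
#'   overlaps.
#' @param mode \code{"one_to_one"} (default) or \code{"many_to_one"}.
#' @return list with counts \code{tp}, \code{fp}, \code{fn} and the
#'   derived \code{ppv}, \code{recall}, \code{f1} (see [ppvF1()]).
#' @export
matchEvents <- function(detected, annotated,
                        mode = c("one_to_one", "many_to_one")) {
  mode <- match.arg(mode)
  validateEventTable(detected, "detected events")
  validateEventTable(annotated, "annotated events")
  if (selfOverlaps(detected)) stopf("detected events overlap each other")
  if (selfOverlaps(annotated)) stopf("annotated events overlap each other")
  det <- detected[order(detected$start), , drop = FALSE]
  ann <- annotated[order(annotated$start), , drop = FALSE]
  nA <- nrow(ann)
  used <- rep(FALSE, nA)
  tp <- 0L
  for (i in seq_len(nrow(det))) {
    s <- det$start[i]; e <- s + det$duration[i]
    hit <- which(!used & ann$start < e & (ann$start + ann$duration) > s)
    if (length(hit)) {
      tp <- tp + 1L
      if (mode == "one_to_one") used[hit[1]] <- TRUE
      else used[hit] <- TRUE
    }
  }
  fp <- nrow(det) - tp
  fn <- if (mode == "one_to_one") sum(!used) else nA - sum(used)
  c(list(tp = tp, fp = fp, fn = fn), ppvF1(tp, fp, fn))
}

#' Precision, recall and F1 from match counts
#'
#' PPV = tp/(tp+fp), recall = tp/(tp+fn), F1 their harmonic mean. The 0/0
#' conventions: with no detections but existing annotations all three are
#' 0; with nothing detected and nothing annotated all three are 1.
#'
#' @param tp,fp,fn nonnegative counts (or a list with those elements as
#'   first argument).
#' @return list \code{ppv}, \code{recall}, \code{f1}.
#' @export
ppvF1 <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) return(list(ppv = 1, recall = 1, f1 = 1))
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (ppv + recall > 0) 2 * ppv * recall / (ppv + recall) else 0
  list(ppv = ppv, recall = recall, f1 = f1)
}

#' Median and (unscaled) median absolute deviation
#'
#' The descriptive median +/- MAD summary: MAD = median(|x - median(x)|)
#' with no consistency factor.
#'
#' @param values nonempty numeric vector.
#' @return named vector \code{median}, \code{mad}.
#' @export
medianMAD <- function(values) {
  if (!length(values)) stopf("median/MAD of an empty vector is undefined")
  m <- median(values)
  c(median = m, mad = median(abs(values - m)))
}

#' Severity confusion matrix
#'
#' 4x4 counts with rows = predicted severity, columns = expert severity,
#' both ordered Normal/Mild/Moderate/Severe.
#'
#' @param pred,truth severity vectors (factors or strings over
#'   [severityLevels()]), equal length.
#' @return 4x4 integer matrix.
#' @export
confusionMatrix4 <- function(pred, truth) {
  if (length(pred) != length(truth))
    stopf("prediction and truth differ in length (%d vs %d)",
          length(pred), length(truth))
  lv <- severityLevels()
  p <- factor(as.character(pred), levels = lv)
  t <- factor(as.character(truth), levels = lv)
  if (anyNA(p) || anyNA(t)) stopf("severity labels must be one of: %s",
                                  paste(lv, collapse = ", "))
  m <- table(Prediction = p, Expert = t)
  matrix(as.integer(m), 4, 4, dimnames = list(Prediction = lv, Expert = lv))
}

#' Per-class sensitivity/PPV and overall accuracy of a 4x4 matrix
#'
#' Sensitivity of a class is its diagonal count over its expert-column
#' sum; PPV over its prediction-row sum; accuracy is trace over total.
#' Classes with zero denominator get NA (undefined), never 0.
#'
#' @param m 4x4 confusion matrix (rows = prediction, columns = expert).
#' @return list \code{sensitivity}, \code{ppv} (named per class),
#'   \code{accuracy}.
#' @export
fourClassMetrics <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 4, ncol(m) == 4)
  lv <- severityLevels()
  cs <- colSums(m); rs <- rowSums(m)
  sens <- ifelse(cs > 0, diag(m) / cs, NA_real_)
  ppv <- ifelse(rs > 0, diag(m) / rs, NA_real_)
  list(sensitivity = setNames(sens, lv), ppv = setNames(ppv, lv),
       accuracy = sum(diag(m)) / sum(m))
}

#' Screening metrics for the moderate-or-worse cutoff
#'
#' Collapses the 4x4 severity matrix to a 2x2 screen with positive =
#' Moderate or Severe (the AHI >= 15 treatment-need cutoff, with the
#' boundary AHI = 15 falling in Mild per the bucket edges) and reports
#' sensitivity, specificity, accuracy and the diagnostic likelihood
#' ratios LR+ = sens/(1 - spec) and LR- = (1 - sens)/spec. Zero
#' denominators give NA.
#'
#' @param m 4x4 confusion matrix (rows = prediction, columns = expert).
#' @return list \code{sensitivity}, \code{specificity}, \code{accuracy},
#'   \code{lr_pos}, \code{lr_neg}.
#' @export
screeningMetrics <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 4, ncol(m) == 4)
  pos <- 3:4; neg <- 1:2
  tp <- sum(m[pos, pos]); fn <- sum(m[neg, pos])
  fp <- sum(m[pos, neg]); tn <- sum(m[neg, neg])
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / sum(m)
  lrp <- if (!is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  lrn <- if (!is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       lr_pos = lrp, lr_neg = lrn)
}
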