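## Neighbor-specific epoch classifier: class balancing, RBF-SVM training,
## state-machine smoothing, desaturation correction.

#' Assemble a training set of epochs
#'
#' @param features epochs x features numeric matrix (named columns).
#' @param labels character vector over \code{NOR}/\code{APN}, one per epoch.
#' @param subjectIds provenance id per epoch.
#' @return a \code{TrainingSet} list.
#' @export
trainingSet <- function(features, labels, subjectIds) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            length(labels) == length(subjectIds))
  bad <- setdiff(unique(labels), c("NOR", "APN"))
  if (length(bad)) stopf("unknown epoch label(s): %s", paste(bad, collapse = ", "))
  structure(list(features = features, labels = as.character(labels),
                 subject_ids = as.character(subjectIds)),
            class = "TrainingSet")
}

#' Balance epoch classes by uniform duplication
#'
#' Duplicates the minority class until both classes have equal counts: each
#' minority epoch is repeated floor(n_major/n_minor) times and the
#' remainder is drawn without replacement under the given seed. The
#' majority class is untouched. A training set with an empty class is
#' unusable and raises an error.
#'
#' @param train a [trainingSet()].
#' @param seed integer seed for the remainder draw.
#' @return a balanced \code{TrainingSet}.
#' @export
upsampleBalance <- function(train, seed = 1) {
  stopifnot(inherits(train, "TrainingSet"))
  tab <- table(factor(train$labels, levels = c("NOR", "APN")))
  if (any(tab == 0))
    stopf("class '%s' has no epochs: neighbor set unusable",
          names(tab)[tab == 0][1])
  if (tab[1] == tab[2]) return(train)
  minor <- names(tab)[which.min(tab)]
  idxMin <- which(train$labels == minor)
  nMin <- length(idxMin); nMaj <- max(tab)
  reps <- nMaj %/% nMin
  rem <- nMaj - reps * nMin
  extraIdx <- rep(idxMin, reps - 1)
  if (rem > 0)
    extraIdx <- c(extraIdx, withSeed(seed, sample(idxMin, rem, replace = FALSE)))
  keep <- c(seq_along(train$labels), extraIdx)
  trainingSet(train$features[keep, , drop = FALSE], train$labels[keep],
              train$subject_ids[keep])
}

#' Train the neighbor-specific epoch classifier
#'
#' Z-scores each feature with the training-set mean and standard deviation
#' (zero-variance features are dropped with a warning) and fits a
#' C-classification support vector machine with radial-basis-function
#' kernel. The returned object carries the standardization parameters so
#' prediction applies the identical transform.
#'
#' @param train a (balanced) [trainingSet()].
#' @param gamma RBF kernel width; default \code{NULL} means 1/n_features
#'   after standardization.
#' @param C soft-margin cost (default 1).
#' @return an \linkS4class{EpochClassifier}.
#' @export
trainEpochClassifier <- function(train, gamma = NULL, C = 1) {
  stopifnot(inherits(train, "TrainingSet"))
  X <- train$features
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  dropped <- colnames(X)[scl < 1e-12 | !is.finite(scl)]
  if (length(dropped)) {
    warnf("dropping zero-variance feature(s): %s",
          paste(dropped, collapse = ", "))
    keep <- setdiff(colnames(X), dropped)
    if (!length(keep)) stopf("no informative features left after dropping")
    X <- X[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(Z)
  y <- factor(train$labels, levels = c("NOR", "APN"))
  fit <- e1071::svm(Z, y, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = C, scale = FALSE)
  new("EpochClassifier", model = fit, center = ctr, scale = scl,
      featureNames = colnames(Z), dropped = as.character(dropped))
}

#' Predict per-epoch apnea labels
#'
#' @param model an \linkS4class{EpochClassifier}.
#' @param features epochs x features matrix with (at least) the columns the
#'   model was trained on.
#' @param epochStart epoch start times (defaults to a 0.5-s grid).
#' @return data.frame \code{epoch_start}, \code{label} (NOR/APN),
#'   \code{score} (signed margin, positive towards APN).
#' @export
predictEpochs <- function(model, features,
                          epochStart = (seq_len(nrow(features)) - 1) * 0.5) {
  stopifnot(is(model, "EpochClassifier"), is.matrix(features))
  miss <- setdiff(model@featureNames, colnames(features))
  if (length(miss))
    stopf("feature schema mismatch: missing column(s) %s",
          paste(miss, collapse = ", "))
  X <- features[, model@featureNames, drop = FALSE]
  Z <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  pr <- predict(model@model, Z, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # orient the margin so positive means APN
  if (grepl("^NOR", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
  data.frame(epoch_start = epochStart, label = as.character(pr),
             score = as.numeric(dv), stringsAsFactors = FALSE)
}

#' State-machine configuration
#'
#' @param enter_threshold consecutive APN epochs required to open an event
#'   candidate (default 4, i.e. 2 s of 0.5-s hops).
#' @param exit_threshold consecutive NOR epochs required to close an event
#'   (default 4).
#' @param paradox_gate paradox value below which entry needs only
#'   ceiling(enter_threshold/2) epochs (default -0.5).
#' @return a validated \code{StateMachineConfig} list.
#' @export
stateMachineConfig <- function(enter_threshold = 4, exit_threshold = 4,
                               paradox_gate = -0.5) {
  cfg <- list(enter_threshold = as.integer(enter_threshold),
              exit_threshold = as.integer(exit_threshold),
              paradox_gate = as.numeric(paradox_gate))
  if (cfg$enter_threshold < 1 || cfg$exit_threshold < 1)
    stopf("state-machine thresholds must be >= 1")
  class(cfg) <- "StateMachineConfig"
  cfg
}

#' Temporal smoothing of epoch predictions by a three-state machine
#'
#' NORMAL -> CANDIDATE -> IN_EVENT automaton over the epoch sequence: an
#' event opens after \code{enter_threshold} consecutive APN predictions
#' (only half as many when the epoch's thoraco-abdominal paradox falls
#' below \code{paradox_gate}, the fast-entry path for clearly obstructive
#' epochs), and closes after \code{exit_threshold} consecutive NOR
#' predictions. APN bursts too short to open an event are debounced to
#' NOR; NOR gaps inside an event shorter than the exit requirement are
#' bridged to APN.
#'
#' @param pred data.frame from [predictEpochs()].
#' @param paradox per-epoch paradox values, aligned with \code{pred}.
#' @param cfg a [stateMachineConfig()].
#' @return \code{pred} with smoothed labels.
#' @export
applyStateMachine <- function(pred, paradox, cfg = stateMachineConfig()) {
  stopifnot(inherits(cfg, "StateMachineConfig"))
  if (length(paradox) != nrow(pred))
    stopf("paradox sequence length (%d) does not match epochs (%d)",
          length(paradox), nrow(pred))
  apn <- pred$label == "APN"
  n <- length(apn)
  out <- logical(n)
  enter <- cfg$enter_threshold
  fast <- as.integer(ceiling(enter / 2))
  exitT <- cfg$exit_threshold
  gate <- cfg$paradox_gate
  inEvent <- FALSE
  runA <- 0L; runN <- 0L
  for (i in seq_len(n)) {
    if (!inEvent) {
      if (apn[i]) {
        runA <- runA + 1L
        thr <- if (!is.na(paradox[i]) && paradox[i] < gate) fast else enter
        if (runA >= thr) {
          inEvent <- TRUE
          out[(i - runA + 1L):i] <- TRUE
          runN <- 0L
        }
      } else runA <- 0L
    } else {
      if (apn[i]) {
        if (runN > 0L) out[(i - runN):(i - 1L)] <- TRUE
        runN <- 0L
        out[i] <- TRUE
      } else {
        runN <- runN + 1L
        if (runN >= exitT) {
          inEvent <- FALSE
          runA <- 0L; runN <- 0L
        }
      }
    }
  }
  pred$label <- ifelse(out, "APN", "NOR")
  pred
}

#' Desaturation correction of normal epochs
#'
#' Every epoch classified NOR whose SpO2 satisfies the desaturation rule
#' (segment minimum at least 3 points below the preceding 20-s baseline
#' median) is corrected to APN. APN epochs are never changed, so the
#' correction is monotone: apneic time can only grow.
#'
#' @param pred data.frame of epoch labels ([predictEpochs()] /
#'   [applyStateMachine()] output).
#' @param spo2 1-Hz \linkS4class{ChannelSignal}; ignored when \code{desat}
#'   is supplied.
#' @param desat optional precomputed logical desaturation flags per epoch
#'   (e.g. from [extractFeatures()]).
#' @param config pipeline configuration, see [apneaConfig()].
#' @return \code{pred} with corrected labels.
#' @export
desaturationCorrection <- function(pred, spo2 = NULL, desat = NULL,
                                   config = apneaConfig()) {
  if (is.null(desat)) {
    if (is.null(spo2)) stopf("either spo2 or precomputed desat flags required")
    desat <- desatFlags(spo2, pred$epoch_start, config$features)
  }
  if (length(desat) != nrow(pred))
    stopf("desaturation flags length (%d) does not match epochs (%d)",
          length(desat), nrow(pred))
  pred$label[pred$label == "NOR" & desat] <- "APN"
  pred
}
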