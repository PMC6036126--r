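## Orchestration: the per-subject screening chain.

# pool neighbor epochs into a capped, balanced training set
buildNeighborTraining <- function(featList, ids, config, seed) {
  X <- do.call(rbind, lapply(featList, `[[`, "features"))
  y <- unlist(lapply(featList, `[[`, "labels"), use.names = FALSE)
  if (is.null(y) || length(y) != nrow(X))
    stopf("neighbor feature sets must carry ground-truth epoch labels")
  sid <- rep(ids, vapply(featList, function(f) nrow(f$features), integer(1)))
  mpc <- config$svm$max_per_class
  keep <- withSeed(seed, {
    unlist(lapply(c("NOR", "APN"), function(cl) {
      idx <- which(y == cl)
      if (length(idx) > mpc) sort(sample(idx, mpc)) else idx
    }))
  })
  ts <- trainingSet(X[keep, , drop = FALSE], y[keep], sid[keep])
  upsampleBalance(ts, seed = seed)
}

#' Screen a new-arriving subject against an annotated database
#'
#' The full inter-individual chain for one query subject: the modified KNN
#' scheme picks the K phenotypically most similar database subjects; their
#' epochs (pooled, capped per class and balanced by duplication) train the
#' neighbor-specific RBF-SVM; the query's epochs are predicted, smoothed
#' by the state machine using the paradox feature, and corrected by the
#' desaturation rule; epoch labels become timed events, an REI over the
#' light-off..light-on period, and a severity grade. The query's own
#' annotations, if any, are never read.
#'
#' @param query a \linkS4class{Subject} (annotations not required).
#' @param db an annotated \linkS4class{ApneaCohort}.
#' @param config an [apneaConfig()].
#' @param featureCache optional named list of precomputed
#'   [extractFeatures()] results (by subject id) to avoid re-extraction.
#' @param seed seed for the training subsample/balancing draw (defaults
#'   to \code{config$seed}).
#' @return list: \code{neighbors} (the [modifiedKNN()] selection),
#'   \code{pred} (raw classifier labels), \code{labels} (final smoothed +
#'   corrected labels), \code{events}, \code{rei}, \code{severity}, and
#'   the trained \code{classifier}.
#' @export
screenSubject <- function(query, db, config = apneaConfig(),
                          featureCache = NULL, seed = config$seed) {
  stopifnot(is(query, "Subject"), is(db, "ApneaCohort"))
  getFeat <- function(s) {
    if (!is.null(featureCache) && s@id %in% names(featureCache))
      featureCache[[s@id]]
    else extractFeatures(s, config)
  }
  sel <- modifiedKNN(query@profile, db, K = config$knn$K,
                     K_prime = config$knn$K_prime,
                     params = configMetricParams(config))
  nbSubjects <- db@subjects[sel$neighbors]
  nbFeat <- lapply(nbSubjects, getFeat)
  train <- buildNeighborTraining(nbFeat, sel$neighbors, config, seed)
  clf <- trainEpochClassifier(train, gamma = config$svm$gamma,
                              C = config$svm$C)
  qf <- getFeat(query)
  pred <- predictEpochs(clf, qf$features, epochStart = qf$epoch_start)
  sm <- applyStateMachine(pred, qf$paradox, configSMConfig(config))
  lab <- desaturationCorrection(sm, desat = qf$desat, config = config)
  events <- epochsToEvents(lab, win = config$features$win_s,
                           hop = config$features$hop_s,
                           minEvent = config$scoring$min_event_s,
                           maxEvent = config$scoring$max_event_s,
                           timeline = config$scoring$timeline)
  rec <- query@recording
  rei <- computeREI(events, rec@lightOff, rec@lightOn)
  list(neighbors = sel, pred = pred, labels = lab, events = events,
       rei = rei, severity = as.character(classifySeverity(rei)),
       classifier = clf)
}
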