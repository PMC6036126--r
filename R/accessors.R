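#' Accessors for the screening data model
#'
#' Small accessor generics over \linkS4class{ChannelSignal},
#' \linkS4class{Recording}, \linkS4class{Subject} and
#' \linkS4class{ApneaCohort}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("samples", "ChannelSignal", function(x) x@samples)

#' @rdname accessors
setMethod("sampleRate", "ChannelSignal", function(x) x@rate)

#' @rdname accessors
setMethod("startOffset", "ChannelSignal", function(x) x@startOffset)

#' @rdname accessors
setMethod("signalDuration", "ChannelSignal",
          function(x) nrow(x@samples) / x@rate)

#' @rdname accessors
setMethod("thoracic", "Recording", function(x) x@thoracic)

#' @rdname accessors
setMethod("abdominal", "Recording", function(x) x@abdominal)

#' @rdname accessors
setMethod("spo2", "Recording", function(x) x@spo2)

#' @rdname accessors
setMethod("lightOff", "Recording", function(x) x@lightOff)

#' @rdname accessors
setMethod("lightOn", "Recording", function(x) x@lightOn)

#' @rdname accessors
setMethod("phenotype", "Subject", function(x) x@profile)

#' @rdname accessors
setMethod("recording", "Subject", function(x) x@recording)

#' @rdname accessors
setMethod("annotations", "Subject", function(x) x@annotations)

#' @rdname accessors
setMethod("subjectId", "Subject", function(x) x@id)

#' @rdname accessors
setMethod("subjects", "ApneaCohort", function(x) x@subjects)

#' @rdname accessors
setMethod("subjectIds", "ApneaCohort",
          function(x) vapply(x@subjects, function(s) s@id, character(1),
                             USE.NAMES = FALSE))

#' @rdname accessors
setMethod("nSubjects", "ApneaCohort", function(x) length(x@subjects))

setMethod("show", "PhenotypeProfile", function(object) {
  cm <- names(object@comorbidities)[object@comorbidities]
  cat(sprintf("PhenotypeProfile: %s, %.1f y, BMI %.1f, comorbidities: %s\n",
              object@gender, object@age, object@bmi,
              if (length(cm)) paste(cm, collapse = "+") else "none"))
})

setMethod("show", "ChannelSignal", function(object) {
  cat(sprintf("ChannelSignal: %d samples x %d axis(es) @ %g Hz (%.1f s)%s\n",
              nrow(object@samples), ncol(object@samples), object@rate,
              signalDuration(object),
              if (nzchar(object@units)) paste0(" [", object@units, "]") else ""))
})

setMethod("show", "Recording", function(object) {
  cat("Recording\n")
  cat("  thoracic : "); show(object@thoracic)
  cat("  abdominal: "); show(object@abdominal)
  cat("  SpO2     : "); show(object@spo2)
  cat(sprintf("  analysis period: light off %.1f s -> light on %.1f s (%.2f h)\n",
              object@lightOff, object@lightOn,
              (object@lightOn - object@lightOff) / 3600))
})

setMethod("show", "Subject", function(object) {
  cat(sprintf("Subject '%s' (%d annotated events)\n", object@id,
              nrow(object@annotations)))
  show(object@profile)
  show(object@recording)
})

setMethod("show", "ApneaCohort", function(object) {
  cat(sprintf("ApneaCohort: %d subjects (%s)\n", nSubjects(object),
              object@provenance))
  ann <- vapply(object@subjects, function(s) nrow(s@annotations), integer(1))
  cat(sprintf("  annotated events per subject: median %g (range %g-%g)\n",
              median(ann), min(ann), max(ann)))
})

setMethod("show", "EpochClassifier", function(object) {
  cat(sprintf("EpochClassifier: RBF SVM on %d feature(s), %d support vectors\n",
              length(object@featureNames), object@model$tot.nSV))
  if (length(object@dropped))
    cat("  dropped zero-variance feature(s):",
        paste(object@dropped, collapse = ", "), "\n")
})
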