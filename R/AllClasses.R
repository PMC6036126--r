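#' Phenotype profile of a subject
#'
#' Demographic and comorbidity attributes entering the phenotype metric:
#' gender, age, body-mass index, and three boolean comorbidity flags
#' (hypertension, diabetes, hypothyroidism).
#'
#' @slot gender character, \code{"male"} or \code{"female"}.
#' @slot age years, positive.
#' @slot bmi kg/m^2, positive.
#' @slot comorbidities named logical vector with entries
#'   \code{hypertension}, \code{diabetes}, \code{hypothyroidism}.
#'
#' @export
setClass("PhenotypeProfile",
  representation(gender = "character", age = "numeric", bmi = "numeric",
                 comorbidities = "logical"))

.COMORBIDITIES <- c("hypertension", "diabetes", "hypothyroidism")

setValidity("PhenotypeProfile", function(object) {
  msg <- character()
  if (length(object@gender) != 1L || !object@gender %in% c("male", "female"))
    msg <- c(msg, "gender must be 'male' or 'female'")
  if (length(object@age) != 1L || !is.finite(object@age) || object@age <= 0)
    msg <- c(msg, "age must be a positive number (years)")
  if (length(object@bmi) != 1L || !is.finite(object@bmi) || object@bmi <= 0)
    msg <- c(msg, "bmi must be a positive number (kg/m^2)")
  cm <- object@comorbidities
  if (length(cm) != 3L || !setequal(names(cm), .COMORBIDITIES) || anyNA(cm))
    msg <- c(msg, sprintf("comorbidities must be the three named flags: %s",
                          paste(.COMORBIDITIES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param gender,age,bmi see slots.
#' @param hypertension,diabetes,hypothyroidism comorbidity flags.
#' @rdname PhenotypeProfile-class
#' @export
PhenotypeProfile <- function(gender, age, bmi, hypertension = FALSE,
                             diabetes = FALSE, hypothyroidism = FALSE) {
  new("PhenotypeProfile", gender = as.character(gender), age = as.numeric(age),
      bmi = as.numeric(bmi),
      comorbidities = c(hypertension = as.logical(hypertension),
                        diabetes = as.logical(diabetes),
                        hypothyroidism = as.logical(hypothyroidism)))
}

#' A sampled physiological channel
#'
#' A uniformly sampled signal: one column per axis (1 for SpO2, 3 for the
#' tri-axial accelerometers), a sampling rate in Hz, and an offset of the
#' first sample from the recording time origin.
#'
#' @slot samples numeric matrix, samples x axes.
#' @slot rate sampling rate, Hz.
#' @slot units free-text units.
#' @slot startOffset seconds from recording start to the first sample.
#'
#' @export
setClass("ChannelSignal",
  representation(samples = "matrix", rate = "numeric", units = "character",
                 startOffset = "numeric"))

setValidity("ChannelSignal", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a positive number (Hz)")
  if (!ncol(object@samples) %in% c(1L, 3L))
    msg <- c(msg, "samples must have 1 or 3 axis columns")
  if (length(object@startOffset) != 1L || !is.finite(object@startOffset))
    msg <- c(msg, "startOffset must be a finite number (s)")
  if (length(msg)) msg else TRUE
})

#' @param samples numeric vector (1 axis) or matrix (samples x axes).
#' @param rate sampling rate in Hz.
#' @param units free-text unit label.
#' @param startOffset seconds from recording start.
#' @rdname ChannelSignal-class
#' @export
ChannelSignal <- function(samples, rate, units = "", startOffset = 0) {
  if (!is.matrix(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  new("ChannelSignal", samples = samples, rate = as.numeric(rate),
      units = as.character(units), startOffset = as.numeric(startOffset))
}

#' A synchronized overnight recording
#'
#' Tri-axial thoracic and abdominal effort channels, a 1-Hz SpO2 channel,
#' and the light-off / light-on markers delimiting the analysis period.
#' SpO2 must lie in [0, 100] and every channel must cover the
#' light-off..light-on interval.
#'
#' @slot thoracic,abdominal 3-axis \linkS4class{ChannelSignal}.
#' @slot spo2 1-axis \linkS4class{ChannelSignal}, percent.
#' @slot lightOff,lightOn seconds from recording start.
#'
#' @export
setClass("Recording",
  representation(thoracic = "ChannelSignal", abdominal = "ChannelSignal",
                 spo2 = "ChannelSignal", lightOff = "numeric",
                 lightOn = "numeric"))

setValidity("Recording", function(object) {
  msg <- character()
  if (ncol(object@thoracic@samples) != 3L)
    msg <- c(msg, "thoracic channel must be 3-axis")
  if (ncol(object@abdominal@samples) != 3L)
    msg <- c(msg, "abdominal channel must be 3-axis")
  if (ncol(object@spo2@samples) != 1L)
    msg <- c(msg, "SpO2 channel must be 1-axis")
  sp <- object@spo2@samples
  if (length(sp) && (min(sp) < 0 || max(sp) > 100))
    msg <- c(msg, "SpO2 out of [0,100]")
  if (length(object@lightOn) != 1L || length(object@lightOff) != 1L ||
      !(object@lightOn > object@lightOff)) {
    msg <- c(msg, "light_on must be greater than light_off")
  } else {
    covers <- function(ch, slack) {
      t0 <- ch@startOffset
      t1 <- t0 + nrow(ch@samples) / ch@rate
      t0 <= object@lightOff + slack && t1 >= object@lightOn - slack
    }
    # allow one-sample slack at either end
    if (!covers(object@thoracic, 1 / object@thoracic@rate) ||
        !covers(object@abdominal, 1 / object@abdominal@rate) ||
        !covers(object@spo2, 1 / object@spo2@rate))
      msg <- c(msg, "all channels must cover [light_off, light_on]")
  }
  if (length(msg)) msg else TRUE
})

#' @param thoracic,abdominal,spo2,lightOff,lightOn see slots.
#' @rdname Recording-class
#' @export
Recording <- function(thoracic, abdominal, spo2, lightOff, lightOn) {
  new("Recording", thoracic = thoracic, abdominal = abdominal, spo2 = spo2,
      lightOff = as.numeric(lightOff), lightOn = as.numeric(lightOn))
}

#' A subject: phenotype, signals and (optionally) expert annotations
#'
#' @slot id unique subject identifier.
#' @slot profile \linkS4class{PhenotypeProfile}.
#' @slot recording \linkS4class{Recording}.
#' @slot annotations data.frame of typed timed events with columns
#'   \code{etype} (CSA/MSA/OSA/HYP/APN), \code{start} and \code{duration}
#'   in seconds; zero rows when the subject is unannotated.
#'
#' @export
setClass("Subject",
  representation(id = "character", profile = "PhenotypeProfile",
                 recording = "Recording", annotations = "data.frame"))

setValidity("Subject", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a non-empty string")
  ok <- tryCatch({
    validateEventTable(object@annotations,
                       where = sprintf("subject '%s' annotations", object@id))
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (length(msg)) msg else TRUE
})

#' @param id,profile,recording,annotations see slots.
#' @rdname Subject-class
#' @export
Subject <- function(id, profile, recording, annotations = makeEventTable()) {
  new("Subject", id = as.character(id), profile = profile,
      recording = recording, annotations = annotations)
}

#' An annotated cohort database
#'
#' The self-learning database: a list of subjects with expert annotations
#' and phenotype information, queried by the modified KNN scheme.
#'
#' @slot subjects list of \linkS4class{Subject}.
#' @slot provenance free text describing the cohort's origin.
#'
#' @export
setClass("ApneaCohort",
  representation(subjects = "list", provenance = "character"))

setValidity("ApneaCohort", function(object) {
  msg <- character()
  if (length(object@subjects) < 1L)
    msg <- c(msg, "a cohort needs at least one subject")
  if (!all(vapply(object@subjects, is, logical(1), class2 = "Subject")))
    msg <- c(msg, "all elements of subjects must be Subject objects")
  else {
    ids <- vapply(object@subjects, function(s) s@id, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "subject ids must be unique within a cohort")
  }
  if (length(msg)) msg else TRUE
})

#' @param subjects list of \linkS4class{Subject}.
#' @param provenance free text.
#' @rdname ApneaCohort-class
#' @export
ApneaCohort <- function(subjects, provenance = "unspecified") {
  sub <- as.list(subjects)
  names(sub) <- vapply(sub, function(s) s@id, character(1))
  new("ApneaCohort", subjects = sub, provenance = as.character(provenance))
}

#' Neighbor-specific epoch classifier
#'
#' An RBF-kernel SVM trained on the pooled epochs of the phenotype
#' neighbors, together with the z-scoring parameters of its training set
#' (applied to any features it later predicts on).
#'
#' @slot model fitted \code{e1071::svm} object.
#' @slot center,scale per-feature training mean and standard deviation.
#' @slot featureNames feature columns the model expects, in order.
#' @slot dropped names of zero-variance features removed before training.
#'
#' @export
setClass("EpochClassifier",
  representation(model = "ANY", center = "numeric", scale = "numeric",
                 featureNames = "character", dropped = "character"))
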