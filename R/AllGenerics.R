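#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("startOffset", function(x) standardGeneric("startOffset"))

#' @rdname accessors
#' @export
setGeneric("signalDuration", function(x) standardGeneric("signalDuration"))

#' @rdname accessors
#' @export
setGeneric("thoracic", function(x) standardGeneric("thoracic"))

#' @rdname accessors
#' @export
setGeneric("abdominal", function(x) standardGeneric("abdominal"))

#' @rdname accessors
#' @export
setGeneric("spo2", function(x) standardGeneric("spo2"))

#' @rdname accessors
#' @export
setGeneric("lightOff", function(x) standardGeneric("lightOff"))

#' @rdname accessors
#' @export
setGeneric("lightOn", function(x) standardGeneric("lightOn"))

#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname accessors
#' @export
setGeneric("recording", function(x) standardGeneric("recording"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
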