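#' @useDynLib ApneaScreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats fft median prcomp quantile rbinom rnorm runif sd var predict approx setNames
#' @importFrom utils head tail modifyList
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Severity class levels
#'
#' Fixed ordering of the four clinical severity grades used throughout the
#' package: Normal (AHI <= 5), Mild (5 < AHI <= 15), Moderate
#' (15 < AHI <= 30), Severe (AHI > 30).
#'
#' @return Character vector of the four levels, in order.
#' @export
severityLevels <- function() c("Normal", "Mild", "Moderate", "Severe")

.EVENT_TYPES <- c("CSA", "MSA", "OSA", "HYP", "APN")
.APNEA_MIN_S <- 10
.APNEA_MAX_S <- 120

#' Build a typed, timed event table
#'
#' The canonical event container: a data.frame with columns \code{etype}
#' (one of CSA, MSA, OSA, HYP, APN), \code{start} and \code{duration} in
#' seconds from recording start. Intervals are half-open,
#' [start, start + duration).
#'
#' @param etype,start,duration equal-length vectors.
#' @return data.frame with the three columns.
#' @export
makeEventTable <- function(etype = character(), start = numeric(),
                           duration = numeric()) {
  data.frame(etype = as.character(etype), start = as.numeric(start),
             duration = as.numeric(duration), stringsAsFactors = FALSE)
}

validateEventTable <- function(ev, where = "events") {
  if (!is.data.frame(ev))
    stopf("%s: expected a data.frame with columns etype, start, duration", where)
  need <- c("etype", "start", "duration")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stopf("%s: missing column(s) %s", where, paste(miss, collapse = ", "))
  if (nrow(ev) == 0) return(invisible(ev))
  bad <- setdiff(unique(ev$etype), .EVENT_TYPES)
  if (length(bad))
    stopf("%s: unknown event type label(s): %s", where, paste(bad, collapse = ", "))
  if (any(ev$start < 0))
    stopf("%s: event start must be >= 0", where)
  apn <- ev$etype %in% c("CSA", "MSA", "OSA", "APN", "HYP")
  if (any(apn & (ev$duration < .APNEA_MIN_S | ev$duration > .APNEA_MAX_S)))
    stopf("%s: event duration outside the admissible [%g, %g] s scoring range",
          where, .APNEA_MIN_S, .APNEA_MAX_S)
  invisible(ev)
}

# TRUE if intervals within one table overlap each other
selfOverlaps <- function(ev) {
  if (nrow(ev) < 2) return(FALSE)
  o <- order(ev$start)
  s <- ev$start[o]; e <- ev$start[o] + ev$duration[o]
  any(s[-1] < e[-length(e)] - 1e-9)
}

# seeded evaluation without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# derive a stream-specific sub-seed (kept within 32-bit integer range)
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12347L) %% 2147483647)
}
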