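#' Pipeline configuration
#'
#' Builds the nested configuration driving every stage, validating section
#' and key names (unknown keys are rejected, not silently ignored).
#' Sections and defaults:
#' \describe{
#'   \item{metric}{\code{w_age = 1}, \code{w_bmi = 1}, \code{w_gender = 1},
#'     \code{scale_mode = "mad"}, \code{s_age = 10}, \code{s_bmi = 4} --
#'     see [metricParams()].}
#'   \item{knn}{\code{K = 5} neighbors kept, \code{K_prime = 2} pruned.}
#'   \item{features}{band edges \code{band_low_hz = 0.05},
#'     \code{band_high_hz = 1}; \code{breath_band = c(0.1, 0.6)} Hz;
#'     \code{target_rate = 10} Hz analysis rate; \code{win_s = 10} s
#'     epochs with \code{hop_s = 0.5} s hop; \code{context_s = 20} s
#'     desaturation context; \code{baseline_s = 20} s desaturation
#'     baseline; \code{desat_threshold = 3} points.}
#'   \item{svm}{\code{gamma = NULL} (1/n_features), \code{C = 1},
#'     \code{max_per_class = 2000} training epochs drawn per class before
#'     balancing.}
#'   \item{sm}{state machine: \code{enter_threshold = 4},
#'     \code{exit_threshold = 4}, \code{paradox_gate = -0.5}.}
#'   \item{scoring}{\code{min_event_s = 10}, \code{max_event_s = 120},
#'     \code{timeline = "nearest"}.}
#'   \item{evaluation}{\code{matching = "one_to_one"}.}
#'   \item{seed}{base seed for every stochastic step (default 1).}
#' }
#'
#' @param ... named sections with partial overrides, e.g.
#'   \code{knn = list(K = 3)}.
#' @return a validated nested \code{ApneaConfig} list.
#' @export
apneaConfig <- function(...) {
  defaults <- list(
    metric = list(w_age = 1, w_bmi = 1, w_gender = 1, scale_mode = "mad",
                  s_age = 10, s_bmi = 4),
    knn = list(K = 5, K_prime = 2),
    features = list(band_low_hz = 0.05, band_high_hz = 1,
                    breath_band = c(0.1, 0.6), target_rate = 10,
                    win_s = 10, hop_s = 0.5, context_s = 20,
                    baseline_s = 20, desat_threshold = 3),
    svm = list(gamma = NULL, C = 1, max_per_class = 2000),
    sm = list(enter_threshold = 4, exit_threshold = 4, paradox_gate = -0.5),
    scoring = list(min_event_s = 10, max_event_s = 120,
                   timeline = "nearest"),
    evaluation = list(matching = "one_to_one"),
    seed = 1)
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  badSec <- setdiff(names(user), names(defaults))
  if (length(badSec))
    stopf("unknown config section(s): %s", paste(badSec, collapse = ", "))
  cfg <- defaults
  for (sec in names(user)) {
    if (sec == "seed") { cfg$seed <- as.integer(user$seed); next }
    if (!is.list(user[[sec]])) stopf("config section '%s' must be a list", sec)
    badKey <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(badKey))
      stopf("unknown key(s) in config section '%s': %s", sec,
            paste(badKey, collapse = ", "))
    cfg[[sec]] <- modifyList(defaults[[sec]], user[[sec]],
                             keep.null = TRUE)
  }
  class(cfg) <- "ApneaConfig"
  cfg
}

configMetricParams <- function(config) {
  metricParams(w_age = config$metric$w_age, w_bmi = config$metric$w_bmi,
               w_gender = config$metric$w_gender,
               s_age = config$metric$s_age, s_bmi = config$metric$s_bmi,
               scale_mode = config$metric$scale_mode)
}

configSMConfig <- function(config) {
  stateMachineConfig(enter_threshold = config$sm$enter_threshold,
                     exit_threshold = config$sm$exit_threshold,
                     paradox_gate = config$sm$paradox_gate)
}
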