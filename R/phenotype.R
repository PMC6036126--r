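#' Parameters of the phenotype metric
#'
#' The phenotype distance between two subjects is a weighted, scale-free
#' combination of age difference, BMI difference and a gender-mismatch
#' penalty:
#' \deqn{d = w_{age} |\Delta age| / s_{age} + w_{bmi} |\Delta bmi| / s_{bmi}
#'       + w_{gender} [gender_a \ne gender_b].}
#' With \code{scale_mode = "mad"} the scales are taken as the (unscaled)
#' median absolute deviation of age and BMI across the training cohort,
#' making the metric unit-free; \code{"fixed"} uses \code{s_age}/\code{s_bmi}
#' verbatim.
#'
#' @param w_age,w_bmi,w_gender nonnegative weights (defaults 1).
#' @param s_age,s_bmi positive scales in years and kg/m^2 (used directly
#'   when \code{scale_mode = "fixed"}, and as fallbacks when a cohort MAD
#'   is zero).
#' @param scale_mode \code{"mad"} or \code{"fixed"}.
#' @return a validated \code{MetricParams} list.
#' @export
metricParams <- function(w_age = 1, w_bmi = 1, w_gender = 1,
                         s_age = 10, s_bmi = 4, scale_mode = c("mad", "fixed")) {
  scale_mode <- match.arg(scale_mode)
  p <- list(w_age = as.numeric(w_age), w_bmi = as.numeric(w_bmi),
            w_gender = as.numeric(w_gender), s_age = as.numeric(s_age),
            s_bmi = as.numeric(s_bmi), scale_mode = scale_mode)
  if (any(vapply(p[1:3], function(w) !is.finite(w) || w < 0, logical(1))))
    stopf("metric weights must be nonnegative finite numbers")
  if (p$s_age <= 0 || p$s_bmi <= 0)
    stopf("metric scales must be positive")
  class(p) <- "MetricParams"
  p
}

# resolve MAD scales against a set of profiles
resolveScales <- function(params, profiles) {
  if (params$scale_mode == "mad" && length(profiles)) {
    ages <- vapply(profiles, function(p) p@age, numeric(1))
    bmis <- vapply(profiles, function(p) p@bmi, numeric(1))
    sa <- median(abs(ages - median(ages)))
    sb <- median(abs(bmis - median(bmis)))
    if (sa > 0) params$s_age <- sa
    if (sb > 0) params$s_bmi <- sb
  }
  params
}

#' Phenotype distance between two subjects
#'
#' @param a,b \linkS4class{PhenotypeProfile} objects.
#' @param params a [metricParams()] object; \code{scale_mode = "mad"} is
#'   resolved against a cohort by [modifiedKNN()], so here the stored
#'   \code{s_age}/\code{s_bmi} are used as-is.
#' @return nonnegative distance; 0 for identical profiles, symmetric.
#' @export
phenotypeDistance <- function(a, b, params = metricParams()) {
  stopifnot(is(a, "PhenotypeProfile"), is(b, "PhenotypeProfile"))
  params$w_age * abs(a@age - b@age) / params$s_age +
    params$w_bmi * abs(a@bmi - b@bmi) / params$s_bmi +
    params$w_gender * as.numeric(a@gender != b@gender)
}

#' Comorbidity correction distance
#'
#' Hamming distance over the three comorbidity flags (hypertension,
#' diabetes, hypothyroidism): 0 for identical comorbidity profiles, up to 3
#' when all flags differ. Used to prune phenotype-nearest candidates in the
#' modified KNN scheme.
#'
#' @param a,b \linkS4class{PhenotypeProfile} objects.
#' @return integer in 0..3.
#' @export
correctionDistance <- function(a, b) {
  stopifnot(is(a, "PhenotypeProfile"), is(b, "PhenotypeProfile"))
  sum(a@comorbidities[.COMORBIDITIES] != b@comorbidities[.COMORBIDITIES])
}

cohortProfiles <- function(db) {
  if (is(db, "ApneaCohort")) {
    profs <- lapply(db@subjects, function(s) s@profile)
    names(profs) <- subjectIds(db)
  } else if (is.list(db) &&
             all(vapply(db, is, logical(1), class2 = "PhenotypeProfile"))) {
    profs <- db
    if (is.null(names(profs)) || any(!nzchar(names(profs))) ||
        anyDuplicated(names(profs)))
      stopf("a profile list database must carry unique non-empty names")
  } else {
    stopf("db must be an ApneaCohort or a named list of PhenotypeProfile")
  }
  profs
}

#' Modified K-nearest-neighbor subject selection
#'
#' Selects the K database subjects most similar to a query phenotype. The
#' K + K' phenotype-nearest candidates are taken first; among them, the K'
#' candidates with the largest comorbidity correction distance are removed.
#' If fewer than K' candidates have a correction distance greater than 0,
#' all of those are removed and the remainder of the K' removals falls on
#' the candidates with the largest phenotype distance. Ties are broken by
#' larger phenotype distance, then by reverse lexicographic id (so the
#' earlier id is preferentially kept), making the selection deterministic.
#'
#' @param query a \linkS4class{PhenotypeProfile}.
#' @param db an \linkS4class{ApneaCohort} or named list of profiles.
#' @param K number of neighbors to keep (positive).
#' @param K_prime number of candidates to prune (nonnegative).
#' @param params [metricParams()]; with \code{scale_mode = "mad"} the
#'   age/BMI scales are the database MADs.
#' @return list with elements \code{neighbors} (ids, by increasing
#'   phenotype distance), \code{distances}, \code{K}, \code{K_prime},
#'   \code{removed} (ids pruned from the candidate set), and the resolved
#'   \code{params}.
#' @export
modifiedKNN <- function(query, db, K = 5, K_prime = 2,
                        params = metricParams()) {
  stopifnot(is(query, "PhenotypeProfile"))
  K <- as.integer(K); K_prime <- as.integer(K_prime)
  if (K < 1) stopf("K must be a positive integer")
  if (K_prime < 0) stopf("K_prime must be a nonnegative integer")
  profs <- cohortProfiles(db)
  if (length(profs) < K + K_prime)
    stopf("database has %d subjects but K + K' = %d are required",
          length(profs), K + K_prime)
  params <- resolveScales(params, profs)
  ids <- names(profs)
  d <- vapply(profs, phenotypeDistance, numeric(1), a = query, params = params)
  cand <- order(d, ids)[seq_len(K + K_prime)]
  cid <- ids[cand]; cd <- d[cand]
  corr <- vapply(profs[cand], correctionDistance, numeric(1), a = query)
  removed <- character()
  if (K_prime > 0) {
    m <- sum(corr > 0)
    if (m >= K_prime) {
      # prune by largest correction distance; ties by larger phenotype
      # distance, then later id
      ord <- order(-corr, -cd, cid, decreasing = c(FALSE, FALSE, TRUE),
                   method = "radix")
      removed <- cid[ord][seq_len(K_prime)]
    } else {
      removed <- cid[corr > 0]
      left <- setdiff(cid, removed)
      ld <- cd[match(left, cid)]
      ord <- order(-ld, left, decreasing = c(FALSE, TRUE), method = "radix")
      removed <- c(removed, left[ord][seq_len(K_prime - m)])
    }
  }
  keep <- setdiff(cid, removed)
  kd <- cd[match(keep, cid)]
  ord <- order(kd, keep, method = "radix")
  structure(list(neighbors = keep[ord], distances = unname(kd[ord]),
                 K = K, K_prime = K_prime, removed = removed,
                 params = params),
            class = "NeighborSelection")
}

#' @export
print.NeighborSelection <- function(x, ...) {
  cat(sprintf("NeighborSelection: K = %d (K' = %d pruned)\n", x$K, x$K_prime))
  cat(sprintf("  %s (d = %s)\n", x$neighbors,
              formatC(x$distances, digits = 3, format = "g")), sep = "")
  invisible(x)
}
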