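#' RPQ three-factor item map
#'
#' Loads the 16-item factor assignment (cognitive / somatic / emotional) from
#' the package's editable YAML table.
#'
#' @param path Optional path to an alternative YAML factor table.
#' @return \code{data.frame} with columns \code{index}, \code{label},
#'   \code{factor}.
#' @export
rpq_factor_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rpq_factors.yaml", package = "natriq")
  y <- yaml::read_yaml(path)
  map <- do.call(rbind, lapply(y$items, as.data.frame))
  if (nrow(map) != 16L || !setequal(map$index, 1:16))
    stop("factor map must cover items 1-16 exactly")
  if (!all(map$factor %in% c("cognitive", "somatic", "emotional")))
    stop("unknown factor label in map")
  map[order(map$index), ]
}

#' Score the Rivermead post-concussion symptoms questionnaire
#'
#' Total score is the sum of all 16 items (0-4 each, range 0-64); the three
#' factor subscores sum the cognitive, somatic and emotional items. Items
#' scored above 1 qualify as post-concussion symptoms (present and worsened
#' since the injury) and are reported as \code{qualifying_items}.
#'
#' @param items Integer vector of 16 item scores, each in 0-4.
#' @param factors Factor map (default \code{\link{rpq_factor_map}()}).
#' @return List of class \code{"rpq_scores"}: \code{total}, \code{cognitive},
#'   \code{somatic}, \code{emotional}, \code{qualifying_items}.
#' @examples
#' score_rpq(rep(4L, 16))$total  # 64, the instrument maximum
#' @export
score_rpq <- function(items, factors = rpq_factor_map()) {
  if (length(items) != 16L)
    stop("RPQ has 16 items; got ", length(items))
  if (any(is.na(items)) || any(items != as.integer(items)) ||
      any(items < 0L) || any(items > 4L))
    stop("RPQ items must be integers in 0-4")
  items <- as.integer(items)
  sub <- function(f) sum(items[factors$index[factors$factor == f]])
  structure(list(total = sum(items),
                 cognitive = sub("cognitive"),
                 somatic = sub("somatic"),
                 emotional = sub("emotional"),
                 qualifying_items = which(items > 1L)),
            class = "rpq_scores")
}

#' Synthetic BTACT normative values
#'
#' Placeholder means/SDs for the six subtests, shipped for simulation and
#' testing only; see the packaged YAML for provenance notes.
#'
#' @param path Optional path to an alternative YAML norms table.
#' @return List with \code{name}, \code{mean}, \code{sd} vectors (length 6).
#' @export
btact_norms_synthetic <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "btact_norms_synthetic.yaml", package = "natriq")
  y <- yaml::read_yaml(path)
  list(name = vapply(y$subtests, `[[`, "", "name"),
       mean = vapply(y$subtests, `[[`, 0, "mean"),
       sd = vapply(y$subtests, `[[`, 0, "sd"))
}

#' Score the brief test of adult cognition by telephone
#'
#' Standardizes each of the six subtest raw scores against its normative mean
#' and SD, and compiles the composite as the unweighted mean of the subtest
#' z-scores.
#'
#' @param raw Numeric vector of 6 subtest raw scores (NA allowed).
#' @param norms List with \code{mean} and \code{sd} vectors of length 6
#'   (default the synthetic placeholder norms).
#' @param impute_policy \code{"none"} (composite is NA when any subtest is
#'   missing) or \code{"available"} (mean of the available z-scores).
#' @return List of class \code{"btact_scores"}: \code{subtest_z} (length 6),
#'   \code{composite_z}.
#' @examples
#' n <- list(mean = rep(3, 6), sd = rep(2, 6))
#' score_btact(1:6, n)$composite_z  # 0.25
#' @export
score_btact <- function(raw, norms = btact_norms_synthetic(),
                        impute_policy = c("none", "available")) {
  impute_policy <- match.arg(impute_policy)
  if (length(raw) != 6L) stop("BTACT has 6 subtests; got ", length(raw))
  if (any(norms$sd <= 0)) stop("normative SDs must be positive")
  z <- (raw - norms$mean) / norms$sd
  composite <- if (!anyNA(z)) mean(z)
  else if (impute_policy == "available" && any(!is.na(z))) mean(z, na.rm = TRUE)
  else NA_real_
  structure(list(subtest_z = z, composite_z = composite),
            class = "btact_scores")
}

#' Dichotomize the extended Glasgow outcome scale
#'
#' Recovered is complete recovery only: GOSE = 8. Any score from 3 to 7 is
#' non-recovered.
#'
#' @param gose Integer in 3-8 (vectorized; NA passes through).
#' @return Logical: \code{TRUE} iff GOSE = 8.
#' @export
dichotomize_gose <- function(gose) {
  ok <- is.na(gose) | (gose >= 3 & gose <= 8 & gose == as.integer(gose))
  if (!all(ok)) stop("GOSE must be an integer in 3-8")
  gose == 8L
}

#' Per-day rate of change between two visits
#'
#' Signed difference divided by the days elapsed: positive when the value
#' increased. \code{absolute = TRUE} gives the unsigned rate.
#'
#' @param value_late,value_early Measurements at the later/earlier visit.
#' @param days_between Days between the two visits, > 0.
#' @param absolute Take the absolute difference (default FALSE, signed).
#' @return Rate per day.
#' @examples
#' rate_of_change(38.6, 35.0, 90)  # 0.04 mM/day
#' @export
rate_of_change <- function(value_late, value_early, days_between,
                           absolute = FALSE) {
  if (any(days_between <= 0, na.rm = TRUE))
    stop("days_between must be positive")
  diff <- value_late - value_early
  if (absolute) diff <- abs(diff)
  diff / days_between
}

#' Append instrument scores to a cohort table
#'
#' Adds RPQ total and factor subscores, BTACT subtest and composite z-scores,
#' and the dichotomized GOSE recovery status to each row of a long-format
#' cohort table.
#'
#' @param cohort Cohort \code{data.frame} (see \code{\link{generate_cohort}}).
#' @param norms BTACT norms (default synthetic placeholders).
#' @param factors RPQ factor map.
#' @return The cohort with columns \code{rpq_total}, \code{rpq_cognitive},
#'   \code{rpq_somatic}, \code{rpq_emotional}, \code{btact_z1..z6},
#'   \code{btact_composite}, \code{recovered} appended.
#' @export
score_cohort <- function(cohort, norms = btact_norms_synthetic(),
                         factors = rpq_factor_map()) {
  validate_cohort(cohort)
  rpq_cols <- paste0("rpq_", sprintf("%02d", 1:16))
  btact_cols <- paste0("btact_", 1:6)
  rpq <- t(apply(as.matrix(cohort[rpq_cols]), 1, function(it) {
    s <- score_rpq(as.integer(it), factors)
    c(s$total, s$cognitive, s$somatic, s$emotional)
  }))
  cohort$rpq_total <- rpq[, 1]; cohort$rpq_cognitive <- rpq[, 2]
  cohort$rpq_somatic <- rpq[, 3]; cohort$rpq_emotional <- rpq[, 4]
  z <- t(apply(as.matrix(cohort[btact_cols]), 1, function(r)
    score_btact(as.numeric(r), norms)$subtest_z))
  colnames(z) <- paste0("btact_z", 1:6)
  cohort <- cbind(cohort, z)
  cohort$btact_composite <- rowMeans(z)
  cohort$recovered <- dichotomize_gose(cohort$gose)
  cohort
}
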