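#' Design parameters for a synthetic longitudinal concussion cohort
#'
#' Encodes the generative model behind \code{\link{generate_cohort}}: group
#' sizes and attrition, control aTSC distributions, the patients' acute GM/WM
#' deficit (in control-SD units), per-day recovery rates of aTSC, a latent
#' injury-severity factor that drives RPQ scores up, BTACT scores down and
#' GOSE below 8, and a coupling strength tying the aTSC deficit to that
#' latent factor. Defaults mirror a two-group design of 27 patients and 21
#' controls at the first visit with 20 outcome (17 imaging) returnees at
#' visit 2 and 15 at visit 3, a 2.0-SD grey-matter deficit and a GM recovery
#' rate of 0.04 +/- 0.04 mM/day.
#'
#' @param n_patients,n_controls Group sizes at visit 1.
#' @param retention_v2,retention_v3 Fraction of patients contributing outcome
#'   data at visits 2 and 3 (in \[0,1\]).
#' @param imaging_retention_v2 Fraction of visit-2 returnees who also
#'   complete the sodium scan.
#' @param gm_mean,gm_sd,wm_mean,wm_sd Control aTSC distributions (mM).
#' @param deficit_gm_sd,deficit_wm_sd Patient visit-1 deficit in control-SD
#'   units (positive = lower aTSC).
#' @param rate_gm_mean,rate_gm_sd,rate_wm_mean,rate_wm_sd Per-day aTSC
#'   recovery rates (mM/day) between visits 1 and 2.
#' @param days_v1_mean,days_v1_sd,days_v2_mean,days_v2_sd,days_v3_mean,days_v3_sd
#'   Days from injury at each visit (visit-1 range clamped to \[5, 53\]).
#' @param severity_base Mean latent injury severity of patients at visit 1
#'   (controls use \code{control_severity}); arbitrary units.
#' @param severity_sd SD of the between-patient severity spread.
#' @param control_severity Residual symptom level in controls.
#' @param recovery_tau_days Exponential time-constant of severity decay; use
#'   \code{Inf} for no recovery (null designs).
#' @param coupling Correlation strength in \[0,1\] between the latent factor
#'   and the aTSC deficit; 0 makes aTSC and outcomes independent.
#' @param btact_effect Composite BTACT z-score depression per unit severity.
#' @param rpq_item_rate Mean RPQ item score per unit severity.
#' @param gose_threshold Severity below which a patient scores GOSE = 8.
#' @param vent_ratio_mean,vent_ratio_sd Normalized ventricular volume
#'   (bilateral ventricles / eTIV) distribution.
#' @param etiv_mean,etiv_sd eTIV distribution (mm^3).
#' @param seed RNG seed.
#' @return A \code{"na_cohort_design"} list.
#' @export
cohort_design <- function(n_patients = 27L, n_controls = 21L,
                          retention_v2 = 20 / 27, retention_v3 = 15 / 27,
                          imaging_retention_v2 = 17 / 20,
                          gm_mean = 35, gm_sd = 1.8, wm_mean = 30, wm_sd = 1.6,
                          deficit_gm_sd = 2.0, deficit_wm_sd = 0.6,
                          rate_gm_mean = 0.04, rate_gm_sd = 0.04,
                          rate_wm_mean = 0.01, rate_wm_sd = 0.03,
                          days_v1_mean = 22, days_v1_sd = 10,
                          days_v2_mean = 112, days_v2_sd = 21,
                          days_v3_mean = 420, days_v3_sd = 49,
                          severity_base = 1, severity_sd = 0.5,
                          control_severity = 0.15,
                          recovery_tau_days = 250,
                          coupling = 0.6,
                          btact_effect = 0.5, rpq_item_rate = 1.2,
                          gose_threshold = 0.8,
                          vent_ratio_mean = 0.0099, vent_ratio_sd = 0.0045,
                          etiv_mean = 1.5e6, etiv_sd = 1.5e5,
                          seed = 1L) {
  d <- as.list(environment())
  if (any(c(d$retention_v2, d$retention_v3, d$imaging_retention_v2) > 1) ||
      any(c(d$retention_v2, d$retention_v3, d$imaging_retention_v2) < 0))
    stop("retention fractions must lie in [0, 1]")
  sds <- c(gm_sd, wm_sd, rate_gm_sd, rate_wm_sd, days_v1_sd, days_v2_sd,
           days_v3_sd, severity_sd, vent_ratio_sd, etiv_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (coupling < 0 || coupling > 1) stop("'coupling' must lie in [0, 1]")
  if (n_patients < 1 || n_controls < 1) stop("group sizes must be >= 1")
  structure(d, class = "na_cohort_design")
}

#' Generate a synthetic longitudinal cohort table
#'
#' Draws one cohort realisation from the generative model in a
#' \code{\link{cohort_design}}. Each patient carries a latent injury factor
#' \code{u}; their visit-1 aTSC is the control distribution shifted down by
#' the configured deficit, with residual spread correlated with \code{u} at
#' the design's coupling strength. aTSC recovers linearly between visits 1
#' and 2 at a per-subject per-day rate; severity decays exponentially over
#' days from injury and generates RPQ items (0-4 each), six BTACT subtest raw
#' scores and the GOSE. Controls are measured once (visit 1) and have no
#' GOSE or days-from-injury. Deterministic given the design (including its
#' seed).
#'
#' @param design A \code{\link{cohort_design}}.
#' @param norms BTACT norms used to convert generated z-scores to raw scores
#'   (default \code{\link{btact_norms_synthetic}()}).
#' @return A long-format \code{data.frame} of class \code{"na_cohort"}, one
#'   row per subject-visit: \code{subject_id}, \code{group}, \code{visit},
#'   \code{days_from_injury}, \code{atsc_gm}, \code{atsc_wm},
#'   \code{rpq_01}..\code{rpq_16}, \code{btact_1}..\code{btact_6},
#'   \code{gose}, \code{ventricle_volume_mm3}, \code{etiv_mm3}. aTSC is
#'   \code{NA} for visits without imaging (all of visit 3, and visit-2
#'   non-imaging returnees).
#' @export
generate_cohort <- function(design = cohort_design(),
                            norms = btact_norms_synthetic()) {
  stopifnot(inherits(design, "na_cohort_design"))
  with_seed(design$seed, generate_cohort_impl(design, norms))
}

generate_cohort_impl <- function(d, norms) {
  np <- d$n_patients; nc <- d$n_controls
  n_v2 <- round(d$retention_v2 * np)
  n_v3 <- round(d$retention_v3 * np)
  n_img2 <- round(d$imaging_retention_v2 * n_v2)

  ## latent injury factor and correlated aTSC residuals (patients)
  u <- stats::rnorm(np)
  mix <- function(rho) rho * u + sqrt(1 - rho^2) * stats::rnorm(np)
  atsc_gm1 <- d$gm_mean - d$deficit_gm_sd * d$gm_sd - d$gm_sd * d$coupling * u +
    d$gm_sd * sqrt(1 - d$coupling^2) * stats::rnorm(np)
  atsc_wm1 <- d$wm_mean - d$deficit_wm_sd * d$wm_sd - d$wm_sd * d$coupling * u +
    d$wm_sd * sqrt(1 - d$coupling^2) * stats::rnorm(np)
  sev0 <- pmax(0, d$severity_base + d$severity_sd * mix(d$coupling))
  rate_gm <- stats::rnorm(np, d$rate_gm_mean, d$rate_gm_sd)
  rate_wm <- stats::rnorm(np, d$rate_wm_mean, d$rate_wm_sd)

  days1 <- pmin(pmax(round(stats::rnorm(np, d$days_v1_mean, d$days_v1_sd)), 5), 53)
  days2 <- pmax(days1 + 14, round(stats::rnorm(np, d$days_v2_mean, d$days_v2_sd)))
  days3 <- pmax(days2 + 30, round(stats::rnorm(np, d$days_v3_mean, d$days_v3_sd)))

  returns_v2 <- sort(sample.int(np, n_v2))
  returns_v3 <- sort(sample.int(np, n_v3))
  imaging_v2 <- sort(sample(returns_v2, n_img2))

  etiv <- stats::rnorm(np + nc, d$etiv_mean, d$etiv_sd)
  vent <- pmax(0.0005, stats::rnorm(np + nc, d$vent_ratio_mean, d$vent_ratio_sd)) * etiv

  rows <- list()
  severity_at <- function(s0, days)
    if (is.finite(d$recovery_tau_days)) s0 * exp(-days / d$recovery_tau_days) else s0

  for (i in seq_len(np)) {
    id <- sprintf("P%02d", i)
    visits <- c("v1", if (i %in% returns_v2) "v2", if (i %in% returns_v3) "v3")
    for (v in visits) {
      days <- switch(v, v1 = days1[i], v2 = days2[i], v3 = days3[i])
      sev <- severity_at(sev0[i], days - days1[i])
      img <- (v == "v1") || (v == "v2" && i %in% imaging_v2)
      gm <- if (!img) NA_real_ else if (v == "v1") atsc_gm1[i] else
        atsc_gm1[i] + rate_gm[i] * (days - days1[i])
      wm <- if (!img) NA_real_ else if (v == "v1") atsc_wm1[i] else
        atsc_wm1[i] + rate_wm[i] * (days - days1[i])
      rows[[length(rows) + 1L]] <- cohort_row(id, "patient", v, days, gm, wm,
                                              sev, d, norms, vent[i], etiv[i])
    }
  }
  for (j in seq_len(nc)) {
    id <- sprintf("C%02d", j)
    rows[[length(rows) + 1L]] <- cohort_row(id, "control", "v1", NA_real_,
                                            stats::rnorm(1, d$gm_mean, d$gm_sd),
                                            stats::rnorm(1, d$wm_mean, d$wm_sd),
                                            d$control_severity, d, norms,
                                            vent[np + j], etiv[np + j])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("na_cohort", "data.frame")
  validate_cohort(out)
  out
}

cohort_row <- function(id, group, visit, days, gm, wm, sev, d, norms, vent, etiv) {
  ## RPQ items: severity sets the mean item score; truncated Poisson keeps
  ## the 0-4 ordinal support
  items <- pmin(4L, stats::rpois(16L, lambda = pmax(0, sev * d$rpq_item_rate)))
  ## BTACT: severity depresses each subtest z-score
  z <- -d$btact_effect * sev + stats::rnorm(6L, 0, 0.7)
  btact_raw <- norms$mean + norms$sd * z
  gose <- if (group == "control") NA_integer_ else {
    if (sev < d$gose_threshold) 8L
    else as.integer(max(3L, 7L - floor((sev - d$gose_threshold) / 0.5)))
  }
  df <- data.frame(subject_id = id, group = group, visit = visit,
                   days_from_injury = days, atsc_gm = gm, atsc_wm = wm,
                   stringsAsFactors = FALSE)
  df[paste0("rpq_", sprintf("%02d", 1:16))] <- as.list(as.integer(items))
  df[paste0("btact_", 1:6)] <- as.list(btact_raw)
  df$gose <- gose
  df$ventricle_volume_mm3 <- vent
  df$etiv_mm3 <- etiv
  df
}

#' Validate the schema and invariants of a cohort table
#'
#' Checks the long-format cohort schema: unique (subject, visit) pairs, every
#' patient present at visit 1, strictly increasing days per subject, RPQ
#' items in 0-4 and GOSE in 3-8 where present.
#'
#' @param cohort A cohort \code{data.frame}.
#' @return The cohort, invisibly; errors describe the violated field.
#' @export
validate_cohort <- function(cohort) {
  required <- c("subject_id", "group", "visit", "days_from_injury",
                "atsc_gm", "atsc_wm", paste0("rpq_", sprintf("%02d", 1:16)),
                paste0("btact_", 1:6), "gose")
  missing <- setdiff(required, names(cohort))
  if (length(missing))
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(cohort[c("subject_id", "visit")]))
    stop("duplicate (subject_id, visit) rows")
  if (!all(cohort$visit %in% c("v1", "v2", "v3")))
    stop("visit must be one of v1, v2, v3")
  pat <- unique(cohort$subject_id[cohort$group == "patient"])
  has_v1 <- pat %in% cohort$subject_id[cohort$visit == "v1"]
  if (!all(has_v1))
    stop("patients without a v1 row: ", paste(pat[!has_v1], collapse = ", "))
  for (id in pat) {
    dd <- cohort$days_from_injury[cohort$subject_id == id]
    dd <- dd[order(match(cohort$visit[cohort$subject_id == id], c("v1", "v2", "v3")))]
    if (any(diff(dd) <= 0)) stop("visit days must strictly increase for ", id)
  }
  rpq <- as.matrix(cohort[paste0("rpq_", sprintf("%02d", 1:16))])
  if (any(rpq < 0 | rpq > 4, na.rm = TRUE)) stop("RPQ items must lie in 0-4")
  if (any(cohort$gose < 3 | cohort$gose > 8, na.rm = TRUE))
    stop("GOSE must lie in 3-8")
  invisible(cohort)
}
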