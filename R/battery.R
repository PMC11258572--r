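#' Configuration for the six-hypothesis battery
#'
#' @param alpha Two-sided significance level (default 0.05, no
#'   multiple-comparison correction).
#' @param spearman_mc_draws Monte-Carlo permutations for Spearman tests with
#'   n > 8.
#' @param seed Base seed for Monte-Carlo permutation p-values (each
#'   comparison offsets it deterministically).
#' @param exact Exactness policy passed to the rank tests ("auto", "always",
#'   "never").
#' @return List of class \code{"na_battery_config"}.
#' @export
battery_config <- function(alpha = 0.05, spearman_mc_draws = 1e4, seed = 1L,
                           exact = "auto") {
  stopifnot(alpha > 0, alpha < 1, spearman_mc_draws >= 100)
  structure(list(alpha = alpha, spearman_mc_draws = spearman_mc_draws,
                 seed = as.integer(seed), exact = exact),
            class = "na_battery_config")
}

## paired per-subject values of `var` at two visits (patients contributing
## serial data only); returns late and early vectors plus days between
paired_visits <- function(cohort, var, early = "v1", late = "v2") {
  p <- cohort[cohort$group == "patient", ]
  a <- p[p$visit == early, c("subject_id", "days_from_injury", var)]
  b <- p[p$visit == late, c("subject_id", "days_from_injury", var)]
  m <- merge(a, b, by = "subject_id", suffixes = c("_early", "_late"))
  keep <- !(is.na(m[[paste0(var, "_early")]]) | is.na(m[[paste0(var, "_late")]]))
  m <- m[keep, ]
  list(early = m[[paste0(var, "_early")]], late = m[[paste0(var, "_late")]],
       days = m$days_from_injury_late - m$days_from_injury_early,
       subject_id = m$subject_id)
}

visit_values <- function(cohort, var, visit, group = "patient") {
  v <- cohort[cohort$group == group & cohort$visit == visit, var]
  v[!is.na(v)]
}

## comparison-row builders; failures from degenerate subsets become
## "insufficient data" rows excluded from verdicts
comparison_row <- function(hypothesis, variable, comparison, test, result) {
  data.frame(hypothesis = hypothesis, variable = variable,
             comparison = comparison, test = test,
             statistic = if (is.null(result)) NA_real_ else result$statistic,
             p_value = if (is.null(result)) NA_real_ else result$p_value,
             effect_size = if (is.null(result) || is.null(result$effect_size))
               NA_real_ else result$effect_size,
             n = if (is.null(result)) 0L else
               sum(unlist(result[intersect(c("n", "n1", "n2"), names(result))])),
             method = if (is.null(result)) "insufficient data" else result$method,
             stringsAsFactors = FALSE)
}

run_test_safely <- function(fun) tryCatch(fun(), error = function(e) NULL)

#' Run the six-hypothesis nonparametric battery
#'
#' Executes the study's pre-specified H1-H6 comparisons on a scored cohort
#' table:
#' \describe{
#'   \item{H1}{Within-subject outcome change (RPQ total and factor scores,
#'     BTACT composite and subtests) at v2-v1 and v3-v1, by Wilcoxon
#'     signed-rank.}
#'   \item{H2}{Within-subject aTSC change (GM, WM) at v2-v1, by Wilcoxon
#'     signed-rank.}
#'   \item{H3}{Patients at v2 vs controls on aTSC, Mann-Whitney U with
#'     Cohen's d.}
#'   \item{H4}{aTSC(v2) vs outcomes(v2) by Spearman permutation correlation,
#'     plus Mann-Whitney of v2 aTSC against controls within the v2
#'     GOSE-recovered / non-recovered split.}
#'   \item{H5}{aTSC(v1) vs outcomes(v2, v3) by Spearman, plus Mann-Whitney
#'     of v1 aTSC against controls within the future (v2) GOSE split.}
#'   \item{H6}{Rate of change of aTSC (v2-v1, per day) vs rates of change of
#'     outcomes (v2-v1 and v3-v1) by Spearman, plus Mann-Whitney of GM/WM
#'     aTSC rates between patients newly recovered at v2 and those still
#'     non-recovered.}
#' }
#' Serial comparisons use only subjects contributing both visits. Each
#' hypothesis's verdict is "supported" when all its testable comparisons are
#' significant at the configured alpha, "partially supported" when some are,
#' "rejected" when none is.
#'
#' @param cohort Cohort table; scored automatically if score columns absent.
#' @param config A \code{\link{battery_config}}.
#' @return List of class \code{"na_battery"}: per-hypothesis list with a
#'   \code{comparisons} data.frame and a \code{verdict}, plus \code{alpha}
#'   and the pooled comparison table as \code{table}.
#' @export
run_h_battery <- function(cohort, config = battery_config()) {
  stopifnot(inherits(config, "na_battery_config"))
  if (!"rpq_total" %in% names(cohort)) cohort <- score_cohort(cohort)
  validate_cohort(cohort)
  ex <- config$exact
  mc <- config$spearman_mc_draws
  seed0 <- config$seed
  rows <- list()
  add <- function(h, var, cmp, test, res)
    rows[[length(rows) + 1L]] <<- comparison_row(h, var, cmp, test, res)
  spearman_seed <- function() seed0 + length(rows)

  outcome_vars <- c("rpq_total", "rpq_cognitive", "rpq_somatic", "rpq_emotional",
                    "btact_composite", paste0("btact_z", 1:6))
  ## H1: outcome change over time (WSRT)
  for (late in c("v2", "v3")) for (var in outcome_vars) {
    pv <- paired_visits(cohort, var, late = late)
    res <- if (length(pv$early) >= 1)
      run_test_safely(function() wilcoxon_signed_rank(pv$late - pv$early, exact = ex))
    add("H1", var, paste0(late, "-v1"), "WSRT", res)
  }
  ## H2: aTSC change over time (WSRT, imaging pairs)
  for (var in c("atsc_gm", "atsc_wm")) {
    pv <- paired_visits(cohort, var)
    res <- if (length(pv$early) >= 1)
      run_test_safely(function() wilcoxon_signed_rank(pv$late - pv$early, exact = ex))
    add("H2", var, "v2-v1", "WSRT", res)
  }
  ## H3: patients at v2 vs controls (MW + Cohen's d)
  for (var in c("atsc_gm", "atsc_wm")) {
    pat <- visit_values(cohort, var, "v2")
    ctl <- visit_values(cohort, var, "v1", group = "control")
    res <- run_test_safely(function() {
      r <- mann_whitney_u(pat, ctl, exact = ex)
      r$effect_size <- cohens_d(pat, ctl)
      r
    })
    add("H3", var, "patients v2 vs controls", "MW", res)
  }
  ## H4: cross-sectional association at v2
  p2 <- cohort[cohort$group == "patient" & cohort$visit == "v2", ]
  for (tis in c("atsc_gm", "atsc_wm")) for (var in c("rpq_total", "btact_composite")) {
    res <- run_test_safely(function()
      spearman_exact(p2[[tis]], p2[[var]], mc_draws = mc, seed = spearman_seed()))
    add("H4", paste(tis, "vs", var), "v2", "Spearman", res)
  }
  ctl_gm <- visit_values(cohort, "atsc_gm", "v1", group = "control")
  ctl_wm <- visit_values(cohort, "atsc_wm", "v1", group = "control")
  for (tis in c("atsc_gm", "atsc_wm")) for (rec in c(TRUE, FALSE)) {
    grp <- p2[[tis]][!is.na(p2$recovered) & p2$recovered == rec]
    ctl <- if (tis == "atsc_gm") ctl_gm else ctl_wm
    res <- if (length(grp[!is.na(grp)]) >= 1)
      run_test_safely(function() mann_whitney_u(grp, ctl, exact = ex))
    add("H4", tis, paste0("v2 ", if (rec) "recovered" else "non-recovered",
                          " vs controls"), "MW", res)
  }
  ## H5: v1 aTSC predicting later outcomes
  p1 <- cohort[cohort$group == "patient" & cohort$visit == "v1", ]
  for (late in c("v2", "v3")) {
    pl <- cohort[cohort$group == "patient" & cohort$visit == late, ]
    m <- merge(p1[c("subject_id", "atsc_gm", "atsc_wm")],
               pl[c("subject_id", "rpq_total", "btact_composite")],
               by = "subject_id")
    for (tis in c("atsc_gm", "atsc_wm")) for (var in c("rpq_total", "btact_composite")) {
      res <- run_test_safely(function()
        spearman_exact(m[[tis]], m[[var]], mc_draws = mc, seed = spearman_seed()))
      add("H5", paste(tis, "v1 vs", var), late, "Spearman", res)
    }
  }
  rec2 <- p2[c("subject_id", "recovered")]
  m15 <- merge(p1, rec2, by = "subject_id", suffixes = c("", "_v2"))
  for (tis in c("atsc_gm", "atsc_wm")) for (rec in c(TRUE, FALSE)) {
    grp <- m15[[tis]][!is.na(m15$recovered_v2) & m15$recovered_v2 == rec]
    ctl <- if (tis == "atsc_gm") ctl_gm else ctl_wm
    res <- if (length(grp[!is.na(grp)]) >= 1)
      run_test_safely(function() mann_whitney_u(grp, ctl, exact = ex))
    add("H5", tis, paste0("v1, ", if (rec) "future recovered" else
      "future non-recovered", " vs controls"), "MW", res)
  }
  ## H6: rates of change
  rates <- list()
  for (tis in c("atsc_gm", "atsc_wm")) {
    pv <- paired_visits(cohort, tis)
    rates[[tis]] <- data.frame(subject_id = pv$subject_id,
                               rate = rate_of_change(pv$late, pv$early, pv$days))
  }
  for (late in c("v2", "v3")) for (var in c("rpq_total", "btact_composite")) {
    pv <- paired_visits(cohort, var, late = late)
    orate <- data.frame(subject_id = pv$subject_id,
                        rate = rate_of_change(pv$late, pv$early, pv$days))
    for (tis in c("atsc_gm", "atsc_wm")) {
      m <- merge(rates[[tis]], orate, by = "subject_id")
      res <- run_test_safely(function()
        spearman_exact(m$rate.x, m$rate.y, mc_draws = mc, seed = spearman_seed()))
      add("H6", paste(tis, "rate vs", var, "rate"), paste0(late, "-v1"),
          "Spearman", res)
    }
  }
  ## newly recovered at v2 (non-recovered at v1) vs still non-recovered at v2
  rec1 <- p1[c("subject_id", "recovered")]
  names(rec1)[2] <- "recovered_v1"
  for (tis in c("atsc_gm", "atsc_wm")) {
    m <- merge(merge(rates[[tis]], rec2, by = "subject_id"), rec1,
               by = "subject_id")
    newly <- m$rate[!m$recovered_v1 & m$recovered]
    still <- m$rate[!m$recovered]
    res <- if (length(newly) >= 1 && length(still) >= 1)
      run_test_safely(function() mann_whitney_u(newly, still, exact = ex))
    add("H6", paste(tis, "rate"), "newly recovered vs non-recovered at v2",
        "MW", res)
  }

  tab <- do.call(rbind, rows)
  out <- list()
  for (h in paste0("H", 1:6)) {
    sub <- tab[tab$hypothesis == h, ]
    testable <- sub[!is.na(sub$p_value), ]
    sig <- sum(testable$p_value < config$alpha)
    verdict <- if (nrow(testable) == 0) "untestable"
    else if (sig == nrow(testable)) "supported"
    else if (sig > 0) "partially supported" else "rejected"
    out[[h]] <- list(comparisons = sub, verdict = verdict,
                     n_significant = sig, n_testable = nrow(testable))
  }
  structure(list(hypotheses = out, alpha = config$alpha, table = tab),
            class = "na_battery")
}

#' @export
print.na_battery <- function(x, ...) {
  cat(sprintf("Hypothesis battery (alpha = %g, two-sided, uncorrected)\n", x$alpha))
  for (h in names(x$hypotheses)) {
    hh <- x$hypotheses[[h]]
    cat(sprintf("  %s: %s (%d/%d comparisons significant)\n", h, hh$verdict,
                hh$n_significant, hh$n_testable))
  }
  invisible(x)
}
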