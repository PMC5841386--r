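# Longitudinal cohort labeling rules and the mixed-effects validation
# models.
#
# Labeling: aMCI subjects are converters iff they are diagnosed AD during
# the first year of follow-up without subsequent reversion inside that
# window; AD subjects are fast decliners iff CDR-SB rises by strictly more
# than 5 points from baseline to the third-year visit.
#
# Models: random-intercept linear mixed models fit by REML through lme4,
# fixed effects [intercept, predictor, time, predictor x time], with
# large-sample Wald normal p-values (a documented approximation; no
# Satterthwaite correction).

sort_visits <- function(visits) {
  visits[order(visits$visit_time), , drop = FALSE]
}

#' Label an aMCI subject as converter or non-converter
#'
#' @param visits data frame of one subject's visits with columns
#'   `visit_time` (years, baseline 0) and `diagnosis`.
#' @param window follow-up window in years (default 1) within which
#'   conversion is assessed.
#' @param tol tolerance on visit times when matching the window.
#' @return a list with `label` (`"converter"` / `"non_converter"`) and
#'   `cohort = "aMCI"`.
#' @export
label_conversion <- function(visits, window = 1, tol = 0.01) {
  visits <- sort_visits(visits)
  base <- visits[visits$visit_time <= tol, , drop = FALSE]
  if (nrow(base) == 0L || base$diagnosis[1L] != "aMCI")
    abort("cohort_error", "baseline diagnosis must be aMCI")
  fu <- visits[visits$visit_time > tol &
                 visits$visit_time <= window + tol, , drop = FALSE]
  if (nrow(fu) == 0L)
    abort("insufficient_data",
          sprintf("no follow-up visit within %g years", window))
  ad_at <- which(fu$diagnosis == "AD")
  label <- "non_converter"
  if (length(ad_at) > 0L) {
    after_first_ad <- fu$diagnosis[ad_at[1L]:nrow(fu)]
    if (all(after_first_ad == "AD")) label <- "converter"
  }
  list(subject_id = visits$subject_id[1L] %||% NA_character_,
       cohort = "aMCI", label = label)
}

#' Label an AD subject as fast or slow decliner
#'
#' Fast decline means the CDR-SB score increased by strictly more than
#' `delta` points between baseline and the `horizon`-year visit (a change of
#' exactly `delta` is slow decline).
#'
#' @param visits data frame of one subject's visits with `visit_time` and
#'   `cdr_sb` columns.
#' @param horizon follow-up horizon in years (default 3).
#' @param delta CDR-SB change cut point (default 5, strict inequality).
#' @param time_tol how far a visit may sit from `0`/`horizon` and still count
#'   as the baseline / horizon assessment (default 0.25 y).
#' @return a list with `label` (`"fast_decliner"` / `"slow_decliner"`) and
#'   `cohort = "AD"`.
#' @export
label_decline <- function(visits, horizon = 3, delta = 5, time_tol = 0.25) {
  visits <- sort_visits(visits)
  if (!"cdr_sb" %in% names(visits))
    abort("insufficient_data", "cdr_sb column required")
  at <- function(target) {
    cand <- visits[abs(visits$visit_time - target) <= time_tol &
                     is.finite(visits$cdr_sb), , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_real_)
    cand$cdr_sb[which.min(abs(cand$visit_time - target))]
  }
  c0 <- at(0)
  c3 <- at(horizon)
  if (!is.finite(c0) || !is.finite(c3))
    abort("insufficient_data",
          sprintf("CDR-SB required at baseline and year %g", horizon))
  list(subject_id = visits$subject_id[1L] %||% NA_character_,
       cohort = "AD",
       label = if (c3 - c0 > delta) "fast_decliner" else "slow_decliner",
       cdr_sb_change = c3 - c0)
}

check_visit_design <- function(d, min_frac = 0.8) {
  nvis <- table(d$subject_id)
  if (mean(nvis >= 2L) < min_frac)
    abort("insufficient_data",
          sprintf("only %.0f%% of subjects have >= 2 visits (need >= %.0f%%)",
                  100 * mean(nvis >= 2L), 100 * min_frac))
}

fit_lmm <- function(d, formula, predictor) {
  fit <- suppressMessages(lme4::lmer(
    formula, data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  # Wald normal p-values underflow for extreme z; keep them in (0, 1]
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(coefficients = data.frame(term = names(est), estimate = unname(est),
                                   se = unname(se), z = unname(z),
                                   p = unname(p)),
         random_intercept_var = vc$vcov[vc$grp == "subject_id"][1L],
         residual_var = vc$vcov[vc$grp == "Residual"][1L],
         n_subjects = length(unique(d$subject_id)),
         n_observations = nrow(d),
         predictor = predictor,
         interaction_term = paste0(predictor, ":time"),
         time_coding = "years from baseline, uncentered",
         method = "REML, Wald normal p-values",
         fit = fit),
    class = "atrophy_lmm"
  )
}

#' @export
print.atrophy_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept mixed model (%s)\n", x$method))
  cat(sprintf("  %d subjects, %d observations; predictor: %s\n",
              x$n_subjects, x$n_observations, x$predictor))
  co <- x$coefficients
  co$estimate <- signif(co$estimate, 4)
  co$se <- signif(co$se, 4)
  co$p <- signif(co$p, 3)
  print(co[, c("term", "estimate", "se", "p")], row.names = FALSE)
  cat(sprintf("  random-intercept var %.4g, residual var %.4g\n",
              x$random_intercept_var, x$residual_var))
  invisible(x)
}

#' Extract one fixed-effect row from a mixed-model fit
#'
#' @param fit an `atrophy_lmm`.
#' @param term term name (default the interaction).
#' @return named list `estimate`, `se`, `p`.
#' @export
lmm_term <- function(fit, term = fit$interaction_term) {
  co <- fit$coefficients
  row <- co[co$term == term, , drop = FALSE]
  if (nrow(row) == 0L)
    abort("argument_error", sprintf("no term '%s' in fit", term))
  list(estimate = row$estimate, se = row$se, p = row$p)
}

#' Mixed model of a clinical outcome on atrophy similarity and time
#'
#' Fits `outcome ~ similarity + time + similarity:time + (1 | subject)` by
#' REML, where `similarity` is each subject's baseline AD-specific atrophy
#' similarity (time-invariant), so the interaction measures how the rate of
#' change in the outcome varies with baseline atrophy similarity.
#'
#' @param visits data frame with columns `subject_id`, `visit_time`,
#'   `similarity` and the outcome.
#' @param outcome name of the outcome column (e.g. `"mmse"`, `"cdr_sb"`).
#' @return an `atrophy_lmm`.
#' @export
fit_similarity_by_time <- function(visits, outcome) {
  if (!outcome %in% names(visits))
    abort("argument_error", sprintf("no outcome column '%s'", outcome))
  d <- visits[is.finite(visits[[outcome]]), , drop = FALSE]
  if (stats::sd(d[[outcome]]) == 0)
    abort("degenerate_error", sprintf("outcome '%s' is constant", outcome))
  check_visit_design(d)
  base <- d[order(d$subject_id, d$visit_time), ]
  base_sim <- tapply(base$similarity, base$subject_id, function(x) x[1L])
  d$sim_baseline <- as.numeric(base_sim[as.character(d$subject_id)])
  d$outcome_value <- d[[outcome]]
  d$time <- d$visit_time
  fit <- fit_lmm(d, outcome_value ~ sim_baseline * time + (1 | subject_id),
                 predictor = "similarity")
  fit$coefficients$term <- sub("sim_baseline", "similarity",
                               fit$coefficients$term)
  fit$interaction_term <- "similarity:time"
  fit$outcome <- outcome
  fit
}

#' Mixed model of atrophy similarity on group and time
#'
#' Fits `similarity ~ group + time + group:time + (1 | subject)` where
#' `group` is a binary progression label (converter vs non-converter, or
#' fast vs slow decliner; the progressing group is coded 1). The interaction
#' is the extra similarity worsening per year in the progressing group.
#'
#' @param visits data frame with `subject_id`, `visit_time`, `similarity`.
#' @param labels data frame with `subject_id` and `label`, or a named
#'   character vector of labels per subject.
#' @return an `atrophy_lmm`.
#' @export
fit_group_by_time <- function(visits, labels) {
  lab <- normalize_labels(labels)
  d <- visits
  d$label <- lab[as.character(d$subject_id)]
  if (anyNA(d$label))
    abort("label_error", "every subject needs a group label")
  pos <- c("converter", "fast_decliner")
  d$group <- as.numeric(d$label %in% pos)
  if (length(unique(d$group)) < 2L)
    abort("label_error", "both groups must be present")
  check_visit_design(d)
  d$time <- d$visit_time
  fit <- fit_lmm(d, similarity ~ group * time + (1 | subject_id),
                 predictor = "group")
  fit$interaction_term <- "group:time"
  fit
}

normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    stats::setNames(as.character(labels$label),
                    as.character(labels$subject_id))
  } else {
    stats::setNames(as.character(labels), names(labels))
  }
}

#' Welch two-sample comparison of similarity at one visit
#'
#' @param visits data frame with `subject_id`, `visit_time`, `similarity`.
#' @param labels group labels as in [fit_group_by_time()].
#' @param visit_time which visit to compare (default baseline 0).
#' @param time_tol visit-time matching tolerance (default 0.25 y).
#' @return an object of class `htest` (Welch t-test).
#' @export
compare_groups_at_visit <- function(visits, labels, visit_time = 0,
                                    time_tol = 0.25) {
  lab <- normalize_labels(labels)
  d <- visits[abs(visits$visit_time - visit_time) <= time_tol, , drop = FALSE]
  d$label <- lab[as.character(d$subject_id)]
  pos <- d$label %in% c("converter", "fast_decliner")
  x <- d$similarity[pos]
  y <- d$similarity[!pos & !is.na(d$label)]
  if (length(x) < 2L || length(y) < 2L)
    abort("insufficient_data",
          "each group needs at least 2 subjects at this visit")
  stats::t.test(x, y)
}
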