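#' Stratum labels for a visit table
#'
#' Resolves one of the supported stratification factors to a label per
#' visit: `sex`, `age_band` (banded from `age_days` when the column is
#' absent), `complaint_type` (medical/surgical, derived from
#' `complaint_category` when absent) , `complaint_category` or
#' `diagnosis`. Visits whose label is missing are `NA` and are reported
#' as unclassified rather than silently dropped.
#'
#' @param visits Visit data frame.
#' @param factor One of `"sex"`, `"age_band"`, `"complaint_type"`,
#'   `"complaint_category"`, `"diagnosis"`.
#' @return Character vector of stratum labels (`NA` = unclassified).
#' @export
stratum_labels <- function(visits,
                           factor = c("sex", "age_band", "complaint_type",
                                      "complaint_category", "diagnosis")) {
  factor <- match.arg(factor)
  if (factor == "age_band" && is.null(visits$age_band)) {
    return(as.character(age_band(visits$age_days)))
  }
  if (factor == "complaint_type" && is.null(visits$complaint_type)) {
    return(complaint_type(visits$complaint_category))
  }
  if (is.null(visits[[factor]])) {
    ped_stop("pedtriage_incomplete_visit",
             paste0("visits lack a '", factor, "' column"))
  }
  as.character(visits[[factor]])
}

#' Stratified diagnostic validity
#'
#' Recomputes the full diagnostic summary within each stratum of a
#' factor: per-stratum 2x5 crosstab, dichotomization, and the validity
#' panel, alongside the prevalence of high-level assignments by the index
#' test (levels 1--2) and by the reference standard. Strata with zero
#' denominators get `NA` statistics, not zeros; an empty stratum is a
#' report with `n = 0`, not an error.
#'
#' @param visits Visit data frame with `final_level` and `acuity`.
#' @param factor Stratification factor, see [stratum_labels()].
#' @param strata Optional character vector fixing the stratum order;
#'   default is the sorted observed labels.
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `stratified_validity`: one element per stratum
#'   (plus `"unclassified"` when present) with `stratum`, `n`,
#'   `prevalence_test_high`, `prevalence_ref_high`, `summary`.
#' @export
stratified_validity <- function(visits, factor, strata = NULL,
                                conf_level = 0.95) {
  labels <- stratum_labels(visits, factor)
  if (is.null(strata)) strata <- sort(unique(labels[!is.na(labels)]))
  unclassified <- sum(is.na(labels) | !(labels %in% strata))
  reports <- lapply(strata, function(s) {
    sub <- visits[!is.na(labels) & labels == s, , drop = FALSE]
    stratum_report(s, sub, conf_level)
  })
  names(reports) <- strata
  structure(list(factor = factor, reports = reports,
                 unclassified = unclassified, n = nrow(visits)),
            class = "stratified_validity")
}

stratum_report <- function(label, sub, conf_level = 0.95) {
  n <- nrow(sub)
  if (n == 0L) {
    return(list(stratum = label, n = 0L,
                prevalence_test_high = na_estimate(),
                prevalence_ref_high = na_estimate(), summary = NULL))
  }
  ct <- build_crosstab(sub)
  conf <- dichotomize(ct)
  list(stratum = label, n = n,
       prevalence_test_high = safe_prop_pct(conf$tp + conf$fp, n, conf_level),
       prevalence_ref_high = safe_prop_pct(conf$tp + conf$fn, n, conf_level),
       summary = diagnostic_summary(conf, conf_level))
}

#' @export
print.stratified_validity <- function(x, digits = 1, ...) {
  cat("<stratified_validity> by ", x$factor, ", n = ",
      format(x$n, big.mark = ","), "\n", sep = "")
  for (r in x$reports) {
    s <- r$summary
    cat(sprintf("  %-28s n=%-7d sens %-18s spec %-18s LR+ %s\n",
                r$stratum, r$n,
                if (is.null(s)) "NA" else format_estimate(s$sensitivity, digits),
                if (is.null(s)) "NA" else format_estimate(s$specificity, digits),
                if (is.null(s)) "NA" else format_estimate(s$lr_pos, digits)))
  }
  if (x$unclassified > 0L) {
    cat("  (", x$unclassified, " unclassified visits)\n", sep = "")
  }
  invisible(x)
}

OUTCOME_LEVELS <- c("icu", "hospitalization", "transfer", "discharged")

#' Outcome rates by triage level
#'
#' Per triage level, the proportion of visits ending in ICU admission,
#' ward hospitalization, transfer to another establishment, or discharge
#' home, each with an exact binomial 95% CI. Whether the rates decrease
#' monotonically with level is reported, not enforced.
#'
#' @param visits Visit data frame with `final_level` and `outcome`
#'   (one of `icu`, `hospitalization`, `transfer`, `discharged`).
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `outcome_summary`: per level a named list of
#'   [interval_estimate()]s (percent) plus `n`; and
#'   `hospitalization_monotone`, `TRUE` when the hospitalization rate is
#'   non-increasing from level 1 to 5.
#' @export
outcome_rates_by_level <- function(visits, conf_level = 0.95) {
  stopifnot(all(c("final_level", "outcome") %in% names(visits)))
  bad <- setdiff(unique(as.character(visits$outcome)), OUTCOME_LEVELS)
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0L) {
    ped_stop("pedtriage_outcome_vocabulary",
             paste0("unknown outcome label(s): ",
                    paste(bad, collapse = ", "),
                    "; expected: ", paste(OUTCOME_LEVELS, collapse = ", ")))
  }
  per_level <- lapply(1:5, function(l) {
    sub <- visits[visits$final_level == l & !is.na(visits$outcome), ,
                  drop = FALSE]
    n <- nrow(sub)
    rates <- lapply(OUTCOME_LEVELS, function(o) {
      safe_prop_pct(sum(sub$outcome == o), n, conf_level)
    })
    names(rates) <- OUTCOME_LEVELS
    c(rates, list(n = n))
  })
  names(per_level) <- paste0("L", 1:5)
  hosp <- vapply(per_level, function(x) x$hospitalization$point, numeric(1))
  structure(list(levels = per_level,
                 hospitalization_monotone =
                   !anyNA(hosp) && all(diff(hosp) <= 0)),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, digits = 1, ...) {
  cat("<outcome_summary> outcome rates (%) by triage level\n")
  for (l in names(x$levels)) {
    r <- x$levels[[l]]
    cat(sprintf("  %s (n=%d): icu %s, hosp %s, transfer %s, discharged %s\n",
                l, r$n, format_estimate(r$icu, digits),
                format_estimate(r$hospitalization, digits),
                format_estimate(r$transfer, digits),
                format_estimate(r$discharged, digits)))
  }
  cat("  hospitalization rate monotone decreasing:",
      x$hospitalization_monotone, "\n")
  invisible(x)
}

#' One-way ANOVA of length of stay across triage levels
#'
#' Fixed-effects one-way analysis of variance computed from the
#' between/within sum-of-squares decomposition: F = MSB/MSW with
#' (k - 1, N - k) degrees of freedom, followed by Scheffe simultaneous
#' pairwise contrasts at the study-wide significance level (default
#' 0.001). Levels with fewer than two observations are dropped with a
#' warning.
#'
#' @param visits Visit data frame with `final_level` and `los_minutes`.
#' @param alpha Significance level for the Scheffe contrasts, default
#'   0.001.
#' @return A list of class `los_summary`: `groups` (per level: n, mean,
#'   sd), `anova` (F, df1, df2, p_value, ss_between, ss_within) and
#'   `scheffe` (data frame of pairwise contrasts with simultaneous
#'   confidence bounds and significance flags).
#' @export
los_anova <- function(visits, alpha = 0.001) {
  stopifnot(all(c("final_level", "los_minutes") %in% names(visits)))
  keep <- !is.na(visits$los_minutes) & !is.na(visits$final_level)
  y <- as.numeric(visits$los_minutes[keep])
  g <- factor(visits$final_level[keep], levels = 1:5)
  sizes <- table(g)
  small <- names(sizes)[sizes > 0 & sizes < 2]
  if (length(small) > 0L) {
    ped_warn("pedtriage_small_group",
             paste0("dropping triage level(s) with < 2 LOS observations: ",
                    paste(small, collapse = ", ")))
  }
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < 2L) {
    ped_stop("pedtriage_insufficient_groups",
             "need at least two triage levels with >= 2 LOS observations")
  }
  sel <- g %in% usable
  y <- y[sel]
  g <- droplevels(g[sel])
  k <- nlevels(g)
  N <- length(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  sds <- tapply(y, g, stats::sd)
  grand <- mean(y)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- k - 1L
  df2 <- N - k
  msw <- ssw / df2
  f <- (ssb / df1) / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)

  crit <- sqrt(df1 * stats::qf(1 - alpha, df1, df2))  # Scheffe critical value
  pairs <- utils::combn(levels(g), 2)
  scheffe <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- means[[a]] - means[[b]]
    se <- sqrt(msw * (1 / ns[[a]] + 1 / ns[[b]]))
    data.frame(level_a = a, level_b = b, diff = diff, se = se,
               lower = diff - crit * se, upper = diff + crit * se,
               significant = abs(diff) > crit * se,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    groups = data.frame(level = levels(g), n = as.vector(ns),
                        mean = as.vector(means), sd = as.vector(sds),
                        stringsAsFactors = FALSE),
    anova = list(F = f, df1 = df1, df2 = df2, p_value = p,
                 ss_between = ssb, ss_within = ssw),
    scheffe = scheffe, alpha = alpha),
    class = "los_summary")
}

#' @export
print.los_summary <- function(x, ...) {
  cat("<los_summary> one-way ANOVA of LOS by triage level\n")
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  L%s: n=%d, mean %.1f min (sd %.1f)\n",
                x$groups$level[i], x$groups$n[i], x$groups$mean[i],
                x$groups$sd[i]))
  }
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g\n", x$anova$df1, x$anova$df2,
              x$anova$F, x$anova$p_value))
  cat(sprintf("  Scheffe contrasts at alpha = %g: %d of %d significant\n",
              x$alpha, sum(x$scheffe$significant), nrow(x$scheffe)))
  invisible(x)
}
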