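#' Interval estimate container
#'
#' @param point,lower,upper Numeric scalars (may be `NA`).
#' @param method Identifier of the interval method.
#' @return A list of class `interval_estimate`.
#' @export
interval_estimate <- function(point, lower, upper, method = "unspecified") {
  if (!anyNA(c(point, lower, upper)) &&
      is.finite(point) && (lower > point || point > upper)) {
    ped_stop("pedtriage_bad_interval", "interval must satisfy lower <= point <= upper")
  }
  structure(list(point = point, lower = lower, upper = upper,
                 method = method),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, digits = 1, ...) {
  cat(format_estimate(x, digits), " [", x$method, "]\n", sep = "")
  invisible(x)
}

format_estimate <- function(x, digits = 1) {
  if (is.na(x$point) || !is.finite(x$point)) return("NA")
  sprintf("%.*f (%.*f-%.*f)", digits, x$point, digits, x$lower,
          digits, x$upper)
}

#' Confidence interval for a binomial proportion
#'
#' Two methods are offered. `"exact"` (the default) is the
#' Clopper-Pearson interval, computed from beta quantiles; it is the
#' method that reproduces the reference cohort's printed bounds at
#' one-decimal rounding and is what diagnostic-accuracy reports
#' conventionally use. `"wilson"` is the Wilson score interval, which
#' inverts the score test, behaves sensibly near 0 and 1 and never
#' leaves \[0, 1\].
#'
#' @param x Number of successes.
#' @param n Number of trials; must be positive.
#' @param conf_level Confidence level, default 0.95.
#' @param method `"exact"` (Clopper-Pearson) or `"wilson"`.
#' @return An [interval_estimate()] on the proportion scale.
#' @export
#' @examples
#' proportion_ci(1710, 2238)            # 0.764 (0.746-0.782)
#' proportion_ci(1710, 2238, method = "wilson")
proportion_ci <- function(x, n, conf_level = 0.95,
                          method = c("exact", "wilson")) {
  method <- match.arg(method)
  if (!is_count1(n) || n == 0L) {
    ped_stop("pedtriage_empty", "n must be a positive count")
  }
  if (!is_count1(x) || x > n) {
    ped_stop("pedtriage_empty", "x must be a count with 0 <= x <= n")
  }
  alpha <- 1 - conf_level
  p <- x / n
  if (method == "exact") {
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    return(interval_estimate(p, lower, upper, method = "exact"))
  }
  z <- stats::qnorm(1 - alpha / 2)
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  interval_estimate(p, (centre - half) / denom, (centre + half) / denom,
                    method = "wilson")
}

#' Cross-tabulate triage levels against reference acuity
#'
#' Builds the 2 (reference acuity: high/low) x 5 (triage level 1--5)
#' contingency table at the heart of the validation: each cell counts the
#' visits assigned that triage level whose reference standard (PEWS)
#' classified them high or low.
#'
#' @param visits Data frame with columns `final_level` (integer 1--5) and
#'   `acuity` (`"high"`/`"low"`), e.g. the output of [triage_cohort()].
#' @return A `triage_crosstab`: an integer matrix with rows
#'   `c("high","low")` and columns `L1..L5`, with attribute `n`.
#' @export
build_crosstab <- function(visits) {
  stopifnot(is.data.frame(visits))
  if (!all(c("final_level", "acuity") %in% names(visits))) {
    ped_stop("pedtriage_incomplete_visit",
             "visits need final_level and acuity columns")
  }
  bad <- which(is.na(visits$final_level) | is.na(visits$acuity) |
                 !(visits$final_level %in% 1:5) |
                 !(as.character(visits$acuity) %in% c("high", "low")))
  if (length(bad) > 0L) {
    ped_stop("pedtriage_incomplete_visit",
             paste0("visits with missing/invalid level or acuity at rows: ",
                    paste(utils::head(bad, 10L), collapse = ", "),
                    if (length(bad) > 10L) " ..."),
             rows = bad)
  }
  counts <- table(factor(as.character(visits$acuity),
                         levels = c("high", "low")),
                  factor(visits$final_level, levels = 1:5))
  crosstab(unclass(counts))
}

#' Construct a triage cross-tabulation from counts
#'
#' @param counts 2x5 matrix of non-negative counts; row 1 = reference
#'   high, row 2 = reference low; columns = triage levels 1..5.
#' @return A `triage_crosstab`.
#' @export
crosstab <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 5L)),
            all(counts >= 0), all(counts == trunc(counts)))
  storage.mode(counts) <- "double"  # cohort-scale counts exceed toy sizes
  dimnames(counts) <- list(acuity = c("high", "low"),
                           level = paste0("L", 1:5))
  structure(counts, n = sum(counts), class = c("triage_crosstab", "matrix"))
}

#' @export
print.triage_crosstab <- function(x, ...) {
  cat("<triage_crosstab> n =", format(attr(x, "n"), big.mark = ","), "\n")
  m <- cbind(unclass(x), Total = rowSums(x))
  m <- rbind(m, Total = colSums(m))
  print(m)
  invisible(x)
}

#' Dichotomize the cross-tabulation into a 2x2 confusion table
#'
#' Triage levels 1--2 are the index test's high-level emergencies, levels
#' 3--5 low-level. Crossed with the reference acuity this gives TP
#' (high, level 1--2), FN (high, level 3--5), FP (low, level 1--2) and TN
#' (low, level 3--5).
#'
#' @param ct A `triage_crosstab`.
#' @return A `confusion_2x2` list with elements `tp`, `fp`, `fn`, `tn`.
#' @export
dichotomize <- function(ct) {
  stopifnot(inherits(ct, "triage_crosstab"))
  confusion_2x2(tp = sum(ct["high", 1:2]), fp = sum(ct["low", 1:2]),
                fn = sum(ct["high", 3:5]), tn = sum(ct["low", 3:5]))
}

#' Construct a 2x2 confusion table
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A list of class `confusion_2x2`.
#' @export
confusion_2x2 <- function(tp, fp, fn, tn) {
  vals <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(vals >= 0), all(vals == trunc(vals)))
  structure(as.list(vals), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  cat("<confusion_2x2> tp =", x$tp, " fp =", x$fp, " fn =", x$fn,
      " tn =", x$tn, "\n")
  invisible(x)
}

#' Likelihood-ratio confidence interval (log method)
#'
#' Computes LR+ = sens/(1 - spec) or LR- = (1 - sens)/spec with the
#' standard log-transform interval: exp(ln LR +/- z * SE), where for LR+
#' SE^2 = 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn), and the mirrored formula
#' for LR-.
#'
#' @param c A [confusion_2x2()].
#' @param which `"positive"` or `"negative"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An [interval_estimate()], method `"log"`; all-`NA` when a zero
#'   cell makes the variance undefined (the reason is attached as the
#'   `reason` attribute).
#' @export
likelihood_ratio_ci <- function(c, which = c("positive", "negative"),
                                conf_level = 0.95) {
  stopifnot(inherits(c, "confusion_2x2"))
  which <- match.arg(which)
  sens <- c$tp / (c$tp + c$fn)
  spec <- c$tn / (c$tn + c$fp)
  if (which == "positive") {
    point <- sens / (1 - spec)
    cells <- c(c$tp, c$fp)
    se2 <- 1 / c$tp - 1 / (c$tp + c$fn) + 1 / c$fp - 1 / (c$fp + c$tn)
  } else {
    point <- (1 - sens) / spec
    cells <- c(c$fn, c$tn)
    se2 <- 1 / c$fn - 1 / (c$tp + c$fn) + 1 / c$tn - 1 / (c$fp + c$tn)
  }
  if (any(cells == 0) || !is.finite(point) || !is.finite(se2)) {
    out <- interval_estimate(NA_real_, NA_real_, NA_real_, method = "log")
    attr(out, "reason") <- "zero cell: log-method variance undefined"
    attr(out, "point_unbounded") <- is.infinite(point)
    return(out)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  interval_estimate(point, exp(log(point) - z * sqrt(se2)),
                    exp(log(point) + z * sqrt(se2)), method = "log")
}

pct <- function(est) {
  interval_estimate(100 * est$point, 100 * est$lower, 100 * est$upper,
                    method = est$method)
}

na_estimate <- function(method = "exact") {
  interval_estimate(NA_real_, NA_real_, NA_real_, method = method)
}

safe_prop_pct <- function(x, n, conf_level) {
  if (n == 0) na_estimate() else pct(proportion_ci(x, n, conf_level))
}

#' Diagnostic-accuracy summary of a 2x2 confusion table
#'
#' Computes the full validity panel for an index test against a binary
#' reference standard: sensitivity, specificity, PPV and NPV (percent,
#' exact binomial 95% CIs), positive and negative likelihood ratios
#' (log-method CIs), and the agreement / over-triage / under-triage
#' partition of the cohort (percent). Over-triage is the proportion classified
#' high by the index test but low by the reference (FP/n); under-triage
#' the converse (FN/n). Any statistic with a zero denominator is `NA`,
#' never 0.
#'
#' @param c A [confusion_2x2()].
#' @param conf_level Confidence level for all intervals, default 0.95.
#' @return A list of class `diagnostic_summary` whose statistic elements
#'   are [interval_estimate()]s, plus `n` and the input `counts`.
#' @export
#' @examples
#' ct <- crosstab(rbind(c(82, 1628, 489, 38, 1),
#'                      c(135, 14947, 34343, 41264, 7579)))
#' diagnostic_summary(dichotomize(ct))
diagnostic_summary <- function(c, conf_level = 0.95) {
  stopifnot(inherits(c, "confusion_2x2"))
  n <- c$tp + c$fp + c$fn + c$tn
  if (n == 0) {
    ped_stop("pedtriage_empty_table", "empty confusion table")
  }
  structure(list(
    sensitivity = safe_prop_pct(c$tp, c$tp + c$fn, conf_level),
    specificity = safe_prop_pct(c$tn, c$tn + c$fp, conf_level),
    ppv = safe_prop_pct(c$tp, c$tp + c$fp, conf_level),
    npv = safe_prop_pct(c$tn, c$tn + c$fn, conf_level),
    lr_pos = likelihood_ratio_ci(c, "positive", conf_level),
    lr_neg = likelihood_ratio_ci(c, "negative", conf_level),
    agreement = safe_prop_pct(c$tp + c$tn, n, conf_level),
    over_triage = safe_prop_pct(c$fp, n, conf_level),
    under_triage = safe_prop_pct(c$fn, n, conf_level),
    n = n, counts = c),
    class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, digits = 1, ...) {
  cat("<diagnostic_summary> n =", format(x$n, big.mark = ","), "\n")
  stats <- c("sensitivity", "specificity", "ppv", "npv", "lr_pos",
             "lr_neg", "agreement", "over_triage", "under_triage")
  for (s in stats) {
    unit <- if (s %in% c("lr_pos", "lr_neg")) "" else "%"
    cat(sprintf("  %-13s %s%s\n", s, format_estimate(x[[s]], digits), unit))
  }
  invisible(x)
}

#' Agreement / over- / under-triage counts
#'
#' The canonical (`"dichotomized"`) reading pools triage levels 1--2 vs
#' 3--5 and compares with the binary reference class, so over-triage =
#' FP and under-triage = FN. The optional `"ordinal"` reading instead
#' anchors each reference class at its nearest compatible level (high ->
#' level 2, low -> level 3) and counts any strictly more severe
#' assignment as over-triage and strictly less severe as under-triage;
#' it is provided for exploration and is not the reported definition.
#'
#' @param ct A `triage_crosstab`.
#' @param scale `"dichotomized"` (default) or `"ordinal"`.
#' @return Named numeric vector with `agreement`, `over`, `under`; sums
#'   to `n`.
#' @export
over_under_counts <- function(ct, scale = c("dichotomized", "ordinal")) {
  stopifnot(inherits(ct, "triage_crosstab"))
  scale <- match.arg(scale)
  lev <- 1:5
  if (scale == "dichotomized") {
    over <- sum(ct["low", lev <= 2])
    under <- sum(ct["high", lev >= 3])
  } else {
    over <- sum(ct["high", lev < 2]) + sum(ct["low", lev < 3])
    under <- sum(ct["high", lev > 2]) + sum(ct["low", lev > 3])
  }
  n <- attr(ct, "n")
  c(agreement = n - over - under, over = over, under = under)
}

#' Pearson chi-squared test of independence
#'
#' @param table An r x c matrix of counts with at least two rows, two
#'   columns, and no zero margin.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L ||
      any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    ped_stop("pedtriage_degenerate_margin",
             "table needs >= 2 rows and columns with positive margins")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Bonferroni-adjusted significance threshold
#'
#' The study-wide significance level (default 0.001, chosen conservative
#' for a very large cohort) divided across a declared family of
#' comparisons.
#'
#' @param m Number of comparisons in the family.
#' @param alpha Family-wise significance level, default 0.001.
#' @return Per-comparison threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.001) {
  stopifnot(is_count1(m), m >= 1)
  alpha / m
}
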