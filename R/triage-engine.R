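#' Fractile response-time targets
#'
#' Each triage level carries a target maximum delay, in minutes, before
#' the patient should be seen by a physician: 0, 15, 60, 120 and 240
#' minutes for levels 1 to 5.
#'
#' @param level Integer vector of triage levels (1--5).
#' @return Integer vector of target minutes.
#' @export
#' @examples
#' fractile_target(1:5)
fractile_target <- function(level) {
  if (!all(level %in% 1:5)) {
    ped_stop("pedtriage_invalid_level",
             "triage level must be an integer in 1..5")
  }
  c(0L, 15L, 60L, 120L, 240L)[level]
}

#' Construct a vital-signs record
#'
#' Absence is a first-class state: an unmeasured vital is `NA`, never 0,
#' and is treated as normal downstream.
#'
#' @param glasgow Pediatric Glasgow score, integer 3--15, or `NA`.
#' @param heart_rate Beats per minute, or `NA`.
#' @param resp_rate Breaths per minute, or `NA`.
#' @param spo2 Pulsed oxygen saturation in percent (0--100), or `NA`.
#' @param oxygen_support Oxygen flow in L/min (0 = ambient air), or `NA`.
#' @return A named list of class `vital_signs`.
#' @export
vital_signs <- function(glasgow = NA, heart_rate = NA, resp_rate = NA,
                        spo2 = NA, oxygen_support = NA) {
  chk <- function(x, lo, hi, what) {
    if (!is.na(x) && (!is.numeric(x) || x < lo || x > hi)) {
      ped_stop("pedtriage_bad_vital",
               sprintf("%s must be in [%s, %s] or NA", what, lo, hi))
    }
    as.numeric(x)
  }
  structure(list(glasgow = chk(glasgow, 3, 15, "glasgow"),
                 heart_rate = chk(heart_rate, 0, 400, "heart_rate"),
                 resp_rate = chk(resp_rate, 0, 200, "resp_rate"),
                 spo2 = chk(spo2, 0, 100, "spo2"),
                 oxygen_support = chk(oxygen_support, 0, 100,
                                      "oxygen_support")),
            class = "vital_signs")
}

#' Construct a triage presentation
#'
#' One patient at the triage desk: age, sex, whether the nurse judged the
#' child critical on the ABCDE primary survey, the selected complaint
#' items, any flagged risk conditions, and the vital signs entered.
#'
#' @param age_days Non-negative integer age in days.
#' @param sex `"male"` or `"female"`.
#' @param critical_flag Logical; `TRUE` stops triage at level 1.
#' @param selected_items Character vector of item labels (non-empty unless
#'   `critical_flag` is set or a risk condition is flagged).
#' @param risk_conditions Character vector of risk-condition labels.
#' @param vitals A [vital_signs()] record.
#' @return An object of class `presentation`.
#' @export
presentation <- function(age_days, sex = c("male", "female"),
                         critical_flag = FALSE,
                         selected_items = character(),
                         risk_conditions = character(),
                         vitals = vital_signs()) {
  sex <- match.arg(sex)
  stopifnot(is_count1(age_days), is.logical(critical_flag),
            inherits(vitals, "vital_signs"))
  if (!critical_flag && length(risk_conditions) == 0L &&
      length(selected_items) == 0L) {
    ped_stop("pedtriage_no_items",
             "a non-critical presentation without risk conditions must select at least one item")
  }
  structure(list(age_days = as.integer(age_days), sex = sex,
                 critical_flag = critical_flag,
                 selected_items = as.character(selected_items),
                 risk_conditions = as.character(risk_conditions),
                 vitals = vitals),
            class = "presentation")
}

#' Aggregate selected complaint items by maximum severity
#'
#' When several items are selected, the most severe one (the numerically
#' smallest level) determines the suggested triage level.
#'
#' @param selected Character vector of item labels; must be non-empty.
#' @param table An [item_table()].
#' @return Integer triage level in 1..5.
#' @export
#' @examples
#' tab <- default_triage_config()$items
#' aggregate_items(c("fever", "respiratory distress"), tab)  # 2
aggregate_items <- function(selected, table) {
  if (length(selected) == 0L) {
    ped_stop("pedtriage_no_items", "no items selected")
  }
  min(lookup_items(table, selected)$base_level)
}

#' Apply risk-condition overrides
#'
#' A matched risk condition forces the level to at most its assigned
#' level; overrides never decrease severity. Conditions declaring an
#' `age_max_days` (e.g. newborn, < 28 days) are matched automatically
#' from the age, whether or not they were flagged.
#'
#' @param level Integer level in 1..5.
#' @param conditions Character vector of flagged risk-condition labels.
#' @param age_days Age in days.
#' @param risks A [risk_conditions()] table.
#' @return Integer level in 1..5.
#' @export
apply_risk_overrides <- function(level, conditions, age_days, risks) {
  stopifnot(is_level(level), inherits(risks, "risk_conditions"))
  unknown <- setdiff(conditions, risks$label)
  if (length(unknown) > 0L) {
    ped_stop("pedtriage_unknown_risk_condition",
             paste0("unknown risk condition(s): ",
                    paste(unknown, collapse = ", ")))
  }
  auto <- !is.na(risks$age_max_days) & age_days < risks$age_max_days
  matched <- risks$label %in% conditions | auto
  if (!any(matched)) return(as.integer(level))
  as.integer(min(level, min(risks$assigned_level[matched])))
}

# out-of-range test for one vital against one range row; NA value is
# "not measured", treated as normal
vital_out_of_range <- function(value, min, max) {
  if (is.na(value)) return(FALSE)
  (!is.na(min) && value < min) || (!is.na(max) && value > max)
}

#' Moderate a triage level by out-of-range vital signs
#'
#' Any measured vital falling outside its age-band reference range
#' upgrades the level to at most the range's configured escalation level;
#' moderation never downgrades. Vitals that were not entered are treated
#' as normal.
#'
#' @param level Integer level in 1..5.
#' @param vitals A [vital_signs()] record.
#' @param age_days Age in days.
#' @param ranges A [vital_ranges()] table; must cover the visit's age band.
#' @return Integer level in 1..5.
#' @export
moderate_by_vitals <- function(level, vitals, age_days, ranges) {
  stopifnot(is_level(level), inherits(vitals, "vital_signs"),
            inherits(ranges, "vital_ranges"))
  band <- as.character(age_band(age_days))
  rows <- ranges[!is.na(band) & ranges$band == band, , drop = FALSE]
  if (nrow(rows) == 0L) {
    ped_stop("pedtriage_range_coverage",
             sprintf("no vital-sign ranges configured for age band of %s days",
                     age_days))
  }
  out <- as.integer(level)
  for (i in seq_len(nrow(rows))) {
    v <- vitals[[rows$vital[i]]]
    if (vital_out_of_range(v, rows$min[i], rows$max[i])) {
      out <- min(out, rows$escalation_level[i])
    }
  }
  out
}

#' Run the full triage decision rule on one presentation
#'
#' The rule mirrors nurse-led five-level triage: (1) a critical child
#' (ABCDE failure) stops triage immediately at level 1; otherwise (2) the
#' selected complaint items are aggregated by maximum severity, (3) risk
#' conditions force the level to at most their assigned level, and (4)
#' out-of-range vital signs escalate further. Severity only ever
#' increases along the chain. The result carries the fractile
#' response-time target of the final level and an audit trail of which
#' pathways fired.
#'
#' @param pres A [presentation()].
#' @param config A [triage_config()].
#' @return An object of class `triage_result` with elements
#'   `suggested_level` (item aggregation alone), `final_level`,
#'   `moderation_applied` (named logical: critical, risk, vitals),
#'   `override_applied`, `fractile_minutes`.
#' @export
#' @examples
#' cfg <- default_triage_config()
#' p <- presentation(age_days = 10, sex = "male",
#'                   selected_items = "limb trauma, no deformity")
#' evaluate_triage(p, cfg)  # newborn override: level 2
evaluate_triage <- function(pres, config) {
  stopifnot(inherits(pres, "presentation"), inherits(config, "triage_config"))
  flags <- c(critical = FALSE, risk = FALSE, vitals = FALSE)
  if (pres$critical_flag) {
    flags["critical"] <- TRUE
    return(new_triage_result(1L, 1L, flags))
  }
  # A purely risk-flagged presentation (no items) starts from the least
  # severe level; the override then sets the condition's assigned level.
  suggested <- if (length(pres$selected_items) > 0L) {
    aggregate_items(pres$selected_items, config$items)
  } else 5L
  lvl <- apply_risk_overrides(suggested, pres$risk_conditions,
                              pres$age_days, config$risk_conditions)
  if (lvl < suggested) flags["risk"] <- TRUE
  lvl2 <- moderate_by_vitals(lvl, pres$vitals, pres$age_days,
                             config$vital_ranges)
  if (lvl2 < lvl) flags["vitals"] <- TRUE
  new_triage_result(as.integer(suggested), as.integer(lvl2), flags)
}

new_triage_result <- function(suggested, final, flags,
                              override = FALSE) {
  structure(list(suggested_level = suggested, final_level = final,
                 moderation_applied = flags, override_applied = override,
                 fractile_minutes = fractile_target(final)),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  fired <- names(x$moderation_applied)[x$moderation_applied]
  cat("<triage_result> final level ", x$final_level,
      " (suggested ", x$suggested_level, "), see physician within ",
      x$fractile_minutes, " min", sep = "")
  if (length(fired)) cat("; moderation:", paste(fired, collapse = ", "))
  if (x$override_applied) cat("; nurse override")
  cat("\n")
  invisible(x)
}

#' Apply an upgrade-only nurse override
#'
#' The triage nurse may upgrade (make more severe, i.e. lower the number
#' of) the suggested level after consulting a physician, but never
#' downgrade it. A downgrade request is refused with a warning and the
#' result is returned unchanged.
#'
#' @param result A `triage_result`.
#' @param requested_level Integer level in 1..5 requested by the nurse.
#' @return An updated `triage_result`.
#' @export
nurse_override <- function(result, requested_level) {
  stopifnot(inherits(result, "triage_result"))
  if (!is_level(requested_level)) {
    ped_stop("pedtriage_invalid_level", "requested level must be in 1..5")
  }
  if (requested_level < result$final_level) {
    result$final_level <- as.integer(requested_level)
    result$override_applied <- TRUE
    result$fractile_minutes <- fractile_target(result$final_level)
  } else if (requested_level > result$final_level) {
    ped_warn("pedtriage_downgrade_refused",
             sprintf("override to level %d refused: cannot downgrade from level %d",
                     requested_level, result$final_level))
  }
  result
}
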