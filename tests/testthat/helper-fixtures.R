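# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain loops/enumerations so they share no code path with the
# package implementation they check.

toy_item_table <- function() {
  item_table(data.frame(
    label = c("a1", "b2", "c3", "d4", "e5", "f3"),
    category = c("pulmonary", "pulmonary", "infectious", "digestive",
                 "dermatology", "digestive"),
    base_level = c(1L, 2L, 3L, 4L, 5L, 3L)),
    version = "toy")
}

toy_crosstab <- function(high = c(1, 2, 3, 4, 5), low = c(5, 4, 3, 2, 1)) {
  crosstab(rbind(high, low))
}

# the reference validation cohort's agreement table
refcohort_crosstab <- function() {
  crosstab(rbind(c(82, 1628, 489, 38, 1),
                 c(135, 14947, 34343, 41264, 7579)))
}

# brute-force diagnostic statistics: every formula written out separately
brute_summary <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  list(sens = 100 * tp / (tp + fn), spec = 100 * tn / (tn + fp),
       ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn),
       lr_pos = (tp / (tp + fn)) / (1 - tn / (tn + fp)),
       lr_neg = (1 - tp / (tp + fn)) / (tn / (tn + fp)),
       agreement = 100 * (tp + tn) / n, over = 100 * fp / n,
       under = 100 * fn / n)
}

# brute-force triage reference: enumerates every rule independently of
# evaluate_triage()
reference_triage <- function(pres, config) {
  if (pres$critical_flag) return(1L)
  items <- config$items$items
  lev <- 5L
  if (length(pres$selected_items) > 0L) {
    lev <- 99L
    for (lab in pres$selected_items) {
      row <- which(items$label == lab)
      if (items$base_level[row] < lev) lev <- items$base_level[row]
    }
  }
  rc <- config$risk_conditions
  for (j in seq_len(nrow(rc))) {
    hit <- rc$label[j] %in% pres$risk_conditions
    if (!is.na(rc$age_max_days[j]) && pres$age_days < rc$age_max_days[j]) {
      hit <- TRUE
    }
    if (hit && rc$assigned_level[j] < lev) lev <- rc$assigned_level[j]
  }
  band <- as.character(age_band(pres$age_days))
  rng <- config$vital_ranges
  for (i in seq_len(nrow(rng))) {
    if (rng$band[i] != band) next
    v <- pres$vitals[[rng$vital[i]]]
    if (is.na(v)) next
    out <- (!is.na(rng$min[i]) && v < rng$min[i]) ||
      (!is.na(rng$max[i]) && v > rng$max[i])
    if (out && rng$escalation_level[i] < lev) lev <- rng$escalation_level[i]
  }
  as.integer(lev)
}

# random presentation against the default config
random_presentation <- function(config, n_items_max = 3) {
  labels <- config$items$items$label
  crit <- runif(1) < 0.1
  items <- if (crit) character() else
    sample(labels, sample.int(n_items_max, 1))
  risks <- if (runif(1) < 0.2) "immunosuppressed" else character()
  age <- sample(0:6574, 1)
  vit <- if (runif(1) < 0.5) vital_signs() else
    vital_signs(glasgow = sample(3:15, 1), heart_rate = sample(30:250, 1),
                resp_rate = sample(5:90, 1), spo2 = sample(80:100, 1),
                oxygen_support = sample(c(0, 0, 2, 6), 1))
  presentation(age_days = age, sex = sample(c("male", "female"), 1),
               critical_flag = crit, selected_items = items,
               risk_conditions = risks, vitals = vit)
}

# minimal raw visit rows for pipeline tests
toy_visits <- function(levels, acuity_high, config = default_triage_config()) {
  n <- length(levels)
  data.frame(
    visit_id = sprintf("T%03d", seq_len(n)),
    age_days = rep(800L, n),
    sex = rep("male", n),
    critical_flag = FALSE,
    items = sprintf("pulmonary/L%d", levels),
    risk_conditions = "",
    glasgow = NA_real_, heart_rate = NA_real_, resp_rate = NA_real_,
    spo2 = NA_real_, oxygen_support = NA_real_,
    pews_behavior = ifelse(acuity_high, 3L, 0L),
    pews_cardiovascular = ifelse(acuity_high, 2L, 1L),
    pews_respiratory = 0L,
    outcome = "discharged",
    los_minutes = 100,
    stringsAsFactors = FALSE)
}
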