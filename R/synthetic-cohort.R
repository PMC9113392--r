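#' Cohort simulation parameters
#'
#' Bundles everything the synthetic-cohort generator needs: the triage
#' level marginal, the probability of a high reference (PEWS) acuity
#' given each level, per-level conditionals for sex, age band, complaint
#' category, outcome and diagnosis, the per-level length-of-stay moments,
#' and the PEWS cutoff. Conditionals are modelled as independent given
#' the triage level.
#'
#' @param level_counts Numeric vector of 5 visit counts (levels 1--5);
#'   the marginal is `level_counts / sum(level_counts)`.
#' @param pews_high_counts Numeric vector of 5 counts of reference-high
#'   visits per level; `pews_high_counts / level_counts` is P(high | level).
#' @param sex_male Probability of male sex per level (length 5).
#' @param age_band_probs 7 x 5 matrix, P(age band | level); columns sum
#'   to 1 (rows ordered as [AGE_BANDS]).
#' @param category_probs 20 x 5 matrix, P(complaint category | level),
#'   rows named by [COMPLAINT_CATEGORIES] labels; columns sum to 1.
#' @param outcome_probs 4 x 5 matrix, P(outcome | level), rows `icu`,
#'   `hospitalization`, `transfer`, `discharged`; columns sum to 1.
#' @param diagnosis_probs Matrix of P(diagnosis | level) with named rows
#'   (last row a catch-all); columns sum to 1.
#' @param los_mean,los_sd Length-of-stay mean and SD in minutes per level
#'   (LOS is drawn from a normal truncated at 0).
#' @param cutoff PEWS cutoff defining high acuity, default 4.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(level_counts, pews_high_counts, sex_male,
                          age_band_probs, category_probs, outcome_probs,
                          diagnosis_probs, los_mean, los_sd, cutoff = 4L) {
  stopifnot(length(level_counts) == 5L, all(level_counts > 0),
            length(pews_high_counts) == 5L,
            all(pews_high_counts >= 0),
            all(pews_high_counts <= level_counts),
            length(sex_male) == 5L, all(sex_male >= 0 & sex_male <= 1),
            length(los_mean) == 5L, length(los_sd) == 5L,
            all(los_sd > 0), cutoff %in% 1:9)
  norm_cols <- function(m, what, nr = NULL) {
    m <- as.matrix(m)
    if (!is.null(nr)) stopifnot(nrow(m) == nr)
    stopifnot(ncol(m) == 5L, all(m >= 0))
    sums <- colSums(m)
    if (any(sums <= 0)) {
      ped_stop("pedtriage_bad_params",
               paste0(what, ": every level needs positive total probability"))
    }
    if (any(abs(sums - 1) > 1e-9)) m <- sweep(m, 2, sums, "/")
    m
  }
  age_band_probs <- norm_cols(age_band_probs, "age_band_probs", 7L)
  rownames(age_band_probs) <- AGE_BANDS
  category_probs <- norm_cols(category_probs, "category_probs", 20L)
  stopifnot(setequal(rownames(category_probs),
                     unlist(COMPLAINT_CATEGORIES)))
  outcome_probs <- norm_cols(outcome_probs, "outcome_probs", 4L)
  rownames(outcome_probs) <- OUTCOME_LEVELS
  diagnosis_probs <- norm_cols(diagnosis_probs, "diagnosis_probs")
  structure(list(level_counts = as.numeric(level_counts),
                 level_marginal = level_counts / sum(level_counts),
                 pews_high_counts = as.numeric(pews_high_counts),
                 pews_high_given_level = pews_high_counts / level_counts,
                 sex_male = as.numeric(sex_male),
                 age_band_probs = age_band_probs,
                 category_probs = category_probs,
                 outcome_probs = outcome_probs,
                 diagnosis_probs = diagnosis_probs,
                 los_mean = as.numeric(los_mean),
                 los_sd = as.numeric(los_sd),
                 cutoff = as.integer(cutoff)),
            class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params> reference cohort n =",
      format(sum(x$level_counts), big.mark = ","), "\n")
  cat("  level marginal:",
      paste(sprintf("%.3f", x$level_marginal), collapse = " "), "\n")
  cat("  P(ref high | level):",
      paste(sprintf("%.4f", x$pews_high_given_level), collapse = " "), "\n")
  cat("  PEWS cutoff:", x$cutoff, "\n")
  invisible(x)
}

#' Default cohort parameters (reference validation cohort)
#'
#' Encodes the published characteristics of a 100,506-visit pediatric ED
#' validation cohort: the joint triage-level x reference-acuity counts of
#' its agreement table, and the per-level sex, age-band, complaint,
#' outcome and length-of-stay conditionals of its descriptive tables.
#' Percentages are as printed (one decimal) and are renormalized to exact
#' probability vectors; conditionals not jointly tabulated are treated as
#' independent given the level.
#'
#' @return A [cohort_params()] object.
#' @export
default_cohort_params <- function() {
  # agreement table: visits per triage level, and reference-high per level
  level_counts <- c(217, 16575, 34832, 41302, 7580)
  pews_high_counts <- c(82, 1628, 489, 38, 1)

  sex_male <- c(0.599, 0.594, 0.551, 0.529, 0.547)

  # P(age band | level), percent by column (levels 1..5)
  age_band_probs <- matrix(c(
    1.8,  6.5,  0.2,  0.2,  0.4,   # 0-28d
    2.8,  7.9,  1.6,  1.2,  1.6,   # 28d-3m
    14.3, 12.9, 11.5,  7.1, 11.8,  # 3m-1y
    29.0, 21.4, 25.9, 20.1, 22.6,  # 1y-3y
    24.9, 22.2, 29.7, 27.2, 26.9,  # 3y-7y
    14.3, 15.6, 18.3, 26.1, 21.6,  # 7y-12y
    12.9, 13.6, 12.9, 18.1, 15.1), # 12y-18y
    nrow = 7, byrow = TRUE) / 100

  # P(complaint category | level), percent by column
  cat_rows <- c(
    ent = c(1.8, 3.0, 4.3, 14.8, 14.6),
    pulmonary = c(42.9, 31.0, 18.1, 0.1, 0.1),
    cardiovascular = c(5.1, 3.0, 0.8, 1.5, 1.9),
    neurology = c(18.0, 5.4, 2.8, 1.7, 0.05),
    digestive = c(2.8, 21.2, 23.8, 11.8, 1.4),
    urology_nephrology = c(0.05, 3.9, 3.1, 2.8, 0.1),
    gynecology = c(0.05, 0.2, 0.3, 0.2, 0.1),
    dermatology = c(1.4, 2.2, 3.1, 12.3, 20.6),
    endocrinology_metabolism = c(3.2, 1.0, 0.2, 0.02, 0.02),
    infectious = c(4.6, 7.8, 15.4, 12.2, 15.3),
    rheumatology_pain = c(0.05, 4.0, 4.1, 2.7, 0.02),
    hematology = c(0.05, 0.7, 0.1, 0.02, 0.02),
    poisoning = c(1.4, 0.4, 0.2, 0.1, 0.1),
    other_medical = c(0.05, 3.2, 0.1, 1.1, 1.3),
    head_neck_trauma = c(5.5, 5.3, 13.2, 5.9, 19.5),
    upper_limb_trauma = c(0.5, 4.3, 6.3, 15.0, 12.0),
    lower_limb_trauma = c(0.05, 1.1, 2.0, 16.3, 12.7),
    trunk_pelvis_urogenital_trauma = c(0.05, 0.5, 1.0, 1.2, 0.1),
    burns = c(4.6, 0.7, 0.6, 0.2, 0.2),
    other_surgical = c(8.3, 1.3, 0.8, 0.2, 0.02))
  category_probs <- matrix(cat_rows, nrow = 20, byrow = TRUE,
                           dimnames = list(sub("[0-9]+$", "",
                                               names(cat_rows)[seq(1, 100, 5)]),
                                           NULL)) / 100

  # P(outcome | level), percent by column
  outcome_probs <- matrix(c(
    13.8, 0.5, 0.03, 0.01, 0.02,   # icu
    53.5, 21.8, 4.8,  1.0,  0.6,   # hospitalization
    0.02, 0.3,  0.07, 0.03, 0.01,  # transfer
    32.7, 77.4, 95.1, 99.0, 99.4), # discharged
    nrow = 4, byrow = TRUE) / 100

  # P(diagnosis | level); 11 most frequent diagnoses + catch-all
  dg <- matrix(c(
    0.5,  6.8, 18.4, 17.2, 17.6,   # ent_infection
    3.7, 12.0, 14.5,  4.5,  1.6,   # acute_gastroenteritis
    22.1, 10.0, 3.1,  0.1,  0.1,   # asthma
    8.3,  6.6,  1.4,  0.1,  0.2,   # bronchiolitis
    0.5,  1.6,  2.5,  1.2,  0.8,   # flu
    1.4,  4.5,  5.8,  3.7,  4.1,   # fever
    6.5,  3.4,  6.5,  3.3, 15.6,   # mild_traumatic_brain_injury
    0.9,  4.9,  6.6, 14.7, 11.4,   # upper_limb_trauma
    0.9,  1.5,  2.5, 15.6, 11.0,   # lower_limb_trauma
    4.6,  0.7,  0.6,  0.3,  0.2,   # burn
    0.02, 2.8,  1.4,  0.4, 0.02),  # visceral_pathology
    nrow = 11, byrow = TRUE) / 100
  dg <- rbind(dg, pmax(0, 1 - colSums(dg)))
  rownames(dg) <- c("ent_infection", "acute_gastroenteritis", "asthma",
                    "bronchiolitis", "flu", "fever",
                    "mild_traumatic_brain_injury", "upper_limb_trauma",
                    "lower_limb_trauma", "burn", "visceral_pathology",
                    "other")

  cohort_params(level_counts = level_counts,
                pews_high_counts = pews_high_counts,
                sex_male = sex_male,
                age_band_probs = age_band_probs,
                category_probs = category_probs,
                outcome_probs = outcome_probs,
                diagnosis_probs = dg,
                los_mean = c(176, 136.9, 125, 107, 96.5),
                los_sd = c(124.4, 88.9, 82.6, 69.7, 63.1),
                cutoff = 4L)
}

#' Reference cross-tabulation encoded by a parameter set
#'
#' Reconstructs the 2x5 triage-by-acuity contingency table from the
#' counts carried by a [cohort_params()] object. With
#' [default_cohort_params()] this is the validation cohort's agreement
#' table (n = 100,506).
#'
#' @param params A [cohort_params()]; default [default_cohort_params()].
#' @return A `triage_crosstab`.
#' @export
reference_crosstab <- function(params = default_cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  crosstab(rbind(params$pews_high_counts,
                 params$level_counts - params$pews_high_counts))
}

#' Diagnostic-summary points implied by parameters
#'
#' Closed-form expectations of the validity statistics under a parameter
#' set, with no sampling: population sensitivity, specificity, predictive
#' values, likelihood ratios, agreement and over-/under-triage computed
#' from the level marginal and P(reference high | level). These are the
#' values the sampled pipeline estimates converge to, so they anchor
#' parameter-recovery tests.
#'
#' @param params A [cohort_params()].
#' @return Named numeric vector (percent for proportions, plain ratio for
#'   `lr_pos` / `lr_neg`).
#' @export
implied_metrics <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  m <- params$level_marginal
  p <- params$pews_high_given_level
  test_high <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  tp <- sum(m[test_high] * p[test_high])
  fp <- sum(m[test_high] * (1 - p[test_high]))
  fn <- sum(m[!test_high] * p[!test_high])
  tn <- sum(m[!test_high] * (1 - p[!test_high]))
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  c(sensitivity = 100 * sens, specificity = 100 * spec,
    ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn),
    lr_pos = sens / (1 - spec), lr_neg = (1 - sens) / spec,
    agreement = 100 * (tp + tn), over_triage = 100 * fp,
    under_triage = 100 * fn)
}

# inverse-CDF categorical draw: one uniform per draw, so streams extend
# cleanly when n grows
sample_cat <- function(u, probs) {
  findInterval(u, cumsum(probs) / sum(probs),
               rightmost.closed = TRUE, left.open = TRUE) + 1L
}

# derive independent sub-seeds below 2^31 from (seed, stream index)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103 + k * 12347) %% 2147483647)
}

uniform_streams <- function(seed, n, n_streams) {
  lapply(seq_len(n_streams), function(k) {
    set.seed(derive_seed(seed, k))
    stats::runif(n)
  })
}

# compositions of total into three parts each in 0..3, as a matrix
pews_compositions <- function(total) {
  grid <- expand.grid(b = 0:3, c = 0:3, r = 0:3)
  as.matrix(grid[grid$b + grid$c + grid$r == total, , drop = FALSE])
}

#' Generate a synthetic pediatric ED cohort
#'
#' Samples visits level-first: triage level from the marginal, reference
#' acuity given level, then sex, age band (with an exact day drawn
#' uniformly within the band), complaint category, outcome, diagnosis and
#' LOS (normal truncated at 0) given level. Each visit carries a raw
#' presentation — complaint items whose max-severity aggregation equals
#' the intended level, an ABCDE critical flag for half of the level-1
#' visits, and vital signs that are absent or in-range — so the cohort
#' round-trips through the triage engine, plus PEWS components whose
#' total falls on the intended side of the cutoff. Draws use one
#' fixed-count uniform stream per attribute, so increasing `n` extends a
#' cohort without reshuffling earlier visits.
#'
#' Because the engine automatically caps newborns (< 28 days) at the
#' newborn risk level, visits drawn at a less severe intended level have
#' their age band resampled among the older bands; the age marginal is
#' distorted by well under half a percent.
#'
#' @param n Number of visits; must be positive.
#' @param params A [cohort_params()]; default [default_cohort_params()].
#' @param seed Integer seed; identical `(n, params, seed)` give identical
#'   cohorts.
#' @param config The [triage_config()] whose item table labels the
#'   presentations; default [default_triage_config()].
#' @return A visit data frame (one row per visit) with presentation,
#'   PEWS, outcome and LOS columns plus the latent `intended_level` and
#'   `intended_acuity`.
#' @export
generate_cohort <- function(n, params = default_cohort_params(),
                            seed = 1L, config = default_triage_config()) {
  if (!is_count1(n) || n == 0) {
    ped_stop("pedtriage_bad_params", "n must be a positive integer")
  }
  stopifnot(inherits(params, "cohort_params"),
            inherits(config, "triage_config"))
  s <- uniform_streams(seed, n, 18L)

  level <- sample_cat(s[[1]], params$level_marginal)
  acuity_high <- s[[2]] < params$pews_high_given_level[level]
  sex <- ifelse(s[[3]] < params$sex_male[level], "male", "female")

  band_idx <- vapply(seq_len(n), function(i) {
    sample_cat(s[[4]][i], params$age_band_probs[, level[i]])
  }, integer(1))
  # newborn band is only compatible with levels at or above (as severe
  # as) the automatic newborn assigned level; resample older bands
  newborn_cap <- {
    rc <- config$risk_conditions
    auto <- !is.na(rc$age_max_days) & rc$age_max_days <= 28
    if (any(auto)) min(rc$assigned_level[auto]) else 5L
  }
  conflict <- band_idx == 1L & level > newborn_cap
  if (any(conflict)) {
    band_idx[conflict] <- vapply(which(conflict), function(i) {
      pr <- params$age_band_probs[, level[i]]
      pr[1] <- 0
      sample_cat(s[[15]][i], pr) # sample_cat renormalizes
    }, integer(1))
  }
  # integer days strictly inside the half-open band [brk_i, brk_{i+1})
  brk <- age_band_breaks()
  lo <- ceiling(brk[band_idx])
  hi <- ceiling(brk[band_idx + 1L]) - 1
  age_days <- lo + floor(s[[5]] * (hi - lo + 1))

  category <- rownames(params$category_probs)[
    vapply(seq_len(n), function(i) {
      sample_cat(s[[6]][i], params$category_probs[, level[i]])
    }, integer(1))]
  outcome <- OUTCOME_LEVELS[vapply(seq_len(n), function(i) {
    sample_cat(s[[7]][i], params$outcome_probs[, level[i]])
  }, integer(1))]
  diagnosis <- rownames(params$diagnosis_probs)[
    vapply(seq_len(n), function(i) {
      sample_cat(s[[8]][i], params$diagnosis_probs[, level[i]])
    }, integer(1))]

  # LOS ~ Normal(mean, sd) truncated at 0 via inverse CDF
  mu <- params$los_mean[level]
  sd <- params$los_sd[level]
  p0 <- stats::pnorm(0, mu, sd)
  los <- round(stats::qnorm(p0 + s[[9]] * (1 - p0), mu, sd), 1)

  # PEWS total uniform on the intended side of the cutoff, then a
  # uniformly chosen composition into the three components
  cutoff <- params$cutoff
  total <- ifelse(acuity_high,
                  cutoff + floor(s[[10]] * (10 - cutoff)),
                  floor(s[[11]] * cutoff))
  comp_tables <- lapply(0:9, pews_compositions)
  comps <- t(vapply(seq_len(n), function(i) {
    tab <- comp_tables[[total[i] + 1L]]
    tab[floor(s[[12]][i] * nrow(tab)) + 1L, ]
  }, integer(3)))

  # presentation: critical shortcut for half the level-1 visits,
  # otherwise a category item at the intended level, sometimes plus a
  # milder item (which max-severity aggregation ignores)
  critical <- level == 1L & s[[14]] < 0.5
  main_item <- sprintf("%s/L%d", category, level)
  extra <- !critical & level < 5L & s[[13]] < 0.3
  extra_level <- level + 1L + floor(s[[16]] * (5L - level))
  items <- ifelse(critical, "",
                  ifelse(extra,
                         paste0(main_item, ";",
                                sprintf("%s/L%d", category,
                                        pmin(extra_level, 5L))),
                         main_item))

  # vitals: measured for ~half the visits, drawn inside the age band's
  # reference range (moderation must not fire on intended-level visits)
  vit_present <- s[[17]] < 0.5
  rng <- config$vital_ranges
  get_rng <- function(vital, col) {
    v <- rng[rng$vital == vital, ]
    v[match(AGE_BANDS[band_idx], v$band), col]
  }
  hr_lo <- get_rng("heart_rate", "min"); hr_hi <- get_rng("heart_rate", "max")
  rr_lo <- get_rng("resp_rate", "min"); rr_hi <- get_rng("resp_rate", "max")
  u_hr <- s[[18]]
  heart_rate <- ifelse(vit_present, round(hr_lo + u_hr * (hr_hi - hr_lo)),
                       NA_real_)
  resp_rate <- ifelse(vit_present, round(rr_lo + u_hr * (rr_hi - rr_lo)),
                      NA_real_)
  spo2 <- ifelse(vit_present, round(95 + u_hr * 5), NA_real_)

  data.frame(
    visit_id = sprintf("V%07d", seq_len(n)),
    age_days = as.integer(age_days),
    age_band = AGE_BANDS[band_idx],
    sex = sex,
    critical_flag = critical,
    items = items,
    risk_conditions = NA_character_,
    glasgow = ifelse(vit_present, 15, NA_real_),
    heart_rate = heart_rate,
    resp_rate = resp_rate,
    spo2 = spo2,
    oxygen_support = NA_real_,
    pews_behavior = comps[, 1],
    pews_cardiovascular = comps[, 2],
    pews_respiratory = comps[, 3],
    outcome = outcome,
    los_minutes = los,
    complaint_category = category,
    complaint_type = complaint_type(category),
    diagnosis = diagnosis,
    intended_level = level,
    intended_acuity = ifelse(acuity_high, "high", "low"),
    stringsAsFactors = FALSE)
}
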