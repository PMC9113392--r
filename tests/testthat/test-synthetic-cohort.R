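test_that("default parameters encode the reference cohort tables", {
  params <- default_cohort_params()
  expect_equal(sum(params$level_counts), 100506)
  expect_equal(params$level_marginal,
               c(217, 16575, 34832, 41302, 7580) / 100506)
  expect_equal(params$pews_high_given_level[3], 489 / 34832)
  expect_true(all(params$pews_high_given_level >= 0 &
                    params$pews_high_given_level <= 1))
  # every conditional is a proper probability vector
  expect_equal(unname(colSums(params$age_band_probs)), rep(1, 5),
               tolerance = 1e-9)
  expect_equal(unname(colSums(params$category_probs)), rep(1, 5),
               tolerance = 1e-9)
  expect_equal(unname(colSums(params$outcome_probs)), rep(1, 5),
               tolerance = 1e-9)
  expect_equal(unname(colSums(params$diagnosis_probs)), rep(1, 5),
               tolerance = 1e-9)
  expect_true(all(params$los_sd > 0))
  # the crosstab reconstructed from the params is the agreement table
  expect_equal(unclass(reference_crosstab(params)),
               unclass(refcohort_crosstab()), ignore_attr = TRUE)
})

test_that("invalid parameters are rejected before sampling", {
  params <- default_cohort_params()
  expect_error(cohort_params(level_counts = c(1, 1, 1, 1, 0),
                             pews_high_counts = rep(0, 5),
                             sex_male = rep(0.5, 5),
                             age_band_probs = params$age_band_probs,
                             category_probs = params$category_probs,
                             outcome_probs = params$outcome_probs,
                             diagnosis_probs = params$diagnosis_probs,
                             los_mean = rep(100, 5), los_sd = rep(10, 5)))
  expect_error(generate_cohort(0), class = "pedtriage_bad_params")
  expect_error(generate_cohort(-3), class = "pedtriage_bad_params")
})

test_that("implied metrics reproduce closed-form expectations", {
  params <- default_cohort_params()
  m <- implied_metrics(params)
  # the default params encode the agreement table exactly
  expect_equal(round(m[["sensitivity"]], 1), 76.4)
  expect_equal(round(m[["specificity"]], 1), 84.7)
  expect_equal(round(m[["agreement"]], 1), 84.5)
  # perfect concordance: reference high exactly on levels 1-2
  perfect <- cohort_params(level_counts = params$level_counts,
                           pews_high_counts = c(217, 16575, 0, 0, 0),
                           sex_male = params$sex_male,
                           age_band_probs = params$age_band_probs,
                           category_probs = params$category_probs,
                           outcome_probs = params$outcome_probs,
                           diagnosis_probs = params$diagnosis_probs,
                           los_mean = params$los_mean,
                           los_sd = params$los_sd)
  mp <- implied_metrics(perfect)
  expect_equal(mp[["sensitivity"]], 100)
  expect_equal(mp[["specificity"]], 100)
  # partition identity holds for arbitrary params
  set.seed(41)
  for (i in 1:5) {
    pr <- cohort_params(level_counts = sample(50:500, 5),
                        pews_high_counts = c(10, 10, 5, 2, 1),
                        sex_male = runif(5),
                        age_band_probs = params$age_band_probs,
                        category_probs = params$category_probs,
                        outcome_probs = params$outcome_probs,
                        diagnosis_probs = params$diagnosis_probs,
                        los_mean = params$los_mean, los_sd = params$los_sd)
    mi <- implied_metrics(pr)
    expect_equal(mi[["agreement"]] + mi[["over_triage"]] +
                   mi[["under_triage"]], 100, tolerance = 1e-9)
  }
})

test_that("generation is deterministic and extends without reshuffling", {
  a <- generate_cohort(300, seed = 5)
  b <- generate_cohort(300, seed = 5)
  expect_identical(a, b)
  bigger <- generate_cohort(450, seed = 5)
  expect_identical(a, bigger[seq_len(300), ])
  different <- generate_cohort(300, seed = 6)
  expect_false(identical(a$items, different$items))
})

test_that("every generated presentation re-triages to its intended level", {
  v <- generate_cohort(3000, seed = 13)
  out <- pews_cohort(triage_cohort(v))
  expect_equal(out$final_level, out$intended_level)
  expect_equal(out$acuity, out$intended_acuity)
  # PEWS totals land on the intended side of the cutoff by construction
  expect_true(all(out$pews_total[out$intended_acuity == "high"] >= 4))
  expect_true(all(out$pews_total[out$intended_acuity == "low"] <= 3))
  # structural sanity of the visit table
  expect_false(anyDuplicated(v$visit_id) > 0)
  expect_true(all(v$age_days >= 0 & v$age_days < 18 * 365.25))
  expect_true(all(v$los_minutes >= 0))
  expect_equal(as.character(age_band(v$age_days)), v$age_band)
})

test_that("sampled marginals track the parameters within binomial error", {
  params <- default_cohort_params()
  n <- 20000
  v <- generate_cohort(n, params, seed = 17)
  for (l in 1:5) {
    p <- params$level_marginal[l]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(v$intended_level == l) - p), 4 * se,
              label = paste("level", l, "marginal"))
  }
  # sex conditional at the two biggest levels
  for (l in 4:5) {
    sub <- v[v$intended_level == l, ]
    p <- params$sex_male[l]
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(mean(sub$sex == "male") - p), 4 * se)
  }
  # LOS moments at level 4 against the truncated-normal expectation
  sub <- v[v$intended_level == 4, ]
  mu <- params$los_mean[4]; s <- params$los_sd[4]
  alpha <- -mu / s
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  trunc_mean <- mu + s * lambda
  trunc_sd <- s * sqrt(1 + alpha * lambda - lambda^2)
  se_mean <- trunc_sd / sqrt(nrow(sub))
  expect_lt(abs(mean(sub$los_minutes) - trunc_mean), 4 * se_mean)
  expect_lt(abs(sd(sub$los_minutes) - trunc_sd), 4 * se_mean)
})
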