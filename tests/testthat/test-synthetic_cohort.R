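test_that("cohort_spec validates its fields", {
  expect_error(cohort_spec(n_participants = 0), "n_participants")
  expect_error(cohort_spec(outcome_missing_rate = 1.2),
               "outcome_missing_rate")
  expect_error(cohort_spec(frequency_split = c(0.5, 0.5, 0.5)),
               "frequency_split")
  expect_error(cohort_spec(confounding_strength = -1),
               "confounding_strength")
})

test_that("generation is deterministic and calibrated to the spec", {
  spec <- cohort_spec(n_participants = 2842, seed = 4)
  sim <- generate_cohort(spec)
  expect_identical(sim, generate_cohort(spec))
  co <- sim$cohort

  # treated count lands in the target-trial range
  expect_gte(sim$truth$n_treated, 655)
  expect_lte(sim$truth$n_treated, 820)

  # marginal calibration within 3 percentage points
  expect_lt(abs(mean(co$died_before_followup) -
                spec$death_rate_untreated), 0.03)
  surv <- co$died_before_followup == 0
  expect_lt(abs(mean(is.na(co$ptau181_fu[surv])) -
                spec$outcome_missing_rate), 0.03)
  expect_lt(abs(mean(is.na(co$ha_prescription)) -
                spec$exposure_missing_rate), 0.03)
  expect_lt(abs(mean(is.na(co$pta_better_ear)) -
                spec$audiometry_missing_rate), 0.03)

  # positivity for the default configuration
  expect_true(all(sim$truth$propensity > 0.02 &
                  sim$truth$propensity < 0.98))
})

test_that("structural zeros hold in every generated row", {
  for (seed in 1:3) {
    co <- generate_cohort(cohort_spec(n_participants = 1500,
                                      seed = seed))$cohort
    dead <- co$died_before_followup == 1
    expect_true(all(is.na(co$ptau181_fu[dead])))
    expect_true(all(is.na(co$nfl_fu[dead])))
    expect_true(all(is.na(co$gfap_fu[dead])))
    expect_true(all(is.na(co$abeta_ratio_fu[dead])))
    both <- !is.na(co$ha_prescription) & !is.na(co$ha_frequency)
    expect_true(all(co$ha_frequency[both & co$ha_prescription == 0] ==
                    "never"))
    expect_true(all(co$ha_prescription[both &
                                       co$ha_frequency != "never"] == 1))
    expect_true(all(co$abeta_ratio_bl > 0))
    expect_true(all(co[, paste0(BIOMARKERS, "_bl")] > 0))
  }
})

test_that("treatment is confounded and the null world is null", {
  # confounded world: treated are older on average
  co <- generate_cohort(cohort_spec(n_participants = 4000, seed = 2,
                                    exposure_missing_rate = 0))$cohort
  expect_gt(mean(co$age[co$ha_prescription == 1]),
            mean(co$age[co$ha_prescription == 0]))

  # null structural model: no treated/untreated outcome difference
  spec0 <- recovery_spec(4000, seed = 3, effect = 0,
                         confounding_strength = 0)
  co0 <- generate_cohort(spec0)$cohort
  s <- co0[co0$died_before_followup == 0, ]
  tt <- t.test(s$ptau181_fu[s$ha_prescription == 1],
               s$ptau181_fu[s$ha_prescription == 0])
  expect_lt(abs(tt$statistic), 3)
})

test_that("truth oracle recovers injected effects and the null", {
  spec <- cohort_spec(n_participants = 2000, seed = 5,
                      true_mean_diff = c(ptau181 = 2))
  tr <- truth_contrasts(spec, n_oracle = 2e5)
  expect_lt(abs(tr$trial1$HA$mean_diff["ptau181"] - 2),
            4 * tr$trial1$HA$mc_se["ptau181"])
  expect_lt(abs(tr$trial2$often_always$mean_diff["ptau181"] - 2),
            4 * tr$trial2$often_always$mc_se["ptau181"])
  expect_lt(abs(tr$trial1$HA$mean_diff["nfl"]),
            4 * tr$trial1$HA$mc_se["nfl"])

  spec0 <- cohort_spec(n_participants = 2000, seed = 5)
  tr0 <- truth_contrasts(spec0, n_oracle = 2e5)
  for (k in BIOMARKERS) {
    expect_lt(abs(tr0$trial1$HA$mean_diff[k]), 4 * tr0$trial1$HA$mc_se[k])
    expect_lt(abs(tr0$trial1$HA$quantile_diff[k]), 0.6)
  }
  expect_error(truth_contrasts(spec, n_oracle = 100), "1e5")
})

test_that("quantile truth matches an independent empirical oracle", {
  # second-seed draw from the same structural world, direct quantile
  spec <- cohort_spec(n_participants = 2000, seed = 11,
                      true_mean_diff = c(ptau181 = 3),
                      treatment_death_lor = 0)
  tr <- truth_contrasts(spec, n_oracle = 1.5e5, seed = 77)
  big <- generate_cohort(cohort_spec(n_participants = 2e5, seed = 78,
                                     true_mean_diff = c(ptau181 = 3),
                                     outcome_missing_rate = 0,
                                     exposure_missing_rate = 0,
                                     confounding_strength = 0,
                                     frequency_split = c(0, 0, 1)))
  co <- big$cohort
  s <- co[co$died_before_followup == 0, ]
  direct <- quantile(s$ptau181_fu[s$ha_prescription == 1], 0.9) -
    quantile(s$ptau181_fu[s$ha_prescription == 0], 0.9)
  expect_lt(abs(tr$trial1$HA$quantile_diff["ptau181"] - direct), 0.75)
})

test_that("cohort CSV round-trips with JSON sidecar", {
  sim <- generate_cohort(cohort_spec(n_participants = 300, seed = 9))
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(sim, path)
  back <- read_cohort(path)
  expect_equal(dim(back), dim(sim$cohort))
  expect_equal(back$ptau181_bl, sim$cohort$ptau181_bl, tolerance = 1e-12)
  expect_identical(levels(back$ha_frequency), HA_FREQ_LEVELS)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  expect_equal(side$spec$n_participants, 300)
  expect_length(side$truth$propensity, 300)
  unlink(c(path, paste0(path, ".json")))
})
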