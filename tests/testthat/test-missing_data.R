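test_that("PMM preserves observed cells, support, and reproducibility", {
  withr_seed(31, {
    n <- 600
    x <- rnorm(n)
    z <- rbinom(n, 1, 0.5)
    y <- 1 + 2 * x + z + rnorm(n)
    g <- factor(sample(c("a", "b", "c"), n, TRUE))
    miss_y <- rbinom(n, 1, plogis(-0.8 + x)) == 1
    miss_g <- rbinom(n, 1, 0.2) == 1
    d <- data.frame(x = x, z = z, y = y, g = g)
    d$y[miss_y] <- NA
    d$g[miss_g] <- NA
    d_orig <- d
  })
  sp <- imputation_spec(seed = 3, n_cycles = 5)
  imps <- chained_pmm_impute(d, sp, m = 3)
  for (imp in imps) {
    expect_false(anyNA(imp$data))
    # observed cells bit-identical
    expect_identical(imp$data$y[!miss_y], d_orig$y[!miss_y])
    expect_identical(imp$data$g[!miss_g], d_orig$g[!miss_g])
    expect_identical(imp$data$x, d_orig$x)
    # imputed values in the observed support
    expect_true(all(imp$data$y[miss_y] %in% d_orig$y[!miss_y]))
    expect_true(all(imp$data$g[miss_g] %in% levels(d_orig$g)))
  }
  # (spec, seed, m) fixed => identical imputations
  expect_identical(chained_pmm_impute(d, sp, m = 3)[[2]]$data,
                   imps[[2]]$data)
  # different seed => different draws
  sp2 <- sp; sp2$seed <- 4L
  expect_false(identical(chained_pmm_impute(d, sp2, m = 1)[[1]]$data$y,
                         imps[[1]]$data$y))

  # complete variable returned unchanged even if listed
  sp3 <- imputation_spec(variables = c("x", "y"), seed = 1)
  expect_identical(chained_pmm_impute(d, sp3, m = 1)[[1]]$data$x, d$x)

  all_na <- d; all_na$y <- NA_real_
  expect_error(chained_pmm_impute(all_na, sp, m = 1), "no observed")
})

test_that("MCAR-masked Gaussian column mean is recovered", {
  withr_seed(32, {
    n <- 5000
    x <- rnorm(n)
    y_full <- 3 + x + rnorm(n)
    d <- data.frame(x = x, y = y_full)
    d$y[sample.int(n, round(0.3 * n))] <- NA
  })
  imps <- chained_pmm_impute(d, imputation_spec(seed = 5, n_cycles = 3),
                             m = 20)
  pooled <- mean(vapply(imps, function(i) mean(i$data$y), numeric(1)))
  expect_lt(abs(pooled - mean(y_full)) / sd(y_full), 0.05)
})

test_that("MAR imputation recovers the pre-masking outcome mean", {
  spec <- cohort_spec(n_participants = 3000, seed = 33,
                      exposure_missing_rate = 0,
                      audiometry_missing_rate = 0)
  sim <- generate_cohort(spec)
  co <- sim$cohort
  surv <- co$died_before_followup == 0
  full_mean <- mean(sim$truth$full_outcomes[surv, "ptau181"])
  sd_full <- sd(sim$truth$full_outcomes[surv, "ptau181"])
  sp <- imputation_spec(
    variables = "ptau181_fu",
    predictors = list(ptau181_fu = c("age", "ptau181_bl", "nfl_bl",
                                     "aux_3ms_w1", "aux_3ms_w2",
                                     "ha_prescription")),
    restrict = list(ptau181_fu = function(df) df$died_before_followup == 0),
    n_cycles = 3, seed = 6)
  imps <- chained_pmm_impute(co, sp, m = 20)
  pooled <- mean(vapply(imps, function(i) mean(i$data$ptau181_fu[surv]),
                        numeric(1)))
  expect_lt(abs(pooled - full_mean) / sd_full, 0.15)
})

test_that("passive terms and structural rules are maintained", {
  withr_seed(34, {
    d <- data.frame(x = rnorm(200), y = rnorm(200))
    d$y[sample.int(200, 60)] <- NA
    d$y2 <- d$y^2
  })
  sp <- imputation_spec(
    variables = "y", predictors = list(y = "x"),
    passive_terms = list(y2 = function(df) df$y^2), seed = 2)
  imp <- chained_pmm_impute(d, sp, m = 1)[[1]]
  expect_equal(imp$data$y2, imp$data$y^2)
})

test_that("LASSO auxiliary selection keeps signal, drops noise, forces", {
  gen <- function(seed) {
    withr_seed(seed, {
      n <- 3000
      u1 <- rnorm(n); u2 <- rnorm(n); noise <- rnorm(n)
      y <- 2 + 1.5 * u1 + 0.8 * u2 + rnorm(n)
      y[rbinom(n, 1, 0.2) == 1] <- NA
      data.frame(u1 = u1, u2 = u2, noise = noise, y = y)
    })
  }
  hits_noise <- 0L
  hits_signal <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    sel <- select_auxiliaries(gen(s), c("u1", "u2", "noise"), "y",
                              seed = s, quadratic = FALSE,
                              products = FALSE)
    hits_noise <- hits_noise + ("noise" %in% sel)
    hits_signal <- hits_signal + all(c("u1", "u2") %in% sel)
  }
  expect_lte(hits_noise / n_rep, 0.2)      # null excluded >= 80%
  expect_equal(hits_signal, n_rep)         # signal always kept

  # forced terms survive even with zero coefficient
  sel <- select_auxiliaries(gen(1), c("u1", "u2", "noise"), "y",
                            forced = "trt:apoe", seed = 1)
  expect_true("trt:apoe" %in% sel)

  # pure-noise candidates: modal outcome is the forced set only
  null_gen <- function(seed) {
    withr_seed(seed, {
      n <- 800
      d <- data.frame(a = rnorm(n), b = rnorm(n), y = rnorm(n))
      d$y[rbinom(n, 1, 0.2) == 1] <- NA
      d
    })
  }
  only_forced <- vapply(1:15, function(s) {
    identical(select_auxiliaries(null_gen(s), c("a", "b"), "y",
                                 forced = "f1", seed = s,
                                 quadratic = FALSE, products = FALSE),
              "f1")
  }, logical(1))
  expect_gt(mean(only_forced), 0.5)

  tiny <- data.frame(a = rnorm(20), y = c(rnorm(5), rep(NA, 15)))
  expect_error(select_auxiliaries(tiny, "a", "y"), "fewer than 10")
})

test_that("imputed datasets round-trip to CSV with parallel flags", {
  d <- data.frame(x = c(1, 2, NA, 4), z = c(0, 1, 1, 0))
  imp <- chained_pmm_impute(d, imputation_spec(variables = "x",
                                               predictors = list(x = "z"),
                                               n_cycles = 1, seed = 1),
                            m = 1)[[1]]
  dir <- file.path(tempdir(), "impout")
  path <- write_imputed(imp, dir)
  expect_true(file.exists(path))
  flags <- read.csv(file.path(dir, "imp_b0_m1_flags.csv"))
  expect_identical(flags$x, c(FALSE, FALSE, TRUE, FALSE))
  unlink(dir, recursive = TRUE)
})

test_that("delta shift hits exactly the qualifying imputed cells", {
  # observed follow-up values engineered to SD exactly 10
  base <- 50
  obs_vals <- c(base - 10 * sqrt(2) / 2, base + 10 * sqrt(2) / 2)
  d <- data.frame(
    died_before_followup = c(0, 0, 0, 0, 1),
    ptau181_fu = c(obs_vals, 40, 41, NA),
    abeta_ratio_fu = c(obs_vals, 60, 61, NA))
  flags <- cbind(ptau181_fu = c(FALSE, FALSE, TRUE, TRUE, FALSE),
                 abeta_ratio_fu = c(FALSE, FALSE, TRUE, TRUE, FALSE))
  imp <- structure(list(data = d, flags = flags, b = 1L, m = 1L),
                   class = "imputed_dataset")
  expect_equal(sd(d$ptau181_fu[1:2]), 10)

  shifted <- apply_delta_shift(imp, delta_spec(0.25))
  expect_equal(shifted$data$ptau181_fu[3:4], c(40, 41) + 2.5)
  # amyloid ratio shifts down
  expect_equal(shifted$data$abeta_ratio_fu[3:4], c(60, 61) - 2.5)
  # observed cells untouched
  expect_identical(shifted$data$ptau181_fu[1:2], d$ptau181_fu[1:2])

  # delta = 0 is the identity
  expect_identical(apply_delta_shift(imp, delta_spec(0)), imp)

  # 0.05 variant scales linearly
  s2 <- apply_delta_shift(imp, delta_spec(0.05))
  expect_equal(s2$data$abeta_ratio_fu[3], 60 - 0.05 * 10)

  expect_error(apply_delta_shift(list(data = d), delta_spec(0.25)),
               "flags")
})
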