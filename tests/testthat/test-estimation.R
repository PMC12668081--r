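test_that("truncation bound evaluates the printed rule and is monotone", {
  expect_equal(truncation_bound(2842), 30.07, tolerance = 5e-4)
  expect_equal(truncation_bound(100), 4.29, tolerance = 5e-3)
  expect_gt(truncation_bound(2843), truncation_bound(2842))
  expect_error(truncation_bound(1), ">= 2")
})

test_that("propensity fits are calibrated, normalized and truncated", {
  # null model: probabilities ~0.5 under randomization
  d <- make_randomized(2000, seed = 41)
  pf <- fit_propensity(d, "w")
  expect_lt(abs(mean(pf$prob[, "HA"]) - 0.5), 0.025)
  expect_lt(mean(abs(pf$prob[, "HA"] - 0.5)), 0.05)
  expect_equal(rowSums(pf$prob), rep(1, 2000), tolerance = 1e-12)

  # coefficient recovery for a known logistic generator
  reps <- vapply(1:20, function(s) {
    withr_seed(s, {
      n <- 5000
      w <- rnorm(n)
      a <- rbinom(n, 1, plogis(-1 + 0.8 * w))
      dd <- data.frame(strategy = factor(a, levels = 0:1), w = w)
      X <- cbind(1, w)
      fit <- suppressWarnings(glm.fit(X, a, family = binomial()))
      fit$coefficients[2]
    })
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.8), 2 * sd(reps) / sqrt(20))

  # three-strategy fit: rows normalized, truncation recorded
  withr_seed(42, {
    n <- 900
    w <- rnorm(n)
    p2 <- plogis(-2 + 2 * w); p3 <- plogis(-2 - 2 * w)
    u <- runif(n)
    a <- ifelse(u < p2, "rare_sometimes",
                ifelse(u < p2 + p3, "often_always", "never"))
    d3 <- data.frame(strategy = factor(a, levels = HA_FREQ_LEVELS), w = w)
  })
  pf3 <- fit_propensity(d3, "w")
  expect_equal(rowSums(pf3$prob), rep(1, 900), tolerance = 1e-8)
  expect_true(all(1 / pf3$g_trunc <= pf3$bound + 1e-8))
  expect_gt(pf3$n_truncated, 0)

  # perfect separation errors with guidance
  sep <- data.frame(strategy = factor(rep(c("a", "b"), each = 30)),
                    w = rep(c(0, 1), each = 30))
  expect_error(fit_propensity(sep, "w"), "separation")
})

test_that("TMLE equals saturated g-computation on discrete data", {
  for (seed in c(1, 2, 7, 13)) {
    d <- make_discrete(40, seed)
    if (is.null(d)) next
    pf <- fit_propensity(d, "w", bound = 1e9, min_rows = 2)
    tm <- tmle_mean_contrast(d, "y", "w", pf, outcome_formula =
                               ~ strategy * factor(w))
    expect_equal(unname(tm$means), unname(gcomp_saturated(d)),
                 tolerance = 1e-10)
    expect_lt(max(abs(tm$score)), 1e-8)
  }
})

test_that("TMLE needs no targeting when the initial fit solves the score", {
  # bounded covariate and noise keep the linear fit inside the outcome
  # range, the regime where g-computation equality is exact
  withr_seed(43, {
    w <- runif(3000, -1, 1)
    a <- rbinom(3000, 1, 0.5)
    y <- 10 + 3 * w + 2 * a + runif(3000, -1, 1)
    d <- data.frame(strategy = factor(ifelse(a == 1, "HA", "no_HA"),
                                      levels = c("no_HA", "HA")),
                    w = w, y = y, died_before_followup = 0)
  })
  # known constant design probability: intercept-only propensity
  pf <- fit_propensity(d, character(0))
  tm <- tmle_mean_contrast(d, "y", "w", pf)
  # guard: the fixture really is in the no-clipping regime
  fit <- lm(y ~ strategy + w, data = d)
  preds <- c(predict(fit, transform(d, strategy = factor("HA",
    levels = levels(d$strategy)))),
    predict(fit, transform(d, strategy = factor("no_HA",
    levels = levels(d$strategy)))))
  expect_true(all(preds > min(d$y) & preds < max(d$y)))
  # correctly specified linear outcome model: epsilon ~ 0 and TMLE
  # matches plain g-computation
  expect_lt(max(abs(tm$epsilon)), 1e-6)
  gcomp <- mean(predict(fit, transform(d, strategy = factor("HA",
    levels = levels(d$strategy))))) -
    mean(predict(fit, transform(d, strategy = factor("no_HA",
    levels = levels(d$strategy)))))
  expect_equal(unname(tm$contrasts), gcomp, tolerance = 1e-6)
})

test_that("TMLE respects its invariants on every run", {
  for (seed in 1:5) {
    surv <- recovery_survivors(recovery_spec(1200, seed))
    pf <- fit_propensity(surv, correct_propensity_terms())
    tm <- tmle_mean_contrast(surv, "ptau181_fu",
                             c("age", "ptau181_bl"), pf)
    # score equation solved
    expect_lt(max(abs(tm$score)), 1e-8)
    # targeted means within the outcome scaling bounds
    expect_true(all(tm$means >= tm$bounds[1] & tm$means <= tm$bounds[2]))
    # influence curve centered
    expect_lt(abs(mean(tm$ic)), 1e-8)
  }
})

test_that("contrasts are invariant to affine outcome rescaling", {
  surv <- recovery_survivors(recovery_spec(1500, 44))
  pf <- fit_propensity(surv, correct_propensity_terms())
  tm1 <- tmle_mean_contrast(surv, "ptau181_fu", c("age", "ptau181_bl"),
                            pf)
  surv2 <- surv
  surv2$ptau181_fu <- 3 * surv2$ptau181_fu + 7
  tm2 <- tmle_mean_contrast(surv2, "ptau181_fu", c("age", "ptau181_bl"),
                            pf)
  expect_equal(unname(tm2$contrasts), 3 * unname(tm1$contrasts),
               tolerance = 1e-8)
  expect_equal(unname(tm2$means), 3 * unname(tm1$means) + 7,
               tolerance = 1e-8)

  const <- surv
  const$ptau181_fu <- 5
  expect_error(tmle_mean_contrast(const, "ptau181_fu", "age", pf),
               "constant")
})

test_that("weighted quantile matches hand enumeration and brute force", {
  expect_equal(weighted_quantile(1:4, rep(1, 4), 0.5), 2)
  expect_equal(weighted_quantile(1:4, c(0.1, 0.1, 0.1, 0.7), 0.5), 4)
  # exhaustive comparison against the brute-force CDF oracle
  for (seed in 1:30) {
    withr_seed(seed, {
      n <- sample(2:50, 1)
      y <- round(rnorm(n), 1)          # ties likely
      w <- rexp(n)
      tau <- runif(1, 0.05, 0.95)
    })
    expect_equal(weighted_quantile(y, w, tau),
                 brute_weighted_quantile(y, w, tau))
  }
})

test_that("IPW quantile contrast reduces to unweighted under null design", {
  d <- make_randomized(4000, effect = 0, seed = 45)
  pf <- fit_propensity(d, "w")
  qe <- ipw_quantile_contrast(d, "y", pf, 0.9)
  raw <- vapply(split(d$y, d$strategy), quantile, numeric(1), 0.9)
  expect_lt(max(abs(qe$quantiles - raw)), 0.35)
  expect_true(all(qe$quantiles >= tapply(d$y, d$strategy, min)[
    names(qe$quantiles)]))
  tiny <- d[c(which(d$strategy == "no_HA")[1:30],
              which(d$strategy == "HA")[1:5]), ]
  pf_t <- fit_propensity(tiny, "w", min_rows = 2)
  expect_warning(ipw_quantile_contrast(tiny, "y", pf_t, 0.5),
                 "fewer than 20")
})

test_that("restricted cubic spline basis has the natural-spline shape", {
  kn <- c(1, 5, 9)
  x <- seq(-3, 13, by = 0.01)
  b <- rcs_basis(x, kn)
  expect_equal(ncol(b), 2L)
  expect_equal(max(abs(b[x < 1, 2])), 0)       # zero left of first knot
  f <- function(z) rcs_basis(z, kn)[, 2]
  h <- 1e-3
  for (z in c(-2, 12)) {                        # linear beyond boundaries
    d2 <- (f(z + h) - 2 * f(z) + f(z - h)) / h^2
    expect_lt(abs(d2), 1e-6)
  }
  expect_error(rcs_basis(x, c(1, 1, 2)), "increasing")
  expect_error(rcs_basis(x, c(1, 2)), "increasing|3")
})

test_that("saturated strategy-only MSM reproduces the TMLE means", {
  surv <- recovery_survivors(recovery_spec(1500, 46))
  surv$grp <- rbinom(nrow(surv), 1, 0.5)
  pf <- fit_propensity(surv, correct_propensity_terms())
  tm <- tmle_mean_contrast(surv, "ptau181_fu", c("age", "ptau181_bl"), pf)
  mm <- tmle_msm_effect_modification(surv, "ptau181_fu",
                                     c("age", "ptau181_bl"), pf, "grp",
                                     tmle = tm)
  # curves averaged over the modifier levels reproduce per-strategy means
  w0 <- mean(surv$grp == 0)
  for (l in tm$levels) {
    rows <- mm$curves$strategy == l
    implied <- sum(mm$curves$predicted[rows] * c(w0, 1 - w0))
    expect_equal(implied, unname(tm$means[l]), tolerance = 1e-8)
  }
  expect_error(tmle_msm_effect_modification(
    transform(surv, cst = 1), "ptau181_fu", "age", pf, "cst"),
    "constant")
})

test_that("MARS recovers hinge structure and respects the degree cap", {
  withr_seed(47, {
    X <- matrix(rnorm(600 * 4), 600, 4)
    y <- 1 + 2 * pmax(X[, 1] - 0.3, 0) + X[, 2] +
      1.5 * pmax(X[, 1], 0) * pmax(X[, 3] - 0.2, 0) + rnorm(600, 0, 0.3)
  })
  fit <- mars_fit(X, y)
  expect_lt(sqrt(mean((mars_predict(fit, X) - y)^2)), 0.8)
  expect_lte(max(lengths(fit$terms)), 2L)   # no term multiplies 3 hinges

  # truly linear data: MARS-TMLE agrees with GLM-TMLE
  surv <- recovery_survivors(recovery_spec(1500, 48))
  pf_glm <- fit_propensity(surv, correct_propensity_terms())
  pf_mars <- fit_propensity(surv, correct_propensity_terms(),
                            nuisance = "mars")
  cov <- c("age", "ptau181_bl")
  tm_glm <- tmle_mean_contrast(surv, "ptau181_fu", cov, pf_glm)
  tm_mars <- tmle_mean_contrast(surv, "ptau181_fu", cov, pf_mars,
                                nuisance = "mars")
  expect_true(all(pf_mars$prob > 0 & pf_mars$prob < 1))
  expect_lt(abs(tm_mars$contrasts - tm_glm$contrasts), 1)
  expect_lt(max(abs(tm_mars$score)), 1e-8)
})

test_that("MARS beats a linear fit under a threshold confounder effect", {
  withr_seed(49, {
    bias <- replicate(30, {
      n <- 500
      w <- rnorm(n)
      a <- rbinom(n, 1, plogis(1.2 * pmax(w, 0) - 0.6))
      y <- 2 * a + 3 * pmax(w - 0.2, 0) + rnorm(n, 0, 0.5)
      d <- data.frame(strategy = factor(a, levels = 0:1), w = w, y = y,
                      died_before_followup = 0)
      pf_g <- fit_propensity(d, "w")
      c(glm = unname(tmle_mean_contrast(d, "y", "w", pf_g,
          outcome_formula = ~ strategy + w)$contrasts),
        mars = unname(tmle_mean_contrast(d, "y", "w", pf_g,
          nuisance = "mars")$contrasts))
    })
  })
  expect_lt(abs(mean(bias["mars", ]) - 2),
            abs(mean(bias["glm", ]) - 2) + 0.05)
})
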