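# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no stored data.

# Small randomized two-arm dataset with a known additive effect.
make_randomized <- function(n, effect = 2, seed = 1) {
  withr_seed(seed, {
    w <- rnorm(n)
    a <- rbinom(n, 1, 0.5)
    y <- 10 + 3 * w + effect * a + rnorm(n)
    data.frame(
      strategy = factor(ifelse(a == 1, "HA", "no_HA"),
                        levels = c("no_HA", "HA")),
      w = w, y = y, died_before_followup = 0)
  })
}

# Discrete dataset (binary confounder, binary treatment) for the
# saturated g-computation oracle.
make_discrete <- function(n, seed = 1) {
  withr_seed(seed, {
    w <- rbinom(n, 1, 0.5)
    a <- rbinom(n, 1, 0.3 + 0.4 * w)
    y <- rbinom(n, 3, 0.3 + 0.1 * w + 0.2 * a)
    # ensure every (a, w) cell is populated
    if (length(unique(paste(a, w))) < 4L) return(NULL)
    data.frame(
      strategy = factor(ifelse(a == 1, "t", "c"), levels = c("c", "t")),
      w = w, y = as.numeric(y), died_before_followup = 0)
  })
}

# Saturated nonparametric g-computation on a discrete dataset.
gcomp_saturated <- function(d) {
  lev <- levels(d$strategy)
  ws <- sort(unique(d$w))
  pw <- as.numeric(table(factor(d$w, levels = ws))) / nrow(d)
  vapply(lev, function(a) {
    sum(vapply(seq_along(ws), function(i) {
      mean(d$y[d$strategy == a & d$w == ws[i]]) * pw[i]
    }, numeric(1)))
  }, numeric(1))
}

# Brute-force weighted type-1 quantile by CDF enumeration.
brute_weighted_quantile <- function(y, w, tau) {
  ys <- sort(unique(y))
  cdf <- vapply(ys, function(t) sum(w[y <= t]) / sum(w), numeric(1))
  ys[which(cdf >= tau - 1e-12)[1L]]
}

# Run code under a seed without disturbing the global RNG stream.
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Cohort spec for estimator-recovery runs: complete exposures/outcomes so
# estimator properties are tested without the imputation layer.
recovery_spec <- function(n, seed, effect = 2, ...) {
  cohort_spec(n_participants = n, seed = seed,
              true_mean_diff = c(ptau181 = effect),
              outcome_missing_rate = 0, exposure_missing_rate = 0,
              audiometry_missing_rate = 0, ...)
}

correct_propensity_terms <- function() {
  c("age", "pta_better_ear", "hearing_problem_selfreport",
    "cognition_3ms")
}

# Survivors of a recovery cohort with the trial-1 strategy column.
recovery_survivors <- function(spec) {
  co <- generate_cohort(spec)$cohort
  surv <- co[co$died_before_followup == 0, ]
  surv$strategy <- factor(ifelse(surv$ha_prescription == 1, "HA", "no_HA"),
                          levels = c("no_HA", "HA"))
  surv
}
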