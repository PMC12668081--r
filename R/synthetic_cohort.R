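# Synthetic cohort generator with known ground truth.
#
# The generator emulates the structure of an observational hearing-aid
# cohort of community-dwelling adults aged 70+: confounded treatment
# uptake, death before the follow-up blood draw, heavy missingness in
# audiometry and follow-up biomarkers, and longitudinal cognition
# auxiliaries that drive outcome missingness.  All randomness flows
# through a single seed so that identical (spec, seed) pairs produce
# byte-identical cohorts, and the same structural equations back a
# Monte-Carlo oracle for the true survivor-conditional contrasts.

#' Biomarker names used throughout the package
#'
#' pTau181, NfL and GFAP are plasma concentrations in pg/mL; the amyloid
#' ratio is (Abeta42 x 1000) / Abeta40.
#' @export
BIOMARKERS <- c("ptau181", "nfl", "gfap", "abeta_ratio")

#' Hearing-aid use frequency levels
#' @export
HA_FREQ_LEVELS <- c("never", "rare_sometimes", "often_always")

# Log-scale marginal parameters for the four plasma biomarkers, chosen to
# loosely match reported cohort quartiles (pTau181 ~37 (23, 44) pg/mL,
# NfL ~21 (15, 25), GFAP ~131 (85, 160), amyloid ratio ~62 (54, 69)).
.bm_meanlog <- c(ptau181 = log(34), nfl = log(20), gfap = log(125),
                 abeta_ratio = log(62))
.bm_sdlog <- c(ptau181 = 0.40, nfl = 0.35, gfap = 0.45, abeta_ratio = 0.17)

# Fixed log-scale correlation: neurodegeneration markers positively
# correlated with each other, negatively with the amyloid ratio.
.bm_cor <- matrix(c(
  1.00, 0.40, 0.45, -0.25,
  0.40, 1.00, 0.50, -0.15,
  0.45, 0.50, 1.00, -0.20,
  -0.25, -0.15, -0.20, 1.00), 4, 4,
  dimnames = list(BIOMARKERS, BIOMARKERS))

# Age loadings on the log-scale baseline biomarkers (per SD of age):
# neurodegeneration markers rise with age, the amyloid ratio declines.
# These make treatment (which tracks age and hearing) genuinely
# confounded with respect to the biomarker outcomes.
.bm_age_load <- c(ptau181 = 0.15, nfl = 0.25, gfap = 0.25,
                  abeta_ratio = -0.10)

# Baseline-to-follow-up drift on the log scale: follow-up log value is
# mu + drift + persistence * (baseline log - mu) + noise.
.bm_drift <- c(ptau181 = 0.22, nfl = 0.45, gfap = 0.30, abeta_ratio = -0.08)
.bm_persistence <- 0.6
.bm_resid_sdlog <- c(ptau181 = 0.28, nfl = 0.25, gfap = 0.30,
                     abeta_ratio = 0.13)

#' Specification of a synthetic cohort
#'
#' Describes the stochastic world a cohort is drawn from: size,
#' confounding, true treatment effects, death and missingness rates.
#' Treatment effects are injected additively on the natural (pg/mL or
#' ratio-unit) scale among survivors, so the configured value *is* the
#' true survivor-conditional mean difference.
#'
#' @param n_participants positive integer cohort size.
#' @param seed integer RNG seed; identical (spec, seed) pairs give
#'   byte-identical cohorts.
#' @param true_mean_diff named numeric over [BIOMARKERS]: true
#'   survivor-conditional mean difference under hearing-aid prescription
#'   (natural units).
#' @param confounding_strength nonnegative log-odds scale magnitude of the
#'   confounder effects on treatment uptake (0 = randomized).
#' @param treated_rate target marginal proportion receiving a new
#'   hearing-aid prescription.
#' @param death_rate_untreated proportion of untreated participants dying
#'   before the follow-up blood draw.
#' @param outcome_missing_rate proportion of *surviving* participants with
#'   missing follow-up biomarkers.
#' @param exposure_missing_rate proportion with missing hearing-aid
#'   prescription / frequency data.
#' @param audiometry_missing_rate proportion with missing pure-tone
#'   audiometry.
#' @param mnar_delta_sd additive shift (in SD units of the latent
#'   follow-up log outcome) on the outcome-missingness score; 0 = MAR.
#' @param frequency_split length-3 proportions over
#'   [HA_FREQ_LEVELS] among the treated; must sum to 1.
#' @param effect_by_frequency multiplier applied to `true_mean_diff` for
#'   each use-frequency level among the treated.
#' @param treatment_death_lor log odds ratio of treatment on death
#'   (0 by default so survivor conditioning induces no selection).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 2842L,
                        seed = 1L,
                        true_mean_diff = c(ptau181 = 0, nfl = 0, gfap = 0,
                                           abeta_ratio = 0),
                        confounding_strength = 0.4,
                        treated_rate = 0.26,
                        death_rate_untreated = 0.105,
                        outcome_missing_rate = 0.55,
                        exposure_missing_rate = 0.18,
                        audiometry_missing_rate = 0.91,
                        mnar_delta_sd = 0,
                        frequency_split = c(never = 0, rare_sometimes = 0.45,
                                            often_always = 0.55),
                        effect_by_frequency = c(never = 0, rare_sometimes = 1,
                                                often_always = 1),
                        treatment_death_lor = 0) {
  if (length(n_participants) != 1L || is.na(n_participants) ||
      n_participants < 1) {
    stop("n_participants must be a positive integer", call. = FALSE)
  }
  n_participants <- as.integer(n_participants)
  stopifnot(length(seed) == 1L, is.finite(seed))
  diff <- rep_len(0, 4); names(diff) <- BIOMARKERS
  diff[names(true_mean_diff)] <- true_mean_diff
  if (confounding_strength < 0) {
    stop("confounding_strength must be nonnegative", call. = FALSE)
  }
  props <- c(treated_rate = treated_rate,
             death_rate_untreated = death_rate_untreated,
             outcome_missing_rate = outcome_missing_rate,
             exposure_missing_rate = exposure_missing_rate,
             audiometry_missing_rate = audiometry_missing_rate)
  bad <- names(props)[!is.finite(props) | props < 0 | props > 1]
  if (length(bad)) {
    stop("proportion outside [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(frequency_split) != 3L ||
      abs(sum(frequency_split) - 1) > 1e-8 || any(frequency_split < 0)) {
    stop("frequency_split must be 3 nonnegative proportions summing to 1",
         call. = FALSE)
  }
  frequency_split <- stats::setNames(as.numeric(frequency_split),
                                     HA_FREQ_LEVELS)
  effect_by_frequency <- stats::setNames(as.numeric(effect_by_frequency),
                                         HA_FREQ_LEVELS)
  structure(list(
    n_participants = n_participants, seed = as.integer(seed),
    true_mean_diff = diff, confounding_strength = confounding_strength,
    treated_rate = treated_rate,
    death_rate_untreated = death_rate_untreated,
    outcome_missing_rate = outcome_missing_rate,
    exposure_missing_rate = exposure_missing_rate,
    audiometry_missing_rate = audiometry_missing_rate,
    mnar_delta_sd = mnar_delta_sd, frequency_split = frequency_split,
    effect_by_frequency = effect_by_frequency,
    treatment_death_lor = treatment_death_lor), class = "cohort_spec")
}

# Run code with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Solve the intercept b0 so that mean(plogis(b0 + lp)) == target.
calibrate_intercept <- function(lp, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(b0) mean(stats::plogis(b0 + lp)) - target,
                 interval = c(-25, 25), tol = 1e-10)$root
}

# Draw everything stochastic about n participants *except* treatment
# realisation and downstream masking -- the shared latent world that
# factual and counterfactual outcomes are both computed from.
sim_latent <- function(n, spec) {
  age <- 70 + stats::rgamma(n, shape = 2.2, scale = 2.2)
  sex <- stats::rbinom(n, 1, 0.48)
  education <- sample.int(6, n, replace = TRUE,
                          prob = c(0.14, 0.31, 0.11, 0.16, 0.09, 0.19))
  race_white <- stats::rbinom(n, 1, 0.985)
  cognition_3ms <- round(pmin(100, 100 - stats::rgamma(n, 1.8, scale = 3.5)))
  bmi <- round(stats::rnorm(n, 28, 4), 1)
  diabetes <- stats::rbinom(n, 1, 0.08)
  antihypertensive_use <- stats::rbinom(n, 1, 0.03)
  smoking <- factor(sample(c("never", "former", "current"), n, TRUE,
                           prob = c(0.55, 0.425, 0.025)),
                    levels = c("never", "former", "current"))
  sbp <- round(stats::rnorm(n, 139, 17))
  apoe_e4 <- stats::rbinom(n, 1, 0.255)
  pta <- pmax(0, round(stats::rnorm(n, 29, 10), 1))
  hearing_problem <- stats::rbinom(n, 1, stats::plogis(1.7 + 0.06 * (pta - 29)))
  prior_ha_use <- stats::rbinom(n, 1, 0.04)
  dementia_at_t0 <- stats::rbinom(n, 1, 0.02)

  # correlated log-scale baseline biomarkers with age loadings
  L <- chol(.bm_cor)
  z <- matrix(stats::rnorm(n * 4), n, 4) %*% L
  logs_bl <- sweep(sweep(z, 2, .bm_sdlog, `*`), 2, .bm_meanlog, `+`) +
    scale01(age) %o% .bm_age_load
  colnames(logs_bl) <- BIOMARKERS

  # follow-up latent log values (before treatment effect)
  logs_fu <- matrix(0, n, 4, dimnames = list(NULL, BIOMARKERS))
  for (k in BIOMARKERS) {
    logs_fu[, k] <- .bm_meanlog[k] + .bm_drift[k] +
      .bm_persistence * (logs_bl[, k] - .bm_meanlog[k]) +
      stats::rnorm(n, 0, .bm_resid_sdlog[k])
  }

  # out-of-sample 10-year dementia indicator driven by baseline biomarkers
  zb <- scale(logs_bl)
  dem_lp <- stats::qlogis(0.09) + 0.50 * zb[, "ptau181"] +
    0.35 * zb[, "nfl"] + 0.30 * zb[, "gfap"] - 0.35 * zb[, "abeta_ratio"]
  dementia_10yr <- stats::rbinom(n, 1, stats::plogis(dem_lp))

  # longitudinal cognition auxiliaries: wave 1 near baseline, wave 2 after
  # a decline that tracks age and baseline neurodegeneration
  aux_w1 <- round(pmin(100, cognition_3ms - 1 + stats::rnorm(n, 0, 3)))
  decline <- 2 + 1.5 * scale01(age) * 3 + 1.2 * zb[, "nfl"] +
    stats::rnorm(n, 0, 2.5)
  aux_w2 <- round(pmin(100, aux_w1 - pmax(0, decline)))

  # negative-control exposure: skin-cancer physical exam in the prior year,
  # mildly age-related, no effect on anything downstream
  skin_exam <- stats::rbinom(n, 1, stats::plogis(-0.3 + 0.25 * scale01(age)))

  list(age = age, sex = sex, education = education, race_white = race_white,
       cognition_3ms = cognition_3ms, bmi = bmi, diabetes = diabetes,
       antihypertensive_use = antihypertensive_use, smoking = smoking,
       sbp = sbp, apoe_e4 = apoe_e4, pta = pta,
       hearing_problem = hearing_problem, prior_ha_use = prior_ha_use,
       dementia_at_t0 = dementia_at_t0, dementia_10yr = dementia_10yr,
       logs_bl = logs_bl, logs_fu = logs_fu, aux_w1 = aux_w1,
       aux_w2 = aux_w2, skin_exam = skin_exam, zb = zb,
       u_trt = stats::runif(n), u_freq = stats::runif(n),
       u_death = stats::runif(n), u_missy = stats::runif(n),
       u_missx = stats::runif(n), u_pta = stats::runif(n),
       u_aux1 = stats::runif(n), u_aux2 = stats::runif(n))
}

scale01 <- function(x) as.numeric(scale(x))

# Treatment linear predictor (no intercept): older age, worse audiometric
# and self-rated hearing, and lower cognition all push uptake.
treatment_lp <- function(lat, spec) {
  spec$confounding_strength *
    (0.8 * scale01(lat$age) + 0.6 * scale01(lat$pta) +
     0.5 * (lat$hearing_problem - mean(lat$hearing_problem)) -
     0.4 * scale01(lat$cognition_3ms))
}

# Death-before-follow-up linear predictor, excluding treatment.
death_lp <- function(lat) {
  0.5 * scale01(lat$age) + 0.35 * lat$diabetes + 0.4 * lat$zb[, "nfl"]
}

# Frequency level for treated participants from shared uniforms.
draw_frequency <- function(u, split) {
  HA_FREQ_LEVELS[findInterval(u, cumsum(split), left.open = TRUE) + 1L]
}

# Counterfactual follow-up outcomes (natural scale) for every participant
# under a fixed assignment: treated TRUE/FALSE plus a frequency level.
counterfactual_outcomes <- function(lat, spec, treated, frequency) {
  mult <- ifelse(treated, spec$effect_by_frequency[frequency], 0)
  out <- exp(lat$logs_fu)
  for (k in BIOMARKERS) out[, k] <- out[, k] + mult * spec$true_mean_diff[k]
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a participant table from the structural model described by a
#' [cohort_spec()], applies the missingness mechanisms, and returns the
#' observable table together with a truth record holding each
#' participant's true propensity score and the analytic
#' survivor-conditional contrasts implied by the additive effect
#' injection.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `cohort` (data.frame, one row per
#'   participant; `NA` = missing), `truth` (list: `propensity`,
#'   `trial1_mean_diff`, `trial2_mean_diff`, plus the complete
#'   pre-masking outcome matrix `full_outcomes` for oracle use), and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_participants
    lat <- sim_latent(n, spec)

    lp_a <- treatment_lp(lat, spec)
    b0 <- calibrate_intercept(lp_a, spec$treated_rate)
    propensity <- stats::plogis(b0 + lp_a)
    ha_prescription <- as.integer(lat$u_trt < propensity)
    ha_frequency <- rep("never", n)
    ha_frequency[ha_prescription == 1] <-
      draw_frequency(lat$u_freq[ha_prescription == 1], spec$frequency_split)
    ha_frequency <- factor(ha_frequency, levels = HA_FREQ_LEVELS)

    lp_d <- death_lp(lat) + spec$treatment_death_lor * ha_prescription
    d0 <- calibrate_intercept(death_lp(lat)[ha_prescription == 0],
                              spec$death_rate_untreated)
    died <- as.integer(lat$u_death < stats::plogis(d0 + lp_d))

    y_fu <- counterfactual_outcomes(lat, spec, ha_prescription == 1,
                                    as.character(ha_frequency))

    # outcome missingness among survivors: worse auxiliary-cognition
    # trajectory and older age raise the odds of a missed blood draw; the
    # MNAR term shifts the score by the latent follow-up pTau level.
    zfu <- (lat$logs_fu[, "ptau181"] - mean(lat$logs_fu[, "ptau181"])) /
      stats::sd(lat$logs_fu[, "ptau181"])
    lp_m <- -0.7 * scale01(lat$aux_w2) + 0.3 * scale01(lat$age) +
      spec$mnar_delta_sd * zfu
    surv <- died == 0
    m0 <- calibrate_intercept(lp_m[surv], spec$outcome_missing_rate)
    miss_y <- surv & (lat$u_missy < stats::plogis(m0 + lp_m))

    # exposure missingness (prescription + frequency together), mildly MAR
    lp_x <- 0.3 * scale01(lat$age)
    x0 <- calibrate_intercept(lp_x, spec$exposure_missing_rate)
    miss_x <- lat$u_missx < stats::plogis(x0 + lp_x)

    miss_pta <- lat$u_pta < spec$audiometry_missing_rate
    miss_a1 <- lat$u_aux1 < 0.08
    miss_a2 <- lat$u_aux2 < 0.20

    cohort <- data.frame(
      id = seq_len(n),
      age = round(lat$age, 1), sex = lat$sex, education = lat$education,
      race_white = lat$race_white, cognition_3ms = lat$cognition_3ms,
      bmi = lat$bmi, diabetes = lat$diabetes,
      antihypertensive_use = lat$antihypertensive_use,
      smoking = lat$smoking, sbp = lat$sbp, apoe_e4 = lat$apoe_e4,
      pta_better_ear = ifelse(miss_pta, NA_real_, lat$pta),
      hearing_problem_selfreport = lat$hearing_problem,
      prior_ha_use = lat$prior_ha_use, dementia_at_t0 = lat$dementia_at_t0,
      dementia_10yr = lat$dementia_10yr,
      ptau181_bl = exp(lat$logs_bl[, "ptau181"]),
      nfl_bl = exp(lat$logs_bl[, "nfl"]),
      gfap_bl = exp(lat$logs_bl[, "gfap"]),
      abeta_ratio_bl = exp(lat$logs_bl[, "abeta_ratio"]),
      ha_prescription = ifelse(miss_x, NA_integer_, ha_prescription),
      ha_frequency = factor(ifelse(miss_x, NA_character_,
                                   as.character(ha_frequency)),
                            levels = HA_FREQ_LEVELS),
      skin_exam_negctrl = lat$skin_exam,
      died_before_followup = died,
      ptau181_fu = ifelse(surv & !miss_y, y_fu[, "ptau181"], NA_real_),
      nfl_fu = ifelse(surv & !miss_y, y_fu[, "nfl"], NA_real_),
      gfap_fu = ifelse(surv & !miss_y, y_fu[, "gfap"], NA_real_),
      abeta_ratio_fu = ifelse(surv & !miss_y, y_fu[, "abeta_ratio"],
                              NA_real_),
      aux_3ms_w1 = ifelse(miss_a1, NA_real_, lat$aux_w1),
      aux_3ms_w2 = ifelse(miss_a2, NA_real_, lat$aux_w2),
      stringsAsFactors = FALSE)

    eff <- sum(spec$frequency_split * spec$effect_by_frequency)
    truth <- list(
      propensity = propensity,
      n_treated = sum(ha_prescription),
      n_died = sum(died),
      trial1_mean_diff = eff * spec$true_mean_diff,
      trial2_mean_diff = list(
        rare_sometimes = spec$effect_by_frequency["rare_sometimes"] *
          spec$true_mean_diff,
        often_always = spec$effect_by_frequency["often_always"] *
          spec$true_mean_diff),
      full_outcomes = y_fu)

    list(cohort = cohort, truth = truth, spec = spec)
  })
}

#' Monte-Carlo ground-truth contrasts
#'
#' Draws a large auxiliary sample from the same structural model, sets
#' treatment deterministically to each strategy, and computes the true
#' survivor-conditional mean and quantile contrasts the pipeline
#' estimates, with Monte-Carlo standard errors.
#'
#' @param spec a [cohort_spec()].
#' @param n_oracle number of Monte-Carlo draws (>= 1e5).
#' @param seed oracle seed (defaults to `spec$seed + 1` so the oracle draw
#'   is independent of the generated cohort).
#' @return list with `mean_diff` and `quantile_diff` (per strategy
#'   contrast, per biomarker), `mc_se`, and the quantile levels used
#'   (0.9, or 0.1 for the amyloid ratio).
#' @export
truth_contrasts <- function(spec, n_oracle = 2e5, seed = spec$seed + 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_oracle < 1e5) stop("n_oracle must be at least 1e5", call. = FALSE)
  taus <- c(ptau181 = 0.9, nfl = 0.9, gfap = 0.9, abeta_ratio = 0.1)
  with_seed(seed, {
    lat <- sim_latent(n_oracle, spec)
    lp_d <- death_lp(lat)
    d0 <- calibrate_intercept(lp_d, spec$death_rate_untreated)

    arm_outcomes <- function(treated, frequency) {
      p_die <- stats::plogis(d0 + lp_d +
                             spec$treatment_death_lor * treated)
      surv <- lat$u_death >= p_die
      counterfactual_outcomes(lat, spec, treated,
                              rep(frequency, n_oracle))[surv, , drop = FALSE]
    }

    arms <- list(
      no_HA = arm_outcomes(FALSE, "never"),
      rare_sometimes = arm_outcomes(TRUE, "rare_sometimes"),
      often_always = arm_outcomes(TRUE, "often_always"))
    # trial-1 "HA" arm: frequency drawn from the configured split
    freq_mix <- draw_frequency(lat$u_freq, spec$frequency_split)
    p_die_t <- stats::plogis(d0 + lp_d + spec$treatment_death_lor)
    surv_t <- lat$u_death >= p_die_t
    arms$HA <- counterfactual_outcomes(lat, spec, TRUE,
                                       freq_mix)[surv_t, , drop = FALSE]

    contrast <- function(arm, ref) {
      md <- colMeans(arms[[arm]]) - colMeans(arms[[ref]])
      qd <- vapply(BIOMARKERS, function(k) {
        stats::quantile(arms[[arm]][, k], taus[k], names = FALSE) -
          stats::quantile(arms[[ref]][, k], taus[k], names = FALSE)
      }, numeric(1))
      se <- vapply(BIOMARKERS, function(k) {
        sqrt(stats::var(arms[[arm]][, k]) / nrow(arms[[arm]]) +
             stats::var(arms[[ref]][, k]) / nrow(arms[[ref]]))
      }, numeric(1))
      list(mean_diff = md, quantile_diff = qd, mc_se = se)
    }

    list(trial1 = list(HA = contrast("HA", "no_HA")),
         trial2 = list(rare_sometimes = contrast("rare_sometimes", "no_HA"),
                       often_always = contrast("often_always", "no_HA")),
         tau = taus, n_oracle = n_oracle)
  })
}

#' Write / read a cohort as CSV with a JSON sidecar
#'
#' The CSV has one row per participant with empty cells for missing
#' values; the sidecar records the generating [cohort_spec()] and the
#' truth record (minus the bulky full-outcome matrix).
#'
#' @param x result of [generate_cohort()].
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x$cohort, path, row.names = FALSE, na = "")
  sidecar <- list(spec = unclass(x$spec),
                  truth = x$truth[c("propensity", "trial1_mean_diff",
                                    "trial2_mean_diff")])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @param factors re-level `smoking` and `ha_frequency` on read.
#' @export
read_cohort <- function(path, factors = TRUE) {
  df <- utils::read.csv(path, na.strings = c("", "NA"),
                        stringsAsFactors = FALSE)
  if (factors) {
    if ("smoking" %in% names(df)) {
      df$smoking <- factor(df$smoking,
                           levels = c("never", "former", "current"))
    }
    if ("ha_frequency" %in% names(df)) {
      df$ha_frequency <- factor(df$ha_frequency, levels = HA_FREQ_LEVELS)
    }
  }
  df
}
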