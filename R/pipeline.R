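# Orchestration: run both target-trial emulations and the sensitivity
# analyses end-to-end from one configuration, producing a tidy results
# table (per-strategy targeted means, mean differences, quantile
# differences with bootstrap-MI intervals) and effect-modification
# curves.

default_adjustment_set <- function() {
  c("age", "sex", "education", "race_white", "cognition_3ms", "bmi",
    "diabetes", "antihypertensive_use", "smoking", "sbp", "apoe_e4",
    "pta_better_ear", "hearing_problem_selfreport", "risk_score")
}

#' Analysis configuration
#'
#' Every analysis constant is a named key with the headline default:
#' B = 250 bootstrap samples, M = 2 imputations per sample, quantile
#' levels 0.9 (0.1 for the amyloid ratio), NARFCS deltas in
#' {0, 0.05, 0.25}, spline knots at the 10th/50th/90th percentiles, and
#' the `sqrt(n ln n)/5` weight-truncation rule.  The `"ci"` profile is a
#' scaled-down variant (n = 800, B = 50) for desk-scale runs and the
#' test suite.
#'
#' @param cohort a [cohort_spec()] or a path to a cohort CSV (as written
#'   by [write_cohort()]).  `NULL` = synthetic cohort at the profile's
#'   default size.
#' @param trials integer subset of `c(1, 2)`.
#' @param biomarkers subset of [BIOMARKERS].
#' @param estimators subset of `c("tmle_mean", "ipw_quantile")`.
#' @param modifiers effect-modifier columns for MSM curves (run on a
#'   single full-data imputation pass, not bootstrapped).
#' @param covariates adjustment columns; the analyzed biomarker's
#'   baseline value is always appended.
#' @param delta NARFCS shift in SD units (0 = primary analysis).
#' @param mars_nuisance use MARS nuisance fits instead of GLMs.
#' @param audiometric_eligibility enforce the 30 dB HL pure-tone-average
#'   criterion (re-applied per imputation).
#' @param pta_threshold_db audiometric threshold used when active.
#' @param B,M,seed bootstrap/imputation settings.
#' @param n_cycles,pmm_donor_count chained-imputation settings.
#' @param profile `"paper"` (headline constants) or `"ci"` (scaled-down).
#' @param risk_training_n size of the synthetic out-of-sample cohort for
#'   the dementia risk score (headline scale 8329).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = NULL,
                            trials = c(1L, 2L),
                            biomarkers = BIOMARKERS,
                            estimators = c("tmle_mean", "ipw_quantile"),
                            modifiers = character(0),
                            covariates = default_adjustment_set(),
                            delta = 0,
                            mars_nuisance = FALSE,
                            audiometric_eligibility = FALSE,
                            pta_threshold_db = 30,
                            B = NULL, M = 2L, seed = 1L,
                            n_cycles = NULL, pmm_donor_count = 5L,
                            profile = c("paper", "ci"),
                            risk_training_n = NULL) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") {
    list(B = 250L, n = 2842L, n_cycles = 10L, risk_n = 8329L)
  } else {
    list(B = 50L, n = 800L, n_cycles = 5L, risk_n = 3000L)
  }
  if (is.null(B)) B <- defaults$B
  if (is.null(n_cycles)) n_cycles <- defaults$n_cycles
  if (is.null(risk_training_n)) risk_training_n <- defaults$risk_n
  if (is.null(cohort)) {
    cohort <- cohort_spec(n_participants = defaults$n, seed = seed)
  }
  stopifnot(length(trials) >= 1L, all(trials %in% 1:2),
            length(biomarkers) >= 1L, all(biomarkers %in% BIOMARKERS),
            length(estimators) >= 1L,
            all(estimators %in% c("tmle_mean", "ipw_quantile")),
            length(seed) == 1L, is.finite(seed))
  structure(list(cohort = cohort, trials = as.integer(trials),
                 biomarkers = biomarkers, estimators = estimators,
                 modifiers = modifiers, covariates = covariates,
                 delta = delta, mars_nuisance = mars_nuisance,
                 audiometric_eligibility = audiometric_eligibility,
                 pta_threshold_db = pta_threshold_db,
                 B = as.integer(B), M = as.integer(M),
                 seed = as.integer(seed), n_cycles = as.integer(n_cycles),
                 pmm_donor_count = as.integer(pmm_donor_count),
                 profile = profile,
                 risk_training_n = as.integer(risk_training_n)),
            class = "analysis_config")
}

quantile_level <- function(biomarker) {
  if (biomarker == "abeta_ratio") 0.1 else 0.9
}

resolve_cohort <- function(config) {
  if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)$cohort
  } else if (is.character(config$cohort)) {
    read_cohort(config$cohort)
  } else {
    stop("cohort must be a cohort_spec or a CSV path", call. = FALSE)
  }
}

# Synthetic out-of-sample training cohort for the dementia risk score
# (stand-in for the participants excluded from the analytic sample).
train_risk_score <- function(config) {
  spec <- cohort_spec(n_participants = config$risk_training_n,
                      seed = derive_seed(config$seed, 9901L))
  fit_dementia_risk_score(generate_cohort(spec)$cohort)
}

# Imputation spec for the standard cohort layout.
cohort_imputation_spec <- function(cohort, config, auxiliaries = NULL) {
  fu <- paste0(BIOMARKERS, "_fu")
  candidates <- intersect(
    c("pta_better_ear", "ha_prescription", "ha_frequency", fu,
      "aux_3ms_w1", "aux_3ms_w2"), names(cohort))
  vars <- candidates[vapply(candidates, function(v) anyNA(cohort[[v]]),
                            logical(1))]
  base_preds <- intersect(
    c("age", "sex", "education", "cognition_3ms", "bmi", "diabetes",
      "smoking", "sbp", "apoe_e4", "hearing_problem_selfreport",
      paste0(BIOMARKERS, "_bl"), "died_before_followup",
      if (!is.null(auxiliaries)) auxiliaries else
        c("aux_3ms_w1", "aux_3ms_w2")),
    names(cohort))
  preds <- stats::setNames(
    lapply(vars, function(v) {
      union(base_preds, setdiff(c("ha_prescription", fu), v))
    }), vars)
  # audiometry is ~91% missing: its regression rests on few observed
  # rows, so it gets a compact predictor set
  if ("pta_better_ear" %in% vars) {
    preds$pta_better_ear <- intersect(
      c("age", "sex", "cognition_3ms", "hearing_problem_selfreport",
        "ha_prescription"), names(cohort))
  }
  restrict <- list()
  for (v in intersect(fu, vars)) {
    restrict[[v]] <- function(df) df$died_before_followup == 0
  }
  if ("ha_frequency" %in% vars) {
    restrict$ha_frequency <- function(df) {
      is.na(df$ha_prescription) | df$ha_prescription == 1
    }
    # frequency model conditions on treated rows; prescription itself is
    # not a useful predictor there
    preds$ha_frequency <- setdiff(preds$ha_frequency, "ha_prescription")
  }
  post <- list()
  enforce_never <- function(df) {
    bad <- !is.na(df$ha_prescription) & df$ha_prescription == 0
    df$ha_frequency[bad] <- "never"
    df
  }
  if (all(c("ha_prescription", "ha_frequency") %in% names(cohort))) {
    post$ha_prescription <- enforce_never
    post$ha_frequency <- enforce_never
  }
  imputation_spec(variables = vars, predictors = preds,
                  pmm_donor_count = config$pmm_donor_count,
                  n_cycles = config$n_cycles, restrict = restrict,
                  post_update = post, seed = config$seed)
}

# Estimator applied to one completed dataset: eligibility, strategy
# assignment, risk score, then every requested (trial, biomarker,
# estimand) on survivors.  Returns a named vector
# "trial<k>|<biomarker>|<estimand>|<strategy>".
emulation_estimator <- function(config, criteria, risk_model,
                                dspec = NULL, exposure = NULL) {
  force(config); force(criteria); force(risk_model)
  function(imp) {
    if (inherits(imp, "imputed_dataset")) {
      if (!is.null(dspec)) imp <- apply_delta_shift(imp, dspec)
      df <- imp$data
    } else {
      df <- imp
    }
    elig <- apply_eligibility(df, criteria)$eligible
    elig$risk_score <- stats::predict(risk_model, elig)
    surv <- elig[elig$died_before_followup == 0, , drop = FALSE]
    nuis <- if (config$mars_nuisance) "mars" else "glm"
    out <- numeric(0)
    trial_frames <- if (is.null(exposure)) {
      lapply(config$trials, function(tid) {
        list(id = paste0("trial", tid),
             data = assign_strategies(surv, trial_definition(tid)))
      })
    } else {
      x <- surv[[exposure]]
      if (length(unique(x)) < 2L) {
        stop("degenerate exposure '", exposure, "'", call. = FALSE)
      }
      s <- surv
      s$strategy <- factor(ifelse(x == 1, "exposed", "unexposed"),
                           levels = c("unexposed", "exposed"))
      list(list(id = "negctrl", data = s))
    }
    for (tf in trial_frames) {
      s <- tf$data
      prop_terms <- unique(c(setdiff(config$covariates, "risk_score"),
                             "risk_score", paste0(BIOMARKERS, "_bl")))
      pf <- fit_propensity(s, prop_terms, nuisance = nuis)
      # truncation diagnostics aggregated into the results metadata
      # rather than warned per bootstrap replicate
      out[paste(tf$id, ".meta", "trunc_frac", ".", sep = "|")] <-
        pf$n_truncated / length(pf$g_trunc)
      for (bm in config$biomarkers) {
        ycol <- paste0(bm, "_fu")
        cov <- unique(c(config$covariates, paste0(bm, "_bl")))
        if ("tmle_mean" %in% config$estimators) {
          tm <- suppressWarnings(
            tmle_mean_contrast(s, ycol, cov, pf, nuisance = nuis))
          for (l in tm$levels) {
            out[paste(tf$id, bm, "mean", l, sep = "|")] <- tm$means[l]
          }
          for (l in names(tm$contrasts)) {
            out[paste(tf$id, bm, "mean_diff", l, sep = "|")] <-
              tm$contrasts[l]
          }
        }
        if ("ipw_quantile" %in% config$estimators) {
          tau <- quantile_level(bm)
          qe <- suppressWarnings(
            ipw_quantile_contrast(s, ycol, pf, tau))
          for (l in names(qe$quantiles)) {
            out[paste(tf$id, bm, "quantile", l, sep = "|")] <-
              qe$quantiles[l]
          }
          for (l in names(qe$contrasts)) {
            out[paste(tf$id, bm, "quantile_diff", l, sep = "|")] <-
              qe$contrasts[l]
          }
        }
      }
    }
    out
  }
}

results_table <- function(boot) {
  parts <- strsplit(names(boot$point), "|", fixed = TRUE)
  meta_rows <- vapply(parts, `[[`, character(1), 2L) == ".meta"
  meta <- data.frame(
    trial = vapply(parts[meta_rows], `[[`, character(1), 1L),
    quantity = vapply(parts[meta_rows], `[[`, character(1), 3L),
    value = unname(boot$point[meta_rows]))
  parts <- parts[!meta_rows]
  boot$point <- boot$point[!meta_rows]
  boot$ci <- boot$ci[!meta_rows, , drop = FALSE]
  df <- data.frame(
    trial = vapply(parts, `[[`, character(1), 1L),
    biomarker = vapply(parts, `[[`, character(1), 2L),
    estimand = vapply(parts, `[[`, character(1), 3L),
    strategy = vapply(parts, `[[`, character(1), 4L),
    point = unname(boot$point),
    ci_low = unname(boot$ci[, "lower"]),
    ci_high = unname(boot$ci[, "upper"]),
    stringsAsFactors = FALSE)
  df$excludes_zero <- df$ci_low > 0 | df$ci_high < 0
  df$excludes_zero[!grepl("_diff$", df$estimand)] <- NA
  df$n_failed_replicates <- boot$n_failed
  attr(df, "metadata") <- meta
  df
}

#' Run a full target-trial emulation
#'
#' Generates or loads the cohort, trains the out-of-sample dementia risk
#' score, screens eligibility (rows with missing criterion variables are
#' retained and re-screened after each imputation), and runs
#' bootstrap-then-MI over the whole estimation pipeline: chained-PMM
#' imputation, strategy assignment, propensity fitting with adaptive
#' truncation, TMLE mean contrasts and IPW quantile contrasts per
#' (trial, biomarker).  Optional NARFCS delta shift and MARS nuisance
#' fits per the configuration.
#'
#' @param config an [analysis_config()].
#' @param cache optional environment; imputations keyed by replicate
#'   seed are stored there so that sensitivity analyses re-use the
#'   primary analysis's imputed datasets.
#' @return list of class `emulation_result`: `results` (tidy table),
#'   `boot` ([bootstrap_mi()] output), `curves` (effect-modification
#'   data.frame or NULL), `log` (character), `config`.
#' @export
run_emulation <- function(config, cache = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  log <- c(sprintf("profile=%s seed=%d B=%d M=%d", config$profile,
                   config$seed, config$B, config$M))
  cohort <- resolve_cohort(config)
  risk_model <- train_risk_score(config)
  criteria <- eligibility_criteria(
    pta_threshold_db = if (config$audiometric_eligibility) {
      config$pta_threshold_db
    } else NULL)
  base <- apply_eligibility(cohort, criteria)
  log <- c(log, sprintf("base eligibility: %d retained, %d excluded (%s)",
                        nrow(base$eligible), base$n_excluded,
                        paste(names(base$tally), base$tally, sep = "=",
                              collapse = ", ")))
  data <- base$eligible
  ispec <- cohort_imputation_spec(data, config)
  dspec <- if (config$delta > 0) delta_spec(config$delta) else NULL
  impute_fn <- make_impute_fn(ispec, cache)
  est <- emulation_estimator(config, criteria, risk_model, dspec)
  boot <- bootstrap_mi(data, est, impute_fn = impute_fn, B = config$B,
                       M = config$M, seed = config$seed)
  log <- c(log, sprintf("bootstrap-MI: %d/%d replicates failed",
                        boot$n_failed, config$B))

  curves <- NULL
  if (length(config$modifiers)) {
    curves <- effect_modification_curves(data, config, criteria,
                                         risk_model, ispec)
  }
  structure(list(results = results_table(boot), boot = boot,
                 curves = curves, log = log, config = config),
            class = "emulation_result")
}

make_impute_fn <- function(ispec, cache = NULL) {
  force(ispec)
  function(data, m, seed) {
    key <- as.character(seed)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    sp <- ispec
    sp$seed <- seed
    sp$variables <- intersect(
      if (is.null(sp$variables)) names(data) else sp$variables,
      names(data)[vapply(data, anyNA, logical(1))])
    out <- chained_pmm_impute(data, sp, m = m)
    if (!is.null(cache)) cache[[key]] <- out
    out
  }
}

# Effect-modification curves from a single full-data imputation pass
# (averaged over the M imputations; bootstrap ribbons are out of the
# default profile's budget and left NA).
effect_modification_curves <- function(data, config, criteria, risk_model,
                                       ispec) {
  imps <- chained_pmm_impute(data, ispec, m = config$M)
  nuis <- if (config$mars_nuisance) "mars" else "glm"
  all_curves <- list()
  for (imp in imps) {
    elig <- apply_eligibility(imp$data, criteria)$eligible
    elig$risk_score <- stats::predict(risk_model, elig)
    surv <- elig[elig$died_before_followup == 0, , drop = FALSE]
    for (tid in config$trials) {
      s <- assign_strategies(surv, trial_definition(tid))
      prop_terms <- unique(c(setdiff(config$covariates, "risk_score"),
                             "risk_score", paste0(BIOMARKERS, "_bl")))
      pf <- fit_propensity(s, prop_terms, nuisance = nuis)
      for (bm in config$biomarkers) {
        ycol <- paste0(bm, "_fu")
        cov <- unique(c(config$covariates, paste0(bm, "_bl")))
        for (mod in config$modifiers) {
          mm <- tmle_msm_effect_modification(s, ycol, cov, pf, mod,
                                             nuisance = nuis)
          cv <- mm$curves
          cv$trial <- paste0("trial", tid)
          cv$biomarker <- bm
          cv$effect_modifier <- mod
          cv$m <- imp$m
          all_curves[[length(all_curves) + 1L]] <- cv
        }
      }
    }
  }
  cv <- do.call(rbind, all_curves)
  agg <- stats::aggregate(predicted ~ modifier + strategy + trial +
                            biomarker + effect_modifier, data = cv, mean)
  agg$ci_low <- NA_real_
  agg$ci_high <- NA_real_
  agg
}

#' Negative treatment control analysis
#'
#' Re-runs the pipeline with the skin-cancer physical exam (an exposure
#' with no plausible effect on the biomarkers) in place of hearing-aid
#' treatment.  Contrasts whose interval excludes zero are flagged: an
#' elevated rate of such flags indicates residual confounding, e.g.
#' through healthcare utilisation.
#'
#' @inheritParams run_emulation
#' @param exposure negative-control column name.
#' @return `emulation_result` whose results table carries the
#'   `excludes_zero` flags.
#' @export
run_negative_control <- function(config, cache = NULL,
                                 exposure = "skin_exam_negctrl") {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- resolve_cohort(config)
  if (is.null(cohort[[exposure]])) {
    stop("negative-control column '", exposure, "' not present",
         call. = FALSE)
  }
  if (length(unique(cohort[[exposure]])) < 2L) {
    stop("degenerate exposure '", exposure,
         "': column is constant", call. = FALSE)
  }
  risk_model <- train_risk_score(config)
  criteria <- eligibility_criteria()
  data <- apply_eligibility(cohort, criteria)$eligible
  ispec <- cohort_imputation_spec(data, config)
  est <- emulation_estimator(config, criteria, risk_model,
                             exposure = exposure)
  boot <- bootstrap_mi(data, est, impute_fn = make_impute_fn(ispec, cache),
                       B = config$B, M = config$M, seed = config$seed)
  structure(list(results = results_table(boot), boot = boot,
                 curves = NULL,
                 log = sprintf("negative control exposure=%s", exposure),
                 config = config),
            class = "emulation_result")
}

#' Audiometric-eligibility sensitivity analysis
#'
#' Re-runs the emulation with the better-ear pure-tone-average criterion
#' (default 30 dB HL) enforced, resolved within each imputed dataset
#' (audiometry is mostly missing and multiply imputed).
#'
#' @inheritParams run_emulation
#' @return `emulation_result`.
#' @export
run_audiometric_eligibility <- function(config, cache = NULL) {
  config$audiometric_eligibility <- TRUE
  run_emulation(config, cache = cache)
}
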