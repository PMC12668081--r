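# Target-trial protocol: eligibility screening, strategy assignment and
# the out-of-sample biomarker dementia risk score.

#' Eligibility criteria for the emulated trials
#'
#' Defaults encode the primary emulation: aged 70+, global cognition
#' (3MS) strictly above 77, self-reported hearing problems, no past
#' hearing-aid use, dementia-free at time zero.  `pta_threshold_db`
#' activates the audiometric criterion (better-ear 4-frequency pure tone
#' average at or above the threshold) used in sensitivity analysis.
#'
#' @param min_age minimum age in years (inclusive).
#' @param min_3ms 3MS threshold; retention requires score strictly above.
#' @param require_hearing_problem require self-reported hearing problems.
#' @param exclude_prior_ha exclude participants with past hearing-aid use.
#' @param pta_threshold_db optional dB HL threshold (`NULL` = inactive).
#' @param require_dementia_free_at_t0 exclude dementia at time zero.
#' @return object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(min_age = 70,
                                 min_3ms = 77,
                                 require_hearing_problem = TRUE,
                                 exclude_prior_ha = TRUE,
                                 pta_threshold_db = NULL,
                                 require_dementia_free_at_t0 = TRUE) {
  stopifnot(is.finite(min_age), is.finite(min_3ms),
            is.null(pta_threshold_db) || is.finite(pta_threshold_db))
  structure(list(min_age = min_age, min_3ms = min_3ms,
                 require_hearing_problem = require_hearing_problem,
                 exclude_prior_ha = exclude_prior_ha,
                 pta_threshold_db = pta_threshold_db,
                 require_dementia_free_at_t0 = require_dementia_free_at_t0),
            class = "eligibility_criteria")
}

#' Apply eligibility criteria
#'
#' Screens a cohort against [eligibility_criteria()].  A row is removed
#' only when a criterion variable is observed *and* violates the
#' criterion; rows with a missing criterion variable are retained and
#' flagged in `pending_eligibility` so the criteria can be re-applied
#' after imputation.  Criteria are applied in a fixed order (age, 3MS,
#' hearing problem, prior hearing-aid use, dementia at time zero,
#' optional audiometry) and the exclusion tally attributes each removed
#' row to the first criterion it fails.
#'
#' @param cohort data.frame of participants.
#' @param criteria an [eligibility_criteria()].
#' @return list: `eligible` (retained rows, with a logical
#'   `pending_eligibility` column), `tally` (named integer vector of
#'   exclusions per criterion), `n_excluded`.
#' @export
apply_eligibility <- function(cohort, criteria = eligibility_criteria()) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  need <- c("age", "cognition_3ms")
  if (criteria$require_hearing_problem) {
    need <- c(need, "hearing_problem_selfreport")
  }
  if (criteria$exclude_prior_ha) need <- c(need, "prior_ha_use")
  if (criteria$require_dementia_free_at_t0) need <- c(need, "dementia_at_t0")
  if (!is.null(criteria$pta_threshold_db)) need <- c(need, "pta_better_ear")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  checks <- list(
    age = cohort$age >= criteria$min_age,
    `3ms` = cohort$cognition_3ms > criteria$min_3ms)
  if (criteria$require_hearing_problem) {
    checks$hearing <- cohort$hearing_problem_selfreport == 1
  }
  if (criteria$exclude_prior_ha) {
    checks$prior_ha <- cohort$prior_ha_use == 0
  }
  if (criteria$require_dementia_free_at_t0) {
    checks$dementia_t0 <- cohort$dementia_at_t0 == 0
  }
  if (!is.null(criteria$pta_threshold_db)) {
    checks$pta <- cohort$pta_better_ear >= criteria$pta_threshold_db
  }

  n <- nrow(cohort)
  excluded_by <- rep(NA_character_, n)
  pending <- rep(FALSE, n)
  for (nm in names(checks)) {
    chk <- checks[[nm]]
    hit <- is.na(excluded_by) & !is.na(chk) & !chk
    excluded_by[hit] <- nm
    pending <- pending | (is.na(excluded_by) & is.na(chk))
  }
  keep <- is.na(excluded_by)
  tally <- vapply(names(checks),
                  function(nm) sum(excluded_by == nm, na.rm = TRUE),
                  integer(1))
  eligible <- cohort[keep, , drop = FALSE]
  eligible$pending_eligibility <- pending[keep]
  list(eligible = eligible, tally = tally, n_excluded = sum(!keep))
}

#' Write an eligibility exclusion tally as JSON
#'
#' @param screened result of [apply_eligibility()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_tally <- function(screened, path) {
  jsonlite::write_json(list(tally = as.list(screened$tally),
                            n_excluded = screened$n_excluded,
                            n_eligible = nrow(screened$eligible)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Definition of an emulated target trial
#'
#' Trial 1 contrasts hearing-aid prescription vs none; trial 2 contrasts
#' initiation of each frequency of hearing-aid use against never using
#' them.  The reference strategy is always the first label.
#'
#' @param trial_id 1 or 2.
#' @return object of class `trial_definition` with `strategy_labels` and
#'   `reference_strategy`.
#' @export
trial_definition <- function(trial_id) {
  trial_id <- as.integer(trial_id)
  if (!trial_id %in% 1:2) stop("trial_id must be 1 or 2", call. = FALSE)
  labels <- if (trial_id == 1L) c("no_HA", "HA") else HA_FREQ_LEVELS
  structure(list(trial_id = trial_id, strategy_labels = labels,
                 reference_strategy = labels[1L]),
            class = "trial_definition")
}

#' Assign participants to treatment strategies
#'
#' Trial 1: `HA` iff `ha_prescription == 1`.  Trial 2: `never` for
#' participants with no prescription or who report never using their
#' hearing aids; otherwise the reported frequency level.  Assignment is a
#' total function of (prescription, frequency); inputs are expected to be
#' complete (post-imputation).
#'
#' @param cohort data.frame with `ha_prescription` (and, for trial 2,
#'   `ha_frequency`).
#' @param trial a [trial_definition()].
#' @return `cohort` with a `strategy` factor column (levels =
#'   `trial$strategy_labels`).
#' @export
assign_strategies <- function(cohort, trial) {
  stopifnot(inherits(trial, "trial_definition"))
  rx <- cohort$ha_prescription
  if (is.null(rx)) stop("ha_prescription column required", call. = FALSE)
  if (anyNA(rx)) stop("ha_prescription has missing values; impute first",
                      call. = FALSE)
  if (trial$trial_id == 1L) {
    strategy <- ifelse(rx == 1, "HA", "no_HA")
  } else {
    freq <- as.character(cohort$ha_frequency)
    if (is.null(cohort$ha_frequency)) {
      stop("ha_frequency column required for trial 2", call. = FALSE)
    }
    if (anyNA(freq[rx == 1])) {
      stop("ha_frequency missing among prescribed; impute first",
           call. = FALSE)
    }
    known <- freq[rx == 1]
    if (!all(known %in% HA_FREQ_LEVELS)) {
      stop("unknown ha_frequency level: ",
           paste(unique(setdiff(known, HA_FREQ_LEVELS)), collapse = ", "),
           call. = FALSE)
    }
    strategy <- ifelse(rx == 0 | freq == "never", "never", freq)
  }
  cohort$strategy <- factor(strategy, levels = trial$strategy_labels)
  cohort
}

#' Fit the biomarker-based dementia risk score
#'
#' Logistic regression of a 10-year dementia indicator on the four
#' standardized log-scale baseline biomarkers, fitted on an out-of-sample
#' cohort (participants not eligible for the analysis sample).  Large
#' scores indicate high-risk baseline biomarker profiles.  The
#' standardization constants are stored in the model so that predictions
#' are invariant to affine rescaling of the biomarker units.
#'
#' @param training data.frame with `dementia_10yr` and the four baseline
#'   biomarker columns (`ptau181_bl`, `nfl_bl`, `gfap_bl`,
#'   `abeta_ratio_bl`).
#' @return object of class `risk_score_model`.
#' @export
fit_dementia_risk_score <- function(training) {
  y <- training$dementia_10yr
  if (is.null(y)) stop("dementia_10yr column required", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("dementia outcome is constant; risk model inestimable",
         call. = FALSE)
  }
  logs <- log(as.matrix(training[, paste0(BIOMARKERS, "_bl")]))
  colnames(logs) <- BIOMARKERS
  ctr <- colMeans(logs)
  scl <- apply(logs, 2, stats::sd)
  z <- sweep(sweep(logs, 2, ctr, `-`), 2, scl, `/`)
  fit <- stats::glm.fit(cbind(1, z), y,
                        family = stats::binomial())
  structure(list(coef = stats::setNames(fit$coefficients,
                                        c("(Intercept)", BIOMARKERS)),
                 center = ctr, scale = scl, training_n = length(y),
                 link = "logistic"),
            class = "risk_score_model")
}

#' Predict dementia risk scores
#'
#' @param object a `risk_score_model`.
#' @param newdata data.frame with the four `_bl` biomarker columns.
#' @param ... unused.
#' @return numeric vector of risks in (0, 1).
#' @export
predict.risk_score_model <- function(object, newdata, ...) {
  logs <- log(as.matrix(newdata[, paste0(BIOMARKERS, "_bl")]))
  z <- sweep(sweep(logs, 2, object$center, `-`), 2, object$scale, `/`)
  as.numeric(stats::plogis(cbind(1, z) %*% object$coef))
}
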