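# Multiple imputation by chained predictive mean matching (PMM), with
# LASSO-selected auxiliary terms, passive imputation of derived terms,
# and post-hoc delta adjustment of imputed outcomes for MNAR sensitivity
# analysis.

derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 2654435 + i * 40503) %% 2147483647)
}

#' Specification of the chained imputation models
#'
#' @param variables columns to impute; default (`NULL`) = every column
#'   with missing values.
#' @param predictors named list mapping an imputed variable to its
#'   predictor columns; unlisted variables use `default_predictors`.
#' @param default_predictors predictor columns for variables without an
#'   entry in `predictors`; default (`NULL`) = all other modelled
#'   variables.
#' @param pmm_donor_count donors per missing cell (uniform draw among the
#'   nearest-predicted).
#' @param n_cycles chained-equation cycles.
#' @param passive_terms named list of `function(data)` recomputed after
#'   every variable update (derived quadratic / product columns).
#' @param restrict named list mapping a variable to a `function(data)`
#'   returning the logical rows where the variable is defined at all;
#'   rows outside it are structural missing and never imputed (e.g.
#'   follow-up biomarkers among the dead).
#' @param post_update named list of `function(data)` applied after the
#'   named variable is updated, for structural consistency rules (e.g.
#'   hearing-aid frequency forced to "never" without a prescription).
#' @param seed integer seed; (spec, seed, m) fixed implies identical
#'   imputations.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(variables = NULL, predictors = list(),
                            default_predictors = NULL,
                            pmm_donor_count = 5L, n_cycles = 10L,
                            passive_terms = list(), restrict = list(),
                            post_update = list(), seed = 1L) {
  stopifnot(pmm_donor_count >= 1, n_cycles >= 1)
  structure(list(variables = variables, predictors = predictors,
                 default_predictors = default_predictors,
                 pmm_donor_count = as.integer(pmm_donor_count),
                 n_cycles = as.integer(n_cycles),
                 passive_terms = passive_terms, restrict = restrict,
                 post_update = post_update, seed = as.integer(seed)),
            class = "imputation_spec")
}

# Numeric design matrix (with intercept) for the given predictor columns.
# Factors expand to treatment-coded dummies; any residual NA (structural
# missingness in a predictor) is mean-filled for the regression only.
impute_design <- function(data, vars) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (v in vars) {
    x <- data[[v]]
    if (is.factor(x)) {
      lv <- levels(x)
      for (l in lv[-1]) cols[[paste0(v, l)]] <- as.numeric(x == l)
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X
}

# Drop collinear columns via rank-revealing QR; constant columns (other
# than the intercept) are design artefacts of subsetting and go quietly,
# genuine collinearity gets a logged warning.
drop_collinear <- function(X, context) {
  if (ncol(X) > 1L) {
    const <- c(FALSE, apply(X[, -1L, drop = FALSE], 2,
                            function(v) all(v == v[1L])))
    X <- X[, !const, drop = FALSE]
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping collinear predictor(s) for ", context, ": ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# One Bayesian-draw PMM update: regress observed y on X, draw
# (sigma, beta) from the posterior, and for each missing row copy the
# observed value of one of the `donors` nearest-predicted donors.
pmm_draw <- function(y_obs, X_obs, X_mis, donors) {
  qr_x <- qr(X_obs)
  beta_hat <- qr.coef(qr_x, y_obs)
  beta_hat[is.na(beta_hat)] <- 0
  res <- y_obs - drop(X_obs %*% beta_hat)
  df <- max(length(y_obs) - qr_x$rank, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qr_x)[seq_len(qr_x$rank), seq_len(qr_x$rank), drop = FALSE]
  piv <- qr_x$pivot[seq_len(qr_x$rank)]
  beta_draw <- beta_hat
  pert <- backsolve(R, stats::rnorm(qr_x$rank)) * sqrt(sigma2)
  beta_draw[piv] <- beta_draw[piv] + pert
  yhat_obs <- drop(X_obs %*% beta_hat)     # type-1 matching: obs by
  yhat_mis <- drop(X_mis %*% beta_draw)    # beta-hat, mis by beta-draw
  ord <- order(yhat_obs)
  sorted <- yhat_obs[ord]
  n_obs <- length(sorted)
  k <- min(donors, n_obs)
  # the k nearest-predicted donors form a contiguous block of the sorted
  # predictions; pick the block minimizing its worst end-distance, then a
  # uniform donor within it
  pos <- findInterval(yhat_mis, sorted)
  n_mis <- length(yhat_mis)
  s_min <- pmax(1L, pos - k + 1L)
  s_max <- pmin(pmax(pos + 1L, 1L), n_obs - k + 1L)
  s_min <- pmin(s_min, s_max)
  best_s <- s_min
  best_score <- rep(Inf, n_mis)
  for (off in 0:k) {
    s <- s_min + off
    valid <- s <= s_max
    dl <- abs(yhat_mis - sorted[pmin(pmax(s, 1L), n_obs)])
    dr <- abs(sorted[pmin(s + k - 1L, n_obs)] - yhat_mis)
    sc <- pmax(dl, dr)
    sc[!valid] <- Inf
    upd <- sc < best_score
    best_s[upd] <- s[upd]
    best_score[upd] <- sc[upd]
  }
  pick <- best_s + floor(stats::runif(n_mis) * k)
  y_obs[ord[pick]]
}

#' Multiple imputation by chained predictive mean matching
#'
#' Iterates over the incomplete variables in ascending order of
#' missingness (ties alphabetical): each is regressed on its predictor
#' set over the currently-completed data, a posterior parameter draw
#' produces predictions for the missing cells, and each missing cell
#' copies the observed value of a uniformly drawn donor among the
#' `pmm_donor_count` nearest-predicted observed cells.  Passive terms are
#' recomputed after every variable update.  Imputed values therefore
#' always lie in the observed support, and observed cells are returned
#' bit-identical.
#'
#' @param data incomplete data.frame.
#' @param spec an [imputation_spec()].
#' @param m number of imputations.
#' @return list of `m` objects of class `imputed_dataset`, each with
#'   `$data` (completed data.frame), `$flags` (logical matrix, TRUE where
#'   a cell was imputed), `$m`, `$b` (NA here; set by [bootstrap_mi()]).
#' @export
chained_pmm_impute <- function(data, spec = imputation_spec(), m = 1L) {
  stopifnot(inherits(spec, "imputation_spec"), m >= 1)
  vars <- spec$variables
  if (is.null(vars)) vars <- names(data)[vapply(data, anyNA, logical(1))]
  if (!length(vars)) {
    return(lapply(seq_len(m), function(i) {
      structure(list(data = data,
                     flags = matrix(FALSE, nrow(data), 0,
                                    dimnames = list(NULL, character(0))),
                     b = NA_integer_, m = i), class = "imputed_dataset")
    }))
  }

  restrict_rows <- lapply(vars, function(v) {
    f <- spec$restrict[[v]]
    if (is.null(f)) rep(TRUE, nrow(data)) else f(data)
  })
  names(restrict_rows) <- vars
  flags <- vapply(vars, function(v) is.na(data[[v]]) & restrict_rows[[v]],
                  logical(nrow(data)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = nrow(data),
                                           dimnames = list(NULL, vars))
  for (v in vars) {
    n_obs <- sum(!is.na(data[[v]][restrict_rows[[v]]]))
    if (n_obs == 0L) {
      stop("variable '", v, "' has no observed values", call. = FALSE)
    }
  }

  # visit order: ascending missingness fraction, ties alphabetical
  frac <- colMeans(flags)[vars]
  visit <- vars[order(frac, vars)]

  preds <- lapply(visit, function(v) {
    p <- spec$predictors[[v]]
    if (is.null(p)) p <- spec$default_predictors
    if (is.null(p)) p <- setdiff(vars, v)
    setdiff(p, v)
  })
  names(preds) <- visit

  run_passive <- function(df) {
    for (nm in names(spec$passive_terms)) {
      df[[nm]] <- spec$passive_terms[[nm]](df)
    }
    df
  }

  impute_once <- function(i) {
    seen_warn <- character(0)
    withCallingHandlers(
    with_seed(derive_seed(spec$seed, i), {
      df <- data
      # initial fill: random draws from the observed values
      for (v in visit) {
        mis <- flags[, v]
        obs_vals <- df[[v]][restrict_rows[[v]] & !is.na(df[[v]])]
        if (any(mis)) {
          df[[v]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
        }
        pu <- spec$post_update[[v]]
        if (!is.null(pu)) df <- pu(df)
      }
      df <- run_passive(df)
      for (cycle in seq_len(spec$n_cycles)) {
        for (v in visit) {
          mis <- flags[, v]
          if (!any(mis)) next
          rows <- restrict_rows[[v]]
          obs <- rows & !mis
          X <- impute_design(df, preds[[v]])
          X_obs <- drop_collinear(X[obs, , drop = FALSE], v)
          X_mis <- X[mis, colnames(X_obs), drop = FALSE]
          y <- df[[v]]
          if (is.factor(y)) {
            codes <- as.integer(y)
            imp <- pmm_draw(codes[obs], X_obs, X_mis, spec$pmm_donor_count)
            df[[v]][mis] <- levels(y)[imp]
          } else {
            imp <- pmm_draw(as.numeric(y[obs]), X_obs, X_mis,
                            spec$pmm_donor_count)
            df[[v]][mis] <- imp
          }
          pu <- spec$post_update[[v]]
          if (!is.null(pu)) df <- pu(df)
          df <- run_passive(df)
        }
      }
      structure(list(data = df, flags = flags, b = NA_integer_, m = i),
                class = "imputed_dataset")
    }),
    warning = function(w) {
      # rank-deficiency messages repeat across cycles; warn once
      msg <- conditionMessage(w)
      if (msg %in% seen_warn) {
        invokeRestart("muffleWarning")
      } else {
        seen_warn <<- c(seen_warn, msg)
      }
    })
  }
  lapply(seq_len(m), impute_once)
}

#' LASSO selection of auxiliary imputation terms
#'
#' Builds the candidate term set (linear, quadratic and pairwise product
#' terms of the candidate variables), mean-imputes it for selection only,
#' and retains the terms with nonzero coefficients in a cross-validated
#' LASSO of the outcome.  Forced terms (treatment-by-effect-modifier
#' products) are always included regardless of their LASSO coefficient.
#' Cross-validation folds are fixed by the seed, so selection is
#' deterministic.
#'
#' @param data data.frame.
#' @param candidates candidate auxiliary column names (numeric).
#' @param outcome outcome column name (rows with observed outcome are the
#'   selection sample).
#' @param forced character vector of term labels always retained.
#' @param seed fold seed.
#' @param quadratic,products include derived candidate terms.
#' @return character vector of selected term labels (`x`, `I(x^2)`,
#'   `x1:x2`), forced terms first.
#' @export
select_auxiliaries <- function(data, candidates, outcome,
                               forced = character(), seed = 1L,
                               quadratic = TRUE, products = TRUE) {
  y <- data[[outcome]]
  use <- !is.na(y)
  if (sum(use) < 10L) {
    stop("fewer than 10 complete rows for auxiliary selection",
         call. = FALSE)
  }
  cols <- list()
  for (v in candidates) cols[[v]] <- as.numeric(data[[v]])
  if (quadratic) {
    for (v in candidates) cols[[paste0("I(", v, "^2)")]] <-
        as.numeric(data[[v]])^2
  }
  if (products && length(candidates) > 1L) {
    cmb <- utils::combn(candidates, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      cols[[paste0(a, ":", b)]] <- as.numeric(data[[a]]) *
        as.numeric(data[[b]])
    }
  }
  X <- do.call(cbind, cols)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  Xu <- X[use, , drop = FALSE]
  yu <- y[use]
  foldid <- with_seed(seed, sample(rep_len(1:10, length(yu))))
  cv <- glmnet::cv.glmnet(Xu, yu, foldid = foldid, family = "gaussian")
  # the 1-SE rule: parsimonious cross-validated penalty, so that
  # null candidates are reliably excluded
  b <- stats::coef(cv, s = "lambda.1se")
  sel <- rownames(b)[as.numeric(b) != 0]
  sel <- setdiff(sel, "(Intercept)")
  union(forced, sel)
}

#' Write an imputed dataset (and its flags) as CSV
#'
#' Completed data go to `imp_b<b>_m<m>.csv`; the parallel boolean
#' imputation-flag matrix goes to `imp_b<b>_m<m>_flags.csv`.
#'
#' @param imputed an `imputed_dataset`.
#' @param dir output directory (created if needed).
#' @return the data CSV path, invisibly.
#' @export
write_imputed <- function(imputed, dir) {
  stopifnot(inherits(imputed, "imputed_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- if (is.na(imputed$b)) 0L else imputed$b
  stem <- sprintf("imp_b%d_m%d", b, imputed$m)
  path <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(imputed$data, path, row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(imputed$flags),
                   file.path(dir, paste0(stem, "_flags.csv")),
                   row.names = FALSE)
  invisible(path)
}

#' NARFCS delta-adjustment specification
#'
#' A sensitivity shift applied to *imputed* follow-up biomarker values of
#' participants lost to follow-up: positive for pTau181, NfL and GFAP,
#' negative for the amyloid ratio (where lower values indicate worse
#' pathology).  `delta` is in units of the observed-data standard
#' deviation of each follow-up biomarker.
#'
#' @param delta nonnegative shift in SD units (the primary analyses use
#'   0, 0.05 and 0.25).
#' @param sign named shift sign per biomarker.
#' @return object of class `delta_spec`.
#' @export
delta_spec <- function(delta = 0,
                       sign = c(ptau181 = 1, nfl = 1, gfap = 1,
                                abeta_ratio = -1)) {
  stopifnot(delta >= 0, all(BIOMARKERS %in% names(sign)))
  structure(list(delta = delta, sign = sign[BIOMARKERS]),
            class = "delta_spec")
}

#' Apply a NARFCS delta shift to an imputed dataset
#'
#' Each follow-up biomarker cell that was (i) imputed and (ii) belongs to
#' a participant lost to follow-up (alive but with an unobserved blood
#' draw) is incremented by `sign * delta * SD`, where SD is the standard
#' deviation of the *observed* follow-up values of that biomarker.
#' Observed cells are untouched; `delta = 0` is the identity.
#'
#' @param imputed an `imputed_dataset` from [chained_pmm_impute()].
#' @param delta a [delta_spec()].
#' @return the shifted `imputed_dataset`.
#' @export
apply_delta_shift <- function(imputed, delta) {
  stopifnot(inherits(delta, "delta_spec"))
  if (!inherits(imputed, "imputed_dataset") || is.null(imputed$flags)) {
    stop("delta shift requires an imputed_dataset with imputation flags",
         call. = FALSE)
  }
  if (delta$delta == 0) return(imputed)
  df <- imputed$data
  alive <- df$died_before_followup == 0
  for (k in BIOMARKERS) {
    col <- paste0(k, "_fu")
    if (!col %in% colnames(imputed$flags)) next
    imp_cells <- imputed$flags[, col] & alive
    obs_sd <- stats::sd(df[[col]][!imputed$flags[, col] & alive],
                        na.rm = TRUE)
    df[[col]][imp_cells] <- df[[col]][imp_cells] +
      delta$sign[k] * delta$delta * obs_sd
  }
  imputed$data <- df
  imputed
}
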