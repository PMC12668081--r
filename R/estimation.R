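# Causal estimators: TMLE for survivor-conditional mean contrasts,
# adaptive propensity truncation, inverse-probability-weighted quantile
# contrasts, and MSM projection for effect modification.

#' Adaptive truncation bound for inverse-probability weights
#'
#' Returns `sqrt(n * ln(n)) / 5`, the sample-size-adaptive upper bound
#' applied to inverse-probability weights (equivalently, propensity
#' scores are floored at its reciprocal).  At n = 2842 the bound is about
#' 30.1, so it cannot bound probabilities directly and is read as a
#' weight bound.
#'
#' @param n sample size (>= 2).
#' @return positive scalar bound.
#' @export
truncation_bound <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2) {
    stop("n must be a single number >= 2", call. = FALSE)
  }
  sqrt(n * log(n)) / 5
}

# Newton-Raphson multinomial logistic regression (reference = first
# level).  Small K and p, so the full (K-1)p square Hessian is fine.
mlogit_fit <- function(X, y, maxit = 100L, tol = 1e-10) {
  lev <- levels(y)
  K <- length(lev)
  p <- ncol(X)
  Y <- vapply(lev[-1], function(l) as.numeric(y == l), numeric(nrow(X)))
  # standardize columns (except intercept) for Newton conditioning
  ctr <- colMeans(X); ctr[1] <- 0
  scl <- apply(X, 2, stats::sd); scl[1] <- 1; scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr, `-`), 2, scl, `/`)
  X <- Xs
  B <- matrix(0, p, K - 1L)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- X %*% B
    den <- 1 + rowSums(exp(eta))
    P <- exp(eta) / den
    grad <- as.numeric(crossprod(X, Y - P))
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (j in seq_len(K - 1L)) {
      for (k in seq_len(K - 1L)) {
        w <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
        blk <- crossprod(X, X * w)
        rows <- (j - 1L) * p + seq_len(p)
        cols <- (k - 1L) * p + seq_len(p)
        H[rows, cols] <- blk
      }
    }
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), grad)
    })
    B <- B + matrix(step, p, K - 1L)
    if (max(abs(grad)) < tol * nrow(X)) {
      converged <- TRUE
      break
    }
  }
  eta <- X %*% B
  den <- 1 + rowSums(exp(eta))
  probs <- cbind(1 / den, exp(eta) / den)
  colnames(probs) <- lev
  # separation drives standardized coefficients to +/- infinity
  if (!converged || max(abs(B)) > 15) {
    stop("propensity model shows (near-)perfect separation; ",
         "consider removing product terms", call. = FALSE)
  }
  list(coef = B, prob = probs)
}

#' Fit and truncate the propensity model
#'
#' Binary trials use a logistic GLM; three-level trials use a multinomial
#' logistic model.  Fitted probabilities always sum to one across
#' strategies; for weighting, each strategy's probability is additionally
#' floored at `1 / bound` (the adaptive [truncation_bound()]), and the
#' number of floored values is recorded.
#'
#' @param data data.frame holding the strategy column and covariates.
#' @param terms character vector of covariate column names.
#' @param strategy_col name of the strategy factor column.
#' @param bound weight bound; default [truncation_bound()] at `nrow(data)`.
#' @param nuisance `"glm"` (pre-specified parametric model) or `"mars"`
#'   (multivariate adaptive regression splines, sensitivity analysis).
#' @param min_rows minimum rows per strategy (relax for tiny discrete
#'   oracle checks).
#' @return object of class `propensity_fit`: `prob` (n x K, sums to 1),
#'   `g_trunc` (floored probabilities used for weighting), `bound`,
#'   `n_truncated`, `terms`.
#' @export
fit_propensity <- function(data, terms, strategy_col = "strategy",
                           bound = truncation_bound(nrow(data)),
                           nuisance = c("glm", "mars"),
                           min_rows = 10L) {
  nuisance <- match.arg(nuisance)
  a <- data[[strategy_col]]
  if (is.null(a)) stop("strategy column '", strategy_col, "' not found",
                       call. = FALSE)
  a <- droplevels(factor(a))
  tab <- table(a)
  if (length(tab) < 2L || any(tab < min_rows)) {
    stop("each strategy needs at least 10 rows (counts: ",
         paste(tab, collapse = ", "), ")", call. = FALSE)
  }
  X <- drop_collinear(impute_design(data, terms), "propensity model")
  lev <- levels(a)
  if (nuisance == "mars") {
    prob <- mars_propensity(X[, -1, drop = FALSE], a)
  } else if (length(lev) == 2L) {
    y <- as.numeric(a == lev[2L])
    # standardize (except intercept) so the separation check is
    # scale-free: diverging standardized coefficients flag separation
    ctr <- colMeans(X); ctr[1] <- 0
    scl <- apply(X, 2, stats::sd); scl[1] <- 1; scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, ctr, `-`), 2, scl, `/`)
    fit <- suppressWarnings(
      stats::glm.fit(Xs, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100)))
    if (!fit$converged || max(abs(fit$coefficients[-1]),
                              0, na.rm = TRUE) > 15) {
      stop("propensity model shows (near-)perfect separation; ",
           "consider removing product terms", call. = FALSE)
    }
    p1 <- fit$fitted.values
    prob <- cbind(1 - p1, p1)
    colnames(prob) <- lev
  } else {
    prob <- mlogit_fit(X, a)$prob
  }
  floor_g <- 1 / bound
  g_trunc <- pmax(prob, floor_g)
  structure(list(prob = prob, g_trunc = g_trunc, bound = bound,
                 n_truncated = sum(prob < floor_g), terms = terms,
                 levels = lev, nuisance = nuisance),
            class = "propensity_fit")
}

clip01 <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

#' TMLE for survivor-conditional strategy-specific means
#'
#' Targeted maximum likelihood estimation of the counterfactual mean
#' outcome under each treatment strategy, among survivors, with
#' contrasts against the reference strategy.  The outcome is linearly
#' scaled to `[0, 1]` by its observed range, an initial conditional-mean
#' regression is fitted (pre-specified GLM by default, MARS for the
#' sensitivity analysis), and a single logistic fluctuation with clever
#' covariates `I(A = a) / g_a(W)` and offset `logit(initial fit)` targets
#' the strategy-specific means, which are rescaled to natural units.
#'
#' @param data imputed data.frame restricted to survivors (rows with
#'   `died_before_followup == 1`, if the column is present, are dropped
#'   with a check).
#' @param outcome outcome column name (complete, post-imputation).
#' @param covariates character vector of adjustment column names.
#' @param propensity a [fit_propensity()] result on the same rows.
#' @param strategy_col strategy factor column name.
#' @param outcome_formula optional right-hand-side formula for the
#'   initial outcome regression (default
#'   `~ strategy + <covariates>`); a saturated formula such as
#'   `~ strategy * w` reproduces nonparametric g-computation exactly on
#'   discrete data.
#' @param nuisance `"glm"` or `"mars"` for the initial outcome fit.
#' @return object of class `tmle_estimate`: `means` (targeted mean per
#'   strategy, natural units), `contrasts` (vs reference), `epsilon`,
#'   `ic` (influence-curve matrix, one column per contrast),
#'   `score` (post-fluctuation clever-covariate residual means),
#'   `bounds` (a, b), `qstar` (n x K targeted predictions, natural
#'   units), `se` (IC-based standard errors of the contrasts).
#' @export
tmle_mean_contrast <- function(data, outcome, covariates, propensity,
                               strategy_col = "strategy",
                               outcome_formula = NULL,
                               nuisance = c("glm", "mars")) {
  nuisance <- match.arg(nuisance)
  stopifnot(inherits(propensity, "propensity_fit"))
  if (!is.null(data$died_before_followup) &&
      any(data$died_before_followup == 1)) {
    stop("tmle_mean_contrast expects survivors only; filter ",
         "died_before_followup == 1 first", call. = FALSE)
  }
  a <- droplevels(factor(data[[strategy_col]]))
  lev <- levels(a)
  y <- as.numeric(data[[outcome]])
  if (anyNA(y)) stop("outcome has missing values; impute first",
                     call. = FALSE)
  lo <- min(y); hi <- max(y)
  if (hi - lo < .Machine$double.eps * 10) {
    stop("outcome is constant; degenerate scaling", call. = FALSE)
  }
  y01 <- (y - lo) / (hi - lo)
  n <- length(y)
  g <- propensity$g_trunc[, lev, drop = FALSE]
  if (propensity$n_truncated > 0.2 * n) {
    warning("propensity truncation affected > 20% of rows",
            call. = FALSE)
  }

  # initial outcome fit and per-strategy predictions on [0, 1]
  if (nuisance == "mars") {
    Xo <- cbind(strata_dummies(a, lev),
                impute_design(data, covariates)[, -1, drop = FALSE])
    fit <- mars_fit(Xo, y01)
    q_init <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
    for (l in lev) {
      Xl <- Xo
      Xl[, seq_along(lev[-1])] <- rep(as.numeric(lev[-1] == l),
                                      each = n)
      q_init[, l] <- mars_predict(fit, Xl)
    }
  } else {
    if (is.null(outcome_formula)) {
      outcome_formula <- stats::reformulate(c(strategy_col, covariates))
    }
    df <- data
    df[[strategy_col]] <- a
    mm <- stats::model.matrix(outcome_formula, df)
    cf <- qr.coef(qr(mm), y01)
    cf[is.na(cf)] <- 0
    q_init <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
    for (l in lev) {
      dfl <- df
      dfl[[strategy_col]] <- factor(l, levels = lev)
      q_init[, l] <- drop(stats::model.matrix(outcome_formula, dfl) %*% cf)
    }
  }
  q_init <- clip01(q_init)

  # logistic fluctuation with one clever covariate per strategy
  H <- vapply(lev, function(l) as.numeric(a == l) / g[, l], numeric(n))
  q_at_a <- q_init[cbind(seq_len(n), match(a, lev))]
  fluct <- suppressWarnings(stats::glm.fit(
    H, y01, family = stats::quasibinomial(),
    offset = stats::qlogis(q_at_a),
    control = stats::glm.control(epsilon = 1e-14, maxit = 200)))
  eps <- fluct$coefficients
  eps[is.na(eps)] <- 0

  q_star <- stats::plogis(
    stats::qlogis(q_init) + rep(eps, each = n) / g)
  q_star_at_a <- q_star[cbind(seq_len(n), match(a, lev))]
  score <- colMeans(H * (y01 - q_star_at_a))

  psi01 <- colMeans(q_star)
  means <- lo + (hi - lo) * psi01
  ref <- lev[1L]
  others <- lev[-1L]
  contrasts <- means[others] - means[ref]

  ic <- vapply(others, function(l) {
    (hi - lo) * ((H[, l] - H[, ref]) * (y01 - q_star_at_a) +
                 (q_star[, l] - q_star[, ref]) -
                 (psi01[l] - psi01[ref]))
  }, numeric(n))
  se <- sqrt(colSums(ic^2) / n^2)

  structure(list(means = means, contrasts = contrasts, epsilon = eps,
                 ic = ic, score = score, bounds = c(lo, hi),
                 qstar = lo + (hi - lo) * q_star, se = se,
                 reference = ref, levels = lev,
                 n_truncated = propensity$n_truncated),
            class = "tmle_estimate")
}

strata_dummies <- function(a, lev) {
  vapply(lev[-1], function(l) as.numeric(a == l), numeric(length(a)))
}

#' Weighted empirical quantile (type 1)
#'
#' The smallest observed value whose normalized cumulative weight reaches
#' `tau`; ties share cumulative weight.
#'
#' @param y numeric values.
#' @param w nonnegative weights.
#' @param tau quantile level in (0, 1).
#' @export
weighted_quantile <- function(y, w, tau) {
  stopifnot(length(y) == length(w), tau > 0, tau < 1, all(w >= 0))
  ord <- order(y)
  cw <- cumsum(w[ord]) / sum(w)
  y[ord][which(cw >= tau - 1e-12)[1L]]
}

#' Inverse-probability-weighted quantile contrast
#'
#' For each strategy, the weighted empirical `tau`-quantile of the
#' outcome among rows following that strategy, with weights
#' `1 / g_a(W)` (truncated), and its difference against the reference
#' strategy.  The headline analyses use `tau = 0.9` (0.1 for the amyloid
#' ratio, where low values are adverse).
#'
#' @inheritParams tmle_mean_contrast
#' @param tau quantile level in (0, 1).
#' @return object of class `quantile_estimate`: `tau`, `quantiles` (per
#'   strategy), `contrasts` (vs reference).
#' @export
ipw_quantile_contrast <- function(data, outcome, propensity, tau,
                                  strategy_col = "strategy") {
  stopifnot(inherits(propensity, "propensity_fit"), tau > 0, tau < 1)
  a <- droplevels(factor(data[[strategy_col]]))
  lev <- levels(a)
  y <- as.numeric(data[[outcome]])
  qs <- stats::setNames(numeric(length(lev)), lev)
  for (l in lev) {
    rows <- a == l
    if (!any(rows)) stop("strategy '", l, "' has no rows", call. = FALSE)
    if (sum(rows) < 20L) {
      warning("strategy '", l, "' has fewer than 20 rows", call. = FALSE)
    }
    qs[l] <- weighted_quantile(y[rows],
                               1 / propensity$g_trunc[rows, l], tau)
  }
  structure(list(tau = tau, quantiles = qs,
                 contrasts = qs[lev[-1]] - qs[lev[1]],
                 reference = lev[1]),
            class = "quantile_estimate")
}

#' Restricted (natural) cubic spline basis
#'
#' Truncated-power natural cubic spline basis: for k knots, k - 1
#' columns (a linear column plus k - 2 nonlinear columns), linear beyond
#' the boundary knots.  With the 3 knots used for continuous effect
#' modifiers (10th/50th/90th percentiles) this yields 2 columns.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot locations (>= 3).
#' @return matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 3L || any(diff(knots) <= 0)) {
    stop("knots must be at least 3 strictly increasing values",
         call. = FALSE)
  }
  k <- length(knots)
  t1 <- knots[1]; tk1 <- knots[k - 1]; tk <- knots[k]
  cub <- function(u) pmax(u, 0)^3
  norm <- (tk - t1)^2
  nl <- vapply(seq_len(k - 2L), function(j) {
    tj <- knots[j]
    (cub(x - tj) - cub(x - tk1) * (tk - tj) / (tk - tk1) +
       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }, numeric(length(x)))
  out <- cbind(x, nl)
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2L)))
  out
}

#' Effect modification via an MSM over targeted predictions
#'
#' Projects the per-participant targeted strategy-specific predictions
#' from [tmle_mean_contrast()] onto a marginal structural model in
#' treatment strategy, the effect modifier, and their products, by least
#' squares.  Continuous modifiers enter through a restricted cubic spline
#' with knots at their 10th/50th/90th percentiles; binary or categorical
#' modifiers enter as indicators.  Predicted per-strategy mean curves are
#' evaluated on a grid spanning the modifier's 2.5th to 97.5th
#' percentiles.
#'
#' @inheritParams tmle_mean_contrast
#' @param modifier modifier column name (complete post-imputation).
#' @param tmle optional precomputed [tmle_mean_contrast()] result (to
#'   reuse its targeted predictions); fitted if `NULL`.
#' @param grid_n grid points for the predicted curves.
#' @return object of class `msm_estimate`: `coef`, `knots`, `curves`
#'   (data.frame: modifier, strategy, predicted), `design_labels`.
#' @export
tmle_msm_effect_modification <- function(data, outcome, covariates,
                                         propensity, modifier,
                                         strategy_col = "strategy",
                                         tmle = NULL, grid_n = 25L,
                                         nuisance = "glm") {
  mod <- data[[modifier]]
  if (is.null(mod)) stop("modifier column '", modifier, "' not found",
                         call. = FALSE)
  if (length(unique(mod[!is.na(mod)])) < 2L) {
    stop("modifier is constant", call. = FALSE)
  }
  if (is.null(tmle)) {
    # the pre-specified outcome model always carries the forced
    # treatment-by-modifier product so modification is expressible
    rhs <- paste(strategy_col, "*", modifier)
    extra <- setdiff(covariates, modifier)
    if (length(extra)) {
      rhs <- paste(rhs, "+", paste(extra, collapse = " + "))
    }
    of <- stats::as.formula(paste("~", rhs))
    tmle <- tmle_mean_contrast(data, outcome, covariates, propensity,
                               strategy_col = strategy_col,
                               outcome_formula = if (nuisance == "glm") of,
                               nuisance = nuisance)
  }
  lev <- tmle$levels
  n <- nrow(tmle$qstar)

  continuous <- is.numeric(mod) && length(unique(mod)) > 3L
  if (continuous) {
    knots <- stats::quantile(mod, c(0.1, 0.5, 0.9), names = FALSE)
    if (any(diff(knots) <= 0)) {
      stop("modifier percentiles are tied; cannot place spline knots",
           call. = FALSE)
    }
    basis <- rcs_basis(mod, knots)
    grid <- seq(stats::quantile(mod, 0.025), stats::quantile(mod, 0.975),
                length.out = grid_n)
    grid_basis <- rcs_basis(grid, knots)
  } else {
    knots <- NULL
    f <- factor(mod)
    basis <- strata_dummies(f, levels(f))
    colnames(basis) <- paste0(modifier, levels(f)[-1])
    grid <- if (is.numeric(mod)) sort(unique(mod)) else levels(f)
    gf <- factor(grid, levels = levels(f))
    grid_basis <- strata_dummies(gf, levels(f))
    colnames(grid_basis) <- colnames(basis)
  }

  # stack (participant x strategy) targeted predictions
  sd_mat <- strata_dummies(factor(rep(lev, each = n), levels = lev), lev)
  colnames(sd_mat) <- paste0("strategy", lev[-1])
  Brep <- basis[rep(seq_len(n), length(lev)), , drop = FALSE]
  inter <- do.call(cbind, lapply(seq_len(ncol(sd_mat)), function(j) {
    out <- Brep * sd_mat[, j]
    colnames(out) <- paste0(colnames(sd_mat)[j], ":", colnames(Brep))
    out
  }))
  X <- cbind(`(Intercept)` = 1, sd_mat, Brep, inter)
  yv <- as.numeric(tmle$qstar[, lev])
  cf <- qr.coef(qr(X), yv)
  cf[is.na(cf)] <- 0

  curves <- do.call(rbind, lapply(lev, function(l) {
    sg <- matrix(rep(as.numeric(lev[-1] == l), each = nrow(grid_basis)),
                 nrow(grid_basis))
    ig <- do.call(cbind, lapply(seq_len(ncol(sg)), function(j) {
      grid_basis * sg[, j]
    }))
    Xg <- cbind(1, sg, grid_basis, ig)
    data.frame(modifier = grid, strategy = l,
               predicted = drop(Xg %*% cf),
               stringsAsFactors = FALSE)
  }))

  structure(list(coef = cf, knots = knots, curves = curves,
                 levels = lev, modifier = modifier,
                 continuous = continuous, tmle = tmle),
            class = "msm_estimate")
}
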