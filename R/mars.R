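# Compact multivariate adaptive regression splines (forward hinge-pair
# selection, backward GCV pruning, interactions capped at degree 2),
# used as the data-adaptive nuisance fit in the TMLE sensitivity
# analysis.  Basis selection is by least squares; the propensity variant
# refits the selected basis with a logistic link so fitted values lie in
# (0, 1).

new_hinge <- function(x, knot, dir) {
  if (dir > 0) pmax(x - knot, 0) else pmax(knot - x, 0)
}

#' Fit a MARS model
#'
#' Forward pass: starting from the intercept, repeatedly add the hinge
#' pair `parent * (x - t)+`, `parent * (t - x)+` that most reduces the
#' residual sum of squares, over all existing basis terms of degree < 2,
#' predictor variables not already in the parent, and candidate knots at
#' predictor quantiles.  Backward pass: prune terms by generalized
#' cross-validation.  No basis term ever multiplies more than
#' `degree` hinge functions.
#'
#' @param X numeric predictor matrix.
#' @param y numeric response.
#' @param degree maximum interaction degree (default 2).
#' @param max_terms maximum number of basis terms (incl. intercept).
#' @param n_knots candidate knots per predictor (interior quantiles).
#' @param penalty GCV penalty per knot (classical default 3).
#' @return object of class `mars_model` with `terms` (list of
#'   hinge descriptions), `coef`, `gcv`.
#' @export
mars_fit <- function(X, y, degree = 2L, max_terms = 13L, n_knots = 7L,
                     penalty = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  knot_list <- lapply(seq_len(p), function(j) {
    ks <- unique(stats::quantile(X[, j],
                                 probs = seq(0.1, 0.9,
                                             length.out = n_knots),
                                 names = FALSE))
    ks[ks > min(X[, j]) & ks < max(X[, j])]
  })

  # terms[[i]]: list of hinges, each (var, knot, dir); intercept = empty
  terms <- list(list())
  B <- matrix(1, n, 1)
  rss0 <- sum((y - mean(y))^2)
  best_rss <- rss0

  term_degree <- function(tm) length(tm)
  term_vars <- function(tm) vapply(tm, `[[`, numeric(1), "var")
  eval_term <- function(tm, M) {
    v <- rep(1, nrow(M))
    for (h in tm) v <- v * new_hinge(M[, h$var], h$knot, h$dir)
    v
  }

  while (ncol(B) < max_terms - 1L) {
    # score candidate hinge pairs by projecting the current residual on
    # the pair residualized against the current basis (one QR per step)
    qrB <- qr(B)
    r <- qr.resid(qrB, y)
    best <- NULL
    for (i in seq_along(terms)) {
      tm <- terms[[i]]
      if (term_degree(tm) >= degree) next
      for (j in seq_len(p)) {
        if (j %in% term_vars(tm)) next
        for (t in knot_list[[j]]) {
          b_up <- B[, i] * new_hinge(X[, j], t, 1)
          b_dn <- B[, i] * new_hinge(X[, j], t, -1)
          U <- qr.resid(qrB, cbind(b_up, b_dn))
          G <- crossprod(U)
          g <- crossprod(U, r)
          red <- tryCatch(sum(g * solve(G + diag(1e-10 * (diag(G) + 1)),
                                        g)),
                          error = function(e) 0)
          rss <- sum(r^2) - red
          if (is.null(best) || rss < best$rss - 1e-12) {
            best <- list(rss = rss, parent = i, var = j, knot = t)
          }
        }
      }
    }
    if (is.null(best) || best$rss > best_rss * (1 - 1e-4)) break
    tm <- terms[[best$parent]]
    terms <- c(terms,
               list(c(tm, list(list(var = best$var, knot = best$knot,
                                    dir = 1))),
                    c(tm, list(list(var = best$var, knot = best$knot,
                                    dir = -1)))))
    B <- cbind(B,
               B[, best$parent] * new_hinge(X[, best$var], best$knot, 1),
               B[, best$parent] * new_hinge(X[, best$var], best$knot, -1))
    best_rss <- best$rss
  }

  gcv <- function(rss, r) {
    cm <- r + penalty * (r - 1) / 2
    if (cm >= n) return(Inf)
    (rss / n) / (1 - cm / n)^2
  }

  # backward pruning
  keep <- seq_along(terms)
  fit <- .lm.fit(B, y)
  best_model <- list(keep = keep, gcv = gcv(sum(fit$residuals^2),
                                            length(keep)))
  cur <- keep
  while (length(cur) > 1L) {
    cand_best <- NULL
    for (drop_i in cur[-1]) {    # never drop the intercept
      sub <- setdiff(cur, drop_i)
      f <- .lm.fit(B[, sub, drop = FALSE], y)
      g <- gcv(sum(f$residuals^2), length(sub))
      if (is.null(cand_best) || g < cand_best$gcv) {
        cand_best <- list(keep = sub, gcv = g)
      }
    }
    cur <- cand_best$keep
    if (cand_best$gcv < best_model$gcv) best_model <- cand_best
  }

  keep <- best_model$keep
  Bk <- B[, keep, drop = FALSE]
  cf <- qr.coef(qr(Bk), y)
  cf[is.na(cf)] <- 0
  structure(list(terms = terms[keep], coef = cf, gcv = best_model$gcv,
                 var_names = colnames(X)),
            class = "mars_model")
}

mars_basis <- function(model, X) {
  X <- as.matrix(X)
  B <- matrix(1, nrow(X), length(model$terms))
  for (i in seq_along(model$terms)) {
    v <- rep(1, nrow(X))
    for (h in model$terms[[i]]) v <- v * new_hinge(X[, h$var], h$knot,
                                                   h$dir)
    B[, i] <- v
  }
  B
}

#' @rdname mars_fit
#' @param model a `mars_model`.
#' @export
mars_predict <- function(model, X) {
  drop(mars_basis(model, X) %*% model$coef)
}

# Propensity variant: basis selected by least squares against the
# strategy coding, probabilities from a (multinomial) logistic refit of
# the selected basis so fitted values are proper probabilities.
mars_propensity <- function(X, a) {
  lev <- levels(a)
  fit <- mars_fit(X, as.numeric(a != lev[1]))
  B <- mars_basis(fit, X)
  B <- drop_collinear(B, "MARS propensity basis")
  if (length(lev) == 2L) {
    g <- suppressWarnings(
      stats::glm.fit(B, as.numeric(a == lev[2]),
                     family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100)))
    p1 <- g$fitted.values
    prob <- cbind(1 - p1, p1)
  } else {
    prob <- mlogit_fit(B, a)$prob
  }
  colnames(prob) <- lev
  prob
}
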