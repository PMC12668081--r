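# Bootstrap-then-multiple-imputation confidence intervals: participants
# are resampled with replacement, each resample is imputed M times, the
# estimator is applied to every completed dataset, and the point
# estimate / interval are pooled across the whole B x M array.

#' Bootstrap-then-MI confidence intervals
#'
#' For each of `B` bootstrap replicates, resamples participants with
#' replacement, imputes the resample `M` times with `impute_fn`, and
#' applies `estimator` to every completed dataset.  The pooled point
#' estimate is the grand mean of all B x M estimates and the 95%
#' interval is the 2.5th/97.5th percentile of the B within-replicate
#' means (the "MI Boot" percentile pooling).  Imputation is nested
#' inside resampling so that imputation uncertainty enters the bootstrap
#' distribution.  Replicates where the estimator fails are dropped and
#' counted; more than `fail_limit` failures is an error.
#'
#' @param data incomplete cohort data.frame.
#' @param impute_fn `function(data, m, seed)` returning a list of `m`
#'   completed datasets (`imputed_dataset` objects or plain data.frames).
#'   The default performs no imputation (complete-data bootstrap).
#' @param estimator `function(imputed)` returning a (named) numeric
#'   vector of estimates; scalars are fine.
#' @param B bootstrap replicates (the headline analyses use 250).
#' @param M imputations per replicate (headline: 2).
#' @param seed integer seed; all resampling and imputation randomness
#'   derives from it.
#' @param fail_limit maximum tolerated fraction of failed replicates.
#' @param level confidence level.
#' @return object of class `bootstrap_mi_result`: `estimates` (B x M x P
#'   array), `point` (length-P named vector), `ci` (P x 2 matrix),
#'   `n_failed`, `B`, `M`.
#' @export
bootstrap_mi <- function(data, estimator,
                         impute_fn = function(data, m, seed) {
                           replicate(m, data, simplify = FALSE)
                         },
                         B = 250L, M = 2L, seed = 1L,
                         fail_limit = 0.05, level = 0.95) {
  stopifnot(B >= 2L, M >= 1L)
  n <- nrow(data)
  first <- NULL
  res <- vector("list", B)
  failures <- character(0)
  for (b in seq_len(B)) {
    sb <- derive_seed(seed, b)
    idx <- with_seed(sb, sample.int(n, n, replace = TRUE))
    boot <- data[idx, , drop = FALSE]
    rownames(boot) <- NULL
    ests <- tryCatch({
      imps <- impute_fn(boot, M, derive_seed(sb, 1L))
      lapply(seq_len(M), function(m) {
        imp <- imps[[m]]
        if (inherits(imp, "imputed_dataset")) imp$b <- b
        est <- estimator(imp)
        if (anyNA(est)) stop("estimator returned NA")
        est
      })
    }, error = function(e) e)
    if (inherits(ests, "error")) {
      failures <- c(failures, sprintf("b=%d: %s", b,
                                      conditionMessage(ests)))
      next
    }
    if (is.null(first)) first <- ests[[1L]]
    res[[b]] <- do.call(rbind, ests)
  }
  n_failed <- length(failures)
  if (n_failed > fail_limit * B) {
    stop(sprintf("estimator failed on %d of %d bootstrap replicates:\n%s",
                 n_failed, B,
                 paste(utils::head(failures, 5L), collapse = "\n")),
         call. = FALSE)
  }
  if (is.null(first)) stop("all bootstrap replicates failed",
                           call. = FALSE)
  P <- length(first)
  pnames <- names(first)
  if (is.null(pnames)) pnames <- paste0("est", seq_len(P))
  est_arr <- array(NA_real_, dim = c(B, M, P),
                   dimnames = list(NULL, NULL, pnames))
  for (b in seq_len(B)) if (!is.null(res[[b]])) est_arr[b, , ] <- res[[b]]

  alpha <- (1 - level) / 2
  point <- apply(est_arr, 3, mean, na.rm = TRUE)
  within_b <- apply(est_arr, c(1, 3), mean)     # B x P replicate means
  ci <- t(apply(within_b, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE))
  dimnames(ci) <- list(pnames, c("lower", "upper"))

  structure(list(estimates = est_arr, point = point, ci = ci,
                 n_failed = n_failed, B = B, M = M, level = level,
                 failures = failures),
            class = "bootstrap_mi_result")
}

#' Pool an existing B x M estimate array
#'
#' Re-pools a persisted estimate array with the same rules as
#' [bootstrap_mi()]: grand-mean point estimate, percentile interval of
#' the within-replicate means.
#'
#' @param estimates numeric B x M matrix (one parameter).
#' @param level confidence level.
#' @return list with `point`, `lower`, `upper`.
#' @export
pool_bootstrap_mi <- function(estimates, level = 0.95) {
  estimates <- as.matrix(estimates)
  alpha <- (1 - level) / 2
  wb <- rowMeans(estimates, na.rm = TRUE)
  qs <- stats::quantile(wb, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(point = mean(estimates, na.rm = TRUE), lower = qs[1], upper = qs[2])
}
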