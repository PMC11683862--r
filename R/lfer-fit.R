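#' Calibrate a 2p-LFER (or any small OLS model) on a chemical table
#'
#' Fits the response by ordinary least squares on the given predictor
#' columns, exactly as a 2p-LFER is calibrated: no weighting, no
#' regularization. Returns the coefficients with analytic standard errors
#' and the regression statistics used to report such calibrations:
#' R-squared (`1 - SSE/SST`, SST centered), adjusted R-squared
#' (`1 - (1 - R2)(n-1)/df_res`), the overall F-statistic
#' (`(R2/p) / ((1-R2)/df_res)`), RMSE, and per-record residuals, fitted
#' values and leverages (hat values).
#'
#' RMSE is `sqrt(SSE/n)` by default, the convention common in the LFER
#' literature where RMSE is quoted as a prediction error alongside a
#' separately degree-of-freedom-corrected adjusted R-squared; the
#' df-corrected `sqrt(SSE/df_res)` is also returned as `rmse_df`.
#'
#' @param table A [chem_table] (or plain data.frame with the needed
#'   columns).
#' @param response Response column name, or a phase name resolved to its
#'   `logK_<phase>` column.
#' @param predictors Character vector of predictor columns (default the
#'   2p-LFER pair `logKow`, `logKaw`).
#' @param include_intercept Fit an intercept term (default `TRUE`).
#' @return An object of class `lfer_fit` with elements `coefficients`
#'   (named, dropped terms exactly 0), `dropped`, `analytic_se`,
#'   `bootstrap_se` (filled by [bootstrap_coefficient_se()]), `n`, `p`,
#'   `r2`, `adj_r2`, `rmse`, `rmse_df`, `f_stat`, `residuals`, `fitted`,
#'   `leverage`, and the data/spec needed to refit.
#' @examples
#' spec <- generator_spec(n = 40, noise_sigma = 0.3, seed = 7)
#' tab <- generate_observations(generate_chemicals(spec), spec,
#'                              phase = "combined_structural_protein")
#' fit_ols(tab, "combined_structural_protein")
#' @export
fit_ols <- function(table, response, predictors = c("logKow", "logKaw"),
                    include_intercept = TRUE) {
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!response %in% names(df)) {
    alt <- paste0("logK_", canonical_phase(response))
    if (alt %in% names(df)) response <- alt
    else stop_lfer("response column '", response, "' not found")
  }
  missing_pred <- setdiff(predictors, names(df))
  if (length(missing_pred)) {
    stop_lfer("predictor column(s) not found: ",
              paste(missing_pred, collapse = ", "))
  }
  keep <- stats::complete.cases(df[c(response, predictors)])
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  p <- length(predictors)
  if (n < p + 2) {
    stop_lfer("need at least p + 2 = ", p + 2, " complete records, got ", n)
  }
  ids <- if ("id" %in% names(df)) df$id else as.character(seq_len(n))
  X <- .design_matrix(df, predictors, include_intercept)
  y <- df[[response]]
  fit <- .ols_engine(X, y)
  term_names <- colnames(X)

  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  df_res <- n - ncol(X)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  f_stat <- (r2 / p) / ((1 - r2) / df_res)

  coefficients <- stats::setNames(fit$coefficients, term_names)
  analytic_se <- stats::setNames(fit$se, term_names)
  structure(list(
    coefficients = coefficients,
    dropped = stats::setNames(rep(FALSE, length(term_names)), term_names),
    analytic_se = analytic_se,
    bootstrap_se = NULL,
    n = n, p = p, df_res = df_res,
    r2 = r2, adj_r2 = adj_r2,
    rmse = sqrt(sse / n), rmse_df = sqrt(sse / df_res),
    f_stat = f_stat,
    residuals = stats::setNames(fit$residuals, ids),
    fitted = stats::setNames(fit$fitted, ids),
    leverage = stats::setNames(fit$leverage, ids),
    sigma2 = sse / df_res,
    response = response, predictors = predictors,
    include_intercept = include_intercept,
    data = cbind(data.frame(id = ids, stringsAsFactors = FALSE),
                 df[c(response, predictors)])
  ), class = "lfer_fit")
}

.design_matrix <- function(df, predictors, include_intercept) {
  X <- as.matrix(df[predictors])
  storage.mode(X) <- "double"
  if (include_intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

# QR-based least squares with rank diagnostics; the numerical core behind
# fit_ols and the resampling loops.
.ols_engine <- function(X, y, se = TRUE) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dependent <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop_lfer("design matrix is rank deficient; collinear column(s): ",
              paste(dependent, collapse = ", "))
  }
  coef <- qr.coef(qrx, y)
  fitted <- drop(X %*% coef)
  residuals <- y - fitted
  out <- list(coefficients = coef, fitted = fitted, residuals = residuals)
  if (se) {
    df_res <- nrow(X) - ncol(X)
    sigma2 <- sum(residuals^2) / df_res
    xtx_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
    out$se <- sqrt(sigma2 * diag(xtx_inv))
    out$leverage <- rowSums(qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]^2)
  }
  out
}

#' @export
print.lfer_fit <- function(x, ...) {
  cat(sprintf("LFER fit: %s ~ %s%s (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "),
              if (x$include_intercept) " + 1" else " - 1", x$n))
  tab <- data.frame(estimate = x$coefficients,
                    analytic_se = x$analytic_se[names(x$coefficients)])
  if (!is.null(x$bootstrap_se)) {
    tab$bootstrap_se <- x$bootstrap_se[names(x$coefficients)]
  }
  if (any(x$dropped)) tab$dropped <- x$dropped
  print(round(tab, 4))
  cat(sprintf("R2 = %.4f, Adj R2 = %.4f, F = %.2f, RMSE = %.4f (df-corrected %.4f)\n",
              x$r2, x$adj_r2, x$f_stat, x$rmse, x$rmse_df))
  invisible(x)
}

#' Predict from a fitted LFER
#'
#' @param object An `lfer_fit`.
#' @param newdata Data frame with the predictor columns; defaults to the
#'   calibration data.
#' @param ... Unused.
#' @export
predict.lfer_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  active <- object$predictors[!object$dropped[object$predictors]]
  X <- .design_matrix(as.data.frame(newdata), active,
                      object$include_intercept)
  drop(X %*% object$coefficients[colnames(X)])
}

#' Bootstrap standard errors for LFER coefficients
#'
#' Case (pairs) bootstrap: chemicals are resampled with replacement at full
#' size n, the model refitted on each resample, and the standard deviation
#' of each coefficient across the `replicates` refits reported. This is the
#' resampling scheme behind the coefficient uncertainties quoted for the
#' built-in calibrations (1000 resamples). Rank-deficient resamples are
#' redrawn and counted; more than 10% redraws is an error because it signals
#' a degenerate design.
#'
#' @param fit An [fit_ols()] result.
#' @param replicates Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; the same seed always yields the same SEs.
#' @return Named numeric vector of bootstrap SEs (one per fitted term), with
#'   attributes `redraws` (count of redrawn degenerate resamples) and
#'   `replicates`.
#' @export
bootstrap_coefficient_se <- function(fit, replicates = 1000, seed = NULL) {
  stopifnot(inherits(fit, "lfer_fit"))
  if (replicates < 2) stop_lfer("replicates must be >= 2")
  active <- fit$predictors[!fit$dropped[fit$predictors]]
  X <- .design_matrix(fit$data, active, fit$include_intercept)
  y <- fit$data[[fit$response]]
  n <- nrow(X)
  coefs <- matrix(NA_real_, replicates, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        if (qr(Xb)$rank == ncol(X)) break
        redraws <- redraws + 1L
        if (redraws > 0.1 * replicates) {
          stop_lfer("more than 10% of bootstrap resamples were rank ",
                    "deficient; the design is too degenerate to bootstrap")
        }
      }
      coefs[r, ] <- .ols_engine(Xb, y[idx], se = FALSE)$coefficients
    }
  })
  se <- apply(coefs, 2, stats::sd)
  attr(se, "redraws") <- redraws
  attr(se, "replicates") <- replicates
  se
}

#' Backward elimination of statistically insignificant terms
#'
#' Repeatedly removes the least significant term whose two-sided t-test
#' p-value exceeds `alpha` and refits, until every remaining term is
#' significant. Removed terms are reported with coefficient exactly 0 and a
#' `dropped` flag; this mirrors the published protocol in which a
#' statistically-zero intercept is excluded and the regression repeated (the
#' serum-albumin calibration is the documented case). The operation is
#' idempotent.
#'
#' @param fit An [fit_ols()] result.
#' @param alpha Significance level (default 0.05).
#' @param strict If `TRUE`, error when elimination would remove every term;
#'   otherwise the last surviving model is returned.
#' @return An `lfer_fit` whose `dropped` entries mark eliminated terms.
#' @export
drop_insignificant_terms <- function(fit, alpha = 0.05, strict = FALSE) {
  stopifnot(inherits(fit, "lfer_fit"))
  all_terms <- names(fit$coefficients)
  current <- fit
  repeat {
    active_terms <- names(current$coefficients)[!current$dropped]
    tval <- current$coefficients[active_terms] /
      current$analytic_se[active_terms]
    pval <- 2 * stats::pt(-abs(tval), df = current$df_res)
    worst <- which.max(pval)
    if (pval[worst] <= alpha) break
    victim <- active_terms[worst]
    keep_pred <- setdiff(current$predictors[!current$dropped[current$predictors]],
                         victim)
    keep_intercept <- current$include_intercept && victim != "(Intercept)"
    if (length(keep_pred) == 0 && !keep_intercept) {
      if (strict) stop_lfer("backward elimination removed every term")
      break
    }
    refit <- fit_ols(current$data, current$response, predictors = keep_pred,
                     include_intercept = keep_intercept)
    current <- .restore_dropped(refit, fit, victim, current)
  }
  current
}

# Re-expand a reduced refit to report all original terms, with eliminated
# ones pinned at exactly 0.
.restore_dropped <- function(refit, original, victim, previous) {
  all_terms <- names(original$coefficients)
  coefficients <- stats::setNames(rep(0, length(all_terms)), all_terms)
  dropped <- stats::setNames(rep(TRUE, length(all_terms)), all_terms)
  analytic_se <- stats::setNames(rep(NA_real_, length(all_terms)), all_terms)
  got <- names(refit$coefficients)
  coefficients[got] <- refit$coefficients
  dropped[got] <- FALSE
  analytic_se[got] <- refit$analytic_se
  refit$coefficients <- coefficients
  refit$dropped <- dropped
  refit$analytic_se <- analytic_se
  refit$predictors <- original$predictors
  refit
}

#' z-test comparison of coefficients between two fits
#'
#' For every term fitted in both models, computes
#' `z = (b1 - b2) / sqrt(SE1^2 + SE2^2)` and flags `|z| > critical`
#' (default 1.96, the 5% two-sided level). Used to check that a hold-out
#' refit is statistically consistent with the full-data calibration.
#'
#' @param fit1,fit2 [fit_ols()] results sharing at least one fitted term.
#' @param critical Significance threshold on |z|.
#' @param se Which standard errors to use: `"analytic"` (default) or
#'   `"bootstrap"` (requires [bootstrap_coefficient_se()] stored on both
#'   fits as `$bootstrap_se`).
#' @return A data.frame of class `coefficient_comparison` with columns
#'   `term, b1, b2, se1, se2, z, significant`. Swapping the two fits flips
#'   the sign of every z.
#' @export
compare_coefficients_z <- function(fit1, fit2, critical = 1.96,
                                   se = c("analytic", "bootstrap")) {
  se <- match.arg(se)
  get_se <- function(fit) {
    if (se == "bootstrap") {
      if (is.null(fit$bootstrap_se)) {
        stop_lfer("fit has no bootstrap SEs; run bootstrap_coefficient_se()")
      }
      fit$bootstrap_se
    } else fit$analytic_se
  }
  shared <- intersect(names(fit1$coefficients)[!fit1$dropped],
                      names(fit2$coefficients)[!fit2$dropped])
  if (length(shared) == 0) stop_lfer("the two fits share no fitted terms")
  se1 <- get_se(fit1)[shared]
  se2 <- get_se(fit2)[shared]
  z <- (fit1$coefficients[shared] - fit2$coefficients[shared]) /
    sqrt(se1^2 + se2^2)
  out <- data.frame(term = shared,
                    b1 = unname(fit1$coefficients[shared]),
                    b2 = unname(fit2$coefficients[shared]),
                    se1 = unname(se1), se2 = unname(se2),
                    z = unname(z),
                    significant = unname(abs(z) > critical),
                    stringsAsFactors = FALSE)
  class(out) <- c("coefficient_comparison", "data.frame")
  attr(out, "critical") <- critical
  out
}
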