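#' Seeded train/test split of a chemical table
#'
#' Ids are sorted canonically, shuffled with the seed, and the first
#' `round(n * test_fraction)` (half away from zero) become the test set, so
#' membership is reproducible and independent of the input row order.
#'
#' @param table A [chem_table] or data.frame with an `id` column.
#' @param test_fraction Proportion of records held out (0 < f < 1). The
#'   default 0.2 gives the conventional 80% train / 20% test split.
#' @param seed Integer seed.
#' @return List with `train` and `test` tables (disjoint, exhaustive).
#' @export
holdout_split <- function(table, test_fraction = 0.2, seed = NULL) {
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_lfer("test_fraction must be strictly between 0 and 1")
  }
  n <- nrow(df)
  n_test <- as.integer(round_half_away(n * test_fraction))
  if (n_test < 1 || n - n_test < 3) {
    stop_lfer("degenerate split: ", n_test, " test / ", n - n_test,
              " train records")
  }
  ord <- order(df$id)
  shuffled <- with_seed(seed, sample(ord))
  test_rows <- shuffled[seq_len(n_test)]
  train_rows <- shuffled[-seq_len(n_test)]
  restore <- function(rows) {
    out <- df[sort(rows), , drop = FALSE]
    rownames(out) <- NULL
    if (inherits(table, "chem_table")) chem_table(out) else out
  }
  list(train = restore(train_rows), test = restore(test_rows))
}

# Held-out coefficient of determination: 1 - SS_err/SS_tot around the
# held-out mean (not squared correlation), the Q2-style score convention.
.r2_score <- function(observed, predicted) {
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

.fold_assignment <- function(ids, k, seed) {
  shuffled <- with_seed(seed, sample(sort(ids)))
  stats::setNames(rep_len(seq_len(k), length(ids)), shuffled)
}

#' k-fold and repeated k-fold cross-validation of an LFER calibration
#'
#' Ids are shuffled (after canonical sorting, so the result is independent
#' of input order) and dealt round-robin into `k` folds; each fold in turn
#' is held out, the model refitted on the rest, and the held-out R-squared
#' recorded. With `repeats > 1` the fold assignment is re-randomized each
#' repeat and all `k * repeats` scores pooled.
#'
#' @param table Calibration table.
#' @param response,predictors,include_intercept Model spec as in
#'   [fit_ols()].
#' @param k Number of folds (default 5; 10 is the other conventional
#'   choice).
#' @param repeats Number of repeats (default 1).
#' @param seed Integer seed.
#' @return A `validation_result` list: `scheme`, `scores` (R2 per held-out
#'   fold), `rmse` (per fold), `mean_score`, `sd_score`, `seed`.
#' @export
kfold_cv <- function(table, response, predictors = c("logKow", "logKaw"),
                     include_intercept = TRUE, k = 5, repeats = 1,
                     seed = NULL) {
  if (k < 2) stop_lfer("k must be >= 2")
  full <- fit_ols(table, response, predictors, include_intercept)
  df <- full$data
  n <- nrow(df)
  if (floor(n / k) < 2) {
    stop_lfer("folds would hold fewer than 2 test records; use smaller k")
  }
  scores <- numeric(0)
  rmses <- numeric(0)
  for (rep in seq_len(repeats)) {
    rep_seed <- if (is.null(seed)) NULL else substream_seed(seed, paste0("fold", rep))
    folds <- .fold_assignment(df$id, k, rep_seed)
    for (fold in seq_len(k)) {
      test_ids <- names(folds)[folds == fold]
      train <- df[!df$id %in% test_ids, , drop = FALSE]
      test <- df[df$id %in% test_ids, , drop = FALSE]
      fit <- fit_ols(train, full$response, predictors, include_intercept)
      pred <- predict(fit, test)
      scores <- c(scores, .r2_score(test[[full$response]], pred))
      rmses <- c(rmses, sqrt(mean((test[[full$response]] - pred)^2)))
    }
  }
  .validation_result(if (repeats > 1) "repeated_kfold" else "kfold",
                     scores, rmses, seed,
                     details = list(k = k, repeats = repeats))
}

#' Leave-one-out cross-validation (Q2 and PRESS)
#'
#' PRESS is computed by the exact hat-matrix shortcut
#' `PRESS = sum((e_i / (1 - h_ii))^2)` (each term is the squared prediction
#' error for record i when it is left out), and `Q2 = 1 - PRESS/SST`. An
#' explicit n-refit loop is available via `method = "refit"` and must agree
#' with the shortcut to numerical precision.
#'
#' @inheritParams kfold_cv
#' @param method `"hat"` (closed form, default) or `"refit"` (explicit
#'   loop).
#' @return A `validation_result` with `q2`, `press`, and per-record
#'   held-out prediction errors in `scores` slot `loo_errors`.
#' @export
loocv <- function(table, response, predictors = c("logKow", "logKaw"),
                  include_intercept = TRUE, method = c("hat", "refit")) {
  method <- match.arg(method)
  full <- fit_ols(table, response, predictors, include_intercept)
  if (full$n < full$p + 3) stop_lfer("LOOCV needs n >= p + 3")
  y <- full$data[[full$response]]
  if (method == "hat") {
    h <- full$leverage
    if (any(h >= 1 - 1e-12)) {
      stop_lfer("a record has leverage 1 (exact interpolation point); ",
                "LOOCV is undefined for it")
    }
    loo_errors <- full$residuals / (1 - h)
  } else {
    loo_errors <- vapply(seq_len(full$n), function(i) {
      fit <- fit_ols(full$data[-i, , drop = FALSE], full$response,
                     predictors, include_intercept)
      y[i] - predict(fit, full$data[i, , drop = FALSE])
    }, numeric(1))
    names(loo_errors) <- names(full$residuals)
  }
  press <- sum(loo_errors^2)
  sst <- sum((y - mean(y))^2)
  out <- .validation_result("loocv", scores = numeric(0), rmses = numeric(0),
                            seed = NULL)
  out$q2 <- 1 - press / sst
  out$press <- press
  out$loo_errors <- loo_errors
  out$mean_score <- out$q2
  out
}

#' Bootstrap validation of an LFER calibration
#'
#' Each replicate draws `round(n * sample_fraction)` records with
#' replacement, refits the model on the resample, and scores R-squared on
#' the full table; the mean and standard deviation over replicates measure
#' the stability of the calibration. The published protocol for the
#' built-in calibrations used 1000 replicates at 50% sample size.
#'
#' @inheritParams kfold_cv
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param sample_fraction Resample size as a fraction of n (default 0.5).
#' @return A `validation_result` with one score per replicate.
#' @export
bootstrap_validation <- function(table, response,
                                 predictors = c("logKow", "logKaw"),
                                 include_intercept = TRUE,
                                 replicates = 1000, sample_fraction = 0.5,
                                 seed = NULL) {
  if (replicates < 2) stop_lfer("replicates must be >= 2")
  full <- fit_ols(table, response, predictors, include_intercept)
  df <- full$data
  n <- nrow(df)
  m <- as.integer(round_half_away(n * sample_fraction))
  if (m < full$p + 2) stop_lfer("resample size ", m, " too small to fit")
  y <- df[[full$response]]
  scores <- numeric(replicates)
  rmses <- numeric(replicates)
  redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      repeat {
        idx <- sample.int(n, m, replace = TRUE)
        ok <- tryCatch({
          fit <- fit_ols(df[idx, , drop = FALSE], full$response, predictors,
                         include_intercept)
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
        redraws <- redraws + 1L
        if (redraws > 0.1 * replicates) {
          stop_lfer("more than 10% of bootstrap resamples failed to fit")
        }
      }
      pred <- predict(fit, df)
      scores[r] <- .r2_score(y, pred)
      rmses[r] <- sqrt(mean((y - pred)^2))
    }
  })
  out <- .validation_result("bootstrap", scores, rmses, seed,
                            details = list(replicates = replicates,
                                           sample_fraction = sample_fraction,
                                           redraws = redraws))
  out
}

.validation_result <- function(scheme, scores, rmses, seed, details = list()) {
  structure(list(
    scheme = scheme,
    scores = scores,
    rmse = rmses,
    mean_score = if (length(scores)) mean(scores) else NA_real_,
    sd_score = if (length(scores) > 1) stats::sd(scores) else NA_real_,
    seed = seed,
    details = details
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Validation (%s): ", x$scheme))
  if (x$scheme == "loocv") {
    cat(sprintf("Q2 = %.4f, PRESS = %.4f (n = %d)\n", x$q2, x$press,
                length(x$loo_errors)))
  } else {
    cat(sprintf("mean score = %.4f, sd = %.4f over %d resamples\n",
                x$mean_score, x$sd_score, length(x$scores)))
  }
  invisible(x)
}

#' Bland-Altman agreement analysis between two paired measurement sets
#'
#' Used to judge whether two measurement series of the same quantity (for
#' example chicken- and fish-muscle protein-water partition coefficients
#' for the same chemicals) agree closely enough to be pooled. Computes the
#' paired differences `a - b`, their mean (bias), standard deviation, the
#' 95% limits of agreement `bias +/- 1.96 sd`, and the pairs falling
#' outside those limits.
#'
#' @param a,b Paired numeric vectors of equal length (>= 3, all finite).
#' @param ids Optional identifiers for the pairs.
#' @return List of class `bland_altman` with `bias`, `sd_diff`, `limits`,
#'   `differences`, `means`, `outliers` (ids/indices outside the limits).
#' @examples
#' ba <- bland_altman(c(1, 3, 5), c(2, 3, 4))
#' ba$bias; ba$limits
#' @export
bland_altman <- function(a, b, ids = NULL) {
  if (length(a) != length(b)) stop_lfer("a and b must be the same length")
  if (length(a) < 3) stop_lfer("need at least 3 pairs")
  check_finite(a, "a"); check_finite(b, "b")
  ids <- ids %||% as.character(seq_along(a))
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  limits <- bias + c(-1.96, 1.96) * sd_diff
  outside <- d < limits[1] | d > limits[2]
  structure(list(
    bias = bias, sd_diff = sd_diff, limits = limits,
    differences = stats::setNames(d, ids),
    means = stats::setNames((a + b) / 2, ids),
    outliers = ids[outside]
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, sd %.4f, limits [%.4f, %.4f], %d outlier(s)\n",
              x$bias, x$sd_diff, x$limits[1], x$limits[2],
              length(x$outliers)))
  invisible(x)
}
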