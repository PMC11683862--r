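#' Predict a phase-water partition coefficient from logKow and logKaw
#'
#' Evaluates the two-parameter linear free energy relationship
#' \deqn{\log K_{phase-water} = \lambda_1 \log K_{ow} + \lambda_2 \log K_{aw}
#'   + \lambda_3.}
#' `logKow` is a hydrophobicity proxy; `logKaw` captures the balance of
#' volatility against aqueous solubility, and acts mostly as a proxy for
#' hydrogen-bonding interactions that octanol under-represents.
#'
#' @param logKow,logKaw Finite numeric vectors (recycled to a common
#'   length).
#' @param coeffs A [phase_coefficients_2p], e.g. from
#'   [get_2p_coefficients()].
#' @return Numeric vector of predicted log10 phase-water partition
#'   coefficients.
#' @examples
#' combined <- get_2p_coefficients("combined_structural_protein")
#' predict_2p(6.13, -4.73, combined)  # benzo[a]pyrene -> 4.572
#' @export
predict_2p <- function(logKow, logKaw, coeffs) {
  stopifnot(inherits(coeffs, "phase_coefficients_2p"))
  check_finite(logKow, "logKow")
  check_finite(logKaw, "logKaw")
  coeffs$lambda1 * logKow + coeffs$lambda2 * logKaw + coeffs$lambda3
}

#' One-parameter (octanol-based) LFER prediction
#'
#' The classical screening model `slope * logKow + intercept`. No slope or
#' intercept values are shipped: supply a published calibration. Identical to
#' [predict_2p()] with `lambda2 = 0`.
#'
#' @param logKow Finite numeric vector.
#' @param slope,intercept Calibration constants.
#' @export
predict_1p <- function(logKow, slope, intercept) {
  check_finite(logKow, "logKow")
  check_finite(slope, "slope")
  check_finite(intercept, "intercept")
  slope * logKow + intercept
}

#' Poly-parameter (Abraham) LFER prediction
#'
#' Evaluates `c + eE + sS + aA + bB + vV` (V-form) or
#' `c + eE + sS + aA + bB + lL` (L-form) for one chemical's Abraham solute
#' descriptors under a phase-specific [abraham_system()].
#'
#' @param descriptors Named list or vector with entries `E, S, A, B` and `V`
#'   or `L` as the system's form requires.
#' @param system An [abraham_system].
#' @export
predict_pp <- function(descriptors, system) {
  stopifnot(inherits(system, "abraham_system"))
  descriptors <- as.list(descriptors)
  needed <- c("E", "S", "A", "B", if (system$form == "v") "V" else "L")
  missing <- needed[!vapply(needed, function(d) {
    !is.null(descriptors[[d]]) && is.finite(descriptors[[d]])
  }, logical(1))]
  if (length(missing)) {
    stop_lfer("missing required descriptor(s): ",
              paste(missing, collapse = ", "))
  }
  co <- system$coefficients
  co[["c"]] + co[["e"]] * descriptors$E + co[["s"]] * descriptors$S +
    co[["a"]] * descriptors$A + co[["b"]] * descriptors$B +
    if (system$form == "v") co[["v"]] * descriptors$V else co[["l"]] * descriptors$L
}

#' Predict a whole chemical table and score against observations
#'
#' Applies a 1p-, 2p- or pp-LFER to every record of a [chem_table] and, where
#' the table carries an observed `logK_<phase>` column, computes residuals
#' (observed minus predicted) and summary error statistics. Records lacking
#' the required inputs are skipped and counted by default
#' (`on_missing = "skip"`); `on_missing = "error"` makes them fatal, which is
#' the right choice for curated calibration tables.
#'
#' @param table A [chem_table].
#' @param phase Phase name; used to locate the observed column and, for
#'   `model = "2p"` with `coeffs = NULL`, to look up the built-in registry.
#' @param model One of `"1p"`, `"2p"`, `"pp"`.
#' @param coeffs Model coefficients: a [phase_coefficients_2p] for `"2p"`, a
#'   list `list(slope=, intercept=)` for `"1p"`, an [abraham_system] for
#'   `"pp"`.
#' @param on_missing `"skip"` (default) or `"error"`.
#' @return A list of class `lfer_predictions`: `predictions` (data.frame
#'   with id, phase, predicted, observed, residual, model), `summary`
#'   (`rmse`, `mae`, `bias`, `n_observed`, `n_predicted`, `n_skipped`).
#' @export
batch_predict <- function(table, phase, model = c("2p", "1p", "pp"),
                          coeffs = NULL, on_missing = c("skip", "error")) {
  stopifnot(inherits(table, "chem_table"))
  model <- match.arg(model)
  on_missing <- match.arg(on_missing)
  phase <- canonical_phase(phase)
  if (model == "2p" && is.null(coeffs)) coeffs <- get_2p_coefficients(phase)

  predict_one <- function(i) {
    row <- table[i, , drop = FALSE]
    switch(model,
      "2p" = {
        if (is.na(row$logKow) || is.na(row$logKaw)) return(NA_real_)
        predict_2p(row$logKow, row$logKaw, coeffs)
      },
      "1p" = {
        if (is.na(row$logKow)) return(NA_real_)
        predict_1p(row$logKow, coeffs$slope, coeffs$intercept)
      },
      "pp" = {
        needed <- c("E", "S", "A", "B", if (coeffs$form == "v") "V" else "L")
        if (!all(needed %in% names(row)) ||
            anyNA(unlist(row[needed]))) return(NA_real_)
        predict_pp(row[needed], coeffs)
      })
  }
  has_input <- switch(model,
    "2p" = !is.na(table$logKow) & !is.na(table$logKaw),
    "1p" = !is.na(table$logKow),
    "pp" = {
      needed <- c("E", "S", "A", "B", if (coeffs$form == "v") "V" else "L")
      if (!all(needed %in% names(table))) rep(FALSE, nrow(table))
      else !Reduce(`|`, lapply(table[needed], is.na))
    })
  if (!any(has_input)) stop_lfer("no record has the inputs required by the ",
                                 model, " model")
  if (on_missing == "error" && !all(has_input)) {
    stop_lfer("missing model inputs for id(s): ",
              paste(table$id[!has_input], collapse = ", "))
  }
  idx <- which(has_input)
  predicted <- vapply(idx, predict_one, numeric(1))
  obs_col <- paste0("logK_", phase)
  observed <- if (obs_col %in% names(table)) table[[obs_col]][idx] else rep(NA_real_, length(idx))
  residual <- observed - predicted
  preds <- data.frame(id = table$id[idx], phase = phase,
                      predicted = predicted, observed = observed,
                      residual = residual, model = model,
                      stringsAsFactors = FALSE)
  with_obs <- !is.na(residual)
  summary <- list(
    rmse = if (any(with_obs)) sqrt(mean(residual[with_obs]^2)) else NA_real_,
    mae = if (any(with_obs)) mean(abs(residual[with_obs])) else NA_real_,
    bias = if (any(with_obs)) mean(residual[with_obs]) else NA_real_,
    n_observed = sum(with_obs),
    n_predicted = length(idx),
    n_skipped = sum(!has_input)
  )
  structure(list(predictions = preds, summary = summary),
            class = "lfer_predictions")
}

#' @export
print.lfer_predictions <- function(x, ...) {
  s <- x$summary
  cat(sprintf("LFER predictions (%s model, phase %s): %d predicted, %d skipped\n",
              x$predictions$model[1], x$predictions$phase[1],
              s$n_predicted, s$n_skipped))
  if (s$n_observed > 0) {
    cat(sprintf("  vs %d observations: RMSE %.3f, MAE %.3f, bias %+.3f\n",
                s$n_observed, s$rmse, s$mae, s$bias))
  }
  invisible(x)
}
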