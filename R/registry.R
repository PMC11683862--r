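#' Two-parameter LFER coefficient sets
#'
#' A `phase_coefficients_2p` object holds the calibrated coefficients of a
#' 2p-LFER for one phase-water system,
#' \deqn{\log K_{phase-water} = \lambda_1 \log K_{ow} + \lambda_2 \log K_{aw}
#'   + \lambda_3,}
#' together with their reported standard errors and the regression
#' statistics of the calibration (n, R-squared, adjusted R-squared,
#' F-statistic, RMSE). `lambda3 = 0` with `intercept_dropped = TRUE` encodes
#' an intercept that was found statistically indistinguishable from zero and
#' excluded before refitting (the serum-albumin system is the one built-in
#' case).
#'
#' @param phase Canonical phase name (lower_snake_case).
#' @param lambda1,lambda2,lambda3 Coefficients on `logKow`, `logKaw` and the
#'   intercept.
#' @param se1,se2,se3 Standard errors (NA where a term was dropped).
#' @param n Calibration size; `r2`, `adj_r2`, `rmse`, `f_stat` the fit
#'   statistics; `source` a free-text citation.
#' @param intercept_dropped Logical flag; must agree with `lambda3 == 0`.
#' @return An object of class `phase_coefficients_2p`.
#' @export
phase_coefficients_2p <- function(phase, lambda1, lambda2, lambda3,
                                  se1 = NA_real_, se2 = NA_real_,
                                  se3 = NA_real_, n = NA_integer_,
                                  r2 = NA_real_, adj_r2 = NA_real_,
                                  rmse = NA_real_, f_stat = NA_real_,
                                  source = "user",
                                  intercept_dropped = FALSE) {
  check_finite(lambda1, "lambda1"); check_finite(lambda2, "lambda2")
  check_finite(lambda3, "lambda3")
  if (intercept_dropped && lambda3 != 0) {
    stop_lfer("lambda3 must be exactly 0 when the intercept is dropped")
  }
  if (!intercept_dropped && lambda3 == 0 && is.na(se3)) {
    intercept_dropped <- TRUE
  }
  if (!is.na(n) && n < 3) stop_lfer("a fitted coefficient set needs n >= 3")
  structure(
    list(phase = phase, lambda1 = lambda1, lambda2 = lambda2,
         lambda3 = lambda3, se1 = se1, se2 = se2, se3 = se3,
         n = as.integer(n), r2 = r2, adj_r2 = adj_r2, rmse = rmse,
         f_stat = f_stat, source = source,
         intercept_dropped = isTRUE(intercept_dropped)),
    class = "phase_coefficients_2p"
  )
}

#' @export
print.phase_coefficients_2p <- function(x, ...) {
  cat(sprintf("2p-LFER coefficients: %s\n", x$phase))
  cat(sprintf("  logK = %.3f*logKow + %.3f*logKaw %s\n",
              x$lambda1, x$lambda2,
              if (x$intercept_dropped) "(intercept dropped)"
              else sprintf("%+.3f", x$lambda3)))
  if (!is.na(x$r2)) {
    cat(sprintf("  n = %s, R2 = %.3f, Adj R2 = %.3f, RMSE = %.3f, F = %.1f\n",
                ifelse(is.na(x$n), "?", x$n), x$r2, x$adj_r2, x$rmse,
                x$f_stat))
  }
  cat("  source:", x$source, "\n")
  invisible(x)
}

# Built-in registry: published 2p-LFER calibrations for protein and lipid
# phases. SEs are the reported bootstrap-derived standard errors.
.builtin_2p <- list(
  chicken_structural_protein = list(
    lambda = c(0.813, -0.077, -0.874), se = c(0.049, 0.024, 0.223),
    n = 46L, r2 = 0.882, adj_r2 = 0.877, f_stat = 161.7, rmse = 0.323,
    dropped = FALSE, source = "current study"),
  fish_structural_protein = list(
    lambda = c(0.886, -0.097, -1.243), se = c(0.055, 0.027, 0.246),
    n = 45L, r2 = 0.870, adj_r2 = 0.864, f_stat = 140.8, rmse = 0.353,
    dropped = FALSE, source = "current study"),
  combined_structural_protein = list(
    lambda = c(0.851, -0.092, -1.080), se = c(0.049, 0.025, 0.220),
    n = 51L, r2 = 0.878, adj_r2 = 0.873, f_stat = 173.3, rmse = 0.334,
    dropped = FALSE, source = "current study"),
  bsa = list(
    lambda = c(0.788, -0.053, 0.000), se = c(0.046, 0.018, NA_real_),
    n = 83L, r2 = 0.760, adj_r2 = 0.759, f_stat = 130.5, rmse = 0.422,
    dropped = TRUE, source = "current study"),
  phospholipid = list(
    lambda = c(1.070, -0.056, -0.247), se = c(0.021, 0.013, 0.095),
    n = NA_integer_, r2 = 0.953, adj_r2 = 0.952, f_stat = 1293, rmse = 0.414,
    dropped = FALSE, source = "Khawar et al. (lipid 2p-LFERs)"),
  storage_lipid = list(
    lambda = c(1.102, 0.069, -0.236), se = c(0.016, 0.010, 0.043),
    n = NA_integer_, r2 = 0.971, adj_r2 = 0.970, f_stat = 5046, rmse = 0.375,
    dropped = FALSE, source = "Khawar et al. (lipid 2p-LFERs)")
)

.phase_synonyms <- c(
  pw = "combined_structural_protein",
  structural_protein = "combined_structural_protein",
  combined_structural_proteins = "combined_structural_protein",
  ch = "chicken_structural_protein",
  chicken = "chicken_structural_protein",
  fish = "fish_structural_protein",
  bsa = "bsa", albumin = "bsa", serum_albumin = "bsa",
  bovine_serum_albumin = "bsa",
  lw = "storage_lipid", lipid = "storage_lipid",
  phw = "phospholipid", membrane_lipid = "phospholipid"
)

#' Resolve a phase name to its canonical lower_snake_case form
#'
#' @param phase A phase name or synonym (`"pw"`, `"BSA"`, `"storage lipid"`
#'   ...).
#' @param strict If `TRUE`, unknown names are an error; otherwise they are
#'   normalized (lowercased, separators to `_`) and returned.
#' @export
canonical_phase <- function(phase, strict = FALSE) {
  key <- .normalize_header(phase)
  if (key %in% names(.phase_synonyms)) return(unname(.phase_synonyms[key]))
  if (key %in% names(.builtin_2p)) return(key)
  if (strict) {
    stop_lfer("unknown phase '", phase, "'; registered phases: ",
              paste(list_2p_phases(), collapse = ", "))
  }
  key
}

.registry <- new.env(parent = emptyenv())

.registry_get_all <- function() {
  user <- as.list(.registry)
  builtin <- lapply(names(.builtin_2p), function(ph) {
    b <- .builtin_2p[[ph]]
    phase_coefficients_2p(ph, b$lambda[1], b$lambda[2], b$lambda[3],
                          b$se[1], b$se[2], b$se[3], n = b$n, r2 = b$r2,
                          adj_r2 = b$adj_r2, rmse = b$rmse, f_stat = b$f_stat,
                          source = b$source, intercept_dropped = b$dropped)
  })
  names(builtin) <- names(.builtin_2p)
  utils::modifyList(builtin, user)
}

#' Look up, list and register 2p-LFER coefficient sets
#'
#' The built-in registry ships published calibrations for six phase-water
#' systems: chicken, fish and combined structural protein, bovine serum
#' albumin (`bsa`), phospholipid and storage lipid. Users may register
#' additional sets for their own phases; registered sets shadow built-ins of
#' the same name.
#'
#' @param phase Phase name or synonym (see [canonical_phase()]).
#' @return `get_2p_coefficients()` returns a [phase_coefficients_2p].
#' @examples
#' get_2p_coefficients("combined_structural_protein")
#' get_2p_coefficients("pw")  # synonym for the same set
#' @export
get_2p_coefficients <- function(phase) {
  key <- canonical_phase(phase)
  all <- .registry_get_all()
  if (!key %in% names(all)) {
    stop_lfer("unknown phase '", phase, "'; registered phases: ",
              paste(sort(names(all)), collapse = ", "))
  }
  all[[key]]
}

#' @rdname get_2p_coefficients
#' @export
list_2p_phases <- function() {
  sort(names(.registry_get_all()))
}

#' @rdname get_2p_coefficients
#' @param coeffs A [phase_coefficients_2p] to register under its own phase
#'   name.
#' @export
register_2p_coefficients <- function(coeffs) {
  stopifnot(inherits(coeffs, "phase_coefficients_2p"))
  assign(canonical_phase(coeffs$phase), coeffs, envir = .registry)
  invisible(coeffs)
}

#' Abraham solvation systems for pp-LFER predictions
#'
#' A poly-parameter LFER (pp-LFER) predicts a log partition coefficient from
#' the Abraham solute descriptors via phase-specific system coefficients,
#' either in the V-form `c + eE + sS + aA + bB + vV` or the L-form
#' `c + eE + sS + aA + bB + lL`. System coefficient values for protein
#' phases are published elsewhere and are not shipped here: construct or
#' load them from a config file with [read_abraham_systems()].
#'
#' @param phase Phase name.
#' @param c,e,s,a,b System coefficients.
#' @param v,l Exactly one of the two must be supplied; this selects the
#'   equation form.
#' @return An object of class `abraham_system`.
#' @examples
#' sys <- abraham_system("demo", c = 0.5, e = 0.1, s = -0.2, a = -1,
#'                       b = -3, v = 2)
#' sys$form
#' @export
abraham_system <- function(phase, c, e, s, a, b, v = NULL, l = NULL) {
  if (is.null(v) == is.null(l)) {
    stop_lfer("supply exactly one of 'v' (V-form) or 'l' (L-form)")
  }
  vals <- c(c = c, e = e, s = s, a = a, b = b,
            if (!is.null(v)) c(v = v) else c(l = l))
  check_finite(unname(vals), "system coefficients")
  structure(list(phase = phase, coefficients = vals,
                 form = if (!is.null(v)) "v" else "l"),
            class = "abraham_system")
}

#' @rdname abraham_system
#' @param path JSON or YAML file mapping phase names to system coefficient
#'   sets, e.g. `{"myphase": {"c":0.1,"e":0.2,"s":0,"a":0,"b":0,"v":1}}`.
#' @return `read_abraham_systems()` returns a named list of `abraham_system`
#'   objects.
#' @export
read_abraham_systems <- function(path) {
  if (!file.exists(path)) stop_lfer("file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- lapply(names(raw), function(ph) {
    co <- as.list(raw[[ph]])
    abraham_system(ph, c = co$c, e = co$e, s = co$s, a = co$a, b = co$b,
                   v = co$v, l = co$l)
  })
  names(out) <- names(raw)
  out
}

#' Path to the frozen built-in coefficient registry file
#'
#' The built-in Table of 2p-LFER calibrations is also shipped as a JSON file
#' so that the constants can be diffed and audited outside R; the package's
#' tests assert that the in-memory registry and this file agree
#' digit-for-digit.
#' @export
registry_json_path <- function() {
  system.file("extdata", "coefficients_2p.json", package = "lfer2p",
              mustWork = TRUE)
}
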