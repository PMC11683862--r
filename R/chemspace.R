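#' Principal component analysis of a chemical descriptor matrix
#'
#' Eigen-decomposes the Pearson correlation matrix of the columns (the
#' variables are standardized first, the right choice when log partition
#' coefficients and Abraham descriptors of different scales share one
#' matrix; `standardize = FALSE` uses the covariance matrix instead).
#' Reports, per principal dimension, the fraction of total variance and,
#' per variable, the squared cosine (cos2, the quality of representation of
#' that variable in that dimension) along with the variable loadings
#' (variable-component correlations). Eigenvector signs follow the
#' convention that each component's largest-magnitude loading is positive.
#'
#' @param x Numeric matrix or data.frame, chemicals in rows, variables in
#'   columns; at least 3 rows and 2 columns, no missing values, no
#'   zero-variance columns.
#' @param standardize Use the correlation matrix (default `TRUE`).
#' @return List of class `pca_result` with `variance_proportion`,
#'   `cumulative`, `eigenvalues`, `loadings` (variables x dimensions),
#'   `variable_cos2` (squared loadings rescaled so each variable's cos2
#'   sums to 1 across dimensions).
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
#' p <- pca_analysis(m)
#' sum(p$variance_proportion)  # 1
#' @export
pca_analysis <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2) stop_lfer("need >= 3 rows and >= 2 columns")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)
    cells <- apply(utils::head(bad, 10), 1, function(rc) {
      paste0("(", rc[1], ",", colnames(x)[rc[2]] %||% rc[2], ")")
    })
    stop_lfer("missing values at cell(s): ", paste(cells, collapse = ", "))
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_lfer("zero-variance column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
  }
  S <- if (standardize) stats::cor(x) else stats::cov(x)
  eig <- eigen(S, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(vectors))) {
    j <- which.max(abs(vectors[, k]))
    if (vectors[j, k] < 0) vectors[, k] <- -vectors[, k]
  }
  loadings <- vectors %*% diag(sqrt(values), nrow = length(values))
  if (!standardize) {
    # convert to variable-component correlations on the covariance scale
    loadings <- loadings / sds
  }
  dimnames(loadings) <- list(colnames(x), paste0("dim", seq_along(values)))
  cos2 <- loadings^2
  cos2 <- cos2 / rowSums(cos2)
  structure(list(
    eigenvalues = values,
    variance_proportion = values / sum(values),
    cumulative = cumsum(values / sum(values)),
    loadings = loadings,
    variable_cos2 = cos2,
    standardized = standardize
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA (", if (x$standardized) "correlation" else "covariance",
      " matrix), ", length(x$eigenvalues), " dimensions\n", sep = "")
  cat("variance proportions:",
      paste(sprintf("%.3f", x$variance_proportion), collapse = " "), "\n")
  cat("first two dimensions:",
      sprintf("%.1f%%", 100 * x$cumulative[min(2, length(x$cumulative))]),
      "\n")
  invisible(x)
}

#' Pearson correlation matrix of chemical descriptors
#'
#' @param x Numeric matrix or data.frame (chemicals x variables).
#' @param use `"complete"` (drop rows with any missing value, default) or
#'   `"pairwise"` (pairwise-complete observations per entry).
#' @return List of class `correlation_matrix` with `r` (symmetric Pearson
#'   matrix, unit diagonal) and `n` (observations used). Constant columns
#'   yield NA entries and a warning, never a silent zero.
#' @export
pearson_matrix <- function(x, use = c("complete", "pairwise")) {
  use <- match.arg(use)
  x <- as.matrix(x)
  r <- suppressWarnings(stats::cor(
    x, use = if (use == "complete") "complete.obs" else "pairwise.complete.obs",
    method = "pearson"))
  diag(r) <- 1
  if (anyNA(r)) {
    warning("undefined correlations (constant column or too few ",
            "complete pairs) left as NA", call. = FALSE)
  }
  structure(list(r = r, variables = colnames(x), use = use,
                 n = sum(stats::complete.cases(x))),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Pearson correlation matrix (", x$use, " observations)\n", sep = "")
  print(round(x$r, 2))
  invisible(x)
}

#' Leverage (hat) values of a design matrix
#'
#' Diagonal of the projection matrix `X (X'X)^-1 X'`. Leverages lie in
#' (0, 1] and sum to the number of fitted parameters.
#'
#' @param design Numeric design matrix, including the intercept column if
#'   the model has one.
#' @return Numeric vector of hat values.
#' @export
leverage_values <- function(design) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop_lfer("design matrix is rank deficient")
  rowSums(qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]^2)
}

#' Williams-plot applicability-domain classification
#'
#' The applicability domain of a QSPR calibration is screened with a
#' Williams plot: standardized residuals against leverage. A record is
#' flagged out-of-domain when its standardized residual exceeds
#' `residual_bound` in magnitude (response outlier) or its leverage exceeds
#' `leverage_threshold` (descriptor-space outlier). Residuals are
#' internally studentized by default, `e_i / (s sqrt(1 - h_ii))` with
#' `s^2 = SSE/(n - p - 1)`; `residual_type = "external"` uses the
#' leave-one-out variance estimate instead.
#'
#' @param fit An [fit_ols()] result.
#' @param leverage_threshold Leverage cutoff h*; default `3 (p + 1) / n`.
#'   Published analyses of the built-in calibrations used a fixed 0.06.
#' @param residual_bound Standardized-residual cutoff (default 2).
#' @param residual_type `"internal"` (default) or `"external"`
#'   studentization.
#' @return Data.frame of class `domain_diagnostics`: `id`, `leverage`,
#'   `std_residual`, `high_leverage`, `residual_outlier`, `in_domain`;
#'   thresholds as attributes.
#' @export
williams_classification <- function(fit, leverage_threshold = NULL,
                                    residual_bound = 2,
                                    residual_type = c("internal", "external")) {
  stopifnot(inherits(fit, "lfer_fit"))
  residual_type <- match.arg(residual_type)
  h <- fit$leverage
  e <- fit$residuals
  n <- fit$n
  n_par <- sum(!fit$dropped)
  leverage_threshold <- leverage_threshold %||% (3 * n_par / n)
  s2 <- fit$sigma2
  std <- numeric(n)
  at_one <- h >= 1 - 1e-12
  if (any(at_one)) {
    warning("record(s) with leverage ~1 flagged with infinite residual: ",
            paste(names(h)[at_one], collapse = ", "), call. = FALSE)
  }
  if (s2 < 1e-20) {
    # an (essentially) perfect fit: residual scale is zero, nothing is a
    # response outlier
    std <- numeric(n)
  } else if (residual_type == "internal") {
    std <- e / sqrt(s2 * (1 - h))
  } else {
    # external: variance estimated without record i
    s2_i <- (fit$df_res * s2 - e^2 / (1 - h)) / (fit$df_res - 1)
    std <- e / sqrt(s2_i * (1 - h))
  }
  std[at_one] <- sign(e[at_one]) * Inf
  out <- data.frame(
    id = names(h), leverage = unname(h), std_residual = unname(std),
    high_leverage = unname(h > leverage_threshold),
    residual_outlier = unname(abs(std) > residual_bound),
    stringsAsFactors = FALSE
  )
  out$in_domain <- !(out$high_leverage | out$residual_outlier)
  attr(out, "leverage_threshold") <- leverage_threshold
  attr(out, "residual_bound") <- residual_bound
  attr(out, "residual_type") <- residual_type
  class(out) <- c("domain_diagnostics", "data.frame")
  out
}

#' Draw a Williams plot
#'
#' @param diagnostics A [williams_classification()] result.
#' @param ... Passed to [plot()].
#' @export
williams_plot <- function(diagnostics, ...) {
  stopifnot(inherits(diagnostics, "domain_diagnostics"))
  h_star <- attr(diagnostics, "leverage_threshold")
  bound <- attr(diagnostics, "residual_bound")
  plot(diagnostics$leverage, diagnostics$std_residual,
       xlab = "leverage (hat value)", ylab = "standardized residual",
       pch = ifelse(diagnostics$in_domain, 1, 19),
       col = ifelse(diagnostics$in_domain, "black", "red"), ...)
  graphics::abline(h = c(-bound, bound), col = "orange", lty = 2)
  graphics::abline(v = h_star, col = "darkgreen", lty = 2)
  flagged <- !diagnostics$in_domain
  if (any(flagged)) {
    graphics::text(diagnostics$leverage[flagged],
                   diagnostics$std_residual[flagged],
                   labels = diagnostics$id[flagged], pos = 4, cex = 0.7)
  }
  invisible(diagnostics)
}
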