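# Shared fixture builders and independent oracles.

# Tiny table whose response is exactly affine in the predictors.
exact_table <- function(n = 8, lambda = c(0.851, -0.092, -1.080)) {
  set.seed(42)
  df <- data.frame(
    id = sprintf("c%02d", seq_len(n)),
    logKow = seq(1.5, 6, length.out = n),
    logKaw = seq(-8, 2, length.out = n) * rep(c(1, -0.5), length.out = n)
  )
  df$logK_combined_structural_protein <-
    lambda[1] * df$logKow + lambda[2] * df$logKaw + lambda[3]
  chem_table(df)
}

# Hand-checkable 4-point regression fixture: known solution
# (b0, b1, b2) = (-0.25, 1.5, 1.5), R2 = 18/19, RMSE(n) = 0.25.
four_point_fixture <- function() {
  data.frame(id = letters[1:4],
             x1 = c(0, 1, 0, 1), x2 = c(0, 0, 1, 1), y = c(0, 1, 1, 3))
}

# Independent OLS oracle: textbook normal equations, no shared code with
# fit_ols (which goes through QR).
normal_equations_oracle <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- drop(X %*% b)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  list(coefficients = drop(b), r2 = 1 - sse / sst,
       rmse_n = sqrt(sse / length(y)),
       leverage = diag(X %*% solve(t(X) %*% X) %*% t(X)))
}

# Two-pass Pearson correlation oracle (explicit centered sums).
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Two columns whose sample Pearson correlation is exactly r: built from an
# orthonormalized pair of centered vectors.
exact_correlation_matrix <- function(r, n = 12) {
  set.seed(7)
  u <- rnorm(n); v <- rnorm(n)
  u <- u - mean(u); u <- u / sqrt(sum(u^2))
  v <- v - mean(v) - sum((v - mean(v)) * u) * u
  v <- v / sqrt(sum(v^2))
  cbind(x = u, y = r * u + sqrt(1 - r^2) * v)
}

# CSV writer for reader tests.
write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
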