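test_that("noise-free data is recovered exactly", {
  set.seed(2)
  df <- data.frame(id = as.character(1:5), x1 = c(0, 1, 2, 3, 5),
                   x2 = c(1, -1, 0, 2, 1))
  df$y <- 2 * df$x1 + 0 * df$x2 + 1
  fit <- fit_ols(df, "y", c("x1", "x2"))
  expect_equal(unname(fit$coefficients),
               c(1, 2, 0), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
})

test_that("fit_ols agrees with the normal-equations oracle on the 4-point fixture", {
  df <- four_point_fixture()
  fit <- fit_ols(df, "y", c("x1", "x2"))
  X <- cbind(1, df$x1, df$x2)
  oracle <- normal_equations_oracle(X, df$y)
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-9)
  expect_equal(unname(fit$coefficients), c(-0.25, 1.5, 1.5),
               tolerance = 1e-9)
  expect_equal(fit$r2, 0.947368, tolerance = 1e-6)
  expect_equal(fit$rmse, 0.25, tolerance = 1e-9)      # sqrt(SSE/n)
  expect_equal(unname(fit$leverage), unname(oracle$leverage),
               tolerance = 1e-9)
})

test_that("fit_ols matches the oracle on random small instances", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    p <- sample(1:2, 1)
    X <- matrix(rnorm(n * p), n, p)
    df <- data.frame(id = as.character(seq_len(n)), X)
    names(df)[-1] <- paste0("x", seq_len(p))
    df$y <- rnorm(n)
    fit <- fit_ols(df, "y", paste0("x", seq_len(p)))
    oracle <- normal_equations_oracle(cbind(1, X), df$y)
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-9)
    expect_equal(fit$r2, oracle$r2, tolerance = 1e-9)
  }
})

test_that("fit statistics satisfy their defining identities", {
  spec <- generator_spec(n = 51, noise_sigma = 0.3, seed = 14)
  tab <- generate_observations(generate_chemicals(spec), spec)
  fit <- fit_ols(tab, "combined_structural_protein")
  # F recomputed from (R2, n, p)
  expect_equal(fit$f_stat,
               (fit$r2 / fit$p) / ((1 - fit$r2) / (fit$n - fit$p - 1)),
               tolerance = 1e-9)
  expect_equal(fit$adj_r2,
               1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - fit$p - 1),
               tolerance = 1e-12)
  expect_lte(fit$adj_r2, fit$r2)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
  expect_equal(sum(fit$leverage), fit$p + 1, tolerance = 1e-9)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-9)
  # analytic SEs agree with lm's
  lmfit <- stats::lm(logK_combined_structural_protein ~ logKow + logKaw,
                     data = as.data.frame(tab))
  expect_equal(unname(fit$analytic_se),
               unname(summary(lmfit)$coefficients[, "Std. Error"]),
               tolerance = 1e-9)
})

test_that("degenerate designs are rejected with named columns", {
  df <- data.frame(id = as.character(1:6), x1 = 1:6, x2 = 2 * (1:6),
                   y = rnorm(6))
  expect_error(fit_ols(df, "y", c("x1", "x2")), "rank deficient")
  expect_error(fit_ols(df[1:3, ], "y", c("x1", "x2")), "at least")
  expect_error(fit_ols(df, "nope", "x1"), "not found")
})

test_that("bootstrap SEs vanish on exact data and are seed-deterministic", {
  fit <- fit_ols(exact_table(10), "combined_structural_protein")
  se <- bootstrap_coefficient_se(fit, replicates = 50, seed = 1)
  expect_true(all(se < 1e-8))
  spec <- generator_spec(n = 30, noise_sigma = 0.3, seed = 5)
  tab <- generate_observations(generate_chemicals(spec), spec)
  fit2 <- fit_ols(tab, "combined_structural_protein")
  s1 <- bootstrap_coefficient_se(fit2, replicates = 100, seed = 99)
  s2 <- bootstrap_coefficient_se(fit2, replicates = 100, seed = 99)
  expect_identical(s1, s2)
  s3 <- bootstrap_coefficient_se(fit2, replicates = 100, seed = 100)
  expect_false(identical(s1, s3))
})

test_that("bootstrap SEs approach analytic SEs at moderate n", {
  spec <- generator_spec(n = 200, noise_sigma = 0.3, seed = 11)
  tab <- generate_observations(generate_chemicals(spec), spec)
  fit <- fit_ols(tab, "combined_structural_protein")
  se <- bootstrap_coefficient_se(fit, replicates = 500, seed = 8)
  rel <- abs(se - fit$analytic_se[names(se)]) / fit$analytic_se[names(se)]
  expect_true(all(rel < 0.15))
})

test_that("backward elimination drops only insignificant terms and is idempotent", {
  # strong model: nothing dropped
  spec <- generator_spec(n = 100, noise_sigma = 0.2, seed = 6)
  tab <- generate_observations(generate_chemicals(spec), spec)
  strong <- fit_ols(tab, "combined_structural_protein")
  kept <- drop_insignificant_terms(strong)
  expect_equal(kept$coefficients, strong$coefficients)
  expect_false(any(kept$dropped))

  # pure-noise predictor is eliminated; the real coefficients survive
  tab2 <- as.data.frame(tab)
  set.seed(60)
  tab2$junk <- rnorm(nrow(tab2))
  fit2 <- fit_ols(tab2, "logK_combined_structural_protein",
                  c("logKow", "logKaw", "junk"))
  red <- drop_insignificant_terms(fit2)
  expect_true(red$dropped[["junk"]])
  expect_identical(red$coefficients[["junk"]], 0)
  expect_equal(red$coefficients[c("logKow", "logKaw")],
               strong$coefficients[c("logKow", "logKaw")],
               tolerance = 0.05)
  # idempotent
  again <- drop_insignificant_terms(red)
  expect_equal(again$coefficients, red$coefficients)
  expect_equal(again$dropped, red$dropped)
})

test_that("a statistically-zero intercept is excluded and reported as exactly 0", {
  # generating model has no intercept, mimicking the serum-albumin case
  spec <- generator_spec(n = 80, noise_sigma = 0.3,
                         true_coefficients = c(0.788, -0.053, 0), seed = 1)
  tab <- generate_observations(generate_chemicals(spec), spec, phase = "bsa")
  fit <- fit_ols(tab, "bsa")
  red <- drop_insignificant_terms(fit)
  expect_true(red$dropped[["(Intercept)"]])
  expect_identical(red$coefficients[["(Intercept)"]], 0)
  expect_false(red$include_intercept)
  expect_false(any(red$dropped[c("logKow", "logKaw")]))
})

test_that("coefficient z-comparison matches hand arithmetic and is antisymmetric", {
  mk <- function(b, se) {
    fit <- fit_ols(four_point_fixture(), "y", c("x1", "x2"))
    fit$coefficients[["x1"]] <- b
    fit$analytic_se[["x1"]] <- se
    fit
  }
  same <- compare_coefficients_z(mk(0.9, 0.05), mk(0.9, 0.05))
  expect_equal(same$z[same$term == "x1"], 0)
  expect_false(any(same$significant[same$term == "x1"]))

  cmp <- compare_coefficients_z(mk(0.9, 0.05), mk(0.8, 0.05))
  expect_equal(cmp$z[cmp$term == "x1"], 1.414, tolerance = 1e-3)
  expect_false(cmp$significant[cmp$term == "x1"])

  cmp2 <- compare_coefficients_z(mk(1.0, 0.05), mk(0.7, 0.05))
  expect_equal(cmp2$z[cmp2$term == "x1"], 4.243, tolerance = 1e-3)
  expect_true(cmp2$significant[cmp2$term == "x1"])

  # swap flips signs
  fwd <- compare_coefficients_z(mk(1.0, 0.05), mk(0.7, 0.05))
  rev <- compare_coefficients_z(mk(0.7, 0.05), mk(1.0, 0.05))
  expect_equal(fwd$z, -rev$z)
})

test_that("parameter recovery stays within 3 analytic SEs of the truth", {
  hits <- 0L
  reps <- 60L
  for (r in seq_len(reps)) {
    spec <- generator_spec(n = 500, noise_sigma = 0.3, seed = 1000 + r)
    tab <- generate_observations(generate_chemicals(spec), spec)
    fit <- fit_ols(tab, "combined_structural_protein")
    truth <- c(`(Intercept)` = -1.080, logKow = 0.851, logKaw = -0.092)
    ok <- abs(fit$coefficients[names(truth)] - truth) <=
      3 * fit$analytic_se[names(truth)]
    hits <- hits + all(ok)
  }
  expect_gte(hits / reps, 0.95)
})
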