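---
title: "Two-parameter LFERs for protein, lipid and tissue partitioning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-parameter LFERs for protein, lipid and tissue partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfer2p)
```

## The model and its assumptions

A linear free energy relationship (LFER) asserts that the free energy of
transferring a solute between two phases — and hence the log of its
partition coefficient — is a linear function of solute properties. The
poly-parameter (pp-LFER) formulation uses six Abraham solute descriptors
(E, S, A, B, V, L) against phase-specific system coefficients; it is
accurate but requires descriptors that exist for fewer than ~8000
chemicals. The two-parameter form implemented here replaces the
six-descriptor interaction space with two macroscopic, widely tabulated
quantities:

$$\log K_{\mathrm{phase\text{-}water}} =
  \lambda_1 \log K_{\mathrm{ow}} + \lambda_2 \log K_{\mathrm{aw}} +
  \lambda_3$$

log *K*~ow~ carries the hydrophobicity signal; log *K*~aw~ — the ratio of
volatility to aqueous solubility — acts largely as a proxy for
hydrogen-bonding interactions that octanol under-represents. The
dimensionality analysis tools in this package (standardized PCA with
square cosines, Pearson matrices) exist to make that argument
quantitative on a user's own calibration table: if the response's
information is concentrated in the first two principal dimensions and
those dimensions are well represented by log *K*~ow~ and log *K*~aw~, a
two-parameter model is justified.

Assumptions worth keeping in mind:

* **Neutral species only.** Nothing corrects for ionization; predictions
  for ionizable chemicals (acidic PFAS, phenols at high pH, amines) can
  be off by orders of magnitude.
* **Equilibrium partitioning.** The multiphase model is a thermodynamic
  mixture model, not a kinetic/PBPK model.
* **Linearity and additivity.** Sorption is assumed concentration-
  independent and phase capacities additive.

All partition coefficients are base-10 logarithms of dimensionless
concentration ratios.

## Built-in calibrations

`get_2p_coefficients()` exposes six published calibrations (chicken,
fish and combined structural protein; bovine serum albumin; phospholipid;
storage lipid) exactly as reported, together with their bootstrap-derived
standard errors and regression statistics. The same constants are frozen
in `inst/extdata/coefficients_2p.json`, and a test asserts the two copies
agree digit for digit. The serum-albumin set carries `lambda3 = 0` with
`intercept_dropped = TRUE`: its fitted intercept was statistically
equivalent to zero, so the term was excluded and the regression repeated —
the protocol `drop_insignificant_terms()` automates (backward elimination,
two-sided t-test, alpha = 0.05).

The combined structural-protein set was produced by averaging chicken and
fish observations for chemicals present in both source datasets.
`average_protein_datasets()` implements this with a **union policy**:
chemicals observed in only one species are retained with their single
value. The source datasets have n = 46 and 45 but the combined
calibration has n = 51, which an intersection could not produce; the
union is the only simple rule consistent with those counts, and it
maximizes the chemical diversity of the combined set.
`bland_altman()` provides the agreement analysis used to justify pooling
two measurement series in the first place.

## Fitting and its statistics

`fit_ols()` is plain multiple linear regression (QR-based, no weighting,
no regularization — deliberately, since nonlinear/ML regressors defeat
the interpretability that motivates an LFER). Statistics follow the
textbook definitions: R² = 1 − SSE/SST with SST centered (also for
no-intercept models, so R² stays comparable across the two cases);
Adj R² = 1 − (1 − R²)(n − 1)/df~res~; F = (R²/p)/((1 − R²)/df~res~).

Two reporting conventions are genuinely ambiguous in the LFER literature
and are resolved as follows:

* **RMSE denominator.** `rmse` is √(SSE/n), the prediction-error
  convention usual where RMSE is quoted alongside a separately
  df-corrected Adj R²; the df-corrected √(SSE/df~res~) is always
  available as `rmse_df`.
* **Coefficient uncertainty.** `bootstrap_coefficient_se()` reports the
  standard deviation of the coefficients over case-bootstrap refits
  (1000 resamples at full n by default), matching how the built-in
  calibrations' "±SE" values were generated; the analytic OLS standard
  errors are always reported alongside, and the two agree within ~15%
  at moderate n, which a test verifies.

`compare_coefficients_z()` tests whether two calibrations (say, a
hold-out refit vs. the full-data fit) differ: z = (b₁ − b₂)/√(SE₁² + SE₂²)
against a 1.96 threshold.

## Validation protocol

All resampling is seed-deterministic and independent of input row order:
ids are sorted canonically, then shuffled with the seed.

* `holdout_split()` — default 20% test / 80% train. (The conventional
  phrasing "training-to-testing ratio" is direction-ambiguous in parts of
  the literature; this package always trains on the larger side by
  default and the fraction is a parameter.) Test size is
  round-half-away-from-zero of n·fraction, which is platform-stable.
* `kfold_cv()` — round-robin folds after a seeded shuffle; `repeats`
  re-randomizes the folds and pools all k·repeats scores. k = 5 is the
  default; k = 10 is equally conventional and one keystroke away.
* The CV **score is the held-out coefficient of determination**
  (1 − SS~err~/SS~tot~ around the held-out mean), not a squared
  correlation — the Q² convention, and what "mean score" means
  throughout.
* `loocv()` — PRESS by the exact hat-matrix shortcut
  Σ(e~i~/(1 − h~ii~))², with an explicit n-refit loop available; a test
  requires the two to agree to 1e−9.
* `bootstrap_validation()` — resamples of size round(n·fraction) (default
  50%) with replacement, scored on the full table; 1000 replicates by
  default.

## Applicability domain

`williams_classification()` flags records with |standardized residual| > 2
(response outlier) or leverage above a threshold (descriptor-space
outlier). Residuals are internally studentized, e/(s√(1 − h)) with
s² = SSE/(n − p − 1) — the pragmatic middle ground where sources say
"Studentized" and "standardized" interchangeably — with externally
studentized residuals behind an option. The default leverage threshold is
the classic 3(p + 1)/n; a fixed cutoff (published analyses of the
built-in calibrations used 0.06) can be supplied explicitly. Perfect fits
(zero residual variance) are classified as entirely in-domain rather than
0/0.

## PCA conventions

`pca_analysis()` eigen-decomposes the correlation matrix by default:
the analyzed matrices mix log partition coefficients with Abraham
descriptors on very different scales, and square-cosine plots presume
standardized variables. Variable cos² values are squared
variable–component correlations rescaled to sum to one per variable;
eigenvector signs are fixed by making each component's
largest-magnitude loading positive, so loadings are reproducible across
platforms. Zero-variance columns and missing cells are hard errors with
named offenders, never silently dropped.

## Multiphase partitioning

The tissue model adds phase capacities linearly,
K~tissue~ = f~water~ + Σ f~phase~·10^{log K~phase~}, with the aqueous
phase's capacity fixed at 1 — the standard equilibrium mixture
formulation behind organ:plasma distribution ratios, per-phase load
fractions (f~i~K~i~/Σf~j~K~j~) and milk-water partitioning. Fractions are
interpreted as mass fractions with partition coefficients on a matching
basis; blood, plasma and milk are ordinary compositions with no special-
case code.

The shipped `tissue_compositions_synthetic.csv` is **synthetic**: a set
of illustrative, order-of-magnitude mammalian compositions assembled so
examples and tests run self-contained. It is not a transcription of any
published composition table, and quantitative organ-distribution work
should replace it (any CSV/YAML/JSON file with the same columns works).
For milk, dissolved lactose and minerals are lumped into the aqueous
phase so fractions close to one. Compositions whose fractions sum to
1 ± 0.02 (literature rounding) are renormalized with a warning; larger
deviations are errors.

## The synthetic-data generator

`generator_spec()` encodes the study conditions the generator emulates:
uniform marginals over the combined structural-protein calibration
ranges (log *K*~ow~ 1.4–6.1, log *K*~aw~ −8.6–2.1; Abraham descriptor
ranges available too, and the wider BSA ranges via `bsa_ranges()`), an
optional Gaussian-copula correlation between the two predictors (latent
correlation 2·sin(πr/6) so the uniform margins hit the target Pearson r),
and an additive Gaussian noise model around a true affine 2p-LFER with
default truth (0.851, −0.092, −1.080) and residual SD 0.3 log units —
the scale of the published calibration RMSEs. Uniform marginals are the
honest choice where only ranges are stated; the generator makes no
attempt to mimic chemical-class clustering or descriptor
intercorrelations beyond the single correlation knob, so passing tests
demonstrate statistical correctness of the machinery, not performance on
real chemical space.

One global seed fans out into per-stage substreams (via an
order-sensitive polynomial hash of the stage label), so adding an
observation stage never perturbs the chemical draws, and replicate
streams in simulation experiments are guaranteed distinct.

`parameter_recovery_experiment()` closes the loop: at n = 500, noise 0.3
and 200 replicates, OLS recovers the generating coefficients with
|bias| < 0.01 and ~95% CI coverage, which the test suite and the
acceptance script both verify.

## Numerical choices and degenerate inputs

* Rank-deficient designs error with the collinear columns named, both at
  fit time and per bootstrap resample (degenerate resamples are redrawn,
  with an error once redraws exceed 10%).
* Leverage exactly 1 (an interpolation point) is an error in LOOCV and an
  infinite-residual warning in domain classification.
* CSV ingestion is strict: duplicate ids, missing id columns and
  non-numeric cells are hard errors with row/column context; empty cells
  are missing values; read→write→read round-trips are exact.
* Problem sizes in the tests and the acceptance script (n = 51
  calibration tables, n = 500 recovery runs, 200 replicates, 1000
  bootstrap replicates) mirror the calibration-set scale while keeping
  every check fast enough to run routinely.

## Known limitations

* No ionization handling; ionizable PFAS and other charged species are
  outside the model's domain.
* pp-LFER system coefficients are not shipped; users must supply them.
* The shipped tissue compositions are illustrative stand-ins (see above),
  so absolute organ-distribution numbers from the examples are
  demonstrations, not predictions.
* Extrapolation beyond the calibration descriptor ranges is exactly what
  the Williams plot is there to catch — chemicals at extreme
  hydrophobicity or volatility are flagged, and their predictions should
  be treated with caution.
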