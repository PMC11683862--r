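mixed_comp <- function() {
  tissue_composition("demo", f_water = 0.7, f_storage_lipid = 0.2,
                     f_structural_protein = 0.1)
}
mixed_ks <- c(storage_lipid = 3, structural_protein = 2)

test_that("tissue_k satisfies the single-phase identities and the hand example", {
  pure_water <- tissue_composition("water", f_water = 1)
  expect_equal(tissue_k(pure_water, c()), 0)

  pure_protein <- tissue_composition("protein", f_water = 0,
                                     f_structural_protein = 1)
  expect_equal(tissue_k(pure_protein, c(structural_protein = 2)), 2)

  # log10(0.7 + 0.2*10^3 + 0.1*10^2) = log10(210.7)
  expect_equal(tissue_k(mixed_comp(), mixed_ks), log10(210.7),
               tolerance = 1e-12)
  expect_equal(tissue_k(mixed_comp(), mixed_ks), 2.3236, tolerance = 1e-4)
})

test_that("missing phase log K values are reported by phase name", {
  expect_error(tissue_k(mixed_comp(), c(storage_lipid = 3)),
               "structural_protein")
  # phase synonyms are accepted in the log K map
  expect_equal(tissue_k(mixed_comp(), c(lw = 3, pw = 2)),
               tissue_k(mixed_comp(), mixed_ks))
})

test_that("composition fractions are validated and renormalized", {
  expect_error(tissue_composition("bad", 0.5, 0.1), "sum to")
  expect_error(tissue_composition("neg", 1.1, -0.1), "non-negative")
  expect_warning(c2 <- tissue_composition("rounded", 0.69, 0.2, 0, 0.1, 0),
                 "renormalizing")
  expect_equal(sum(c2$fractions), 1, tolerance = 1e-12)
})

test_that("distribution ratios are differences of tissue log Ks and antisymmetric", {
  comp <- mixed_comp()
  expect_equal(distribution_ratio(comp, comp, mixed_ks), 0)
  pure_water <- tissue_composition("water", f_water = 1)
  expect_equal(distribution_ratio(comp, pure_water, mixed_ks),
               tissue_k(comp, mixed_ks))
  set.seed(31)
  for (i in 1:10) {
    f <- stats::runif(5); f <- f / sum(f)
    a <- tissue_composition("a", f[1], f[2], f[3], f[4], f[5])
    g <- stats::runif(5); g <- g / sum(g)
    b <- tissue_composition("b", g[1], g[2], g[3], g[4], g[5])
    ks <- c(storage_lipid = runif(1, -1, 5), phospholipid = runif(1, -1, 5),
            structural_protein = runif(1, -1, 5), albumin = runif(1, -1, 5))
    expect_equal(distribution_ratio(a, b, ks), -distribution_ratio(b, a, ks),
                 tolerance = 1e-12)
  }
})

test_that("phase loads close to one and match the two-term closure", {
  loads <- phase_loads(mixed_comp(), mixed_ks)
  expect_equal(sum(loads), 1, tolerance = 1e-9)
  expect_equal(loads[["storage_lipid"]], 200 / 210.7, tolerance = 1e-9)
  expect_equal(loads[["storage_lipid"]], 0.9492, tolerance = 1e-4)

  # single non-water phase: load = f K / (f_water + f K)
  comp <- tissue_composition("duo", f_water = 0.9, f_albumin = 0.1)
  l <- phase_loads(comp, c(albumin = 1.5))
  expect_equal(l[["albumin"]],
               0.1 * 10^1.5 / (0.9 + 0.1 * 10^1.5), tolerance = 1e-12)

  set.seed(77)
  for (i in 1:10) {
    f <- stats::runif(5); f <- f / sum(f)
    comp <- tissue_composition("r", f[1], f[2], f[3], f[4], f[5])
    ks <- stats::setNames(runif(4, -2, 6),
                          c("storage_lipid", "phospholipid",
                            "structural_protein", "albumin"))
    expect_equal(sum(phase_loads(comp, ks)), 1, tolerance = 1e-9)
  }
})

test_that("tissue_k is monotone in each phase log K and bounded by the extremes", {
  comp <- mixed_comp()
  ks_lo <- mixed_ks
  for (ph in names(mixed_ks)) {
    ks_hi <- ks_lo
    ks_hi[ph] <- ks_hi[ph] + 1
    expect_gt(tissue_k(comp, ks_hi), tissue_k(comp, ks_lo))
  }
  set.seed(41)
  for (i in 1:10) {
    f <- stats::runif(5); f <- f / sum(f)
    comp <- tissue_composition("r", f[1], f[2], f[3], f[4], f[5])
    ks <- stats::setNames(runif(4, -3, 6),
                          c("storage_lipid", "phospholipid",
                            "structural_protein", "albumin"))
    tk <- tissue_k(comp, ks)
    expect_gte(tk, min(0, ks) - 1e-9)
    expect_lte(tk, max(c(0, ks)) + 1e-9)  # capacities are convex mixtures
  }
})

test_that("milk partitioning delegates to the multiphase model", {
  watery_milk <- tissue_composition("skim", f_water = 1)
  expect_equal(milk_k(c(), milk_composition = watery_milk), 0)

  # fat-dominated milk approaches logKlw + log10(f_sl) for strongly
  # lipophilic chemicals
  fatty <- tissue_composition("cream", f_water = 0.2, f_storage_lipid = 0.8)
  gap <- sapply(c(4, 6, 8), function(k) {
    milk_k(c(storage_lipid = k), milk_composition = fatty) -
      (k + log10(0.8))
  })
  expect_true(all(gap > 0))          # water capacity only adds
  expect_true(all(diff(gap) < 0))    # and vanishes as Klw grows
  expect_lt(gap[3], 1e-8)

  # shipped synthetic composition file loads and covers the milk row
  comps <- load_tissue_compositions()
  expect_true(all(c("plasma", "muscle", "liver", "cow_milk") %in%
                    names(comps)))
  ks <- c(storage_lipid = 3.07, phospholipid = 2.96,
          structural_protein = 1.52, albumin = 2.36)
  m <- milk_k(ks, milk_composition = comps$cow_milk)
  expect_true(is.finite(m) && m > 0)
})

test_that("end-to-end: 2p-LFER predictions parametrize organ distribution ratios", {
  # benzo[a]pyrene-like input, all four phase Ks from the built-in registry
  logKow <- 6.13; logKaw <- -4.73
  ks <- sapply(c(structural_protein = "combined_structural_protein",
                 albumin = "bsa", storage_lipid = "storage_lipid",
                 phospholipid = "phospholipid"),
               function(ph) predict_2p(logKow, logKaw,
                                       get_2p_coefficients(ph)))
  names(ks) <- c("structural_protein", "albumin", "storage_lipid",
                 "phospholipid")
  comps <- load_tissue_compositions()
  ratio <- distribution_ratio(comps$adipose, comps$plasma, ks)
  # a strongly lipophilic chemical concentrates in fatty tissue
  expect_gt(ratio, 1)
  loads <- phase_loads(comps$adipose, ks)
  expect_gt(loads[["storage_lipid"]], 0.9)
})
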