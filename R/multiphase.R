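#' Tissue compositions for multiphase equilibrium partitioning
#'
#' A `tissue_composition` holds the mass fractions of the five sorptive
#' phases the multiphase model distinguishes: water, storage lipid
#' (triglycerides), phospholipid (membrane lipid), structural protein
#' (muscle-type) and albumin (serum protein). Fractions must be
#' non-negative and sum to 1 within [0.98, 1.02] (literature composition
#' tables are rounded); outside exact unity the fractions are renormalized
#' with a warning so that downstream phase loads close exactly.
#'
#' @param tissue Tissue name.
#' @param f_water,f_storage_lipid,f_phospholipid,f_structural_protein,f_albumin
#'   Non-negative mass fractions.
#' @return An object of class `tissue_composition`.
#' @examples
#' plasma <- tissue_composition("plasma", f_water = 0.945,
#'   f_storage_lipid = 0.0023, f_phospholipid = 0.0016,
#'   f_structural_protein = 0.016, f_albumin = 0.035)
#' @export
tissue_composition <- function(tissue, f_water, f_storage_lipid = 0,
                               f_phospholipid = 0,
                               f_structural_protein = 0, f_albumin = 0) {
  f <- c(water = f_water, storage_lipid = f_storage_lipid,
         phospholipid = f_phospholipid,
         structural_protein = f_structural_protein, albumin = f_albumin)
  check_finite(unname(f), "phase fractions")
  if (any(f < 0)) stop_lfer("phase fractions must be non-negative")
  total <- sum(f)
  if (total < 0.98 || total > 1.02) {
    stop_lfer("phase fractions for '", tissue, "' sum to ",
              format(total), "; expected 1 within [0.98, 1.02]")
  }
  if (abs(total - 1) > 1e-9) {
    warning("phase fractions for '", tissue, "' sum to ", format(total),
            "; renormalizing to 1", call. = FALSE)
    f <- f / total
  }
  structure(list(tissue = tissue, fractions = f),
            class = "tissue_composition")
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat("Tissue composition:", x$tissue, "\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Load a table of tissue compositions
#'
#' Reads a CSV (columns `tissue, f_water, f_storage_lipid, f_phospholipid,
#' f_structural_protein, f_albumin`) or a YAML/JSON mapping
#' `tissue -> fractions` into a named list of [tissue_composition] objects.
#' The package ships a synthetic example file of representative mammalian
#' compositions at `system.file("extdata",
#' "tissue_compositions_synthetic.csv", package = "lfer2p")`; its values
#' are illustrative, not a published composition table, so for quantitative
#' work supply compositions from the toxicokinetic literature for your
#' species and tissues of interest.
#'
#' @param path File path; defaults to the shipped example file.
#' @return Named list of `tissue_composition` objects.
#' @export
load_tissue_compositions <- function(path = NULL) {
  path <- path %||% system.file("extdata",
                                "tissue_compositions_synthetic.csv",
                                package = "lfer2p", mustWork = TRUE)
  if (!file.exists(path)) stop_lfer("file not found: ", path)
  rows <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    lapply(names(raw), function(t) c(list(tissue = t), raw[[t]]))
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(names(raw), function(t) c(list(tissue = t), as.list(raw[[t]])))
  } else {
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  out <- lapply(rows, function(r) {
    tissue_composition(r$tissue, r$f_water, r$f_storage_lipid %||% 0,
                       r$f_phospholipid %||% 0,
                       r$f_structural_protein %||% 0, r$f_albumin %||% 0)
  })
  names(out) <- vapply(out, function(x) x$tissue, character(1))
  out
}

.resolve_phase_logK <- function(fractions, phase_logK) {
  phase_logK <- unlist(phase_logK)
  if (length(phase_logK)) {
    names(phase_logK) <- vapply(names(phase_logK), canonical_phase,
                                character(1))
  }
  needed <- setdiff(names(fractions)[fractions > 0], "water")
  # the structural-protein phase accepts any of the three protein
  # calibrations; prefer the combined one
  lookup <- function(phase) {
    if (phase %in% names(phase_logK)) return(phase_logK[[phase]])
    if (phase == "structural_protein") {
      for (alt in c("combined_structural_protein",
                    "chicken_structural_protein",
                    "fish_structural_protein")) {
        if (alt %in% names(phase_logK)) return(phase_logK[[alt]])
      }
    }
    if (phase == "albumin" && "bsa" %in% names(phase_logK)) {
      return(phase_logK[["bsa"]])
    }
    stop_lfer("no log K supplied for phase '", phase,
              "' which has non-zero fraction")
  }
  ks <- vapply(needed, lookup, numeric(1))
  if (length(ks)) check_finite(unname(ks), "phase log K values")
  ks
}

#' Tissue-water partition coefficient from phase composition
#'
#' The multiphase equilibrium model treats a tissue as a fraction-weighted
#' mixture of sorptive phases whose capacities add linearly:
#' \deqn{K_{tissue-water} = f_{water} + \sum_{phase} f_{phase}
#'   10^{\log K_{phase-water}},}
#' with the aqueous phase's capacity fixed at 1. Phase-water log K values
#' typically come from [predict_2p()] with the built-in calibrations.
#'
#' @param composition A [tissue_composition].
#' @param phase_logK Named numeric vector/list of log10 phase-water
#'   partition coefficients; names are phase names (synonyms accepted, so
#'   `pw`, `bsa`, `lw`, `phw` work). Every phase with non-zero fraction
#'   other than water must be covered.
#' @return log10 tissue-water partition coefficient (a single number).
#' @examples
#' comp <- tissue_composition("demo", f_water = 0.7,
#'                            f_storage_lipid = 0.2,
#'                            f_structural_protein = 0.1)
#' tissue_k(comp, c(storage_lipid = 3, structural_protein = 2))  # 2.3236
#' @export
tissue_k <- function(composition, phase_logK) {
  stopifnot(inherits(composition, "tissue_composition"))
  f <- composition$fractions
  ks <- .resolve_phase_logK(f, phase_logK)
  capacity <- f[["water"]] +
    sum(f[names(ks)] * 10^ks)
  log10(capacity)
}

#' Organ-to-reference distribution ratio
#'
#' log10 ratio of the equilibrium concentrations in an organ and a
#' reference tissue (conventionally plasma or blood), computed as the
#' difference of the two tissue-water log partition coefficients. The
#' reference is an ordinary [tissue_composition]; no special-casing of
#' blood or plasma. Antisymmetric under swapping organ and reference.
#'
#' @param organ,reference [tissue_composition] objects.
#' @inheritParams tissue_k
#' @return log10 organ:reference distribution ratio.
#' @export
distribution_ratio <- function(organ, reference, phase_logK) {
  tissue_k(organ, phase_logK) - tissue_k(reference, phase_logK)
}

#' Per-phase chemical load fractions within a tissue
#'
#' At equilibrium the fraction of the total chemical amount residing in
#' phase i is `f_i K_i / sum_j f_j K_j` (water's K is 1). These loads
#' reveal, e.g., whether a chemical's body burden sits in the lipids or in
#' the proteins of a tissue.
#'
#' @inheritParams tissue_k
#' @return Named numeric vector of class `phase_load` (water,
#'   storage_lipid, phospholipid, structural_protein, albumin) summing to
#'   1; phases with zero fraction carry zero load.
#' @export
phase_loads <- function(composition, phase_logK) {
  stopifnot(inherits(composition, "tissue_composition"))
  f <- composition$fractions
  ks <- .resolve_phase_logK(f, phase_logK)
  cap <- stats::setNames(rep(0, length(f)), names(f))
  cap["water"] <- f[["water"]]
  cap[names(ks)] <- f[names(ks)] * 10^ks
  structure(cap / sum(cap), class = "phase_load",
            tissue = composition$tissue)
}

#' Milk-water partition coefficient
#'
#' Milk is handled as one more multiphase mixture (aqueous phase carrying
#' the dissolved solids, milk fat as storage lipid, casein as structural
#' protein, whey protein as albumin), so this simply delegates to
#' [tissue_k()] with a milk composition record.
#'
#' @param milk_composition A [tissue_composition] describing milk; defaults
#'   to the `cow_milk` row of the shipped composition file.
#' @inheritParams tissue_k
#' @return log10 milk-water partition coefficient.
#' @export
milk_k <- function(phase_logK, milk_composition = NULL) {
  milk_composition <- milk_composition %||%
    load_tissue_compositions()[["cow_milk"]]
  tissue_k(milk_composition, phase_logK)
}
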