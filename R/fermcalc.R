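#' Fermentation record
#'
#' Bundles titers and the stoichiometric constants used by the closed-form
#' fermentation arithmetic.  The default molecular weights are the rounded
#' values (isobutanol 74 g/mol, glucose 180 g/mol) that reproduce printed
#' fermentation summaries exactly; exact masses can be supplied instead.
#'
#' @param titers named numeric, species -> titer in g/L.
#' @param glucose_consumed glucose consumed, g/L.
#' @param molecular_weights named numeric, g/mol.
#' @param nadph_per_isobutanol NADPH molecules per isobutanol (default 2:
#'   one in ketol-acid reductoisomerase, one in the aldehyde reduction).
#' @param nadph_per_glucose_via_gapdn NADPH per glucose routed through the
#'   NADP-dependent glyceraldehyde-3-phosphate dehydrogenase (2: one per
#'   triose).
#' @param theoretical_yield mol isobutanol per mol glucose used as divisor
#'   for percent-of-theoretical figures (default 1.0, the pathway maximum).
#' @return list of class `fermentation_record`.
#' @export
fermentation_record <- function(titers = c(),
                                glucose_consumed = NA_real_,
                                molecular_weights = c(isobutanol = 74,
                                                      glucose = 180),
                                nadph_per_isobutanol = 2,
                                nadph_per_glucose_via_gapdn = 2,
                                theoretical_yield = 1.0) {
  stopifnot(all(titers >= 0, na.rm = TRUE), all(molecular_weights > 0),
            nadph_per_isobutanol >= 1, nadph_per_glucose_via_gapdn >= 1)
  structure(list(titers = titers, glucose_consumed = glucose_consumed,
                 molecular_weights = molecular_weights,
                 nadph_per_isobutanol = nadph_per_isobutanol,
                 nadph_per_glucose_via_gapdn = nadph_per_glucose_via_gapdn,
                 theoretical_yield = theoretical_yield),
            class = "fermentation_record")
}

#' Percent change between two titers or rates
#' @param old baseline value (> 0).
#' @param new new value.
#' @return `100 (new - old) / old`.
#' @export
percent_change <- function(old, new) {
  if (any(old <= 0)) stop("baseline must be positive")
  100 * (new - old) / old
}

#' Convert a mass titer to molarity
#' @param grams_per_L titer in g/L.
#' @param mw molecular weight in g/mol.
#' @return concentration in mmol/L.
#' @export
molar_titer <- function(grams_per_L, mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  1000 * grams_per_L / mw
}

#' Fold ratio
#' @param numerator,denominator values; denominator must be positive.
#' @return `numerator / denominator`.
#' @export
ratio_fold <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  numerator / denominator
}

#' Glucose fraction required through the NADP-dependent GAPDH
#'
#' From an isobutanol titer gain, computes the share of consumed glucose
#' that must be catabolized through the NADPH-producing glyceraldehyde-
#' 3-phosphate dehydrogenase (GAPDN) to supply the extra NADPH:
#' NADPH demand = `nadph_per_isobutanol x (delta_titer / MW_isb)` mol/L,
#' glucose through GAPDN = demand / `nadph_per_glucose_via_gapdn`, reported
#' as percent of total consumed glucose (mol basis).
#'
#' @param delta_isobutanol_gL isobutanol titer increase, g/L.
#' @param glucose_consumed_gL total glucose consumed, g/L (> 0).
#' @param record a [fermentation_record()] carrying MWs and NADPH counts.
#' @return percent of consumed glucose.
#' @export
gapdn_glucose_fraction <- function(delta_isobutanol_gL, glucose_consumed_gL,
                                   record = fermentation_record()) {
  if (glucose_consumed_gL <= 0) stop("glucose consumed must be positive")
  mw <- record$molecular_weights
  nadph_mol <- record$nadph_per_isobutanol * delta_isobutanol_gL / mw[["isobutanol"]]
  glc_gapdn_mol <- nadph_mol / record$nadph_per_glucose_via_gapdn
  100 * glc_gapdn_mol / (glucose_consumed_gL / mw[["glucose"]])
}

#' Molar isobutanol yield on glucose
#'
#' @param isb_gL isobutanol titer, g/L.
#' @param glucose_gL glucose consumed, g/L (> 0).
#' @param record a [fermentation_record()].
#' @return list `yield_mol_mol` and `fraction_of_theoretical` (with the
#'   divisor used in `theoretical_yield`).
#' @export
molar_yield <- function(isb_gL, glucose_gL, record = fermentation_record()) {
  if (glucose_gL <= 0) stop("glucose consumed must be positive")
  mw <- record$molecular_weights
  y <- (isb_gL / mw[["isobutanol"]]) / (glucose_gL / mw[["glucose"]])
  list(yield_mol_mol = y,
       fraction_of_theoretical = y / record$theoretical_yield,
       theoretical_yield = record$theoretical_yield)
}

#' Labeled fermentation comparison report
#'
#' Computes the standard before/after fermentation summary between a
#' baseline and an engineered strain: percent titer changes per species,
#' molarity of the isobutanol gain (equivalently, with two NADPH per
#' isobutanol and two NADPH per glucose through GAPDN, the mol-basis NADPH
#' bookkeeping), and the GAPDN glucose fraction.
#'
#' @param baseline,engineered named numeric titer vectors (g/L) sharing at
#'   least the `isobutanol` entry.
#' @param glucose_consumed_gL glucose consumed by the engineered strain, g/L.
#' @param record a [fermentation_record()].
#' @return data.frame with columns `quantity`, `value`, `unit`.
#' @export
fermentation_report <- function(baseline, engineered, glucose_consumed_gL,
                                record = fermentation_record()) {
  shared <- intersect(names(baseline), names(engineered))
  rows <- lapply(shared, function(sp) {
    data.frame(quantity = paste0(sp, "_change"),
               value = percent_change(baseline[[sp]], engineered[[sp]]),
               unit = "%", stringsAsFactors = FALSE)
  })
  d_isb <- engineered[["isobutanol"]] - baseline[["isobutanol"]]
  rows <- c(rows, list(
    data.frame(quantity = "isobutanol_gain_molar",
               value = molar_titer(d_isb, record$molecular_weights[["isobutanol"]]),
               unit = "mmol/L", stringsAsFactors = FALSE),
    data.frame(quantity = "extra_nadph_demand",
               value = record$nadph_per_isobutanol *
                 molar_titer(d_isb, record$molecular_weights[["isobutanol"]]),
               unit = "mmol/L", stringsAsFactors = FALSE),
    data.frame(quantity = "gapdn_glucose_fraction",
               value = gapdn_glucose_fraction(d_isb, glucose_consumed_gL, record),
               unit = "%", stringsAsFactors = FALSE),
    data.frame(quantity = "isobutanol_yield",
               value = molar_yield(engineered[["isobutanol"]],
                                   glucose_consumed_gL, record)$yield_mol_mol,
               unit = "mol/mol", stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
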