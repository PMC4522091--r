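#' Flux map in molar percent of glucose uptake
#'
#' Expresses fluxes of an optimal state as `100 v / |v_basis|`, the molar
#' percentage of the (glucose) uptake basis -- the convention of central
#' metabolism flux maps.  Direction is carried by the sign of the entry;
#' the basis reaction itself reports 100 in magnitude.
#'
#' @param state an optimal [flux_state()].
#' @param model the corresponding `stoichiometric_model`.
#' @param basis_id basis exchange reaction id (glucose uptake).
#' @param panel reaction ids to report (default: all with nonzero flux).
#' @return list of class `flux_map`: `basis_id`, `basis_flux`, `entries`
#'   (data.frame `id`, `flux`, `percent`).
#' @export
flux_percentages <- function(state, model, basis_id, panel = NULL) {
  if (state$status != "optimal") stop("flux_percentages requires an optimal state")
  basis <- state$fluxes[basis_id]
  if (is.na(basis)) stop("unknown basis reaction: ", basis_id)
  if (abs(basis) < 1e-12) stop("zero basis flux: ", basis_id)
  if (is.null(panel)) panel <- names(state$fluxes)[abs(state$fluxes) > 1e-9]
  entries <- data.frame(id = panel,
                        flux = unname(state$fluxes[panel]),
                        percent = unname(100 * state$fluxes[panel] / abs(basis)),
                        stringsAsFactors = FALSE)
  structure(list(basis_id = basis_id, basis_flux = unname(basis),
                 entries = entries), class = "flux_map")
}

#' @export
print.flux_map <- function(x, ...) {
  cat("<flux_map> basis ", x$basis_id, " = ", format(x$basis_flux, digits = 6),
      " (100%)\n", sep = "")
  print(x$entries, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cofactor production/consumption balance sheet
#'
#' For the NADH and NADPH species of a state, reports total production
#' (flux-sum), per-consumer shares of consumption, the share recycled
#' through a named set of reactions (e.g. the lactate/ethanol fermentative
#' branches), and the transhydrogenase couplings: percent of NADPH
#' production carried by the transhydrogenase and percent of NADH
#' consumption (and, for reference, of NADH production) that it drains.
#'
#' @param state an optimal [flux_state()].
#' @param model the corresponding `stoichiometric_model`.
#' @param cof a [cofactor_spec()].
#' @param recycling_set reaction ids counted as fermentative NADH recycling.
#' @param transhydrogenase_id reaction id of the NADH -> NADPH
#'   transhydrogenase (`NULL` to skip those shares).
#' @return nested list, one element per cofactor (`nadh`, `nadph`), each with
#'   `total_production`, `producer_percent`, `consumer_percent`,
#'   `recycling_percent` (NADH), `thd_production_percent` (NADPH),
#'   `thd_consumption_percent` and `thd_of_production_percent` (NADH).
#' @export
cofactor_shares <- function(state, model, cof,
                            recycling_set = character(0),
                            transhydrogenase_id = NULL) {
  one <- function(met) {
    fs <- flux_sum(state, model, met)
    tot <- fs$total_production
    pct <- function(x) if (tot > 0) 100 * x / tot else 0 * x
    list(metabolite_id = met,
         total_production = tot,
         producer_percent = pct(fs$producers),
         consumer_percent = pct(fs$consumers),
         producers = fs$producers,
         consumers = fs$consumers)
  }
  nadh <- one(cof$nadh)
  nadph <- one(cof$nadph)
  nadh$recycling_percent <-
    sum(nadh$consumer_percent[names(nadh$consumer_percent) %in% recycling_set])
  if (!is.null(transhydrogenase_id)) {
    gp <- function(x, id) if (id %in% names(x)) unname(x[id]) else 0
    nadph$thd_production_percent <- gp(nadph$producer_percent, transhydrogenase_id)
    nadh$thd_consumption_percent <- gp(nadh$consumer_percent, transhydrogenase_id)
    # consumption shares are percentages of production (equal totals at
    # steady state), so this is also the share of NADH production drained
    nadh$thd_of_production_percent <- nadh$thd_consumption_percent
  }
  list(nadh = nadh, nadph = nadph)
}

#' Serialize a flux map as TSV
#' @param map a `flux_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_map_tsv <- function(map, path) {
  utils::write.table(map$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
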