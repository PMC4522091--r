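#' Knockout perturbation
#'
#' @param model a `stoichiometric_model`.
#' @param target_id reaction to silence; its bounds are set to `[0, 0]`.
#' @return the perturbed model.
#' @export
build_knockout <- function(model, target_id) {
  set_bounds(model, target_id, 0, 0)
}

#' Overexpression perturbation
#'
#' Fixes the target flux at `N`-fold its reference value by an equality
#' (bounds `[N v_ref, N v_ref]`).  Sign-preserving: a reaction running
#' backwards at reference is amplified in its own direction.
#'
#' @param model a `stoichiometric_model`.
#' @param target_id reaction to amplify.
#' @param N amplification factor.
#' @param reference a [flux_state()] supplying the reference flux.
#' @return the perturbed model.
#' @export
build_overexpression <- function(model, target_id, N, reference) {
  v_ref <- reference$fluxes[target_id]
  if (is.na(v_ref)) stop("no reference flux for ", target_id)
  if (abs(v_ref) < 1e-12)
    stop("overexpression undefined at zero flux (", target_id, ")")
  set_bounds(model, target_id, N * v_ref, N * v_ref)
}

#' Swap the cofactor pair of a reaction
#'
#' Returns a copy of the reaction's stoichiometry with NAD+ and NADP+
#' (and NADH and NADPH) interchanged, coefficients unchanged -- the
#' non-native oxidoreductase obtained by cofactor engineering.  Since the
#' members of each pair differ by the same phosphate group, the swap leaves
#' any elemental balance of the reaction intact.
#'
#' @param model a `stoichiometric_model`.
#' @param target_id reaction to swap; must touch exactly one cofactor pair.
#' @param cof a [cofactor_spec()].
#' @param suffix id suffix for the generated reaction (default `"_swap"`).
#' @return list with `id` (generated reaction id) and `stoichiometry`.
#' @export
swap_cofactor <- function(model, target_id, cof, suffix = "_swap") {
  s <- model$stoichiometry[[target_id]]
  if (is.null(s)) stop("unknown reaction: ", target_id)
  fp <- .cofactor_footprint(s, cof)
  if (fp$nad && fp$nadp)
    stop("dual_cofactor: ", target_id, " touches both cofactor pairs")
  if (!fp$nad && !fp$nadp)
    stop(target_id, " touches no cofactor pair")
  map <- stats::setNames(c(cof$nadp, cof$nadph, cof$nad, cof$nadh),
                         c(cof$nad, cof$nadh, cof$nadp, cof$nadph))
  nm <- names(s)
  hit <- nm %in% names(map)
  nm[hit] <- map[nm[hit]]
  names(s) <- nm
  list(id = paste0(target_id, suffix), stoichiometry = s)
}

#' Cofactor-swap perturbation
#'
#' Adds the swapped reaction, silences the native one (bounds `[0, 0]`) and
#' fixes the swapped flux at `M`-fold the native reference flux
#' (sign-preserving equality).
#'
#' @inheritParams swap_cofactor
#' @param M flux factor for the swapped reaction.
#' @param reference a [flux_state()] supplying the native reference flux.
#' @return the perturbed model; the generated id is in `attr(, "swap_id")`.
#' @export
build_swap <- function(model, target_id, M, reference, cof) {
  v_ref <- reference$fluxes[target_id]
  if (is.na(v_ref)) stop("no reference flux for ", target_id)
  if (abs(v_ref) < 1e-12)
    stop("cofactor swap undefined at zero flux (", target_id, ")")
  sw <- swap_cofactor(model, target_id, cof)
  i <- match(target_id, model$reactions$id)
  model <- add_reaction(model, sw$id,
                        paste0(model$reactions$name[i], " (cofactor swap)"),
                        sw$stoichiometry,
                        lower_bound = M * v_ref, upper_bound = M * v_ref,
                        genes = model$reactions$genes[i],
                        subsystem = model$reactions$subsystem[i],
                        notes = paste0("cofactor swap of ", target_id))
  model <- set_bounds(model, target_id, 0, 0)
  attr(model, "swap_id") <- sw$id
  model
}

#' Phenotypic fraction of a perturbation
#'
#' The ranking score weighting growth and production:
#' `f_PH = f_biomass * f_isobutanol^2` with
#' `f_biomass = mu_mod / mu_ref` and `f_isobutanol = v_mod / v_ref`.
#' The square emphasizes the production rate over growth, so a perturbation
#' that trades some growth for more product can still rank first.
#'
#' @param reference optimal [flux_state()] of the unperturbed model.
#' @param modified [flux_state()] of the perturbed model (from [moma()]).
#' @param product_id exchange reaction id of the product (isobutanol)
#'   whose flux enters `f_isobutanol`.
#' @return named list `f_biomass`, `f_isobutanol`, `f_ph`.
#' @export
f_ph <- function(reference, modified, product_id) {
  mu_ref <- reference$fluxes[reference$objective_id]
  v_ref <- reference$fluxes[product_id]
  if (is.na(mu_ref) || is.na(v_ref) || mu_ref <= 0 || v_ref <= 0)
    stop("reference rates must be positive")
  f_b <- unname(modified$fluxes[reference$objective_id] / mu_ref)
  f_i <- unname(modified$fluxes[product_id] / v_ref)
  list(f_biomass = f_b, f_isobutanol = f_i, f_ph = f_b * f_i^2)
}

#' Ratios from raw rates
#'
#' Convenience form of [f_ph()] taking the four rates directly, e.g. when
#' re-scoring published growth/production rate tables.
#'
#' @param mu_ref,v_ref reference growth and product rates (must be > 0).
#' @param mu_mod,v_mod rates of the modified strain/model.
#' @return named list `f_biomass`, `f_isobutanol`, `f_ph`.
#' @export
f_ph_rates <- function(mu_mod, v_mod, mu_ref, v_ref) {
  if (mu_ref <= 0 || v_ref <= 0) stop("reference rates must be positive")
  f_b <- mu_mod / mu_ref
  f_i <- v_mod / v_ref
  list(f_biomass = f_b, f_isobutanol = f_i, f_ph = f_b * f_i^2)
}

#' Run the full perturbation campaign
#'
#' For every candidate x applicable mode x grid point, builds the
#' perturbation ([build_knockout()], [build_overexpression()],
#' [build_swap()]), re-solves the network by [moma()] against the reference,
#' and scores the outcome with [f_ph()].  Per (candidate, mode) the record
#' with maximal `f_ph` over the grid is flagged `best`; output is sorted by
#' best-record `f_ph` descending with ties broken by reaction id.
#' Individual infeasible grid points are recorded with `status
#' = "infeasible"` and excluded from ranking; they never abort the campaign.
#'
#' @param model the (unperturbed) `stoichiometric_model`.
#' @param candidates a `candidate_set` from [filter_candidates()].
#' @param reference optimal [flux_state()] from [reference_state()].
#' @param cof a [cofactor_spec()].
#' @param product_id product exchange reaction id scored by [f_ph()].
#' @param grid_n overexpression factors (default 1.1 to 2.0 by 0.1).
#' @param grid_m cofactor-swap factors (default 0.1 to 2.0 by 0.1).
#' @param keep_grid keep all grid records (`TRUE`, default) or only the
#'   per-(target, mode) best.
#' @param extra_constraints bound overrides applied to every MOMA solve
#'   (the perturbation itself is encoded in the perturbed model).
#' @return data.frame of class `campaign_result` with columns `target_id`,
#'   `mode`, `factor`, `mu_mod`, `v_isb_mod`, `f_biomass`, `f_isobutanol`,
#'   `f_ph`, `status`, `best`.
#' @export
run_campaign <- function(model, candidates, reference, cof, product_id,
                         grid_n = seq(1.1, 2.0, by = 0.1),
                         grid_m = seq(0.1, 2.0, by = 0.1),
                         keep_grid = TRUE, extra_constraints = NULL) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (reference$status != "optimal") stop("reference must be optimal")
  cand <- candidates$candidates
  rows <- list()
  score_one <- function(target_id, mode, factor, pmodel) {
    st <- moma(pmodel, reference, extra_constraints)
    if (st$status != "optimal") {
      return(data.frame(target_id = target_id, mode = mode, factor = factor,
                        mu_mod = NA_real_, v_isb_mod = NA_real_,
                        f_biomass = NA_real_, f_isobutanol = NA_real_,
                        f_ph = NA_real_, status = st$status,
                        stringsAsFactors = FALSE))
    }
    sc <- f_ph(reference, st, product_id)
    data.frame(target_id = target_id, mode = mode, factor = factor,
               mu_mod = unname(st$fluxes[reference$objective_id]),
               v_isb_mod = unname(st$fluxes[product_id]),
               f_biomass = sc$f_biomass, f_isobutanol = sc$f_isobutanol,
               f_ph = sc$f_ph, status = "optimal", stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(cand))) {
    rid <- cand$id[i]
    modes <- strsplit(cand$modes[i], ",", fixed = TRUE)[[1]]
    for (mode in modes) {
      if (mode == "knockout") {
        rows[[length(rows) + 1]] <-
          score_one(rid, mode, NA_real_, build_knockout(model, rid))
      } else if (mode == "overexpression") {
        for (N in grid_n) {
          rows[[length(rows) + 1]] <-
            score_one(rid, mode, N, build_overexpression(model, rid, N, reference))
        }
      } else if (mode == "cofactor_swap") {
        for (M in grid_m) {
          rows[[length(rows) + 1]] <-
            score_one(rid, mode, M, build_swap(model, rid, M, reference, cof))
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(0), mode = character(0),
               factor = numeric(0), mu_mod = numeric(0), v_isb_mod = numeric(0),
               f_biomass = numeric(0), f_isobutanol = numeric(0),
               f_ph = numeric(0), status = character(0),
               stringsAsFactors = FALSE)
  # flag per-(target, mode) grid maximum, then rank groups
  out$best <- logical(nrow(out))
  if (nrow(out)) {
    key <- paste(out$target_id, out$mode)
    for (k in unique(key)) {
      idx <- which(key == k & out$status == "optimal")
      if (!length(idx)) next
      out$best[idx[which.max(out$f_ph[idx])]] <- TRUE
    }
    best_score <- stats::ave(ifelse(out$best, out$f_ph, -Inf),
                             key, FUN = function(x) max(x))
    out <- out[order(-best_score, out$target_id, out$mode, out$factor), ,
               drop = FALSE]
    rownames(out) <- NULL
    if (!keep_grid) {
      out <- out[out$best | out$status != "optimal", , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("campaign_result", "data.frame")
  out
}

#' Best record per (target, mode) of a campaign
#' @param result a `campaign_result` from [run_campaign()].
#' @return data.frame of the `best`-flagged rows, ranked by `f_ph`.
#' @export
campaign_ranking <- function(result) {
  r <- result[result$best & result$status == "optimal", , drop = FALSE]
  r <- r[order(-r$f_ph, r$target_id), , drop = FALSE]
  rownames(r) <- NULL
  as.data.frame(r)
}

#' Serialize campaign results as TSV
#' @param result a `campaign_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_campaign_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
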