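#' Construct a flux state
#'
#' Container for one flux vector with its objective value and solver status.
#'
#' @param fluxes named numeric vector, reaction id -> flux (mmol/gDCW/h).
#' @param objective_value objective flux at the optimum (`NA` if not optimal).
#' @param objective_id reaction id of the objective.
#' @param status `"optimal"`, `"infeasible"` or `"unbounded"`.
#' @param provenance free-text descriptor of the constraints applied.
#' @return an object of class `flux_state`.
#' @export
flux_state <- function(fluxes, objective_value, objective_id, status,
                       provenance = "") {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 objective_id = objective_id, status = status,
                 provenance = provenance),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status: ", x$status,
      "   objective (", x$objective_id, "): ",
      format(x$objective_value, digits = 6),
      if (nzchar(x$provenance)) paste0("   [", x$provenance, "]"), "\n", sep = "")
  invisible(x)
}

# resolve extra_constraints (named list: length-1 = fixed flux, length-2 =
# c(lb, ub)) against model bounds; returns list(lb, ub)
.apply_constraints <- function(model, extra_constraints) {
  lb <- stats::setNames(model$reactions$lower_bound, model$reactions$id)
  ub <- stats::setNames(model$reactions$upper_bound, model$reactions$id)
  for (id in names(extra_constraints)) {
    if (!id %in% names(lb)) stop("constraint on unknown reaction: ", id)
    v <- extra_constraints[[id]]
    if (length(v) == 1L) { lb[id] <- v; ub[id] <- v }
    else if (length(v) == 2L) { lb[id] <- v[1]; ub[id] <- v[2] }
    else stop("constraint for ", id, " must have length 1 (fixed) or 2 (bounds)")
  }
  if (any(lb > ub)) stop("constraint sets lower bound above upper bound for: ",
                         paste(names(lb)[lb > ub], collapse = ", "))
  list(lb = lb, ub = ub)
}

# steady-state + bound sanity check on an optimal flux vector
.check_state <- function(S, v, lb, ub, tol = 1e-6) {
  resid <- max(abs(S %*% v))
  ok <- resid <= tol * max(1, max(abs(v))) &&
    all(v >= lb - 1e-5) && all(v <= ub + 1e-5)
  if (!ok) warning("flux state fails steady-state/bounds validation (|Sv| = ",
                   format(resid, digits = 3), ")")
  invisible(ok)
}

#' Flux balance analysis
#'
#' Maximizes the objective flux subject to steady state (`S v = 0`) and the
#' flux bounds, optionally overridden by `extra_constraints`.
#'
#' @param model a `stoichiometric_model`.
#' @param objective_id reaction to maximize (default the model objective).
#' @param extra_constraints named list of bound overrides; a length-1 entry
#'   fixes the flux, a length-2 entry `c(lb, ub)` replaces the bounds.
#' @return a [flux_state()].  An infeasible constraint set yields
#'   `status = "infeasible"` (no error).
#' @export
fba <- function(model, objective_id = model$objective_id,
                extra_constraints = NULL) {
  S <- stoich_matrix(model)
  bb <- .apply_constraints(model, extra_constraints)
  if (!objective_id %in% colnames(S)) stop("unknown objective: ", objective_id)
  cvec <- stats::setNames(numeric(ncol(S)), colnames(S))
  cvec[objective_id] <- 1
  res <- .solve_lp(cvec, Aeq = S, beq = rep(0, nrow(S)), lb = bb$lb, ub = bb$ub)
  if (res$status != "optimal")
    return(flux_state(stats::setNames(rep(NA_real_, ncol(S)), colnames(S)),
                      NA_real_, objective_id, res$status, "fba"))
  v <- stats::setNames(res$x, colnames(S))
  .check_state(S, v, bb$lb, bb$ub)
  flux_state(v, unname(v[objective_id]), objective_id, "optimal", "fba")
}

#' Unique reference flux state (parsimonious FBA)
#'
#' Two-stage computation of the "initial fluxes" against which perturbations
#' are compared: (1) FBA for the optimal objective `mu*`; (2) among flux
#' vectors with objective >= `mu* (1 - 1e-9)`, minimize total absolute flux
#' `sum |v|`.  The L1 stage is solved in epigraph form (auxiliary `t` with
#' `-t <= v <= t`), with a small exact-regularization ridge making the
#' minimizer unique, hence reproducible across runs.
#'
#' @inheritParams fba
#' @return a [flux_state()] with `provenance = "reference"`.
#' @export
reference_state <- function(model, objective_id = model$objective_id,
                            extra_constraints = NULL) {
  S <- stoich_matrix(model)
  bb <- .apply_constraints(model, extra_constraints)
  stage1 <- fba(model, objective_id, extra_constraints)
  if (stage1$status != "optimal") return(stage1)
  mu <- stage1$objective_value
  n <- ncol(S)
  # vars z = (v, t): min sum(t) + eps/2 ||z||^2
  Aeq <- cbind(S, matrix(0, nrow(S), n))
  crow <- c(stats::setNames(numeric(n), colnames(S)), numeric(n))
  crow[objective_id] <- 1
  I <- diag(n); Z <- matrix(0, n, n)
  Aineq <- rbind(crow, cbind(I, I), cbind(-I, I))
  bineq <- c(mu * (1 - 1e-9) - 1e-12, rep(0, 2 * n))
  tmax <- pmax(abs(bb$lb), abs(bb$ub))
  out <- .solve_qp(diag(1e-6, 2 * n), c(numeric(n), rep(-1, n)),
                   Aeq = Aeq, beq = rep(0, nrow(S)),
                   Aineq = Aineq, bineq = bineq,
                   lb = c(bb$lb, rep(0, n)), ub = c(bb$ub, tmax))
  if (out$status != "optimal")
    stop("reference stage 2 unexpectedly ", out$status)
  v <- stats::setNames(out$x[seq_len(n)], colnames(S))
  v[abs(v) < 1e-10] <- 0
  .check_state(S, v, bb$lb, bb$ub)
  flux_state(v, unname(v[objective_id]), objective_id, "optimal", "reference")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective staying at
#' or above `fraction_of_optimum` times its FBA optimum.
#'
#' @inheritParams fba
#' @param reaction_ids reactions to scan (default all).
#' @param fraction_of_optimum number in `[0, 1]`.
#' @return data.frame with columns `id`, `min`, `max`.
#' @export
fva <- function(model, reaction_ids = model$reactions$id,
                fraction_of_optimum = 1.0, extra_constraints = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  S <- stoich_matrix(model)
  bb <- .apply_constraints(model, extra_constraints)
  base <- fba(model, extra_constraints = extra_constraints)
  if (base$status != "optimal")
    stop("fva: base problem is ", base$status)
  crow <- stats::setNames(numeric(ncol(S)), colnames(S))
  crow[model$objective_id] <- 1
  Aineq <- matrix(crow, 1)
  bineq <- fraction_of_optimum * base$objective_value - 1e-9
  out <- lapply(reaction_ids, function(rid) {
    cvec <- stats::setNames(numeric(ncol(S)), colnames(S))
    cvec[rid] <- 1
    hi <- .solve_lp(cvec, S, rep(0, nrow(S)), Aineq, bineq, bb$lb, bb$ub)
    lo <- .solve_lp(-cvec, S, rep(0, nrow(S)), Aineq, bineq, bb$lb, bb$ub)
    data.frame(id = rid, min = -lo$value, max = hi$value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Growth after a single-reaction knockout
#'
#' @inheritParams fba
#' @param reaction_id reaction whose bounds are set to `[0, 0]`.
#' @return the FBA objective optimum of the knockout model; infeasible
#'   knockouts return 0.
#' @export
knockout_growth <- function(model, reaction_id, extra_constraints = NULL) {
  if (!reaction_id %in% model$reactions$id)
    stop("unknown reaction: ", reaction_id)
  ec <- c(extra_constraints %||% list(),
          stats::setNames(list(c(0, 0)), reaction_id))
  st <- fba(model, extra_constraints = ec)
  if (st$status != "optimal") 0 else st$objective_value
}

#' Cofactor flux-sum balance
#'
#' Decomposes the turnover of one metabolite in an optimal flux state into
#' producer and consumer reactions.  The flux-sum (total production)
#' is `sum_j max(S_mj v_j, 0)`; at steady state it equals total consumption.
#' Reversible reactions are counted on the side they actually run.
#'
#' @param state an optimal [flux_state()].
#' @param model the corresponding `stoichiometric_model`.
#' @param metabolite_id metabolite to analyze.
#' @return list with `metabolite_id`, `producers`, `consumers` (named
#'   production/consumption fluxes, both positive) and `total_production`.
#' @export
flux_sum <- function(state, model, metabolite_id) {
  if (state$status != "optimal") stop("flux_sum requires an optimal state")
  if (!metabolite_id %in% model$metabolites$id)
    stop("unknown metabolite: ", metabolite_id)
  S <- stoich_matrix(model)
  contrib <- S[metabolite_id, ] * state$fluxes[colnames(S)]
  contrib[abs(contrib) < 1e-12] <- 0
  producers <- contrib[contrib > 0]
  consumers <- -contrib[contrib < 0]
  list(metabolite_id = metabolite_id,
       producers = producers, consumers = consumers,
       total_production = sum(producers))
}
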