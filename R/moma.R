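#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the feasible flux vector of a perturbed model at minimal Euclidean
#' distance from a reference flux distribution:
#' `argmin sum_j (v_j - v_ref_j)^2` subject to `S v = 0` and the perturbed
#' bounds.  This models the immediate, non-reoptimized response of the
#' network to a perturbation.  The distance is taken over all reactions,
#' exchanges included; reactions absent from the reference (e.g. swap-added
#' ones) enter with reference flux 0, so their activation is penalized.
#'
#' @param perturbed_model the perturbed `stoichiometric_model`.
#' @param reference a [flux_state()] (typically from [reference_state()]).
#' @param extra_constraints named list of bound overrides (see [fba()]).
#' @return a [flux_state()] whose `objective_value` is the achieved squared
#'   distance; growth and product rates are read off the returned `fluxes`.
#'   Infeasible perturbations yield `status = "infeasible"`.
#' @export
moma <- function(perturbed_model, reference, extra_constraints = NULL) {
  S <- stoich_matrix(perturbed_model)
  bb <- .apply_constraints(perturbed_model, extra_constraints)
  n <- ncol(S)
  vref <- stats::setNames(rep(0, n), colnames(S))
  common <- intersect(colnames(S), names(reference$fluxes))
  vref[common] <- reference$fluxes[common]
  # min 1/2 v' (2I) v - (2 vref)' v  ==  min ||v - vref||^2 (+ const)
  out <- .solve_qp(diag(2, n), 2 * vref, Aeq = S, beq = rep(0, nrow(S)),
                   lb = bb$lb, ub = bb$ub)
  if (out$status != "optimal")
    return(flux_state(stats::setNames(rep(NA_real_, n), colnames(S)),
                      NA_real_, reference$objective_id, out$status, "moma"))
  v <- stats::setNames(out$x, colnames(S))
  .check_state(S, v, bb$lb, bb$ub)
  flux_state(v, sum((v - vref)^2), reference$objective_id, "optimal", "moma")
}

#' Verify the KKT conditions of a MOMA solution
#'
#' Report-only self-check of the convex QP: at the optimum the gradient
#' `2 (v - v_ref)` must lie in the cone spanned by the steady-state equality
#' normals (free multipliers) and the active bound normals (sign-constrained
#' multipliers).  The stationarity residual is the distance from the
#' gradient to that cone; primal feasibility residuals are reported
#' alongside.
#'
#' @inheritParams moma
#' @param candidate_state a feasible [flux_state()] to test.
#' @param tol residual threshold for `pass` (default `1e-6`).
#' @return list with `stationarity`, `primal_eq`, `primal_bounds`, `pass`.
#' @export
verify_kkt <- function(perturbed_model, reference, candidate_state,
                       extra_constraints = NULL, tol = 1e-6) {
  S <- stoich_matrix(perturbed_model)
  bb <- .apply_constraints(perturbed_model, extra_constraints)
  n <- ncol(S)
  v <- candidate_state$fluxes[colnames(S)]
  vref <- stats::setNames(rep(0, n), colnames(S))
  common <- intersect(colnames(S), names(reference$fluxes))
  vref[common] <- reference$fluxes[common]
  g <- 2 * (v - vref)
  scale <- max(1, max(abs(g)))
  atol <- 1e-7 * max(1, max(abs(v)))
  at_lb <- which(v <= bb$lb + atol)
  at_ub <- which(v >= bb$ub - atol)
  # cone members: S' lambda (free); + e_i mu_i for i at the lower bound and
  # - e_i mu_i at the upper bound (mu >= 0): for min f s.t. v_i >= lb the
  # stationarity is grad f = S' lambda + mu e_i, at ub the sign flips
  B <- NULL
  if (length(at_lb)) {
    Blb <- matrix(0, n, length(at_lb)); Blb[cbind(at_lb, seq_along(at_lb))] <- 1
    B <- cbind(B, Blb)
  }
  if (length(at_ub)) {
    Bub <- matrix(0, n, length(at_ub)); Bub[cbind(at_ub, seq_along(at_ub))] <- -1
    B <- cbind(B, Bub)
  }
  A <- cbind(t(S), B)
  k_free <- nrow(S)
  k <- ncol(A)
  # min ||A y - g||^2 with y[(k_free+1):k] >= 0; the ridge making the
  # Gram matrix positive definite starts tiny and grows only if the
  # factorization fails, so it never inflates the reported residual
  AtA <- crossprod(A)
  dv <- crossprod(A, g)
  nsign <- k - k_free
  Amat <- if (nsign) {
    Ai <- matrix(0, nsign, k); Ai[cbind(seq_len(nsign), k_free + seq_len(nsign))] <- 1
    t(Ai)
  } else matrix(0, k, 0)
  y <- NULL
  for (ridge in c(1e-13, 1e-10, 1e-7) * max(1, max(diag(AtA)))) {
    y <- tryCatch(
      quadprog::solve.QP(AtA + diag(ridge, k), dv, Amat, rep(0, nsign))$solution,
      error = function(e) NULL)
    if (!is.null(y)) break
  }
  if (is.null(y)) stop("multiplier fit failed in verify_kkt")
  stationarity <- max(abs(A %*% y - g)) / scale
  primal_eq <- max(abs(S %*% v)) / max(1, max(abs(v)))
  primal_bounds <- max(0, max(bb$lb - v), max(v - bb$ub)) / max(1, max(abs(v)))
  list(stationarity = stationarity, primal_eq = primal_eq,
       primal_bounds = primal_bounds,
       pass = stationarity <= tol && primal_eq <= tol && primal_bounds <= tol)
}
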