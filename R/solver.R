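# Internal convex-optimization layer.
#
# All flux computations reduce to convex QPs over the flux polytope
# {v : Aeq v = beq, Aineq v >= bineq, lb <= v <= ub} and are solved with the
# Goldfarb-Idnani dual active-set method (quadprog::solve.QP).  Linear
# programs are solved through exact Tikhonov regularization: for a small
# enough ridge eps the minimizer of  eps/2 ||x||^2 - c'x  over the polytope
# is the least-norm maximizer of c'x (Mangasarian & Meyer 1979), so the LP
# optimum and its value are recovered exactly up to solver tolerance.  An
# eps ladder plus a slack-based feasibility phase distinguishes genuine
# infeasibility from numerical failure.

.BIG_BOUND <- 1e6

# consistency check + maximal independent row subset of an equality system
.reduce_eq <- function(Aeq, beq, tol = 1e-8) {
  if (is.null(Aeq) || nrow(Aeq) == 0L)
    return(list(A = NULL, b = numeric(0), consistent = TRUE))
  qrA <- qr(t(Aeq))
  r <- qrA$rank
  keep <- qrA$pivot[seq_len(r)]
  consistent <- TRUE
  if (r < nrow(Aeq)) {
    # dropped rows must be implied by kept ones: check them against the
    # minimum-norm solution of the kept (full-row-rank) subsystem
    Ak <- Aeq[keep, , drop = FALSE]
    fit <- crossprod(Ak, solve(tcrossprod(Ak), beq[keep]))
    resid <- Aeq %*% fit - beq
    consistent <- max(abs(resid)) <= tol * max(1, max(abs(beq)))
  }
  list(A = Aeq[keep, , drop = FALSE], b = beq[keep], consistent = consistent)
}

# slack feasibility phase: is the polytope nonempty?
# (a) positive certificate: a least-norm point solves directly;
# (b) otherwise minimize slacks and measure the true residual of the v part.
.polytope_feasible <- function(Aeq, beq, Aineq, bineq, lb, ub, tol = 1e-5) {
  if (any(lb > ub + 1e-12)) return(FALSE)
  n <- length(lb)
  me <- if (is.null(Aeq)) 0L else nrow(Aeq)
  mi <- if (is.null(Aineq)) 0L else nrow(Aineq)
  if (me + mi == 0L) return(TRUE)
  scale <- max(1, abs(beq), abs(bineq))
  true_viol <- function(v) {
    max(if (me) max(abs(Aeq %*% v - beq)) else 0,
        if (mi) max(pmax(bineq - Aineq %*% v, 0)) else 0)
  }
  # (a) least-norm point of the polytope itself (strictly convex, robust)
  Amat_a <- t(rbind(Aeq, Aineq, diag(n), -diag(n)))
  bvec_a <- c(beq, bineq, lb, -ub)
  res <- tryCatch(
    quadprog::solve.QP(diag(1, n), numeric(n), Amat_a, bvec_a, meq = me),
    error = function(e) NULL)
  if (!is.null(res) && true_viol(res$solution) <= tol * scale) return(TRUE)
  # (b) slack formulation: Aeq v + s_eq = beq, Aineq v + s_in >= bineq
  N <- n + me + mi
  Aeq2 <- if (me) cbind(Aeq, diag(me), matrix(0, me, mi)) else NULL
  rows <- list(); bv <- numeric(0)
  if (mi) {
    rows <- c(rows, list(cbind(Aineq, matrix(0, mi, me), diag(mi))))
    bv <- c(bv, bineq)
    rows <- c(rows, list(cbind(matrix(0, mi, n + me), diag(mi))))
    bv <- c(bv, rep(0, mi))
  }
  rows <- c(rows, list(cbind(diag(n), matrix(0, n, me + mi))))
  bv <- c(bv, lb)
  rows <- c(rows, list(cbind(-diag(n), matrix(0, n, me + mi))))
  bv <- c(bv, -ub)
  Amat <- t(rbind(Aeq2, do.call(rbind, rows)))
  bvec <- c(if (me) beq else numeric(0), bv)
  for (ridge_v in c(1e-9, 1e-7, 1e-5)) {
    D <- diag(c(rep(ridge_v, n), rep(1, me + mi)), N)
    res <- tryCatch(
      quadprog::solve.QP(D, numeric(N), Amat, bvec, meq = me),
      error = function(e) NULL)
    if (!is.null(res) && true_viol(res$solution[seq_len(n)]) <= tol * scale)
      return(TRUE)
  }
  FALSE
}

# generic bounded QP:  min 1/2 x'D x - d'x  on the polytope
# returns list(x, status) with status in optimal/infeasible
.solve_qp <- function(Dmat, dvec, Aeq = NULL, beq = numeric(0),
                      Aineq = NULL, bineq = numeric(0), lb, ub) {
  n <- length(lb)
  lb <- pmax(lb, -.BIG_BOUND); ub <- pmin(ub, .BIG_BOUND)
  if (any(lb > ub)) return(list(x = NULL, status = "infeasible"))
  # fixed variables join the equality system (kinder to the active-set method)
  fixed <- which(ub - lb < 1e-12)
  if (length(fixed)) {
    E <- matrix(0, length(fixed), n)
    E[cbind(seq_along(fixed), fixed)] <- 1
    Aeq <- rbind(Aeq, E); beq <- c(beq, lb[fixed])
    lb[fixed] <- -.BIG_BOUND; ub[fixed] <- .BIG_BOUND
  }
  red <- .reduce_eq(Aeq, beq)
  if (!red$consistent) return(list(x = NULL, status = "infeasible"))
  me <- if (is.null(red$A)) 0L else nrow(red$A)
  Amat <- t(rbind(red$A, Aineq, diag(n), -diag(n)))
  bvec <- c(red$b, bineq, lb, -ub)
  res <- tryCatch(quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = me),
                  error = function(e) e)
  if (inherits(res, "error")) {
    # the dual active-set method reports numerical stress and genuine
    # infeasibility with the same error: retry with growing ridges first
    # (cheap, resolves the stressed-but-solvable cases), then decide
    # feasibility with the dedicated phase
    for (boost in c(10, 100, 1e4, 1e6)) {
      res2 <- tryCatch(
        quadprog::solve.QP(Dmat + diag(boost * 1e-8 * max(diag(Dmat)), n),
                           dvec, Amat, bvec, meq = me),
        error = function(e) NULL)
      if (!is.null(res2)) return(list(x = res2$solution, status = "optimal"))
    }
    if (!.polytope_feasible(red$A, red$b, Aineq, bineq, lb, ub))
      return(list(x = NULL, status = "infeasible"))
    stop("QP solver failed on a feasible problem: ", conditionMessage(res))
  }
  list(x = res$solution, status = "optimal")
}

# LP  max c'x  over the polytope.
#
# Fast path: exact Tikhonov regularization (min eps/2||x||^2 - c'x).  Every
# candidate optimum is then verified -- and, if need be, polished -- by
# proximal-point iteration x+ = argmax c'x - ||x - x_k||^2 / (2t): each step
# is a well-conditioned strictly convex QP, x is optimal iff it is a fixed
# point, and for polyhedral objectives the iteration terminates finitely.
# returns list(x, value, status) with status optimal/infeasible/unbounded
.solve_lp <- function(cvec, Aeq = NULL, beq = numeric(0),
                      Aineq = NULL, bineq = numeric(0), lb, ub,
                      eps = 1e-7) {
  n <- length(lb)
  scale <- max(abs(cvec), 1)
  unbounded_guard <- any(is.infinite(lb) | is.infinite(ub))
  x0 <- NULL
  for (e_try in unique(c(eps, 1e-6, 1e-5))) {
    out <- tryCatch(
      .solve_qp(diag(e_try * scale, n), cvec, Aeq, beq, Aineq, bineq, lb, ub),
      error = function(err) NULL)
    if (is.null(out)) next
    if (out$status == "infeasible")
      return(list(x = NULL, value = NA_real_, status = "infeasible"))
    x0 <- out$x
    break
  }
  if (is.null(x0)) {
    # regularized path failed outright: fetch any feasible point (min ||x||^2
    # is strictly convex and robust) and let the proximal iteration climb
    out <- .solve_qp(diag(scale, n), numeric(n), Aeq, beq, Aineq, bineq, lb, ub)
    if (out$status == "infeasible")
      return(list(x = NULL, value = NA_real_, status = "infeasible"))
    x0 <- out$x
  }
  x <- x0
  t_prox <- 100 / scale
  converged <- FALSE
  for (it in seq_len(300)) {
    step <- tryCatch(
      .solve_qp(diag(1 / t_prox, n), cvec + x / t_prox,
                Aeq, beq, Aineq, bineq, lb, ub),
      error = function(err) NULL)
    if (is.null(step) || step$status != "optimal") {
      t_prox <- t_prox / 10      # shorter, better-conditioned steps
      if (t_prox < 1e-4 / scale) break
      next
    }
    if (max(abs(step$x - x)) <= 1e-9 * max(1, max(abs(x)))) {
      x <- step$x; converged <- TRUE; break
    }
    x <- step$x
  }
  if (!converged && !(unbounded_guard && any(abs(x) > 0.99 * .BIG_BOUND)))
    stop("LP proximal iteration did not converge")
  if (unbounded_guard && any(abs(x) > 0.99 * .BIG_BOUND))
    return(list(x = x, value = sum(cvec * x), status = "unbounded"))
  list(x = x, value = sum(cvec * x), status = "optimal")
}
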