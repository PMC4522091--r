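test_that("FBA solves the chain micro-model to capacity", {
  m <- micro_model()
  st <- fba(m)
  expect_identical(st$status, "optimal")
  expect_equal(st$objective_value, 10, tolerance = 1e-7)
  # capping the inflow caps the objective
  m0 <- set_bounds(m, "R_in", 0, 0)
  expect_equal(fba(m0)$objective_value, 0, tolerance = 1e-9)
})

test_that("infeasible constraint sets yield status infeasible, not an error", {
  m <- micro_model()
  st <- fba(m, extra_constraints = list(R_in = c(0, 0), R_obj = c(5, 10)))
  expect_identical(st$status, "infeasible")
  expect_true(is.na(st$objective_value))
})

test_that("reference state breaks degeneracy by minimal total flux", {
  m <- micro_model()
  ref <- reference_state(m)
  expect_equal(unname(ref$fluxes[c("R_in", "R_obj", "R_alt")]), c(10, 10, 0),
               tolerance = 1e-6)
  expect_identical(ref$provenance, "reference")
  # determinism: two runs give identical vectors
  expect_identical(ref$fluxes, reference_state(m)$fluxes)
})

test_that("reference objective matches the FBA optimum and minimizes total flux among alternate optima", {
  fix <- toy_reference()
  m <- fix$model; ref <- fix$ref
  st <- fba(m)
  expect_equal(ref$objective_value, st$objective_value, tolerance = 1e-7)
  # oracle: alternate optima from random secondary objectives never beat
  # the reference's total absolute flux
  S <- stoich_matrix(m)
  mu <- st$objective_value
  set.seed(42)
  l1_ref <- sum(abs(ref$fluxes))
  for (k in 1:25) {
    w <- stats::rnorm(ncol(S))
    alt <- redoxscreen:::.solve_lp(
      w, Aeq = S, beq = rep(0, nrow(S)),
      Aineq = matrix(as.numeric(colnames(S) == "BIOMASS"), 1),
      bineq = mu * (1 - 1e-9),
      lb = stats::setNames(m$reactions$lower_bound, m$reactions$id),
      ub = stats::setNames(m$reactions$upper_bound, m$reactions$id))
    expect_identical(alt$status, "optimal")
    expect_gte(sum(abs(alt$x)) - l1_ref, -1e-5)
  }
})

test_that("optimal states satisfy steady state and bounds", {
  fix <- toy_reference()
  S <- stoich_matrix(fix$model)
  v <- fix$ref$fluxes
  expect_lt(max(abs(S %*% v)), 1e-6 * max(1, max(abs(v))))
  expect_true(all(v >= fix$model$reactions$lower_bound - 1e-6))
  expect_true(all(v <= fix$model$reactions$upper_bound + 1e-6))
  expect_gt(v[["EX_iboh_e"]], 0)  # secretion constraint active at reference
})

test_that("FVA brackets the reference flux and widens as the optimum is relaxed", {
  m <- micro_model()
  at1 <- fva(m, "R_alt", fraction_of_optimum = 1.0)
  expect_equal(c(at1$min, at1$max), c(0, 0), tolerance = 1e-6)
  at0 <- fva(m, "R_alt", fraction_of_optimum = 0.0)
  expect_equal(c(at0$min, at0$max), c(0, 10), tolerance = 1e-6)
  # sandwich property on the toy fixture
  fix <- toy_reference()
  ids <- c("GAPD", "LDH", "THD", "G6PDH_lump", "EX_iboh_e", "BIOMASS")
  tab <- fva(fix$model, ids, fraction_of_optimum = 1.0)
  for (i in seq_len(nrow(tab))) {
    v <- fix$ref$fluxes[[tab$id[i]]]
    expect_gte(v, tab$min[i] - 1e-5)
    expect_lte(v, tab$max[i] + 1e-5)
  }
})

test_that("knockout growth handles blocking and redundant reactions", {
  m <- micro_model()
  expect_equal(knockout_growth(m, "R_in"), 0, tolerance = 1e-9)
  expect_equal(knockout_growth(m, "R_alt"), 10, tolerance = 1e-6)
  # methylglyoxal-like bypass is redundant at the toy reference
  fix <- toy_reference()
  expect_equal(knockout_growth(fix$model, "MGX_bypass"),
               fix$ref$objective_value, tolerance = 1e-5)
})

test_that("flux sums decompose turnover into matching producer and consumer totals", {
  # hand summation oracle: GAPD +15, PDH +5 produce NADH (total 20);
  # LDH 12, ADHE 6, ETC 2 consume it
  mets <- data.frame(id = c("nadh", "x"), name = c("NADH", "x"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(id = c("GAPD", "PDH", "LDH", "ADHE", "ETC", "EX_x"),
                   name = "r", lower_bound = -1000, upper_bound = 1000,
                   genes = "g", subsystem = "", notes = "",
                   stringsAsFactors = FALSE)
  st <- list(GAPD = c(nadh = 1, x = 1), PDH = c(nadh = 1, x = 1),
             LDH = c(nadh = -1, x = 1), ADHE = c(nadh = -1, x = 1),
             ETC = c(nadh = -1, x = 1), EX_x = c(x = -1))
  m <- new_model("fs", c(c = "c"), mets, rx, st, "EX_x")
  state <- flux_state(c(GAPD = 15, PDH = 5, LDH = 12, ADHE = 6, ETC = 2,
                        EX_x = 0), 0, "EX_x", "optimal")
  fs <- flux_sum(state, m, "nadh")
  expect_equal(fs$total_production, 20)
  expect_equal(sum(fs$producers), sum(fs$consumers), tolerance = 1e-9)
  expect_setequal(names(fs$producers), c("GAPD", "PDH"))
  expect_setequal(names(fs$consumers), c("LDH", "ADHE", "ETC"))
  # reversible reaction counted on the side it runs: negative LDH flux
  # turns it into a producer
  state2 <- flux_state(c(GAPD = 15, PDH = 5, LDH = -12, ADHE = 6, ETC = 2,
                         EX_x = 0), 0, "EX_x", "optimal")
  fs2 <- flux_sum(state2, m, "nadh")
  expect_true("LDH" %in% names(fs2$producers))
  expect_error(flux_sum(state, m, "ghost"), "unknown metabolite")
  # metabolite with no participating reactions
  m2 <- new_model("fs2", c(c = "c"),
                  rbind(mets, data.frame(id = "idle", name = "idle",
                                         compartment = "c")),
                  rx, st, "EX_x")
  expect_equal(flux_sum(state, m2, "idle")$total_production, 0)
})

test_that("production equals consumption for every internal metabolite of an optimal state", {
  fix <- toy_reference()
  internal <- setdiff(fix$model$metabolites$id,
                      unlist(lapply(fix$model$stoichiometry[exchange_ids(fix$model)],
                                    names)))
  for (met in internal) {
    fs <- flux_sum(fix$ref, fix$model, met)
    expect_equal(sum(fs$producers), sum(fs$consumers), tolerance = 1e-6,
                 label = paste("turnover of", met))
  }
})

test_that("regularized LP agrees with an independent simplex solver on random networks", {
  skip_if_not_installed("pracma")
  set.seed(7)
  agreed <- 0
  for (trial in 1:12) {
    n <- 10; mm <- 5
    S <- matrix(stats::rpois(mm * n, 1) * sample(c(-1, 1), mm * n, TRUE), mm, n)
    ub <- stats::runif(n, 5, 20); cc <- stats::runif(n)
    mine <- redoxscreen:::.solve_lp(cc, Aeq = S, beq = rep(0, mm),
                                    lb = rep(0, n), ub = ub)
    ref <- tryCatch(
      pracma::linprog(cc, A = diag(n), b = ub, Aeq = S, beq = rep(0, mm),
                      maximize = TRUE, maxiter = 500),
      error = function(e) NULL)
    if (is.null(ref) || is.null(ref$fval)) next  # simplex failed; skip case
    expect_equal(mine$value, ref$fval, tolerance = 1e-6)
    agreed <- agreed + 1
  }
  expect_gte(agreed, 5)
})
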