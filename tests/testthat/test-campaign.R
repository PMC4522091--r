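test_that("perturbation builders set the documented bounds", {
  fix <- toy_reference()
  m <- fix$model
  ko <- build_knockout(m, "LDH")
  expect_equal(reaction_bounds(ko, "LDH"), c(0, 0))

  # overexpression fixes N-fold reference flux, sign preserved
  ref_mock <- flux_state(c(GAPD = 2.0, LDH = -4.0), NA, "BIOMASS", "optimal")
  oe <- build_overexpression(m, "GAPD", 1.5, ref_mock)
  expect_equal(reaction_bounds(oe, "GAPD"), c(3.0, 3.0))
  oe2 <- build_overexpression(m, "LDH", 2.0, ref_mock)
  expect_equal(reaction_bounds(oe2, "LDH"), c(-8.0, -8.0))
  zero_ref <- flux_state(c(GAPD = 0), NA, "BIOMASS", "optimal")
  expect_error(build_overexpression(m, "GAPD", 1.5, zero_ref),
               "undefined at zero flux")
})

test_that("cofactor swap substitutes the pair and nothing else", {
  fix <- toy_reference()
  sw <- swap_cofactor(fix$model, "GAPD", fix$cof)
  expect_identical(sw$id, "GAPD_swap")
  expect_same_stoichiometry(
    sw$stoichiometry,
    c(g3p = -1, nadp = -1, adp = -1, pep = 1, atp = 1, nadph = 1))
  # NADPH consumer becomes an NADH consumer
  m2 <- add_reaction(fix$model, "GLUD_like", "NADPH consumer",
                     c(pyr = -1, nadph = -1, lac = 1, nadp = 1),
                     lower_bound = 0, genes = "gdhA")
  sw2 <- swap_cofactor(m2, "GLUD_like", fix$cof)
  expect_same_stoichiometry(sw2$stoichiometry,
                            c(pyr = -1, nadh = -1, lac = 1, nad = 1))
  # dual-pair reactions cannot be swapped
  expect_error(swap_cofactor(fix$model, "THD", fix$cof), "dual_cofactor")
})

test_that("swap perturbation silences the native reaction and fixes the swapped flux", {
  fix <- toy_reference()
  v_ref <- fix$ref$fluxes[["GAPD"]]
  pm <- build_swap(fix$model, "GAPD", 0.5, fix$ref, fix$cof)
  expect_equal(reaction_bounds(pm, "GAPD"), c(0, 0))
  expect_equal(reaction_bounds(pm, "GAPD_swap"), rep(0.5 * v_ref, 2))
  expect_identical(attr(pm, "swap_id"), "GAPD_swap")
})

test_that("f_PH recovers the published worked examples from printed rates", {
  # baseline 0.095 1/h growth, 0.65 mM/g/h isobutanol
  thd <- f_ph_rates(0.0797, 0.732, 0.095, 0.65)
  expect_equal(thd$f_ph, 1.064, tolerance = 5e-3)
  ldh <- f_ph_rates(0.005, 1.829, 0.095, 0.65)
  expect_equal(ldh$f_ph, 0.417, tolerance = 5e-3)
  alcd <- f_ph_rates(0.0798, 0.968, 0.095, 0.65)
  expect_equal(alcd$f_ph, 1.860, tolerance = 5e-3)
  expect_error(f_ph_rates(0.1, 0.7, 0, 0.65), "must be positive")
})

test_that("f_PH of an unperturbed state is exactly (1, 1, 1)", {
  fix <- toy_reference()
  sc <- f_ph(fix$ref, fix$ref, "EX_iboh_e")
  expect_equal(sc$f_biomass, 1)
  expect_equal(sc$f_isobutanol, 1)
  expect_equal(sc$f_ph, 1)
  # identity overexpression (N = 1) scores 1 through the whole machinery
  oe <- build_overexpression(fix$model, "GAPD", 1.0, fix$ref)
  st <- moma(oe, fix$ref)
  expect_lt(st$objective_value, 1e-9)
  expect_equal(f_ph(fix$ref, st, "EX_iboh_e")$f_ph, 1, tolerance = 1e-6)
})

test_that("record-level consistency: f_ph = f_biomass * f_isobutanol^2", {
  fix <- toy_reference()
  cs <- filter_candidates(fix$model, fix$ref, fix$cof)
  camp <- run_campaign(fix$model, cs, fix$ref, fix$cof, "EX_iboh_e",
                       grid_n = c(1.5, 2.0), grid_m = c(0.5, 1.0))
  ok <- camp[camp$status == "optimal", ]
  expect_gt(nrow(ok), 0)
  expect_equal(ok$f_ph, ok$f_biomass * ok$f_isobutanol^2, tolerance = 1e-12)
})

test_that("knocking out a reaction required for export zeroes f_PH", {
  fix <- toy_reference()
  # relax the secretion floor so the knockout is feasible rather than
  # infeasible, then silence the only secretion route
  m <- fix$model
  m <- set_bounds(m, "EX_iboh_e", 0, 1000)
  ref <- reference_state(m, extra_constraints = list(EX_iboh_e = c(0.5, 1000)))
  ko <- build_knockout(m, "IBOHt")
  st <- moma(ko, ref)
  expect_identical(st$status, "optimal")
  sc <- f_ph(ref, st, "EX_iboh_e")
  expect_equal(sc$f_ph, 0, tolerance = 1e-9)
})

test_that("the toy campaign ranks the GAPD cofactor swap first", {
  fix <- toy_reference()
  cs <- filter_candidates(fix$model, fix$ref, fix$cof)
  camp <- run_campaign(fix$model, cs, fix$ref, fix$cof, "EX_iboh_e")
  rank <- campaign_ranking(camp)
  expect_identical(rank$target_id[1], "GAPD")
  expect_identical(rank$mode[1], "cofactor_swap")
  score <- function(id, mode) rank$f_ph[rank$target_id == id & rank$mode == mode]
  expect_gt(score("GAPD", "cofactor_swap"), score("LDH", "knockout"))
  expect_gt(score("GAPD", "cofactor_swap"), score("ADHE", "knockout"))
  expect_gt(score("GAPD", "cofactor_swap"), score("THD", "overexpression"))
  expect_gt(score("GAPD", "cofactor_swap"), score("G6PDH_lump", "overexpression"))
})

test_that("campaigns are deterministic and tolerate empty candidate sets", {
  fix <- toy_reference()
  cs <- filter_candidates(fix$model, fix$ref, fix$cof)
  small_n <- c(1.5, 2.0); small_m <- c(0.5, 1.0)
  c1 <- run_campaign(fix$model, cs, fix$ref, fix$cof, "EX_iboh_e",
                     grid_n = small_n, grid_m = small_m)
  c2 <- run_campaign(fix$model, cs, fix$ref, fix$cof, "EX_iboh_e",
                     grid_n = small_n, grid_m = small_m)
  p1 <- tempfile(); p2 <- tempfile()
  write_campaign_tsv(c1, p1); write_campaign_tsv(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
  empty <- structure(list(candidates = data.frame(id = character(0),
                                                  modes = character(0),
                                                  v_ref = numeric(0)),
                          excluded = character(0)),
                     class = "candidate_set")
  c0 <- run_campaign(fix$model, empty, fix$ref, fix$cof, "EX_iboh_e")
  expect_identical(nrow(c0), 0L)
})

test_that("infeasible grid points are logged and excluded from ranking", {
  fix <- toy_reference()
  # overexpressing glucose-fed GAPD far beyond uptake capacity is infeasible
  cs <- structure(list(candidates = data.frame(id = "GAPD",
                                               modes = "overexpression",
                                               v_ref = fix$ref$fluxes[["GAPD"]]),
                       excluded = character(0)),
                  class = "candidate_set")
  camp <- run_campaign(fix$model, cs, fix$ref, fix$cof, "EX_iboh_e",
                       grid_n = c(1.05, 50))
  expect_identical(camp$status[camp$factor == 50], "infeasible")
  expect_false(any(camp$best[camp$status != "optimal"]))
  expect_true(any(camp$best[camp$status == "optimal"]))
})
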