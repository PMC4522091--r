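test_that("model construction enforces structural invariants", {
  m <- micro_model()
  expect_s3_class(m, "stoichiometric_model")
  expect_identical(dim(stoich_matrix(m)), c(1L, 3L))

  bad_rx <- data.frame(id = c("A", "A"), name = "dup", lower_bound = 0,
                       upper_bound = 1, genes = "", subsystem = "", notes = "")
  expect_error(
    new_model("m", c(c = "c"),
              data.frame(id = "X", name = "X", compartment = "c"),
              bad_rx, list(A = c(X = 1), A = c(X = -1)), "A"),
    "duplicate reaction")

  expect_error(set_bounds(micro_model(), "R_in", 5, 1), "lower > upper")
  expect_error(
    new_model("m", c(c = "c"),
              data.frame(id = "X", name = "X", compartment = "c"),
              data.frame(id = "R", name = "r", lower_bound = 0,
                         upper_bound = 1, genes = "", subsystem = "", notes = ""),
              list(R = c(Y = 1)), "R"),
    "unknown metabolite")
  expect_error(
    new_model("m", c(c = "c"),
              data.frame(id = "X", name = "X", compartment = "c"),
              data.frame(id = "R", name = "r", lower_bound = 0,
                         upper_bound = 1, genes = "", subsystem = "", notes = ""),
              list(R = c(X = 1)), "NOPE"),
    "no objective")
})

test_that("exchange detection follows the single-metabolite convention", {
  m <- toy_defaults()
  ex <- exchange_ids(m)
  expect_true(all(c("EX_glc_e", "EX_o2_e", "EX_iboh_e") %in% ex))
  expect_false(any(c("GAPD", "GLCt", "BIOMASS") %in% ex))
})

test_that("JSON and SBML round trips preserve ids, stoichiometry, bounds and objective", {
  m <- toy_defaults()
  m <- set_bounds(m, "PGI", -1000, 1000)  # exercise a -1000 bound explicitly
  for (fmt in c("json", "sbml")) {
    path <- tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(m, path, fmt)
    m2 <- read_model(path)
    expect_setequal(m2$reactions$id, m$reactions$id)
    expect_setequal(m2$metabolites$id, m$metabolites$id)
    ord <- match(m$reactions$id, m2$reactions$id)
    expect_equal(m2$reactions$lower_bound[ord], m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound[ord], m$reactions$upper_bound)
    expect_identical(m2$objective_id, m$objective_id)
    for (rid in m$reactions$id)
      expect_same_stoichiometry(m2$stoichiometry[[rid]], m$stoichiometry[[rid]])
    unlink(path)
  }
})

test_that("swap-generated reaction ids survive a round trip", {
  fix <- toy_reference()
  pm <- build_swap(fix$model, "GAPD", 1.0, fix$ref, fix$cof)
  path <- tempfile(fileext = ".json")
  write_model(pm, path, "json")
  m2 <- read_model(path)
  expect_true("GAPD_swap" %in% m2$reactions$id)
  expect_same_stoichiometry(m2$stoichiometry[["GAPD_swap"]],
                            pm$stoichiometry[["GAPD_swap"]])
  unlink(path)
})

test_that("read_model reports parse and objective failures explicitly", {
  p <- tempfile(fileext = ".json")
  writeLines("{not json", p)
  expect_error(read_model(p), "parse failure")
  writeLines('{"metabolites": [], "reactions": []}', p)
  expect_error(read_model(p), "no objective")
  unlink(p)
  expect_error(read_model(tempfile()), "not found")
})

test_that("isobutanol pathway augmentation adds the five documented reactions", {
  host <- build_toy_model(toy_model_config(include_isobutanol = FALSE))
  ids <- c(kiv = "kiv", nadph = "nadph", nadp = "nadp", h = "h", co2 = "co2")
  aug <- add_isobutanol_pathway(host, met_ids = ids)
  expect_identical(attr(aug, "added"),
                   c("KIVD_c", "YQHD_c", "IBOHt_cp", "IBOHt_pe", "EX_iboh_e"))
  expect_identical(nrow(aug$reactions), nrow(host$reactions) + 5L)
  expect_true("EX_iboh_e" %in% exchange_ids(aug))
  # the added pathway can actually carry flux (LP check)
  st <- fba(aug, "EX_iboh_e")
  expect_identical(st$status, "optimal")
  expect_gt(st$objective_value, 0)
  # applying twice trips the id-collision guard
  expect_error(add_isobutanol_pathway(aug, met_ids = ids), "collision")
  # missing precursor is named
  noKIV <- drop_reactions(host, "ILV_lump")
  noKIV$metabolites <- noKIV$metabolites[noKIV$metabolites$id != "kiv", ]
  expect_error(add_isobutanol_pathway(noKIV, met_ids = ids),
               "missing precursor metabolite.*kiv")
})

test_that("transhydrogenase variant substitution records provenance", {
  m <- toy_defaults()
  m2 <- modify_transhydrogenase(m, "THD")
  expect_match(m2$reactions$notes[m2$reactions$id == "THD"],
               "original stoichiometry")
  expect_same_stoichiometry(m2$stoichiometry[["THD"]], m$stoichiometry[["THD"]])
  variant <- c(nadh = -1, nadp = -1, nad = 1, nadph = 1)  # uncoupled form
  m3 <- modify_transhydrogenase(m, "THD", variant = variant)
  expect_same_stoichiometry(m3$stoichiometry[["THD"]], variant)
  expect_error(modify_transhydrogenase(m, "THD", variant = c(ghost = -1)),
               "unknown metabolite")
  expect_error(modify_transhydrogenase(m, "NOT_THERE"), "not found")
})

test_that("published transhydrogenase direction string parses to periplasmic proton transport", {
  v <- parse_reaction_string(
    "NADH + NADP^+^ + H^+^(extracellular) -> H^+^(intracellular) + NAD^+^ + NADPH")
  expect_equal(v[["h_p"]], -1)
  expect_equal(v[["h_c"]], 1)
  expect_equal(v[["nadh_c"]], -1)
  expect_equal(v[["nadph_c"]], 1)
  expect_equal(v[["nad_c"]], 1)
  expect_equal(v[["nadp_c"]], -1)
})

test_that("elemental mass balance flags corrupted coefficients and skips formula-free reactions", {
  m <- formula_model()
  rep0 <- validate_mass_balance(m)
  expect_true("CONV" %in% rep0$balanced)
  expect_length(rep0$imbalanced, 0)
  # corrupt the product coefficient: one extra b leaves 3 carbons unbalanced
  bad <- m
  bad$stoichiometry$CONV["b"] <- 2
  repb <- validate_mass_balance(bad)
  expect_equal(unname(repb$imbalanced$CONV["C"]), 3)
  # lumped reactions without formulas are listed, not failed
  toy <- toy_defaults()
  rept <- validate_mass_balance(toy)
  expect_true("GAPD" %in% rept$skipped)
  expect_length(rept$imbalanced, 0)
})

test_that("cofactor swap leaves the elemental balance report unchanged", {
  m <- formula_model()
  cof <- cofactor_spec(c("nad", "nadh"), c("nadp", "nadph"), model = m)
  sw <- swap_cofactor(m, "CONV", cof)
  m2 <- add_reaction(m, sw$id, "swapped", sw$stoichiometry, lower_bound = 0)
  rep2 <- validate_mass_balance(m2)
  expect_true(all(c("CONV", "CONV_swap") %in% rep2$balanced))
  expect_length(rep2$imbalanced, 0)
})
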