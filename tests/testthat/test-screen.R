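test_that("cofactor reaction location finds exactly the redox-coupled reactions", {
  fix <- toy_reference()
  found <- find_cofactor_reactions(fix$model, fix$cof)
  expect_setequal(found, c("GAPD", "G6PDH_lump", "PDH", "LDH", "ADHE",
                           "SUCC_lump", "THD", "ETC", "ILV_lump", "YQHD",
                           "BIOMASS"))
  # a model with no cofactor species errors on unresolved ids; one whose
  # reactions never touch them returns the empty set
  m <- micro_model()
  m$metabolites <- rbind(m$metabolites,
                         data.frame(id = c("nad", "nadh", "nadp", "nadph"),
                                    name = "cof", compartment = "c",
                                    formula = NA, charge = NA))
  expect_length(find_cofactor_reactions(m, cofactor_spec()), 0)
})

test_that("mode classification follows the production/consumption rules", {
  fix <- toy_reference()
  m <- fix$model; cof <- fix$cof; v <- fix$ref$fluxes
  # NADH producer running forward -> swap only
  expect_setequal(classify_modes(m, "GAPD", v[["GAPD"]], cof), "cofactor_swap")
  # NADH consumer -> knockout
  expect_setequal(classify_modes(m, "LDH", v[["LDH"]], cof), "knockout")
  # dual-pair transhydrogenase: overexpression + knockout, never swap
  expect_setequal(classify_modes(m, "THD", v[["THD"]], cof),
                  c("knockout", "overexpression"))
  # NADPH producer -> overexpression
  expect_setequal(classify_modes(m, "G6PDH_lump", v[["G6PDH_lump"]], cof),
                  "overexpression")
  # single-pair NADPH consumer (glutamate-dehydrogenase-like) -> swap + knockout
  m2 <- add_reaction(m, "GLUD_like", "NADPH-consuming amination",
                     c(pyr = -1, nadph = -1, lac = 1, nadp = 1),
                     lower_bound = 0, genes = "gdhA")
  expect_setequal(classify_modes(m2, "GLUD_like", 1.0, cof),
                  c("cofactor_swap", "knockout"))
  # zero net flux with reversible bounds: forward direction, flagged
  modes <- classify_modes(m, "ADHE", 0, cof)
  expect_true("knockout" %in% modes)
  expect_match(attr(modes, "note"), "forward")
})

test_that("candidate filtering applies the exclusion rules and partitions the located set", {
  fix <- toy_reference()
  cs <- filter_candidates(fix$model, fix$ref, fix$cof)
  cand <- cs$candidates
  # survivors per the fixture design: GAPD (bypass keeps it non-essential),
  # fermentative branches, transhydrogenase, oxidative PP shunt
  expect_true(all(c("GAPD", "LDH", "ADHE", "THD", "G6PDH_lump") %in% cand$id))
  expect_identical(unname(cs$excluded["BIOMASS"]), "objective")
  # essential pathway steps are excluded: ILV/YQHD carry the forced secretion
  expect_identical(unname(cs$excluded["ILV_lump"]), "essential")
  expect_identical(unname(cs$excluded["YQHD"]), "essential")
  expect_identical(unname(cs$excluded["PDH"]), "essential")
  # partition property: located = candidates + excluded, no overlap
  located <- find_cofactor_reactions(fix$model, fix$cof)
  expect_setequal(located, c(cand$id, names(cs$excluded)))
  expect_length(intersect(cand$id, names(cs$excluded)), 0)
  # deterministic ordering by id
  expect_identical(cand$id, sort(cand$id))
})

test_that("orphan and no-flux reactions are excluded with their reason codes", {
  fix <- toy_reference()
  m <- fix$model
  # orphan: cofactor reaction with an empty gene set, carrying flux
  m2 <- m
  m2$reactions$genes[m2$reactions$id == "LDH"] <- ""
  ref2 <- reference_state(m2)
  cs2 <- filter_candidates(m2, ref2, fix$cof)
  expect_identical(unname(cs2$excluded["LDH"]), "orphan")
  # no_flux: a cofactor reaction that cannot carry flux (dead-end substrate)
  m3 <- add_reaction(m, "DEAD", "dead-end oxidoreductase",
                     c(kiv = -1, nadh = -1, lac = 1, nad = 1),
                     lower_bound = 0, upper_bound = 0, genes = "deadA",
                     new_metabolites = NULL)
  ref3 <- reference_state(m3)
  cs3 <- filter_candidates(m3, ref3, fix$cof)
  expect_identical(unname(cs3$excluded["DEAD"]), "no_flux")
  # spontaneous tag
  m4 <- m
  m4$reactions$genes[m4$reactions$id == "LDH"] <- "s0001"
  cs4 <- filter_candidates(m4, reference_state(m4), fix$cof)
  expect_identical(unname(cs4$excluded["LDH"]), "spontaneous")
})

test_that("blocklist filtering is monotone and case-insensitive", {
  fix <- toy_reference()
  m <- fix$model
  m$reactions$subsystem[m$reactions$id == "G6PDH_lump"] <-
    "Inorganic Ion Transport and Metabolism"  # force a blocklist hit
  ref <- reference_state(m)
  full <- filter_candidates(m, ref, fix$cof)
  expect_identical(unname(full$excluded["G6PDH_lump"]), "excluded_subsystem")
  # removing entries from the blocklist never shrinks the candidate set
  relaxed <- filter_candidates(m, ref, fix$cof, subsystem_blocklist = character(0))
  expect_true(all(full$candidates$id %in% relaxed$candidates$id))
  expect_true("G6PDH_lump" %in% relaxed$candidates$id)
})

test_that("candidate sets serialize to a stable TSV", {
  fix <- toy_reference()
  cs <- filter_candidates(fix$model, fix$ref, fix$cof)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_candidates_tsv(cs, p1)
  write_candidates_tsv(cs, p2)
  expect_identical(readLines(p1), readLines(p2))
  tab <- utils::read.delim(p1)
  expect_setequal(tab$id, c(cs$candidates$id, names(cs$excluded)))
  unlink(c(p1, p2))
})
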