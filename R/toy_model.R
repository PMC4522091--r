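#' Configuration of the packaged toy network
#'
#' Study conditions for the microaerobic, formate-lyase-deleted,
#' isobutanol-producing E. coli-like toy network: glucose-limited uptake,
#' a low oxygen cap that leaves excess NADH to be recycled through reduced
#' byproducts, a growth-independent ATP maintenance demand, and a minimal
#' isobutanol secretion standing in for the measured production of the
#' producer strain.
#'
#' @param glucose_uptake_bound maximal glucose uptake, mmol/gDCW/h.
#' @param o2_uptake_bound maximal O2 uptake, mmol/gDCW/h (2 = microaerobic).
#' @param atp_maintenance non-growth ATP demand, mmol/gDCW/h.
#' @param isobutanol_secretion_min minimal isobutanol secretion,
#'   mmol/gDCW/h -- the experimentally observed production imposed on the
#'   reference state.
#' @param include_isobutanol include the KIV -> isobutanol branch (default
#'   `TRUE`; set `FALSE` to obtain the pre-pathway host model).
#' @param include_gapdn add the NADP-dependent glyceraldehyde-3-phosphate
#'   dehydrogenase route (`GAPDN`) alongside the native NAD-dependent one.
#' @param gapdn_cap flux cap of the GAPDN route (promoter-strength proxy).
#' @param seed integer seed for randomized model variants.
#' @return list of class `toy_model_config`.
#' @export
toy_model_config <- function(glucose_uptake_bound = 10,
                             o2_uptake_bound = 2,
                             atp_maintenance = 3,
                             isobutanol_secretion_min = 0.5,
                             include_isobutanol = TRUE,
                             include_gapdn = FALSE,
                             gapdn_cap = 1000,
                             seed = 1L) {
  stopifnot(glucose_uptake_bound >= 0, o2_uptake_bound >= 0,
            atp_maintenance >= 0, isobutanol_secretion_min >= 0,
            gapdn_cap >= 0)
  structure(list(glucose_uptake_bound = glucose_uptake_bound,
                 o2_uptake_bound = o2_uptake_bound,
                 atp_maintenance = atp_maintenance,
                 isobutanol_secretion_min = isobutanol_secretion_min,
                 include_isobutanol = include_isobutanol,
                 include_gapdn = include_gapdn,
                 gapdn_cap = gapdn_cap,
                 seed = as.integer(seed)),
            class = "toy_model_config")
}

#' Carbon counts of the toy metabolites
#'
#' The lumped toy reactions omit water, phosphate and protons, so full
#' elemental balancing does not apply; carbon bookkeeping does.  This map
#' supports the carbon-conservation checks of the fixture.
#' @return named integer vector, metabolite id -> carbon atoms.
#' @export
toy_carbon_counts <- function() {
  c(glc_e = 6, glc = 6, g6p = 6, f6p = 6, g3p = 3, pep = 3, pyr = 3,
    accoa = 2, ru5p = 5, co2 = 1, co2_e = 1, kiv = 5, ibald = 4, iboh = 4,
    iboh_e = 4, lac = 3, lac_e = 3, etoh = 2, etoh_e = 2, ac = 2, ac_e = 2,
    succ = 4, succ_e = 4,
    o2 = 0, o2_e = 0, nad = 0, nadh = 0, nadp = 0, nadph = 0,
    atp = 0, adp = 0, h = 0, h_e = 0)
}

#' Build the packaged toy E. coli-like network
#'
#' Deterministic ~35-reaction network emulating the redox structure of a
#' microaerobic, pflB-deleted, isobutanol-producing E. coli: EMP glycolysis
#' with an NAD-dependent GAPD lump, an NADPH-generating oxidative pentose
#' phosphate branch, NADH-consuming lactate/ethanol/succinate fermentative
#' branches (no formate branch), an ATP-coupled NADH -> NADPH
#' transhydrogenase, a respiratory chain capped by the O2 bound, ATP
#' maintenance, a biomass reaction consuming NADPH and ATP, and a
#' 2-NADPH-per-molecule isobutanol pathway.  Glucose enters by a non-PTS
#' lump (transport + hexokinase) and a cofactor-free methylglyoxal-like
#' bypass keeps the GAPD step non-essential, as in the genome-scale host.
#' At the default conditions the reference state secretes reduced
#' byproducts and turns over several-fold more NADH than NADPH -- the
#' imbalance that motivates redox-target screening.
#'
#' @param config a [toy_model_config()].
#' @return a `stoichiometric_model`.
#' @export
build_toy_model <- function(config = toy_model_config()) {
  stopifnot(inherits(config, "toy_model_config"))
  cmp <- c(c = "cytosol", p = "periplasm", e = "extracellular")
  met <- function(id, name, comp) data.frame(id = id, name = name,
                                             compartment = comp,
                                             stringsAsFactors = FALSE)
  mets <- rbind(
    met("glc_e", "D-glucose", "e"), met("glc", "D-glucose", "c"),
    met("g6p", "glucose 6-phosphate", "c"), met("f6p", "fructose 6-phosphate", "c"),
    met("g3p", "glyceraldehyde 3-phosphate", "c"),
    met("pep", "phosphoenolpyruvate", "c"), met("pyr", "pyruvate", "c"),
    met("accoa", "acetyl-CoA", "c"), met("ru5p", "ribulose 5-phosphate", "c"),
    met("co2", "CO2", "c"), met("co2_e", "CO2", "e"),
    met("o2", "O2", "c"), met("o2_e", "O2", "e"),
    met("kiv", "2-ketoisovalerate", "c"),
    met("lac", "D-lactate", "c"), met("lac_e", "D-lactate", "e"),
    met("etoh", "ethanol", "c"), met("etoh_e", "ethanol", "e"),
    met("ac", "acetate", "c"), met("ac_e", "acetate", "e"),
    met("succ", "succinate", "c"), met("succ_e", "succinate", "e"),
    met("nad", "NAD+", "c"), met("nadh", "NADH", "c"),
    met("nadp", "NADP+", "c"), met("nadph", "NADPH", "c"),
    met("atp", "ATP", "c"), met("adp", "ADP", "c"),
    met("h", "H+", "c"), met("h_e", "H+", "e"))
  if (config$include_isobutanol) {
    mets <- rbind(mets,
                  met("ibald", "isobutyraldehyde", "c"),
                  met("iboh", "isobutanol", "c"),
                  met("iboh_e", "isobutanol", "e"))
  }
  mets$formula <- NA_character_
  mets$charge <- NA_integer_

  rxn <- list()
  add <- function(id, name, s, lb = 0, ub = 1000, genes = "",
                  subsystem = "", notes = "") {
    rxn[[id]] <<- list(id = id, name = name, s = s, lb = lb, ub = ub,
                       genes = genes, subsystem = subsystem, notes = notes)
  }
  add("GLCt", "glucose transport", c(glc_e = -1, glc = 1), genes = "galP",
      subsystem = "Transport")
  add("HEX", "hexokinase", c(glc = -1, atp = -1, g6p = 1, adp = 1),
      genes = "glk", subsystem = "Glycolysis")
  add("PGI", "phosphoglucose isomerase", c(g6p = -1, f6p = 1), lb = -1000,
      genes = "pgi", subsystem = "Glycolysis")
  add("PFK_ALD", "phosphofructokinase + aldolase lump",
      c(f6p = -1, atp = -1, g3p = 2, adp = 1), genes = "pfkA;fbaA",
      subsystem = "Glycolysis")
  add("GAPD", "NAD-dependent GAPDH lump (G3P -> PEP)",
      c(g3p = -1, nad = -1, adp = -1, pep = 1, atp = 1, nadh = 1),
      genes = "gapA;pgk;gpmA;eno", subsystem = "Glycolysis")
  add("PYK", "pyruvate kinase", c(pep = -1, adp = -1, pyr = 1, atp = 1),
      genes = "pykF", subsystem = "Glycolysis")
  add("G6PDH_lump", "oxidative pentose phosphate lump",
      c(g6p = -1, nadp = -2, ru5p = 1, co2 = 1, nadph = 2),
      genes = "zwf;pgl;gnd", subsystem = "Pentose phosphate pathway")
  add("TKT_lump", "non-oxidative pentose phosphate lump",
      c(ru5p = -3, f6p = 2, g3p = 1), genes = "tktA;talB",
      subsystem = "Pentose phosphate pathway")
  add("MGX_bypass", "methylglyoxal-like bypass (cofactor-free)",
      c(g3p = -1, pyr = 1), genes = "mgsA", subsystem = "Glycolysis")
  add("PDH", "pyruvate dehydrogenase",
      c(pyr = -1, nad = -1, accoa = 1, co2 = 1, nadh = 1),
      genes = "aceE;aceF;lpd", subsystem = "Central carbon")
  add("LDH", "D-lactate dehydrogenase",
      c(pyr = -1, nadh = -1, lac = 1, nad = 1), genes = "ldhA",
      subsystem = "Fermentation")
  add("ADHE", "acetaldehyde/alcohol dehydrogenase lump",
      c(accoa = -1, nadh = -2, etoh = 1, nad = 2), genes = "adhE",
      subsystem = "Fermentation")
  add("PTACK", "phosphotransacetylase + acetate kinase",
      c(accoa = -1, adp = -1, ac = 1, atp = 1), genes = "pta;ackA",
      subsystem = "Fermentation")
  add("SUCC_lump", "reductive succinate branch lump",
      c(pep = -1, co2 = -1, nadh = -2, succ = 1, nad = 2),
      genes = "ppc;mdh;fumB;frdA", subsystem = "Fermentation")
  add("ILV_lump", "2-ketoisovalerate biosynthesis lump",
      c(pyr = -2, nadph = -1, kiv = 1, co2 = 1, nadp = 1),
      genes = "alsS;ilvC;ilvD", subsystem = "Valine branch")
  add("THD", "proton-coupled transhydrogenase (ATP as pmf proxy)",
      c(nadh = -1, nadp = -1, atp = -1, nad = 1, nadph = 1, adp = 1),
      genes = "pntA;pntB", subsystem = "Redox")
  add("ETC", "respiratory chain lump",
      c(nadh = -1, o2 = -0.5, adp = -2, nad = 1, atp = 2),
      genes = "ndh;cyoA", subsystem = "Oxidative phosphorylation")
  add("ATPM", "ATP maintenance", c(atp = -1, adp = 1),
      lb = config$atp_maintenance, subsystem = "Maintenance",
      notes = "non-growth maintenance demand")
  add("BIOMASS", "biomass lump",
      c(g6p = -0.2, pyr = -1, accoa = -0.5, nadph = -4, atp = -15,
        adp = 15, nadp = 4),
      subsystem = "Biomass")
  if (config$include_isobutanol) {
    add("KIVD", "2-ketoisovalerate decarboxylase",
        c(kiv = -1, ibald = 1, co2 = 1), genes = "kivd",
        subsystem = "Isobutanol synthesis")
    add("YQHD", "isobutanol dehydrogenase (NADPH)",
        c(ibald = -1, nadph = -1, iboh = 1, nadp = 1), genes = "yqhD",
        subsystem = "Isobutanol synthesis")
    add("IBOHt", "isobutanol secretion", c(iboh = -1, iboh_e = 1),
        subsystem = "Transport")
    add("EX_iboh_e", "isobutanol exchange", c(iboh_e = -1),
        lb = config$isobutanol_secretion_min, subsystem = "Exchange")
  }
  if (config$include_gapdn) {
    add("GAPDN", "NADP-dependent GAPDH lump (G3P -> PEP)",
        c(g3p = -1, nadp = -1, adp = -1, pep = 1, atp = 1, nadph = 1),
        ub = config$gapdn_cap, genes = "gapN", subsystem = "Glycolysis")
  }
  add("O2t", "O2 diffusion", c(o2_e = -1, o2 = 1), subsystem = "Transport")
  add("CO2t", "CO2 diffusion", c(co2 = -1, co2_e = 1), lb = -1000,
      subsystem = "Transport")
  add("LACt", "lactate secretion", c(lac = -1, lac_e = 1), subsystem = "Transport")
  add("ETOHt", "ethanol secretion", c(etoh = -1, etoh_e = 1), subsystem = "Transport")
  add("ACt", "acetate secretion", c(ac = -1, ac_e = 1), subsystem = "Transport")
  add("SUCCt", "succinate secretion", c(succ = -1, succ_e = 1), subsystem = "Transport")
  add("Ht", "proton diffusion", c(h_e = -1, h = 1), lb = -1000, subsystem = "Transport")
  add("EX_glc_e", "glucose exchange", c(glc_e = -1),
      lb = -config$glucose_uptake_bound, ub = 0, subsystem = "Exchange")
  add("EX_o2_e", "O2 exchange", c(o2_e = -1),
      lb = -config$o2_uptake_bound, ub = 0, subsystem = "Exchange")
  add("EX_co2_e", "CO2 exchange", c(co2_e = -1), subsystem = "Exchange")
  add("EX_lac_e", "lactate exchange", c(lac_e = -1), subsystem = "Exchange")
  add("EX_etoh_e", "ethanol exchange", c(etoh_e = -1), subsystem = "Exchange")
  add("EX_ac_e", "acetate exchange", c(ac_e = -1), subsystem = "Exchange")
  add("EX_succ_e", "succinate exchange", c(succ_e = -1), subsystem = "Exchange")
  add("EX_h_e", "proton exchange", c(h_e = -1), lb = -1000, subsystem = "Exchange")

  reactions <- do.call(rbind, lapply(rxn, function(r) {
    data.frame(id = r$id, name = r$name, lower_bound = r$lb,
               upper_bound = r$ub, genes = r$genes, subsystem = r$subsystem,
               notes = r$notes, stringsAsFactors = FALSE)
  }))
  stoich <- lapply(rxn, `[[`, "s")
  names(stoich) <- names(rxn)
  new_model(id = "toy_redox", compartments = cmp, metabolites = mets,
            reactions = reactions, stoichiometry = stoich,
            objective_id = "BIOMASS")
}

#' Cofactor spec of the toy model
#' @return a [cofactor_spec()] naming the toy NAD(H)/NADP(H) species.
#' @export
toy_cofactor_spec <- function() {
  cofactor_spec(c("nad", "nadh"), c("nadp", "nadph"))
}

#' Seeded random cofactor network for property tests
#'
#' Generates a small feasible stoichiometric network: a linear backbone
#' pathway from an uptaken substrate to a secreted sink (guaranteeing a
#' nonzero objective flux), plus random branch reactions, with NAD or NADP
#' cofactor pairs attached to a random subset of conversions.
#'
#' @param seed integer seed; identical seeds give identical models.
#' @param n_backbone backbone length (metabolites), >= 2.
#' @param n_branches number of random branch reactions.
#' @return a `stoichiometric_model` whose objective is the sink exchange.
#' @export
random_cofactor_model <- function(seed = 1L, n_backbone = 6L, n_branches = 8L) {
  stopifnot(n_backbone >= 2L, n_backbone + n_branches <= 50L)
  rng <- .seeded_rng(seed)
  ids <- paste0("m", seq_len(n_backbone))
  mets <- data.frame(id = c(ids, "nad", "nadh", "nadp", "nadph"),
                     name = c(ids, "NAD+", "NADH", "NADP+", "NADPH"),
                     compartment = "c", formula = NA_character_,
                     charge = NA_integer_, stringsAsFactors = FALSE)
  rxn_ids <- character(0); stoich <- list()
  rows <- list()
  addr <- function(id, s, lb, ub, genes = "g") {
    rxn_ids <<- c(rxn_ids, id)
    stoich[[id]] <<- s
    rows[[id]] <<- data.frame(id = id, name = id, lower_bound = lb,
                              upper_bound = ub, genes = genes, subsystem = "",
                              notes = "", stringsAsFactors = FALSE)
  }
  addr("UPT", stats::setNames(1, ids[1]), 0, 10)
  cof_count <- c(nad = 0, nadp = 0)
  for (i in seq_len(n_backbone - 1L)) {
    s <- stats::setNames(c(-1, 1), c(ids[i], ids[i + 1]))
    roll <- rng()
    if (roll < 0.4) {
      s <- c(s, c(nad = -1, nadh = 1)); cof_count["nad"] <- cof_count["nad"] + 1
    } else if (roll < 0.7) {
      s <- c(s, c(nadp = -1, nadph = 1)); cof_count["nadp"] <- cof_count["nadp"] + 1
    }
    addr(paste0("B", i), s, 0, 1000)
  }
  # cofactor regeneration loops keep redox-carrying backbones feasible
  addr("REGEN_NAD", c(nadh = -1, nad = 1), 0, 1000)
  addr("REGEN_NADP", c(nadph = -1, nadp = 1), 0, 1000)
  for (b in seq_len(n_branches)) {
    from <- ids[1L + floor(rng() * (n_backbone - 1L))]
    to <- ids[1L + floor(rng() * n_backbone)]
    if (from == to) next
    s <- stats::setNames(c(-1, 1), c(from, to))
    roll <- rng()
    if (roll < 0.3) s <- c(s, c(nad = -1, nadh = 1))
    else if (roll < 0.5) s <- c(s, c(nadh = -1, nad = 1))
    else if (roll < 0.65) s <- c(s, c(nadp = -1, nadph = 1))
    else if (roll < 0.8) s <- c(s, c(nadph = -1, nadp = 1))
    addr(paste0("R", b), s, 0, 1000)
  }
  addr("SINK", stats::setNames(-1, ids[n_backbone]), 0, 1000)
  reactions <- do.call(rbind, rows[rxn_ids])
  new_model(id = paste0("random_cofactor_", seed),
            compartments = c(c = "cytosol"),
            metabolites = mets, reactions = reactions,
            stoichiometry = stoich, objective_id = "SINK")
}

# small deterministic RNG (linear congruential), independent of the global
# .Random.seed so model generation never perturbs user RNG state
.seeded_rng <- function(seed) {
  state <- as.numeric(seed) %% 2147483647
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}
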