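# Shared fixtures, built in code.

# three-reaction chain with a redundant drain: R_in fills X, R_obj and R_alt
# drain it; FBA optimum 10 through R_obj, reference (10, 10, 0)
micro_model <- function(ub = 10) {
  new_model(
    id = "micro", compartments = c(c = "c"),
    metabolites = data.frame(id = "X", name = "X", compartment = "c",
                             stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("R_in", "R_obj", "R_alt"),
      name = c("inflow", "objective drain", "alternate drain"),
      lower_bound = 0, upper_bound = ub, genes = "g", subsystem = "",
      notes = "", stringsAsFactors = FALSE),
    stoichiometry = list(R_in = c(X = 1), R_obj = c(X = -1), R_alt = c(X = -1)),
    objective_id = "R_obj")
}

# two-metabolite model with full elemental formulas, for mass-balance tests
formula_model <- function(conv_stoich = c(a = -1, nad = -1, b = 1, nadh = 1)) {
  new_model(
    id = "formulas", compartments = c(c = "c"),
    metabolites = data.frame(
      id = c("a", "b", "nad", "nadh", "nadp", "nadph"),
      name = c("a", "b", "NAD+", "NADH", "NADP+", "NADPH"),
      compartment = "c",
      formula = c("C3H6O3", "C3H5O3", "C21H26N7O14P2", "C21H27N7O14P2",
                  "C21H25N7O17P3", "C21H26N7O17P3"),
      charge = NA_integer_, stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("CONV", "EX_a", "EX_b"),
      name = c("conversion", "a exchange", "b exchange"),
      lower_bound = c(0, -10, 0), upper_bound = 10,
      genes = c("g1", "", ""), subsystem = "", notes = "",
      stringsAsFactors = FALSE),
    stoichiometry = list(CONV = conv_stoich, EX_a = c(a = 1), EX_b = c(b = -1)),
    objective_id = "EX_b")
}

toy_defaults <- function() build_toy_model()

toy_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- build_toy_model()
      cache <<- list(model = m, ref = reference_state(m),
                     cof = toy_cofactor_spec())
    }
    cache
  }
})

expect_same_stoichiometry <- function(a, b) {
  expect_setequal(names(a), names(b))
  expect_equal(a[order(names(a))], b[order(names(b))])
}
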