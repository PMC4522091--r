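#' Add the NADPH-dependent isobutanol pathway to a model
#'
#' Appends the two conversion steps of the Ehrlich route from
#' 2-ketoisovalerate (KIV) -- KIV decarboxylase (`KIVD_c`:
#' kiv + h -> isobutyraldehyde + co2) and the NADPH-dependent isobutanol
#' dehydrogenase (`YQHD_c`: isobutyraldehyde + nadph + h -> isobutanol +
#' nadp) -- plus the transport chain moving isobutanol cytosol -> periplasm
#' -> extracellular and its boundary exchange (`IBOHt_cp`, `IBOHt_pe`,
#' `EX_iboh_e`).  Five reactions in total; the isobutanol metabolites are
#' created in all three compartments.  Applying the function twice raises an
#' id-collision error.
#'
#' @param model a `stoichiometric_model` containing KIV, NADPH/NADP, H+ and
#'   CO2 in the cytosolic compartment.
#' @param compartment_ids named character of compartment ids,
#'   `c(c = ..., p = ..., e = ...)`.
#' @param met_ids named character giving the ids of the required cytosolic
#'   precursors (`kiv`, `nadph`, `nadp`, `h`, `co2`).
#' @param prefix named character overriding the generated ids; defaults
#'   are `KIVD_c`, `YQHD_c`, `IBOHt_cp`, `IBOHt_pe`, `EX_iboh_e` with
#'   metabolites `iboh_c`, `iboh_p`, `iboh_e` and intermediate `ibald_c`.
#' @return the augmented model, with a manifest of added reaction ids in
#'   `attr(, "added")`.
#' @export
add_isobutanol_pathway <- function(model,
                                   compartment_ids = c(c = "c", p = "p", e = "e"),
                                   met_ids = c(kiv = "kiv_c", nadph = "nadph_c",
                                               nadp = "nadp_c", h = "h_c",
                                               co2 = "co2_c"),
                                   prefix = c(kivd = "KIVD_c", adh = "YQHD_c",
                                              t_cp = "IBOHt_cp", t_pe = "IBOHt_pe",
                                              ex = "EX_iboh_e")) {
  for (k in names(met_ids)) {
    if (!met_ids[[k]] %in% model$metabolites$id)
      stop("missing precursor metabolite for isobutanol pathway: ", met_ids[[k]])
  }
  clash <- intersect(prefix, model$reactions$id)
  if (length(clash))
    stop("reaction id collision (pathway already present?): ",
         paste(clash, collapse = ", "))
  for (cid in compartment_ids[c("p", "e")]) {
    if (!cid %in% names(model$compartments))
      model$compartments[cid] <- cid
  }
  new_mets <- data.frame(
    id = c("ibald_c", "iboh_c", "iboh_p", "iboh_e"),
    name = c("isobutyraldehyde", "isobutanol", "isobutanol", "isobutanol"),
    compartment = c(compartment_ids[["c"]], compartment_ids[["c"]],
                    compartment_ids[["p"]], compartment_ids[["e"]]),
    formula = c("C4H8O", "C4H10O", "C4H10O", "C4H10O"),
    stringsAsFactors = FALSE)
  new_mets <- new_mets[!new_mets$id %in% model$metabolites$id, , drop = FALSE]

  model <- add_reaction(
    model, prefix[["kivd"]], "2-ketoisovalerate decarboxylase",
    stats::setNames(c(-1, -1, 1, 1),
                    c(met_ids[["kiv"]], met_ids[["h"]], "ibald_c", met_ids[["co2"]])),
    lower_bound = 0, genes = "kivd", subsystem = "Isobutanol synthesis",
    new_metabolites = new_mets)
  model <- add_reaction(
    model, prefix[["adh"]], "isobutanol dehydrogenase (NADPH)",
    stats::setNames(c(-1, -1, -1, 1, 1),
                    c("ibald_c", met_ids[["nadph"]], met_ids[["h"]],
                      "iboh_c", met_ids[["nadp"]])),
    lower_bound = 0, genes = "yqhD", subsystem = "Isobutanol synthesis")
  model <- add_reaction(model, prefix[["t_cp"]], "isobutanol transport c->p",
                        c(iboh_c = -1, iboh_p = 1), lower_bound = 0,
                        subsystem = "Transport")
  model <- add_reaction(model, prefix[["t_pe"]], "isobutanol transport p->e",
                        c(iboh_p = -1, iboh_e = 1), lower_bound = 0,
                        subsystem = "Transport")
  model <- add_reaction(model, prefix[["ex"]], "isobutanol exchange",
                        c(iboh_e = -1), lower_bound = 0,
                        subsystem = "Exchange")
  validate_model(model)
  attr(model, "added") <- unname(prefix)
  model
}

#' Replace the transhydrogenase stoichiometry
#'
#' Substitutes the stoichiometry of the membrane-bound, proton-translocating
#' transhydrogenase (pntAB; reaction `THD2pp` in iJO1366) with a supplied
#' variant.  The original stoichiometry is recorded in the reaction notes for
#' provenance.  The default keeps the native proton-coupled form
#' (NADH + NADP+ + 2 H+(periplasm) -> NAD+ + NADPH + 2 H+(cytosol)), i.e. the
#' call is a no-op apart from the provenance note unless a variant is given.
#'
#' @param model a `stoichiometric_model`.
#' @param reaction_id transhydrogenase reaction id (default `"THD2pp"`).
#' @param variant named numeric stoichiometry to install, or `NULL` to keep
#'   the current one.
#' @return the modified model.
#' @export
modify_transhydrogenase <- function(model, reaction_id = "THD2pp",
                                    variant = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("transhydrogenase reaction not found: ", reaction_id)
  old <- model$stoichiometry[[reaction_id]]
  if (!is.null(variant)) {
    unknown <- setdiff(names(variant), model$metabolites$id)
    if (length(unknown))
      stop("variant references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (!length(variant) || all(variant == 0))
      stop("variant stoichiometry is empty")
    model$stoichiometry[[reaction_id]] <- variant
  }
  prov <- paste0("original stoichiometry: ",
                 paste(sprintf("%s:%g", names(old), old), collapse = " "))
  note <- model$reactions$notes[i]
  model$reactions$notes[i] <- if (nzchar(note)) paste(note, prov, sep = " | ") else prov
  model
}

#' Parse a transhydrogenase direction string into a stoichiometry variant
#'
#' Parses descriptors of the form
#' `"NADH + NADP+ + H+(extracellular) -> H+(intracellular) + NAD+ + NADPH"`
#' into a named coefficient vector, mapping the species labels to model ids.
#' Proton transport across the membrane is kept by mapping
#' `(extracellular)`/`(intracellular)` protons to the periplasmic and
#' cytosolic species.
#'
#' @param text direction string with `->` (or unicode arrow) separating
#'   substrates from products; species separated by `+` surrounded by spaces;
#'   an integer prefix is read as the coefficient.
#' @param species named character mapping species labels (upper-case,
#'   superscripts stripped) to metabolite ids.
#' @return named numeric stoichiometry.
#' @export
parse_reaction_string <- function(text,
                                  species = c("NADH" = "nadh_c",
                                              "NADP+" = "nadp_c",
                                              "NAD+" = "nad_c",
                                              "NADPH" = "nadph_c",
                                              "H+(EXTRACELLULAR)" = "h_p",
                                              "H+(INTRACELLULAR)" = "h_c")) {
  text <- gsub("→|⇒|=>", "->", text)
  text <- gsub("\\^|\\*", "", text)  # strip markup superscripts
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("expected exactly one '->' in: ", text)
  parse_side <- function(side, sign) {
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (t in terms) {
      mm <- regmatches(t, regexec("^([0-9.]+)\\s+(.*)$", t))[[1]]
      coef <- 1
      lab <- t
      if (length(mm) == 3L) { coef <- as.numeric(mm[2]); lab <- mm[3] }
      key <- toupper(gsub("\\s", "", lab))
      if (!key %in% names(species))
        stop("unknown species label '", lab, "' in reaction string")
      id <- species[[key]]
      out[id] <- (if (id %in% names(out)) out[[id]] else 0) + sign * coef
    }
    out
  }
  c(parse_side(sides[1], -1), parse_side(sides[2], +1))
}

#' Elemental mass-balance report
#'
#' For every reaction whose metabolites all carry elemental formulas,
#' reports the per-element imbalance `sum(coefficient x element count)`.
#' Exchange reactions are exempt (they cross the system boundary by
#' construction); reactions with any formula-free metabolite are skipped and
#' listed, not failed.
#'
#' @param model a `stoichiometric_model`.
#' @return list with `balanced` (character), `imbalanced` (named list of
#'   nonzero element imbalance vectors), `skipped` (reactions with missing
#'   formulas) and `exchanges`.
#' @export
validate_mass_balance <- function(model, tol = 1e-9) {
  ex <- exchange_ids(model)
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  balanced <- character(0); skipped <- character(0); imb <- list()
  for (rid in setdiff(model$reactions$id, ex)) {
    s <- model$stoichiometry[[rid]]
    f <- formulas[names(s)]
    if (anyNA(f)) { skipped <- c(skipped, rid); next }
    counts <- lapply(f, parse_formula)
    elements <- unique(unlist(lapply(counts, names)))
    bal <- stats::setNames(numeric(length(elements)), elements)
    for (k in seq_along(s)) {
      ck <- counts[[k]]
      bal[names(ck)] <- bal[names(ck)] + s[[k]] * ck
    }
    if (any(abs(bal) > tol)) imb[[rid]] <- bal[abs(bal) > tol]
    else balanced <- c(balanced, rid)
  }
  list(balanced = balanced, imbalanced = imb, skipped = skipped, exchanges = ex)
}

#' Parse an elemental formula
#'
#' @param formula string such as `"C6H12O6"`; element symbols are one upper
#'   case letter optionally followed by a lower case letter, counts default
#'   to 1.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  out <- numeric(0)
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    add <- if (nzchar(n)) as.numeric(n) else 1
    out[el] <- if (el %in% names(out)) out[[el]] + add else add
  }
  out
}
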