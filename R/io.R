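#' Read a stoichiometric model from disk
#'
#' Supports BiGG-style JSON (the format distributed by the BiGG database)
#' and SBML Level 3 with the Flux Balance Constraints (FBC) extension.
#' Missing bounds default to +/-1000 mmol/gDCW/h; the objective is taken
#' from the `objective_coefficient` fields (JSON) or the active FBC
#' objective (SBML).
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; the default guesses from the file
#'   extension (`.json` vs `.xml`/`.sbml`).
#' @return a validated `stoichiometric_model`.
#' @seealso [write_model()]
#' @export
read_model <- function(path, format = c("guess", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format, json = .read_model_json(path), sbml = .read_model_sbml(path))
}

#' Write a stoichiometric model to disk
#'
#' The emitted file re-reads (with [read_model()]) to a model with identical
#' id sets, stoichiometry, bounds and objective.
#'
#' @param model a `stoichiometric_model`.
#' @param path output file path.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  switch(format, json = .write_model_json(model, path),
         sbml = .write_model_sbml(model, path))
  invisible(path)
}

## ---- BiGG-style JSON ----

.read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e)))
  for (k in c("metabolites", "reactions")) {
    if (is.null(doc[[k]])) stop("format error: missing '", k, "' array")
  }
  cmp <- if (!is.null(doc$compartments) && length(doc$compartments)) {
    unlist(doc$compartments)
  } else {
    cc <- unique(vapply(doc$metabolites, function(m) m$compartment %||% "c",
                        character(1)))
    stats::setNames(cc, cc)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("format error: metabolite without id")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% names(cmp)[1],
               formula = m$formula %||% NA_character_,
               charge = as.integer(m$charge %||% NA_integer_),
               stringsAsFactors = FALSE)
  }))
  obj <- character(0)
  stoich <- list()
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("format error: reaction without id")
    s <- unlist(r$metabolites)
    stoich[[r$id]] <<- s
    if (isTRUE((r$objective_coefficient %||% 0) != 0)) obj <<- c(obj, r$id)
    data.frame(id = r$id, name = r$name %||% r$id,
               lower_bound = as.numeric(r$lower_bound %||% -1000),
               upper_bound = as.numeric(r$upper_bound %||% 1000),
               genes = .genes_from_rule(r$gene_reaction_rule %||% ""),
               subsystem = r$subsystem %||% "",
               notes = r$notes %||% "",
               stringsAsFactors = FALSE)
  }))
  if (length(obj) != 1L)
    stop("no objective: expected exactly one reaction with nonzero ",
         "objective_coefficient, found ", length(obj))
  new_model(id = doc$id %||% basename(path), compartments = cmp,
            metabolites = mets, reactions = rxns, stoichiometry = stoich,
            objective_id = obj)
}

.write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    compartments = as.list(model$compartments),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      s <- model$stoichiometry[[r$id]]
      list(id = r$id, name = r$name, metabolites = as.list(s),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = gsub(";", " or ", r$genes, fixed = TRUE),
           subsystem = r$subsystem, notes = r$notes,
           objective_coefficient = as.integer(r$id == model$objective_id))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# flatten a BiGG gene_reaction_rule to the set of gene tokens, ";"-joined
.genes_from_rule <- function(rule) {
  if (is.null(rule) || !nzchar(rule)) return("")
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  toks <- toks[nzchar(toks) & !tolower(toks) %in% c("and", "or")]
  paste(unique(toks), collapse = ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- SBML Level 3 + FBC ----

.SBML_NS <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
              fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e)))
  ns <- .SBML_NS
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("format error: no <model> element")
  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  cmp <- stats::setNames(
    vapply(comp_nodes, function(n) xml2::xml_attr(n, "name") %||na%
             xml2::xml_attr(n, "id"), character(1)),
    vapply(comp_nodes, xml2::xml_attr, character(1), attr = "id"))
  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(
    as.numeric(vapply(params, xml2::xml_attr, character(1), attr = "value")),
    vapply(params, xml2::xml_attr, character(1), attr = "id"))

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp, function(n) {
    data.frame(id = xml2::xml_attr(n, "id"),
               name = xml2::xml_attr(n, "name") %||na% xml2::xml_attr(n, "id"),
               compartment = xml2::xml_attr(n, "compartment"),
               formula = xml2::xml_attr(n, "fbc:chemicalFormula", ns = ns),
               charge = suppressWarnings(as.integer(xml2::xml_attr(n, "fbc:charge", ns = ns))),
               stringsAsFactors = FALSE)
  }))

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("format error: no reactions")
  stoich <- list()
  rxns <- do.call(rbind, lapply(rx, function(n) {
    rid <- xml2::xml_attr(n, "id")
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(n, xp, ns)
      if (!length(nodes)) return(numeric(0))
      stats::setNames(
        sign * as.numeric(vapply(nodes, xml2::xml_attr, character(1),
                                 attr = "stoichiometry")),
        vapply(nodes, xml2::xml_attr, character(1), attr = "species"))
    }
    s <- c(refs("./s:listOfReactants/s:speciesReference", -1),
           refs("./s:listOfProducts/s:speciesReference", +1))
    if (!length(s)) stop("format error: reaction ", rid, " has no species references")
    s <- tapply(s, names(s), sum)  # merge duplicated species
    stoich[[rid]] <<- stats::setNames(as.numeric(s), names(s))
    lb_id <- xml2::xml_attr(n, "fbc:lowerFluxBound", ns = ns)
    ub_id <- xml2::xml_attr(n, "fbc:upperFluxBound", ns = ns)
    gp <- xml2::xml_find_all(n, ".//fbc:geneProductRef", ns)
    genes <- unique(vapply(gp, xml2::xml_attr, character(1), attr = "fbc:geneProduct", ns = ns))
    notes_n <- xml2::xml_find_first(n, "./s:notes", ns)
    notes <- if (inherits(notes_n, "xml_missing")) "" else
      trimws(xml2::xml_text(notes_n))
    subsystem <- ""
    if (grepl("SUBSYSTEM:", notes)) {
      subsystem <- trimws(sub(".*SUBSYSTEM:\\s*([^|]*).*", "\\1", notes))
      notes <- trimws(sub("SUBSYSTEM:[^|]*\\|?", "", notes))
    }
    data.frame(id = rid,
               name = xml2::xml_attr(n, "name") %||na% rid,
               lower_bound = if (!is.na(lb_id)) pval[[lb_id]] else -1000,
               upper_bound = if (!is.na(ub_id)) pval[[ub_id]] else 1000,
               genes = paste(genes, collapse = ";"),
               subsystem = subsystem, notes = notes,
               stringsAsFactors = FALSE)
  }))

  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing")) stop("no objective: missing FBC objective")
  obj <- xml2::xml_attr(fo, "fbc:reaction", ns = ns)

  new_model(id = xml2::xml_attr(mdl, "id") %||na% basename(path),
            compartments = cmp, metabolites = mets, reactions = rxns,
            stoichiometry = stoich, objective_id = obj)
}

`%||na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

.write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', .SBML_NS[["s"]], '" xmlns:fbc="', .SBML_NS[["fbc"]],
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(model$id), '" fbc:strict="true">')
  w('    <listOfCompartments>')
  for (i in seq_along(model$compartments))
    w('      <compartment id="', esc(names(model$compartments)[i]), '" name="',
      esc(model$compartments[[i]]), '" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$formula)) extra <- paste0(extra, ' fbc:chemicalFormula="', esc(m$formula), '"')
    if (!is.na(m$charge)) extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
    w('      <species id="', esc(m$id), '" name="', esc(m$name),
      '" compartment="', esc(m$compartment),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
      extra, '/>')
  }
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    w('      <parameter id="lb_', i, '" value="', num(r$lower_bound), '" constant="true"/>')
    w('      <parameter id="ub_', i, '" value="', num(r$upper_bound), '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[[r$id]]
    w('      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', tolower(r$lower_bound < 0), '" fast="false"',
      ' fbc:lowerFluxBound="lb_', i, '" fbc:upperFluxBound="ub_', i, '">')
    notes <- r$notes
    if (nzchar(r$subsystem))
      notes <- paste0("SUBSYSTEM: ", r$subsystem,
                      if (nzchar(notes)) paste0(" | ", notes) else "")
    if (nzchar(notes)) w('        <notes>', esc(notes), '</notes>')
    rs <- s[s < 0]; ps <- s[s > 0]
    if (length(rs)) {
      w('        <listOfReactants>')
      for (k in seq_along(rs))
        w('          <speciesReference species="', esc(names(rs)[k]),
          '" stoichiometry="', num(-rs[k]), '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(ps)) {
      w('        <listOfProducts>')
      for (k in seq_along(ps))
        w('          <speciesReference species="', esc(names(ps)[k]),
          '" stoichiometry="', num(ps[k]), '" constant="true"/>')
      w('        </listOfProducts>')
    }
    genes <- if (nzchar(r$genes)) strsplit(r$genes, ";", fixed = TRUE)[[1]] else character(0)
    if (length(genes)) {
      w('        <fbc:geneProductAssociation>')
      if (length(genes) > 1L) w('          <fbc:or>')
      pad <- if (length(genes) > 1L) '            ' else '          '
      for (g in genes)
        w(pad, '<fbc:geneProductRef fbc:geneProduct="', esc(g), '"/>')
      if (length(genes) > 1L) w('          </fbc:or>')
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('        <fbc:listOfFluxObjectives>')
  w('          <fbc:fluxObjective fbc:reaction="', esc(model$objective_id),
    '" fbc:coefficient="1"/>')
  w('        </fbc:listOfFluxObjectives>')
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  w('  </model>')
  w('</sbml>')
}
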