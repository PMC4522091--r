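#' Construct a stoichiometric metabolic model
#'
#' A `stoichiometric_model` bundles metabolites, reactions with bounds and a
#' biomass objective into the container used by every other function in the
#' package.  Reactions are stored as sparse stoichiometry maps
#' (metabolite id -> coefficient, negative = consumed); the dense
#' stoichiometric matrix is derived on demand with [stoich_matrix()].
#'
#' @param id model identifier.
#' @param compartments named character vector, compartment id -> label
#'   (e.g. `c(c = "cytosol", p = "periplasm", e = "extracellular")`).
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   and optionally `formula` (elemental formula string, `NA` when unknown)
#'   and `charge`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `genes` (semicolon-separated gene tokens, `""` for
#'   orphans), `subsystem`, `notes`.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients.
#' @param objective_id reaction id of the biomass (objective) reaction.
#' @return an object of class `stoichiometric_model`.
#' @seealso [validate_model()], [read_model()], [build_toy_model()]
#' @export
new_model <- function(id, compartments, metabolites, reactions, stoichiometry,
                      objective_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  for (col in c("genes", "subsystem", "notes")) {
    if (is.null(reactions[[col]])) reactions[[col]] <- ""
    reactions[[col]][is.na(reactions[[col]])] <- ""
  }
  m <- structure(
    list(id = id, compartments = compartments, metabolites = metabolites,
         reactions = reactions, stoichiometry = stoichiometry,
         objective_id = objective_id),
    class = "stoichiometric_model")
  validate_model(m)
  m
}

#' Validate a stoichiometric model
#'
#' Checks the structural invariants: unique non-empty ids, compartments
#' drawn from the declared set, bounds ordered, every stoichiometry entry
#' resolving to a metabolite, at least one nonzero coefficient per reaction,
#' and an existing objective reaction.
#'
#' @param model a `stoichiometric_model`.
#' @return the model, invisibly; errors on the first violated invariant.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids: ",
                                  paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (any(!nzchar(met$id))) stop("empty metabolite id")
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids: ",
                                  paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  bad <- setdiff(met$compartment, names(model$compartments))
  if (length(bad)) stop("undeclared compartment(s): ", paste(bad, collapse = ", "))
  if (any(rxn$lower_bound > rxn$upper_bound))
    stop("lower_bound > upper_bound for: ",
         paste(rxn$id[rxn$lower_bound > rxn$upper_bound], collapse = ", "))
  if (!setequal(names(model$stoichiometry), rxn$id))
    stop("stoichiometry list and reaction table disagree")
  for (rid in rxn$id) {
    s <- model$stoichiometry[[rid]]
    if (!length(s) || all(s == 0)) stop("reaction ", rid, " has empty stoichiometry")
    unknown <- setdiff(names(s), met$id)
    if (length(unknown))
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!model$objective_id %in% rxn$id)
    stop("no objective: reaction '", model$objective_id, "' not in model")
  invisible(model)
}

#' @export
print.stoichiometric_model <- function(x, ...) {
  cat("<stoichiometric_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model a `stoichiometric_model`.
#' @return numeric matrix S (metabolites x reactions) with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rids <- model$reactions$id
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (j in seq_along(rids)) {
    s <- model$stoichiometry[[rids[j]]]
    S[names(s), j] <- s
  }
  S
}

#' Boundary (exchange) reactions of a model
#'
#' An exchange reaction touches exactly one metabolite, crossing the system
#' boundary.  By the BiGG sign convention a negative exchange flux is uptake.
#'
#' @param model a `stoichiometric_model`.
#' @return character vector of reaction ids.
#' @export
exchange_ids <- function(model) {
  model$reactions$id[vapply(model$stoichiometry[model$reactions$id],
                            function(s) sum(s != 0) == 1L, logical(1))]
}

#' Look up reaction bounds
#' @param model a `stoichiometric_model`.
#' @param id reaction id.
#' @return numeric `c(lower, upper)`.
#' @export
reaction_bounds <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id)
  c(model$reactions$lower_bound[i], model$reactions$upper_bound[i])
}

#' Set reaction bounds
#' @inheritParams reaction_bounds
#' @param lower,upper new bounds (flux, mmol/gDCW/h).
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lower, upper) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id)
  if (lower > upper) stop("lower > upper for ", id)
  model$reactions$lower_bound[i] <- lower
  model$reactions$upper_bound[i] <- upper
  model
}

#' Gene tokens of a reaction
#' @inheritParams reaction_bounds
#' @return character vector (possibly empty) of gene tokens.
#' @export
reaction_genes <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id)
  g <- model$reactions$genes[i]
  if (!nzchar(g)) character(0) else strsplit(g, ";", fixed = TRUE)[[1]]
}

#' Add a reaction to a model
#'
#' @param model a `stoichiometric_model`.
#' @param id,name reaction id (must be new) and display name.
#' @param stoichiometry named numeric vector of coefficients; metabolites
#'   not yet in the model must be declared via `new_metabolites`.
#' @param lower_bound,upper_bound flux bounds.
#' @param genes,subsystem,notes annotation fields.
#' @param new_metabolites optional data.frame (`id`, `name`, `compartment`,
#'   optional `formula`, `charge`) of metabolites to add first.
#' @return the extended model.
#' @export
add_reaction <- function(model, id, name, stoichiometry,
                         lower_bound = -1000, upper_bound = 1000,
                         genes = "", subsystem = "", notes = "",
                         new_metabolites = NULL) {
  if (id %in% model$reactions$id) stop("reaction id collision: ", id)
  if (!is.null(new_metabolites)) {
    new_metabolites <- as.data.frame(new_metabolites, stringsAsFactors = FALSE)
    if (is.null(new_metabolites$formula)) new_metabolites$formula <- NA_character_
    if (is.null(new_metabolites$charge)) new_metabolites$charge <- NA_integer_
    clash <- intersect(new_metabolites$id, model$metabolites$id)
    if (length(clash)) stop("metabolite id collision: ", paste(clash, collapse = ", "))
    model$metabolites <- rbind(model$metabolites,
                               new_metabolites[names(model$metabolites)])
  }
  unknown <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(unknown))
    stop("reaction ", id, " references unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, name = name, lower_bound = lower_bound, upper_bound = upper_bound,
    genes = genes, subsystem = subsystem, notes = notes,
    stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoichiometry
  model
}

#' Remove reactions from a model
#' @param model a `stoichiometric_model`.
#' @param ids reaction ids to drop.
#' @return the reduced model.
#' @export
drop_reactions <- function(model, ids) {
  missing <- setdiff(ids, model$reactions$id)
  if (length(missing)) stop("unknown reaction(s): ", paste(missing, collapse = ", "))
  keep <- !model$reactions$id %in% ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model
}
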