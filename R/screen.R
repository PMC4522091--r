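#' Default excluded subsystems for candidate filtering
#'
#' Biosynthetic and transport subsystems whose oxidoreductases are poor
#' engineering targets (membrane assembly, tRNA charging, ion transport):
#' manipulating them is either lethal in vivo or irrelevant to central redox
#' metabolism.
#' @export
default_subsystem_blocklist <- function() {
  c("cell envelope biosynthesis",
    "glycerophospholipid metabolism",
    "inorganic ion transport and metabolism",
    "lipopolysaccharide biosynthesis and recycling",
    "membrane lipid metabolism",
    "murein biosynthesis and recycling",
    "trna charging",
    "inner membrane transport",
    "outer membrane transport")
}

#' Locate NAD(H)/NADP(H)-dependent reactions
#'
#' Returns every non-exchange reaction whose stoichiometry touches any of
#' the four cofactor species, sorted by id.
#'
#' @param model a `stoichiometric_model`.
#' @param cof a [cofactor_spec()].
#' @return character vector of reaction ids.
#' @export
find_cofactor_reactions <- function(model, cof) {
  ids <- c(cof$nad, cof$nadh, cof$nadp, cof$nadph)
  missing <- setdiff(ids, model$metabolites$id)
  if (length(missing))
    stop("cofactor id(s) not in model: ", paste(missing, collapse = ", "))
  ex <- exchange_ids(model)
  hit <- vapply(model$reactions$id, function(rid) {
    s <- model$stoichiometry[[rid]]
    any(names(s) %in% ids & s != 0)
  }, logical(1))
  sort(setdiff(model$reactions$id[hit], ex))
}

#' Applicable manipulation modes of a cofactor reaction
#'
#' Classifies, from the net direction at the reference state, which of the
#' three manipulations apply: cofactor swap for reactions that produce NADH
#' or consume NADPH (and touch only one cofactor pair), knockout for
#' reactions that consume NADH or NADPH, and overexpression for reactions
#' that produce NADPH.
#'
#' @param model a `stoichiometric_model`.
#' @param reaction_id reaction to classify.
#' @param reference_flux net reference flux of the reaction; its sign gives
#'   the running direction of reversible reactions.  Zero flux with
#'   reversible bounds is classified from the forward direction (flagged in
#'   the `note` attribute).
#' @param cof a [cofactor_spec()].
#' @return character vector, subset of
#'   `c("cofactor_swap", "knockout", "overexpression")`; possibly empty.
#' @export
classify_modes <- function(model, reaction_id, reference_flux, cof) {
  s <- model$stoichiometry[[reaction_id]]
  if (is.null(s)) stop("unknown reaction: ", reaction_id)
  note <- NULL
  dir <- sign(reference_flux)
  if (dir == 0) { dir <- 1; note <- "zero net flux; classified from forward direction" }
  eff <- s * dir
  coef <- function(id) if (id %in% names(eff)) unname(eff[id]) else 0
  produces_nadh <- coef(cof$nadh) > 0
  consumes_nadh <- coef(cof$nadh) < 0
  produces_nadph <- coef(cof$nadph) > 0
  consumes_nadph <- coef(cof$nadph) < 0
  fp <- .cofactor_footprint(s, cof)
  dual <- fp$nad && fp$nadp
  modes <- character(0)
  if ((produces_nadh || consumes_nadph) && !dual) modes <- c(modes, "cofactor_swap")
  if (consumes_nadh || consumes_nadph) modes <- c(modes, "knockout")
  if (produces_nadph) modes <- c(modes, "overexpression")
  if (!is.null(note)) attr(modes, "note") <- note
  modes
}

#' Filter cofactor reactions down to the candidate set
#'
#' Applies, in order, the exclusion rules that reduce the located cofactor
#' reactions to engineering candidates: boundary and objective reactions;
#' no-flux reactions (reference flux below `1e-6` *and* FVA max absolute
#' flux below `1e-6` at 99.9% of the optimum, so degenerate optima are not
#' mistaken for blocked reactions); essential reactions (knockout growth
#' below `essentiality_threshold` times the reference growth); orphan
#' reactions (empty gene set); spontaneous reactions (gene token `s0001` or
#' a `spontaneous` note); and reactions in blocklisted subsystems
#' (case-insensitive).  Survivors are annotated with their applicable modes
#' from [classify_modes()]; reactions with no applicable mode are excluded
#' with reason `dual_cofactor`.
#'
#' @param model a `stoichiometric_model`.
#' @param reference an optimal [flux_state()] from [reference_state()].
#' @param cof a [cofactor_spec()].
#' @param essentiality_threshold fraction of reference growth below which a
#'   knockout is called essential (default 0.01).
#' @param subsystem_blocklist character vector of excluded subsystems.
#' @param extra_constraints constraint overrides used for the essentiality
#'   and FVA probes (must match those of the reference).
#' @return an object of class `candidate_set`: list with `candidates`
#'   (data.frame `id`, `modes` (comma-joined), `v_ref`) and `excluded`
#'   (named character of reason codes).
#' @export
filter_candidates <- function(model, reference, cof,
                              essentiality_threshold = 0.01,
                              subsystem_blocklist = default_subsystem_blocklist(),
                              extra_constraints = NULL) {
  if (reference$status != "optimal")
    stop("filter_candidates requires an optimal reference state")
  located <- find_cofactor_reactions(model, cof)
  mu_ref <- reference$objective_value
  excluded <- character(0)
  exclude <- function(id, reason) excluded[id] <<- reason
  ex_ids <- exchange_ids(model)
  sub <- stats::setNames(tolower(model$reactions$subsystem), model$reactions$id)
  blocklist <- tolower(subsystem_blocklist)

  # FVA once for the located set (robust no-flux detection)
  fva_tab <- fva(model, located, fraction_of_optimum = 0.999,
                 extra_constraints = extra_constraints)
  fva_maxabs <- stats::setNames(pmax(abs(fva_tab$min), abs(fva_tab$max)),
                                fva_tab$id)

  keep <- character(0)
  for (rid in located) {
    if (rid == model$objective_id) { exclude(rid, "objective"); next }
    if (rid %in% ex_ids) { exclude(rid, "boundary"); next }
    v <- abs(reference$fluxes[rid])
    if (v < 1e-6 && fva_maxabs[rid] < 1e-6) { exclude(rid, "no_flux"); next }
    mu_ko <- knockout_growth(model, rid, extra_constraints)
    if (mu_ko < essentiality_threshold * mu_ref) { exclude(rid, "essential"); next }
    genes <- reaction_genes(model, rid)
    if (!length(genes)) { exclude(rid, "orphan"); next }
    notes <- model$reactions$notes[match(rid, model$reactions$id)]
    if ("s0001" %in% genes || grepl("spontaneous", notes, ignore.case = TRUE)) {
      exclude(rid, "spontaneous"); next
    }
    if (sub[rid] %in% blocklist) { exclude(rid, "excluded_subsystem"); next }
    keep <- c(keep, rid)
  }
  cand <- do.call(rbind, lapply(keep, function(rid) {
    modes <- classify_modes(model, rid, reference$fluxes[rid], cof)
    data.frame(id = rid, modes = paste(modes, collapse = ","),
               v_ref = unname(reference$fluxes[rid]), stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) {
    cand <- data.frame(id = character(0), modes = character(0),
                       v_ref = numeric(0), stringsAsFactors = FALSE)
  } else {
    nomode <- !nzchar(cand$modes)
    for (rid in cand$id[nomode]) exclude(rid, "dual_cofactor")
    cand <- cand[!nomode, , drop = FALSE]
    cand <- cand[order(cand$id), , drop = FALSE]
    rownames(cand) <- NULL
  }
  structure(list(candidates = cand, excluded = excluded[sort(names(excluded))]),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", nrow(x$candidates), " candidates, ",
      length(x$excluded), " excluded\n", sep = "")
  if (nrow(x$candidates)) print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Serialize a candidate set as TSV
#'
#' One row per located cofactor reaction: candidates with their modes and
#' reference flux, excluded reactions with their reason code.
#'
#' @param cs a `candidate_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(cs, path) {
  cand <- cs$candidates
  tab <- rbind(
    data.frame(id = cand$id, modes = cand$modes, v_ref = cand$v_ref,
               reason = "", stringsAsFactors = FALSE),
    data.frame(id = names(cs$excluded), modes = "", v_ref = NA_real_,
               reason = unname(cs$excluded), stringsAsFactors = FALSE))
  tab <- tab[order(tab$id), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
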