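#' Declare the NAD(H)/NADP(H) species of a model
#'
#' Names the two redox cofactor pairs that the screening and cofactor-swap
#' machinery operates on.  For iJO1366-style models these are the cytosolic
#' species (`nad_c`, `nadh_c`, `nadp_c`, `nadph_c`).
#'
#' @param nad_pair character of length 2, `c(oxidized, reduced)` NAD species.
#' @param nadp_pair character of length 2, `c(oxidized, reduced)` NADP species.
#' @param model optional `stoichiometric_model`; when given, all four ids are
#'   checked to resolve in it.
#' @return an object of class `cofactor_spec` with elements `nad`, `nadh`,
#'   `nadp`, `nadph`.
#' @export
cofactor_spec <- function(nad_pair = c("nad", "nadh"),
                          nadp_pair = c("nadp", "nadph"),
                          model = NULL) {
  ids <- c(nad_pair, nadp_pair)
  if (length(ids) != 4L || anyDuplicated(ids))
    stop("cofactor pairs must be four distinct metabolite ids")
  if (!is.null(model)) {
    missing <- setdiff(ids, model$metabolites$id)
    if (length(missing))
      stop("cofactor id(s) not in model: ", paste(missing, collapse = ", "))
  }
  structure(list(nad = nad_pair[1], nadh = nad_pair[2],
                 nadp = nadp_pair[1], nadph = nadp_pair[2]),
            class = "cofactor_spec")
}

# which cofactor species of `spec` a stoichiometry touches
.cofactor_footprint <- function(stoich, spec) {
  list(nad  = any(names(stoich) %in% c(spec$nad, spec$nadh) & stoich != 0),
       nadp = any(names(stoich) %in% c(spec$nadp, spec$nadph) & stoich != 0))
}
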