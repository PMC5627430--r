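# Derive a product-specific model from a base reconstruction: remove
# secondary-metabolism subsystems, add product-pathway reactions, apply
# bespoke bound constraints.

#' Edit script constructor
#'
#' An edit script is the auditable record of how a product-specific model
#' is derived from its base reconstruction.  [apply_edit_script()] applies
#' removals, then additions, then bound edits, in that order (so bounds
#' may be set on freshly added reactions).
#'
#' @param remove_subsystems Character vector of subsystem tokens whose
#'   reactions are removed.
#' @param remove_reactions Character vector of reaction ids removed
#'   explicitly (the auditable alternative to pattern matching).
#' @param add_reactions List of [reaction()] objects to add.
#' @param add_metabolites Optional list of [metabolite()] objects declared
#'   for the added reactions (new metabolites referenced only in
#'   stoichiometries are created automatically).
#' @param bound_edits A [bound_edits()] data frame.
#' @return A list of class `"edit_script"`.
#' @export
#' @examples
#' edit_script(bound_edits = bound_edits(
#'   c("GND2", "GND", "G1DH", "PGL", "PPC"),
#'   c("upper", "upper", "upper", "lower", "lower"),
#'   c(0, 1000, 0, 0.2, 0.1)))
edit_script <- function(remove_subsystems = character(),
                        remove_reactions = character(),
                        add_reactions = list(),
                        add_metabolites = list(),
                        bound_edits = NULL) {
  if (inherits(add_reactions, "asc_reaction")) add_reactions <- list(add_reactions)
  add_ids <- vapply(add_reactions, `[[`, character(1), "id")
  both <- intersect(remove_reactions, add_ids)
  if (length(both))
    stop("edit script removes and adds the same reaction(s): ",
         paste(both, collapse = ", "))
  structure(list(remove_subsystems = as.character(remove_subsystems),
                 remove_reactions = as.character(remove_reactions),
                 add_reactions = add_reactions,
                 add_metabolites = add_metabolites,
                 bound_edits = bound_edits),
            class = "edit_script")
}

#' Remove subsystems from a model
#'
#' Deletes every reaction carrying one of the named subsystem tokens,
#' e.g. the secondary-metabolism clusters (actinorhodin,
#' undecylprodigiosin, calcium-dependent antibiotic, germicidin
#' biosynthesis) that are stripped when repurposing a base model for a
#' different producer.  The objective reaction is never removed;
#' attempting to remove its subsystem is an error.
#'
#' @param model A [metabolic_model()].
#' @param names Non-empty character vector of subsystem tokens.
#' @param drop_orphans Also delete metabolites left in no reaction
#'   (default `TRUE`); when `FALSE` they remain and are flagged by
#'   [validate_model()].
#' @return The edited model.  Naming a subsystem absent from the model
#'   leaves it unchanged with a warning.
#' @export
remove_subsystems <- function(model, names, drop_orphans = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!length(names)) stop("no subsystem names given")
  subsys <- vapply(model$reactions, `[[`, character(1), "subsystem")
  absent <- setdiff(names, subsys)
  if (length(absent))
    warning("subsystem(s) not present in model: ",
            paste(absent, collapse = ", "))
  doomed <- names(subsys)[subsys %in% names]
  if (model$objective_id %in% doomed)
    stop("refusing to remove subsystem '",
         subsys[[model$objective_id]],
         "': it contains the objective reaction ", model$objective_id)
  keep <- setdiff(reaction_ids(model), doomed)
  .rebuild_model(model, keep, drop_orphans = drop_orphans)
}

.rebuild_model <- function(model, keep_rxns, drop_orphans = TRUE,
                           extra_mets = list(), extra_rxns = list()) {
  rxns <- c(model$reactions[keep_rxns], extra_rxns)
  mets <- c(model$metabolites, extra_mets)
  if (drop_orphans) {
    used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
    mets <- mets[names(mets) %in% used |
                   vapply(mets, `[[`, character(1), "id") %in% used]
  }
  metabolic_model(unname(mets), unname(rxns),
                  objective_id = model$objective_id,
                  product_id = if (is.na(model$product_id)) NULL
                               else if (model$product_id %in%
                                        vapply(rxns, `[[`, character(1), "id"))
                                 model$product_id else NULL)
}

#' Apply an edit script to a model
#'
#' Applies removals, then additions, then bound edits.  The returned
#' model passes the structural checks of [validate_model()]; a bound edit
#' naming an unknown reaction, or an added reaction referencing a
#' metabolite that is neither in the model nor declared in the script, is
#' an error.
#'
#' @param model A [metabolic_model()].
#' @param script An [edit_script()].
#' @param declare_metabolites When `TRUE` (default), metabolites
#'   referenced only by added reactions are auto-declared; set `FALSE` to
#'   require explicit declaration in the script.
#' @return The edited model.
#' @export
apply_edit_script <- function(model, script, declare_metabolites = TRUE) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(script, "edit_script"))
  m <- model
  if (length(script$remove_subsystems))
    m <- remove_subsystems(m, script$remove_subsystems, drop_orphans = TRUE)
  if (length(script$remove_reactions)) {
    unknown <- setdiff(script$remove_reactions, reaction_ids(m))
    if (length(unknown))
      warning("removal list names reaction(s) not in model: ",
              paste(unknown, collapse = ", "))
    if (model$objective_id %in% script$remove_reactions)
      stop("edit script removes the objective reaction ", model$objective_id)
    keep <- setdiff(reaction_ids(m), script$remove_reactions)
    m <- .rebuild_model(m, keep)
  }
  if (length(script$add_reactions)) {
    known <- c(metabolite_ids(m),
               vapply(script$add_metabolites, `[[`, character(1), "id"))
    if (!declare_metabolites) {
      for (r in script$add_reactions) {
        miss <- setdiff(names(r$stoichiometry), known)
        if (length(miss))
          stop("added reaction '", r$id, "' references undeclared ",
               "metabolite(s): ", paste(miss, collapse = ", "))
      }
    }
    ex <- script$add_metabolites
    names(ex) <- vapply(ex, `[[`, character(1), "id")
    m <- .rebuild_model(m, reaction_ids(m), drop_orphans = FALSE,
                        extra_mets = ex, extra_rxns = script$add_reactions)
  }
  if (!is.null(script$bound_edits) && nrow(script$bound_edits)) {
    ed <- script$bound_edits
    unknown <- setdiff(ed$reaction, reaction_ids(m))
    if (length(unknown))
      stop("bound edit references unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(ed))) {
      r <- m$reactions[[ed$reaction[i]]]
      if (ed$bound[i] == "lower") r$lower_bound <- ed$value[i]
      else r$upper_bound <- ed$value[i]
      m$reactions[[ed$reaction[i]]] <- r
    }
  }
  m
}

# canonical ethylmalonyl-CoA completion steps, in fixture stoichiometry
# (pseudo-formula balanced; see make_core_ascomycin_toy)
.emc_canonical <- function() {
  list(
    ACACT1r = reaction("ACACT1r", c(accoa_c = -2, aacoa_c = 1),
                       name = "acetyl-CoA C-acetyltransferase",
                       lower_bound = -1000, upper_bound = 1000,
                       subsystem = "ethylmalonyl-CoA pathway",
                       genes = "fadA"),
    HACD1 = reaction("HACD1", c(aacoa_c = -1, nadh_c = -1,
                                hbcoa_c = 1, nad_c = 1),
                     name = "3-hydroxybutyryl-CoA dehydrogenase",
                     subsystem = "ethylmalonyl-CoA pathway",
                     genes = "hcd"),
    ECOAH1 = reaction("ECOAH1", c(hbcoa_c = -1, b2coa_c = 1, h2o_c = 1),
                      name = "3-hydroxybutyryl-CoA dehydratase",
                      subsystem = "ethylmalonyl-CoA pathway",
                      genes = "crt"),
    CCCR = reaction("CCCR", c(b2coa_c = -1, co2_c = -1, nadh_c = -1,
                              emcoa_c = 1, nad_c = 1),
                    name = "crotonyl-CoA carboxylase/reductase",
                    subsystem = "ethylmalonyl-CoA pathway",
                    genes = "ccr"))
}

#' Complete the ethylmalonyl-CoA pathway in a model
#'
#' Base reconstructions of many actinomycetes lack part of the
#' ethylmalonyl-CoA route (acetyl-CoA -> acetoacetyl-CoA ->
#' 3-hydroxybutyryl-CoA -> crotonyl-CoA -> ethylmalonyl-CoA) that
#' supplies polyketide extender units.  This operation adds whichever of
#' the canonical steps `ACACT1r`, `HACD1`, `ECOAH1`, `CCCR` are missing
#' (matched by id), with default bounds, leaving existing steps
#' untouched.  Idempotent: applying twice equals applying once.
#'
#' @param model A [metabolic_model()].
#' @return The completed model.
#' @export
complete_emc_pathway <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  canon <- .emc_canonical()
  missing <- setdiff(names(canon), reaction_ids(model))
  if (!length(missing)) return(model)
  .rebuild_model(model, reaction_ids(model), drop_orphans = FALSE,
                 extra_rxns = canon[missing])
}
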