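#' @keywords internal
"_PACKAGE"

#' Create a metabolite
#'
#' Metabolites are the rows of the stoichiometric matrix.  Each carries an
#' id (unique within a model), a display name, a compartment token (e.g.
#' `"c"` for cytosol, `"e"` for extracellular) and an optional elemental
#' formula used by the element-balance check of [validate_model()].
#'
#' @param id Short unique token.
#' @param name Free-text name; defaults to the id.
#' @param compartment Compartment token; must be non-empty.
#' @param formula Optional elemental formula such as `"C6H12O6"`.
#'   Pseudo-element tokens (any capital letter, optionally followed by a
#'   lower-case letter and a count) are allowed.
#' @return A list of class `"asc_metabolite"`.
#' @export
#' @examples
#' metabolite("glc_c", "glucose", "c", "C6H12O6")
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(compartment) || length(compartment) != 1L || !nzchar(compartment))
    stop("metabolite '", id, "': compartment must be a non-empty string")
  structure(list(id = id, name = as.character(name),
                 compartment = compartment,
                 formula = as.character(formula)),
            class = "asc_metabolite")
}

#' Create a reaction
#'
#' A reaction is a signed stoichiometry over metabolite ids (negative
#' coefficients are substrates) together with flux bounds in
#' mmol/gDCW/h, a subsystem token and an optional gene list.
#'
#' @param id Short unique token (e.g. `"GND2"`, `"PGL"`, `"CCCR"`).
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient.  Must be non-empty with no zero entries.
#' @param name Free-text name; defaults to the id.
#' @param lower_bound,upper_bound Flux bounds.  Defaults are `(0, 1000)`,
#'   the irreversible convention; use `(-1000, 1000)` for reversible steps.
#' @param subsystem Subsystem token (pathway category label).
#' @param genes Optional character vector of gene tokens.
#' @return A list of class `"asc_reaction"`.
#' @export
#' @examples
#' reaction("HEX1", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
#'          subsystem = "glycolysis")
reaction <- function(id, stoichiometry, name = id,
                     lower_bound = 0, upper_bound = 1000,
                     subsystem = "", genes = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a non-empty named numeric vector")
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L)
    stop("reaction '", id, "': stoichiometry has only zero coefficients")
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicate metabolite in stoichiometry")
  if (!is.finite(lower_bound) && lower_bound != -Inf)
    stop("reaction '", id, "': invalid lower bound")
  if (!is.finite(upper_bound) && upper_bound != Inf)
    stop("reaction '", id, "': invalid upper bound")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower bound (", lower_bound,
         ") exceeds upper bound (", upper_bound, ")")
  structure(list(id = id, name = as.character(name),
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 subsystem = as.character(subsystem),
                 genes = as.character(genes)),
            class = "asc_reaction")
}

#' Assemble a constraint-based metabolic model
#'
#' The model is the universe every solver operates on: a set of
#' metabolites, a set of reactions whose stoichiometries define the
#' matrix S (one row per metabolite, one column per reaction), a biomass
#' objective reaction and, optionally, a product reaction whose flux is
#' the production rate being engineered.
#'
#' @param metabolites List of [metabolite()] objects.  Metabolites
#'   referenced by reactions but not listed are created automatically
#'   (compartment taken from a trailing `_<token>` id suffix).
#' @param reactions List of [reaction()] objects.
#' @param objective_id Reaction id of the biomass equation.
#' @param product_id Optional reaction id of the product synthesis or
#'   exchange flux.
#' @return An object of class `"metabolic_model"`.
#' @seealso [validate_model()], [stoich_matrix()], [fba()]
#' @export
metabolic_model <- function(metabolites = list(), reactions = list(),
                            objective_id, product_id = NULL) {
  if (inherits(metabolites, "asc_metabolite")) metabolites <- list(metabolites)
  if (inherits(reactions, "asc_reaction")) reactions <- list(reactions)
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  # auto-declare metabolites that appear only in stoichiometries
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  missing <- setdiff(used, met_ids)
  for (m in missing)
    metabolites[[length(metabolites) + 1L]] <-
      metabolite(m, compartment = .compartment_from_id(m))
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  if (!objective_id %in% rxn_ids)
    stop("objective reaction '", objective_id, "' not in model")
  if (!is.null(product_id) && !product_id %in% rxn_ids)
    stop("product reaction '", product_id, "' not in model")
  structure(list(metabolites = metabolites, reactions = reactions,
                 objective_id = objective_id,
                 product_id = if (is.null(product_id)) NA_character_ else product_id),
            class = "metabolic_model")
}

.compartment_from_id <- function(id) {
  m <- regmatches(id, regexpr("_[A-Za-z0-9]+$", id))
  if (length(m) == 1L && nzchar(m)) sub("^_", "", m) else "c"
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Constraint-based metabolic model\n")
  cat("  metabolites:", length(x$metabolites),
      " reactions:", length(x$reactions), "\n")
  cat("  objective:  ", x$objective_id, "\n")
  if (!is.na(x$product_id)) cat("  product:    ", x$product_id, "\n")
  subs <- table(vapply(x$reactions, `[[`, character(1), "subsystem"))
  subs <- subs[nzchar(names(subs))]
  if (length(subs))
    cat("  subsystems: ", paste0(names(subs), " (", subs, ")", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  rxns <- object$reactions
  df <- data.frame(
    id = names(rxns),
    lower_bound = vapply(rxns, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(rxns, `[[`, numeric(1), "upper_bound"),
    subsystem = vapply(rxns, `[[`, character(1), "subsystem"),
    n_metabolites = vapply(rxns, function(r) length(r$stoichiometry), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(reactions = df, n_metabolites = length(object$metabolites),
                 objective_id = object$objective_id,
                 product_id = object$product_id),
            class = "summary.metabolic_model")
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("Model with", nrow(x$reactions), "reactions /", x$n_metabolites,
      "metabolites; objective", x$objective_id, "\n")
  print(x$reactions)
  invisible(x)
}

#' Reaction ids of a model
#' @param model A [metabolic_model()].
#' @return Character vector of reaction ids in model (column) order.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Metabolite ids of a model
#' @param model A [metabolic_model()].
#' @return Character vector of metabolite ids in model (row) order.
#' @export
metabolite_ids <- function(model) names(model$metabolites)

#' Stoichiometric matrix of a model
#'
#' @param model A [metabolic_model()].
#' @return Dense numeric matrix with one row per metabolite and one column
#'   per reaction; `S[m, r]` is the signed coefficient of metabolite `m`
#'   in reaction `r`.
#' @export
stoich_matrix <- function(model) {
  mets <- metabolite_ids(model)
  rxns <- reaction_ids(model)
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (r in rxns) {
    st <- model$reactions[[r]]$stoichiometry
    S[names(st), r] <- st
  }
  S
}

#' Flux bounds of a model
#' @param model A [metabolic_model()].
#' @return Two-column numeric matrix (`lower`, `upper`), one row per reaction.
#' @export
flux_bounds <- function(model) {
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  cbind(lower = lb, upper = ub)
}

# parse "C6H12O6" / "RH2O" / "X6" into a named count vector
.parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (sum(nchar(toks)) != nchar(f)) return(NA)  # unparseable
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1
  tapply(n, el, sum)
}

.is_boundary_reaction <- function(r, objective_id) {
  r$id == objective_id || length(r$stoichiometry) == 1L ||
    grepl("^(EX_|DM_|SK_|sink_)", r$id)
}

#' Validate a metabolic model
#'
#' Report-only structural check: lists orphan metabolites (appearing in no
#' reaction), bound violations, and -- when `element_check = TRUE` and
#' formulas are available -- reactions that are not elementally balanced.
#' Exchange, demand/sink and biomass (objective) reactions are exempt from
#' the element check, as is conventional for pseudo-reactions.
#'
#' @param model A [metabolic_model()].
#' @param element_check Logical; check elemental balance of reactions
#'   whose metabolites all carry formulas.
#' @return A data frame of class `"model_validation"` with columns
#'   `type`, `id`, `message`; zero rows means no defects found.
#' @export
validate_model <- function(model, element_check = FALSE) {
  defects <- list()
  add <- function(type, id, message)
    defects[[length(defects) + 1L]] <<-
      data.frame(type = type, id = id, message = message,
                 stringsAsFactors = FALSE)
  used <- unique(unlist(lapply(model$reactions,
                               function(r) names(r$stoichiometry))))
  for (m in setdiff(metabolite_ids(model), used))
    add("orphan_metabolite", m, "metabolite appears in no reaction")
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound)
      add("bound_violation", r$id,
          sprintf("lower bound %g exceeds upper bound %g",
                  r$lower_bound, r$upper_bound))
    missing <- setdiff(names(r$stoichiometry), metabolite_ids(model))
    for (m in missing)
      add("unknown_metabolite", r$id,
          paste0("references undeclared metabolite '", m, "'"))
  }
  if (element_check) {
    for (r in model$reactions) {
      if (.is_boundary_reaction(r, model$objective_id)) next
      fs <- lapply(names(r$stoichiometry),
                   function(m) .parse_formula(model$metabolites[[m]]$formula))
      if (any(vapply(fs, is.null, logical(1)))) next  # formulas incomplete
      if (any(vapply(fs, function(x) length(x) == 1 && all(is.na(x)), logical(1)))) {
        add("formula_parse", r$id, "unparseable formula among metabolites")
        next
      }
      els <- unique(unlist(lapply(fs, names)))
      bal <- stats::setNames(numeric(length(els)), els)
      for (i in seq_along(fs))
        bal[names(fs[[i]])] <- bal[names(fs[[i]])] +
          r$stoichiometry[[i]] * fs[[i]]
      off <- bal[abs(bal) > 1e-9]
      if (length(off))
        add("element_imbalance", r$id,
            paste0("net atoms: ",
                   paste0(names(off), "=", signif(off, 6), collapse = ", ")))
    }
  }
  out <- if (length(defects)) do.call(rbind, defects)
         else data.frame(type = character(), id = character(),
                         message = character(), stringsAsFactors = FALSE)
  class(out) <- c("model_validation", class(out))
  out
}

#' @export
print.model_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Model validation: no defects found\n")
  } else {
    cat("Model validation:", nrow(x), "defect(s)\n")
    print.data.frame(x)
  }
  invisible(x)
}

#' Bound-edit table constructor
#'
#' Convenience constructor for the `(reaction, bound, value)` triples used
#' by [apply_edit_script()], [fba()] and [moma()].
#'
#' @param reaction Character vector of reaction ids.
#' @param bound `"lower"` or `"upper"`, recycled.
#' @param value Numeric values, recycled.
#' @return Data frame with columns `reaction`, `bound`, `value`.
#' @export
#' @examples
#' bound_edits(c("GND2", "PGL"), c("upper", "lower"), c(0, 0.2))
bound_edits <- function(reaction, bound, value) {
  bound <- match.arg(bound, c("lower", "upper"), several.ok = TRUE)
  df <- data.frame(reaction = as.character(reaction), bound = bound,
                   value = as.numeric(value), stringsAsFactors = FALSE)
  df
}

# apply a bound-edit data frame (and/or named fix vector) to lb/ub vectors
.apply_bounds <- function(model, lb, ub, edits = NULL, fix = NULL) {
  if (!is.null(edits) && nrow(edits)) {
    unknown <- setdiff(edits$reaction, reaction_ids(model))
    if (length(unknown))
      stop("bound edit references unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(edits))) {
      j <- edits$reaction[i]
      if (edits$bound[i] == "lower") lb[j] <- edits$value[i]
      else ub[j] <- edits$value[i]
    }
  }
  if (!is.null(fix) && length(fix)) {
    unknown <- setdiff(names(fix), reaction_ids(model))
    if (length(unknown))
      stop("fixed flux references unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    lb[names(fix)] <- fix
    ub[names(fix)] <- fix
  }
  list(lb = lb, ub = ub)
}
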