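# Model input/output: TSV reaction table, JSON dialect, SBML Level 3 + FBC.
#
# TSV dialect: UTF-8, tab-separated, header row required, columns
#   rxn_id  name  equation  lower_bound  upper_bound  subsystem  genes
# Equation grammar: "2 A_c + B_c -> C_c" (irreversible) or "A_c <=> B_c"
# (reversible); coefficients optional (default 1); the token after the last
# underscore is the compartment.  Either side may be empty (exchanges).
# Optional directive lines "#! objective: <id>" and "#! product: <id>"
# carry the objective/product so that save/load round-trips.
#
# JSON dialect mirrors the COBRA community JSON layout: top-level
# "metabolites" and "reactions" arrays plus "objective_id"/"product_id".

.parse_equation <- function(eq, rxn_id) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (rev) "<=>" else "->"
  if (!rev && !grepl("->", eq, fixed = TRUE))
    stop("reaction '", rxn_id, "': equation lacks '->' or '<=>': ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric()
    for (t in terms) {
      if (!nzchar(t)) stop("reaction '", rxn_id, "': empty term in equation")
      parts <- strsplit(t, "[ \t]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; met <- parts
      } else if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef))
          stop("reaction '", rxn_id, "': bad coefficient '", parts[1], "'")
        met <- parts[2]
      } else stop("reaction '", rxn_id, "': cannot parse term '", t, "'")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, numeric())
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[m] else 0) + rhs[m]
  list(stoichiometry = st[st != 0], reversible = rev)
}

.format_equation <- function(r) {
  st <- r$stoichiometry
  fmt <- function(v) {
    if (!length(v)) return("")
    paste(vapply(seq_along(v), function(i) {
      if (abs(v[i] - 1) < 1e-12) names(v)[i]
      else paste(format(v[i], scientific = FALSE, trim = TRUE), names(v)[i])
    }, character(1)), collapse = " + ")
  }
  arrow <- if (r$lower_bound < 0) "<=>" else "->"
  paste(fmt(-st[st < 0]), arrow, fmt(st[st > 0]))
}

#' Load a metabolic model
#'
#' Reads a model from SBML Level 3 (+ FBC flux bounds), the package JSON
#' dialect, or the TSV reaction-table dialect (see the package vignette
#' for the grammars).  When a format does not state bounds they default to
#' `(-1000, 1000)` for reversible and `(0, 1000)` for irreversible
#' reactions.
#'
#' @param path File path.
#' @param format `"sbml"`, `"json"` or `"tsv"`; guessed from the file
#'   extension when omitted.
#' @return A [metabolic_model()].
#' @seealso [save_model()]
#' @export
load_model <- function(path, format = c("guess", "sbml", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", json = "json",
                     tsv = "tsv", txt = "tsv",
                     stop("cannot guess model format from extension '.",
                          ext, "'"))
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         tsv = .load_model_tsv(path),
         json = .load_model_json(path),
         sbml = .load_model_sbml(path))
}

#' Save a metabolic model
#'
#' Writes a model so that [load_model()] recovers an equivalent model:
#' save-then-load preserves reaction and metabolite ids, every
#' stoichiometric coefficient, every bound and every subsystem, in all
#' three formats.
#'
#' @param model A valid [metabolic_model()].
#' @param path Output file path.
#' @param format `"sbml"`, `"json"` or `"tsv"`; guessed from the
#'   extension when omitted.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path, format = c("guess", "sbml", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", json = "json",
                     tsv = "tsv", txt = "tsv",
                     stop("cannot guess model format from extension '.",
                          ext, "'"))
  }
  stopifnot(inherits(model, "metabolic_model"))
  comps <- vapply(model$metabolites, `[[`, character(1), "compartment")
  if (any(!nzchar(comps)))
    stop("refusing to write model: metabolite(s) with unnamed compartment: ",
         paste(names(comps)[!nzchar(comps)], collapse = ", "))
  v <- validate_model(model)
  v <- v[v$type %in% c("bound_violation", "unknown_metabolite"), , drop = FALSE]
  if (nrow(v))
    stop("refusing to write invalid model: ", v$message[1], " (", v$id[1], ")")
  switch(format,
         tsv = .save_model_tsv(model, path),
         json = .save_model_json(model, path),
         sbml = .save_model_sbml(model, path))
  invisible(path)
}

## ---- TSV ----

.load_model_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  directives <- grep("^#!", lines, value = TRUE)
  objective_id <- product_id <- NULL
  for (d in directives) {
    kv <- strsplit(sub("^#!\\s*", "", d), ":")[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "objective") objective_id <- val
    if (key == "product") product_id <- val
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("TSV model file '", path, "' has no content")
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("rxn_id", "equation")
  if (!all(needed %in% names(df)))
    stop("TSV model file '", path, "' lacks required column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  rxns <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pe <- .parse_equation(df$equation[i], df$rxn_id[i])
    lb <- if ("lower_bound" %in% names(df) && nzchar(df$lower_bound[i]))
      as.numeric(df$lower_bound[i]) else if (pe$reversible) -1000 else 0
    ub <- if ("upper_bound" %in% names(df) && nzchar(df$upper_bound[i]))
      as.numeric(df$upper_bound[i]) else 1000
    if (is.na(lb) || is.na(ub))
      stop("TSV model file '", path, "', line for reaction '", df$rxn_id[i],
           "': non-numeric bound")
    if (lb > ub)
      stop("reaction '", df$rxn_id[i], "': lower bound (", lb,
           ") exceeds upper bound (", ub, ")")
    rxns[[i]] <- reaction(
      df$rxn_id[i], pe$stoichiometry,
      name = if ("name" %in% names(df)) df$name[i] else df$rxn_id[i],
      lower_bound = lb, upper_bound = ub,
      subsystem = if ("subsystem" %in% names(df)) df$subsystem[i] else "",
      genes = if ("genes" %in% names(df) && nzchar(df$genes[i]))
        strsplit(df$genes[i], ";")[[1]] else character())
  }
  if (is.null(objective_id)) {
    guess <- grep("^(BIO|biomass)", df$rxn_id, value = TRUE)
    if (length(guess) != 1L)
      stop("TSV model file '", path,
           "' has no '#! objective:' directive and no unique biomass reaction")
    objective_id <- guess
  }
  metabolic_model(reactions = rxns, objective_id = objective_id,
                  product_id = product_id)
}

.save_model_tsv <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#! objective: ", model$objective_id), con)
  if (!is.na(model$product_id))
    writeLines(paste0("#! product: ", model$product_id), con)
  header <- c("rxn_id", "name", "equation", "lower_bound", "upper_bound",
              "subsystem", "genes")
  writeLines(paste(header, collapse = "\t"), con)
  for (r in model$reactions) {
    writeLines(paste(c(r$id, r$name, .format_equation(r),
                       format(r$lower_bound, scientific = FALSE, trim = TRUE,
                              digits = 15),
                       format(r$upper_bound, scientific = FALSE, trim = TRUE,
                              digits = 15),
                       r$subsystem, paste(r$genes, collapse = ";")),
                     collapse = "\t"), con)
  }
}

## ---- JSON ----

.load_model_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("JSON parse failure in '", path,
                                         "': ", conditionMessage(e)))
  mets <- lapply(x$metabolites, function(m)
    metabolite(m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               formula = m$formula %||% NA_character_))
  rxns <- lapply(x$reactions, function(r) {
    st <- unlist(r$metabolites)
    reaction(r$id, st, name = r$name %||% r$id,
             lower_bound = r$lower_bound %||% 0,
             upper_bound = r$upper_bound %||% 1000,
             subsystem = r$subsystem %||% "",
             genes = unlist(r$genes) %||% character())
  })
  metabolic_model(mets, rxns, objective_id = x$objective_id,
                  product_id = x$product_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.save_model_json <- function(model, path) {
  x <- list(
    id = "ascoflux_model",
    objective_id = model$objective_id,
    metabolites = unname(lapply(model$metabolites, function(m)
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = if (is.na(m$formula)) NULL else m$formula))),
    reactions = unname(lapply(model$reactions, function(r)
      list(id = r$id, name = r$name, metabolites = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           subsystem = r$subsystem, genes = as.list(r$genes)))))
  if (!is.na(model$product_id)) x$product_id <- model$product_id
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

## ---- SBML Level 3 + FBC version 2 ----

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML ids must match SId; encode leading digits and odd characters
.sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.save_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "ascoflux_model",
                             "fbc:strict" = "true")
  if (!is.na(model$product_id)) {
    notes <- xml2::xml_add_child(mdl, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("PRODUCT: ", model$product_id))
  }
  comps <- unique(vapply(model$metabolites, `[[`, character(1), "compartment"))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cm in comps)
    xml2::xml_add_child(lc, "compartment", id = .sid(cm), constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    sp <- xml2::xml_add_child(ls, "species", id = .sid(m$id), name = m$name,
                              compartment = .sid(m$compartment),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(m$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  bnds <- unique(as.vector(flux_bounds(model)))
  bnd_key <- vapply(bnds, format, character(1), digits = 17)
  bnd_id <- stats::setNames(paste0("bnd_", seq_along(bnds)), bnd_key)
  for (i in seq_along(bnds))
    xml2::xml_add_child(lp, "parameter", id = unname(bnd_id[i]),
                        value = format(bnds[i], digits = 17),
                        constant = "true")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lr, "reaction", id = .sid(r$id), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false")
    xml2::xml_set_attr(rx, "fbc:lowerFluxBound",
                       unname(bnd_id[format(r$lower_bound, digits = 17)]))
    xml2::xml_set_attr(rx, "fbc:upperFluxBound",
                       unname(bnd_id[format(r$upper_bound, digits = 17)]))
    meta <- character()
    if (nzchar(r$subsystem)) meta <- c(meta, paste0("SUBSYSTEM: ", r$subsystem))
    if (length(r$genes))
      meta <- c(meta, paste0("GENE_ASSOCIATION: ", paste(r$genes, collapse = " ")))
    meta <- c(meta, paste0("ORIGINAL_ID: ", r$id))
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    for (p in meta) xml2::xml_add_child(body, "p", p)
    st <- r$stoichiometry
    if (any(st < 0)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(st)[st < 0])
        xml2::xml_add_child(lre, "speciesReference", species = .sid(m),
                            stoichiometry = format(-st[[m]], digits = 17),
                            constant = "true")
    }
    if (any(st > 0)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(st)[st > 0])
        xml2::xml_add_child(lpr, "speciesReference", species = .sid(m),
                            stoichiometry = format(st[[m]], digits = 17),
                            constant = "true")
    }
  }
  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives")
  xml2::xml_set_attr(lo, "fbc:activeObjective", "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective")
  xml2::xml_set_attr(ob, "fbc:id", "obj")
  xml2::xml_set_attr(ob, "fbc:type", "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  fo <- xml2::xml_add_child(lfo, "fbc:fluxObjective")
  xml2::xml_set_attr(fo, "fbc:reaction", .sid(model$objective_id))
  xml2::xml_set_attr(fo, "fbc:coefficient", "1")
  xml2::write_xml(doc, path)
}

# attribute accessor tolerant of prefixed and unprefixed serializations
.xattr <- function(node, name, ns) {
  v <- xml2::xml_attr(node, name)
  if (!is.na(v)) return(v)
  v <- tryCatch(xml2::xml_attr(node, paste0("fbc:", name), ns = ns),
                error = function(e) NA_character_)
  v
}

.load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = .SBML_NS, fbc = .FBC_NS, x = "http://www.w3.org/1999/xhtml")
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("SBML file '", path, "' has no <model> element")
  notes_p <- xml2::xml_text(xml2::xml_find_all(
    mdl, "./s:notes//x:p | ./s:notes//p", ns))
  product_id <- NULL
  pm <- grep("^PRODUCT:", notes_p, value = TRUE)
  if (length(pm)) product_id <- trimws(sub("^PRODUCT:", "", pm[1]))
  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  mets <- lapply(xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns),
                 function(sp) {
    f <- .xattr(sp, "chemicalFormula", ns)
    metabolite(xml2::xml_attr(sp, "id"),
               name = xml2::xml_attr(sp, "name") %||%
                 xml2::xml_attr(sp, "id"),
               compartment = xml2::xml_attr(sp, "compartment"),
               formula = if (is.na(f)) NA_character_ else f)
  })
  rxn_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rxn_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    np <- xml2::xml_text(xml2::xml_find_all(rx, "./s:notes//x:p | ./s:notes//p", ns))
    orig <- grep("^ORIGINAL_ID:", np, value = TRUE)
    if (length(orig)) id <- trimws(sub("^ORIGINAL_ID:", "", orig[1]))
    sub_m <- grep("^SUBSYSTEM:", np, value = TRUE)
    subsystem <- if (length(sub_m)) trimws(sub("^SUBSYSTEM:", "", sub_m[1])) else ""
    gene_m <- grep("^GENE_ASSOCIATION:", np, value = TRUE)
    genes <- if (length(gene_m))
      strsplit(trimws(sub("^GENE_ASSOCIATION:", "", gene_m[1])), "[ ]+")[[1]]
      else character()
    st <- numeric()
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns))
      st[xml2::xml_attr(sr, "species")] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns))
      st[xml2::xml_attr(sr, "species")] <-
        (if (is.na(st[xml2::xml_attr(sr, "species")])) 0
         else st[xml2::xml_attr(sr, "species")]) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    lb_ref <- .xattr(rx, "lowerFluxBound", ns)
    ub_ref <- .xattr(rx, "upperFluxBound", ns)
    reversible <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else if (reversible) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]]
          else 1000
    reaction(id, st, name = xml2::xml_attr(rx, "name") %||% id,
             lower_bound = lb, upper_bound = ub,
             subsystem = subsystem, genes = genes)
  })
  # recover original metabolite ids if reactions used them verbatim
  obj_node <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  obj_rxn <- .xattr(obj_node, "reaction", ns)
  if (is.na(obj_rxn))
    stop("SBML file '", path, "' declares no flux objective")
  rxn_ids <- vapply(rxns, `[[`, character(1), "id")
  # the SId encoding is injective on our own output; map back via position
  sid_map <- stats::setNames(rxn_ids, vapply(rxn_nodes, xml2::xml_attr,
                                             character(1), "id"))
  objective_id <- if (obj_rxn %in% names(sid_map)) sid_map[[obj_rxn]] else obj_rxn
  metabolic_model(mets, rxns, objective_id = objective_id,
                  product_id = product_id)
}
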