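# Deterministic synthetic-data generators: mass-balanced toy metabolic
# networks (including a curated ascomycin-like fixture with an
# ethylmalonyl-CoA branch) and alignment hit tables with planted
# conservation structure.  All generators are pure functions of their
# arguments: identical inputs give byte-identical outputs.

#' Generate a parameterized branched toy metabolic network
#'
#' Builds a small mass-balanced network with a glucose input, a set of
#' competing conversion branches with configurable precursor yields, a
#' biomass sink draining the precursor, and (optionally) an
#' ethylmalonyl-CoA-like product branch.  Metabolites carry one
#' pseudo-element (`X`) so the element-balance check of
#' [validate_model()] is exact: glucose is `X6` and branch `i` converts
#' it to `yield_i` precursor units plus `6 - yield_i` waste units.  The
#' FBA optimum is therefore `uptake * max(branch_yields)` in closed form.
#'
#' @param n_branches Number of competing branches (>= 1); defaults to
#'   `length(branch_yields)`.
#' @param branch_yields Positive yields, one per branch, each at most 6
#'   (glucose carries six pseudo-atoms).
#' @param include_emc_branch Add an acetyl-CoA / ethylmalonyl-CoA-like
#'   chain feeding a product reaction (ids `ACACT1r`, `HACD1`, `ECOAH1`,
#'   `CCCR` and sink `DM_asc`).
#' @param product_stoichiometry Named coefficients of the product
#'   synthesis step when the branch is included (default
#'   `c(emcoa_c = 1)`).
#' @param uptake Maximum glucose uptake rate (mmol/gDCW/h), default 1.
#' @param seed Kept for interface symmetry with the other generators; the
#'   construction is fully deterministic.
#' @return A [metabolic_model()] that passes [validate_model()] with
#'   `element_check = TRUE` and is FBA-feasible with positive growth.
#' @export
#' @examples
#' m <- make_toy_model(branch_yields = c(1, 2))
#' fba(m)$objective_value   # 2: all flux routed through the yield-2 branch
make_toy_model <- function(n_branches = length(branch_yields),
                           branch_yields = c(1, 2),
                           include_emc_branch = FALSE,
                           product_stoichiometry = NULL,
                           uptake = 1, seed = 1L) {
  if (n_branches < 1) stop("need at least one branch")
  if (length(branch_yields) != n_branches)
    stop("branch_yields must have length n_branches")
  if (any(branch_yields <= 0)) stop("branch yields must be positive")
  if (any(branch_yields > 6)) stop("branch yields cannot exceed 6")
  mets <- list(
    metabolite("glc_e", "glucose (ext)", "e", "X6"),
    metabolite("glc_c", "glucose", "c", "X6"),
    metabolite("prec_c", "biomass precursor", "c", "X1"),
    metabolite("waste_c", "waste unit", "c", "X1"),
    metabolite("waste_e", "waste unit (ext)", "e", "X1"))
  rxns <- list(
    reaction("EX_glc", c(glc_e = -1), "glucose exchange",
             lower_bound = -uptake, upper_bound = 1000,
             subsystem = "exchange"),
    reaction("GLCt", c(glc_e = -1, glc_c = 1), "glucose transport",
             subsystem = "transport"),
    reaction("WASTEt", c(waste_c = -1, waste_e = 1), "waste transport",
             subsystem = "transport"),
    reaction("EX_waste", c(waste_e = -1), "waste exchange",
             lower_bound = 0, upper_bound = 1000, subsystem = "exchange"),
    reaction("BIO", c(prec_c = -1), "biomass equation",
             subsystem = "biomass"))
  for (i in seq_len(n_branches)) {
    y <- branch_yields[i]
    st <- c(glc_c = -1, prec_c = y)
    if (y < 6) st <- c(st, waste_c = 6 - y)
    rxns[[length(rxns) + 1L]] <-
      reaction(sprintf("BRANCH%d", i), st,
               sprintf("conversion branch %d (yield %g)", i, y),
               subsystem = "central carbon metabolism")
  }
  product_id <- NULL
  if (include_emc_branch) {
    mets <- c(mets, list(
      metabolite("accoa_c", "acetyl-CoA (toy)", "c", "X2"),
      metabolite("aacoa_c", "acetoacetyl-CoA (toy)", "c", "X4"),
      metabolite("hbcoa_c", "3-hydroxybutyryl-CoA (toy)", "c", "X4"),
      metabolite("b2coa_c", "crotonyl-CoA (toy)", "c", "X4"),
      metabolite("emcoa_c", "ethylmalonyl-CoA (toy)", "c", "X5"),
      metabolite("asc_c", "polyketide product (toy)", "c",
                 NA_character_)))
    if (is.null(product_stoichiometry))
      product_stoichiometry <- c(emcoa_c = 1)
    prod_st <- c(-product_stoichiometry, asc_c = 1)
    rxns <- c(rxns, list(
      reaction("ACCOAS", c(glc_c = -1, accoa_c = 3),
               "acetyl-CoA synthesis (toy)",
               subsystem = "central carbon metabolism"),
      reaction("ACACT1r", c(accoa_c = -2, aacoa_c = 1),
               "acetyl-CoA C-acetyltransferase",
               lower_bound = -1000, upper_bound = 1000,
               subsystem = "ethylmalonyl-CoA pathway"),
      reaction("HACD1", c(aacoa_c = -1, hbcoa_c = 1),
               "3-hydroxybutyryl-CoA dehydrogenase (toy, redox-free)",
               subsystem = "ethylmalonyl-CoA pathway"),
      reaction("ECOAH1", c(hbcoa_c = -1, b2coa_c = 1),
               "3-hydroxybutyryl-CoA dehydratase (toy)",
               subsystem = "ethylmalonyl-CoA pathway"),
      reaction("CCCR", c(b2coa_c = -1, waste_c = -1, emcoa_c = 1),
               "crotonyl-CoA carboxylase/reductase (toy)",
               subsystem = "ethylmalonyl-CoA pathway"),
      reaction("ASCS", prod_st, "product synthesis (toy)",
               subsystem = "product biosynthesis"),
      reaction("DM_asc", c(asc_c = -1), "product sink",
               lower_bound = 0, upper_bound = 1000,
               subsystem = "exchange")))
    product_id <- "DM_asc"
  }
  metabolic_model(mets, rxns, objective_id = "BIO", product_id = product_id)
}

#' The curated ascomycin-like toy model
#'
#' A fixed, versioned ~20-reaction network emulating the topology that
#' matters for ascomycin precursor supply: glucose uptake and a toy
#' glycolysis to acetyl-CoA; an NAD/NADH couple closed by an oxidation
#' step; the ethylmalonyl-CoA chain `ACACT1r -> HACD1 -> ECOAH1 -> CCCR`;
#' a methylmalonyl-CoA route (`SUCS`, `MMM`, `MME`); a product synthesis
#' step (`ASCS`) condensing ethylmalonyl-CoA, methylmalonyl-CoA and
#' acetyl-CoA, with sink `DM_asc` carrying a baseline production lower
#' bound of `5e-4` mmol/gDCW/h so the wild-type product flux (and hence
#' the f_PH denominator) is positive; a biomass equation; and an
#' obligatory overflow drain (`DRAIN`, lower bound 0.05) that competes
#' with growth for acetyl-CoA.  All non-boundary reactions are balanced
#' under pseudo-element formulas, so the fixture passes
#' [validate_model()] with `element_check = TRUE`.
#'
#' @return A [metabolic_model()] with `objective_id = "BIO"` and
#'   `product_id = "DM_asc"`.
#' @export
#' @examples
#' m <- make_core_ascomycin_toy()
#' reference_flux(m)$objective_value
make_core_ascomycin_toy <- function() {
  mets <- list(
    metabolite("glc_e", "glucose (ext)", "e", "C6"),
    metabolite("glc_c", "glucose", "c", "C6"),
    metabolite("accoa_c", "acetyl-CoA (toy)", "c", "C2"),
    metabolite("aacoa_c", "acetoacetyl-CoA (toy)", "c", "C4"),
    metabolite("hbcoa_c", "3-hydroxybutyryl-CoA (toy)", "c", "C4H2O"),
    metabolite("b2coa_c", "crotonyl-CoA (toy)", "c", "C4"),
    metabolite("emcoa_c", "ethylmalonyl-CoA (toy)", "c", "C5H2O"),
    metabolite("succoa_c", "succinyl-CoA (toy)", "c", "C4"),
    metabolite("mmcoa_r_c", "(R)-methylmalonyl-CoA (toy)", "c", "C4"),
    metabolite("mmcoa_c", "(S)-methylmalonyl-CoA (toy)", "c", "C4"),
    metabolite("asc_c", "ascomycin (toy)", "c", "C11H2O"),
    metabolite("nad_c", "NAD (toy)", "c", "R"),
    metabolite("nadh_c", "NADH (toy)", "c", "RH2O"),
    metabolite("h2o_c", "water (toy)", "c", "H2O"),
    metabolite("h2o_e", "water (ext)", "e", "H2O"),
    metabolite("co2_c", "CO2 (toy)", "c", "C"),
    metabolite("co2_e", "CO2 (ext)", "e", "C"),
    metabolite("waste_c", "overflow byproduct (toy)", "c", "C2"),
    metabolite("waste_e", "overflow byproduct (ext)", "e", "C2"))
  emc <- .emc_canonical()
  rxns <- list(
    reaction("EX_glc", c(glc_e = -1), "glucose exchange",
             lower_bound = -1, upper_bound = 1000, subsystem = "exchange"),
    reaction("GLCt", c(glc_e = -1, glc_c = 1), "glucose transport",
             subsystem = "transport"),
    reaction("GLYC", c(glc_c = -1, accoa_c = 3), "glycolysis (toy lump)",
             subsystem = "glycolysis"),
    reaction("OX", c(accoa_c = -1, nad_c = -2, h2o_c = -2,
                     co2_c = 2, nadh_c = 2),
             "acetyl-CoA oxidation (toy respiration)",
             subsystem = "central carbon metabolism"),
    emc$ACACT1r, emc$HACD1, emc$ECOAH1, emc$CCCR,
    reaction("SUCS", c(accoa_c = -2, succoa_c = 1),
             "succinyl-CoA synthesis (toy lump)",
             subsystem = "citric acid cycle"),
    reaction("MMM", c(succoa_c = -1, mmcoa_r_c = 1),
             "methylmalonyl-CoA mutase", subsystem =
               "methylmalonyl-CoA metabolism", genes = "mcm"),
    reaction("MME", c(mmcoa_r_c = -1, mmcoa_c = 1),
             "methylmalonyl-CoA epimerase",
             lower_bound = -1000, upper_bound = 1000,
             subsystem = "methylmalonyl-CoA metabolism", genes = "mce"),
    reaction("ASCS", c(emcoa_c = -1, mmcoa_c = -1, accoa_c = -1,
                       asc_c = 1),
             "ascomycin synthesis (toy condensation)",
             subsystem = "ascomycin biosynthesis", genes = "fkbB"),
    reaction("DM_asc", c(asc_c = -1), "ascomycin sink",
             lower_bound = 5e-4, upper_bound = 1000,
             subsystem = "exchange"),
    reaction("BIO", c(accoa_c = -3, nadh_c = -1, nad_c = 1),
             "biomass equation (toy)", subsystem = "biomass"),
    reaction("DRAIN", c(accoa_c = -1, waste_c = 1),
             "obligatory overflow drain (toy)",
             lower_bound = 0.05, upper_bound = 1000,
             subsystem = "byproduct secretion"),
    reaction("WASTEt", c(waste_c = -1, waste_e = 1), "overflow transport",
             subsystem = "transport"),
    reaction("EX_waste", c(waste_e = -1), "overflow exchange",
             lower_bound = 0, upper_bound = 1000, subsystem = "exchange"),
    reaction("CO2t", c(co2_c = -1, co2_e = 1), "CO2 transport",
             subsystem = "transport"),
    reaction("EX_co2", c(co2_e = -1), "CO2 exchange",
             lower_bound = 0, upper_bound = 1000, subsystem = "exchange"),
    reaction("H2Ot", c(h2o_e = -1, h2o_c = 1), "water transport",
             lower_bound = -1000, upper_bound = 1000,
             subsystem = "transport"),
    reaction("EX_h2o", c(h2o_e = -1), "water exchange",
             lower_bound = -1000, upper_bound = 1000,
             subsystem = "exchange"))
  metabolic_model(mets, rxns, objective_id = "BIO", product_id = "DM_asc")
}

#' Random small network for solver stress tests
#'
#' Draws a random stoichiometric matrix with small integer coefficients
#' and random finite bounds containing zero, so the flux polytope is
#' bounded and non-empty and brute-force LP/QP oracles apply.  Intended
#' for solver validation, not for biological realism.
#'
#' @param n_reactions Number of reactions (2-8 recommended; vertex
#'   enumeration is exponential).
#' @param n_metabolites Number of metabolites; default
#'   `max(1, n_reactions - 2)`.
#' @param seed Integer seed; the instance is a pure function of it.
#' @return A [metabolic_model()] whose objective is the last reaction.
#' @export
random_toy_model <- function(n_reactions = 5,
                             n_metabolites = max(1L, n_reactions - 2L),
                             seed = 1L) {
  stopifnot(n_reactions >= 2, n_metabolites >= 1)
  rs <- .Random.seed_guard(seed)
  on.exit(rs())
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 1, 2), n_metabolites * n_reactions,
                       replace = TRUE, prob = c(.1, .3, .2, .3, .1)),
                n_metabolites, n_reactions)
    ok <- all(colSums(abs(S)) > 0) && all(rowSums(abs(S)) > 0)
    if (ok) break
  }
  lb <- -sample(0:10, n_reactions, replace = TRUE)
  ub <- sample(1:10, n_reactions, replace = TRUE)
  rxns <- lapply(seq_len(n_reactions), function(j) {
    st <- S[, j]; names(st) <- sprintf("m%02d_c", seq_len(n_metabolites))
    reaction(sprintf("R%02d", j), st[st != 0],
             lower_bound = lb[j], upper_bound = ub[j],
             subsystem = "random")
  })
  metabolic_model(reactions = rxns,
                  objective_id = sprintf("R%02d", n_reactions))
}

# run code under a seed without clobbering the caller's RNG state
.Random.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate an alignment hit table with planted conservation structure
#'
#' Writes a 12-column tabular hit file, a query-length table and a
#' subsystem map such that running the conservation pipeline
#' ([parse_hits()] -> [best_hit_per_query()] -> [call_conservation()])
#' at the default thresholds recovers the planted per-strain conserved
#' fraction exactly.  For each strain, a seeded permutation selects
#' `planted_fraction * n_queries` queries (must be an integer) that
#' receive a clearly passing top hit (identity 80, full-length alignment,
#' e-value 1e-50); every third query additionally receives a decoy hit at
#' identity 30, coverage 0.3 and e-value 1e-3, which fails all three
#' thresholds simultaneously so boundary semantics never affect recovery.
#'
#' @param n_queries Number of reference enzymes.
#' @param strains Character vector of strain tokens.
#' @param planted_fraction Single value or named-per-strain vector of
#'   conserved fractions in \[0,1\].
#' @param n_subsystems Queries are assigned cyclically to this many
#'   subsystem tokens.
#' @param seed Integer seed controlling which queries are conserved.
#' @param dir Output directory (created if needed).
#' @return List with file paths (`hits`, `query_lengths`,
#'   `subsystem_map`) and the ground truth (`conserved` per strain).
#' @export
make_hit_table <- function(n_queries = 200, strains = "S01",
                           planted_fraction = 0.75, n_subsystems = 4,
                           seed = 1L, dir = tempfile("hittab")) {
  if (length(planted_fraction) == 1L && is.null(names(planted_fraction)))
    planted_fraction <- stats::setNames(rep(planted_fraction,
                                            length(strains)), strains)
  stopifnot(all(strains %in% names(planted_fraction)),
            all(planted_fraction >= 0 & planted_fraction <= 1))
  n_cons <- planted_fraction[strains] * n_queries
  if (any(abs(n_cons - round(n_cons)) > 1e-9))
    stop("planted_fraction * n_queries must be an integer for exact recovery")
  n_cons <- round(n_cons)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  queries <- sprintf("Q%04d", seq_len(n_queries))
  qlen <- 100 + (seq_len(n_queries) - 1L) %% 400
  names(qlen) <- queries
  subsys <- sprintf("subsys_%d", ((seq_len(n_queries) - 1L) %% n_subsystems) + 1L)
  rs <- .Random.seed_guard(seed)
  on.exit(rs())
  rows <- list()
  truth <- list()
  for (s in strains) {
    cons <- sample(queries, n_cons[[s]])
    truth[[s]] <- sort(cons)
    for (i in seq_len(n_queries)) {
      q <- queries[i]
      if (q %in% cons) {
        rows[[length(rows) + 1L]] <- c(
          q, paste0(s, "|hit_", q), "80.0", as.character(qlen[[q]]),
          "10", "1", "1", as.character(qlen[[q]]), "1",
          as.character(qlen[[q]]), "1e-50", "500")
      }
      if (i %% 3L == 0L) {      # decoy failing every threshold
        rows[[length(rows) + 1L]] <- c(
          q, paste0(s, "|decoy_", q), "30.0",
          as.character(max(1L, floor(0.3 * qlen[[q]]))),
          "50", "5", "1", as.character(floor(0.3 * qlen[[q]])), "1",
          as.character(floor(0.3 * qlen[[q]])), "1e-3", "40")
      }
    }
  }
  hits_path <- file.path(dir, "hits.tsv")
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), hits_path)
  ql_path <- file.path(dir, "query_lengths.tsv")
  utils::write.table(data.frame(query_id = queries, length = unname(qlen)),
                     ql_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sm_path <- file.path(dir, "subsystem_map.tsv")
  utils::write.table(data.frame(query_id = queries, subsystem = subsys),
                     sm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(hits = hits_path, query_lengths = ql_path, subsystem_map = sm_path,
       conserved = truth, n_queries = n_queries, strains = strains,
       planted_fraction = planted_fraction[strains])
}
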