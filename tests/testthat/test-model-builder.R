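# Model curation: subsystem removal, edit scripts, bound edits,
# ethylmalonyl-CoA completion.

base_with_ppp <- function() {
  # minimal base containing the five bound-edit reactions plus a path to
  # biomass, so the edit-script example is checkable end to end
  metabolic_model(reactions = list(
    reaction("EX_glc", c(glc_e = -1), lower_bound = -1, subsystem = "exchange"),
    reaction("GLCt", c(glc_e = -1, g6p_c = 1), subsystem = "transport"),
    reaction("GND", c(g6p_c = -1, ru5p_c = 1),
             subsystem = "pentose phosphate pathway"),
    reaction("GND2", c(g6p_c = -1, ru5p_c = 1),
             subsystem = "pentose phosphate pathway"),
    reaction("G1DH", c(glc_e = -1, g6p_c = 1),
             subsystem = "alternate carbon metabolism"),
    reaction("PGL", c(g6p_c = -1, ru5p_c = 1),
             subsystem = "pentose phosphate pathway"),
    reaction("PPC", c(g6p_c = -1, oaa_c = 1),
             subsystem = "anaplerotic reactions"),
    reaction("OAASINK", c(oaa_c = -1), subsystem = "citric acid cycle"),
    reaction("BIO", c(ru5p_c = -1), subsystem = "biomass")),
    objective_id = "BIO")
}

test_that("remove_subsystems deletes exactly the named subsystems", {
  m <- metabolic_model(reactions = list(
    reaction("A1", c(x_c = -1, y_c = 1), subsystem = "keep"),
    reaction("D1", c(y_c = -1, z_c = 1), subsystem = "dummy"),
    reaction("D2", c(z_c = -1, y_c = 1), subsystem = "dummy"),
    reaction("BIO", c(y_c = -1), subsystem = "biomass")),
    objective_id = "BIO")
  m2 <- remove_subsystems(m, "dummy")
  expect_setequal(reaction_ids(m2), c("A1", "BIO"))
  subsys <- vapply(m2$reactions, `[[`, character(1), "subsystem")
  expect_false(any(subsys == "dummy"))
  expect_false("z_c" %in% metabolite_ids(m2))
})

test_that("removing an absent subsystem warns and is a no-op", {
  m <- make_toy_model(branch_yields = 2)
  expect_warning(m2 <- remove_subsystems(m, "no such subsystem"),
                 "not present")
  expect_equal(reaction_ids(m2), reaction_ids(m))
  expect_equal(stoich_matrix(m2), stoich_matrix(m))
})

test_that("the objective's subsystem is protected", {
  m <- make_toy_model(branch_yields = 2)
  expect_error(remove_subsystems(m, "biomass"), "objective")
  expect_error(remove_subsystems(m, character()), "no subsystem")
})

test_that("the five published bound edits land on the right bounds", {
  es <- edit_script(bound_edits = bound_edits(
    c("GND2", "GND", "G1DH", "PGL", "PPC"),
    c("upper", "upper", "upper", "lower", "lower"),
    c(0, 1000, 0, 0.2, 0.1)))
  m <- apply_edit_script(base_with_ppp(), es)
  expect_equal(m$reactions[["GND2"]]$upper_bound, 0)
  expect_equal(m$reactions[["GND"]]$upper_bound, 1000)
  expect_equal(m$reactions[["G1DH"]]$upper_bound, 0)
  expect_equal(m$reactions[["PGL"]]$lower_bound, 0.2)
  expect_equal(m$reactions[["PPC"]]$lower_bound, 0.1)
})

test_that("after the bound edits every feasible flux has v(GND2) = 0 and
           v(PGL) >= 0.2", {
  es <- edit_script(bound_edits = bound_edits(
    c("GND2", "G1DH", "PGL", "PPC"),
    c("upper", "upper", "lower", "lower"),
    c(0, 0, 0.2, 0.1)))
  m <- apply_edit_script(base_with_ppp(), es)
  sol <- reference_flux(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$fluxes[["GND2"]], 0, tolerance = 1e-9)
  expect_gte(sol$fluxes[["PGL"]], 0.2 - 1e-9)
})

test_that("an empty edit script is the identity", {
  m <- make_core_ascomycin_toy()
  m2 <- apply_edit_script(m, edit_script())
  expect_equal(stoich_matrix(m2), stoich_matrix(m))
  expect_equal(flux_bounds(m2), flux_bounds(m))
})

test_that("edit scripts are internally checked", {
  expect_error(
    edit_script(remove_reactions = "X",
                add_reactions = list(reaction("X", c(a = 1)))),
    "removes and adds")
  m <- base_with_ppp()
  expect_error(
    apply_edit_script(m, edit_script(bound_edits =
      bound_edits("NOPE", "lower", 0))),
    "NOPE")
  expect_error(
    apply_edit_script(m, edit_script(add_reactions =
      list(reaction("NEW", c(mystery_c = -1, oaa_c = 1)))),
      declare_metabolites = FALSE),
    "mystery_c")
})

test_that("apply_edit_script is deterministic: byte-identical output", {
  es <- edit_script(
    remove_subsystems = "citric acid cycle",
    add_reactions = list(reaction("NEW", c(oaa_c = -1, ru5p_c = 1),
                                  subsystem = "added")),
    bound_edits = bound_edits("NEW", "upper", 5))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  save_model(apply_edit_script(base_with_ppp(), es), p1)
  save_model(apply_edit_script(base_with_ppp(), es), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("edits never change the objective reaction's stoichiometry", {
  m <- make_core_ascomycin_toy()
  es <- edit_script(remove_subsystems = "byproduct secretion",
                    bound_edits = bound_edits("GLYC", "upper", 50))
  m2 <- apply_edit_script(m, es)
  expect_equal(m2$reactions[[m2$objective_id]]$stoichiometry,
               m$reactions[[m$objective_id]]$stoichiometry)
})

test_that("complete_emc_pathway restores missing canonical steps and is
           idempotent", {
  full <- make_core_ascomycin_toy()
  # knock CCCR out, then complete
  gutted <- apply_edit_script(full, edit_script(remove_reactions = "CCCR"))
  expect_false("CCCR" %in% reaction_ids(gutted))
  healed <- complete_emc_pathway(gutted)
  expect_true("CCCR" %in% reaction_ids(healed))
  st <- healed$reactions[["CCCR"]]$stoichiometry
  # crotonyl-CoA + CO2 + redox cofactor -> ethylmalonyl-CoA
  expect_equal(st[c("b2coa_c", "co2_c", "nadh_c", "emcoa_c")],
               c(b2coa_c = -1, co2_c = -1, nadh_c = -1, emcoa_c = 1),
               ignore_attr = TRUE)
  # untouched when already complete; applying twice equals once
  expect_equal(stoich_matrix(complete_emc_pathway(full)),
               stoich_matrix(full))
  expect_equal(stoich_matrix(complete_emc_pathway(healed)),
               stoich_matrix(healed))
})

test_that("completing the pathway restores a feasible ethylmalonyl route
           to the product", {
  full <- make_core_ascomycin_toy()
  gutted <- apply_edit_script(full, edit_script(remove_reactions = "CCCR"))
  # without CCCR there is no ethylmalonyl-CoA source, so the baseline
  # product demand cannot be met
  expect_equal(fba(gutted)$status, "infeasible")
  healed <- complete_emc_pathway(gutted)
  sol <- reference_flux(healed)
  expect_equal(sol$status, "optimal")
  expect_gte(sol$fluxes[["CCCR"]], 5e-4 - 1e-9)
})
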