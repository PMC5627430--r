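# f_PH scoring and the overexpression target scan.

test_that("compute_fph is the product of the two flux ratios", {
  expect_equal(compute_fph(1, 1, 1, 1)$f_ph, 1.0)
  sc <- compute_fph(0.05, 0.10, 2e-4, 6e-4)
  expect_equal(sc$f_biomass, 2)
  expect_equal(sc$f_ascomycin, 3)
  expect_equal(sc$f_ph, 6)
  expect_identical(sc$f_ph, sc$f_biomass * sc$f_ascomycin)
  expect_error(compute_fph(1, 1, 0, 1), "product flux")
  expect_error(compute_fph(0, 1, 1, 1), "biomass flux")
})

test_that("identity amplification (k = 1) scores every reaction at
           f_PH = 1", {
  m <- make_core_ascomycin_toy()
  rk <- scan_targets(m, k = 1, exclude_subsystems = "exchange")
  sc <- rk$scores[rk$scores$status == "scored", ]
  expect_gt(nrow(sc), 5)
  expect_true(all(abs(sc$f_ph - 1) < 1e-6))
})

test_that("excluded subsystems and reactions never appear in the rows", {
  m <- make_core_ascomycin_toy()
  ref <- reference_flux(m)
  rk <- scan_targets(m, ref, k = 2,
                     exclude_subsystems = c("exchange", "transport"),
                     exclude_reactions = "DRAIN")
  expect_false(any(rk$scores$subsystem %in% c("exchange", "transport")))
  expect_false("DRAIN" %in% rk$scores$reaction_id)
  expect_true("DRAIN" %in% rk$excluded)
  # the objective and product pseudo-reactions are never scanned
  expect_false(any(c("BIO", "DM_asc") %in% rk$scores$reaction_id))
})

test_that("rows are sorted by f_PH descending then id, each scanned
           reaction exactly once", {
  m <- make_core_ascomycin_toy()
  rk <- scan_targets(m, k = 2, exclude_subsystems = "exchange")
  sc <- rk$scores
  expect_false(any(duplicated(sc$reaction_id)))
  scored <- sc[sc$status == "scored", ]
  expect_true(all(diff(scored$f_ph) <= 1e-12))
  # the row order is exactly (f_ph descending, id ascending)
  expect_equal(order(-ifelse(is.na(sc$f_ph), -Inf, sc$f_ph),
                     sc$reaction_id), seq_len(nrow(sc)))
})

test_that("the scan is deterministic: identical rankings and identical
           serialized tables", {
  m <- make_core_ascomycin_toy()
  rk1 <- scan_targets(m, k = 2, exclude_subsystems = "exchange")
  rk2 <- scan_targets(m, k = 2, exclude_subsystems = "exchange")
  expect_identical(rk1$scores, rk2$scores)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  utils::write.table(rk1$scores, p1, sep = "\t", row.names = FALSE)
  utils::write.table(rk2$scores, p2, sep = "\t", row.names = FALSE)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("ethylmalonyl-pathway amplification is beneficial and
           outranks the competing drain", {
  m <- make_core_ascomycin_toy()
  rk <- scan_targets(m, k = 2, exclude_subsystems = "exchange")
  sc <- rk$scores
  emc <- c("ACACT1r", "HACD1", "ECOAH1", "CCCR")
  emc_rows <- sc[sc$reaction_id %in% emc, ]
  expect_equal(nrow(emc_rows), 4)
  expect_true(all(emc_rows$status == "scored"))
  expect_true(all(emc_rows$f_ph > 1))
  drain <- sc[sc$reaction_id == "DRAIN", ]
  expect_lte(drain$f_ph, 1 + 1e-9)
  expect_lt(max(which(sc$reaction_id %in% emc)),
            which(sc$reaction_id == "DRAIN"))
})

test_that("a perturbation already satisfied by the reference scores 1", {
  m <- make_core_ascomycin_toy()
  ref <- reference_flux(m)
  sol <- moma(m, ref, fix = c(SUCS = ref$fluxes[["SUCS"]]))
  sc <- compute_fph(ref$fluxes[["BIO"]], sol$fluxes[["BIO"]],
                    ref$fluxes[["DM_asc"]], sol$fluxes[["DM_asc"]])
  expect_equal(sc$f_ph, 1, tolerance = 1e-6)
})

test_that("infeasible targets are carried with status infeasible and do
           not abort the scan", {
  m <- make_core_ascomycin_toy()
  rk <- scan_targets(m, k = 2, exclude_subsystems = "exchange")
  expect_true("infeasible" %in% rk$scores$status)   # e.g. GLYC at 2x uptake
  expect_true(all(is.na(rk$scores$f_ph[rk$scores$status == "infeasible"])))
  # at most one MOMA solve per scanned reaction: rows <= reactions
  expect_lte(nrow(rk$scores), length(m$reactions))
})

test_that("min-mode amplification (raised bound) is never worse for the
           product than wild type on the toy", {
  m <- make_core_ascomycin_toy()
  rk <- scan_targets(m, k = 2, exclude_subsystems = "exchange",
                     mode = "min")
  sc <- rk$scores[rk$scores$status == "scored", ]
  expect_true(all(sc$f_ascomycin >= 1 - 1e-6))
})

test_that("scan preconditions are enforced", {
  m <- make_core_ascomycin_toy()
  expect_error(scan_targets(m, k = 0.5), "k must be")
  m_noprod <- m; m_noprod$product_id <- NA_character_
  expect_error(scan_targets(m_noprod), "product")
  # product baseline of zero leaves the f_PH denominator undefined
  m0 <- m
  m0$reactions[["DM_asc"]]$lower_bound <- 0
  expect_error(scan_targets(m0), "positive lower bound|not positive")
})

test_that("count_targets splits by threshold and secondary set", {
  m <- make_core_ascomycin_toy()
  rk <- scan_targets(m, k = 2, exclude_subsystems = "exchange")
  ct <- count_targets(rk, threshold = 1,
                      secondary_subsystems = "ascomycin biosynthesis")
  expect_equal(ct$n_total, ct$n_primary + ct$n_secondary)
  expect_true(all(ct$targets$f_ph > 1))
  # threshold 0 counts every scored row
  ct0 <- count_targets(rk, threshold = 0)
  expect_equal(ct0$n_total, sum(rk$scores$status == "scored"))
  # synthetic mini ranking: values {1.5, 1.0, 0.8} at threshold 1 -> 1
  rk2 <- rk
  rk2$scores <- data.frame(
    reaction_id = c("A", "B", "C"), subsystem = "s",
    v_wild = 1, v_amplified = 2,
    f_biomass = 1, f_ascomycin = 1,
    f_ph = c(1.5, 1.0, 0.8), status = "scored",
    stringsAsFactors = FALSE)
  expect_equal(count_targets(rk2, 1)$n_total, 1L)
})
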