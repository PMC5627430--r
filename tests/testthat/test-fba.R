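# FBA linear program and the deterministic parsimonious reference.

chain_toy <- function() {
  # EX -> transport -> biomass, uptake capped at 1, unit yield
  metabolic_model(reactions = list(
    reaction("EX_s", c(s_e = -1), lower_bound = -1, subsystem = "exchange"),
    reaction("St", c(s_e = -1, s_c = 1), subsystem = "transport"),
    reaction("BIO", c(s_c = -1), subsystem = "biomass")),
    objective_id = "BIO")
}

test_that("chain toy attains its capacity of 1.0", {
  sol <- fba(chain_toy())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1.0, tolerance = 1e-9)
})

test_that("branched toy routes all flux through the better branch", {
  m <- make_toy_model(branch_yields = c(1, 2))
  sol <- fba(m)
  expect_equal(sol$objective_value, 2, tolerance = 1e-9)
  ref <- reference_flux(m)
  expect_equal(ref$fluxes[["BRANCH2"]], 1, tolerance = 1e-8)
  expect_equal(ref$fluxes[["BRANCH1"]], 0, tolerance = 1e-8)
})

test_that("every optimal solution satisfies steady state and bounds", {
  for (m in list(chain_toy(), make_toy_model(branch_yields = c(1, 2)),
                 make_core_ascomycin_toy())) {
    for (sol in list(fba(m), reference_flux(m))) {
      expect_equal(sol$status, "optimal")
      S <- stoich_matrix(m)
      expect_lt(max(abs(S %*% sol$fluxes[colnames(S)])), 1e-6)
      bb <- flux_bounds(m)
      expect_true(all(sol$fluxes >= bb[, "lower"] - 1e-9))
      expect_true(all(sol$fluxes <= bb[, "upper"] + 1e-9))
    }
  }
})

test_that("objective value is invariant to reaction and metabolite order", {
  m <- make_core_ascomycin_toy()
  ref_val <- fba(m)$objective_value
  set.seed(42)
  for (rep in 1:3) {
    rxns <- sample(m$reactions)
    mets <- sample(m$metabolites)
    m2 <- metabolic_model(unname(mets), unname(rxns),
                          objective_id = m$objective_id,
                          product_id = m$product_id)
    expect_equal(fba(m2)$objective_value, ref_val, tolerance = 1e-8)
  }
})

test_that("extra bounds and fixed fluxes constrain the solve", {
  m <- make_toy_model(branch_yields = c(1, 2))
  sol <- fba(m, extra_bounds = bound_edits("EX_glc", "lower", -0.5))
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  sol2 <- fba(m, fix = c(BRANCH2 = 0))
  expect_equal(sol2$objective_value, 1, tolerance = 1e-9)  # yield-1 branch
  expect_error(fba(m, fix = c(NOPE = 1)), "NOPE")
})

test_that("infeasible and unbounded programs are reported faithfully", {
  # lower bound on a blocked reaction: BRANCH2 forced but uptake forbidden
  m <- make_toy_model(branch_yields = c(1, 2))
  inf <- fba(m, extra_bounds = bound_edits(c("BRANCH2", "EX_glc"),
                                           c("lower", "lower"),
                                           c(0.2, 0)),
             fix = c(EX_glc = 0))
  expect_equal(inf$status, "infeasible")
  expect_true(all(is.na(inf$fluxes)))
  # unbounded: free objective with an uncapped internal cycle
  m2 <- metabolic_model(reactions = list(
    reaction("A", c(x_c = -1, y_c = 1), lower_bound = -Inf,
             upper_bound = Inf),
    reaction("BIO", c(y_c = -1, x_c = 1), lower_bound = -Inf,
             upper_bound = Inf)),
    objective_id = "BIO")
  expect_equal(fba(m2)$status, "unbounded")
})

test_that("FBA matches the vertex-enumeration oracle on random
           instances", {
  for (seed in 1:25) {
    inst <- random_lp_instance(seed)
    got <- fba(inst$model)
    want <- lp_vertex_oracle(inst$cvec, inst$S, inst$lb, inst$ub)
    expect_equal(got$status, want$status, info = paste("seed", seed))
    if (want$status == "optimal")
      expect_equal(got$objective_value, want$objective,
                   tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("FBA optimum dominates random feasible points", {
  for (seed in c(3, 11, 19)) {
    inst <- random_lp_instance(seed, n_reactions = 5)
    sol <- fba(inst$model)
    if (sol$status != "optimal") next
    set.seed(seed)
    n <- length(inst$cvec)
    Sq <- inst$S
    # project random box points onto the null space of S, keep those in
    # bounds: cheap feasible-point sampler
    NS <- {
      sv <- svd(Sq, nv = n)
      r <- sum(sv$d > 1e-9)
      if (r < n) sv$v[, (r + 1):n, drop = FALSE] else NULL
    }
    if (is.null(NS)) next
    for (i in 1:1000) {
      z <- stats::runif(ncol(NS), -10, 10)
      v <- as.numeric(NS %*% z)
      if (all(v >= inst$lb - 1e-9) && all(v <= inst$ub + 1e-9))
        expect_lte(sum(inst$cvec * v), sol$objective_value + 1e-6)
    }
  }
})

test_that("parallel identical paths split deterministically 50/50 under
           the parsimonious reference", {
  m <- metabolic_model(reactions = list(
    reaction("EX_a", c(a_e = -1), lower_bound = -1, subsystem = "exchange"),
    reaction("P1", c(a_e = -1, b_c = 1)),
    reaction("P2", c(a_e = -1, b_c = 1)),
    reaction("BIO", c(b_c = -1), subsystem = "biomass")),
    objective_id = "BIO")
  # L1 oracle: any split p1 + p2 = 1 has the same total |v|; the L2
  # tie-break must give the symmetric point
  r1 <- reference_flux(m)
  r2 <- reference_flux(m)
  expect_equal(r1$fluxes[["P1"]], 0.5, tolerance = 1e-7)
  expect_equal(r1$fluxes[["P2"]], 0.5, tolerance = 1e-7)
  expect_identical(r1$fluxes, r2$fluxes)   # bit-identical across runs
})

test_that("reference_flux reproduces a unique optimum and never exceeds
           the FBA total flux", {
  m <- make_core_ascomycin_toy()
  f <- fba(m)
  r <- reference_flux(m)
  expect_equal(r$objective_value, f$objective_value, tolerance = 1e-8)
  expect_lte(sum(abs(r$fluxes)), sum(abs(f$fluxes)) + 1e-6)
  # chain toy has a unique optimum: pfba equals fba there
  ct <- chain_toy()
  expect_equal(reference_flux(ct)$fluxes, fba(ct)$fluxes,
               tolerance = 1e-8)
})
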