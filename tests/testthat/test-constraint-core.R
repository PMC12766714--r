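test_that("FBA solves a hand-checkable linear chain", {
  m <- chain_model(uptake = 10)
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes["EX_A"]), -10, tolerance = 1e-8)

  # forcing biomass to zero forces zero growth
  m0 <- set_bounds(m, "BIOMASS", lb = 0, ub = 0)
  expect_equal(solve_fba(m0)$growth_rate, 0)

  # unsatisfiable maintenance (no ATP supply, NGAM > 0) is infeasible
  m_inf <- chain_model(uptake = 10, ngam = 1, atp_supply = FALSE)
  expect_equal(solve_fba(m_inf)$status, "infeasible")

  expect_error(solve_fba(m, objective = "NOPE"), "unknown objective")
})

test_that("optimal solutions satisfy steady state and match the vertex
          enumeration oracle", {
  m <- chain_model(uptake = 7, ngam = 0.5)
  sol <- solve_fba(m)
  expect_lt(steady_state_residual(sol, m), 1e-6)
  oracle <- enumerate_fba_optimum(m)
  expect_equal(sol$objective_value, oracle, tolerance = 1e-8)

  # randomized bounds, re-checked against the oracle
  set.seed(42)
  for (i in 1:5) {
    mi <- set_bounds(m, "EX_A", lb = -runif(1, 1, 12))
    mi <- set_bounds(mi, "ATPS", ub = runif(1, 0.5, 5))
    soli <- solve_fba(mi)
    expect_equal(soli$objective_value, enumerate_fba_optimum(mi),
                 tolerance = 1e-8)
  }
})

test_that("FBA optimum is invariant to scaling a metabolite's row", {
  m <- chain_model(uptake = 10)
  base <- solve_fba(m)$objective_value
  m$stoichiometry["A", ] <- m$stoichiometry["A", ] * 3.7
  expect_equal(solve_fba(m)$objective_value, base, tolerance = 1e-8)
})

test_that("tightening an uptake bound never increases the optimum", {
  m <- make_pao_model()
  med <- apply_minimal_medium(m)
  prev <- Inf
  for (lb in c(-10, -6, -3, -1, 0)) {
    sol <- solve_fba(set_bounds(med, "EX_ac_e", lb = lb))
    mu <- if (sol$status == "optimal") sol$growth_rate else -Inf
    expect_lte(mu, prev + 1e-9)
    prev <- mu
  }
})

test_that("pFBA routes flux through the shorter of two redundant pathways", {
  # A_e -> A; A -> B directly (R1) or via C (R2a, R2b); biomass eats B
  mets <- rbind(met_row("A_e", "extracellular", carbon = 1,
                        role = "carbon_substrate"),
                met_row("A", carbon = 1), met_row("B", carbon = 1),
                met_row("C", carbon = 1))
  rxns <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -5, ub = 1000,
         tags = "exchange"),
    list(id = "T_A", stoich = c(A_e = -1, A = 1), lb = 0, ub = 1000,
         tags = "transport"),
    list(id = "R1", stoich = c(A = -1, B = 1), lb = 0, ub = 1000,
         tags = "internal"),
    list(id = "R2a", stoich = c(A = -1, C = 1), lb = 0, ub = 1000,
         tags = "internal"),
    list(id = "R2b", stoich = c(C = -1, B = 1), lb = 0, ub = 1000,
         tags = "internal"),
    list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 1000,
         tags = "biomass"))
  m <- tiny_model(mets, rxns, biomass_reaction = "BIOMASS",
                  maintenance_reaction = "ATPM",
                  carbon_exchanges = "EX_A", id = "parallel")
  sol <- solve_pfba(m)
  expect_equal(sol$growth_rate, 5, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes["R1"]), 5, tolerance = 1e-6)
  expect_lt(abs(sol$fluxes["R2a"]), 1e-6)

  # single-pathway model: pFBA fluxes equal FBA fluxes
  m1 <- tiny_model(mets, rxns[-c(4, 5)], biomass_reaction = "BIOMASS",
                   maintenance_reaction = "ATPM",
                   carbon_exchanges = "EX_A", id = "single")
  expect_equal(solve_pfba(m1)$fluxes, solve_fba(m1)$fluxes,
               tolerance = 1e-6)
})

test_that("pFBA total flux never exceeds the plain FBA vertex at equal
          growth", {
  m <- apply_minimal_medium(make_pao_model())
  fba <- solve_fba(m)
  pfba <- solve_pfba(m)
  expect_equal(pfba$growth_rate, fba$growth_rate, tolerance = 1e-5)
  expect_lte(pfba$total_abs_flux, fba$total_abs_flux + 1e-6)
})

test_that("total-flux minimization reproduces anaerobic storage metabolism", {
  m <- set_bounds(make_pao_model(), "BIOMASS", lb = 0, ub = 0)
  m <- apply_anaerobic(set_maintenance(m))
  sol <- solve_min_total_flux(m, "EX_ac_e", 3)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$fluxes["EX_ac_e"]), -3, tolerance = 1e-8)
  expect_gt(sol$fluxes["SINK_PHA"], 0)     # PHA accumulates
  expect_lt(sol$fluxes["SINK_POLYP"], 0)   # polyphosphate is consumed
  expect_lt(steady_state_residual(sol, m), 1e-6)

  # uptake 0 with no maintenance: the zero vector is optimal
  m0 <- set_bounds(make_pao_model(), "BIOMASS", lb = 0, ub = 0)
  m0 <- apply_anaerobic(set_maintenance(m0, 0))
  sol0 <- solve_min_total_flux(m0, "EX_ac_e", 0)
  expect_equal(sol0$objective_value, 0, tolerance = 1e-9)

  expect_error(solve_min_total_flux(m, "ACS", 1), "carbon_exchanges")
})

test_that("total-flux minimum matches vertex enumeration on a small model", {
  # chain with a parallel 2-step route: L1 optimum is enumerable
  mets <- rbind(met_row("A_e", "extracellular", carbon = 1,
                        role = "carbon_substrate"),
                met_row("A", carbon = 1), met_row("B", carbon = 1))
  rxns <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -1000, ub = 1000,
         tags = "exchange"),
    list(id = "T_A", stoich = c(A_e = -1, A = 1), lb = 0, ub = 1000,
         tags = "transport"),
    list(id = "R1", stoich = c(A = -1, B = 1), lb = 0, ub = 10,
         tags = "internal"),
    list(id = "R2", stoich = c(A = -1, B = 1), lb = 0, ub = 10,
         tags = "internal"),
    list(id = "SINK_B", stoich = c(B = -1), lb = 2, ub = 2,
         tags = "biomass"))
  m <- tiny_model(mets, rxns, biomass_reaction = "SINK_B",
                  maintenance_reaction = "ATPM",
                  carbon_exchanges = "EX_A", id = "l1toy")
  sol <- solve_min_total_flux(m, "EX_A", 2)
  # forced: uptake 2, transport 2, R1+R2 = 2, sink 2 -> total 8
  expect_equal(sol$objective_value, 8, tolerance = 1e-8)
})

test_that("anaerobic and aerobic constraint application is idempotent and
          targeted", {
  m <- make_pao_model()
  an <- apply_anaerobic(m)
  expect_equal(get_bounds(an, "ETC"), c(0, 0))
  expect_equal(get_bounds(an, "EX_o2_e")[1], 0)
  expect_gte(get_bounds(an, "EX_o2_e")[2], 0)
  expect_identical(apply_anaerobic(an), an)

  ae <- apply_aerobic(m)
  expect_equal(get_bounds(ae, "EX_ac_e")[1], 0)
  expect_equal(get_bounds(ae, "EX_o2_e")[1], m$o2_uptake_limit)
  # amino-acid exchanges are not carbon exchanges and stay untouched
  expect_equal(get_bounds(ae, "EX_aa_his_e"),
               get_bounds(m, "EX_aa_his_e"))
  expect_identical(apply_aerobic(ae), ae)

  # a model whose biomass needs ETC ATP with no storage route dies
  # anaerobically
  m_noetc <- chain_model(uptake = 10, ngam = 1, atp_supply = FALSE)
  expect_equal(solve_fba(m_noetc)$status, "infeasible")
})

test_that("maintenance bound is set and enforced", {
  m <- make_pao_model(ngam = 0)
  m2 <- set_maintenance(m, 0.398)
  expect_equal(get_bounds(m2, "ATPM")[1], 0.398)
  expect_error(set_maintenance(m, -1), "non-negative")
  # maintenance exceeding any achievable ATP production is infeasible
  m3 <- apply_anaerobic(set_maintenance(m, 1e5))
  m3 <- set_bounds(m3, "BIOMASS", lb = 0, ub = 0)
  m3 <- set_bounds(m3, "SINK_POLYP", lb = 0)   # no polyP reserve
  m3 <- set_bounds(m3, "SINK_GLYCO", lb = 0)
  sol <- solve_min_total_flux(m3, "EX_ac_e", 1)
  expect_equal(sol$status, "infeasible")
})

test_that("the simplex core agrees with an industrial LP solver", {
  m <- chain_model(uptake = 10, ngam = 0.25)
  sol <- solve_fba(m)
  keep <- m$metabolites$compartment != "pool"
  S <- as.matrix(m$stoichiometry[keep, , drop = FALSE])
  lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
  lb[lb < -1e5] <- -1e5; ub[ub > 1e5] <- 1e5
  cost <- as.numeric(m$reactions$id == "BIOMASS")
  pylist <- function(x) paste0("[", paste(x, collapse = ","), "]")
  py <- sprintf(paste0(
    "import numpy as np\nfrom scipy.optimize import linprog\n",
    "S = np.array(%s).reshape(%d, %d)\n",
    "r = linprog(%s, A_eq=S, b_eq=np.zeros(%d), bounds=list(zip(%s, %s)))\n",
    "print(repr(-r.fun))\n"),
    pylist(as.numeric(t(S))), nrow(S), ncol(S),
    pylist(-cost), nrow(S), pylist(lb), pylist(ub))
  out <- tryCatch(system2("python", "-", input = py, stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) NULL)
  skip_if(is.null(out) || !length(out), "python/scipy not runnable")
  expect_equal(sol$objective_value, as.numeric(out[length(out)]),
               tolerance = 1e-6)
})
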