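test_that("FBA recovers bound-limited optima on linear chains", {
  expect_equal(solve_fba(toy_chain_model())$objective_value, 10)
  expect_equal(solve_fba(toy_chain_model(yield = 0.5))$objective_value, 5)
  s <- solve_fba(toy_chain_model(), "EX_A", maximize = FALSE)
  expect_equal(s$objective_value, -10)
})

test_that("optimal FBA solutions satisfy steady state and bounds", {
  for (seed in 1:5) {
    gen <- generate_toy_model(synthetic_spec(seed = seed))
    s <- solve_fba(gen$model)
    expect_equal(s$status, "optimal")
    S <- as.matrix(stoichiometric_matrix(gen$model))
    expect_lt(max(abs(S %*% s$fluxes[colnames(S)])), 1e-6)
    for (rxn in gen$model$reactions) {
      expect_gte(s$fluxes[rxn$id], rxn$lower_bound - 1e-6)
      expect_lte(s$fluxes[rxn$id], rxn$upper_bound + 1e-6)
    }
  }
})

test_that("FBA optimum agrees with an independent LP encoding", {
  for (seed in 1:10) {
    gen <- generate_toy_model(synthetic_spec(seed = seed))
    mine <- solve_fba(gen$model)$objective_value
    orac <- oracle_lp_flux(gen$model, gen$model$biomass_reaction_id)
    expect_equal(mine, orac$objective, tolerance = 1e-8)
  }
})

test_that("FVA brackets optima and pins forced reactions", {
  m <- toy_chain_model()
  fv <- flux_variability(m, objective_fraction = 1)
  expect_equal(fv$min[fv$reaction_id == "EX_A"], -10)
  expect_equal(fv$max[fv$reaction_id == "EX_A"], -10)  # sole carbon source
  # a dead-end side reaction spans (0, 0)
  gi <- generate_gapfill_instance(seed = 1)
  fv2 <- flux_variability(gi$model, objective_fraction = 0)
  expect_equal(fv2$min[fv2$reaction_id == "R_QZ"], 0)
  expect_equal(fv2$max[fv2$reaction_id == "R_QZ"], 0)
  # FVA min <= optimal flux <= FVA max per reaction
  gen <- generate_toy_model(synthetic_spec(seed = 4))
  opt <- solve_fba(gen$model)
  fv3 <- flux_variability(gen$model, objective_fraction = 1)
  for (k in seq_len(nrow(fv3))) {
    expect_gte(opt$fluxes[fv3$reaction_id[k]], fv3$min[k] - 1e-6)
    expect_lte(opt$fluxes[fv3$reaction_id[k]], fv3$max[k] + 1e-6)
  }
})

test_that("FVA ranges match independent per-reaction LP pairs", {
  gen <- generate_toy_model(synthetic_spec(seed = 6))
  fv <- flux_variability(gen$model, objective_fraction = 0)
  for (k in seq_len(nrow(fv))) {
    rid <- fv$reaction_id[k]
    expect_equal(fv$max[k],
                 oracle_lp_flux(gen$model, rid, TRUE)$objective,
                 tolerance = 1e-7)
    expect_equal(fv$min[k],
                 oracle_lp_flux(gen$model, rid, FALSE)$objective,
                 tolerance = 1e-7)
  }
})

test_that("minimal uptake for a growth target inverts the yield", {
  expect_equal(estimate_uptake_for_growth(toy_chain_model(), "EX_A",
                                          10)$uptake, 10)
  expect_equal(estimate_uptake_for_growth(toy_chain_model(yield = 0.5),
                                          "EX_A", 5)$uptake, 10)
  u <- estimate_uptake_for_growth(toy_chain_model(), "EX_A", 99)
  expect_equal(u$status, "unreachable")
  expect_error(estimate_uptake_for_growth(toy_chain_model(), "R1", 1),
               "exchange")
})
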