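test_that("generation is deterministic and structurally sound", {
  spec <- synthetic_spec(seed = 1)
  g1 <- generate_toy_model(spec)
  g2 <- generate_toy_model(spec)
  expect_identical(g1, g2)
  expect_identical(generate_condition_omics(g1$model, g1$truth, spec),
                   generate_condition_omics(g2$model, g2$truth, spec))
  s <- model_summary(g1$model)
  expect_equal(s$metabolites, spec$n_metabolites)
  expect_equal(s$reactions, spec$n_reactions)
})

test_that("every generated model is balanced, feasible and growing", {
  for (seed in 1:30) {
    gen <- generate_toy_model(synthetic_spec(seed = seed))
    expect_equal(nrow(check_balance(gen$model)), 0L)
    sol <- solve_fba(gen$model)
    expect_equal(sol$status, "optimal")
    expect_gt(sol$objective_value, 0)
  }
})

test_that("planted flux states are steady states within 1e-9", {
  for (seed in c(1, 8, 23)) {
    gen <- generate_toy_model(synthetic_spec(seed = seed))
    S <- as.matrix(stoichiometric_matrix(gen$model))
    expect_lt(max(abs(S %*% gen$truth$v_ref[colnames(S)])), 1e-9)
    expect_lt(max(abs(S %*% gen$truth$v_pert[colnames(S)])), 1e-9)
    # and both satisfy the model bounds
    for (rxn in gen$model$reactions) {
      expect_gte(gen$truth$v_ref[rxn$id], rxn$lower_bound - 1e-12)
      expect_lte(gen$truth$v_ref[rxn$id], rxn$upper_bound + 1e-12)
    }
  }
})

test_that("GPR and Gibbs-energy coverage meet the requested fractions", {
  spec <- synthetic_spec(seed = 9)
  gen <- generate_toy_model(spec)
  internal <- Filter(function(r) !r$kind %in% c("exchange", "biomass"),
                     gen$model$reactions)
  gpr_frac <- mean(vapply(internal, function(r) nzchar(r$gpr),
                          logical(1)))
  expect_gte(gpr_frac, spec$gpr_coverage - 1e-9)
  n_thermo_rxn <- length(remiflux:::reaction_dGr(gen$model, gen$thermo))
  expect_gte(n_thermo_rxn / length(internal), spec$rxn_dg_coverage - 0.05)
  expect_equal(length(gen$thermo$dGf_std),
               round(spec$met_dg_coverage * nrow(gen$model$metabolites)))
})

test_that("an unsatisfiable specification is rejected up front", {
  expect_error(synthetic_spec(n_metabolites = 6), "unsatisfiable")
  expect_error(synthetic_spec(n_reactions = 10), "unsatisfiable")
  expect_error(synthetic_spec(n_consistent_gene_signals = 50),
               "unsatisfiable")
  expect_error(synthetic_spec(growth_ratio = 2), "growth_ratio")
})

test_that("contradictory-only omics yields a zero consistency score", {
  spec <- synthetic_spec(seed = 10, n_consistent_gene_signals = 0,
                         n_metabolite_signals = 0)
  gen <- generate_toy_model(spec)
  om <- generate_condition_omics(gen$model, gen$truth, spec)
  res <- solve_mcs(build_remi_problem(gen$model, gen$thermo, om,
                                      remi_settings("tgexm")))
  expect_gt(res$tmcs, 0)                 # claims exist...
  expect_equal(res$mcs, 0L)              # ...but none can be satisfied
})

test_that("recovered consistency is non-increasing as noise grows", {
  # planted ratios sit near the fold threshold (and equal branch splits
  # keep every signal at the same ratio), so noise can only gate
  # candidates out of significance or flip them into conflicting claims
  mean_mcs <- vapply(c(0, 0.6, 1.2), function(ns) {
    mcss <- vapply(1:8, function(seed) {
      spec <- synthetic_spec(seed = seed, noise_sd = ns,
                             growth_ratio = 0.3,
                             branch_split_ref = c(0.5, 0.5),
                             branch_split_pert = c(0.5, 0.5))
      gen <- generate_toy_model(spec)
      om <- generate_condition_omics(gen$model, gen$truth, spec)
      solve_mcs(build_remi_problem(gen$model, gen$thermo, om,
                                   remi_settings("tgexm")))$mcs
    }, integer(1))
    mean(mcss)
  }, numeric(1))
  expect_gte(mean_mcs[1], mean_mcs[2] - 1e-9)
  expect_gte(mean_mcs[2], mean_mcs[3] - 1e-9)
})
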