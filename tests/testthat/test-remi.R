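test_that("expression mapping follows the GPR aggregation contract", {
  m <- toy_chain_model()
  m$reactions$R1 <- set_gpr_test(m$reactions$R1, "g1")
  om <- omics_data(genes = data.frame(gene_id = "g1", log2fc = 2,
                                      fdr = 0.01))
  reg <- map_expression_to_reactions(m, om)
  expect_equal(reg$reaction_id, "R1")
  expect_equal(reg$ratio, 4)
  expect_equal(reg$direction, "up")

  # AND takes the minimum fold-change: values (2,8) -> aggregate 2
  m$reactions$R1 <- set_gpr_test(m$reactions$R1, "g1 and g2")
  om2 <- omics_data(genes = data.frame(gene_id = c("g1", "g2"),
                                       log2fc = c(1, 3), fdr = 0.01))
  reg2 <- map_expression_to_reactions(m, om2)
  expect_equal(reg2$ratio, 2)
  expect_equal(reg2$direction, "up")

  # below-threshold or non-significant genes never create regulations
  om3 <- omics_data(genes = data.frame(gene_id = "g1", log2fc = 0.5,
                                       fdr = 0.01))
  m$reactions$R1 <- set_gpr_test(m$reactions$R1, "g1")
  expect_equal(nrow(map_expression_to_reactions(m, om3)), 0L)
  om4 <- omics_data(genes = data.frame(gene_id = "g1", log2fc = 3,
                                       fdr = 0.5))
  expect_equal(nrow(map_expression_to_reactions(m, om4)), 0L)
})

test_that("random GPR trees aggregate like the reference evaluator", {
  set.seed(11)
  rules <- c("(gx and gy) or gz", "gx or (gy and gz)",
             "gx and gy and gz", "(gx or gy) and (gz or gw)")
  for (rule in rules) {
    fc <- setNames(2^runif(4, -3, 3), c("gx", "gy", "gz", "gw"))
    m <- toy_chain_model()
    m$reactions$R1 <- set_gpr_test(m$reactions$R1, rule)
    om <- omics_data(genes = data.frame(gene_id = names(fc),
                                        log2fc = log2(fc), fdr = 0.01))
    reg <- map_expression_to_reactions(m, om, theta = 1.0001)
    expected <- oracle_gpr_eval(rule, fc)
    if (nrow(reg)) expect_equal(reg$ratio, expected)
    else expect_lt(abs(log2(expected)), log2(1.0001) + 1e-9)
  }
})

test_that("a variant without matching data yields a zero-score result", {
  m <- toy_chain_model()
  res <- solve_mcs(build_remi_problem(m, NULL, omics_data(),
                                      remi_settings("tm")))
  expect_equal(res$tmcs, 0L)
  expect_equal(res$mcs, 0L)
})

test_that("a single satisfiable up-candidate is integrated and enforced", {
  m <- toy_chain_model()
  m$reactions$R1 <- set_gpr_test(m$reactions$R1, "g1")
  om <- omics_data(genes = data.frame(gene_id = "g1", log2fc = 2,
                                      fdr = 0.01))
  pr <- build_remi_problem(m, NULL, om, remi_settings("tgex"))
  res <- solve_mcs(pr)
  expect_equal(res$tmcs, 1L)
  expect_equal(res$mcs, 1L)
  expect_equal(res$active_set, "g:R1")
  # with the constraint active the perturbed activity exceeds 4x reference
  lp <- lp_clone(pr$lp)
  lp_set_bounds(lp, "z_g:R1", lb = 1, ub = 1)
  lp_set_objective(lp, setNames(1, "ref.f_R1"))
  s <- lp_solve(lp, maximize = TRUE)
  expect_equal(s$status, "optimal")
  expect_gte(s$x[["pert.f_R1"]], 4 * s$x[["ref.f_R1"]] - 1e-6)
})

test_that("MCS equals TMCS when every candidate is consistent", {
  spec <- synthetic_spec(seed = 21, n_inconsistent_gene_signals = 0)
  gen <- generate_toy_model(spec)
  om <- generate_condition_omics(gen$model, gen$truth, spec)
  res <- solve_mcs(build_remi_problem(gen$model, gen$thermo, om,
                                      remi_settings("tgexm")))
  expect_equal(res$mcs, res$tmcs)
})

test_that("MCS never exceeds TMCS and grows monotonically with data", {
  spec <- synthetic_spec(seed = 12)
  gen <- generate_toy_model(spec)
  om_full <- generate_condition_omics(gen$model, gen$truth, spec)
  r_full <- solve_mcs(build_remi_problem(gen$model, gen$thermo, om_full,
                                         remi_settings("tgexm")))
  expect_lte(r_full$mcs, r_full$tmcs)
  # drop half the gene records: candidate subset => MCS cannot increase
  om_half <- om_full
  keep <- seq_len(nrow(om_half$genes)) %% 2 == 0
  om_half$genes <- om_half$genes[keep, ]
  r_half <- solve_mcs(build_remi_problem(gen$model, gen$thermo, om_half,
                                         remi_settings("tgexm")))
  expect_lte(r_half$mcs, r_full$mcs)
  expect_lte(r_half$tmcs, r_full$tmcs)
})

test_that("swapping condition labels leaves TMCS and MCS unchanged", {
  spec <- synthetic_spec(seed = 13)
  gen <- generate_toy_model(spec)
  om <- generate_condition_omics(gen$model, gen$truth, spec)
  om_swapped <- om
  om_swapped$genes$log2fc <- -om$genes$log2fc
  om_swapped$metabolites$ratio <- 1 / om$metabolites$ratio
  r1 <- solve_mcs(build_remi_problem(gen$model, gen$thermo, om,
                                     remi_settings("tgexm")))
  r2 <- solve_mcs(build_remi_problem(gen$model, gen$thermo, om_swapped,
                                     remi_settings("tgexm")))
  expect_equal(r1$tmcs, r2$tmcs)
  expect_equal(r1$mcs, r2$mcs)
})

test_that("alternative enumeration is exhaustive on conflict toys", {
  tc <- toy_conflict_pair()
  pr <- build_remi_problem(tc$model, NULL, tc$omics,
                           remi_settings("tgex"))
  res <- solve_mcs(pr)
  expect_equal(res$tmcs, 2L)
  expect_equal(res$mcs, 1L)              # claims conflict through the series
  res <- enumerate_alternatives(pr, res)
  expect_equal(length(res$alternatives), 2L)
  expect_setequal(vapply(res$alternatives, paste, character(1)),
                  c("g:R1", "g:R2"))
  # brute-force agreement
  bf <- oracle_mcs_exhaustive(pr)
  expect_equal(bf$mcs, 1L)
  expect_setequal(vapply(bf$sets, paste, collapse = ",", character(1)),
                  vapply(res$alternatives, paste, collapse = ",",
                         character(1)))

  # a toy with a unique optimum returns exactly one set
  m <- toy_chain_model()
  m$reactions$R1 <- set_gpr_test(m$reactions$R1, "g1")
  om <- omics_data(genes = data.frame(gene_id = "g1", log2fc = 2,
                                      fdr = 0.01))
  pr2 <- build_remi_problem(m, NULL, om, remi_settings("tgex"))
  r2 <- enumerate_alternatives(pr2, solve_mcs(pr2))
  expect_equal(length(r2$alternatives), 1L)
})

test_that("every enumerated alternative re-verifies at the MCS", {
  spec <- synthetic_spec(seed = 14)
  gen <- generate_toy_model(spec)
  om <- generate_condition_omics(gen$model, gen$truth, spec)
  pr <- build_remi_problem(gen$model, gen$thermo, om,
                           remi_settings("tgexm"))
  res <- enumerate_alternatives(pr, solve_mcs(pr))
  expect_gte(length(res$alternatives), 1L)
  for (alt in res$alternatives) {
    expect_equal(length(alt), res$mcs)
    # fixing the set must be feasible (condition_growth would error)
    expect_silent(condition_growth(pr, alt))
  }
  expect_equal(anyDuplicated(vapply(res$alternatives, paste,
                                    collapse = ",", character(1))), 0L)
})

test_that("an empty active set reproduces the plain TFA optimum", {
  spec <- synthetic_spec(seed = 15)
  gen <- generate_toy_model(spec)
  om <- generate_condition_omics(gen$model, gen$truth, spec)
  pr <- build_remi_problem(gen$model, gen$thermo, om,
                           remi_settings("tgexm"))
  g <- condition_growth(pr, character())
  tfa <- solve_tfa(gen$model, gen$thermo)$objective_value
  expect_equal(unname(g["growth_reference"]), tfa, tolerance = 1e-6)
  expect_equal(unname(g["growth_perturbed"]), tfa, tolerance = 1e-6)
})

test_that("common/varying constraint partitioning is a set identity", {
  one <- list(c("g:a", "g:b", "m:x"))
  cv1 <- common_and_variable_constraints(one)
  expect_equal(cv1$common$candidate_id, sort(one[[1]]))
  expect_equal(nrow(cv1$varying), 0L)
  two <- list(c("g:a", "g:b"), c("g:a", "m:x"))
  cv2 <- common_and_variable_constraints(two)
  expect_equal(cv2$common$candidate_id, "g:a")
  expect_setequal(cv2$varying$candidate_id, c("g:b", "m:x"))
  expect_equal(cv2$varying$source[cv2$varying$candidate_id == "m:x"],
               "metabolite")
})

test_that("the representative alternative minimizes L1 distance to the median", {
  spec <- synthetic_spec(seed = 16)
  gen <- generate_toy_model(spec)
  om <- generate_condition_omics(gen$model, gen$truth, spec)
  prec <- suppressWarnings(list_bbbs(gen$model))$metabolite_id
  pr <- build_remi_problem(gen$model, gen$thermo, om,
                           remi_settings("tgexm"),
                           extra_demand_mets = prec)
  res <- enumerate_alternatives(pr, solve_mcs(pr))
  sel <- select_representative(pr, res$alternatives)
  # brute-force distance recomputation
  vecs <- vapply(sel$productions, as.numeric,
                 numeric(2L * length(prec)))
  med <- apply(vecs, 1, median)
  d <- colSums(abs(vecs - med))
  expect_equal(sel$index, which.min(d))
  expect_equal(sel$distances, d)
  # identical alternatives -> first returned
  sel2 <- select_representative(pr, rep(res$alternatives[1], 3))
  expect_equal(sel2$index, 1L)
})
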