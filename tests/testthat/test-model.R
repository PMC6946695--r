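test_that("a hand-written 3-reaction model round-trips its structure", {
  m <- toy_chain_model()
  s <- model_summary(m)
  expect_equal(s$metabolites, 2L)
  expect_equal(s$reactions, 3L)
  expect_equal(unname(s$reactions_by_kind["exchange"]), 1L)
  expect_equal(unname(s$reactions_by_kind["biomass"]), 1L)
})

test_that("validation rejects broken models with informative errors", {
  mets <- data.frame(id = "A_c", name = "A", compartment = "c",
                     stringsAsFactors = FALSE)
  r_bad <- list(reaction("R1", c(A_c = -1, GHOST_c = 1)))
  expect_error(
    metabolic_model(mets, r_bad, c(c = "cytosol"), NULL),
    "GHOST_c")
  expect_error(reaction("R0", numeric()), "non-empty")
  expect_error(reaction("R0", c(A_c = 1), lower_bound = 5,
                        upper_bound = 1), "lower_bound")
  mets2 <- rbind(mets, mets)
  expect_error(metabolic_model(mets2, list(reaction("R1", c(A_c = -1))),
                               c(c = "cytosol"), NULL), "duplicate")
})

test_that("GPR parsing honours precedence, case and parentheses", {
  t1 <- parse_gpr("g1 and g2 or g3")
  expect_equal(t1$op, "or")               # and binds tighter
  expect_equal(t1$children[[1]]$op, "and")
  t2 <- parse_gpr("g1 AND (g2 OR g3)")
  expect_equal(t2$op, "and")
  expect_setequal(gpr_genes(t2), c("g1", "g2", "g3"))
  expect_warning(t3 <- parse_gpr("g1 and (g2"), "unparseable")
  expect_null(t3)
  expect_null(parse_gpr(""))
})

test_that("GPR aggregation matches a reference recursive evaluator", {
  set.seed(8)
  rules <- c("g1", "g1 and g2", "g1 or g2", "(g1 and g2) or g3",
             "g1 and (g2 or g3) and g4",
             "((g1 or g2) and g3) or (g4 and g5)")
  for (rule in rules) {
    vals <- setNames(runif(5, 0.1, 8), paste0("g", 1:5))
    expect_equal(eval_gpr(parse_gpr(rule), vals),
                 oracle_gpr_eval(rule, vals))
  }
})

test_that("formula parsing and balance checking behave per contract", {
  expect_equal(unname(parse_formula("C6H12O6")[c("C", "H", "O")]),
               c(6L, 12L, 6L))
  expect_equal(unname(parse_formula("CH4")["H"]), 4L)
  expect_error(parse_formula("C6H12O6)"), "malformed")

  m <- toy_chain_model()                  # A(C2H4) -> B(C2H4): balanced
  expect_equal(nrow(check_balance(m)), 0L)

  m$metabolites$formula[2] <- "C2H3"      # drop one H
  bal <- check_balance(m)
  expect_equal(bal$element, "H")
  expect_equal(bal$imbalance, -1)
  expect_equal(bal$status, "imbalanced")

  m$metabolites$formula[2] <- NA          # missing formula
  bal2 <- check_balance(m)
  expect_equal(bal2$status, "unverifiable")

  m$metabolites$formula[2] <- "C2H3R"     # pseudo-element
  bal3 <- check_balance(m)
  expect_equal(bal3$status, "unverifiable")
})

test_that("balance checking is idempotent and order-independent", {
  gen <- generate_toy_model(synthetic_spec(seed = 5))
  b1 <- check_balance(gen$model)
  b2 <- check_balance(gen$model)
  expect_identical(b1, b2)
  m2 <- gen$model
  m2$reactions <- rev(m2$reactions)
  b3 <- check_balance(m2)
  expect_setequal(paste(b3$reaction_id, b3$element),
                  paste(b1$reaction_id, b1$element))
})

test_that("JSON, SBML and TSV round-trips preserve the model", {
  m <- toy_chain_model()
  m$reactions$R1 <- set_gpr_test(m$reactions$R1, "g1 and (g2 or g3)")
  m$genes <- gpr_genes(m$reactions$R1$gpr_tree)

  jp <- withr::local_tempfile(fileext = ".json")
  write_model(m, jp, format = "json")
  mj <- read_model(jp)
  expect_identical(model_summary(mj), model_summary(m))
  expect_identical(mj$reactions$R1$stoichiometry,
                   m$reactions$R1$stoichiometry)
  expect_identical(mj$reactions$R1$gpr, m$reactions$R1$gpr)

  sp <- withr::local_tempfile(fileext = ".xml")
  write_model(m, sp, format = "sbml")
  ms <- read_model(sp)
  expect_equal(sort(names(ms$reactions)), sort(names(m$reactions)))
  for (rid in names(m$reactions)) {
    expect_equal(ms$reactions[[rid]]$stoichiometry[
                   order(names(ms$reactions[[rid]]$stoichiometry))],
                 m$reactions[[rid]]$stoichiometry[
                   order(names(m$reactions[[rid]]$stoichiometry))])
    expect_equal(ms$reactions[[rid]]$lower_bound,
                 m$reactions[[rid]]$lower_bound)
    expect_equal(ms$reactions[[rid]]$upper_bound,
                 m$reactions[[rid]]$upper_bound)
  }
  expect_setequal(gpr_genes(ms$reactions$R1$gpr_tree), c("g1", "g2", "g3"))

  tp <- withr::local_tempfile()
  write_model(m, tp, format = "tsv")
  mt <- read_model(tp, format = "tsv")
  expect_identical(model_summary(mt), model_summary(m))

  # a full synthetic model also survives the JSON round-trip
  gen <- generate_toy_model(synthetic_spec(seed = 2))
  jp2 <- withr::local_tempfile(fileext = ".json")
  write_model(gen$model, jp2)
  m2 <- read_model(jp2)
  expect_identical(model_summary(m2), model_summary(gen$model))
  expect_equal(solve_fba(m2)$objective_value,
               solve_fba(gen$model)$objective_value)
})

test_that("degenerate writes and reads are refused with clear errors", {
  m <- toy_chain_model()
  m0 <- m
  m0$reactions <- list()
  expect_error(write_model(m0, tempfile(), "json"), "no reactions")
  expect_error(read_model(file.path(tempdir(), "nope_xyz.json")),
               "not found")
})
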