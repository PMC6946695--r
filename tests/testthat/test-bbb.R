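test_that("biomass precursors are listed and grouped", {
  m <- toy_chain_model()
  expect_warning(bb <- list_bbbs(m), "unclassified")
  expect_equal(bb$metabolite_id, "B_c")
  expect_equal(bb$coefficient, 1)
  gm <- data.frame(metabolite_id = "B_c", group = "carbohydrates")
  bb2 <- list_bbbs(m, gm)
  expect_equal(bb2$group, "carbohydrates")
  m0 <- m
  m0$biomass_reaction_id <- NULL
  expect_error(list_bbbs(m0), "biomass")
})

test_that("maximal production respects uptake ceilings and blockage", {
  m <- toy_chain_model()
  p <- max_bbb_production(m, "B_c")
  expect_equal(p$flux, 10)
  expect_equal(p$status, "ok")
  gi <- generate_gapfill_instance(seed = 3)
  pz <- max_bbb_production(gi$model, "Z_c")
  expect_equal(pz$flux, 0)
  expect_equal(pz$status, "blocked")
  # production under thermodynamic constraints never exceeds plain FBA
  gen <- generate_toy_model(synthetic_spec(seed = 17))
  prec <- suppressWarnings(list_bbbs(gen$model))$metabolite_id[1]
  expect_lte(max_bbb_production(gen$model, prec, gen$thermo)$flux,
             max_bbb_production(gen$model, prec)$flux + 1e-7)
})

test_that("production under consistency constraints never exceeds free TFA", {
  spec <- synthetic_spec(seed = 18)
  gen <- generate_toy_model(spec)
  om <- generate_condition_omics(gen$model, gen$truth, spec)
  prec <- suppressWarnings(list_bbbs(gen$model))$metabolite_id
  pr <- build_remi_problem(gen$model, gen$thermo, om,
                           remi_settings("tgexm"),
                           extra_demand_mets = prec)
  res <- solve_mcs(pr)
  prod <- remi_bbb_production(pr, res$active_set)
  for (p in prec) {
    free <- max_bbb_production(gen$model, p, gen$thermo)$flux
    expect_lte(prod[p, "ref"], free + 1e-6)
    expect_lte(prod[p, "pert"], free + 1e-6)
  }
})

test_that("fold-change reports are computed and antisymmetric", {
  prods <- list(matrix(c(4, 2, 0, 1, 2, 0), nrow = 3,
                       dimnames = list(c("P1", "P2", "P3"),
                                       c("ref", "pert"))),
                matrix(c(4.2, 2, 0, 1, 2.1, 0), nrow = 3,
                       dimnames = list(c("P1", "P2", "P3"),
                                       c("ref", "pert"))))
  rep1 <- bbb_fold_changes(prods, representative = 1)
  expect_equal(rep1$fold_change[rep1$metabolite_id == "P1"], 4)
  expect_equal(rep1$fold_change[rep1$metabolite_id == "P2"], 1)
  expect_equal(rep1$flag[rep1$metabolite_id == "P3"], "blocked")
  cnt <- attr(rep1, "counts")
  expect_equal(unname(cnt["higher_in_reference"]), 1L)
  expect_equal(unname(cnt["unchanged"]), 2L)
  expect_equal(sum(cnt), nrow(rep1))
  # swapping conditions inverts the fold-changes
  swapped <- lapply(prods, function(m) {
    m2 <- m[, c("pert", "ref")]
    colnames(m2) <- c("ref", "pert")
    m2
  })
  rep2 <- bbb_fold_changes(swapped, representative = 1)
  ok <- rep1$flag == "ok" & rep1$fold_change > 0
  expect_equal(rep2$fold_change[ok], 1 / rep1$fold_change[ok])
  # identical condition models: all fold-changes 1, no "higher" counts
  same <- list(matrix(c(3, 3), 1, 2,
                      dimnames = list("P1", c("ref", "pert"))))
  rep3 <- bbb_fold_changes(same)
  expect_equal(rep3$fold_change, 1)
  expect_equal(unname(attr(rep3, "counts")["higher_in_reference"]), 0L)
  expect_true(is.na(rep3$p_value))        # <2 alternatives
})

test_that("a vanishing denominator is flagged rather than divided", {
  prods <- list(matrix(c(5, 0), 1, 2,
                       dimnames = list("P1", c("ref", "pert"))))
  rep <- bbb_fold_changes(prods)
  expect_equal(rep$flag, "denominator_zero")
  expect_true(is.na(rep$fold_change))
})

test_that("pathway tallies count multi-membership and unannotated items", {
  ann <- data.frame(id = c("r1", "r2", "r2", "m1"),
                    pathway_id = c("map1", "map1", "map2", "map1"),
                    pathway_name = c("Alpha", "Alpha", "Beta", "Alpha"))
  tab <- tally_deregulated_pathways(c("g:r1", "g:r2", "m:m1"), ann)
  expect_equal(tab$count[tab$pathway_id == "map1"], 3L)
  expect_equal(tab$count[tab$pathway_id == "map2"], 1L)
  expect_true(all(diff(tab$count) <= 0))
  tab2 <- tally_deregulated_pathways(c("g:r1", "g:zz"), ann)
  expect_equal(tab2$count[tab2$pathway_id == "unannotated"], 1L)
  # hand-computed tally on a planted common set
  items <- c("g:a", "g:b", "m:c")
  ann2 <- data.frame(id = c("a", "b", "c"), pathway_id = "p",
                     pathway_name = "P")
  expect_equal(tally_deregulated_pathways(items, ann2)$count, 3L)
})
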