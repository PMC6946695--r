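two_chain_model <- function(join_via_atp = FALSE) {
  ids <- c("A_c", "B_c", "C_c", "D_c", if (join_via_atp) "atp_c")
  mets <- data.frame(id = ids, name = ids, compartment = "c",
                     formula = "C2H4", stringsAsFactors = FALSE)
  st1 <- c(A_c = -1, B_c = 1)
  st2 <- c(C_c = -1, D_c = 1)
  if (join_via_atp) {
    st1 <- c(st1, atp_c = -1)
    st2 <- c(st2, atp_c = 1)
  }
  rxns <- list(
    reaction("EX_A", c(A_c = -1), kind = "exchange"),
    reaction("R_AB", st1), reaction("EX_B", c(B_c = -1),
                                    kind = "exchange"),
    reaction("EX_C", c(C_c = -1), kind = "exchange"),
    reaction("R_CD", st2), reaction("EX_D", c(D_c = -1),
                                    kind = "exchange"))
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  metabolic_model(mets, rxns, setNames("cytosol", "c"), NULL, id = "two")
}

test_that("network decomposition separates disjoint chains", {
  comps <- decompose_network(two_chain_model())
  expect_equal(length(comps), 2L)
  expect_true(comps[[1]]$is_main)
  expect_false(comps[[2]]$is_main)
  all_r <- sort(unname(unlist(lapply(comps, `[[`, "reaction_ids"))))
  expect_equal(all_r, sort(names(two_chain_model()$reactions)))
})

test_that("currency metabolites control connectivity, never flux", {
  joined <- two_chain_model(join_via_atp = TRUE)
  with_cur <- decompose_network(joined)       # atp removed -> 2 components
  expect_equal(length(with_cur), 2L)
  without_cur <- decompose_network(joined, currency = character())
  expect_equal(length(without_cur), 1L)
})

test_that("blocked detection matches the per-reaction LP oracle", {
  for (seed in 1:6) {
    gen <- generate_toy_model(synthetic_spec(seed = seed))
    mine <- find_blocked_reactions(gen$model)
    expect_identical(mine, oracle_blocked(gen$model))
    expect_true(all(gen$truth$blocked %in% mine))
  }
})

test_that("blocked status survives reaction reordering and bound scaling", {
  gen <- generate_toy_model(synthetic_spec(seed = 7))
  ref <- find_blocked_reactions(gen$model)
  m2 <- gen$model
  m2$reactions <- rev(m2$reactions)
  expect_identical(find_blocked_reactions(m2), ref)
  m3 <- gen$model
  for (rid in names(m3$reactions)) {
    m3$reactions[[rid]]$lower_bound <- 2.5 * m3$reactions[[rid]]$lower_bound
    m3$reactions[[rid]]$upper_bound <- 2.5 * m3$reactions[[rid]]$upper_bound
  }
  expect_identical(find_blocked_reactions(m3), ref)
})

test_that("gap-fill minimal size is certified against brute force", {
  for (seed in 1:6) {
    k <- 1 + (seed %% 3)
    gi <- generate_gapfill_instance(seed = seed, path_length = k,
                                    n_decoys = 5)
    sol <- gapfill(gi$model, gapfill_task(gi$target, gi$universal_db))
    bf <- oracle_gapfill_bruteforce(gi$model, gi$universal_db, gi$target)
    expect_equal(sol$size, bf$size)
    expect_equal(sol$size, gi$truth$minimal_size)
    expect_true(list(sol$added_reaction_ids) %in% bf$sets ||
                  identical(sort(sol$added_reaction_ids),
                            bf$sets[[1]]))
  }
})

test_that("curated pathway fixtures behave as designed", {
  fx <- fixture_blocked_pathways()
  # the replica toluene route is blocked while the model still grows
  bt <- find_blocked_reactions(fx$toluene$model)
  expect_setequal(bt, fx$toluene$route)
  expect_gt(solve_fba(fx$toluene$model)$objective_value, 0)
  sol_t <- gapfill(fx$toluene$model,
                   gapfill_task(fx$toluene$target, fx$universal_db))
  expect_equal(sol_t$size, 1L)
  expect_equal(sol_t$added_reaction_ids, "U_2.8.3.6")

  bp <- find_blocked_reactions(fx$phenylalanine$model)
  expect_true(all(c("PHE_2", "PHE_5") %in% bp))
  sol_p <- gapfill(fx$phenylalanine$model,
                   gapfill_task(fx$phenylalanine$target, fx$universal_db))
  expect_equal(sol_p$size, 3L)
  expect_setequal(sol_p$added_reaction_ids,
                  c("U_4.1.1.28", "U_1.14.14.54", "U_1.14.13.x"))

  # decoys are never part of any minimal set (exhaustive subset check)
  bf_t <- oracle_gapfill_bruteforce(fx$toluene$model, fx$universal_db,
                                    fx$toluene$target)
  expect_equal(bf_t$size, 1L)
  expect_false(any(grepl("DK", unlist(bf_t$sets))))
  bf_p <- oracle_gapfill_bruteforce(fx$phenylalanine$model,
                                    fx$universal_db,
                                    fx$phenylalanine$target)
  expect_equal(bf_p$size, 3L)
  expect_false(any(grepl("DK", unlist(bf_p$sets))))
})

test_that("omics evidence drives prioritization", {
  fx <- fixture_blocked_pathways()
  bt <- find_blocked_reactions(fx$toluene$model)
  tasks <- prioritize_blocked(fx$toluene$model, bt, fx$toluene$omics,
                              fx$universal_db)
  expect_gt(length(tasks), 0)
  # the three DE genes of the route all appear as evidence
  ev <- unlist(lapply(tasks, `[[`, "omics_evidence"))
  expect_setequal(intersect(ev, fx$toluene$de_genes),
                  fx$toluene$de_genes)
  # scores are sorted descending
  scores <- vapply(tasks, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0))

  bp <- find_blocked_reactions(fx$phenylalanine$model)
  tasks_p <- prioritize_blocked(fx$phenylalanine$model, bp,
                                fx$phenylalanine$omics, fx$universal_db)
  # the three measured exometabolites on the blocked route are evidence
  # (phenylalanine itself sits on the functional uptake branch)
  ev_p <- unlist(lapply(tasks_p, `[[`, "omics_evidence"))
  expect_setequal(intersect(ev_p, fx$phenylalanine$measured_metabolites),
                  c("peamn_e", "hpac_e", "pacald_e"))

  # a blocked reaction with no omics link is excluded
  empty <- omics_data()
  expect_length(prioritize_blocked(fx$toluene$model, bt, empty,
                                   fx$universal_db), 0)
})

test_that("applying a gap-fill unblocks the target and never blocks more", {
  gi <- generate_gapfill_instance(seed = 4, path_length = 2)
  before <- find_blocked_reactions(gi$model)
  sol <- gapfill(gi$model, gapfill_task(gi$target, gi$universal_db))
  m2 <- apply_gapfill(gi$model, sol, gi$universal_db)
  after <- find_blocked_reactions(m2)
  expect_false(gi$target %in% after)
  expect_lte(length(after), length(before))

  # empty solution leaves the model unchanged
  empty_sol <- structure(list(status = "unfillable",
                              added_reaction_ids = character()),
                         class = "gapfill_solution")
  expect_identical(apply_gapfill(gi$model, empty_sol, gi$universal_db),
                   gi$model)
})

test_that("an unfillable target is reported, not errored", {
  gi <- generate_gapfill_instance(seed = 2, path_length = 2)
  db0 <- gi$universal_db
  db0$reactions <- db0$reactions["DK01"]          # decoys only
  used <- unique(unlist(lapply(db0$reactions,
                               function(r) names(r$stoichiometry))))
  db0$metabolites <- db0$metabolites[db0$metabolites$id %in% used, ]
  sol <- gapfill(gi$model, gapfill_task(gi$target, db0))
  expect_equal(sol$status, "unfillable")
})
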