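# Independent oracles used to validate the package's optimization paths.
# They are deliberately naive: direct matrix LP encodings, exhaustive
# enumeration, and brute-force subset search.

# Direct LP encoding built from the stoichiometric matrix (bypasses the
# package's constraint-builder code path entirely).
oracle_lp_flux <- function(model, objective, maximize = TRUE,
                           extra_lb = NULL) {
  S <- as.matrix(remiflux::stoichiometric_matrix(model))
  rids <- colnames(S)
  lb <- vapply(model$reactions[rids], `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions[rids], `[[`, numeric(1), "upper_bound")
  obj <- as.numeric(rids == objective)
  r <- remiflux:::.solve_milp_cpp(S, rep(0, nrow(S)),
                                  rep(0L, nrow(S)), obj, lb, ub,
                                  integer(0), rep(-1L, length(obj)),
                                  maximize = maximize)
  r
}

# Per-reaction flux range by direct LP pairs.
oracle_blocked <- function(model, open_bound = 1000, tol = 1e-6) {
  m <- model
  for (rid in names(m$reactions)) {
    if (m$reactions[[rid]]$kind == "exchange") {
      m$reactions[[rid]]$lower_bound <- -open_bound
      m$reactions[[rid]]$upper_bound <- open_bound
    }
  }
  blocked <- character()
  for (rid in names(m$reactions)) {
    up <- oracle_lp_flux(m, rid, maximize = TRUE)
    dn <- oracle_lp_flux(m, rid, maximize = FALSE)
    if (up$status == "optimal" && dn$status == "optimal" &&
        abs(up$objective) < tol && abs(dn$objective) < tol)
      blocked <- c(blocked, rid)
  }
  sort(blocked)
}

# Exhaustive direction-pattern enumeration for TFA on a model whose
# thermodynamically covered reactions are all irreversible: each covered
# reaction is either on (flux allowed, dG <= -delta) or off (zero flux),
# and concentrations are shared across the whole pattern.
oracle_tfa_enum <- function(model, thermo, objective,
                            settings = remiflux::tfa_settings()) {
  dGr <- remiflux:::reaction_dGr(model, thermo)
  covered <- names(dGr)
  stopifnot(length(covered) <= 10)
  for (rid in covered)
    stopifnot(model$reactions[[rid]]$lower_bound >= 0)
  RT <- thermo$R * thermo$temperature
  best <- -Inf
  feasible_any <- FALSE
  n_pat <- 2^length(covered)
  for (code in 0:(n_pat - 1)) {
    on <- as.logical(bitwAnd(code, 2^(seq_along(covered) - 1)))
    lp <- remiflux::lp_problem()
    for (rxn in model$reactions)
      remiflux::lp_add_var(lp, rxn$id, lb = rxn$lower_bound,
                           ub = rxn$upper_bound)
    mids <- model$metabolites$id
    lnc_ids <- setdiff(
      unique(unlist(lapply(covered, function(r)
        names(model$reactions[[r]]$stoichiometry)))),
      thermo$fixed_activity)
    for (mid in lnc_ids) {
      cb <- remiflux:::met_conc_bounds(thermo, mid)
      remiflux::lp_add_var(lp, paste0("lnc_", mid), lb = log(cb[1]),
                           ub = log(cb[2]))
    }
    S <- as.matrix(remiflux::stoichiometric_matrix(model))
    for (i in seq_len(nrow(S))) {
      nz <- which(S[i, ] != 0)
      remiflux::lp_add_con(lp, setNames(S[i, nz], colnames(S)[nz]),
                           "=", 0)
    }
    ok <- TRUE
    for (k in seq_along(covered)) {
      rid <- covered[k]
      st <- model$reactions[[rid]]$stoichiometry
      terms <- st[!(names(st) %in% thermo$fixed_activity)]
      if (on[k]) {
        # dGr0 + RT sum s lnc <= -delta
        co <- setNames(RT * unname(terms),
                       paste0("lnc_", names(terms)))
        remiflux::lp_add_con(lp, co, "<=",
                             -settings$dG_margin - dGr[[rid]])
      } else {
        remiflux::lp_set_bounds(lp, rid, lb = 0, ub = 0)
      }
    }
    if (!ok) next
    remiflux::lp_set_objective(lp, setNames(1, objective))
    s <- remiflux::lp_solve(lp, maximize = TRUE)
    if (s$status == "optimal") {
      feasible_any <- TRUE
      best <- max(best, s$objective)
    }
  }
  list(objective = if (feasible_any) best else NA_real_,
       feasible = feasible_any)
}

# Exhaustive top-down subset search for the maximum consistency score:
# the largest candidate subset whose constraints are simultaneously
# LP-feasible (indicators fixed, all other structure identical).
oracle_mcs_exhaustive <- function(problem) {
  cands <- problem$candidates$candidate_id
  n <- length(cands)
  stopifnot(n <= 12)
  feasible_subset <- function(sub) {
    lp <- remiflux::lp_clone(problem$lp)
    for (cid in cands) {
      on <- cid %in% sub
      remiflux::lp_set_bounds(lp, paste0("z_", cid),
                              lb = as.numeric(on), ub = as.numeric(on))
    }
    remiflux::lp_set_objective(lp, setNames(0, lp$var_names[1]))
    remiflux::lp_solve(lp, maximize = TRUE)$status == "optimal"
  }
  for (size in n:0) {
    if (size == 0) return(list(mcs = 0L, sets = list(character())))
    combs <- utils::combn(cands, size, simplify = FALSE)
    ok <- combs[vapply(combs, feasible_subset, logical(1))]
    if (length(ok))
      return(list(mcs = size, sets = lapply(ok, sort)))
  }
}

# Brute-force minimal gap-fill: subsets of database reactions in
# increasing size; feasibility = merged-network LP with the target forced
# to carry min_flux.
oracle_gapfill_bruteforce <- function(model, db, target,
                                      min_flux = 1e-3) {
  db_new <- setdiff(names(db$reactions), names(model$reactions))
  stopifnot(length(db_new) <= 8)
  feasible_with <- function(subset) {
    all_rxns <- c(model$reactions, db$reactions[subset])
    lp <- remiflux::lp_problem()
    for (rid in names(all_rxns)) {
      r <- all_rxns[[rid]]
      lb <- r$lower_bound; ub <- r$upper_bound
      if (r$kind == "exchange") { lb <- -1000; ub <- 1000 }
      remiflux::lp_add_var(lp, rid, lb = lb, ub = ub)
    }
    rows <- list()
    for (rid in names(all_rxns)) {
      st <- all_rxns[[rid]]$stoichiometry
      for (k in seq_along(st)) {
        mid <- names(st)[k]
        if (is.null(rows[[mid]])) rows[[mid]] <- numeric()
        rows[[mid]][rid] <- sum(rows[[mid]][rid], unname(st[k]),
                                na.rm = TRUE)
      }
    }
    for (mid in names(rows))
      remiflux::lp_add_con(lp, rows[[mid]], "=", 0)
    remiflux::lp_add_con(lp, setNames(1, target), ">=", min_flux)
    remiflux::lp_set_objective(lp, setNames(0, target))
    remiflux::lp_solve(lp)$status == "optimal"
  }
  for (size in 0:length(db_new)) {
    combs <- if (size == 0) list(character())
             else utils::combn(db_new, size, simplify = FALSE)
    ok <- combs[vapply(combs, feasible_with, logical(1))]
    if (length(ok))
      return(list(size = size, sets = lapply(ok, sort)))
  }
  list(size = NA_integer_, sets = list())
}

set_gpr_test <- function(rxn, rule) remiflux:::set_gpr(rxn, rule)

# Recursive reference evaluator for GPR trees (independent of eval_gpr's
# implementation details).
oracle_gpr_eval <- function(expr_str, values) {
  tree <- remiflux::parse_gpr(expr_str)
  rec <- function(nd) {
    if (!is.null(nd$gene)) return(unname(values[nd$gene]))
    vals <- vapply(nd$children, rec, numeric(1))
    if (nd$op == "and") min(vals) else max(vals)
  }
  rec(tree)
}

# Small hand fixtures shared across tests --------------------------------
toy_chain_model <- function(yield = 1, uptake = 10) {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     compartment = "c", formula = c("C2H4", "C2H4"),
                     stringsAsFactors = FALSE)
  rxns <- list(
    remiflux::reaction("EX_A", c(A_c = -1), lower_bound = -uptake,
                       upper_bound = 0, kind = "exchange"),
    remiflux::reaction("R1", setNames(c(-1, yield), c("A_c", "B_c")),
                       lower_bound = 0),
    remiflux::reaction("BIOMASS", c(B_c = -1), lower_bound = 0,
                       kind = "biomass"))
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  remiflux::metabolic_model(mets, rxns, c(c = "cytosol"), "BIOMASS",
                            id = "chain")
}

# Two reactions in strict series (same flux in every steady state) plus
# conflicting omics claims: at most one claim can be active, giving two
# alternative optima.
toy_conflict_pair <- function() {
  mets <- data.frame(id = c("A_c", "B_c", "C_c"),
                     name = c("A", "B", "C"), compartment = "c",
                     formula = "C2H4", stringsAsFactors = FALSE)
  rxns <- list(
    remiflux::reaction("EX_A", c(A_c = -1), lower_bound = -10,
                       upper_bound = 0, kind = "exchange"),
    remiflux::reaction("R1", c(A_c = -1, B_c = 1), lower_bound = 0,
                       gpr = "gA"),
    remiflux::reaction("R2", c(B_c = -1, C_c = 1), lower_bound = 0,
                       gpr = "gB"),
    remiflux::reaction("BIOMASS", c(C_c = -1), lower_bound = 0,
                       kind = "biomass"))
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  model <- remiflux::metabolic_model(mets, rxns, c(c = "cytosol"),
                                     "BIOMASS", id = "conflict")
  omics <- remiflux::omics_data(
    genes = data.frame(gene_id = c("gA", "gB"), log2fc = c(2, -2),
                       fdr = 0.01))
  list(model = model, omics = omics)
}
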