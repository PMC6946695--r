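#' Settings for two-condition consistency maximization
#'
#' @param variant `"tgexm"` (thermodynamics + gene expression +
#'   metabolomics), `"tgex"` (thermodynamics + gene expression) or `"tm"`
#'   (thermodynamics + metabolomics).
#' @param theta fold-change threshold; a reaction regulation is emitted
#'   only when its expression ratio is `>= theta` or `<= 1/theta`
#'   (default 2, matching the differential-expression cutoff).
#' @param epsilon minimum activity (mmol/gDW/h) the donor side of an
#'   active constraint must carry.
#' @param big_M flux coupling constant.
#' @param rho_max cap applied to ratios inside constraints to keep big-M
#'   numerics stable.
#' @param gamma growth floor as a fraction of the per-condition
#'   unconstrained optimum (0 = feasibility only; growth is reported by
#'   post-hoc maximization).
#' @param fdr_cutoff significance threshold for gene selection.
#' @param time_limit MILP wall-clock limit (seconds).
#' @param max_alternatives cap on enumerated alternative optima.
#' @param max_nodes branch-and-bound node limit.
#' @export
remi_settings <- function(variant = c("tgexm", "tgex", "tm"), theta = 2,
                          epsilon = 1e-3, big_M = 1000, rho_max = 100,
                          gamma = 0, fdr_cutoff = 0.05, time_limit = Inf,
                          max_alternatives = 40L, max_nodes = 200000L) {
  variant <- match.arg(variant)
  stopifnot(theta >= 1, gamma >= 0, gamma < 1, epsilon > 0)
  list(variant = variant, theta = theta, epsilon = epsilon, big_M = big_M,
       rho_max = rho_max, gamma = gamma, fdr_cutoff = fdr_cutoff,
       time_limit = time_limit, max_alternatives = max_alternatives,
       max_nodes = max_nodes)
}

# GPR evaluation where genes without data are dropped from the
# aggregation; returns NA when no member carries data.
eval_gpr_partial <- function(tree, values, and_fun = min, or_fun = max) {
  if (is.null(tree)) return(NA_real_)
  if (!is.null(tree$gene)) {
    v <- values[tree$gene]
    return(if (is.na(v)) NA_real_ else unname(v))
  }
  vals <- vapply(tree$children, eval_gpr_partial, numeric(1),
                 values = values, and_fun = and_fun, or_fun = or_fun)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  if (tree$op == "and") and_fun(vals) else or_fun(vals)
}

#' Map differential gene expression onto reaction regulations
#'
#' Genes passing the significance gate (`fdr < fdr_cutoff` and
#' `|log2fc| >= log2(theta)`) are aggregated through each reaction's GPR
#' (AND = min, OR = max over fold-changes; members without data are
#' dropped); a regulation is emitted when the aggregate ratio
#' (perturbed/reference) is `>= theta` (up) or `<= 1/theta` (down).
#'
#' @param model a [metabolic_model()].
#' @param omics an [omics_data()].
#' @param theta fold threshold.
#' @param fdr_cutoff significance threshold.
#' @param and_fun,or_fun GPR aggregation strategy.
#' @return data.frame: `reaction_id`, `ratio`, `direction`
#'   (`"up"`/`"down"`), `genes` (semicolon-joined contributing genes).
#' @export
map_expression_to_reactions <- function(model, omics, theta = 2,
                                        fdr_cutoff = 0.05,
                                        and_fun = min, or_fun = max) {
  g <- omics$genes
  sig <- g[g$fdr < fdr_cutoff & abs(g$log2fc) >= log2(theta), ]
  fc <- setNames(2^sig$log2fc, sig$gene_id)
  out <- list()
  for (rxn in model$reactions) {
    if (is.null(rxn$gpr_tree)) next
    rho <- eval_gpr_partial(rxn$gpr_tree, fc, and_fun, or_fun)
    if (is.na(rho)) next
    if (rho >= theta) dirn <- "up"
    else if (rho <= 1 / theta) dirn <- "down"
    else next
    used <- intersect(rxn$genes, names(fc))
    out[[length(out) + 1L]] <-
      data.frame(reaction_id = rxn$id, ratio = rho, direction = dirn,
                 genes = paste(used, collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(reaction_id = character(), ratio = numeric(),
                      direction = character(), genes = character()))
  do.call(rbind, out)
}

#' Build the two-condition consistency-maximization problem
#'
#' Duplicates the model into a reference and a perturbed copy (split
#' fluxes, shared thermodynamic constraints) and attaches one binary
#' indicator per candidate constraint. An active up-regulation forces the
#' perturbed activity to exceed `ratio` times the reference activity with
#' the reference side at least `epsilon`; down-regulations are symmetric
#' with the floor on the perturbed side. Metabolite candidates act on the
#' total producing turnover of the metabolite. The objective (installed
#' by [solve_mcs()]) is the number of active indicators.
#'
#' @param model a [metabolic_model()].
#' @param thermo a [thermo_annotation()] (or `NULL` for bounds-only).
#' @param omics an [omics_data()].
#' @param settings a [remi_settings()].
#' @param extra_demand_mets metabolite ids for which closed demand sinks
#'   are embedded in both copies (used by downstream production analysis).
#' @return object of class `remi_problem`.
#' @export
build_remi_problem <- function(model, thermo, omics,
                               settings = remi_settings(),
                               extra_demand_mets = character()) {
  if (is.null(thermo)) thermo <- thermo_annotation()
  model2 <- model
  for (m in extra_demand_mets) {
    did <- paste0("DM_", m)
    model2$reactions[[did]] <-
      reaction(did, setNames(-1, m), lower_bound = 0, upper_bound = 0,
               kind = "demand")
  }
  tfa_set <- tfa_settings(big_M = settings$big_M)
  lp <- lp_problem()
  built_ref <- build_tfa_milp(model2, thermo, tfa_set, lp = lp,
                              prefix = "ref.")
  built_pert <- build_tfa_milp(model2, thermo, tfa_set, lp = lp,
                               prefix = "pert.")

  eps <- settings$epsilon
  cands <- list()
  fvar <- function(cond, rid) paste0(cond, ".f_", rid)
  bvar <- function(cond, rid) paste0(cond, ".b_", rid)
  act <- function(cond, rid)
    setNames(c(1, 1), c(fvar(cond, rid), bvar(cond, rid)))

  add_candidate <- function(cid, donor_expr, receiver_expr, rho, kind,
                            n_genes) {
    # active (z=1): receiver >= rho * donor  and  donor >= eps
    zv <- paste0("z_", cid)
    lp_add_var(lp, zv, lb = 0, ub = 1, integer = TRUE)
    cap <- function(expr) {
      ubs <- vapply(names(expr), function(v) lp$ub[lp$var_idx[[v]]],
                    numeric(1))
      sum(abs(unname(expr)) * pmin(ubs, 1e4))
    }
    M2 <- rho * cap(donor_expr) + 1
    co <- c(rho * donor_expr, -receiver_expr)
    co <- tapply(unname(co), names(co), sum)
    co <- setNames(as.numeric(co), names(co))
    co[zv] <- M2
    lp_add_con(lp, co, "<=", M2)
    flo <- c(-donor_expr)
    flo[zv] <- eps
    lp_add_con(lp, flo, "<=", 0)
    cands[[length(cands) + 1L]] <<-
      data.frame(candidate_id = cid, kind = kind, n_genes = n_genes,
                 stringsAsFactors = FALSE)
  }

  if (settings$variant %in% c("tgex", "tgexm")) {
    reg <- map_expression_to_reactions(model, omics, settings$theta,
                                       settings$fdr_cutoff)
    for (i in seq_len(nrow(reg))) {
      rid <- reg$reaction_id[i]
      ng <- length(strsplit(reg$genes[i], ";", fixed = TRUE)[[1]])
      if (reg$direction[i] == "up") {
        rho <- min(reg$ratio[i], settings$rho_max)
        add_candidate(paste0("g:", rid), act("ref", rid),
                      act("pert", rid), rho, "gene", ng)
      } else {
        rho <- min(1 / reg$ratio[i], settings$rho_max)
        add_candidate(paste0("g:", rid), act("pert", rid),
                      act("ref", rid), rho, "gene", ng)
      }
    }
  }
  if (settings$variant %in% c("tm", "tgexm")) {
    mm <- omics$metabolites
    mm <- mm[mm$significant & abs(log(mm$ratio)) > 1e-12, ]
    prod_expr <- function(cond, mid) {
      co <- numeric()
      for (rxn in model2$reactions) {
        s <- rxn$stoichiometry[mid]
        if (is.na(s) || s == 0) next
        if (s > 0) co[fvar(cond, rxn$id)] <-
            (co[fvar(cond, rxn$id)] %||0% 0) + s
        else co[bvar(cond, rxn$id)] <-
            (co[bvar(cond, rxn$id)] %||0% 0) - s
      }
      co
    }
    for (i in seq_len(nrow(mm))) {
      mid <- mm$metabolite_id[i]
      if (!mid %in% model$metabolites$id) next
      ratio <- mm$ratio[i]
      pr <- prod_expr("ref", mid)
      pp <- prod_expr("pert", mid)
      if (!length(pr)) next
      if (ratio > 1) {
        rho <- min(ratio, settings$rho_max)
        add_candidate(paste0("m:", mid), pr, pp, rho, "metabolite", 0L)
      } else {
        rho <- min(1 / ratio, settings$rho_max)
        add_candidate(paste0("m:", mid), pp, pr, rho, "metabolite", 0L)
      }
    }
  }
  candidates <- if (length(cands)) do.call(rbind, cands)
    else data.frame(candidate_id = character(), kind = character(),
                    n_genes = integer())

  if (settings$gamma > 0) {
    base <- solve_tfa(model, thermo, tfa_set)
    if (base$status == "optimal" && is.finite(base$objective_value))
      for (cond in c("ref", "pert"))
        lp_add_con(lp, act_net(cond, model$biomass_reaction_id),
                   ">=", settings$gamma * base$objective_value)
  }

  structure(list(lp = lp, candidates = candidates, model = model2,
                 thermo = thermo, settings = settings,
                 biomass_id = model$biomass_reaction_id,
                 demand_mets = extra_demand_mets,
                 tmcs = nrow(candidates),
                 tmcs_gene_level = sum(pmax(candidates$n_genes, 1L))),
            class = "remi_problem")
}

act_net <- function(cond, rid)
  setNames(c(1, -1), paste0(cond, c(".f_", ".b_"), rid))

#' @exportS3Method base::print
print.remi_problem <- function(x, ...) {
  cat("<remi_problem> variant ", x$settings$variant, ": TMCS ",
      x$tmcs, " candidate constraints (",
      sum(x$candidates$kind == "gene"), " gene, ",
      sum(x$candidates$kind == "metabolite"), " metabolite)\n", sep = "")
  invisible(x)
}

#' Maximize the consistency score
#'
#' Solves the MILP maximizing the number of candidate constraints that
#' can be active simultaneously. The theoretical maximum consistency
#' score (TMCS) is the number of candidates; the maximum consistency
#' score (MCS) is the optimum.
#'
#' @param problem a [build_remi_problem()] result.
#' @return `consistency_result`: `tmcs`, `tmcs_gene_level`, `mcs`,
#'   `active_set` (candidate ids), `status`, `alternatives` (list holding
#'   the active set; extended by [enumerate_alternatives()]).
#' @export
solve_mcs <- function(problem) {
  zs <- if (nrow(problem$candidates))
    paste0("z_", problem$candidates$candidate_id) else character(0)
  res <- list(tmcs = problem$tmcs,
              tmcs_gene_level = problem$tmcs_gene_level,
              mcs = 0L, active_set = character(),
              status = "optimal", alternatives = list())
  class(res) <- "consistency_result"
  if (!length(zs)) return(res)
  lp <- lp_clone(problem$lp)
  lp_set_objective(lp, setNames(rep(1, length(zs)), zs))
  s <- lp_solve(lp, maximize = TRUE,
                max_nodes = problem$settings$max_nodes,
                time_limit = problem$settings$time_limit)
  if (!s$status %in% c("optimal", "time_limit")) {
    res$status <- s$status
    return(res)
  }
  res$status <- s$status
  res$mcs <- as.integer(round(s$objective))
  res$active_set <- sort(problem$candidates$candidate_id[
    s$x[zs] > 0.5])
  res$alternatives <- list(res$active_set)
  res
}

#' @exportS3Method base::print
print.consistency_result <- function(x, ...) {
  cat("<consistency_result> TMCS ", x$tmcs, ", MCS ", x$mcs, " (",
      length(x$alternatives), " alternative(s), status ", x$status,
      ")\n", sep = "")
  invisible(x)
}

#' Enumerate alternative optimal active sets
#'
#' Fixes the consistency score at the MCS and repeatedly adds integer
#' cuts excluding previously found active sets until the problem becomes
#' infeasible or `max_alternatives` is reached. All returned sets are
#' pairwise distinct and each attains the MCS.
#'
#' @param problem a [build_remi_problem()] result.
#' @param result the [solve_mcs()] result.
#' @param max_alternatives cap (defaults to the problem settings).
#' @return the `consistency_result` with `alternatives` extended.
#' @export
enumerate_alternatives <- function(problem, result,
                                   max_alternatives =
                                     problem$settings$max_alternatives) {
  if (result$mcs == 0L) return(result)
  zs <- paste0("z_", problem$candidates$candidate_id)
  lp <- lp_clone(problem$lp)
  lp_set_objective(lp, setNames(rep(1, length(zs)), zs))
  lp_add_con(lp, setNames(rep(1, length(zs)), zs), "=", result$mcs)
  alts <- result$alternatives
  repeat {
    if (length(alts) >= max_alternatives) break
    prev <- alts[[length(alts)]]
    lp_add_con(lp, setNames(rep(1, length(prev)), paste0("z_", prev)),
               "<=", result$mcs - 1)
    s <- lp_solve(lp, maximize = TRUE,
                  max_nodes = problem$settings$max_nodes,
                  time_limit = problem$settings$time_limit)
    if (s$status != "optimal") break
    alts[[length(alts) + 1L]] <- sort(problem$candidates$candidate_id[
      s$x[zs] > 0.5])
  }
  result$alternatives <- alts
  result
}

#' Per-condition growth under a fixed active set
#'
#' Fixes the candidate indicators to the given active set and maximizes
#' the biomass flux separately in the reference and perturbed copies.
#'
#' @param problem a [build_remi_problem()] result.
#' @param active_set candidate ids to activate (others deactivated).
#' @return named numeric: `growth_reference`, `growth_perturbed` (1/h).
#' @export
condition_growth <- function(problem, active_set) {
  lp <- lp_clone(problem$lp)
  for (cid in problem$candidates$candidate_id) {
    on <- cid %in% active_set
    lp_set_bounds(lp, paste0("z_", cid), lb = as.numeric(on),
                  ub = as.numeric(on))
  }
  out <- numeric(2)
  for (k in 1:2) {
    cond <- c("ref", "pert")[k]
    lp_set_objective(lp, act_net(cond, problem$biomass_id))
    s <- lp_solve(lp, maximize = TRUE,
                  max_nodes = problem$settings$max_nodes,
                  time_limit = problem$settings$time_limit)
    if (s$status != "optimal")
      stop("active set infeasible when maximizing ", cond, " growth (",
           s$status, ")")
    out[k] <- s$objective
  }
  setNames(out, c("growth_reference", "growth_perturbed"))
}

#' Common and varying constraints across alternative optima
#'
#' @param alternatives list of active sets (candidate-id vectors).
#' @return list with `common` (intersection), `varying` (union minus
#'   intersection), each a data.frame with `candidate_id` and `source`
#'   (`"gene"`/`"metabolite"` from the id prefix).
#' @export
common_and_variable_constraints <- function(alternatives) {
  stopifnot(length(alternatives) >= 1)
  common <- Reduce(intersect, alternatives)
  varying <- setdiff(Reduce(union, alternatives), common)
  lab <- function(ids)
    data.frame(candidate_id = sort(ids),
               source = ifelse(startsWith(sort(ids), "g:"), "gene",
                               "metabolite"),
               stringsAsFactors = FALSE)
  list(common = lab(common), varying = lab(varying))
}

#' Maximal precursor production under an active set
#'
#' For each precursor, opens its embedded demand sink in one condition
#' copy at a time and maximizes the demand flux with the candidate
#' indicators fixed.
#'
#' @param problem a [build_remi_problem()] result built with
#'   `extra_demand_mets` covering `precursors`.
#' @param active_set candidate ids to activate.
#' @param precursors metabolite ids (default: all embedded demands).
#' @return matrix (precursors x conditions `ref`,`pert`) of maximal
#'   production fluxes; infeasible probes yield 0.
#' @export
remi_bbb_production <- function(problem, active_set,
                                precursors = problem$demand_mets) {
  stopifnot(all(precursors %in% problem$demand_mets))
  base <- lp_clone(problem$lp)
  for (cid in problem$candidates$candidate_id) {
    on <- cid %in% active_set
    lp_set_bounds(base, paste0("z_", cid), lb = as.numeric(on),
                  ub = as.numeric(on))
  }
  out <- matrix(0, length(precursors), 2,
                dimnames = list(precursors, c("ref", "pert")))
  for (p in precursors) {
    for (cond in c("ref", "pert")) {
      dv <- paste0(cond, ".f_DM_", p)
      lp_set_bounds(base, dv, ub = 1000)
      lp_set_objective(base, setNames(1, dv))
      s <- lp_solve(base, maximize = TRUE,
                    max_nodes = problem$settings$max_nodes,
                    time_limit = problem$settings$time_limit)
      out[p, cond] <- if (s$status == "optimal") s$objective else 0
      lp_set_bounds(base, dv, ub = 0)
    }
  }
  out
}

#' Select the most representative alternative
#'
#' Computes the per-alternative precursor production vector (both
#' conditions stacked) and returns the alternative minimizing the L1
#' distance to the element-wise median vector; ties break on the first
#' index.
#'
#' @param problem a [build_remi_problem()] result with embedded demands.
#' @param alternatives list of active sets.
#' @param precursors metabolite ids (default: embedded demands).
#' @return list: `index`, `active_set`, `productions` (list of matrices
#'   from [remi_bbb_production()]), `distances`.
#' @export
select_representative <- function(problem, alternatives,
                                  precursors = problem$demand_mets) {
  prods <- lapply(alternatives, remi_bbb_production, problem = problem,
                  precursors = precursors)
  vecs <- vapply(prods, as.numeric,
                 numeric(2L * length(precursors)))
  med <- apply(vecs, 1, median)
  dists <- colSums(abs(vecs - med))
  idx <- which.min(dists)
  list(index = idx, active_set = alternatives[[idx]],
       productions = prods, distances = dists)
}

#' Run a full consistency-maximization analysis
#'
#' Convenience wrapper: builds the problem, maximizes the consistency
#' score, enumerates alternative optima and reports per-alternative
#' growth rates.
#'
#' @inheritParams build_remi_problem
#' @param enumerate enumerate alternative optima.
#' @return `consistency_result` with `growth` (matrix alternatives x 2)
#'   and `growth_summary` (mean and sd per condition) attached.
#' @export
remi <- function(model, thermo, omics, settings = remi_settings(),
                 extra_demand_mets = character(), enumerate = TRUE) {
  problem <- build_remi_problem(model, thermo, omics, settings,
                                extra_demand_mets)
  res <- solve_mcs(problem)
  if (enumerate && res$mcs > 0)
    res <- enumerate_alternatives(problem, res)
  if (length(res$alternatives)) {
    gr <- t(vapply(res$alternatives, condition_growth, numeric(2),
                   problem = problem))
    res$growth <- gr
    res$growth_summary <- rbind(mean = colMeans(gr),
                                sd = apply(gr, 2, stats::sd))
  }
  res$problem <- problem
  res
}
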