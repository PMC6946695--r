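#' Default currency metabolite list
#'
#' Ubiquitous cofactors and small inorganics removed from the bipartite
#' graph before network decomposition (never from the flux mathematics).
#' Matching is by metabolite id stripped of its compartment suffix.
#' @export
currency_metabolites <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "h", "h2o",
    "pi", "ppi", "co2", "coa", "o2", "nh4")
}

strip_compartment <- function(ids) sub("_[a-z]+$", "", ids)

#' Decompose a metabolic network into connected components
#'
#' Builds the bipartite reaction-metabolite graph, removes currency
#' metabolites, and returns its connected components ordered by size
#' (descending), ties broken by the lexicographically smallest reaction
#' id. Exactly one component (the largest) is flagged as the main network.
#'
#' @param model a [metabolic_model()].
#' @param currency metabolite base names treated as currency.
#' @return list of `network_component`: `component_id`, `reaction_ids`,
#'   `metabolite_ids`, `is_main`.
#' @export
decompose_network <- function(model, currency = currency_metabolites()) {
  rids <- names(model$reactions)
  mids <- model$metabolites$id
  keep <- mids[!(strip_compartment(mids) %in% currency)]
  edges <- character(0)
  for (rxn in model$reactions) {
    touched <- intersect(names(rxn$stoichiometry), keep)
    if (length(touched))
      edges <- c(edges, rbind(paste0("R::", rxn$id),
                              paste0("M::", touched)))
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(rids) + length(keep),
                            name = c(paste0("R::", rids),
                                     paste0("M::", keep)))
  if (length(edges))
    g <- igraph::add_edges(g, match(edges, igraph::V(g)$name))
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  out <- lapply(groups, function(vs) {
    list(reaction_ids = sort(sub("^R::", "", vs[startsWith(vs, "R::")])),
         metabolite_ids = sort(sub("^M::", "", vs[startsWith(vs, "M::")])))
  })
  # keep only components containing at least one reaction
  out <- out[vapply(out, function(x) length(x$reaction_ids) > 0,
                    logical(1))]
  sizes <- vapply(out, function(x) length(x$reaction_ids), integer(1))
  firsts <- vapply(out, function(x) x$reaction_ids[1], character(1))
  ord <- order(-sizes, firsts)
  out <- out[ord]
  for (k in seq_along(out)) {
    out[[k]]$component_id <- k
    out[[k]]$is_main <- k == 1L
    class(out[[k]]) <- "network_component"
  }
  out
}

#' Detect blocked reactions
#'
#' A reaction is blocked when it cannot carry nonzero flux under any
#' exchange configuration. All exchange reactions are opened to the probe
#' bounds, then flux variability at objective fraction zero is computed;
#' reactions with a (0, 0) range are blocked. The result is independent of
#' the objective and of reaction ordering.
#'
#' @param model a [metabolic_model()].
#' @param open_bound magnitude to which exchange bounds are opened.
#' @param tol flux tolerance below which a range counts as zero.
#' @return sorted character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, open_bound = 1000, tol = 1e-6) {
  probe <- model
  for (rid in names(probe$reactions)) {
    if (probe$reactions[[rid]]$kind == "exchange") {
      probe$reactions[[rid]]$lower_bound <- -open_bound
      probe$reactions[[rid]]$upper_bound <- open_bound
    }
  }
  fv <- flux_variability(probe, objective_fraction = 0)
  sort(fv$reaction_id[abs(fv$min) < tol & abs(fv$max) < tol])
}

#' Group blocked reactions into blocked pathways
#'
#' A blocked pathway is a maximal connected chain of blocked reactions
#' (connected through shared non-currency metabolites).
#'
#' @param model a [metabolic_model()].
#' @param blocked blocked reaction ids (from
#'   [find_blocked_reactions()]).
#' @param currency currency metabolite base names.
#' @return list of character vectors, each one blocked pathway, ordered by
#'   decreasing length then first id.
#' @export
blocked_pathways <- function(model, blocked,
                             currency = currency_metabolites()) {
  if (!length(blocked)) return(list())
  sub <- model
  sub$reactions <- sub$reactions[blocked]
  used <- unique(unlist(lapply(sub$reactions,
                               function(r) names(r$stoichiometry))))
  sub$metabolites <- sub$metabolites[sub$metabolites$id %in% used, ]
  comps <- decompose_network(sub, currency)
  paths <- lapply(comps, `[[`, "reaction_ids")
  lens <- vapply(paths, length, integer(1))
  firsts <- vapply(paths, `[`, character(1), 1)
  paths[order(-lens, firsts)]
}

#' A gap-filling task
#'
#' @param target reaction id to unblock, or metabolite id to make
#'   producible (interpreted as reaction if present in the model's
#'   reaction list, else as metabolite).
#' @param universal_db a [metabolic_model()]-like reaction pool.
#' @param min_flux activation threshold (mmol/gDW/h) the target must
#'   carry.
#' @param max_alternatives maximum number of alternative minimal sets to
#'   enumerate.
#' @param omics_evidence gene/metabolite ids supporting the target
#'   (bookkeeping from prioritization).
#' @param score prioritization score (omics evidence count).
#' @export
gapfill_task <- function(target, universal_db, min_flux = 1e-3,
                         max_alternatives = 10L,
                         omics_evidence = character(), score = NA_real_) {
  stopifnot(min_flux > 0)
  structure(list(target = target, universal_db = universal_db,
                 min_flux = min_flux, max_alternatives = max_alternatives,
                 omics_evidence = omics_evidence, score = score),
            class = "gapfill_task")
}

#' Rank blocked reactions/pathways by omics evidence
#'
#' Scores every blocked pathway by the number of significantly
#' differentially expressed genes in its GPRs plus the number of measured
#' metabolites among its participants; only pathways with positive score
#' become gap-filling tasks, ranked by descending score with ties broken
#' by target id.
#'
#' @param model a [metabolic_model()].
#' @param blocked blocked reaction ids.
#' @param omics an [omics_data()].
#' @param universal_db reaction pool attached to emitted tasks.
#' @param theta fold-change threshold (a gene is DE when
#'   `|log2fc| >= log2(theta)` and `fdr < fdr_cutoff`).
#' @param fdr_cutoff significance threshold.
#' @param ... passed to [gapfill_task()].
#' @return list of [gapfill_task()] objects.
#' @export
prioritize_blocked <- function(model, blocked, omics, universal_db = NULL,
                               theta = 2, fdr_cutoff = 0.05, ...) {
  paths <- blocked_pathways(model, blocked)
  de <- omics$genes$gene_id[abs(omics$genes$log2fc) >= log2(theta) &
                              omics$genes$fdr < fdr_cutoff]
  measured <- omics$metabolites$metabolite_id
  tasks <- list()
  for (pw in paths) {
    genes <- unique(unlist(lapply(model$reactions[pw], `[[`, "genes")))
    mets <- unique(unlist(lapply(model$reactions[pw],
                                 function(r) names(r$stoichiometry))))
    score <- length(intersect(genes, de)) +
      length(intersect(mets, measured))
    if (score > 0) {
      # target: the lexicographically first reaction of the pathway
      tasks[[length(tasks) + 1L]] <-
        gapfill_task(pw[1], universal_db,
                     omics_evidence = c(intersect(genes, de),
                                        intersect(mets, measured)),
                     score = score, ...)
    }
  }
  ord <- order(-vapply(tasks, `[[`, numeric(1), "score"),
               vapply(tasks, `[[`, character(1), "target"))
  tasks[ord]
}

#' Gap-fill a blocked target with a minimal reaction set
#'
#' MILP: binary indicators select database reactions; steady state must
#' hold on the merged network with all exchanges opened; the target must
#' carry at least `min_flux`; the number of added reactions is minimized.
#' Alternative minimal sets of equal size are enumerated with integer
#' cuts.
#'
#' @param model a [metabolic_model()].
#' @param task a [gapfill_task()].
#' @param direction direction in which the target must carry flux.
#' @param open_exchanges open all exchange bounds for the probe (the
#'   blocked-reaction convention).
#' @return `gapfill_solution`: `status` (`"filled"`/`"unfillable"`),
#'   `added_reaction_ids`, `size`, `alternative_sets`, `genes_suggested`.
#' @export
gapfill <- function(model, task, direction = c("forward", "backward"),
                    open_exchanges = TRUE) {
  direction <- match.arg(direction)
  db <- task$universal_db
  db_new <- setdiff(names(db$reactions), names(model$reactions))
  lp <- lp_problem()
  all_rxns <- c(model$reactions, db$reactions[db_new])
  bounds_of <- function(r) {
    lb <- r$lower_bound; ub <- r$upper_bound
    if (open_exchanges && r$kind == "exchange") { lb <- -1000; ub <- 1000 }
    c(lb, ub)
  }
  for (rid in names(all_rxns)) {
    bb <- bounds_of(all_rxns[[rid]])
    lp_add_var(lp, paste0("v_", rid), lb = bb[1], ub = bb[2])
  }
  # steady state on the union metabolite set
  rows <- new.env(parent = emptyenv(), hash = TRUE)
  for (rid in names(all_rxns)) {
    st <- all_rxns[[rid]]$stoichiometry
    for (k in seq_along(st)) {
      mid <- names(st)[k]
      cur <- rows[[mid]]
      if (is.null(cur)) cur <- numeric()
      vkey <- paste0("v_", rid)
      cur[vkey] <- (cur[vkey] %||0% 0) + unname(st[k])
      assign(mid, cur, envir = rows)
    }
  }
  target_is_rxn <- task$target %in% names(all_rxns)
  if (!target_is_rxn) {
    # metabolite target: include a transient demand sink in its balance row
    if (is.null(rows[[task$target]]))
      stop("target '", task$target, "' is neither a reaction nor a ",
           "metabolite of the merged network")
    lp_add_var(lp, "v_DM_target", lb = 0, ub = 1000)
    cur <- rows[[task$target]]
    cur["v_DM_target"] <- -1
    assign(task$target, cur, envir = rows)
  }
  for (mid in ls(rows)) lp_add_con(lp, rows[[mid]], "=", 0)
  # indicator coupling for database reactions
  for (rid in db_new) {
    bb <- bounds_of(db$reactions[[rid]])
    lp_add_var(lp, paste0("y_", rid), lb = 0, ub = 1, integer = TRUE)
    lp_add_con(lp, setNames(c(1, -bb[2]),
                            paste0(c("v_", "y_"), rid)), "<=", 0)
    lp_add_con(lp, setNames(c(1, -bb[1]),
                            paste0(c("v_", "y_"), rid)), ">=", 0)
  }
  # target activation
  if (target_is_rxn) {
    sgn <- if (direction == "forward") 1 else -1
    lp_add_con(lp, setNames(sgn, paste0("v_", task$target)), ">=",
               task$min_flux)
  } else {
    lp_add_con(lp, setNames(1, "v_DM_target"), ">=", task$min_flux)
  }
  lp_set_objective(lp, setNames(rep(1, length(db_new)),
                                paste0("y_", db_new)))
  sol <- lp_solve(lp, maximize = FALSE)
  if (sol$status != "optimal")
    return(structure(list(status = "unfillable",
                          added_reaction_ids = character(),
                          size = NA_integer_,
                          alternative_sets = list(),
                          genes_suggested = character()),
                     class = "gapfill_solution"))
  size <- as.integer(round(sol$objective))
  active <- function(s) sort(db_new[s$x[paste0("y_", db_new)] > 0.5])
  first <- active(sol)
  # enumerate equal-size alternatives with integer cuts
  alts <- list(first)
  lp_add_con(lp, setNames(rep(1, length(db_new)), paste0("y_", db_new)),
             "=", size)
  cur_set <- first
  while (length(alts) < task$max_alternatives) {
    if (length(cur_set))
      lp_add_con(lp, setNames(rep(1, length(cur_set)),
                              paste0("y_", cur_set)), "<=",
                 length(cur_set) - 1)
    else break
    s2 <- lp_solve(lp, maximize = FALSE)
    if (s2$status != "optimal") break
    cur_set <- active(s2)
    alts[[length(alts) + 1L]] <- cur_set
  }
  genes <- sort(unique(unlist(lapply(db$reactions[first], `[[`, "genes"))))
  structure(list(status = "filled", added_reaction_ids = first,
                 size = size, alternative_sets = alts,
                 genes_suggested = genes, target = task$target),
            class = "gapfill_solution")
}

#' @exportS3Method base::print
print.gapfill_solution <- function(x, ...) {
  if (x$status == "unfillable") {
    cat("<gapfill_solution> unfillable\n")
  } else {
    cat("<gapfill_solution> size ", x$size, ": ",
        paste(x$added_reaction_ids, collapse = ", "), " (",
        length(x$alternative_sets), " alternative set(s))\n", sep = "")
  }
  invisible(x)
}

#' Apply a gap-fill solution to a model
#'
#' Adds the selected database reactions (and any metabolites they
#' introduce) to the model. Colliding reaction ids are suffix-renamed with
#' a warning.
#'
#' @param model a [metabolic_model()].
#' @param solution a `gapfill_solution`.
#' @param universal_db the reaction pool the solution was drawn from.
#' @return the augmented [metabolic_model()].
#' @export
apply_gapfill <- function(model, solution, universal_db) {
  if (solution$status != "filled" || !length(solution$added_reaction_ids))
    return(model)
  mets <- model$metabolites
  rxns <- model$reactions
  for (rid in solution$added_reaction_ids) {
    r <- universal_db$reactions[[rid]]
    new_mets <- setdiff(names(r$stoichiometry), mets$id)
    if (length(new_mets))
      mets <- rbind(mets,
                    universal_db$metabolites[
                      universal_db$metabolites$id %in% new_mets, ,
                      drop = FALSE])
    if (r$id %in% names(rxns)) {
      new_id <- paste0(r$id, "_gf")
      warning("gap-fill id collision: ", r$id, " renamed to ", new_id)
      r$id <- new_id
    }
    rxns[[r$id]] <- r
  }
  comps <- model$compartments
  missing_comp <- setdiff(unique(mets$compartment), names(comps))
  if (length(missing_comp))
    comps <- c(comps, setNames(missing_comp, missing_comp))
  metabolic_model(mets, rxns, comps, model$biomass_reaction_id,
                  id = model$id)
}
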