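#' Flux balance analysis
#'
#' Maximizes the flux of `objective_reaction` subject to steady state
#' (S v = 0) and the model's flux bounds.
#'
#' @param model a [metabolic_model()].
#' @param objective_reaction reaction id to maximize; defaults to the
#'   biomass reaction.
#' @param maximize maximize (default) or minimize the objective.
#' @return a `flux_solution`: list with `objective_value`, `fluxes` (named
#'   numeric, mmol/gDW/h), `status`.
#' @export
solve_fba <- function(model, objective_reaction = model$biomass_reaction_id,
                      maximize = TRUE) {
  if (!objective_reaction %in% names(model$reactions))
    stop("objective reaction not in model: ", objective_reaction)
  lp <- build_fba_lp(model)
  lp_set_objective(lp, setNames(1, objective_reaction))
  r <- lp_solve(lp, maximize = maximize)
  as_flux_solution(r, names(model$reactions))
}

build_fba_lp <- function(model) {
  lp <- lp_problem()
  for (rxn in model$reactions)
    lp_add_var(lp, rxn$id, lb = rxn$lower_bound, ub = rxn$upper_bound)
  mass_balance_constraints(lp, model, names(model$reactions))
  lp
}

# Add one steady-state row per metabolite; var_of maps reaction id -> lp
# variable name (identity for plain FBA, used for prefixed condition copies).
mass_balance_constraints <- function(lp, model, rids,
                                     var_of = identity) {
  rows <- new.env(parent = emptyenv(), hash = TRUE)
  for (rid in rids) {
    st <- model$reactions[[rid]]$stoichiometry
    for (k in seq_along(st)) {
      mid <- names(st)[k]
      cur <- rows[[mid]]
      if (is.null(cur)) cur <- numeric()
      cur[var_of(rid)] <- (cur[var_of(rid)] %||0% 0) + unname(st[k])
      assign(mid, cur, envir = rows)
    }
  }
  for (mid in ls(rows))
    lp_add_con(lp, rows[[mid]], "=", 0, name = paste0("mb_", mid))
  invisible(lp)
}

`%||0%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

as_flux_solution <- function(r, rids, extra = list()) {
  status <- r$status
  fluxes <- if (status %in% c("optimal", "time_limit"))
    r$x[rids] else setNames(rep(NA_real_, length(rids)), rids)
  out <- c(list(objective_value = if (status %in% c("optimal", "time_limit"))
                  r$objective else NA_real_,
                fluxes = fluxes, status = status), extra)
  class(out) <- "flux_solution"
  out
}

#' @exportS3Method base::print
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status=", x$status, ", objective=",
      format(x$objective_value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux while the objective is held at a
#' fraction of its optimum. `objective_fraction = 0` probes absolute
#' capability and is the instrument used for blocked-reaction detection.
#'
#' @param model a [metabolic_model()].
#' @param reactions reaction ids to scan (default: all).
#' @param objective_fraction required fraction of the optimal objective.
#' @param objective_reaction objective used for the fraction constraint.
#' @param thermo optional [thermo_annotation()]; when given, ranges are
#'   computed under thermodynamic (TFA) constraints.
#' @param settings [tfa_settings()] used when `thermo` is given.
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
flux_variability <- function(model, reactions = names(model$reactions),
                             objective_fraction = 0,
                             objective_reaction = model$biomass_reaction_id,
                             thermo = NULL, settings = tfa_settings()) {
  use_thermo <- !is.null(thermo)
  if (use_thermo) {
    built <- build_tfa_milp(model, thermo, settings)
    lp <- built$lp
    netvar <- built$net
  } else {
    lp <- build_fba_lp(model)
    netvar <- function(rid) setNames(1, rid)
  }
  obj_expr <- if (use_thermo) netvar(objective_reaction)
              else setNames(1, objective_reaction)
  if (objective_fraction > 0) {
    lp_set_objective(lp, obj_expr)
    base <- lp_solve(lp, maximize = TRUE)
    if (base$status != "optimal")
      stop("base model is ", base$status, "; cannot run FVA")
    lp_add_con(lp, obj_expr, ">=", objective_fraction * base$objective,
               name = "fva_floor")
  } else {
    # feasibility probe before scanning
    lp_set_objective(lp, setNames(0, lp$var_names[1]))
    probe <- lp_solve(lp, maximize = TRUE)
    if (probe$status != "optimal")
      stop("base model is ", probe$status, "; cannot run FVA")
  }
  res <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    rid <- reactions[k]
    lp_set_objective(lp, if (use_thermo) netvar(rid) else setNames(1, rid))
    up <- lp_solve(lp, maximize = TRUE)
    dn <- lp_solve(lp, maximize = FALSE)
    res$max[k] <- if (up$status == "optimal") up$objective else NA_real_
    res$min[k] <- if (dn$status == "optimal") dn$objective else NA_real_
  }
  res
}

#' Minimal substrate uptake required to reach a target growth rate
#'
#' Fixes growth as a lower bound and minimizes the uptake magnitude of an
#' exchange reaction (uptake = negative exchange flux). With a thermodynamic
#' annotation the search runs under TFA constraints.
#'
#' @param model a [metabolic_model()].
#' @param uptake_reaction id of the exchange reaction supplying the
#'   substrate.
#' @param target_growth required growth rate (1/h).
#' @param thermo optional [thermo_annotation()].
#' @param settings [tfa_settings()].
#' @return list with `uptake` (mmol/gDW/h, positive magnitude) and
#'   `status` (`"ok"` or `"unreachable"`).
#' @export
estimate_uptake_for_growth <- function(model, uptake_reaction, target_growth,
                                       thermo = NULL,
                                       settings = tfa_settings()) {
  rxn <- model$reactions[[uptake_reaction]]
  if (is.null(rxn) || rxn$kind != "exchange")
    stop("uptake_reaction must be an exchange reaction in the model")
  if (is.null(thermo)) {
    lp <- build_fba_lp(model)
    obj <- setNames(1, uptake_reaction)
    gr <- setNames(1, model$biomass_reaction_id)
  } else {
    built <- build_tfa_milp(model, thermo, settings)
    lp <- built$lp
    obj <- built$net(uptake_reaction)
    gr <- built$net(model$biomass_reaction_id)
  }
  lp_add_con(lp, gr, ">=", target_growth, name = "growth_floor")
  lp_set_objective(lp, obj)
  r <- lp_solve(lp, maximize = TRUE)   # least-negative exchange flux
  if (r$status != "optimal")
    return(list(uptake = NA_real_, status = "unreachable"))
  list(uptake = -r$objective, status = "ok")
}
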