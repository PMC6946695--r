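#' Thermodynamic annotation of a metabolic model
#'
#' Standard Gibbs energies and metabolite concentration bounds enabling
#' thermodynamics-based flux analysis (TFA). Reaction standard Gibbs
#' energies absent from `dGr_std` are derived as the stoichiometric sum of
#' formation energies when all participants are covered; reactions with any
#' uncovered participant and no direct value receive no thermodynamic
#' constraint.
#'
#' @param dGf_std named numeric, metabolite id -> standard Gibbs free energy
#'   of formation (kJ/mol).
#' @param dGr_std named numeric, reaction id -> standard Gibbs free energy
#'   of reaction (kJ/mol); takes precedence over sums of `dGf_std`.
#' @param conc_lb,conc_ub default metabolite concentration bounds (mol/L);
#'   the defaults 1e-7 and 1e-1 span the physiological range commonly
#'   assumed for intracellular metabolites.
#' @param conc_overrides optional data.frame (`metabolite_id`, `conc_lb`,
#'   `conc_ub`) with per-metabolite bounds.
#' @param temperature temperature in K (default 303.15, cultures at 30 C).
#' @param R gas constant (kJ/mol/K).
#' @param fixed_activity metabolite name patterns excluded from the
#'   log-concentration terms (fixed-activity convention for protons and
#'   water).
#' @return object of class `thermo_annotation`.
#' @export
thermo_annotation <- function(dGf_std = numeric(), dGr_std = numeric(),
                              conc_lb = 1e-7, conc_ub = 1e-1,
                              conc_overrides = NULL,
                              temperature = 303.15, R = 8.314e-3,
                              fixed_activity = c("h", "h2o", "h_c", "h_p",
                                                 "h_e", "h2o_c", "h2o_p",
                                                 "h2o_e")) {
  stopifnot(conc_lb > 0, conc_ub >= conc_lb)
  obj <- list(dGf_std = dGf_std, dGr_std = dGr_std,
              conc_lb = conc_lb, conc_ub = conc_ub,
              conc_overrides = conc_overrides,
              temperature = temperature, R = R,
              fixed_activity = fixed_activity)
  class(obj) <- "thermo_annotation"
  obj
}

#' @exportS3Method base::print
print.thermo_annotation <- function(x, ...) {
  cat("<thermo_annotation> ", length(x$dGf_std), " formation energies, ",
      length(x$dGr_std), " reaction energies, T=", x$temperature, "K\n",
      sep = "")
  invisible(x)
}

#' Read a thermodynamic annotation from TSV
#'
#' Expected columns: `id`, `type` (`metabolite` or `reaction`), `dG`
#' (kJ/mol), and optional `conc_lb`, `conc_ub` for metabolite rows.
#' @param path TSV file.
#' @param ... passed to [thermo_annotation()].
#' @export
read_thermo_tsv <- function(path, ...) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  met <- tab[tab$type == "metabolite", ]
  rxn <- tab[tab$type == "reaction", ]
  ov <- NULL
  if (!is.null(met$conc_lb) && any(!is.na(met$conc_lb)))
    ov <- data.frame(metabolite_id = met$id[!is.na(met$conc_lb)],
                     conc_lb = met$conc_lb[!is.na(met$conc_lb)],
                     conc_ub = met$conc_ub[!is.na(met$conc_lb)])
  thermo_annotation(dGf_std = setNames(met$dG, met$id)[!is.na(met$dG)],
                    dGr_std = setNames(rxn$dG, rxn$id),
                    conc_overrides = ov, ...)
}

#' Write a thermodynamic annotation to TSV
#' @param thermo a [thermo_annotation()].
#' @param path output TSV file.
#' @export
write_thermo_tsv <- function(thermo, path) {
  rows <- rbind(
    if (length(thermo$dGf_std))
      data.frame(id = names(thermo$dGf_std), type = "metabolite",
                 dG = unname(thermo$dGf_std)),
    if (length(thermo$dGr_std))
      data.frame(id = names(thermo$dGr_std), type = "reaction",
                 dG = unname(thermo$dGr_std)))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' TFA solver settings
#'
#' @param big_M flux-direction coupling constant; must exceed the largest
#'   flux bound magnitude.
#' @param dG_margin minimal thermodynamic driving force delta (kJ/mol).
#' @param time_limit MILP wall-clock limit in seconds.
#' @param max_nodes branch-and-bound node limit.
#' @export
tfa_settings <- function(big_M = 1000, dG_margin = 0, time_limit = Inf,
                         max_nodes = 200000L) {
  stopifnot(dG_margin >= 0, big_M > 0)
  list(big_M = big_M, dG_margin = dG_margin, time_limit = time_limit,
       max_nodes = max_nodes)
}

# Effective standard reaction Gibbs energy for every reaction that can get
# one: direct dGr_std first, else the stoichiometric sum of dGf_std.
reaction_dGr <- function(model, thermo) {
  out <- numeric(0)
  for (rxn in model$reactions) {
    if (rxn$kind %in% c("exchange", "biomass", "demand")) next
    if (rxn$id %in% names(thermo$dGr_std)) {
      v <- thermo$dGr_std[[rxn$id]]
      if (!is.na(v)) out[rxn$id] <- v
      next
    }
    st <- rxn$stoichiometry
    if (all(names(st) %in% names(thermo$dGf_std))) {
      out[rxn$id] <- sum(unname(st) * thermo$dGf_std[names(st)])
    }
  }
  out
}

met_conc_bounds <- function(thermo, mid) {
  lo <- thermo$conc_lb; hi <- thermo$conc_ub
  ov <- thermo$conc_overrides
  if (!is.null(ov) && mid %in% ov$metabolite_id) {
    k <- match(mid, ov$metabolite_id)
    lo <- ov$conc_lb[k]; hi <- ov$conc_ub[k]
  }
  c(lo, hi)
}

# Build the TFA MILP on split fluxes. Returns list(lp, net, covered) where
# net(rid) gives the named coefficient vector expressing the net flux of a
# reaction and covered is the set of thermodynamically constrained ids.
# prefix allows duplicated condition copies to share one lp_problem.
build_tfa_milp <- function(model, thermo, settings = tfa_settings(),
                           lp = NULL, prefix = "") {
  if (is.null(lp)) lp <- lp_problem()
  RT <- thermo$R * thermo$temperature
  dGr <- reaction_dGr(model, thermo)
  covered <- names(dGr)
  vn <- function(tag, id) paste0(prefix, tag, "_", id)

  for (rxn in model$reactions) {
    fub <- max(0, rxn$upper_bound)
    bub <- max(0, -rxn$lower_bound)
    lp_add_var(lp, vn("f", rxn$id), lb = 0, ub = fub)
    lp_add_var(lp, vn("b", rxn$id), lb = 0, ub = bub)
    # net bounds (redundant with split bounds but keep lb when lb > 0)
    if (rxn$lower_bound > 0)
      lp_add_con(lp, setNames(c(1, -1), c(vn("f", rxn$id), vn("b", rxn$id))),
                 ">=", rxn$lower_bound)
    if (rxn$upper_bound < 0)
      lp_add_con(lp, setNames(c(1, -1), c(vn("f", rxn$id), vn("b", rxn$id))),
                 "<=", rxn$upper_bound)
  }

  # steady state over split fluxes
  rows <- new.env(parent = emptyenv(), hash = TRUE)
  for (rxn in model$reactions) {
    st <- rxn$stoichiometry
    for (k in seq_along(st)) {
      mid <- names(st)[k]
      cur <- rows[[mid]]
      if (is.null(cur)) cur <- numeric()
      cur[vn("f", rxn$id)] <- (cur[vn("f", rxn$id)] %||0% 0) + unname(st[k])
      cur[vn("b", rxn$id)] <- (cur[vn("b", rxn$id)] %||0% 0) - unname(st[k])
      assign(mid, cur, envir = rows)
    }
  }
  for (mid in ls(rows))
    lp_add_con(lp, rows[[mid]], "=", 0, name = paste0(prefix, "mb_", mid))

  # log-concentration variables for metabolites participating in covered
  # reactions (fixed-activity species excluded)
  lnc_needed <- unique(unlist(lapply(covered, function(rid)
    names(model$reactions[[rid]]$stoichiometry))))
  lnc_needed <- setdiff(lnc_needed, thermo$fixed_activity)
  for (mid in lnc_needed) {
    cb <- met_conc_bounds(thermo, mid)
    lp_add_var(lp, vn("lnc", mid), lb = log(cb[1]), ub = log(cb[2]))
  }

  delta <- settings$dG_margin
  M <- settings$big_M
  for (rid in covered) {
    st <- model$reactions[[rid]]$stoichiometry
    terms <- st[!(names(st) %in% thermo$fixed_activity)]
    # bound on |dG_r| from data; big-K derived from it for tight coupling
    span <- abs(dGr[[rid]]) +
      RT * sum(abs(unname(terms)) *
               vapply(names(terms), function(m)
                 max(abs(log(met_conc_bounds(thermo, m)))), numeric(1))) + 1
    K <- span + delta + 1
    lp_add_var(lp, vn("dG", rid), lb = -span, ub = span)
    # dG_r - RT * sum s_mr lnc_m = dGr0
    co <- setNames(c(1, -RT * unname(terms)),
                   c(vn("dG", rid), vapply(names(terms), vn,
                                           character(1), tag = "lnc")))
    lp_add_con(lp, co, "=", dGr[[rid]])
    # direction indicators only where the corresponding half-reaction can
    # carry flux; each indicator is supported by its half-flux variable
    rxn <- model$reactions[[rid]]
    can_f <- rxn$upper_bound > 0
    can_b <- rxn$lower_bound < 0
    if (can_f) {
      lp_add_var(lp, vn("up", rid), lb = 0, ub = 1, integer = TRUE)
      lp_set_support(lp, vn("up", rid), vn("f", rid))
      lp_add_con(lp, setNames(c(1, -M), c(vn("f", rid), vn("up", rid))),
                 "<=", 0)
      # dG <= -delta + K (1 - up)
      lp_add_con(lp, setNames(c(1, K), c(vn("dG", rid), vn("up", rid))),
                 "<=", K - delta)
    }
    if (can_b) {
      lp_add_var(lp, vn("un", rid), lb = 0, ub = 1, integer = TRUE)
      lp_set_support(lp, vn("un", rid), vn("b", rid))
      lp_add_con(lp, setNames(c(1, -M), c(vn("b", rid), vn("un", rid))),
                 "<=", 0)
      # -dG <= -delta + K (1 - un)
      lp_add_con(lp, setNames(c(-1, K), c(vn("dG", rid), vn("un", rid))),
                 "<=", K - delta)
    }
    if (can_f && can_b)
      lp_add_con(lp, setNames(c(1, 1), c(vn("up", rid), vn("un", rid))),
                 "<=", 1)
  }

  net <- function(rid) setNames(c(1, -1), c(vn("f", rid), vn("b", rid)))
  list(lp = lp, net = net, covered = covered, prefix = prefix,
       lnc_ids = lnc_needed)
}

#' Thermodynamics-based flux analysis
#'
#' FBA augmented with Gibbs-energy variables and binary direction
#' indicators: a reaction may only carry forward (backward) flux when its
#' transformed reaction Gibbs energy, `dG_r = dGr_std + RT * sum(s * ln c)`,
#' is at most `-dG_margin` (at least `+dG_margin`). Reactions without Gibbs
#' data are constrained by their flux bounds only, so with an empty
#' annotation the TFA optimum equals the FBA optimum.
#'
#' @param model a [metabolic_model()].
#' @param thermo a [thermo_annotation()].
#' @param settings a [tfa_settings()].
#' @param objective_reaction reaction id to maximize.
#' @return a `flux_solution` with additional fields `dG` (named kJ/mol) and
#'   `ln_conc` (named, log mol/L) over the thermodynamically covered part.
#' @export
solve_tfa <- function(model, thermo, settings = tfa_settings(),
                      objective_reaction = model$biomass_reaction_id) {
  built <- build_tfa_milp(model, thermo, settings)
  lp <- built$lp
  lp_set_objective(lp, built$net(objective_reaction))
  r <- lp_solve(lp, maximize = TRUE, max_nodes = settings$max_nodes,
                time_limit = settings$time_limit)
  rids <- names(model$reactions)
  if (r$status %in% c("optimal", "time_limit")) {
    v <- r$x[paste0("f_", rids)] - r$x[paste0("b_", rids)]
    names(v) <- rids
    dG <- r$x[paste0("dG_", built$covered)]
    names(dG) <- built$covered
    lnc <- r$x[paste0("lnc_", built$lnc_ids)]
    names(lnc) <- built$lnc_ids
    out <- list(objective_value = r$objective, fluxes = v,
                status = r$status, dG = dG, ln_conc = lnc)
  } else {
    out <- list(objective_value = NA_real_,
                fluxes = setNames(rep(NA_real_, length(rids)), rids),
                status = r$status, dG = NULL, ln_conc = NULL)
  }
  class(out) <- "flux_solution"
  out
}
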