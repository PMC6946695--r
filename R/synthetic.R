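#' Specification for a synthetic test network
#'
#' Defines the size and planted signal content of a generated toy
#' genome-scale model with two planted condition-specific flux states
#' ("reference" = fast growth, "perturbed" = near growth arrest). Defaults
#' emulate the study conditions this package targets: a carbon-limited
#' culture transiting from exponential to stationary phase, with most
#' differential signals pointing down and a perturbed/reference growth
#' ratio of about 1 percent, plus Gibbs-energy coverage of roughly 76
#' percent of metabolites and 84 percent of reactions.
#'
#' @param n_metabolites approximate number of metabolites.
#' @param n_reactions approximate number of reactions.
#' @param n_exchanges minimum number of exchange reactions.
#' @param n_consistent_gene_signals gene signals consistent with the
#'   planted flux states.
#' @param n_inconsistent_gene_signals gene signals planted on
#'   zero-capacity (dead-end) reactions, hence unsatisfiable.
#' @param n_metabolite_signals secreted metabolites with planted abundance
#'   ratios.
#' @param noise_sd Gaussian noise (log2 scale) added to signal ratios.
#' @param growth_ratio planted perturbed/reference growth-rate ratio.
#' @param uptake_bound substrate uptake bound (mmol/gDW/h) in the model
#'   and the planted reference uptake.
#' @param met_dg_coverage,rxn_dg_coverage fraction of metabolites/reactions
#'   with published Gibbs energies.
#' @param gpr_coverage minimum fraction of metabolic reactions with a GPR.
#' @param branch_split_ref,branch_split_pert flux split fractions over each
#'   parallel isoenzyme branch pair in the two planted states; unequal
#'   defaults plant condition-dependent route switching.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_metabolites = 20, n_reactions = 30,
                           n_exchanges = 3,
                           n_consistent_gene_signals = 4,
                           n_inconsistent_gene_signals = 2,
                           n_metabolite_signals = 2,
                           noise_sd = 0, growth_ratio = 0.01,
                           uptake_bound = 10,
                           met_dg_coverage = 0.76, rxn_dg_coverage = 0.84,
                           gpr_coverage = 0.85,
                           branch_split_ref = c(0.8, 0.2),
                           branch_split_pert = c(0.2, 0.8), seed = 1) {
  spec <- as.list(environment())
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  ncleave <- max(spec$n_metabolite_signals, spec$n_exchanges - 1L, 1L)
  ndead <- max(spec$n_inconsistent_gene_signals, 1L)
  nchain <- spec$n_metabolites - 2L * ncleave - ndead - 1L
  if (nchain < 4L)
    stop("unsatisfiable spec: n_metabolites too small for the requested ",
         "signal counts (need a backbone of at least 4 steps)")
  npar <- spec$n_reactions - (nchain + 2L * ncleave + ndead + 2L)
  if (npar < 1L)
    stop("unsatisfiable spec: n_reactions too small relative to ",
         "n_metabolites and signal counts")
  if (ncleave > nchain - 2L)
    stop("unsatisfiable spec: too many metabolite signals for the ",
         "backbone length")
  hosts <- nchain + npar            # backbone steps + extra parallel branches
  if (spec$n_consistent_gene_signals > hosts)
    stop("unsatisfiable spec: more consistent gene signals than ",
         "flux-carrying reactions (", hosts, " available)")
  if (spec$growth_ratio <= 0 || spec$growth_ratio >= 1)
    stop("growth_ratio must lie in (0, 1)")
  invisible(spec)
}

fmt_formula <- function(v) {
  els <- c("C", "H", "O", "N")
  paste0(paste0(els[v > 0], ifelse(v[v > 0] > 1, v[v > 0], "")),
         collapse = "")
}

#' Generate a synthetic metabolic model with planted ground truth
#'
#' Builds a stoichiometrically and elementally consistent toy network: a
#' linear catabolic backbone from a single carbon substrate to a biomass
#' precursor, parallel isoenzyme branch pairs (alternative routes carrying
#' condition-dependent flux splits), cleavage steps secreting measurable
#' byproducts through transport and exchange reactions, and planted
#' dead-end reactions that can never carry flux. Two steady-state flux
#' vectors (reference and perturbed) are planted by construction, together
#' with a thermodynamic annotation consistent with their directions.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `model` ([metabolic_model()]), `thermo`
#'   ([thermo_annotation()]) and `truth` (planted states, blocked set,
#'   signal tables, expected consistency scores).
#' @export
generate_toy_model <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed)
  ncleave <- max(spec$n_metabolite_signals, spec$n_exchanges - 1L, 1L)
  ndead <- max(spec$n_inconsistent_gene_signals, 1L)
  nchain <- spec$n_metabolites - 2L * ncleave - ndead - 1L
  npar <- spec$n_reactions - (nchain + 2L * ncleave + ndead + 2L)

  ## backbone metabolites X0 (substrate) .. X<nchain> (biomass precursor)
  xid <- sprintf("X%02d_c", 0:nchain)
  cleave_steps <- sort(sample(2:(nchain - 1L), ncleave))
  par_steps <- sort(sample(setdiff(1:nchain, cleave_steps),
                           min(npar, nchain - ncleave)))
  npar <- length(par_steps)
  dead_src <- sample(1:(nchain - 1L), ndead, replace = ndead > nchain - 1L)

  ## elemental composition: walk backward from the precursor, adding the
  ## byproduct composition at each cleavage so every reaction balances
  wcomp <- lapply(seq_len(ncleave), function(k)
    c(C = sample(1:2, 1), H = sample(1:4, 1), O = sample(0:2, 1),
      N = sample(0:1, 1)))
  comp <- vector("list", nchain + 1L)
  comp[[nchain + 1L]] <- c(C = 3, H = 6, O = 3, N = 1)
  for (i in nchain:1) {
    comp[[i]] <- comp[[i + 1L]]
    k <- match(i, cleave_steps)
    if (!is.na(k)) comp[[i]] <- comp[[i]] + wcomp[[k]]
  }

  mets <- data.frame(id = xid, name = xid, compartment = "c",
                     formula = vapply(comp, fmt_formula, character(1)),
                     stringsAsFactors = FALSE)
  rxns <- list()
  add <- function(r) rxns[[r$id]] <<- r

  add(reaction("EX_X00", setNames(-1, "X00_c"),
               lower_bound = -spec$uptake_bound, upper_bound = 0,
               kind = "exchange"))
  for (i in seq_len(nchain)) {
    sub <- xid[i]; prod <- xid[i + 1L]
    k <- match(i, cleave_steps)
    if (!is.na(k)) {
      wc <- sprintf("W%02d_c", k)
      st <- setNames(c(-1, 1, 1), c(sub, prod, wc))
      mets <- rbind(mets, data.frame(id = wc, name = wc, compartment = "c",
                                     formula = fmt_formula(wcomp[[k]])))
      add(reaction(sprintf("R%02d", i), st, lower_bound = 0))
      we <- sprintf("W%02d_e", k)
      mets <- rbind(mets, data.frame(id = we, name = we, compartment = "e",
                                     formula = fmt_formula(wcomp[[k]])))
      add(reaction(sprintf("T_W%02d", k), setNames(c(-1, 1), c(wc, we)),
                   lower_bound = 0, kind = "transport"))
      add(reaction(sprintf("EX_W%02d", k), setNames(-1, we),
                   lower_bound = 0, kind = "exchange"))
    } else if (i %in% par_steps) {
      st <- setNames(c(-1, 1), c(sub, prod))
      add(reaction(sprintf("R%02da", i), st, lower_bound = 0))
      add(reaction(sprintf("R%02db", i), st, lower_bound = 0))
    } else {
      add(reaction(sprintf("R%02d", i), setNames(c(-1, 1), c(sub, prod)),
                   lower_bound = 0))
    }
  }
  for (k in seq_len(ndead)) {
    did <- sprintf("D%02d_c", k)
    src <- xid[dead_src[k] + 1L]
    mets <- rbind(mets, data.frame(id = did, name = did, compartment = "c",
                                   formula = mets$formula[mets$id == src]))
    add(reaction(sprintf("DEAD%02d", k), setNames(c(-1, 1), c(src, did)),
                 lower_bound = 0))
  }
  add(reaction("BIOMASS", setNames(-1, xid[nchain + 1L]), lower_bound = 0,
               kind = "biomass"))

  ## planted flux states -------------------------------------------------
  u_ref <- spec$uptake_bound
  u_pert <- spec$growth_ratio * u_ref
  split_ref <- spec$branch_split_ref
  split_pert <- spec$branch_split_pert
  v_ref <- v_pert <- setNames(rep(0, length(rxns)), names(rxns))
  v_ref["EX_X00"] <- -u_ref; v_pert["EX_X00"] <- -u_pert
  v_ref["BIOMASS"] <- u_ref; v_pert["BIOMASS"] <- u_pert
  for (i in seq_len(nchain)) {
    if (i %in% par_steps) {
      v_ref[sprintf("R%02da", i)] <- split_ref[1] * u_ref
      v_ref[sprintf("R%02db", i)] <- split_ref[2] * u_ref
      v_pert[sprintf("R%02da", i)] <- split_pert[1] * u_pert
      v_pert[sprintf("R%02db", i)] <- split_pert[2] * u_pert
    } else {
      v_ref[sprintf("R%02d", i)] <- u_ref
      v_pert[sprintf("R%02d", i)] <- u_pert
    }
  }
  for (k in seq_len(ncleave)) {
    v_ref[sprintf("T_W%02d", k)] <- u_ref
    v_pert[sprintf("T_W%02d", k)] <- u_pert
    v_ref[sprintf("EX_W%02d", k)] <- u_ref
    v_pert[sprintf("EX_W%02d", k)] <- u_pert
  }

  ## gene signals ---------------------------------------------------------
  backbone_plain <- setdiff(seq_len(nchain), c(cleave_steps))
  backbone_plain <- setdiff(backbone_plain, par_steps)
  hosts <- c(sprintf("R%02d", sort(c(backbone_plain, cleave_steps))),
             sprintf("R%02da", par_steps), sprintf("R%02db", par_steps))
  # at least one backbone (non-branch) host anchors the growth-rate cap
  anchor <- sprintf("R%02d", min(c(backbone_plain, cleave_steps)))
  nsig <- spec$n_consistent_gene_signals
  sig_hosts <- if (nsig > 0L)
    unique(c(anchor, sample(setdiff(hosts, anchor), nsig - 1L)))
  else character()
  consistent <- data.frame(
    reaction_id = sig_hosts,
    gene = if (length(sig_hosts)) paste0("g_", sig_hosts) else character(),
    ratio = abs(v_pert[sig_hosts]) / abs(v_ref[sig_hosts]),
    direction = rep("down", length(sig_hosts)),
    stringsAsFactors = FALSE, row.names = NULL)
  dead_ids <- sprintf("DEAD%02d", seq_len(ndead))
  inc_ids <- dead_ids[seq_len(spec$n_inconsistent_gene_signals)]
  inconsistent <- data.frame(
    reaction_id = inc_ids,
    gene = if (length(inc_ids)) paste0("g_", inc_ids) else character(),
    ratio = rep(4, length(inc_ids)),
    direction = rep("up", length(inc_ids)), stringsAsFactors = FALSE)

  ## attach GPRs: signal reactions get their own gene, others filled to
  ## the requested coverage with background genes
  for (i in seq_len(nrow(consistent)))
    rxns[[consistent$reaction_id[i]]] <-
      set_gpr(rxns[[consistent$reaction_id[i]]], consistent$gene[i])
  for (i in seq_len(nrow(inconsistent)))
    rxns[[inconsistent$reaction_id[i]]] <-
      set_gpr(rxns[[inconsistent$reaction_id[i]]], inconsistent$gene[i])
  internal <- names(rxns)[vapply(rxns, function(r)
    !r$kind %in% c("exchange", "biomass"), logical(1))]
  bare <- internal[vapply(rxns[internal], function(r) r$gpr == "",
                          logical(1))]
  need <- ceiling(spec$gpr_coverage * length(internal)) -
    (length(internal) - length(bare))
  gi <- 0L
  for (rid in utils::head(bare, max(0, need))) {
    gi <- gi + 1L
    rule <- if (gi %% 3 == 0)
      sprintf("bg%03d and bg%03d", gi, gi + 500L)
    else if (gi %% 3 == 1) sprintf("bg%03d or bg%03d", gi, gi + 500L)
    else sprintf("bg%03d", gi)
    rxns[[rid]] <- set_gpr(rxns[[rid]], rule)
  }

  ## metabolite signals: secreted byproducts, planted production ratio
  msig <- utils::head(seq_len(ncleave), spec$n_metabolite_signals)
  met_signals <- data.frame(
    metabolite_id = sprintf("W%02d_e", msig),
    ratio = rep(spec$growth_ratio, length(msig)),
    stringsAsFactors = FALSE)

  ## thermodynamic annotation consistent with planted directions ---------
  phi <- setNames(rep(NA_real_, nrow(mets)), mets$id)
  phi[sprintf("W%02d_c", seq_len(ncleave))] <- runif(ncleave, 5, 20)
  phi[xid[nchain + 1L]] <- 0
  for (i in nchain:1) {
    drop <- runif(1, 5, 15)
    k <- match(i, cleave_steps)
    extra <- if (!is.na(k)) phi[sprintf("W%02d_c", k)] else 0
    phi[xid[i]] <- phi[xid[i + 1L]] + extra + drop
  }
  for (k in seq_len(ncleave))
    phi[sprintf("W%02d_e", k)] <- phi[sprintf("W%02d_c", k)] - 1
  for (k in seq_len(ndead))
    phi[sprintf("D%02d_c", k)] <- phi[xid[dead_src[k] + 1L]] - 5
  met_cov <- sample(mets$id, round(spec$met_dg_coverage * nrow(mets)))
  thermo_rxns <- names(rxns)[vapply(rxns, function(r)
    !r$kind %in% c("exchange", "biomass", "demand"), logical(1))]
  rxn_cov <- sample(thermo_rxns,
                    round(spec$rxn_dg_coverage * length(thermo_rxns)))
  dGr <- vapply(rxn_cov, function(rid) {
    st <- rxns[[rid]]$stoichiometry
    sum(unname(st) * phi[names(st)])
  }, numeric(1))
  thermo <- thermo_annotation(dGf_std = phi[met_cov], dGr_std = dGr)

  model <- metabolic_model(mets, rxns,
                           c(c = "cytosol", e = "extracellular"),
                           "BIOMASS",
                           id = sprintf("synthetic_seed%d", spec$seed))
  truth <- list(
    v_ref = v_ref, v_pert = v_pert,
    mu_ref = u_ref, mu_pert = u_pert,
    growth_ratio = spec$growth_ratio,
    blocked = dead_ids,
    consistent_gene_signals = consistent,
    inconsistent_gene_signals = inconsistent,
    metabolite_signals = met_signals,
    expected_mcs = list(tgex = nrow(consistent),
                        tm = nrow(met_signals),
                        tgexm = nrow(consistent) + nrow(met_signals)))
  list(model = model, thermo = thermo, truth = truth)
}

set_gpr <- function(rxn, rule) {
  rxn$gpr <- rule
  rxn$gpr_tree <- parse_gpr(rule)
  rxn$genes <- gpr_genes(rxn$gpr_tree)
  rxn
}

#' Derive two-condition omics tables from planted flux states
#'
#' Consistent gene signals receive log2 fold-changes matching the planted
#' per-reaction activity ratios (plus optional Gaussian noise on the log2
#' scale); inconsistent signals claim activation of zero-capacity
#' reactions; background genes get null fold-changes with high FDR. FDR
#' assignment is deterministic so differential-expression selection is a
#' pure threshold gate.
#'
#' @param model,truth output of [generate_toy_model()].
#' @param spec the [synthetic_spec()] used to generate them.
#' @return an [omics_data()].
#' @export
generate_condition_omics <- function(model, truth, spec) {
  set.seed(spec$seed * 7L + 1L)
  cons <- truth$consistent_gene_signals
  inc <- truth$inconsistent_gene_signals
  g_cons <- data.frame(gene_id = cons$gene,
                       log2fc = log2(cons$ratio) +
                         rnorm(nrow(cons), 0, spec$noise_sd),
                       fdr = rep(0.01, nrow(cons)))
  g_inc <- data.frame(gene_id = inc$gene,
                      log2fc = log2(inc$ratio) +
                        rnorm(nrow(inc), 0, spec$noise_sd),
                      fdr = rep(0.01, nrow(inc)))
  bg <- setdiff(model$genes, c(cons$gene, inc$gene))
  g_bg <- data.frame(gene_id = bg, log2fc = rnorm(length(bg), 0, 0.1),
                     fdr = 0.8)
  ms <- truth$metabolite_signals
  mtab <- data.frame(metabolite_id = ms$metabolite_id,
                     ratio = pmax(1e-6, ms$ratio *
                                    2^rnorm(nrow(ms), 0, spec$noise_sd)),
                     significant = rep(TRUE, nrow(ms)))
  omics_data(rbind(g_cons, g_inc, g_bg), mtab)
}

#' Generate a planted gap-filling instance
#'
#' A working base model (substrate to biomass chain) with a broken branch:
#' the path from a chain metabolite to a target reaction is interrupted by
#' `path_length` missing steps. The universal database contains the
#' missing steps plus structurally useless decoys (reactions into fresh
#' dead-end metabolites or between unreachable ones), so the planted
#' minimal gap-fill has exactly `path_length` reactions.
#'
#' @param seed RNG seed.
#' @param path_length number of missing reactions (1-4).
#' @param n_decoys decoy reactions in the database.
#' @return list with `model`, `universal_db`, `target` (blocked reaction
#'   id) and `truth` (planted minimal set).
#' @export
generate_gapfill_instance <- function(seed = 1, path_length = 2,
                                      n_decoys = 5) {
  stopifnot(path_length >= 1, path_length <= 4)
  set.seed(seed)
  mets <- data.frame(id = c("S_c", "A_c", "B_c", "Q_c", "Z_c"),
                     name = c("S_c", "A_c", "B_c", "Q_c", "Z_c"),
                     compartment = "c", formula = "C2H4O2",
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction("EX_S", c(S_c = -1), lower_bound = -10, upper_bound = 0,
             kind = "exchange"),
    reaction("R_SA", c(S_c = -1, A_c = 1), lower_bound = 0),
    reaction("R_AB", c(A_c = -1, B_c = 1), lower_bound = 0),
    reaction("BIOMASS", c(B_c = -1), lower_bound = 0, kind = "biomass"),
    # broken branch: Q is unreachable, so R_QZ and EX_Z are blocked
    reaction("R_QZ", c(Q_c = -1, Z_c = 1), lower_bound = 0),
    reaction("EX_Z", c(Z_c = -1), lower_bound = 0, kind = "exchange"))
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  model <- metabolic_model(mets, rxns, c(c = "cytosol"), "BIOMASS",
                           id = sprintf("gapfill_seed%d", seed))

  ## universal database: planted path A -> I1 -> ... -> Q plus decoys
  db_mets <- data.frame(id = character(), name = character(),
                        compartment = character(), formula = character())
  db_rxns <- list()
  addm <- function(id) db_mets <<- rbind(db_mets,
    data.frame(id = id, name = id, compartment = "c", formula = "C2H4O2"))
  addm("A_c"); addm("Q_c")
  chain_ids <- if (path_length > 1)
    sprintf("I%02d_c", seq_len(path_length - 1L)) else character()
  for (m in chain_ids) addm(m)
  nodes <- c("A_c", chain_ids, "Q_c")
  planted <- character()
  for (k in seq_len(path_length)) {
    rid <- sprintf("GF%02d", k)
    planted <- c(planted, rid)
    db_rxns[[rid]] <- reaction(rid,
      setNames(c(-1, 1), c(nodes[k], nodes[k + 1L])), lower_bound = 0,
      gpr = sprintf("gfill%02d", k))
  }
  ## decoys: never produce Q_c or intermediates from reachable metabolites
  for (d in seq_len(n_decoys)) {
    rid <- sprintf("DK%02d", d)
    kind <- d %% 3
    if (kind == 0) {          # reachable -> fresh dead end
      zm <- sprintf("ZD%02d_c", d); addm(zm)
      db_rxns[[rid]] <- reaction(rid, setNames(c(-1, 1), c("A_c", zm)),
                                 lower_bound = 0)
    } else if (kind == 1) {   # between fresh unreachable metabolites
      z1 <- sprintf("ZU%02da_c", d); z2 <- sprintf("ZU%02db_c", d)
      addm(z1); addm(z2)
      db_rxns[[rid]] <- reaction(rid, setNames(c(-1, 1), c(z1, z2)),
                                 lower_bound = 0)
    } else {                  # fresh unreachable -> reachable
      z1 <- sprintf("ZW%02d_c", d); addm(z1)
      db_rxns[[rid]] <- reaction(rid, setNames(c(-1, 1), c(z1, "A_c")),
                                 lower_bound = 0)
    }
  }
  db <- metabolic_model(db_mets, db_rxns, c(c = "cytosol"), NULL,
                        id = "universal_db")
  list(model = model, universal_db = db, target = "R_QZ",
       truth = list(minimal_set = planted, minimal_size = path_length))
}

#' Curated two-pathway gap-filling fixtures
#'
#' Topological replicas (unit stoichiometry, synthetic formulas) of two
#' blocked catabolic routes: a second toluene degradation route missing
#' its CoA-transferase step (EC 2.8.3.6), and a phenylalanine degradation
#' route via phenethylamine, phenylacetaldehyde, 2-hydroxyphenylacetate
#' and homogentisate missing three enzymes (EC 4.1.1.28, EC 1.14.14.54,
#' EC 1.14.13.-). Each model grows through a lumped main route while the
#' replica route is blocked; the universal database contains the missing
#' steps plus decoys that cannot complete either route.
#'
#' @return list with `toluene` and `phenylalanine` fixtures (each a list
#'   of `model`, `route` = blocked route reaction ids, `target`,
#'   `de_genes` / `measured_metabolites` omics evidence, `omics`) and the
#'   shared `universal_db`.
#' @export
fixture_blocked_pathways <- function() {
  cpd <- function(id, comp = "c", formula = "C7H8O2")
    data.frame(id = id, name = id, compartment = comp, formula = formula,
               stringsAsFactors = FALSE)

  ## --- toluene fixture: second route blocked by missing EC 2.8.3.6 -----
  tol_mets <- rbind(
    cpd("tol_c", formula = "C7H8"), cpd("mcat_c"), cpd("tolm1_c"),
    cpd("tolm2_c"), cpd("tolm3_c"), cpd("tolm4_c"),
    cpd("accoa_c", formula = "C23H38N7O17"), cpd("pyr_c", formula = "C3H4O3"))
  tol_rxns <- list(
    reaction("EX_tol", c(tol_c = -1), lower_bound = -10, upper_bound = 0,
             kind = "exchange"),
    # lumped functional main route (4-step meta-cleavage branch)
    reaction("MAIN_tol", c(tol_c = -1, pyr_c = 1), lower_bound = 0,
             gpr = "tolMain", ec_numbers = c("1.13.11.2", "4.1.3.39")),
    reaction("PYR_ACCOA", c(pyr_c = -1, accoa_c = 1), lower_bound = 0,
             gpr = "aceEF"),
    # second route: tol -> 3-methylcatechol -> ... -> acetyl-CoA
    reaction("TOL2_1", c(tol_c = -1, mcat_c = 1), lower_bound = 0,
             gpr = "tolR1"),
    reaction("TOL2_2", c(mcat_c = -1, tolm1_c = 1), lower_bound = 0,
             gpr = "tolR2"),
    reaction("TOL2_3", c(tolm1_c = -1, tolm2_c = 1), lower_bound = 0,
             gpr = "tolR3"),
    # MISSING here: EC 2.8.3.6 converting tolm2 -> tolm3
    reaction("TOL2_5", c(tolm3_c = -1, tolm4_c = 1), lower_bound = 0,
             gpr = "tolR5"),
    reaction("TOL2_6", c(tolm4_c = -1, accoa_c = 1), lower_bound = 0,
             gpr = "tolR6"),
    reaction("BIOMASS", c(accoa_c = -1), lower_bound = 0, kind = "biomass"))
  names(tol_rxns) <- vapply(tol_rxns, `[[`, character(1), "id")
  tol_model <- metabolic_model(tol_mets, tol_rxns, c(c = "cytosol"),
                               "BIOMASS", id = "replica_toluene")
  tol_route <- c("TOL2_1", "TOL2_2", "TOL2_3", "TOL2_5", "TOL2_6")
  tol_omics <- omics_data(
    genes = data.frame(
      gene_id = c("tolR1", "tolR2", "tolR5", "tolR3", "tolR6", "tolMain",
                  "aceEF"),
      log2fc = c(-2.5, -2.2, -2.1, -0.2, 0.1, -0.4, 0.2),
      fdr = c(0.01, 0.01, 0.02, 0.6, 0.7, 0.3, 0.8)),
    metabolites = NULL)

  ## --- phenylalanine fixture: three missing steps ----------------------
  phe_mets <- rbind(
    cpd("phe_c", formula = "C9H11NO2"), cpd("peamn_c", formula = "C8H11N"),
    cpd("pacald_c", formula = "C8H8O"), cpd("hpac_c", formula = "C8H8O3"),
    cpd("hgentis_c", formula = "C8H8O4"), cpd("fum_c", formula = "C4H4O4"),
    cpd("acac_c", formula = "C4H6O3"),
    cpd("phe_e", "e", formula = "C9H11NO2"),
    cpd("peamn_e", "e", formula = "C8H11N"),
    cpd("hpac_e", "e", formula = "C8H8O3"),
    cpd("pacald_e", "e", formula = "C8H8O"))
  phe_rxns <- list(
    reaction("EX_phe", c(phe_e = -1), lower_bound = -10, upper_bound = 0,
             kind = "exchange"),
    reaction("T_phe", c(phe_e = -1, phe_c = 1), lower_bound = 0,
             kind = "transport"),
    # lumped functional main catabolism keeping the model growing
    reaction("MAIN_phe", c(phe_c = -1, fum_c = 1), lower_bound = 0,
             gpr = "pheMain"),
    # route: phe -[4.1.1.28 MISSING]-> peamn -> pacald
    #        -[1.14.14.54 MISSING]-> hpac -[1.14.13.- MISSING]-> hgentis
    reaction("PHE_2", c(peamn_c = -1, pacald_c = 1), lower_bound = 0,
             gpr = "pheR2"),
    reaction("PHE_5", c(hgentis_c = -1, fum_c = 1, acac_c = 1),
             lower_bound = 0, gpr = "pheR5"),
    reaction("ACAC_USE", c(acac_c = -1, fum_c = 1), lower_bound = 0,
             gpr = "pheR6"),
    reaction("T_peamn", c(peamn_c = -1, peamn_e = 1), lower_bound = 0,
             kind = "transport"),
    reaction("EX_peamn", c(peamn_e = -1), lower_bound = 0,
             kind = "exchange"),
    reaction("T_hpac", c(hpac_c = -1, hpac_e = 1), lower_bound = 0,
             kind = "transport"),
    reaction("EX_hpac", c(hpac_e = -1), lower_bound = 0, kind = "exchange"),
    reaction("T_pacald", c(pacald_c = -1, pacald_e = 1), lower_bound = 0,
             kind = "transport"),
    reaction("EX_pacald", c(pacald_e = -1), lower_bound = 0,
             kind = "exchange"),
    reaction("BIOMASS", c(fum_c = -1), lower_bound = 0, kind = "biomass"))
  names(phe_rxns) <- vapply(phe_rxns, `[[`, character(1), "id")
  phe_model <- metabolic_model(phe_mets, phe_rxns,
                               c(c = "cytosol", e = "extracellular"),
                               "BIOMASS", id = "replica_phenylalanine")
  phe_route <- c("PHE_2", "PHE_5", "T_peamn", "EX_peamn", "T_hpac",
                 "EX_hpac", "T_pacald", "EX_pacald", "ACAC_USE")
  phe_omics <- omics_data(
    genes = NULL,
    metabolites = data.frame(
      metabolite_id = c("phe_e", "peamn_e", "hpac_e", "pacald_e"),
      ratio = c(0.2, 3.1, 2.4, 1.8),
      significant = TRUE))

  ## --- shared universal database ---------------------------------------
  db_mets <- rbind(
    cpd("tolm2_c"), cpd("tolm3_c"), cpd("phe_c", formula = "C9H11NO2"),
    cpd("peamn_c", formula = "C8H11N"), cpd("pacald_c", formula = "C8H8O"),
    cpd("hpac_c", formula = "C8H8O3"), cpd("hgentis_c", formula = "C8H8O4"),
    cpd("dek1_c"), cpd("dek2_c"), cpd("dek3_c"), cpd("dek4_c"))
  db_rxns <- list(
    reaction("U_2.8.3.6", c(tolm2_c = -1, tolm3_c = 1), lower_bound = 0,
             gpr = "scoA", ec_numbers = "2.8.3.6"),
    reaction("U_4.1.1.28", c(phe_c = -1, peamn_c = 1), lower_bound = 0,
             ec_numbers = "4.1.1.28"),
    reaction("U_1.14.14.54", c(pacald_c = -1, hpac_c = 1), lower_bound = 0,
             gpr = "CYP504", ec_numbers = "1.14.14.54"),
    reaction("U_1.14.13.x", c(hpac_c = -1, hgentis_c = 1), lower_bound = 0,
             ec_numbers = "1.14.13.-"),
    # decoys: consume route metabolites into dead ends or link fresh ones
    reaction("U_DK1", c(tolm2_c = -1, dek1_c = 1), lower_bound = 0),
    reaction("U_DK2", c(dek2_c = -1, dek3_c = 1), lower_bound = 0),
    reaction("U_DK3", c(phe_c = -1, dek4_c = 1), lower_bound = 0),
    reaction("U_DK4", c(dek1_c = -1, dek2_c = 1), lower_bound = 0))
  names(db_rxns) <- vapply(db_rxns, `[[`, character(1), "id")
  db <- metabolic_model(db_mets, db_rxns, c(c = "cytosol"), NULL,
                        id = "universal_db")

  list(toluene = list(model = tol_model, route = tol_route,
                      target = "TOL2_5",
                      de_genes = c("tolR1", "tolR2", "tolR5"),
                      omics = tol_omics),
       phenylalanine = list(model = phe_model, route = phe_route,
                            target = "PHE_5",
                            measured_metabolites = c("phe_e", "peamn_e",
                                                     "hpac_e", "pacald_e"),
                            omics = phe_omics),
       universal_db = db)
}
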