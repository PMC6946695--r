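#' List biomass building blocks
#'
#' Extracts all substrates of the biomass reaction and assigns each to a
#' biochemical group from a configurable mapping table; unmapped
#' precursors are assigned `"unclassified"` with a warning. Canonical
#' groups are carbohydrates, cofactors and vitamins, DNA nucleotides,
#' lipids, minerals, amino acids, and RNA nucleotides.
#'
#' @param model a [metabolic_model()].
#' @param group_map optional data.frame (`metabolite_id`, `group`).
#' @return data.frame: `metabolite_id`, `coefficient` (positive demand
#'   per unit biomass), `group`.
#' @export
list_bbbs <- function(model, group_map = NULL) {
  if (is.null(model$biomass_reaction_id))
    stop("model has no biomass reaction")
  st <- model$reactions[[model$biomass_reaction_id]]$stoichiometry
  subs <- st[st < 0]
  out <- data.frame(metabolite_id = names(subs),
                    coefficient = -unname(subs),
                    group = "unclassified", stringsAsFactors = FALSE)
  if (!is.null(group_map)) {
    k <- match(out$metabolite_id, group_map$metabolite_id)
    out$group[!is.na(k)] <- group_map$group[k[!is.na(k)]]
  }
  if (any(out$group == "unclassified"))
    warning(sum(out$group == "unclassified"),
            " biomass precursor(s) without group mapping assigned ",
            "'unclassified'")
  out[order(out$metabolite_id), ]
}

#' Maximal production of a single precursor
#'
#' Adds a transient irreversible demand sink for the precursor, maximizes
#' its flux under FBA or TFA, and removes the sink (the model is not
#' modified). Infeasibility or a zero ceiling is reported through the
#' `blocked` flag rather than an error.
#'
#' @param model a [metabolic_model()].
#' @param precursor metabolite id.
#' @param thermo optional [thermo_annotation()] for TFA constraints.
#' @param settings [tfa_settings()].
#' @param tol production below this counts as blocked.
#' @return list: `flux` (mmol/gDW/h), `status` (`"ok"` or `"blocked"`).
#' @export
max_bbb_production <- function(model, precursor, thermo = NULL,
                               settings = tfa_settings(), tol = 1e-9) {
  if (!precursor %in% model$metabolites$id)
    stop("unknown metabolite: ", precursor)
  did <- paste0("DM_", precursor)
  m2 <- model
  m2$reactions[[did]] <- reaction(did, setNames(-1, precursor),
                                  lower_bound = 0, upper_bound = 1000,
                                  kind = "demand")
  sol <- if (is.null(thermo)) solve_fba(m2, did)
         else solve_tfa(m2, thermo, settings, did)
  if (sol$status != "optimal" || is.na(sol$objective_value) ||
      sol$objective_value < tol)
    return(list(flux = 0, status = "blocked"))
  list(flux = sol$objective_value, status = "ok")
}

#' Fold-changes of precursor production between two conditions
#'
#' Summarizes per-alternative production matrices (see
#' [remi_bbb_production()]): the reported fold-change
#' (reference/perturbed) comes from the representative alternative;
#' p-values are two-sided Wilcoxon signed-rank tests over the paired
#' per-alternative productions (marked unavailable with fewer than two
#' alternatives). Swapping the two conditions inverts every fold-change.
#'
#' @param prod_list list of matrices (precursors x `ref`,`pert`), one per
#'   alternative.
#' @param representative index of the representative alternative.
#' @param group_map optional data.frame (`metabolite_id`, `group`).
#' @param tol denominator tolerance; below it the fold-change is flagged
#'   `denominator_zero`.
#' @return `bbb_report`: data.frame with per-precursor productions,
#'   `fold_change`, `p_value`, `flag`, `group`; attributes
#'   `counts` (higher in reference / higher in perturbed / unchanged) and
#'   `group_summary`.
#' @export
bbb_fold_changes <- function(prod_list, representative = 1,
                             group_map = NULL, tol = 1e-9) {
  stopifnot(length(prod_list) >= 1)
  rep_mat <- prod_list[[representative]]
  prec <- rownames(rep_mat)
  fc <- rep(NA_real_, length(prec))
  flag <- rep("ok", length(prec))
  pv <- rep(NA_real_, length(prec))
  for (i in seq_along(prec)) {
    a <- rep_mat[i, "ref"]; b <- rep_mat[i, "pert"]
    if (b <= tol && a <= tol) { flag[i] <- "blocked"; fc[i] <- 1 }
    else if (b <= tol) flag[i] <- "denominator_zero"
    else fc[i] <- a / b
    if (length(prod_list) >= 2) {
      av <- vapply(prod_list, function(m) m[i, "ref"], numeric(1))
      bv <- vapply(prod_list, function(m) m[i, "pert"], numeric(1))
      if (any(av != bv))
        pv[i] <- suppressWarnings(
          wilcox.test(av, bv, paired = TRUE, exact = FALSE)$p.value)
      else pv[i] <- 1
    }
  }
  out <- data.frame(metabolite_id = prec,
                    production_ref = rep_mat[, "ref"],
                    production_pert = rep_mat[, "pert"],
                    fold_change = fc, p_value = pv, flag = flag,
                    group = "unclassified",
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(group_map)) {
    k <- match(out$metabolite_id, group_map$metabolite_id)
    out$group[!is.na(k)] <- group_map$group[k[!is.na(k)]]
  }
  eq_tol <- 1e-6
  d <- out$production_ref - out$production_pert
  counts <- c(higher_in_reference = sum(d > eq_tol),
              higher_in_perturbed = sum(d < -eq_tol),
              unchanged = sum(abs(d) <= eq_tol))
  gs <- stats::aggregate(
    cbind(production_ref, production_pert) ~ group, data = out, FUN = sum)
  attr(out, "counts") <- counts
  attr(out, "group_summary") <- gs
  class(out) <- c("bbb_report", "data.frame")
  out
}

#' Tally deregulated pathways
#'
#' Counts deregulated reactions and metabolites per annotated pathway;
#' items belonging to several pathways contribute to each, items without
#' annotation are pooled under `"unannotated"`.
#'
#' @param items character vector of deregulated reaction/metabolite ids
#'   (candidate ids with `g:`/`m:` prefixes are accepted and stripped).
#' @param annotation data.frame (`id`, `pathway_id`, `pathway_name`).
#' @return data.frame (`pathway_id`, `pathway_name`, `count`) sorted by
#'   decreasing count, ties by pathway id.
#' @export
tally_deregulated_pathways <- function(items, annotation) {
  ids <- sub("^[gm]:", "", items)
  rows <- list()
  for (id in ids) {
    hit <- annotation[annotation$id == id, , drop = FALSE]
    if (nrow(hit) == 0)
      rows[[length(rows) + 1L]] <-
        data.frame(pathway_id = "unannotated",
                   pathway_name = "unannotated")
    else
      rows[[length(rows) + 1L]] <- hit[, c("pathway_id", "pathway_name")]
  }
  if (!length(rows))
    return(data.frame(pathway_id = character(),
                      pathway_name = character(), count = integer()))
  all <- do.call(rbind, rows)
  tab <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = all[c("pathway_id", "pathway_name")],
                          FUN = sum)
  tab[order(-tab$count, tab$pathway_id), , drop = FALSE]
}
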