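#' Construct a genome-scale metabolic model
#'
#' The central container of the package: a stoichiometric network with
#' compartments, gene-reaction (GPR) rules and a designated biomass reaction.
#' Reactions are stored as a named list; each reaction carries a named
#' `stoichiometry` vector (negative = substrate, positive = product), flux
#' bounds in mmol/gDW/h, a GPR string and its parsed AND/OR tree, and a
#' `kind` in `metabolic`, `transport`, `exchange`, `biomass`, `demand`.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   and optionally `formula`, `charge`, `kegg_id`.
#' @param reactions list of reaction records (see [reaction()]).
#' @param compartments named character vector, compartment id -> name.
#' @param biomass_reaction_id id of the biomass reaction.
#' @param id model identifier.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, compartments,
                            biomass_reaction_id, id = "model") {
  if (is.null(names(reactions)))
    names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  mets <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  for (col in c("formula", "kegg_id"))
    if (is.null(mets[[col]])) mets[[col]] <- NA_character_
  if (is.null(mets$charge)) mets$charge <- NA_integer_
  if (is.null(mets$name)) mets$name <- mets$id
  reactions <- resolve_kinds(reactions, mets, biomass_reaction_id)
  genes <- sort(unique(unlist(lapply(reactions, `[[`, "genes"))))
  m <- structure(list(id = id,
                      metabolites = mets,
                      reactions = reactions,
                      compartments = compartments,
                      biomass_reaction_id = biomass_reaction_id,
                      genes = genes),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Construct a reaction record
#'
#' @param id unique reaction id.
#' @param stoichiometry named numeric vector over metabolite ids; negative
#'   coefficients are substrates.
#' @param lower_bound,upper_bound flux bounds (mmol/gDW/h); default +/-1000
#'   by community convention.
#' @param gpr gene association string over gene ids with `and`/`or` and
#'   parentheses (case-insensitive; `and` binds tighter than `or`).
#' @param ec_numbers,subsystems optional character annotations.
#' @param kind reaction class; `"auto"` infers it (single-metabolite =
#'   exchange, multi-compartment = transport, otherwise metabolic).
#' @param name display name.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000,
                     upper_bound = 1000, gpr = "", ec_numbers = character(),
                     subsystems = character(), kind = "auto", name = id) {
  if (length(stoichiometry) == 0L)
    stop("reaction '", id, "': stoichiometry must be non-empty")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  tree <- parse_gpr(gpr)
  list(id = id, name = name,
       stoichiometry = stoichiometry,
       lower_bound = lower_bound, upper_bound = upper_bound,
       gpr = gpr, gpr_tree = tree, genes = gpr_genes(tree),
       ec_numbers = ec_numbers, subsystems = subsystems,
       kind = kind)
}

infer_reaction_kind <- function(rxn, met_compartments, biomass_id) {
  if (identical(rxn$id, biomass_id)) return("biomass")
  nmet <- length(rxn$stoichiometry)
  if (nmet == 1L) {
    if (grepl("^DM_", rxn$id)) return("demand")
    return("exchange")
  }
  comps <- unique(met_compartments[names(rxn$stoichiometry)])
  if (length(comps) > 1L) return("transport")
  "metabolic"
}

#' Validate a metabolic model
#'
#' Checks all structural invariants: unique ids, resolvable metabolite and
#' compartment references, presence of the biomass reaction, non-empty
#' stoichiometries, ordered bounds, and single-metabolite exchanges. Errors
#' list the offending ids.
#'
#' @param model a [metabolic_model()].
#' @return the model, invisibly, on success.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  bad_comp <- setdiff(unique(mets$compartment), names(model$compartments))
  if (length(bad_comp))
    stop("metabolite compartments not declared in model: ",
         paste(bad_comp, collapse = ", "))
  met_comp <- setNames(mets$compartment, mets$id)
  for (rxn in model$reactions) {
    unknown <- setdiff(names(rxn$stoichiometry), mets$id)
    if (length(unknown))
      stop("reaction '", rxn$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (length(rxn$stoichiometry) == 0L)
      stop("reaction '", rxn$id, "' has empty stoichiometry")
    if (rxn$lower_bound > rxn$upper_bound)
      stop("reaction '", rxn$id, "': lower_bound > upper_bound")
    if (identical(rxn$kind, "exchange") && length(rxn$stoichiometry) != 1L)
      stop("exchange reaction '", rxn$id,
           "' must touch exactly one metabolite")
  }
  if (!is.null(model$biomass_reaction_id) &&
      !model$biomass_reaction_id %in% rids)
    stop("biomass reaction '", model$biomass_reaction_id,
         "' not present in model")
  used <- unique(unlist(lapply(model$reactions,
                               function(r) names(r$stoichiometry))))
  orphan <- setdiff(mets$id, used)
  if (length(orphan))
    stop("metabolite(s) not referenced by any reaction: ",
         paste(orphan, collapse = ", "))
  invisible(model)
}

# Resolve "auto" kinds in a reaction list (used by constructors/readers).
resolve_kinds <- function(reactions, metabolites, biomass_id) {
  met_comp <- setNames(metabolites$compartment, metabolites$id)
  lapply(reactions, function(r) {
    if (identical(r$kind, "auto"))
      r$kind <- infer_reaction_kind(r, met_comp, biomass_id)
    r
  })
}

#' Stoichiometric matrix
#'
#' @param model a [metabolic_model()].
#' @return sparse `Matrix` (metabolites x reactions).
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, match(names(st), mids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

#' Model component counts
#'
#' Tabulates genes, reactions by kind, and metabolites by compartment by
#' direct enumeration.
#'
#' @param model a [metabolic_model()].
#' @return list with `genes`, `reactions` (total), `reactions_by_kind`,
#'   `metabolites` (total), `metabolites_by_compartment`.
#' @export
model_summary <- function(model) {
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  by_kind <- vapply(c("metabolic", "transport", "exchange", "biomass",
                      "demand"),
                    function(k) sum(kinds == k), integer(1))
  comp <- table(factor(model$metabolites$compartment,
                       levels = names(model$compartments)))
  list(genes = length(model$genes),
       reactions = length(model$reactions),
       reactions_by_kind = by_kind,
       metabolites = nrow(model$metabolites),
       metabolites_by_compartment = setNames(as.integer(comp), names(comp)))
}

#' @exportS3Method base::print
print.metabolic_model <- function(x, ...) {
  s <- model_summary(x)
  cat("<metabolic_model> ", x$id, ": ", s$metabolites, " metabolites, ",
      s$reactions, " reactions, ", s$genes, " genes\n", sep = "")
  cat("  reactions by kind: ",
      paste(names(s$reactions_by_kind), s$reactions_by_kind, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

## ---- elemental formulas and mass balance -----------------------------------

#' Parse a Hill-notation elemental formula
#'
#' @param formula e.g. `"C6H12O6"`. Pseudo-elements (`R`, `X`) are reported
#'   so callers can mark reactions unverifiable rather than imbalanced.
#' @return named integer vector of element counts, or `NULL` for `NA`/empty
#'   input.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!nzchar(paste(parts, collapse = "")) ||
      nchar(paste(parts, collapse = "")) != nchar(formula))
    stop("malformed formula: '", formula, "'")
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(cnt, els, sum)[unique(els)]
  setNames(as.integer(out), names(out))
}

#' Check elemental balance of model reactions
#'
#' For every reaction that is not an exchange, biomass or demand reaction,
#' sums element counts weighted by stoichiometric coefficients. A reaction
#' with a participating metabolite lacking a formula (or carrying a
#' pseudo-element such as R or X) is flagged `unverifiable` instead of
#' imbalanced.
#'
#' @param model a [metabolic_model()].
#' @return data.frame with columns `reaction_id`, `element`, `imbalance`,
#'   `status` (`"imbalanced"` or `"unverifiable"`); zero rows means all
#'   checkable reactions balance.
#' @export
check_balance <- function(model) {
  skip <- c("exchange", "biomass", "demand")
  forms <- setNames(model$metabolites$formula, model$metabolites$id)
  out <- list()
  for (rxn in model$reactions) {
    if (rxn$kind %in% skip) next
    st <- rxn$stoichiometry
    fl <- lapply(names(st), function(mid) parse_formula(forms[[mid]]))
    has_pseudo <- any(vapply(fl, function(f)
      !is.null(f) && any(names(f) %in% c("R", "X")), logical(1)))
    if (any(vapply(fl, is.null, logical(1))) || has_pseudo) {
      out[[length(out) + 1L]] <-
        data.frame(reaction_id = rxn$id, element = NA_character_,
                   imbalance = NA_real_, status = "unverifiable")
      next
    }
    els <- unique(unlist(lapply(fl, names)))
    bal <- vapply(els, function(e) {
      sum(vapply(seq_along(st), function(k) {
        cnt <- fl[[k]][e]
        if (is.na(cnt)) cnt <- 0
        unname(st[k]) * cnt
      }, numeric(1)))
    }, numeric(1))
    nz <- which(abs(bal) > 1e-9)
    for (k in nz)
      out[[length(out) + 1L]] <-
        data.frame(reaction_id = rxn$id, element = els[k],
                   imbalance = unname(bal[k]), status = "imbalanced")
  }
  if (!length(out))
    return(data.frame(reaction_id = character(), element = character(),
                      imbalance = numeric(), status = character()))
  do.call(rbind, out)
}

## ---- GPR parsing -----------------------------------------------------------

#' Parse a gene-reaction rule into an AND/OR tree
#'
#' Grammar: identifiers, parentheses, case-insensitive `and`/`or`; no
#' negation; `and` binds tighter than `or`. Unparseable rules yield an empty
#' tree with a warning, matching the convention that a bad annotation should
#' not invalidate the network.
#'
#' @param gpr rule string; empty or `NA` yields `NULL`.
#' @return nested list: `list(op = "and"|"or", children = ...)` or
#'   `list(gene = id)`; `NULL` for empty rules.
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  toks <- gpr_tokenize(gpr)
  res <- tryCatch(gpr_parse_expr(toks, 1L), error = function(e) e)
  if (inherits(res, "error") || res$pos != length(toks) + 1L) {
    warning("unparseable GPR rule stored as empty: '", gpr, "'")
    return(NULL)
  }
  res$node
}

gpr_tokenize <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# expr := term ( OR term )*
gpr_parse_expr <- function(toks, pos) {
  r <- gpr_parse_term(toks, pos)
  children <- list(r$node)
  pos <- r$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "or") {
    r <- gpr_parse_term(toks, pos + 1L)
    children[[length(children) + 1L]] <- r$node
    pos <- r$pos
  }
  node <- if (length(children) == 1L) children[[1L]]
          else list(op = "or", children = children)
  list(node = node, pos = pos)
}

# term := factor ( AND factor )*
gpr_parse_term <- function(toks, pos) {
  r <- gpr_parse_factor(toks, pos)
  children <- list(r$node)
  pos <- r$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "and") {
    r <- gpr_parse_factor(toks, pos + 1L)
    children[[length(children) + 1L]] <- r$node
    pos <- r$pos
  }
  node <- if (length(children) == 1L) children[[1L]]
          else list(op = "and", children = children)
  list(node = node, pos = pos)
}

gpr_parse_factor <- function(toks, pos) {
  if (pos > length(toks)) stop("unexpected end of GPR rule")
  tk <- toks[pos]
  if (tk == "(") {
    r <- gpr_parse_expr(toks, pos + 1L)
    if (r$pos > length(toks) || toks[r$pos] != ")")
      stop("unbalanced parentheses in GPR rule")
    return(list(node = r$node, pos = r$pos + 1L))
  }
  if (tk %in% c(")", "and", "or", "AND", "OR", "And", "Or"))
    stop("unexpected token '", tk, "' in GPR rule")
  list(node = list(gene = tk), pos = pos + 1L)
}

#' Genes referenced by a GPR tree
#' @param tree result of [parse_gpr()].
#' @return character vector of gene ids (empty for `NULL` tree).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (!is.null(tree$gene)) return(tree$gene)
  sort(unique(unlist(lapply(tree$children, gpr_genes))))
}

#' Evaluate a GPR tree over per-gene values
#'
#' The default aggregation (AND = min, OR = max) mirrors the convention that
#' an enzyme complex is limited by its scarcest subunit while isoenzymes
#' add the most abundant route.
#'
#' @param tree result of [parse_gpr()].
#' @param values named numeric vector of per-gene values.
#' @param and_fun,or_fun aggregation functions.
#' @param missing value used for genes absent from `values`.
#' @return scalar aggregate, or `NA` for a `NULL` tree.
#' @export
eval_gpr <- function(tree, values, and_fun = min, or_fun = max,
                     missing = NA_real_) {
  if (is.null(tree)) return(NA_real_)
  if (!is.null(tree$gene)) {
    v <- values[tree$gene]
    return(if (is.na(v)) missing else unname(v))
  }
  vals <- vapply(tree$children, eval_gpr, numeric(1), values = values,
                 and_fun = and_fun, or_fun = or_fun, missing = missing)
  if (tree$op == "and") and_fun(vals) else or_fun(vals)
}
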