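#' Read a metabolic model
#'
#' Three formats are supported: a JSON dialect mirroring the SBML content
#' one-to-one (see Details), SBML Level 3 with fbc-style flux bounds and
#' gene-product associations, and a pair of TSV tables.
#'
#' @details The JSON schema is an object with fields `id`, `compartments`
#' (object id -> name), `metabolites` (array of objects with `id`, `name`,
#' `compartment`, optional `formula`, `charge`, `kegg_id`), `reactions`
#' (array of objects with `id`, `name`, `stoichiometry` object
#' (metabolite id -> signed coefficient), `lower_bound`, `upper_bound`,
#' `gene_reaction_rule`, `ec_numbers`, `subsystems`, `kind`) and
#' `biomass_reaction_id`. For `format = "tsv"`, `path` is a prefix and the
#' tables `<path>.metabolites.tsv` / `<path>.reactions.tsv` are read.
#'
#' @param path file path (or TSV prefix).
#' @param format `"json"`, `"sbml"` or `"tsv"`; `"auto"` guesses from the
#'   extension.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", xml = "sbml", sbml = "sbml", "tsv")
  }
  switch(format,
         json = read_model_json(path),
         sbml = read_model_sbml(path),
         tsv = read_model_tsv(path))
}

#' Write a metabolic model
#'
#' Inverse of [read_model()]; `read_model(write_model(m, p), ...)` is the
#' identity on all fields for the JSON and TSV formats, and on
#' stoichiometry, bounds and GPRs for SBML.
#'
#' @param model a validated [metabolic_model()].
#' @param path output path (or TSV prefix).
#' @param format `"json"`, `"sbml"` or `"tsv"`.
#' @export
write_model <- function(model, path, format = c("json", "sbml", "tsv")) {
  format <- match.arg(format)
  if (length(model$reactions) == 0L)
    stop("refusing to write a model with no reactions")
  validate_model(model)
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path),
         tsv = write_model_tsv(model, path))
  invisible(path)
}

## ---- JSON ------------------------------------------------------------------

read_model_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e)))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               formula = m$formula %||% NA_character_,
               charge = as.integer(m$charge %||% NA),
               kegg_id = m$kegg_id %||% NA_character_)))
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    st <- setNames(as.numeric(st), names(st))
    reaction(id = r$id, name = r$name %||% r$id,
             stoichiometry = st,
             lower_bound = r$lower_bound %||% -1000,
             upper_bound = r$upper_bound %||% 1000,
             gpr = r$gene_reaction_rule %||% "",
             ec_numbers = as.character(unlist(r$ec_numbers)),
             subsystems = as.character(unlist(r$subsystems)),
             kind = r$kind %||% "auto")
  })
  comps <- unlist(doc$compartments)
  rxns <- resolve_kinds(rxns, mets, doc$biomass_reaction_id)
  metabolic_model(mets, rxns, comps, doc$biomass_reaction_id,
                  id = doc$id %||% "model")
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    compartments = as.list(model$compartments),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      if (!is.na(m$kegg_id)) out$kegg_id <- m$kegg_id
      out
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name,
           stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = r$gpr,
           ec_numbers = as.list(r$ec_numbers),
           subsystems = as.list(r$subsystems),
           kind = r$kind)
    }),
    biomass_reaction_id = model$biomass_reaction_id
  )
  names(doc$reactions) <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- TSV -------------------------------------------------------------------

format_equation <- function(st) {
  side <- function(v) {
    if (!length(v)) return("")
    paste(vapply(seq_along(v), function(k) {
      coef <- abs(unname(v[k]))
      if (coef == 1) names(v)[k]
      else paste(format(coef, digits = 15), names(v)[k])
    }, character(1)), collapse = " + ")
  }
  paste(side(st[st < 0]), "-->", side(st[st > 0]))
}

parse_equation <- function(eq) {
  parts <- strsplit(eq, "-->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed reaction equation: '", eq, "'")
  one_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- trimws(strsplit(s, " + ", fixed = TRUE)[[1]])
    st <- numeric(length(terms))
    nm <- character(length(terms))
    for (k in seq_along(terms)) {
      tk <- strsplit(terms[k], "[[:space:]]+")[[1]]
      if (length(tk) == 1L) { st[k] <- sign; nm[k] <- tk }
      else { st[k] <- sign * as.numeric(tk[1]); nm[k] <- tk[2] }
    }
    setNames(st, nm)
  }
  c(one_side(parts[1], -1), one_side(parts[2], +1))
}

read_model_tsv <- function(prefix) {
  mf <- paste0(prefix, ".metabolites.tsv")
  rf <- paste0(prefix, ".reactions.tsv")
  if (!file.exists(mf) || !file.exists(rf))
    stop("TSV model tables not found at prefix: ", prefix)
  mets <- read.delim(mf, stringsAsFactors = FALSE, na.strings = "")
  rtab <- read.delim(rf, stringsAsFactors = FALSE, na.strings = "")
  rxns <- lapply(seq_len(nrow(rtab)), function(i) {
    r <- rtab[i, ]
    reaction(id = r$id, name = r$name,
             stoichiometry = parse_equation(r$equation),
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             gpr = if (is.na(r$gene_reaction_rule)) "" else
               r$gene_reaction_rule,
             ec_numbers = split_field(r$ec_numbers),
             subsystems = split_field(r$subsystems),
             kind = r$kind)
  })
  biomass <- attr_line <- NULL
  hdr <- readLines(mf, n = 1L)
  comps <- unique(mets$compartment)
  cmeta <- paste0(prefix, ".compartments.tsv")
  if (file.exists(cmeta)) {
    ct <- read.delim(cmeta, stringsAsFactors = FALSE)
    comps <- setNames(ct$name, ct$id)
  } else comps <- setNames(comps, comps)
  biomass <- rtab$id[rtab$kind == "biomass"][1]
  if (is.na(biomass)) biomass <- NULL
  metabolic_model(mets, rxns, comps, biomass,
                  id = sub("^.*/", "", prefix))
}

split_field <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1]]
}

write_model_tsv <- function(model, prefix) {
  write.table(model$metabolites, paste0(prefix, ".metabolites.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  rtab <- do.call(rbind, lapply(model$reactions, function(r)
    data.frame(id = r$id, name = r$name,
               equation = format_equation(r$stoichiometry),
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               gene_reaction_rule = r$gpr,
               ec_numbers = paste(r$ec_numbers, collapse = ";"),
               subsystems = paste(r$subsystems, collapse = ";"),
               kind = r$kind)))
  write.table(rtab, paste0(prefix, ".reactions.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  ct <- data.frame(id = names(model$compartments),
                   name = unname(model$compartments))
  write.table(ct, paste0(prefix, ".compartments.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE, na = "")
}

## ---- SBML Level 3 (fbc-style) ----------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

gpr_to_fbc <- function(tree, parent) {
  if (is.null(tree)) return(invisible(NULL))
  if (!is.null(tree$gene)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", tree$gene))
    return(invisible(NULL))
  }
  node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
  for (ch in tree$children) gpr_to_fbc(ch, node)
  invisible(NULL)
}

fbc_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(sub("^G_", "", g))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_to_gpr, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "false")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (k in seq_along(model$compartments))
    xml2::xml_add_child(lc, "compartment",
                        id = names(model$compartments)[k],
                        name = unname(model$compartments[k]),
                        constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                              compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false",
                              constant = "false")
    if (!is.na(m$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge))
      xml2::xml_set_attr(sp, "fbc:charge", as.character(m$charge))
    if (!is.na(m$kegg_id))
      xml2::xml_set_attr(sp, "metaid", m$kegg_id)
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (r in model$reactions) {
    xml2::xml_add_child(lp, "parameter", id = paste0(r$id, "_lb"),
                        value = format(r$lower_bound, digits = 15),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0(r$id, "_ub"),
                        value = format(r$upper_bound, digits = 15),
                        constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lr, "reaction", id = r$id, name = r$name,
                              reversible = tolower(r$lower_bound < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0(r$id, "_lb"),
                              "fbc:upperFluxBound" = paste0(r$id, "_ub"))
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("KIND: ", r$kind))
    if (length(r$ec_numbers))
      xml2::xml_add_child(body, "p",
                          paste0("EC: ", paste(r$ec_numbers, collapse = ";")))
    if (length(r$subsystems))
      xml2::xml_add_child(body, "p",
                          paste0("SUBSYSTEM: ",
                                 paste(r$subsystems, collapse = ";")))
    st <- r$stoichiometry
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lrt <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(subs))
        xml2::xml_add_child(lrt, "speciesReference",
                            species = names(subs)[k],
                            stoichiometry = format(abs(unname(subs[k])),
                                                   digits = 15),
                            constant = "true")
    }
    if (length(prods)) {
      lpt <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prods))
        xml2::xml_add_child(lpt, "speciesReference",
                            species = names(prods)[k],
                            stoichiometry = format(unname(prods[k]),
                                                   digits = 15),
                            constant = "true")
    }
    if (!is.null(r$gpr_tree)) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      gpr_to_fbc(r$gpr_tree, ga)
    }
  }
  lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes)
    xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                        "fbc:label" = g)
  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = model$biomass_reaction_id,
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
}

read_model_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  comps_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  comps <- setNames(xml2::xml_attr(comps_nodes, "name"),
                    xml2::xml_attr(comps_nodes, "id"))
  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    charge = as.integer(xml2::xml_attr(sp_nodes, "charge")),
    kegg_id = xml2::xml_attr(sp_nodes, "metaid"),
    stringsAsFactors = FALSE)
  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pars <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                   xml2::xml_attr(par_nodes, "id"))
  biomass <- xml2::xml_attr(
    xml2::xml_find_first(mdl, ".//fbc:fluxObjective", ns), "reaction")
  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    sref <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rx, xp, ns)
      if (!length(nodes)) return(numeric(0))
      setNames(sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
               xml2::xml_attr(nodes, "species"))
    }
    st0 <- c(sref(".//s:listOfReactants/s:speciesReference", -1),
             sref(".//s:listOfProducts/s:speciesReference", +1))
    # merge duplicated species across sides
    st <- tapply(unname(st0), names(st0), sum)[unique(names(st0))]
    st <- setNames(as.numeric(st), names(st))
    ga <- xml2::xml_find_first(rx, ".//fbc:geneProductAssociation", ns)
    gpr <- ""
    if (!inherits(ga, "xml_missing")) {
      kid <- xml2::xml_children(ga)
      if (length(kid)) gpr <- fbc_to_gpr(kid[[1]])
    }
    ps <- xml2::xml_text(xml2::xml_find_all(rx, ".//s:notes//*", ns))
    kind <- sub("^KIND: ", "", grep("^KIND: ", ps, value = TRUE))
    ec <- split_field(sub("^EC: ", "", grep("^EC: ", ps, value = TRUE))[1])
    ss <- split_field(sub("^SUBSYSTEM: ", "",
                          grep("^SUBSYSTEM: ", ps, value = TRUE))[1])
    lbid <- xml2::xml_attr(rx, "lowerFluxBound")
    ubid <- xml2::xml_attr(rx, "upperFluxBound")
    reaction(id = id, name = xml2::xml_attr(rx, "name"),
             stoichiometry = st,
             lower_bound = if (!is.na(lbid)) pars[[lbid]] else -1000,
             upper_bound = if (!is.na(ubid)) pars[[ubid]] else 1000,
             gpr = gpr, ec_numbers = ec, subsystems = ss,
             kind = if (length(kind)) kind[1] else "auto")
  })
  mets$formula[is.na(mets$formula)] <- NA_character_
  rxns <- resolve_kinds(rxns, mets, biomass)
  metabolic_model(mets, rxns, comps, biomass,
                  id = xml2::xml_attr(mdl, "id"))
}
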