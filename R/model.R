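#' Construct a metabolic model
#'
#' The container for a constraint-based model: metabolites with
#' compartments, reactions with stoichiometry and flux bounds, optional
#' gene-protein-reaction (GPR) rules, exchange reactions and an optional
#' biomass reaction. Exchange reactions cross the system boundary and must
#' touch exactly one metabolite; by convention negative exchange flux is
#' uptake and positive flux secretion.
#'
#' Infinite bounds are replaced by a finite sentinel (`default_bound`,
#' 1000 flux units by default) so that all linear programs stay bounded.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions named list; each element a list with fields `id`,
#'   `stoich` (named numeric, metabolite id -> coefficient), `lb`, `ub`,
#'   and optional `gpr` (rule string, or NA).
#' @param exchange_ids character vector of exchange reaction ids.
#' @param biomass_id optional biomass reaction id (or NULL).
#' @param default_bound sentinel magnitude substituted for infinite bounds.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, exchange_ids = character(),
                            biomass_id = NULL, default_bound = 1000) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "name", "compartment") %in% names(metabolites)))
  reactions <- lapply(reactions, function(r) {
    r$lb <- max(r$lb, -default_bound)
    r$ub <- min(r$ub, default_bound)
    if (is.null(r$gpr)) r$gpr <- NA_character_
    r$reversible <- r$lb < 0
    r
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      exchange_ids = exchange_ids,
                      biomass_id = biomass_id,
                      default_bound = default_bound),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks that stoichiometry references only declared metabolites, that
#' `lb <= ub` for every reaction, and that each exchange reaction has
#' exactly one nonzero stoichiometric entry.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(names(model$reactions))) stop("duplicate reaction ids")
  for (r in model$reactions) {
    bad <- setdiff(names(r$stoich), met_ids)
    if (length(bad))
      stop(sprintf("reaction %s references undeclared metabolites: %s",
                   r$id, paste(bad, collapse = ", ")))
    if (r$lb > r$ub) stop(sprintf("reaction %s has lb > ub", r$id))
  }
  bad_ex <- setdiff(model$exchange_ids, names(model$reactions))
  if (length(bad_ex))
    stop(sprintf("unknown exchange reactions: %s", paste(bad_ex, collapse = ", ")))
  for (ex in model$exchange_ids) {
    nz <- sum(model$reactions[[ex]]$stoich != 0)
    if (nz != 1L)
      stop(sprintf("exchange reaction %s touches %d metabolites (expected 1)", ex, nz))
  }
  if (!is.null(model$biomass_id) && !model$biomass_id %in% names(model$reactions))
    stop("biomass_id is not a reaction id")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions (%d exchanges%s)\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(x$exchange_ids),
              if (is.null(x$biomass_id)) "" else paste0(", biomass = ", x$biomass_id)))
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id, names(model$reactions)))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

# ---- native JSON format ------------------------------------------------

#' Write a model to the native JSON format
#'
#' A plain mirror of the `metabolic_model` fields: metabolites, reactions
#' (stoichiometry as an id->coefficient map, bounds, GPR string), exchange
#' ids and biomass id.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    id = model$id,
    default_bound = model$default_bound,
    metabolites = model$metabolites,
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, stoich = as.list(r$stoich), lb = r$lb, ub = r$ub,
           gpr = if (is.na(r$gpr)) NULL else r$gpr)),
    exchange_ids = model$exchange_ids,
    biomass_id = model$biomass_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model from the native JSON format
#'
#' @param path file written by [write_model_json()].
#' @return a `metabolic_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, name = m$name, compartment = m$compartment)))
  rxns <- lapply(obj$reactions, function(r) {
    st <- vapply(r$stoich, as.numeric, 0)
    list(id = r$id, stoich = st, lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         gpr = if (is.null(r$gpr)) NA_character_ else r$gpr)
  })
  metabolic_model(id = obj$id, metabolites = mets, reactions = rxns,
                  exchange_ids = unlist(obj$exchange_ids),
                  biomass_id = obj$biomass_id,
                  default_bound = obj$default_bound %||% 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- SBML Level 3 + fbc ------------------------------------------------

#' Write a model as SBML Level 3 with the fbc package
#'
#' Emits species, flux-bound parameters, reactions with
#' `fbc:geneProductAssociation` blocks, gene products, and an fbc objective
#' for the biomass reaction if one is set. Exchange reactions are written
#' with their single species flagged `boundaryCondition="false"` and are
#' recognized on re-read by the `EX_` id prefix or single-entry
#' stoichiometry against the model notes.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', sid(model$id)))

  comps <- unique(model$metabolites$compartment)
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>', sid(comps)),
             "    </listOfCompartments>")

  lines <- c(lines, "    <listOfSpecies>",
             sprintf('      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
                     sid(model$metabolites$id), esc(model$metabolites$name),
                     sid(model$metabolites$compartment)),
             "    </listOfSpecies>")

  # one parameter per distinct bound value
  bounds <- sort(unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub)))))
  pid <- function(v) sprintf("fb_%s", gsub("[^0-9A-Za-z]", "_", format(v, trim = TRUE, scientific = FALSE)))
  lines <- c(lines, "    <listOfParameters>",
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     vapply(bounds, pid, ""), format(bounds, trim = TRUE, scientific = FALSE)),
             "    </listOfParameters>")

  genes <- sort(unique(unlist(lapply(model$reactions, function(r)
    if (!is.na(r$gpr)) gpr_genes(parse_gpr(r$gpr))))))
  if (length(genes))
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>', sid(genes), esc(genes)),
               "    </fbc:listOfGeneProducts>")

  lines <- c(lines, "    <listOfReactions>")
  for (r in model$reactions) {
    rev <- if (r$lb < 0) "true" else "false"
    lines <- c(lines, sprintf('      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
                              sid(r$id), rev, pid(r$lb), pid(r$ub)))
    subs <- r$stoich[r$stoich < 0]; prods <- r$stoich[r$stoich > 0]
    if (length(subs))
      lines <- c(lines, "        <listOfReactants>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         sid(names(subs)), format(-unname(subs), trim = TRUE, scientific = FALSE)),
                 "        </listOfReactants>")
    if (length(prods))
      lines <- c(lines, "        <listOfProducts>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         sid(names(prods)), format(unname(prods), trim = TRUE, scientific = FALSE)),
                 "        </listOfProducts>")
    if (!is.na(r$gpr)) {
      rule <- parse_gpr(r$gpr)
      terms <- vapply(rule$dnf, function(s) {
        refs <- sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>', sid(s))
        if (length(s) > 1L) paste0("<fbc:and>", paste(refs, collapse = ""), "</fbc:and>") else refs
      }, "")
      body <- if (length(terms) > 1L) paste0("<fbc:or>", paste(terms, collapse = ""), "</fbc:or>") else terms
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 paste0("          ", body),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")

  if (!is.null(model$biomass_id))
    lines <- c(lines,
               '    <fbc:listOfObjectives fbc:activeObjective="obj">',
               '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
               sprintf('        <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>', sid(model$biomass_id)),
               "      </fbc:objective>",
               "    </fbc:listOfObjectives>")

  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Read an SBML Level 3 (+fbc) model
#'
#' Supports the constructs emitted by [write_model_sbml()] and the common
#' subset produced by constraint-based modeling tools: species,
#' compartments, bound parameters referenced through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` (falling back to
#' reversibility-based defaults when absent), nested
#' `fbc:geneProductAssociation` and the active objective. Reactions whose
#' id starts with `EX_` (after stripping the conventional `R_` prefix), or
#' that touch exactly one boundary species, are flagged as exchanges.
#'
#' @param path SBML file path.
#' @param default_bound sentinel for missing/infinite bounds.
#' @return a `metabolic_model`.
#' @export
read_model_sbml <- function(path, default_bound = 1000) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  strip <- function(x, pre) ifelse(startsWith(x, pre), substring(x, nchar(pre) + 1L), x)

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), strip(xml2::xml_attr(sp, "id"), "M_"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  boundary_sp <- strip(xml2::xml_attr(sp, "id"), "M_")[xml2::xml_attr(sp, "boundaryCondition") %in% "true"]
  mets <- mets[!mets$id %in% boundary_sp, , drop = FALSE]

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")), xml2::xml_attr(pars, "id"))

  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  assoc_to_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      lbl <- glabel[gid]
      return(if (is.na(lbl)) strip(gid, "G_") else unname(lbl))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_text, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx, function(node) {
    rid <- strip(xml2::xml_attr(node, "id"), "R_")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      met <- strip(xml2::xml_attr(sr, "species"), "M_")
      st[met] <- (if (is.na(st[met])) 0 else st[met]) - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      met <- strip(xml2::xml_attr(sr, "species"), "M_")
      st[met] <- (if (is.na(st[met]) || is.null(st[met])) 0 else st[met]) + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    st <- st[!is.na(st)]
    st <- st[names(st) %in% mets$id]
    lbp <- xml2::xml_attr(node, "lowerFluxBound"); ubp <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else if (rev) -default_bound else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else default_bound
    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr <- NA_character_
    if (!inherits(ga, "xml_missing")) {
      body <- xml2::xml_children(ga)
      if (length(body)) gpr <- assoc_to_text(body[[1]])
    }
    list(id = rid, stoich = st, lb = lb, ub = ub, gpr = gpr)
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")

  exch <- names(reactions)[startsWith(names(reactions), "EX_") |
                             vapply(reactions, function(r) length(r$stoich), 0L) == 0L]
  # reactions that lost all stoichiometry to boundary species are exchanges of
  # the boundary metabolite; re-attach nothing, they stay single/empty-entry
  exch <- exch[vapply(reactions[exch], function(r) sum(r$stoich != 0) == 1L, logical(1))]

  fo <- xml2::xml_find_first(mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  biomass <- if (inherits(fo, "xml_missing")) NULL else strip(xml2::xml_attr(fo, "reaction"), "R_")

  metabolic_model(id = xml2::xml_attr(mdl, "id") %||% "model",
                  metabolites = mets, reactions = reactions,
                  exchange_ids = exch, biomass_id = biomass,
                  default_bound = default_bound)
}

#' Read a model file, dispatching on extension
#'
#' `.xml`/`.sbml` files go through [read_model_sbml()], `.json` through
#' [read_model_json()].
#'
#' @param path model file.
#' @param ... passed to the format reader.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xml = , sbml = read_model_sbml(path, ...),
         json = read_model_json(path),
         stop(sprintf("unsupported model format: '%s'", ext)))
}
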