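#' Read a constraint-based model from SBML
#'
#' Supports the constraint-based subset of SBML Level 2 and Level 3 (+fbc):
#' compartments, species (with `boundaryCondition` and fbc chemical formulas),
#' reactions with stoichiometry, reversibility, flux bounds (fbc bound
#' parameters, kineticLaw `LOWER_BOUND`/`UPPER_BOUND` parameters, or defaults
#' derived from the `reversible` attribute), and gene associations (fbc
#' `geneProductAssociation` or legacy `GENE_ASSOCIATION` notes). A reaction is
#' flagged as boundary when its stoichiometry is one-sided or its sole species
#' carries `boundaryCondition="true"`.
#'
#' @param path SBML file path.
#' @param tag provenance tag; defaults to the SBML model id.
#' @return a [new_model()] object.
#' @export
read_sbml <- function(path, tag = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path, "': ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing")) stop("SBML format error: no <model> element in ", path)
  mid <- xml2::xml_attr(mnode, "id")
  if (is.null(tag)) tag <- if (!is.na(mid)) mid else "model"
  model <- new_model(tag, name = xml2::xml_attr(mnode, "name") %|na|% tag)

  for (cn in xml2::xml_find_all(mnode, ".//listOfCompartments/compartment")) {
    cid <- xml2::xml_attr(cn, "id")
    fields <- notes_fields(cn)
    is_ext <- identical(fields[["EXTRACELLULAR"]], "true") ||
      (is.null(fields[["EXTRACELLULAR"]]) &&
         tolower(cid) %in% c("e", "e0", "extracellular", "external"))
    model <- add_compartment(model, cid, xml2::xml_attr(cn, "name") %|na|% cid, is_ext)
  }

  species_map <- list()   # SBML species id -> met key
  boundary_species <- character()
  for (sn in xml2::xml_find_all(mnode, ".//listOfSpecies/species")) {
    sid <- xml2::xml_attr(sn, "id")
    comp <- xml2::xml_attr(sn, "compartment")
    id <- sbml_species_to_id(sid, comp)
    formula <- xml2::xml_attr(sn, "chemicalFormula") %|na|%
      xml2::xml_attr(sn, "fbc:chemicalFormula")
    srcs <- notes_sources(sn, tag)
    model <- add_metabolite(model, id, comp, formula, srcs)
    species_map[[sid]] <- met_key(id, comp)
    if (identical(xml2::xml_attr(sn, "boundaryCondition"), "true"))
      boundary_species <- c(boundary_species, sid)
  }

  gene_srcs <- list()
  for (gn in xml2::xml_find_all(mnode, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")) {
    gid <- xml2::xml_attr(gn, "label") %|na|% xml2::xml_attr(gn, "id")
    gene_srcs[[gid]] <- notes_sources(gn, tag)
  }

  params <- sbml_parameters(mnode)

  for (rn in xml2::xml_find_all(mnode, ".//listOfReactions/reaction")) {
    rid <- sub("^R_", "", xml2::xml_attr(rn, "id"))
    stoich <- numeric()
    drop_boundary_side <- FALSE
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in xml2::xml_find_all(rn, paste0("./", side, "/speciesReference"))) {
        sp <- xml2::xml_attr(sr, "species")
        coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %|na|% "1")
        if (sp %in% boundary_species) { drop_boundary_side <- TRUE; next }
        key <- species_map[[sp]]
        if (is.null(key)) stop("SBML format error: reaction ", rid,
                               " references unknown species ", sp)
        stoich[key] <- (stoich[key] %|na0|% 0) + sgn * coef
      }
    }
    stoich <- cancel_stoich(stoich)
    if (!length(stoich)) next
    rev_attr <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    fields <- notes_fields(rn)
    bounds <- sbml_reaction_bounds(rn, params)
    if (is.null(bounds)) {
      reversibility <- if (rev_attr) "reversible" else "forward"
      lb <- NULL; ub <- NULL
    } else {
      lb <- bounds[1]; ub <- bounds[2]
      reversibility <- if (lb < 0 && ub > 0) "reversible" else if (ub <= 0) "backward" else "forward"
    }
    if (!is.null(fields[["REVERSIBILITY"]])) reversibility <- fields[["REVERSIBILITY"]]
    gpr <- sbml_reaction_gpr(rn)
    srcs <- notes_sources(rn, tag)
    is_boundary <- drop_boundary_side || all(stoich >= 0) || all(stoich <= 0)
    model <- add_reaction(model, rid, stoich, reversibility, gpr,
                          lb = lb, ub = ub, is_boundary = is_boundary,
                          sources = srcs)
  }

  for (gid in names(gene_srcs)) model <- add_gene(model, gid, gene_srcs[[gid]])

  obj <- xml2::xml_find_first(mnode, ".//*[local-name()='fluxObjective']")
  if (!inherits(obj, "xml_missing")) {
    bid <- sub("^R_", "", xml2::xml_attr(obj, "reaction"))
    if (bid %in% names(model$reactions)) model$biomass_reaction_id <- bid
  }
  validate_model(model)
}

`%|na|%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
`%|na0|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

sbml_species_to_id <- function(sid, comp) {
  id <- sub("^M_", "", sid)
  suffix <- paste0("_", comp)
  if (endsWith(id, suffix)) id <- substr(id, 1, nchar(id) - nchar(suffix))
  id
}

# KEY: value fields from each <p> inside an entity's <notes>.
notes_fields <- function(node) {
  ps <- xml2::xml_find_all(node, "./notes//p")
  out <- list()
  for (p in ps) {
    txt <- trimws(xml2::xml_text(p))
    m <- regexec("^([A-Z_]+):\\s*(.*)$", txt)[[1]]
    if (m[1] != -1) {
      parts <- regmatches(txt, regexec("^([A-Z_]+):\\s*(.*)$", txt))[[1]]
      out[[parts[2]]] <- trimws(parts[3])
    }
  }
  out
}

notes_sources <- function(node, default) {
  f <- notes_fields(node)
  if (is.null(f[["SOURCES"]]) || !nzchar(f[["SOURCES"]])) return(default)
  strsplit(f[["SOURCES"]], ";")[[1]]
}

sbml_parameters <- function(mnode) {
  out <- list()
  for (pn in xml2::xml_find_all(mnode, "./listOfParameters/parameter")) {
    out[[xml2::xml_attr(pn, "id")]] <- as.numeric(xml2::xml_attr(pn, "value"))
  }
  out
}

sbml_reaction_bounds <- function(rn, params) {
  lbp <- xml2::xml_attr(rn, "lowerFluxBound")
  ubp <- xml2::xml_attr(rn, "upperFluxBound")
  if (!is.na(lbp) && !is.na(ubp) && !is.null(params[[lbp]]) && !is.null(params[[ubp]]))
    return(c(params[[lbp]], params[[ubp]]))
  kl <- xml2::xml_find_first(rn, "./kineticLaw")
  if (!inherits(kl, "xml_missing")) {
    lb <- ub <- NA_real_
    for (pn in xml2::xml_find_all(kl, ".//parameter")) {
      pid <- xml2::xml_attr(pn, "id")
      v <- as.numeric(xml2::xml_attr(pn, "value"))
      if (identical(pid, "LOWER_BOUND")) lb <- v
      if (identical(pid, "UPPER_BOUND")) ub <- v
    }
    if (!is.na(lb) && !is.na(ub)) return(c(lb, ub))
  }
  NULL
}

sbml_reaction_gpr <- function(rn) {
  gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
  if (!inherits(gpa, "xml_missing")) {
    kids <- xml2::xml_children(gpa)
    if (length(kids)) return(fbc_assoc_to_gpr(kids[[1]]))
  }
  fields <- notes_fields(rn)
  rule <- fields[["GENE_ASSOCIATION"]]
  if (!is.null(rule) && nzchar(rule)) return(gpr_parse(rule))
  NULL
}

fbc_assoc_to_gpr <- function(node) {
  nm <- sub(".*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef")
    return(xml2::xml_attr(node, "label") %|na|% xml2::xml_attr(node, "geneProduct"))
  kids <- lapply(xml2::xml_children(node), fbc_assoc_to_gpr)
  op <- if (nm == "and") "and" else "or"
  if (length(kids) == 1L) kids[[1]] else list(op = op, args = kids)
}

#' Write a model to SBML
#'
#' Writes SBML Level 3 Version 1 with fbc-style bound parameters, gene
#' products and an active objective for the biomass reaction. Output is
#' deterministic (entity order = insertion order), so two writes of the same
#' model are byte-identical. `read_sbml(write_sbml(m))` reproduces `m` on all
#' fields.
#'
#' @param model a `gsm_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  num <- function(v) trimws(formatC(v, format = "g", digits = 15, width = 1))
  L <- character()
  push <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
       'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
       'level="3" version="1" fbc:required="false">')
  push('  <model id="', esc(model$tag), '" name="', esc(model$name), '" fbc:strict="false">')

  push('    <listOfCompartments>')
  for (i in seq_len(nrow(model$compartments))) {
    cp <- model$compartments[i, ]
    push('      <compartment id="', sid(cp$id), '" name="', esc(cp$name),
         '" constant="true">')
    push('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>EXTRACELLULAR: ',
         tolower(cp$is_extracellular), '</p></body></notes>')
    push('      </compartment>')
  }
  push('    </listOfCompartments>')

  push('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    attrs <- paste0('id="', sid(paste0("M_", mt$id, "_", mt$compartment)),
                    '" name="', esc(mt$id), '" compartment="', sid(mt$compartment),
                    '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"')
    if (!is.na(mt$formula)) attrs <- paste0(attrs, ' fbc:chemicalFormula="', esc(mt$formula), '"')
    push('      <species ', attrs, '>')
    push('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SOURCES: ',
         esc(mt$sources), '</p></body></notes>')
    push('      </species>')
  }
  push('    </listOfSpecies>')

  bounds <- unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub))))
  bounds <- sort(bounds)
  bid <- function(v) paste0("B_", gsub("[^0-9A-Za-z]", "_", gsub("-", "minus", num(v))))
  if (length(bounds)) {
    push('    <listOfParameters>')
    for (v in bounds)
      push('      <parameter id="', bid(v), '" value="', num(v),
           '" constant="true" sboTerm="SBO:0000626"/>')
    push('    </listOfParameters>')
  }

  push('    <listOfReactions>')
  for (rxn in model$reactions) {
    push('      <reaction id="', sid(paste0("R_", rxn$id)), '" name="', esc(rxn$id),
         '" reversible="', tolower(rxn$reversibility == "reversible"),
         '" fast="false" fbc:lowerFluxBound="', bid(rxn$lb),
         '" fbc:upperFluxBound="', bid(rxn$ub), '">')
    push('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SOURCES: ',
         esc(paste(rxn$sources, collapse = ";")), '</p><p>REVERSIBILITY: ',
         rxn$reversibility, '</p></body></notes>')
    if (!is.null(rxn$gpr)) {
      push('        <fbc:geneProductAssociation>')
      push(fbc_gpr_xml(rxn$gpr, indent = "          "))
      push('        </fbc:geneProductAssociation>')
    }
    subs <- rxn$stoich[rxn$stoich < 0]
    prods <- rxn$stoich[rxn$stoich > 0]
    spid <- function(key) {
      p <- met_key_parts(key)
      sid(paste0("M_", p$id, "_", p$compartment))
    }
    if (length(subs)) {
      push('        <listOfReactants>')
      for (k in names(subs))
        push('          <speciesReference species="', spid(k), '" stoichiometry="',
             num(-subs[[k]]), '" constant="true"/>')
      push('        </listOfReactants>')
    }
    if (length(prods)) {
      push('        <listOfProducts>')
      for (k in names(prods))
        push('          <speciesReference species="', spid(k), '" stoichiometry="',
             num(prods[[k]]), '" constant="true"/>')
      push('        </listOfProducts>')
    }
    push('      </reaction>')
  }
  push('    </listOfReactions>')

  if (nrow(model$genes)) {
    push('    <fbc:listOfGeneProducts>')
    for (i in seq_len(nrow(model$genes))) {
      g <- model$genes[i, ]
      push('      <fbc:geneProduct fbc:id="', sid(paste0("G_", g$id)),
           '" fbc:label="', esc(g$id), '">')
      push('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SOURCES: ',
           esc(g$sources), '</p></body></notes>')
      push('      </fbc:geneProduct>')
    }
    push('    </fbc:listOfGeneProducts>')
  }

  if (!is.na(model$biomass_reaction_id)) {
    push('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    push('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    push('        <fbc:listOfFluxObjectives>')
    push('          <fbc:fluxObjective fbc:reaction="',
         sid(paste0("R_", model$biomass_reaction_id)), '" fbc:coefficient="1"/>')
    push('        </fbc:listOfFluxObjectives>')
    push('      </fbc:objective>')
    push('    </fbc:listOfObjectives>')
  }

  push('  </model>')
  push('</sbml>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unlist(L), con, sep = "\n")
  invisible(path)
}

fbc_gpr_xml <- function(rule, indent) {
  if (is.character(rule))
    return(paste0(indent, '<fbc:geneProductRef fbc:geneProduct="',
                  gsub("[^A-Za-z0-9_]", "_", paste0("G_", rule)),
                  '" fbc:label="', rule, '"/>'))
  tagn <- if (rule$op == "and") "fbc:and" else "fbc:or"
  inner <- vapply(rule$args, fbc_gpr_xml, character(1), indent = paste0(indent, "  "))
  paste0(indent, "<", tagn, ">\n", paste(inner, collapse = "\n"), "\n", indent, "</", tagn, ">")
}
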