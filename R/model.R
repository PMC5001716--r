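#' Constraint-based metabolic model objects
#'
#' A `gsm_model` holds the entities of a genome-scale constraint-based
#' metabolic model: compartments, metabolites (one instance per compartment),
#' genes, and reactions with stoichiometry, reversibility, flux bounds, a GPR
#' rule, a boundary flag and per-entity source-model provenance. Metabolite
#' instances are addressed by a key \code{"<id>[<compartment>]"}.
#'
#' @param tag short source label for the model (provenance tag).
#' @param name human-readable model name.
#' @return an empty `gsm_model`.
#' @export
new_model <- function(tag, name = tag) {
  structure(list(
    tag = tag,
    name = name,
    compartments = data.frame(id = character(), name = character(),
                              is_extracellular = logical(), is_unknown = logical(),
                              stringsAsFactors = FALSE),
    metabolites = data.frame(key = character(), id = character(),
                             compartment = character(), formula = character(),
                             sources = character(), stringsAsFactors = FALSE),
    genes = data.frame(id = character(), sources = character(),
                       stringsAsFactors = FALSE),
    reactions = list(),
    biomass_reaction_id = NA_character_
  ), class = "gsm_model")
}

#' @export
print.gsm_model <- function(x, ...) {
  cat(sprintf("<gsm_model '%s'> %d compartments, %d metabolites, %d reactions, %d genes\n",
              x$tag, nrow(x$compartments), nrow(x$metabolites),
              length(x$reactions), nrow(x$genes)))
  invisible(x)
}

#' Metabolite instance key
#' @param id metabolite identifier.
#' @param compartment compartment identifier.
#' @return character key \code{"id[compartment]"}.
#' @export
met_key <- function(id, compartment) paste0(id, "[", compartment, "]")

# Split keys back into id / compartment.
met_key_parts <- function(keys) {
  id <- sub("\\[[^]]*\\]$", "", keys)
  comp <- sub("^.*\\[([^]]*)\\]$", "\\1", keys)
  data.frame(key = keys, id = id, compartment = comp, stringsAsFactors = FALSE)
}

#' The canonical unknown-compartment tag
#' @export
UNKNOWN_COMPARTMENT <- "UNK_COMP"

#' Add a compartment to a model
#' @param model a `gsm_model`.
#' @param id,name compartment id and display name.
#' @param is_extracellular logical; the boundary-facing compartment.
#' @return the updated model.
#' @export
add_compartment <- function(model, id, name = id, is_extracellular = FALSE) {
  if (id %in% model$compartments$id) return(model)
  model$compartments <- rbind(model$compartments, data.frame(
    id = id, name = name, is_extracellular = is_extracellular,
    is_unknown = identical(id, UNKNOWN_COMPARTMENT), stringsAsFactors = FALSE))
  model
}

#' Add a metabolite instance to a model
#' @param model a `gsm_model`.
#' @param id chemical identifier (namespace id).
#' @param compartment compartment id (added on the fly if missing).
#' @param formula elemental formula string or `NA`.
#' @param sources provenance tags; defaults to the model's own tag.
#' @return the updated model.
#' @export
add_metabolite <- function(model, id, compartment, formula = NA_character_,
                           sources = model$tag) {
  model <- add_compartment(model, compartment)
  key <- met_key(id, compartment)
  hit <- match(key, model$metabolites$key)
  if (!is.na(hit)) {
    model$metabolites$sources[hit] <- merge_sources(model$metabolites$sources[hit], sources)
    if (is.na(model$metabolites$formula[hit]) && !is.na(formula))
      model$metabolites$formula[hit] <- formula
    return(model)
  }
  model$metabolites <- rbind(model$metabolites, data.frame(
    key = key, id = id, compartment = compartment, formula = formula,
    sources = paste(sources, collapse = ";"), stringsAsFactors = FALSE))
  model
}

#' Add a gene record
#' @inheritParams add_metabolite
#' @export
add_gene <- function(model, id, sources = model$tag) {
  hit <- match(id, model$genes$id)
  if (!is.na(hit)) {
    model$genes$sources[hit] <- merge_sources(model$genes$sources[hit], sources)
    return(model)
  }
  model$genes <- rbind(model$genes, data.frame(
    id = id, sources = paste(sources, collapse = ";"), stringsAsFactors = FALSE))
  # keep the table sorted so entity order is insertion-independent
  model$genes <- model$genes[order(model$genes$id, method = "radix"), , drop = FALSE]
  rownames(model$genes) <- NULL
  model
}

merge_sources <- function(a, b) {
  paste(sort(unique(c(strsplit(a, ";")[[1]], unlist(strsplit(b, ";"))))), collapse = ";")
}

sources_of <- function(x) sort(unique(unlist(strsplit(x, ";"))))

#' Add a reaction to a model
#'
#' @param model a `gsm_model`; all stoichiometry keys must resolve to existing
#'   metabolite instances and all GPR genes are registered automatically.
#' @param id reaction identifier (unique within the model).
#' @param stoich named numeric vector; names are metabolite keys, negative
#'   coefficients are substrates.
#' @param reversibility one of `"forward"`, `"backward"`, `"reversible"`.
#' @param gpr rule string (see [gpr_parse()]) or parsed rule or `NULL`.
#' @param lb,ub flux bounds; derived from `reversibility` when `NULL`
#'   (reversible `[-1000, 1000]`, forward `[0, 1000]`, backward `[-1000, 0]`).
#' @param is_boundary logical or `NA` (auto-detect: all coefficients one sign).
#' @param sources provenance tags.
#' @return the updated model.
#' @export
add_reaction <- function(model, id, stoich, reversibility = "forward",
                         gpr = NULL, lb = NULL, ub = NULL,
                         is_boundary = NA, sources = model$tag) {
  stopifnot(length(stoich) > 0, !is.null(names(stoich)))
  stoich <- stoich[order(names(stoich), method = "radix")]
  if (id %in% names(model$reactions)) stop("duplicate reaction id: ", id)
  missing <- setdiff(names(stoich), model$metabolites$key)
  if (length(missing)) stop("unknown metabolites in reaction ", id, ": ",
                            paste(missing, collapse = ", "))
  reversibility <- match.arg(reversibility, c("forward", "backward", "reversible"))
  if (is.character(gpr)) gpr <- gpr_parse(gpr)
  for (g in gpr_genes(gpr)) model <- add_gene(model, g, sources)
  bounds <- default_bounds(reversibility)
  if (is.null(lb)) lb <- bounds[1]
  if (is.null(ub)) ub <- bounds[2]
  if (lb > ub) stop("lb > ub for reaction ", id)
  if (is.na(is_boundary))
    is_boundary <- all(stoich >= 0) || all(stoich <= 0)
  model$reactions[[id]] <- list(
    id = id, stoich = stoich, reversibility = reversibility,
    lb = lb, ub = ub, gpr = gpr, is_boundary = is_boundary,
    sources = sort(unique(sources)))
  model
}

default_bounds <- function(reversibility) {
  switch(reversibility,
         reversible = c(-1000, 1000),
         forward = c(0, 1000),
         backward = c(-1000, 0))
}

#' Validate model invariants
#'
#' Checks id uniqueness, stoichiometry resolution, GPR gene registration,
#' bound ordering, single unknown compartment, and one-sidedness of boundary
#' reactions. Errors on the first violation.
#' @param model a `gsm_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "gsm_model"))
  if (anyDuplicated(model$compartments$id)) stop("duplicate compartment ids")
  if (anyDuplicated(model$metabolites$key)) stop("duplicate metabolite instances")
  if (sum(model$compartments$is_unknown) > 1L) stop("more than one unknown compartment")
  if (anyDuplicated(names(model$reactions))) stop("duplicate reaction ids")
  for (rxn in model$reactions) {
    bad <- setdiff(names(rxn$stoich), model$metabolites$key)
    if (length(bad)) stop("reaction ", rxn$id, " references unknown metabolites: ",
                          paste(bad, collapse = ", "))
    if (rxn$lb > rxn$ub) stop("reaction ", rxn$id, ": lb > ub")
    if (rxn$is_boundary && !(all(rxn$stoich >= 0) || all(rxn$stoich <= 0)))
      stop("boundary reaction ", rxn$id, " has metabolites on both sides")
    badg <- setdiff(gpr_genes(rxn$gpr), model$genes$id)
    if (length(badg)) stop("reaction ", rxn$id, " references unknown genes: ",
                           paste(badg, collapse = ", "))
  }
  invisible(model)
}

#' Build the stoichiometric matrix S (m x r)
#'
#' Rows are metabolite instances (keys), columns reactions; `S[i, j]` is the
#' signed coefficient of metabolite i in reaction j.
#'
#' @param model a `gsm_model`.
#' @param reactions optional subset of reaction ids.
#' @return a sparse `Matrix::dgCMatrix` with dimnames (metabolite keys,
#'   reaction ids).
#' @export
build_stoich_matrix <- function(model, reactions = names(model$reactions)) {
  mets <- model$metabolites$key
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(reactions)) {
    st <- model$reactions[[reactions[j]]]$stoich
    ii <- c(ii, match(names(st), mets))
    jj <- c(jj, rep(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(reactions)),
                       dimnames = list(mets, reactions))
}

# Sum duplicate keys and drop (near-)zero coefficients.
cancel_stoich <- function(stoich, tol = 1e-9) {
  if (!length(stoich)) return(stoich)
  s <- tapply(stoich, names(stoich), sum)
  out <- as.numeric(s); names(out) <- names(s)
  out <- out[abs(out) > tol]
  out[order(names(out), method = "radix")]
}

# Net stoichiometry of a reaction with optional currency species zeroed.
reaction_net <- function(rxn, ignore_ids = character()) {
  st <- cancel_stoich(rxn$stoich)
  if (length(ignore_ids) && length(st)) {
    ids <- met_key_parts(names(st))$id
    st <- st[!(ids %in% ignore_ids)]
  }
  st
}

# Canonical direction-insensitive signature of a stoichiometry vector.
# Coefficients are rounded to 9 decimals; the lexicographically smaller of the
# signature and its negation is returned so opposite writings collide.
stoich_signature <- function(stoich, directed = FALSE) {
  if (!length(stoich)) return("")
  o <- order(names(stoich), method = "radix")
  st <- stoich[o]
  fmt <- function(v) paste(sprintf("%s:%.9g", names(v), round(v, 9)), collapse = "|")
  a <- fmt(st)
  if (directed) return(a)
  b <- fmt(-st)
  if (a <= b) a else b
}

support_signature <- function(stoich) {
  if (!length(stoich)) return("")
  paste(sort(names(stoich)), collapse = "|")
}

#' Re-point a metabolite instance to another key
#'
#' All stoichiometries referencing `from` are rewritten to `to`; coefficients
#' of the two instances inside one reaction are summed and exact cancellations
#' removed. A reaction whose stoichiometry cancels completely is deleted.
#' The `from` metabolite record is removed (its sources and formula folded
#' into `to`).
#'
#' @param model a `gsm_model`.
#' @param from,to metabolite keys.
#' @return list with the updated `model`, the ids of `dropped` (fully
#'   cancelled) reactions and of `touched` reactions.
#' @export
repoint_metabolite <- function(model, from, to) {
  stopifnot(from %in% model$metabolites$key)
  pf <- met_key_parts(to)
  if (!(to %in% model$metabolites$key)) {
    i <- match(from, model$metabolites$key)
    model <- add_metabolite(model, pf$id, pf$compartment,
                            formula = model$metabolites$formula[i],
                            sources = sources_of(model$metabolites$sources[i]))
  }
  dropped <- character(); touched <- character()
  for (rid in names(model$reactions)) {
    st <- model$reactions[[rid]]$stoich
    if (!(from %in% names(st))) next
    names(st)[names(st) == from] <- to
    st <- cancel_stoich(st)
    touched <- c(touched, rid)
    if (!length(st)) {
      model$reactions[[rid]] <- NULL
      dropped <- c(dropped, rid)
    } else {
      model$reactions[[rid]]$stoich <- st
    }
  }
  ifrom <- match(from, model$metabolites$key)
  ito <- match(to, model$metabolites$key)
  model$metabolites$sources[ito] <- merge_sources(model$metabolites$sources[ito],
                                                  sources_of(model$metabolites$sources[ifrom]))
  if (is.na(model$metabolites$formula[ito]))
    model$metabolites$formula[ito] <- model$metabolites$formula[ifrom]
  model$metabolites <- model$metabolites[-ifrom, , drop = FALSE]
  rownames(model$metabolites) <- NULL
  list(model = model, dropped = dropped, touched = touched)
}

#' Drop metabolites that no reaction references
#' @param model a `gsm_model`.
#' @return the pruned model.
#' @export
prune_orphan_metabolites <- function(model) {
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich))))
  keep <- model$metabolites$key %in% used
  model$metabolites <- model$metabolites[keep, , drop = FALSE]
  rownames(model$metabolites) <- NULL
  model
}

#' Parse an elemental formula string
#' @param formula e.g. `"C6H12O6"`; `NA` gives `NULL`.
#' @return named integer vector of element counts, or `NULL`.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  parts <- unlist(regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula)))
  if (!length(parts)) return(NULL)
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  tapply(n, el, sum)
}

#' Elemental balance of a reaction
#'
#' @param model a `gsm_model`.
#' @param rid reaction id.
#' @return `TRUE` / `FALSE`, or `NA` when any participating formula is missing
#'   or the reaction is a boundary reaction (never balanced by construction).
#' @export
reaction_balanced <- function(model, rid) {
  rxn <- model$reactions[[rid]]
  if (rxn$is_boundary) return(NA)
  idx <- match(names(rxn$stoich), model$metabolites$key)
  formulas <- model$metabolites$formula[idx]
  if (anyNA(formulas)) return(NA)
  tot <- list()
  for (i in seq_along(formulas)) {
    f <- parse_formula(formulas[i])
    if (is.null(f)) return(NA)
    for (el in names(f)) tot[[el]] <- (tot[[el]] %||% 0) + rxn$stoich[i] * f[[el]]
  }
  all(abs(unlist(tot)) < 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default configuration
#'
#' All tunables of the merging pipeline with their defaults: the metabolite
#' matching percentile (5), the wild-type growth cutoff (1e-6) and minimal
#' relative mutant growth (0.30), the maximum lumped-set size (5), the
#' redox-pair co-occurrence threshold (0.8), the GPR merge mode, currency
#' species ignored in net-formula comparison, compartment aliases, and
#' numerical tolerances.
#' @return a named list.
#' @export
default_config <- function() {
  list(
    percentile = 5,
    auto_confirm = FALSE,
    wt_cutoff = 1e-6,
    rel_growth = 0.30,
    max_lumped_size = 5L,
    lumped_min_shared_genes = 1L,
    redox_cooccur = 0.8,
    gpr_mode = "union",
    direction_mode = "consensus-then-reversible",
    proton_water_ignore = TRUE,
    proton_ids = c("h", "H", "h+", "MNXM1", "proton", "PROTON"),
    water_ids = c("h2o", "H2O", "MNXM2", "water", "WATER"),
    compartment_aliases = c(
      c = "c", cytosol = "c", cytoplasm = "c", Cytosol = "c", Cytoplasm = "c",
      e = "e", extracellular = "e", external = "e", Extracellular = "e",
      extraorganism = "e",
      p = "p", periplasm = "p", Periplasm = "p",
      m = "m", mitochondrion = "m", mitochondria = "m", Mitochondrion = "m"),
    overlap_denominator = "union",
    flux_zero = 1e-9,
    fva_tol = 1e-9,
    seed = 1L
  )
}

currency_ids <- function(config) c(config$proton_ids, config$water_ids)
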