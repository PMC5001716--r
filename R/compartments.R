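#' Compartment-level reconciliation
#'
#' Transport identification and splitting, invalid-transport and
#' invalid-boundary detection, alternative compartmentalization, unknown
#' compartment resolution, and whole-compartment removal.
#'
#' @name compartment_reconciliation
NULL

# Transport criterion: the same metabolite id appears in >= 2 compartments
# within one reaction.
transported_ids <- function(rxn) {
  p <- met_key_parts(names(rxn$stoich))
  tab <- split(p$compartment, p$id)
  names(tab)[vapply(tab, function(x) length(unique(x)) >= 2, logical(1))]
}

#' Compartment connectivity graph
#'
#' Nodes are compartments; an (undirected) edge connects two compartments
#' directly linked by at least one transport reaction. Edge validity defaults
#' to valid and is meant to be reviewed by the user (see
#' [find_invalid_transport()]).
#'
#' @param model a `gsm_model`.
#' @return data.frame `comp_a`, `comp_b` (sorted), `n_reactions`, `valid`.
#' @export
compartment_graph <- function(model) {
  edges <- list()
  for (rxn in model$reactions) {
    ids <- transported_ids(rxn)
    if (!length(ids)) next
    p <- met_key_parts(names(rxn$stoich))
    for (id in ids) {
      comps <- sort(unique(p$compartment[p$id == id]))
      for (ai in seq_along(comps)) for (bi in seq_len(ai - 1L)) {
        key <- paste(comps[bi], comps[ai], sep = "|")
        edges[[key]] <- (edges[[key]] %||% 0L) + 1L
      }
    }
  }
  if (!length(edges))
    return(data.frame(comp_a = character(), comp_b = character(),
                      n_reactions = integer(), valid = logical()))
  parts <- strsplit(names(edges), "|", fixed = TRUE)
  data.frame(comp_a = vapply(parts, `[`, "", 1),
             comp_b = vapply(parts, `[`, "", 2),
             n_reactions = unlist(edges, use.names = FALSE),
             valid = TRUE, stringsAsFactors = FALSE)
}

#' Find alternative transport reactions
#'
#' For each metabolite present in two or more compartments, transport
#' reactions are the reactions where the metabolite appears on both sides of
#' the equation (in different compartments); two or more such reactions
#' moving the metabolite between the same two compartments form an
#' alternative-transport group.
#'
#' @param model a `gsm_model`.
#' @return list of groups: `metabolite` (id), `compartments` (pair),
#'   `members` (reaction ids).
#' @export
find_alternative_transport <- function(model) {
  idx <- list()
  for (rid in names(model$reactions)) {
    rxn <- model$reactions[[rid]]
    p <- met_key_parts(names(rxn$stoich))
    for (id in transported_ids(rxn)) {
      keys <- names(rxn$stoich)[p$id == id]
      sides <- sign(rxn$stoich[keys])
      if (length(unique(sides)) < 2) next       # must be on both sides
      comps <- sort(unique(p$compartment[p$id == id]))
      for (ai in seq_along(comps)) for (bi in seq_len(ai - 1L)) {
        key <- paste(id, comps[bi], comps[ai], sep = "|")
        idx[[key]] <- c(idx[[key]], rid)
      }
    }
  }
  out <- list()
  for (key in names(idx)) {
    if (length(idx[[key]]) < 2) next
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <- list(metabolite = parts[1],
                                    compartments = parts[2:3],
                                    members = sort(unique(idx[[key]])))
  }
  Filter(function(g) length(g$members) >= 2, out)
}

#' Find transport across user-flagged invalid compartment connections
#'
#' @param model a `gsm_model`.
#' @param graph a [compartment_graph()] whose `valid` column the user has
#'   edited; rows with `valid = FALSE` mark unconnected compartment pairs.
#' @return character vector of reaction ids containing metabolites from both
#'   compartments of any invalid edge (empty, with a message, when no edge is
#'   flagged).
#' @export
find_invalid_transport <- function(model, graph) {
  bad <- graph[!graph$valid, , drop = FALSE]
  if (!nrow(bad)) {
    message("no compartment connections flagged invalid; nothing to report")
    return(character())
  }
  hits <- character()
  for (rid in names(model$reactions)) {
    p <- met_key_parts(names(model$reactions[[rid]]$stoich))
    for (i in seq_len(nrow(bad))) {
      if (bad$comp_a[i] %in% p$compartment && bad$comp_b[i] %in% p$compartment)
        hits <- c(hits, rid)
    }
  }
  sort(unique(hits))
}

#' Split a direct transport reaction through an intermediate compartment
#'
#' Replaces a reaction moving metabolites between compartments A and C by an
#' A-B leg and a B-C leg with the same net reaction. The chemistry (protons,
#' ATP cost, any non-transported species) goes to the user-designated leg
#' (default the target-side leg, i.e. the one touching the non-source
#' compartment); the other leg is plain diffusion. Intermediate-compartment
#' metabolite instances are created as needed and the GPR is copied to both
#' legs.
#'
#' @param model a `gsm_model`.
#' @param reaction reaction id.
#' @param via intermediate compartment id (must exist in the model).
#' @param chemistry_leg `"target"` or `"source"`.
#' @param log optional `decision_log`.
#' @return list with `model`, `log`, `legs` (the two new reaction ids).
#' @export
split_transport <- function(model, reaction, via, chemistry_leg = "target",
                            log = NULL) {
  if (!(via %in% model$compartments$id))
    stop("intermediate compartment not in model: ", via)
  rxn <- model$reactions[[reaction]]
  if (is.null(rxn)) stop("no such reaction: ", reaction)
  ids <- transported_ids(rxn)
  if (!length(ids)) stop("reaction ", reaction, " is not a transport reaction")
  p <- met_key_parts(names(rxn$stoich))
  comps <- unique(p$compartment)
  if (length(comps) != 2) stop("can only split two-compartment transports")
  # source compartment: where the transported metabolite is consumed
  tkeys <- names(rxn$stoich)[p$id %in% ids]
  src <- unique(p$compartment[match(tkeys[rxn$stoich[tkeys] < 0], names(rxn$stoich))])[1]
  dst <- setdiff(comps, src)

  leg1 <- rxn$stoich[p$compartment == src]                  # A side
  leg2 <- rxn$stoich[p$compartment == dst]                  # C side
  mid <- numeric()
  for (id in ids) {
    key <- met_key(id, via)
    fi <- match(met_key(id, src), model$metabolites$key)
    model <- add_metabolite(model, id, via,
                            formula = model$metabolites$formula[fi],
                            sources = sources_of(model$metabolites$sources[fi]))
    amount <- abs(rxn$stoich[[met_key(id, src)]])
    mid[key] <- amount
  }
  chem_on_dst <- identical(chemistry_leg, "target")
  # transported species pass A -> B -> C; chemistry rides on one leg
  chem1 <- leg1[!(p$id[match(names(leg1), names(rxn$stoich))] %in% ids)]
  chem2 <- leg2[!(p$id[match(names(leg2), names(rxn$stoich))] %in% ids)]
  tr1 <- leg1[p$id[match(names(leg1), names(rxn$stoich))] %in% ids]
  tr2 <- leg2[p$id[match(names(leg2), names(rxn$stoich))] %in% ids]
  stA <- c(tr1, mid)
  stB <- c(stats::setNames(-mid, names(mid)), tr2)
  if (chem_on_dst) { stB <- c(stB, chem1, chem2) } else { stA <- c(stA, chem1, chem2) }
  stA <- cancel_stoich(stA); stB <- cancel_stoich(stB)
  id1 <- paste0(reaction, "_1"); id2 <- paste0(reaction, "_2")
  model$reactions[[reaction]] <- NULL
  model <- add_reaction(model, id1, stA, rxn$reversibility, gpr = rxn$gpr,
                        lb = rxn$lb, ub = rxn$ub, is_boundary = FALSE,
                        sources = rxn$sources)
  model <- add_reaction(model, id2, stB, rxn$reversibility, gpr = rxn$gpr,
                        lb = rxn$lb, ub = rxn$ub, is_boundary = FALSE,
                        sources = rxn$sources)
  if (!is.null(log))
    log <- log_append(log, "split_transport",
                      list(reaction = reaction, via = via,
                           chemistry_leg = chemistry_leg))
  list(model = model, log = log, legs = c(id1, id2))
}

#' Find identical reactions placed in different compartments
#'
#' Builds one stoichiometric matrix per compartment, restricted to reactions
#' whose metabolites all reside in that compartment, and reports column pairs
#' identical after stripping compartment tags. Transport reactions never
#' appear (they span compartments).
#'
#' @param model a `gsm_model`.
#' @return data.frame `rxn_a`, `rxn_b`, `comp_a`, `comp_b`.
#' @export
find_alt_compartmentalization <- function(model) {
  sigs <- list()
  for (rid in names(model$reactions)) {
    rxn <- model$reactions[[rid]]
    if (rxn$is_boundary) next
    p <- met_key_parts(names(rxn$stoich))
    if (length(unique(p$compartment)) != 1) next
    st <- stats::setNames(unname(rxn$stoich), p$id)
    sigs[[rid]] <- list(sig = stoich_signature(st), comp = p$compartment[1])
  }
  bysig <- split(names(sigs), vapply(sigs, function(s) s$sig, character(1)))
  out <- NULL
  for (g in bysig) {
    if (length(g) < 2) next
    for (ai in seq_along(g)) for (bi in seq_len(ai - 1L)) {
      ca <- sigs[[g[bi]]]$comp; cb <- sigs[[g[ai]]]$comp
      if (ca == cb) next
      out <- rbind(out, data.frame(rxn_a = g[bi], rxn_b = g[ai],
                                   comp_a = ca, comp_b = cb,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(rxn_a = character(), rxn_b = character(),
                               comp_a = character(), comp_b = character())
  else out
}

#' Propose compartments for unknown-compartment reactions
#'
#' For each reaction touching the unknown compartment, reactions of other
#' source models that match on all known-compartment metabolites (support
#' comparison) and involve the same metabolite id in a known compartment are
#' located; the matching instance's compartment is proposed.
#'
#' @param model merged `gsm_model`.
#' @return data.frame `reaction`, `metabolite` (unknown-compartment key),
#'   `proposed_compartment` (`NA` = unresolved), `matched_reaction`.
#' @export
resolve_unknown_compartment <- function(model) {
  unk <- UNKNOWN_COMPARTMENT
  out <- NULL
  rids <- names(model$reactions)
  parts <- lapply(model$reactions, function(r) met_key_parts(names(r$stoich)))
  for (rid in rids) {
    p <- parts[[rid]]
    if (!any(p$compartment == unk)) next
    known <- sort(names(model$reactions[[rid]]$stoich)[p$compartment != unk])
    for (uk in p$id[p$compartment == unk]) {
      prop <- NA_character_; matched <- NA_character_
      for (oid in rids) {
        if (oid == rid) next
        po <- parts[[oid]]
        if (any(po$compartment == unk)) next
        if (!length(setdiff(model$reactions[[oid]]$sources,
                            model$reactions[[rid]]$sources))) next
        okeys <- names(model$reactions[[oid]]$stoich)
        if (!(uk %in% po$id)) next
        ocomp <- po$compartment[po$id == uk][1]
        rest <- sort(setdiff(okeys, met_key(uk, ocomp)))
        if (identical(rest, known)) { prop <- ocomp; matched <- oid; break }
      }
      out <- rbind(out, data.frame(reaction = rid, metabolite = met_key(uk, unk),
                                   proposed_compartment = prop,
                                   matched_reaction = matched,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(reaction = character(), metabolite = character(),
                               proposed_compartment = character(),
                               matched_reaction = character())
  else out
}

#' Find boundary reactions on non-extracellular metabolites
#'
#' Boundary reactions exchange a metabolite with the environment and belong
#' on the extracellular compartment; a boundary reaction whose metabolite
#' lives elsewhere is a merging/lumping artefact.
#'
#' @param model a `gsm_model` with a designated extracellular compartment.
#' @return character vector of offending reaction ids.
#' @export
find_invalid_boundary <- function(model) {
  ext <- model$compartments$id[model$compartments$is_extracellular]
  if (!length(ext)) stop("no extracellular compartment designated")
  bad <- character()
  for (rid in names(model$reactions)) {
    rxn <- model$reactions[[rid]]
    if (!rxn$is_boundary) next
    p <- met_key_parts(names(rxn$stoich))
    if (!all(p$compartment %in% ext)) bad <- c(bad, rid)
  }
  bad
}

#' Repair an invalid boundary reaction
#'
#' Re-points the boundary reaction to the extracellular instance of its
#' metabolite (created if needed) and adds a transport reaction between the
#' extracellular and the original compartment, preserving the net exchange
#' capability.
#'
#' @param model a `gsm_model`.
#' @param reaction offending boundary reaction id.
#' @param log optional `decision_log`.
#' @return list with `model`, `log`, `transport` (new reaction id).
#' @export
repair_boundary_reaction <- function(model, reaction, log = NULL) {
  ext <- model$compartments$id[model$compartments$is_extracellular][1]
  rxn <- model$reactions[[reaction]]
  p <- met_key_parts(names(rxn$stoich))
  stopifnot(nrow(p) == 1)
  if (p$compartment == ext) return(list(model = model, log = log, transport = NA))
  i <- match(names(rxn$stoich), model$metabolites$key)
  model <- add_metabolite(model, p$id, ext,
                          formula = model$metabolites$formula[i],
                          sources = sources_of(model$metabolites$sources[i]))
  extkey <- met_key(p$id, ext)
  tid <- paste0("T_", p$id, "_", ext, "_", p$compartment)
  if (!(tid %in% names(model$reactions))) {
    st <- stats::setNames(c(-1, 1), c(extkey, names(rxn$stoich)))
    model <- add_reaction(model, tid, st, "reversible", sources = rxn$sources)
  }
  model$reactions[[reaction]]$stoich <-
    stats::setNames(unname(rxn$stoich), extkey)
  if (!is.null(log))
    log <- log_append(log, "repair_boundary", list(reaction = reaction))
  list(model = model, log = log, transport = tid)
}

#' Remove a compartment, folding its contents into a target compartment
#'
#' The four reaction categories: (i) reactions entirely inside the removed
#' compartment move to the target; (ii) pure transports between the two
#' cancel away and are removed; (iii) removed-target reactions with a
#' chemical conversion are kept with species re-pointed; (iv) reactions
#' linking the removed compartment to any other compartment are kept with
#' the removed-compartment species re-pointed. Operationally all four reduce
#' to re-pointing every removed-compartment metabolite instance to the
#' target with exact cancellation; fully cancelling reactions (category ii)
#' disappear. Orphaned metabolites and the compartment record are deleted.
#'
#' @param model a `gsm_model`.
#' @param rc compartment to remove.
#' @param tc target compartment.
#' @param log optional `decision_log`.
#' @return list with `model`, `log`, `removed_reactions`.
#' @export
remove_compartment <- function(model, rc, tc, log = NULL) {
  stopifnot(rc != tc, rc %in% model$compartments$id, tc %in% model$compartments$id)
  keys <- model$metabolites$key[model$metabolites$compartment == rc]
  dropped <- character()
  for (from in keys) {
    id <- met_key_parts(from)$id
    res <- repoint_metabolite(model, from, met_key(id, tc))
    model <- res$model
    dropped <- c(dropped, res$dropped)
  }
  model$compartments <- model$compartments[model$compartments$id != rc, , drop = FALSE]
  rownames(model$compartments) <- NULL
  model <- prune_orphan_metabolites(model)
  if (!is.null(log))
    log <- log_append(log, "remove_compartment", list(rc = rc, tc = tc))
  list(model = model, log = log, removed_reactions = dropped)
}
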