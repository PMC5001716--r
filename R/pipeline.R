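#' Naive union of models
#'
#' Combines compartments (by id), metabolites (by id + compartment), genes
#' and reactions of several models into one model with full provenance.
#' Reaction-id collisions between models are disambiguated with the source
#' tag unless the colliding reactions are identical, in which case sources
#' are united.
#'
#' @param models list of `gsm_model`s (compartments already harmonized).
#' @return a merged `gsm_model` tagged with the concatenated input tags.
#' @export
naive_union <- function(models) {
  out <- new_model(paste(vapply(models, function(m) m$tag, character(1)),
                         collapse = "+"))
  for (m in models) {
    for (i in seq_len(nrow(m$compartments))) {
      cp <- m$compartments[i, ]
      j <- match(cp$id, out$compartments$id)
      if (is.na(j)) out$compartments <- rbind(out$compartments, cp)
      else out$compartments$is_extracellular[j] <-
          out$compartments$is_extracellular[j] || cp$is_extracellular
    }
    for (i in seq_len(nrow(m$metabolites))) {
      mt <- m$metabolites[i, ]
      out <- add_metabolite(out, mt$id, mt$compartment, mt$formula,
                            sources_of(mt$sources))
    }
    for (i in seq_len(nrow(m$genes)))
      out <- add_gene(out, m$genes$id[i], sources_of(m$genes$sources[i]))
    for (rid in names(m$reactions)) {
      rxn <- m$reactions[[rid]]
      if (rid %in% names(out$reactions)) {
        prev <- out$reactions[[rid]]
        if (identical(stoich_signature(prev$stoich, directed = TRUE),
                      stoich_signature(rxn$stoich, directed = TRUE)) &&
            prev$reversibility == rxn$reversibility) {
          out$reactions[[rid]]$sources <- sort(unique(c(prev$sources, rxn$sources)))
          next
        }
        rid2 <- paste0(rid, "@", m$tag)
        out$reactions[[rid2]] <- rxn
        out$reactions[[rid2]]$id <- rid2
        next
      }
      out$reactions[[rid]] <- rxn
    }
    if (is.na(out$biomass_reaction_id) && !is.na(m$biomass_reaction_id))
      out$biomass_reaction_id <- m$biomass_reaction_id
  }
  rownames(out$compartments) <- NULL
  validate_model(out)
}

#' Build the Basic Consensus Model (BCM)
#'
#' The naive union of the (namespace-mapped, compartment-harmonized) input
#' models, with strictly identical net reactions across models merged
#' immediately (sources united); every merge is logged. The biomass reaction
#' of the chosen input model becomes the consensus biomass; other inputs'
#' biomass reactions are retained but disabled (bounds 0).
#'
#' @param models list of `gsm_model`s.
#' @param policy a [merge_policy()] (GPR/direction policies for the identical
#'   merge; protons/water are *not* ignored at this stage).
#' @param config tunables.
#' @param biomass_from index of the input model whose biomass reaction the
#'   consensus uses.
#' @return list with `model` (the BCM) and `log` (a started
#'   [new_decision_log()]).
#' @export
build_bcm <- function(models, policy = merge_policy(), config = default_config(),
                      biomass_from = 1L) {
  models <- lapply(models, harmonize_compartments,
                   aliases = config$compartment_aliases)
  log <- new_decision_log(models)
  bcm <- naive_union(models)
  strict <- policy; strict$proton_water_ignore <- FALSE
  for (grp in find_identical_net(bcm, strict, config)) {
    srcs <- unique(unlist(lapply(grp, function(rid) bcm$reactions[[rid]]$sources)))
    if (length(srcs) < 2) next
    res <- merge_reactions(bcm, grp, strict, config, log)
    if (res$status == "merged") { bcm <- res$model; log <- res$log }
  }
  bm <- models[[biomass_from]]$biomass_reaction_id
  if (!is.na(bm) && bm %in% names(bcm$reactions)) {
    bcm$biomass_reaction_id <- bm
    log <- log_append(log, "set_biomass", list(reaction = bm))
    for (m in models[-biomass_from]) {
      ob <- m$biomass_reaction_id
      if (!is.na(ob) && ob != bm && ob %in% names(bcm$reactions)) {
        bcm$reactions[[ob]]$lb <- 0
        bcm$reactions[[ob]]$ub <- 0
        log <- log_append(log, "set_bounds", list(reaction = ob, lb = 0, ub = 0))
      }
    }
  }
  list(model = bcm, log = log)
}

# Per-source, per-metabolite transport edges: for each metabolite id, the
# compartment pairs the tagged reactions transport it across.
tag_met_edges <- function(model, tag) {
  out <- list()
  for (rxn in model$reactions) {
    if (!(tag %in% rxn$sources)) next
    p <- met_key_parts(names(rxn$stoich))
    for (id in transported_ids(rxn)) {
      comps <- sort(unique(p$compartment[p$id == id]))
      for (ai in seq_along(comps)) for (bi in seq_len(ai - 1L))
        out[[id]] <- union(out[[id]], paste(comps[bi], comps[ai], sep = "|"))
    }
  }
  out
}

# Split a source's direct A-C transport of metabolite X when another source
# moves X through an intermediate compartment B (X edges A-B and B-C, no
# direct A-C edge for X).
harmonize_transport <- function(model, log = NULL) {
  tags <- sort(unique(unlist(lapply(model$reactions, function(r) r$sources))))
  edges <- lapply(stats::setNames(tags, tags), tag_met_edges, model = model)
  split_ids <- character()
  for (t in tags) {
    for (rid in names(model$reactions)) {
      rxn <- model$reactions[[rid]]
      if (is.null(rxn) || !(t %in% rxn$sources)) next
      ids <- transported_ids(rxn)
      if (!length(ids)) next
      p <- met_key_parts(names(rxn$stoich))
      comps <- sort(unique(p$compartment))
      if (length(comps) != 2) next
      e <- paste(comps[1], comps[2], sep = "|")
      via <- NULL
      for (o in setdiff(tags, rxn$sources)) {
        for (id in ids) {
          oe <- edges[[o]][[id]]
          if (is.null(oe) || e %in% oe) next
          oc <- strsplit(oe, "|", fixed = TRUE)
          nbrs <- function(x) unique(unlist(lapply(oc, function(pp)
            if (x %in% pp) setdiff(pp, x) else NULL)))
          cand <- setdiff(intersect(nbrs(comps[1]), nbrs(comps[2])), comps)
          if (length(cand)) { via <- sort(cand)[1]; break }
        }
        if (!is.null(via)) break
      }
      if (is.null(via)) next
      res <- split_transport(model, rid, via, log = log)
      model <- res$model; log <- res$log
      split_ids <- c(split_ids, rid)
    }
  }
  list(model = model, log = log, split = split_ids)
}

#' Automatic refinement: BCM to RCM
#'
#' The four-step automatic reconciliation: (1) network-context metabolite
#' matching and merge of confirmed matches; (2) transport splitting to
#' harmonize compartment usage across sources; (3) merge of practically
#' identical net reactions (protons/water ignored) under the direction and
#' GPR policies; (4) merge of alternative-stoichiometry groups where exactly
#' one member is elementally balanced. Every action is appended to the log;
#' items without an automatic resolution are returned as pending, never
#' silently dropped.
#'
#' @param bcm the Basic Consensus Model (see [build_bcm()]).
#' @param policy a [merge_policy()].
#' @param config tunables.
#' @param log the decision log started by [build_bcm()].
#' @param confirmed_matches optional data.frame (`met_a`, `met_b`) of
#'   user-confirmed metabolite matches; when `NULL`, proposals from
#'   [threshold_matches()] are applied automatically (formula conflicts are
#'   still held).
#' @param skip_matching leave out step 1 (ablation experiments).
#' @return list with `model` (the RCM), `log`, and `pending` (data.frame
#'   `class`, `member_ids`, `status`).
#' @export
auto_refine <- function(bcm, policy = merge_policy(), config = default_config(),
                        log = NULL, confirmed_matches = NULL,
                        skip_matching = FALSE) {
  pending <- list()
  note_pending <- function(class, ids)
    pending[[length(pending) + 1L]] <<- data.frame(
      class = class, member_ids = paste(ids, collapse = ";"),
      status = "pending", stringsAsFactors = FALSE)

  # step 1: metabolite matching
  if (!skip_matching) {
    proposals <- confirmed_matches
    if (is.null(proposals)) {
      ctx <- build_context(bcm)
      sc <- score_matches(ctx)
      if (length(sc$shared_scores) && nrow(sc$candidates))
        proposals <- threshold_matches(sc, config = config)
    }
    if (!is.null(proposals) && nrow(proposals)) {
      mm <- merge_matched(bcm, proposals, log = log)
      bcm <- mm$model; log <- mm$log
      if (!is.null(mm$held))
        for (i in seq_len(nrow(mm$held)))
          note_pending("metabolite_match", c(mm$held$met_a[i], mm$held$met_b[i]))
    }
  }

  # step 2: transport splitting
  ht <- harmonize_transport(bcm, log = log)
  bcm <- ht$model; log <- ht$log

  # step 3: practically identical net reactions
  for (grp in find_identical_net(bcm, policy, config)) {
    res <- merge_reactions(bcm, grp, policy, config, log)
    if (res$status == "merged") { bcm <- res$model; log <- res$log }
    else note_pending("identical_net_gpr", grp)
  }

  # step 4: alternative stoichiometries, unique balanced member survives
  for (grp in find_alt_stoichiometry(bcm, policy, config)) {
    if (grp$resolution == "auto") {
      entry <- list(op = "keep_reaction",
                    args = list(members = as.list(grp$members), keep = grp$keep))
      bcm <- apply_decision(bcm, entry)
      if (!is.null(log)) log <- log_append(log, entry$op, entry$args)
    } else {
      note_pending("alt_stoichiometry", grp$members)
    }
  }

  pending <- if (length(pending)) do.call(rbind, pending) else
    data.frame(class = character(), member_ids = character(), status = character())
  list(model = validate_model(bcm), log = log, pending = pending)
}

#' Classify reactions as consensus or unique
#'
#' Consensus reactions carry two or more source tags; unique reactions are
#' binned by the number of distinct inconsistency classes that reference
#' them in the supplied reports (none / single / multiple — the detection
#' methods are not mutually exclusive).
#'
#' @param model a `gsm_model`.
#' @param reports named list: class name -> character vector of reaction ids
#'   referenced by that class (as produced by the `find_*` detectors).
#' @return list with `per_reaction` (data.frame `reaction`, `category`) and
#'   `counts` (named vector over consensus / unique_none / unique_single /
#'   unique_multiple) and `consensus_fraction`.
#' @export
classify_reactions <- function(model, reports = list()) {
  rids <- names(model$reactions)
  n_sources <- vapply(model$reactions, function(r) length(r$sources), integer(1))
  n_classes <- stats::setNames(integer(length(rids)), rids)
  for (cls in names(reports)) {
    ids <- intersect(unique(reports[[cls]]), rids)
    n_classes[ids] <- n_classes[ids] + 1L
  }
  category <- ifelse(n_sources >= 2, "consensus",
                     ifelse(n_classes == 0, "unique_none",
                            ifelse(n_classes == 1, "unique_single", "unique_multiple")))
  counts <- c(consensus = sum(category == "consensus"),
              unique_none = sum(category == "unique_none"),
              unique_single = sum(category == "unique_single"),
              unique_multiple = sum(category == "unique_multiple"))
  list(per_reaction = data.frame(reaction = rids, category = unname(category),
                                 stringsAsFactors = FALSE),
       counts = counts,
       consensus_fraction = if (length(rids)) unname(counts["consensus"]) / length(rids) else 0)
}

#' Inconsistency reports for a merged model
#'
#' Convenience wrapper running all automatic detectors and returning the
#' class -> reaction-id mapping [classify_reactions()] consumes.
#'
#' @param model merged `gsm_model`.
#' @param policy,config see [find_identical_net()].
#' @return named list of character vectors.
#' @export
inconsistency_reports <- function(model, policy = merge_policy(),
                                  config = default_config()) {
  nested <- find_nested(model, policy, config)
  alt_tr <- find_alternative_transport(model)
  list(
    identical_net = unique(unlist(find_identical_net(model, policy, config))),
    alt_stoichiometry = unique(unlist(lapply(
      find_alt_stoichiometry(model, policy, config), function(g) g$members))),
    redox_variant = unique(unlist(lapply(
      find_redox_variants(model, policy = policy, config = config),
      function(g) g$members))),
    nested = unique(c(nested$inner, nested$outer)),
    alt_transport = unique(unlist(lapply(alt_tr, function(g) g$members))),
    alt_compartmentalization = {
      ac <- find_alt_compartmentalization(model)
      unique(c(ac$rxn_a, ac$rxn_b))
    }
  )
}
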