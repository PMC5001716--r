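#' Identifier-mapping tables
#'
#' Offline application of a canonical-namespace mapping (MNXref-style) to a
#' model. Rows map a (source namespace, source id) pair to a canonical
#' metabolite or reaction id; the table is a local file, no web service is
#' involved.
#'
#' @param path TSV with header `source_ns  source_id  canonical_id  description`.
#' @return a `mapping_table` data.frame.
#' @export
read_mapping_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("source_ns", "source_id", "canonical_id") %in% names(tab)))
  if (!"description" %in% names(tab)) tab$description <- ""
  if (anyDuplicated(tab[c("source_ns", "source_id")]))
    stop("mapping table has duplicate (source_ns, source_id) keys")
  if (any(!nzchar(tab$canonical_id))) stop("mapping table has empty canonical ids")
  class(tab) <- c("mapping_table", "data.frame")
  tab
}

#' Construct a mapping table in memory
#' @param source_id,canonical_id character vectors (recycled `source_ns`,
#'   `description` optional).
#' @return a `mapping_table`.
#' @export
mapping_table <- function(source_id, canonical_id, source_ns = "src", description = "") {
  n <- length(source_id)
  tab <- data.frame(source_ns = rep_len(source_ns, n), source_id = source_id,
                    canonical_id = canonical_id,
                    description = rep_len(description, n),
                    stringsAsFactors = FALSE)
  class(tab) <- c("mapping_table", "data.frame")
  tab
}

#' Harmonize compartment ids through an alias map
#'
#' Renames compartments (and all metabolite keys) to canonical short ids so
#' models naming the cytosol `"c"`, `"cytosol"` or `"Cytoplasm"` become
#' comparable. Aliases default to [default_config()]'s map; unknown
#' compartment ids are left untouched.
#'
#' @param model a `gsm_model`.
#' @param aliases named character vector alias -> canonical id.
#' @return the updated model.
#' @export
harmonize_compartments <- function(model, aliases = default_config()$compartment_aliases) {
  for (i in seq_len(nrow(model$compartments))) {
    old <- model$compartments$id[i]
    new <- unname(aliases[old])
    if (is.na(new) || identical(new, old)) next
    if (new %in% model$compartments$id[-i])
      stop("compartment alias collision: ", old, " -> ", new)
    model$compartments$id[i] <- new
    sel <- model$metabolites$compartment == old
    model$metabolites$compartment[sel] <- new
    oldkeys <- model$metabolites$key[sel]
    newkeys <- met_key(model$metabolites$id[sel], new)
    model$metabolites$key[sel] <- newkeys
    ren <- stats::setNames(newkeys, oldkeys)
    for (rid in names(model$reactions)) {
      st <- model$reactions[[rid]]$stoich
      hit <- names(st) %in% oldkeys
      if (any(hit)) {
        names(st)[hit] <- unname(ren[names(st)[hit]])
        model$reactions[[rid]]$stoich <- st[order(names(st), method = "radix")]
      }
    }
  }
  model
}

#' Apply an identifier mapping to a model
#'
#' Every metabolite (and reaction) id found in the table is replaced by its
#' canonical id; ids without a mapping are prefixed with the model tag to
#' guarantee global uniqueness across models. Two metabolites of the same
#' model mapping to the same (canonical id, compartment) are merged with
#' stoichiometries re-pointed — unless they co-occur in a reaction, in which
#' case the pair is flagged for mandatory review instead. A review table from
#' a previous run may be passed back with `status` edited to `rejected` to
#' keep the original (tag-prefixed) id.
#'
#' @param model a `gsm_model`.
#' @param table a `mapping_table`.
#' @param review optional edited `MappingReview` data.frame from a previous run.
#' @return list with the updated `model` and the `review` data.frame
#'   (`old_id`, `proposed`, `status` in `accepted|rejected|unmapped|conflict`).
#' @export
apply_mapping <- function(model, table, review = NULL) {
  lookup <- stats::setNames(table$canonical_id, table$source_id)
  rejected <- character()
  if (!is.null(review))
    rejected <- review$old_id[review$status == "rejected"]

  ids <- unique(model$metabolites$id)
  proposed <- unname(lookup[ids])
  status <- ifelse(is.na(proposed), "unmapped",
                   ifelse(ids %in% rejected, "rejected", "accepted"))
  proposed[is.na(proposed)] <- ""

  # conflicts: two same-model metabolites of one reaction mapping to one id
  conflict_ids <- character()
  eff <- function(id) {
    i <- match(id, ids)
    if (status[i] == "accepted") proposed[i] else id
  }
  for (rxn in model$reactions) {
    parts <- met_key_parts(names(rxn$stoich))
    eff_ids <- paste0(vapply(parts$id, eff, character(1)), "@", parts$compartment)
    dup <- duplicated(eff_ids) | duplicated(eff_ids, fromLast = TRUE)
    if (any(dup)) conflict_ids <- c(conflict_ids, unique(parts$id[dup]))
  }
  conflict_ids <- intersect(unique(conflict_ids), ids[status == "accepted"])
  status[ids %in% conflict_ids] <- "conflict"

  # rename: accepted -> canonical; everything else tag-prefixed (once)
  prefix <- paste0(model$tag, "_")
  new_id <- character(length(ids))
  for (i in seq_along(ids)) {
    new_id[i] <- if (status[i] == "accepted") proposed[i]
    else if (startsWith(ids[i], prefix) || ids[i] %in% table$canonical_id) ids[i]
    else paste0(prefix, ids[i])
  }
  ren <- stats::setNames(new_id, ids)

  pending <- model$metabolites$key[ren[model$metabolites$id] != model$metabolites$id]
  for (from in pending) {
    i <- match(from, model$metabolites$key)
    if (is.na(i)) next                       # already folded into another instance
    to <- met_key(ren[[model$metabolites$id[i]]], model$metabolites$compartment[i])
    if (to %in% model$metabolites$key) {
      model <- repoint_metabolite(model, from, to)$model
    } else {
      model$metabolites$id[i] <- sub("\\[.*$", "", to)
      model$metabolites$key[i] <- to
      for (rid in names(model$reactions)) {
        st <- model$reactions[[rid]]$stoich
        hit <- names(st) == from
        if (any(hit)) {
          names(st)[hit] <- to
          model$reactions[[rid]]$stoich <- st[order(names(st), method = "radix")]
        }
      }
    }
  }

  # reaction id mapping
  for (rid in names(model$reactions)) {
    can <- unname(lookup[rid])
    if (!is.na(can) && !(can %in% names(model$reactions))) {
      rxn <- model$reactions[[rid]]
      rxn$id <- can
      model$reactions[[rid]] <- NULL
      model$reactions[[can]] <- rxn
    }
  }

  out_review <- data.frame(old_id = ids, proposed = proposed, status = status,
                           stringsAsFactors = FALSE)
  list(model = validate_model(model), review = out_review)
}

#' Shared-entity statistics for two or more models
#'
#' Genes are matched by id, metabolite instances by (id, compartment) after
#' compartment harmonization, and reactions by identical direction-insensitive
#' net stoichiometry over matched metabolites. The shared fraction is
#' |intersection| / |union| by default; `config$overlap_denominator =
#' "min"` switches to |intersection| / min(|A|, |B|). Metabolites are
#' additionally counted as unique compounds (compartment-free ids).
#'
#' @param models list of >= 2 `gsm_model`s.
#' @param config tunables.
#' @return data.frame with columns `entity`, `shared`, `union`, `fraction`.
#' @export
overlap_report <- function(models, config = default_config()) {
  stopifnot(length(models) >= 2)
  models <- lapply(models, harmonize_compartments, aliases = config$compartment_aliases)
  sets <- list(
    genes = lapply(models, function(m) unique(m$genes$id)),
    metabolites = lapply(models, function(m) unique(m$metabolites$key)),
    metabolite_compounds = lapply(models, function(m) unique(m$metabolites$id)),
    reactions = lapply(models, function(m) {
      unique(vapply(m$reactions, function(r)
        stoich_signature(cancel_stoich(r$stoich)), character(1)))
    })
  )
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    inter <- Reduce(intersect, s)
    uni <- Reduce(union, s)
    denom <- if (identical(config$overlap_denominator, "min"))
      min(lengths(s)) else length(uni)
    data.frame(entity = nm, shared = length(inter), union = length(uni),
               fraction = if (denom > 0) length(inter) / denom else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
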