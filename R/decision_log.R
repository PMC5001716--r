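#' Replayable decision logs
#'
#' Every automatic or user resolution applied during consensus-model
#' construction is recorded as an ordered log entry. Replaying the log on the
#' same input models reproduces the output model exactly; entries are ordered
#' by sequence number, never wall-clock time. Input identity is checked via a
#' digest of the inputs' entity ids.
#'
#' @name decision_log
NULL

#' Create a decision log for a set of input models
#' @param models list of `gsm_model` inputs, in order.
#' @return a `decision_log` object.
#' @export
new_decision_log <- function(models) {
  structure(list(
    digest = vapply(models, model_digest, character(1)),
    entries = list()
  ), class = "decision_log")
}

#' @export
print.decision_log <- function(x, ...) {
  cat(sprintf("<decision_log> %d entries over %d input models\n",
              length(x$entries), length(x$digest)))
  invisible(x)
}

# FNV-1a over the model's sorted entity ids; stable across sessions.
model_digest <- function(model) {
  ids <- c(sort(model$metabolites$key), sort(names(model$reactions)),
           sort(model$genes$id), sort(model$compartments$id))
  fnv1a(paste(ids, collapse = "\n"))
}

fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so every intermediate stays exactly representable in a double
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Append an entry to a decision log
#' @param log a `decision_log`.
#' @param op operation name (dispatched by [apply_decision()]).
#' @param args named list of operation arguments (entity ids, resolutions).
#' @param origin `"auto"` or `"user"`.
#' @return the updated log.
#' @export
log_append <- function(log, op, args, origin = "auto") {
  log$entries[[length(log$entries) + 1L]] <- list(
    seq = length(log$entries) + 1L, op = op, args = args, origin = origin)
  log
}

#' Serialize / read a decision log as line-delimited JSON
#' @param log a `decision_log`.
#' @param path file path.
#' @return `path` (write) or the log (read).
#' @export
write_decision_log <- function(log, path) {
  header <- jsonlite::toJSON(list(type = "decision_log", digest = as.list(log$digest)),
                             auto_unbox = TRUE)
  lines <- vapply(log$entries, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' @rdname write_decision_log
#' @export
read_decision_log <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  entries <- lapply(lines[-1], function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  entries <- lapply(entries, function(e) {
    e$args <- as.list(e$args)
    e
  })
  structure(list(digest = unlist(header$digest), entries = entries),
            class = "decision_log")
}

#' Apply a single logged decision to a model
#'
#' The shared executor behind the pipeline and [replay()]: both record-and-run
#' and replay funnel through this function, which guarantees that replays
#' reproduce the original output.
#'
#' @param model a `gsm_model`.
#' @param entry a log entry (`op`, `args`).
#' @return the updated model.
#' @export
apply_decision <- function(model, entry) {
  a <- entry$args
  switch(entry$op,
    merge_metabolite = repoint_metabolite(model, a$from, a$to)$model,
    merge_reactions = apply_merge_reactions(model, a),
    keep_reaction = apply_keep_reaction(model, a),
    split_transport = split_transport(model, a$reaction, a$via,
                                      chemistry_leg = a$chemistry_leg %||% "target",
                                      log = NULL)$model,
    remove_compartment = remove_compartment(model, a$rc, a$tc, log = NULL)$model,
    repair_boundary = repair_boundary_reaction(model, a$reaction, log = NULL)$model,
    set_bounds = {
      model$reactions[[a$reaction]]$lb <- a$lb
      model$reactions[[a$reaction]]$ub <- a$ub
      model
    },
    set_biomass = { model$biomass_reaction_id <- a$reaction; model },
    note = model,
    stop("unknown decision op: ", entry$op)
  )
}

apply_merge_reactions <- function(model, a) {
  survivor <- a$survivor
  members <- setdiff(unlist(a$members), survivor)
  rxn <- model$reactions[[survivor]]
  for (rid in members) {
    rxn$sources <- sort(unique(c(rxn$sources, model$reactions[[rid]]$sources)))
    model$reactions[[rid]] <- NULL
  }
  rxn$reversibility <- a$reversibility
  b <- default_bounds(a$reversibility)
  rxn$lb <- a$lb %||% b[1]
  rxn$ub <- a$ub %||% b[2]
  if (!is.null(a$gpr) && nzchar(a$gpr)) rxn$gpr <- gpr_parse(a$gpr)
  model$reactions[[survivor]] <- rxn
  prune_orphan_metabolites(model)
}

apply_keep_reaction <- function(model, a) {
  keep <- a$keep
  drop <- setdiff(unlist(a$members), keep)
  rxn <- model$reactions[[keep]]
  for (rid in drop) {
    rxn$sources <- sort(unique(c(rxn$sources, model$reactions[[rid]]$sources)))
    model$reactions[[rid]] <- NULL
  }
  model$reactions[[keep]] <- rxn
  prune_orphan_metabolites(model)
}

#' Replay a decision log on input models
#'
#' Rebuilds the output model by folding the log's entries over the naive union
#' of the inputs. Inputs are verified against the digests stored at log
#' creation; a mismatch raises a stale-log error.
#'
#' @param log a `decision_log`.
#' @param models list of input `gsm_model`s (same order as at recording).
#' @param policy a [merge_policy()] used for the initial union's
#'   identical-reaction merge (replayed runs record those merges as entries,
#'   so the union here is naive).
#' @return the reconstructed `gsm_model`.
#' @export
replay <- function(log, models) {
  digests <- vapply(models, model_digest, character(1))
  if (length(digests) != length(log$digest) || !all(digests == log$digest)) {
    bad <- which(digests != log$digest)
    stop("stale decision log: input model(s) ", paste(bad, collapse = ", "),
         " differ from the models the log was recorded on")
  }
  model <- naive_union(models)
  for (entry in log$entries) model <- apply_decision(model, entry)
  model
}
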