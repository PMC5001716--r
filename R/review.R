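#' Apply batch answers to pending inconsistencies
#'
#' The automatic pipeline leaves genuinely ambiguous cases pending. This
#' function applies a user-edited answers table headlessly: together with the
#' decision log it makes a run fully reproducible without interaction.
#'
#' Answers are matched to pending rows by `class` and `member_ids`. Decisions:
#' `accept` (merge a metabolite match pair, or merge a reaction group with the
#' union GPR), `reject` (drop the pending item), or `choose:<id>` (keep one
#' member of an alternative-stoichiometry group). Malformed rows are reported
#' with their line number and skipped; the run continues.
#'
#' @param model a `gsm_model` (typically the RCM with pending items).
#' @param pending the `pending` data.frame from [auto_refine()].
#' @param answers data.frame with columns `class`, `member_ids`, `decision`,
#'   or a path to such a TSV.
#' @param policy,config see [merge_reactions()].
#' @param log optional `decision_log`.
#' @return list with `model`, `log`, `resolved` (answered rows) and
#'   `remaining` (still-pending rows).
#' @export
review_answers <- function(model, pending, answers, policy = merge_policy(),
                           config = default_config(), log = NULL) {
  if (is.character(answers))
    answers <- utils::read.delim(answers, stringsAsFactors = FALSE,
                                 colClasses = "character")
  resolved <- logical(nrow(pending))
  for (i in seq_len(nrow(answers))) {
    row <- answers[i, ]
    if (!all(c("class", "member_ids", "decision") %in% names(answers)) ||
        is.na(row$decision) || !nzchar(row$decision)) {
      warning("answers row ", i, " malformed; skipped")
      next
    }
    hit <- which(pending$class == row$class & pending$member_ids == row$member_ids &
                   !resolved)
    if (!length(hit)) { warning("answers row ", i, " matches no pending item"); next }
    members <- strsplit(row$member_ids, ";")[[1]]
    dec <- row$decision
    ok <- TRUE
    if (dec == "reject") {
      # keep the model as is
    } else if (dec == "accept" && row$class == "metabolite_match") {
      to <- min(members); from <- setdiff(members, to)[1]
      model <- repoint_metabolite(model, from, to)$model
      if (!is.null(log))
        log <- log_append(log, "merge_metabolite", list(from = from, to = to),
                          origin = "user")
    } else if (dec == "accept") {
      res <- merge_reactions(model, members, policy, config, log, force = TRUE)
      if (res$status == "merged") { model <- res$model; log <- res$log }
      else ok <- FALSE
    } else if (startsWith(dec, "choose:")) {
      keep <- sub("^choose:", "", dec)
      if (!(keep %in% members)) { warning("answers row ", i, ": unknown member"); next }
      entry <- list(op = "keep_reaction", args = list(members = as.list(members),
                                                      keep = keep))
      model <- apply_decision(model, entry)
      if (!is.null(log)) log <- log_append(log, entry$op, entry$args, origin = "user")
    } else {
      warning("answers row ", i, ": unknown decision '", dec, "'; skipped")
      next
    }
    if (ok) resolved[hit[1]] <- TRUE
  }
  list(model = model, log = log,
       resolved = pending[resolved, , drop = FALSE],
       remaining = pending[!resolved, , drop = FALSE])
}
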