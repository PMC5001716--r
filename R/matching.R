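#' Network-context attribute matrix
#'
#' Characterises each metabolite by the metabolites and genes that share a
#' reaction with it. A boolean metabolite-to-metabolite co-occurrence block is
#' stacked on a boolean gene-to-metabolite block, and every row (attribute) is
#' divided by its sum so its entries sum to 1: a connection contributes more
#' the rarer (the more defining) it is. Rows are restricted to entities
#' present in both models — only shared context can identify matches — and
#' columns to the metabolites still unmatched, plus, for every shared
#' metabolite, one column per source model used to calibrate the score
#' threshold.
#'
#' Columns are computed per source model: the context of metabolite `j` in
#' model `t` uses only reactions tagged with `t`. Columns with all-zero
#' context are flagged `no_signal` and excluded from candidate scoring.
#'
#' @param merged a merged `gsm_model` whose reactions carry source tags (see
#'   [build_bcm()]).
#' @param hidden_rows attribute row names to hide (network-degradation
#'   harness); `NULL` for none.
#' @return an `attribute_matrix`: list with `M` (rows = attributes, columns =
#'   (metabolite, model) instances), `cols` (data.frame `key`, `model`,
#'   `shared`, `no_signal`).
#' @export
build_context <- function(merged, hidden_rows = NULL) {
  if (is.null(hidden_rows)) hidden_rows <- attr(merged, "hidden_context_rows")
  tags <- sort(unique(unlist(lapply(merged$reactions, function(r) r$sources))))
  if (length(tags) < 2) stop("merged model must carry at least two source tags")
  keys <- merged$metabolites$key
  genes <- merged$genes$id

  met_tags <- stats::setNames(vector("list", length(keys)), keys)
  for (rxn in merged$reactions) {
    for (k in names(rxn$stoich))
      met_tags[[k]] <- union(met_tags[[k]], rxn$sources)
  }
  shared_mets <- keys[vapply(met_tags, function(x) length(x) >= 2, logical(1))]
  gene_tags <- lapply(stats::setNames(merged$genes$sources, genes), sources_of)
  shared_genes <- genes[vapply(gene_tags, function(x) length(x) >= 2, logical(1))]

  col_key <- character(); col_model <- character()
  for (k in keys) {
    for (t in met_tags[[k]]) { col_key <- c(col_key, k); col_model <- c(col_model, t) }
  }
  rows <- c(paste0("m:", keys), paste0("g:", genes))
  M <- matrix(0, nrow = length(rows), ncol = length(col_key),
              dimnames = list(rows, paste0(col_key, "::", col_model)))

  for (rxn in merged$reactions) {
    mk <- names(rxn$stoich)
    gk <- gpr_genes(rxn$gpr)
    for (t in rxn$sources) {
      cols <- match(paste0(mk, "::", t), colnames(M))
      cols <- cols[!is.na(cols)]
      for (cl in cols) {
        target <- col_key[cl]
        others <- setdiff(mk, target)
        if (length(others)) M[paste0("m:", others), cl] <- 1
        if (length(gk)) M[paste0("g:", gk), cl] <- 1
      }
    }
  }

  # row normalization before any restriction: each attribute row sums to 1
  rs <- rowSums(M)
  keep <- rs > 0
  M <- M[keep, , drop = FALSE] / rs[keep]

  keep_rows <- rownames(M) %in% c(paste0("m:", shared_mets), paste0("g:", shared_genes))
  M <- M[keep_rows, , drop = FALSE]
  if (!is.null(hidden_rows)) M <- M[!(rownames(M) %in% hidden_rows), , drop = FALSE]

  cols <- data.frame(key = col_key, model = col_model,
                     shared = col_key %in% shared_mets,
                     stringsAsFactors = FALSE)
  cols$no_signal <- apply(M, 2, function(v) sum(v != 0) == 0 || stats::sd(v) == 0)
  structure(list(M = M, cols = cols), class = "attribute_matrix")
}

#' Pearson context-similarity scores for cross-model metabolite pairs
#'
#' Scores a pair of metabolites by the Pearson correlation of their attribute
#' columns. Candidate pairs are non-shared metabolites from different source
#' models in the same compartment; pairs involving a no-signal column are
#' excluded (not scored 0). Shared metabolites are scored between their own
#' two per-model columns, providing the calibration distribution for
#' [threshold_matches()].
#'
#' @param ctx an `attribute_matrix` from [build_context()].
#' @return list with `candidates` (data.frame `met_a`, `met_b`, `model_a`,
#'   `model_b`, `score`) and `shared_scores` (named numeric, one score per
#'   shared metabolite with usable signal in both models).
#' @export
score_matches <- function(ctx) {
  M <- ctx$M; cols <- ctx$cols
  usable <- !cols$no_signal
  comp <- met_key_parts(cols$key)$compartment

  cand_idx <- which(!cols$shared & usable)
  out <- list(); n <- 0L
  if (length(cand_idx) >= 2) {
    for (ai in seq_along(cand_idx)) {
      i <- cand_idx[ai]
      for (bi in seq_len(ai - 1L)) {
        j <- cand_idx[bi]
        if (cols$model[i] == cols$model[j]) next
        if (comp[i] != comp[j]) next
        n <- n + 1L
        out[[n]] <- data.frame(
          met_a = cols$key[min(i, j)], met_b = cols$key[max(i, j)],
          model_a = cols$model[min(i, j)], model_b = cols$model[max(i, j)],
          score = stats::cor(M[, i], M[, j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- if (n) do.call(rbind, out) else
    data.frame(met_a = character(), met_b = character(), model_a = character(),
               model_b = character(), score = numeric(), stringsAsFactors = FALSE)

  shared_scores <- numeric(0)
  for (k in unique(cols$key[cols$shared])) {
    idx <- which(cols$key == k & usable)
    if (length(idx) >= 2) {
      shared_scores[k] <- stats::cor(M[, idx[1]], M[, idx[2]])
    }
  }
  list(candidates = candidates, shared_scores = shared_scores)
}

#' Threshold candidate scores against the shared-metabolite distribution
#'
#' The minimal score for a match proposal is a user-defined percentile of the
#' scores of metabolites known to be shared between the models. Proposals are
#' assigned greedily one-to-one by descending score, ties broken
#' lexicographically by id.
#'
#' @param scores output of [score_matches()].
#' @param percentile percentile (0-100) of the shared-score distribution;
#'   default from `config`.
#' @param config tunables.
#' @return data.frame of match proposals: `met_a`, `met_b`, `score`,
#'   `threshold`, `status` (`"proposed"`).
#' @export
threshold_matches <- function(scores, percentile = NULL, config = default_config()) {
  if (is.null(percentile)) percentile <- config$percentile
  if (!length(scores$shared_scores))
    stop("no shared metabolites between the models: run the namespace mapping first")
  thr <- stats::quantile(scores$shared_scores, probs = percentile / 100,
                         names = FALSE, type = 7)
  cand <- scores$candidates
  cand <- cand[!is.na(cand$score) & cand$score >= thr, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$met_a, cand$met_b), , drop = FALSE]
  used <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$met_a[i] %in% used || cand$met_b[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, cand$met_a[i], cand$met_b[i])
  }
  props <- cand[keep, c("met_a", "met_b", "score"), drop = FALSE]
  if (nrow(props)) { props$threshold <- thr; props$status <- "proposed" }
  else { props$threshold <- numeric(); props$status <- character() }
  rownames(props) <- NULL
  props
}

#' Merge confirmed metabolite matches into the model
#'
#' Each confirmed pair is collapsed to a single metabolite instance (the
#' lexicographically smaller id survives); stoichiometries are re-pointed and
#' exact same-side/other-side cancellations applied. When both members carry
#' an elemental formula and the formulas disagree (different granularity,
#' polymer subunit counts), the pair is *not* merged automatically — it is
#' returned as `held` for user confirmation, since merging could violate mass
#' conservation.
#'
#' @param model a `gsm_model`.
#' @param proposals data.frame with `met_a`, `met_b` (metabolite keys);
#'   usually confirmed output of [threshold_matches()].
#' @param log optional `decision_log` to append merge entries to.
#' @return list with `model`, `log`, `merged` (pairs applied) and `held`
#'   (pairs needing confirmation, with reason).
#' @export
merge_matched <- function(model, proposals, log = NULL) {
  merged <- list(); held <- list()
  for (i in seq_len(nrow(proposals))) {
    a <- proposals$met_a[i]; b <- proposals$met_b[i]
    ia <- match(a, model$metabolites$key); ib <- match(b, model$metabolites$key)
    if (is.na(ia) || is.na(ib)) next
    fa <- model$metabolites$formula[ia]; fb <- model$metabolites$formula[ib]
    if (!is.na(fa) && !is.na(fb) && !identical(parse_formula(fa), parse_formula(fb))) {
      held[[length(held) + 1L]] <- data.frame(met_a = a, met_b = b,
                                              reason = "formula mismatch",
                                              stringsAsFactors = FALSE)
      next
    }
    to <- if (a <= b) a else b
    from <- if (a <= b) b else a
    model <- repoint_metabolite(model, from, to)$model
    if (!is.null(log))
      log <- log_append(log, "merge_metabolite", list(from = from, to = to))
    merged[[length(merged) + 1L]] <- data.frame(met_a = a, met_b = b,
                                                stringsAsFactors = FALSE)
  }
  list(model = model,
       log = log,
       merged = if (length(merged)) do.call(rbind, merged) else NULL,
       held = if (length(held)) do.call(rbind, held) else NULL)
}

#' Degradation benchmark for the metabolite matcher
#'
#' Hides increasing fractions of the attribute rows (the network information)
#' before scoring, and summarises how well known-identical pairs separate
#' from known-different pairs at the calibrated threshold. Ground truth is
#' the `truth$synonyms` table of a fixture pair (see [generate_fixtures()]).
#'
#' @param merged merged model with source tags, containing the planted
#'   synonym instances unmerged.
#' @param truth_pairs data.frame `met_a`, `met_b` of known-identical keys.
#' @param fractions numeric vector of row-discard fractions in [0, 1].
#' @param repeats random repeats per fraction.
#' @param seed RNG seed; all draws derive from it.
#' @param config tunables.
#' @return data.frame `fraction`, `sensitivity`, `specificity`, `sens_sd`,
#'   `spec_sd`.
#' @export
roc_harness <- function(merged, truth_pairs, fractions = c(0, 0.3, 0.6, 0.9),
                        repeats = 5, seed = 1, config = default_config()) {
  base_ctx <- build_context(merged)
  all_rows <- rownames(base_ctx$M)
  truth_sig <- pair_sig(truth_pairs$met_a, truth_pairs$met_b)
  out <- NULL
  set.seed(seed)
  for (f in fractions) {
    sens <- spec <- numeric(repeats)
    for (r in seq_len(repeats)) {
      hidden <- if (f > 0) sample(all_rows, floor(f * length(all_rows))) else character()
      ctx <- build_context(merged, hidden_rows = hidden)
      sc <- score_matches(ctx)
      if (!length(sc$shared_scores) || !nrow(sc$candidates)) {
        sens[r] <- 0; spec[r] <- 0
        next
      }
      thr <- stats::quantile(sc$shared_scores, probs = config$percentile / 100,
                             names = FALSE)
      cand <- sc$candidates[!is.na(sc$candidates$score), , drop = FALSE]
      is_true <- pair_sig(cand$met_a, cand$met_b) %in% truth_sig
      pred <- cand$score >= thr
      tp <- sum(pred & is_true); fn <- sum(!pred & is_true)
      fp <- sum(pred & !is_true); tn <- sum(!pred & !is_true)
      sens[r] <- if (tp + fn > 0) tp / (tp + fn) else 0
      spec[r] <- if (tn + fp > 0) tn / (tn + fp) else 0
    }
    out <- rbind(out, data.frame(fraction = f,
                                 sensitivity = mean(sens), specificity = mean(spec),
                                 sens_sd = stats::sd(sens), spec_sd = stats::sd(spec)))
  }
  out
}

pair_sig <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~~")
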