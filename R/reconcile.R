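#' Reaction-level inconsistency detection and merging
#'
#' Detectors for the reaction-level inconsistency classes that arise when
#' concurrent models of one organism are merged: identical net reactions
#' (up to direction), alternative stoichiometries, redox-pair variants,
#' nested reactions, similar (partially overlapping) reactions, and lumped
#' vs. non-lumped pathway representations.
#'
#' @name reaction_reconciliation
NULL

#' Commonly used redox pairs
#'
#' Default list of cofactor couples, as compartment-free metabolite id pairs;
#' both plain and MNX-style spellings are included. User-extensible: pass a
#' two-column data.frame (`ox`, `red`) to the detectors.
#' @return data.frame with columns `ox`, `red`.
#' @export
default_redox_pairs <- function() {
  data.frame(
    ox = c("nad", "nadp", "fad", "fmn", "q8", "NAD", "NADP", "MNXM8", "MNXM5"),
    red = c("nadh", "nadph", "fadh2", "fmnh2", "q8h2", "NADH", "NADPH", "MNXM10", "MNXM6"),
    stringsAsFactors = FALSE)
}

#' Merge policy for reaction groups
#'
#' @param gpr_mode `"union"` (OR the rules) or `"strict"` (identical gene
#'   sets keep one rule; a subset keeps the superset rule flagged; otherwise
#'   the group is held for user review).
#' @param direction_mode `"consensus-then-reversible"` (agreeing members keep
#'   their direction, conflicting members become reversible) or
#'   `"consensus-then-predictor-hook"` (conflicts are delegated to
#'   `direction_predictor`).
#' @param proton_water_ignore ignore protons and water when comparing net
#'   formulas.
#' @param direction_predictor optional function `(reaction) ->
#'   "forward"|"backward"|"reversible"|"unknown"` used by the predictor hook.
#' @return a `merge_policy` list.
#' @export
merge_policy <- function(gpr_mode = c("union", "strict"),
                         direction_mode = c("consensus-then-reversible",
                                            "consensus-then-predictor-hook"),
                         proton_water_ignore = TRUE,
                         direction_predictor = NULL) {
  structure(list(gpr_mode = match.arg(gpr_mode),
                 direction_mode = match.arg(direction_mode),
                 proton_water_ignore = proton_water_ignore,
                 direction_predictor = direction_predictor),
            class = "merge_policy")
}

ignored_ids <- function(policy, config) {
  if (isTRUE(policy$proton_water_ignore)) currency_ids(config) else character()
}

#' Find groups of identical net reactions
#'
#' Groups reactions whose net stoichiometries are identical up to overall
#' sign (the double matrix `[S, -S]` view), so opposite-direction writings of
#' one conversion collide. With `proton_water_ignore`, proton and water rows
#' are zeroed before comparison ("practically identical"). Boundary reactions
#' are never grouped.
#'
#' @param model a `gsm_model`.
#' @param policy a [merge_policy()].
#' @param config tunables.
#' @return list of character vectors of reaction ids (each length >= 2).
#' @export
find_identical_net <- function(model, policy = merge_policy(), config = default_config()) {
  ign <- ignored_ids(policy, config)
  sigs <- vapply(model$reactions, function(r) {
    if (r$is_boundary) return(NA_character_)
    st <- reaction_net(r, ign)
    if (!length(st)) return(NA_character_)
    stoich_signature(st)
  }, character(1))
  grps <- split(names(sigs)[!is.na(sigs)], sigs[!is.na(sigs)])
  unname(grps[lengths(grps) >= 2])
}

#' Find groups of reactions with alternative stoichiometries
#'
#' Groups reactions with identical metabolite support (boolean view of S) but
#' non-identical coefficient vectors. When elemental formulas allow a balance
#' check and exactly one member is balanced, that member is the proposed
#' automatic resolution; otherwise the group is pending.
#'
#' @inheritParams find_identical_net
#' @return list of groups: each a list with `members` (reaction ids),
#'   `balanced` (ids that pass the elemental balance check, possibly empty),
#'   `resolution` (`"auto"` with `keep`, or `"pending"`).
#' @export
find_alt_stoichiometry <- function(model, policy = merge_policy(),
                                   config = default_config()) {
  ign <- ignored_ids(policy, config)
  nets <- lapply(model$reactions, reaction_net, ignore_ids = ign)
  ok <- !vapply(model$reactions, function(r) r$is_boundary, logical(1)) &
    lengths(nets) > 0
  supp <- vapply(nets, support_signature, character(1))
  grps <- split(names(nets)[ok], supp[ok])
  grps <- grps[lengths(grps) >= 2]
  out <- list()
  for (g in grps) {
    full <- vapply(nets[g], stoich_signature, character(1))
    if (length(unique(full)) < 2) next      # identical net, not alternative stoich
    bal <- vapply(g, function(rid) isTRUE(reaction_balanced(model, rid)), logical(1))
    known <- !vapply(g, function(rid) is.na(reaction_balanced(model, rid)), logical(1))
    balanced <- g[bal]
    res <- if (all(known) && length(balanced) == 1L) "auto" else "pending"
    out[[length(out) + 1L]] <- list(members = g, balanced = balanced,
                                    resolution = res,
                                    keep = if (res == "auto") balanced else NA_character_)
  }
  out
}

# Substitute one redox pair in a reaction's stoichiometry by a unit entry in
# an artificial 'redox pair' row; NULL when the pair is not present on
# opposite sides.
substitute_redox <- function(stoich, ox_keys, red_keys) {
  ox_in <- intersect(names(stoich), ox_keys)
  red_in <- intersect(names(stoich), red_keys)
  if (!length(ox_in) || !length(red_in)) return(NULL)
  if (sign(stoich[[ox_in[1]]]) == sign(stoich[[red_in[1]]])) return(NULL)
  st <- stoich[!(names(stoich) %in% c(ox_in, red_in))]
  st[["~redox~"]] <- 1
  st[order(names(st), method = "radix")]
}

#' Find reactions identical up to a redox pair
#'
#' Replaces each constituent redox pair (e.g. NAD/NADH vs NADP/NADPH) by an
#' artificial unit 'redox pair' row and groups reactions by the support of
#' the substituted stoichiometry, as in the alternative-stoichiometry
#' comparison. Reactions containing two different redox pairs have each
#' substitution tried independently; pair combinations are flagged pending.
#'
#' @param model a `gsm_model`.
#' @param pairs redox pair table (`ox`, `red` compartment-free ids).
#' @param policy,config see [find_identical_net()].
#' @return list of groups: `members` reaction ids, `pending` logical
#'   (multi-pair members present).
#' @export
find_redox_variants <- function(model, pairs = default_redox_pairs(),
                                policy = merge_policy(), config = default_config()) {
  ign <- ignored_ids(policy, config)
  comps <- model$compartments$id
  variants <- list(); multi <- character()
  for (rid in names(model$reactions)) {
    rxn <- model$reactions[[rid]]
    if (rxn$is_boundary) next
    st <- reaction_net(rxn, ign)
    n_sub <- 0L
    for (p in seq_len(nrow(pairs))) {
      ox_keys <- met_key(pairs$ox[p], comps)
      red_keys <- met_key(pairs$red[p], comps)
      sub <- substitute_redox(st, ox_keys, red_keys)
      if (is.null(sub)) next
      n_sub <- n_sub + 1L
      variants[[length(variants) + 1L]] <- data.frame(
        rid = rid, supp = support_signature(sub), stringsAsFactors = FALSE)
    }
    if (n_sub >= 2L) multi <- c(multi, rid)
  }
  if (!length(variants)) return(list())
  tab <- do.call(rbind, variants)
  grps <- split(tab$rid, tab$supp)
  grps <- lapply(grps, unique)
  grps <- grps[lengths(grps) >= 2]
  lapply(unname(grps), function(g)
    list(members = g, pending = any(g %in% multi)))
}

#' Suggest redox-pair candidates from co-occurrence
#'
#' Proposes metabolite pairs that sit on opposite sides of the same reactions
#' in at least `config$redox_cooccur` (default 0.8) of the reactions that
#' contain either member.
#'
#' @param model a `gsm_model`.
#' @param config tunables.
#' @return data.frame `id_a`, `id_b`, `fraction_a`, `fraction_b`, sorted by
#'   descending minimum fraction.
#' @export
suggest_redox_pairs <- function(model, config = default_config()) {
  rxns <- Filter(function(r) !r$is_boundary, model$reactions)
  ids_by_rxn <- lapply(rxns, function(r) {
    p <- met_key_parts(names(r$stoich))
    stats::setNames(sign(r$stoich), p$id)
  })
  counts <- table(unlist(lapply(ids_by_rxn, names)))
  ids <- names(counts)
  out <- NULL
  for (ai in seq_along(ids)) {
    for (bi in seq_len(ai - 1L)) {
      a <- ids[ai]; b <- ids[bi]
      both <- sum(vapply(ids_by_rxn, function(s)
        a %in% names(s) && b %in% names(s) &&
          sign(s[[a]]) != sign(s[[b]]), logical(1)))
      fa <- both / counts[[a]]; fb <- both / counts[[b]]
      if (both > 0 && fa >= config$redox_cooccur && fb >= config$redox_cooccur)
        out <- rbind(out, data.frame(id_a = min(a, b), id_b = max(a, b),
                                     fraction_a = if (a < b) fa else fb,
                                     fraction_b = if (a < b) fb else fa,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(data.frame(id_a = character(), id_b = character(),
                                      fraction_a = numeric(), fraction_b = numeric()))
  out[order(-pmin(out$fraction_a, out$fraction_b)), , drop = FALSE]
}

#' Find nested reaction pairs
#'
#' A reaction is nested in another when its metabolite support is a strict
#' subset of the other's (boolean view of S). Candidate pairs are confirmed
#' by the side-agreement rule: at least two shared metabolites that sit on
#' one side of the inner reaction also sit on one side of the outer reaction.
#'
#' @inheritParams find_identical_net
#' @return data.frame `inner`, `outer` reaction ids.
#' @export
find_nested <- function(model, policy = merge_policy(), config = default_config()) {
  ign <- ignored_ids(policy, config)
  nets <- lapply(model$reactions, reaction_net, ignore_ids = ign)
  ok <- names(nets)[!vapply(model$reactions, function(r) r$is_boundary, logical(1)) &
                      lengths(nets) > 0]
  out <- NULL
  for (a in ok) {
    for (b in ok) {
      if (a == b) next
      sa <- nets[[a]]; sb <- nets[[b]]
      if (length(sa) >= length(sb)) next
      if (!all(names(sa) %in% names(sb))) next
      if (nested_confirmed(sa, sb))
        out <- rbind(out, data.frame(inner = a, outer = b, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(inner = character(), outer = character()) else out
}

# >= 2 metabolites sharing a side in the inner reaction share a side in the
# outer reaction too.
nested_confirmed <- function(inner, outer) {
  shared <- intersect(names(inner), names(outer))
  if (length(shared) < 2) return(FALSE)
  si <- sign(inner[shared]); so <- sign(outer[shared])
  for (side in c(-1, 1)) {
    grp <- shared[si == side]
    if (length(grp) >= 2 && (all(so[grp] == 1) || all(so[grp] == -1))) return(TRUE)
  }
  FALSE
}

#' Find similar reactions across models
#'
#' Cross-model reaction pairs that share at least the required numbers of
#' genes, substrates and products (the intersection of the three pair sets).
#'
#' @param model merged `gsm_model` with source tags.
#' @param min_genes,min_substrates,min_products sharing thresholds.
#' @return data.frame `rxn_a`, `rxn_b`, `shared_genes`, `shared_substrates`,
#'   `shared_products`.
#' @export
find_similar <- function(model, min_genes = 1L, min_substrates = 1L,
                         min_products = 1L) {
  rids <- names(model$reactions)
  info <- lapply(model$reactions, function(r) {
    list(genes = gpr_genes(r$gpr),
         subs = names(r$stoich)[r$stoich < 0],
         prods = names(r$stoich)[r$stoich > 0],
         sources = r$sources)
  })
  out <- NULL
  for (ai in seq_along(rids)) {
    for (bi in seq_len(ai - 1L)) {
      a <- info[[ai]]; b <- info[[bi]]
      if (!length(setdiff(a$sources, b$sources)) &&
          !length(setdiff(b$sources, a$sources))) next
      sg <- length(intersect(a$genes, b$genes))
      ss <- length(intersect(a$subs, b$subs))
      sp <- length(intersect(a$prods, b$prods))
      if (sg >= min_genes && ss >= min_substrates && sp >= min_products)
        out <- rbind(out, data.frame(rxn_a = rids[bi], rxn_b = rids[ai],
                                     shared_genes = sg, shared_substrates = ss,
                                     shared_products = sp, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(rxn_a = character(), rxn_b = character(),
                               shared_genes = integer(), shared_substrates = integer(),
                               shared_products = integer())
  else out
}

# All-forward expansion of a model's non-boundary reactions: backward
# reactions reversed, reversible reactions split into two columns.
irreversible_expansion <- function(model) {
  cols <- list()
  for (rid in names(model$reactions)) {
    rxn <- model$reactions[[rid]]
    if (rxn$is_boundary) next
    if (rxn$reversibility == "forward") {
      cols[[rid]] <- list(rid = rid, stoich = rxn$stoich)
    } else if (rxn$reversibility == "backward") {
      cols[[rid]] <- list(rid = rid, stoich = -rxn$stoich)
    } else {
      cols[[paste0(rid, "#f")]] <- list(rid = rid, stoich = rxn$stoich)
      cols[[paste0(rid, "#r")]] <- list(rid = rid, stoich = -rxn$stoich)
    }
  }
  mets <- sort(unique(unlist(lapply(cols, function(cl) names(cl$stoich)))))
  S <- matrix(0, length(mets), length(cols), dimnames = list(mets, names(cols)))
  for (j in seq_along(cols)) S[names(cols[[j]]$stoich), j] <- cols[[j]]$stoich
  list(S = S, rid = vapply(cols, function(cl) cl$rid, character(1)))
}

#' Identify non-lumped representations of a candidate lumped reaction
#'
#' A lumped reaction and its non-lumped pathway cancel at steady state when
#' run in opposite directions. The model is made all-forward (reversibles
#' split, backward reactions reversed, boundary columns removed) and the LP
#' \deqn{\max c'x \;\; s.t. \;\; S_{irr} x = 0, \; lb \le x \le ub}
#' is solved with every objective coefficient -1 (minimal total flux), except
#' -1000 for the candidate LR whose lower bound is relaxed to -1 so backward
#' flux through it is rewarded. A nonzero solution's support (minus LR) is a
#' non-lumped set NL. Found sets are penalised (their coefficients tripled)
#' and the LP re-solved until no nonzero solution, a recurring set, or a set
#' larger than `config$max_lumped_size` (default 5) appears. Sets are then
#' filtered by GPR overlap with LR (default: at least
#' `config$lumped_min_shared_genes` shared gene; skipped when LR carries no
#' GPR).
#'
#' @param model a `gsm_model`.
#' @param candidate reaction id of the candidate lumped reaction.
#' @param config tunables.
#' @return list of character vectors (non-lumped reaction id sets), each with
#'   attribute `fluxes` (the supporting flux distribution over expansion
#'   columns).
#' @export
find_lumped <- function(model, candidate, config = default_config()) {
  exp <- irreversible_expansion(model)
  S <- exp$S
  n <- ncol(S)
  own <- which(exp$rid == candidate)
  if (!length(own)) stop("candidate reaction not found or boundary: ", candidate)
  i_lr <- own[1]                       # the forward column of LR
  cc <- rep(-1, n); cc[i_lr] <- -1000
  lb <- rep(0, n); ub <- rep(1000, n)
  lb[i_lr] <- -1
  ub[setdiff(own, i_lr)] <- 0          # LR's reverse split must not cancel it
  seen <- character(); out <- list()
  repeat {
    res <- lp_solve(cc, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
    if (res$status != "optimal") break
    x <- res$x
    x[abs(x) < config$flux_zero] <- 0
    if (all(x == 0) || x[i_lr] >= 0) break
    nl <- sort(unique(exp$rid[which(x != 0)]))
    nl <- setdiff(nl, candidate)
    if (!length(nl)) break
    key <- paste(nl, collapse = "|")
    if (key %in% seen) break
    if (length(nl) > config$max_lumped_size) break
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- structure(nl, fluxes = stats::setNames(x, colnames(S)))
    active_cols <- which(x != 0 & seq_len(n) != i_lr)
    cc[active_cols] <- 3 * cc[active_cols]
  }
  # GPR-overlap filter
  lr_genes <- gpr_genes(model$reactions[[candidate]]$gpr)
  if (length(lr_genes) && config$lumped_min_shared_genes > 0) {
    out <- Filter(function(nl) {
      nl_genes <- unique(unlist(lapply(nl, function(rid)
        gpr_genes(model$reactions[[rid]]$gpr))))
      length(intersect(lr_genes, nl_genes)) >= config$lumped_min_shared_genes
    }, out)
  }
  out
}

#' Merge a group of reactions into one
#'
#' Members must have identical net formulas up to direction (after the
#' policy's currency-species filter) unless `force = TRUE`. The surviving
#' reaction (lexicographically smallest id) carries the union of sources;
#' direction follows the policy: members agreeing (after orienting each to
#' the survivor's writing) keep the direction, conflicting members become
#' reversible or are delegated to the predictor hook. GPRs merge per the
#' policy's mode; a strict-mode structural disagreement leaves the group
#' unmerged with status `"pending"`.
#'
#' @param model a `gsm_model`.
#' @param group character vector of reaction ids.
#' @param policy a [merge_policy()].
#' @param config tunables.
#' @param log optional `decision_log`.
#' @param force allow merging different net formulas (user override).
#' @return list with `model`, `log`, `status` (`"merged"`/`"pending"`),
#'   `survivor`, and `gpr_status`.
#' @export
merge_reactions <- function(model, group, policy = merge_policy(),
                            config = default_config(), log = NULL, force = FALSE) {
  stopifnot(length(group) >= 2, all(group %in% names(model$reactions)))
  ign <- ignored_ids(policy, config)
  survivor <- sort(group, method = "radix")[1]   # locale-independent choice
  ref <- reaction_net(model$reactions[[survivor]], ign)
  ref_sig <- stoich_signature(ref, directed = TRUE)
  orient <- stats::setNames(numeric(length(group)), group)
  for (rid in group) {
    st <- reaction_net(model$reactions[[rid]], ign)
    if (identical(stoich_signature(st, directed = TRUE), ref_sig)) orient[rid] <- 1
    else if (identical(stoich_signature(-st, directed = TRUE), ref_sig)) orient[rid] <- -1
    else if (!force)
      stop("refusing to merge reactions with different net formulas: ",
           paste(group, collapse = ", "), " (use force = TRUE to override)")
    else orient[rid] <- 1
  }
  # direction in the survivor's orientation
  dirs <- vapply(group, function(rid) {
    d <- model$reactions[[rid]]$reversibility
    if (orient[rid] < 0) d <- switch(d, forward = "backward", backward = "forward", d)
    d
  }, character(1))
  direction <- if (length(unique(dirs)) == 1L) dirs[[1]] else if
    (policy$direction_mode == "consensus-then-predictor-hook" &&
     !is.null(policy$direction_predictor)) {
    p <- policy$direction_predictor(model$reactions[[survivor]])
    if (identical(p, "unknown")) "reversible" else p
  } else "reversible"

  gm <- gpr_merge(lapply(group, function(rid) model$reactions[[rid]]$gpr),
                  mode = policy$gpr_mode)
  if (gm$status == "pending") {
    return(list(model = model, log = log, status = "pending",
                survivor = survivor, gpr_status = "pending"))
  }
  entry <- list(op = "merge_reactions",
                args = list(members = as.list(group), survivor = survivor,
                            reversibility = direction,
                            gpr = gpr_to_string(gm$rule)))
  model <- apply_decision(model, entry)
  if (!is.null(log)) log <- log_append(log, entry$op, entry$args)
  list(model = model, log = log, status = "merged", survivor = survivor,
       gpr_status = gm$status)
}
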