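# In-code fixtures and independent oracles shared across test files.

# A minimal growing toy: uptake A (<= 10) -> X -> biomass, 1:1:1.
linear_toy <- function() {
  m <- new_model("toy")
  m <- add_compartment(m, "e", is_extracellular = TRUE)
  m <- add_metabolite(m, "A", "e")
  m <- add_metabolite(m, "A", "c")
  m <- add_metabolite(m, "X", "c")
  m <- add_reaction(m, "EX_A", c("A[e]" = -1), "reversible", lb = -10,
                    is_boundary = TRUE)
  m <- add_reaction(m, "TA", c("A[e]" = -1, "A[c]" = 1), "forward", gpr = "gT")
  m <- add_reaction(m, "AX", c("A[c]" = -1, "X[c]" = 1), "forward", gpr = "g1")
  m <- add_reaction(m, "BIO", c("X[c]" = -1), "forward", is_boundary = TRUE)
  m$biomass_reaction_id <- "BIO"
  m
}

# Random small model over one or two compartments; reactions draw 2-4
# metabolites with small integer coefficients. Occasionally plants an exact
# duplicate, a sign-flipped duplicate, or a scaled variant so that the
# detectors have non-trivial work.
random_model <- function(n_rxn = 40, n_met = 25, seed = 1) {
  set.seed(seed)
  m <- new_model("R")
  m <- add_compartment(m, "c")
  mets <- paste0("m", seq_len(n_met))
  for (id in mets) m <- add_metabolite(m, id, "c")
  keys <- met_key(mets, "c")
  sigs <- list()
  for (j in seq_len(n_rxn)) {
    roll <- stats::runif(1)
    if (roll < 0.15 && length(sigs)) {            # duplicate of an earlier one
      st <- sigs[[sample(length(sigs), 1)]]
      if (stats::runif(1) < 0.5) st <- -st
    } else if (roll < 0.25 && length(sigs)) {     # scaled variant: same support
      st <- sigs[[sample(length(sigs), 1)]]
      pick <- sample(length(st), 1)
      st[pick] <- st[pick] * 2
    } else {
      k <- sample(2:4, 1)
      ks <- sample(keys, k)
      coef <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
      if (all(coef > 0)) coef[1] <- -coef[1]
      if (all(coef < 0)) coef[1] <- -coef[1]
      st <- stats::setNames(coef, ks)
    }
    sigs[[j]] <- st
    m <- add_reaction(m, paste0("r", j), st,
                      sample(c("forward", "reversible", "backward"), 1),
                      gpr = if (stats::runif(1) < 0.6)
                        paste0("g", sample(8, 1)) else NULL)
  }
  m
}

rounded_net <- function(model, rid, ignore = character()) {
  st <- gsmerge:::reaction_net(model$reactions[[rid]], ignore)
  st <- round(st[order(names(st), method = "radix")], 9)
  st
}

same_up_to_sign <- function(a, b) {
  if (length(a) != length(b) || !identical(names(a), names(b))) return(FALSE)
  identical(unname(a), unname(b)) || identical(unname(a), unname(-b))
}

# O(r^2) oracle for identical-net groups: connected components of the
# pairwise "identical up to sign" relation, returned as a canonical set of
# sorted groups.
oracle_identical_net <- function(model, ignore = character()) {
  rids <- names(model$reactions)
  rids <- rids[!vapply(model$reactions, function(r) r$is_boundary, logical(1))]
  nets <- lapply(rids, function(r) rounded_net(model, r, ignore))
  names(nets) <- rids
  rids <- rids[lengths(nets[rids]) > 0]
  parent <- stats::setNames(seq_along(rids), rids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ai in seq_along(rids)) for (bi in seq_len(ai - 1)) {
    if (same_up_to_sign(nets[[rids[ai]]], nets[[rids[bi]]])) {
      parent[find(ai)] <- find(bi)
    }
  }
  comp <- vapply(seq_along(rids), find, numeric(1))
  grps <- split(rids, comp)
  canonical_groups(grps[lengths(grps) >= 2])
}

oracle_alt_stoich <- function(model, ignore = character()) {
  rids <- names(model$reactions)
  rids <- rids[!vapply(model$reactions, function(r) r$is_boundary, logical(1))]
  nets <- lapply(rids, function(r) rounded_net(model, r, ignore))
  names(nets) <- rids
  rids <- rids[lengths(nets[rids]) > 0]
  supp <- vapply(nets[rids], function(s) paste(names(s), collapse = "|"), character(1))
  grps <- split(rids, supp)
  grps <- Filter(function(g) {
    length(g) >= 2 && {
      full <- vapply(nets[g], function(s) {
        neg <- -s
        a <- paste(names(s), unname(s), collapse = "|")
        b <- paste(names(neg), unname(neg), collapse = "|")
        min(a, b)
      }, character(1))
      length(unique(full)) >= 2
    }
  }, grps)
  canonical_groups(grps)
}

oracle_nested <- function(model, ignore = character()) {
  rids <- names(model$reactions)
  rids <- rids[!vapply(model$reactions, function(r) r$is_boundary, logical(1))]
  nets <- lapply(rids, function(r) rounded_net(model, r, ignore))
  names(nets) <- rids
  rids <- rids[lengths(nets[rids]) > 0]
  out <- NULL
  for (a in rids) for (b in rids) {
    if (a == b) next
    sa <- nets[[a]]; sb <- nets[[b]]
    if (length(sa) >= length(sb) || !all(names(sa) %in% names(sb))) next
    shared <- names(sa)
    conf <- FALSE
    for (x in shared) for (y in shared) {
      if (x >= y) next
      if (sign(sa[[x]]) == sign(sa[[y]]) && sign(sb[[x]]) == sign(sb[[y]])) conf <- TRUE
    }
    if (conf) out <- rbind(out, data.frame(inner = a, outer = b))
  }
  out
}

oracle_similar <- function(model, min_genes, min_subs, min_prods) {
  rids <- names(model$reactions)
  out <- NULL
  for (a in rids) for (b in rids) {
    if (a >= b) next
    ra <- model$reactions[[a]]; rb <- model$reactions[[b]]
    if (setequal(ra$sources, rb$sources)) next
    if (length(intersect(gpr_genes(ra$gpr), gpr_genes(rb$gpr))) < min_genes) next
    if (length(intersect(names(ra$stoich)[ra$stoich < 0],
                         names(rb$stoich)[rb$stoich < 0])) < min_subs) next
    if (length(intersect(names(ra$stoich)[ra$stoich > 0],
                         names(rb$stoich)[rb$stoich > 0])) < min_prods) next
    out <- rbind(out, data.frame(rxn_a = a, rxn_b = b))
  }
  out
}

oracle_alt_transport <- function(model) {
  groups <- list()
  ids <- unique(model$metabolites$id)
  for (id in ids) {
    insts <- model$metabolites$key[model$metabolites$id == id]
    if (length(insts) < 2) next
    movers <- list()
    for (rid in names(model$reactions)) {
      st <- model$reactions[[rid]]$stoich
      here <- intersect(names(st), insts)
      if (length(here) < 2) next
      if (length(unique(sign(st[here]))) < 2) next
      comps <- sort(vapply(strsplit(here, "[", fixed = TRUE), function(p)
        sub("]", "", p[2], fixed = TRUE), character(1)))
      for (ai in seq_along(comps)) for (bi in seq_len(ai - 1)) {
        key <- paste(id, comps[bi], comps[ai], sep = "/")
        movers[[key]] <- c(movers[[key]], rid)
      }
    }
    for (key in names(movers)) {
      mem <- sort(unique(movers[[key]]))
      if (length(mem) >= 2) groups[[key]] <- mem
    }
  }
  groups
}

canonical_groups <- function(grps) {
  out <- lapply(grps, function(g) sort(unname(g)))
  out <- out[order(vapply(out, paste, "", collapse = "|"))]
  unname(out)
}

# textbook Pearson correlation, written independently of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}
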