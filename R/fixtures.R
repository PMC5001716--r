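#' Specification for a synthetic fixture pair
#'
#' Describes the paired toy models the generator builds: a shared linear
#' backbone with branches and a currency-metabolite layer (so hub effects on
#' the matcher are represented), plus planted, labelled instances of the
#' inconsistency classes. All counts are nonnegative and checked against the
#' base size.
#'
#' @param n_chain backbone length (metabolites).
#' @param n_branch number of two-step side branches.
#' @param synonyms metabolites of model B renamed to synthetic synonym ids.
#' @param stoich_variants resolvable alternative-stoichiometry pairs (exactly
#'   one member elementally balanced).
#' @param polymer_variants unresolvable polymer-style stoichiometry pairs.
#' @param proton_duplicates cross-model duplicates differing only by a proton.
#' @param redox_twins NADH/NADPH twin pairs.
#' @param nested_pairs nested (cofactor-optional) reaction pairs.
#' @param lumped_pairs lumped-vs-chain plantings (the first also gets an
#'   alternative second chain).
#' @param alt_transporters alternative transporter pairs for one metabolite.
#' @param invalid_transports direct extracellular-cytosol shortcuts planted in
#'   the periplasm-bearing model A.
#' @param invalid_boundaries boundary reactions planted on cytosolic
#'   metabolites of model B.
#' @param unknown_reactions reactions of B placed in the unknown compartment
#'   (the last one is unresolvable when > 1).
#' @param split_compartments when `TRUE` model A routes uptake through a
#'   periplasm while model B transports directly (2- vs 3-compartment layout).
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_chain = 8, n_branch = 4, synonyms = 3,
                         stoich_variants = 1, polymer_variants = 1,
                         proton_duplicates = 2, redox_twins = 2,
                         nested_pairs = 1, lumped_pairs = 1,
                         alt_transporters = 1, invalid_transports = 0,
                         invalid_boundaries = 1, unknown_reactions = 2,
                         split_compartments = TRUE, seed = 1L) {
  spec <- as.list(environment())
  stopifnot(all(vapply(spec, function(x) is.logical(x) || x >= 0, logical(1))))
  if (synonyms > n_branch)
    stop("cannot plant more synonyms than branch metabolites")
  structure(spec, class = "fixture_spec")
}

#' Generate a paired fixture with planted inconsistencies
#'
#' Builds models A and B sharing a connected core that guarantees wild-type
#' growth from the declared medium, then perturbs B (and occasionally A)
#' relative to the shared core with one planting per requested inconsistency
#' instance. Ground truth for every planted instance is returned alongside.
#'
#' @param spec a [fixture_spec()].
#' @return list with `a`, `b` (models), `truth` (ground-truth labels),
#'   `medium` (named uptake map), `knockout_genes` (genes whose deletion
#'   stops growth).
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  n <- spec$n_chain
  chain <- paste0("X", seq_len(n))
  branch_in <- sample(seq_len(n - 2), spec$n_branch, replace = TRUE)

  base <- new_model("A")
  base <- add_compartment(base, "e", "extracellular", TRUE)
  if (spec$split_compartments) base <- add_compartment(base, "p", "periplasm")
  base <- add_compartment(base, "c", "cytosol")
  addm <- function(m, id, comp = "c", formula = NA) add_metabolite(m, id, comp, formula)

  build_core <- function(m, via_periplasm) {
    m <- addm(m, "S", "e", "C6H12O6")
    m <- addm(m, "S", "c", "C6H12O6")
    for (x in chain) m <- addm(m, x)
    m <- addm(m, "atp"); m <- addm(m, "adp")
    m <- addm(m, "nad"); m <- addm(m, "nadh")
    m <- addm(m, "h", "c"); m <- addm(m, "h2o", "c")
    m <- addm(m, "bm", "c"); m <- addm(m, "bm", "e")
    m <- add_reaction(m, "EX_S", c("S[e]" = -1), "reversible", lb = -10,
                      is_boundary = TRUE)
    m <- addm(m, "h", "e")
    m <- add_reaction(m, "EX_h", c("h[e]" = -1), "reversible", is_boundary = TRUE)
    if (via_periplasm) {
      m <- addm(m, "S", "p", "C6H12O6")
      m <- addm(m, "h", "p")
      m <- add_reaction(m, "TS1", c("S[e]" = -1, "S[p]" = 1), "reversible", gpr = "gT")
      m <- add_reaction(m, "TS2", c("S[p]" = -1, "S[c]" = 1), "reversible", gpr = "gT")
      m <- add_reaction(m, "TH1", c("h[c]" = -1, "h[p]" = 1), "reversible")
      m <- add_reaction(m, "TH2", c("h[p]" = -1, "h[e]" = 1), "reversible")
    } else {
      m <- add_reaction(m, "TS", c("S[e]" = -1, "S[c]" = 1), "reversible", gpr = "gT")
      m <- add_reaction(m, "TH", c("h[c]" = -1, "h[e]" = 1), "reversible")
    }
    m <- add_reaction(m, "R0", c("S[c]" = -1, "X1[c]" = 1), "forward", gpr = "g0")
    for (i in seq_len(n - 1)) {
      st <- stats::setNames(c(-1, 1), c(met_key(chain[i], "c"), met_key(chain[i + 1], "c")))
      if (i %% 3 == 1) st <- c(st, "atp[c]" = -1, "adp[c]" = 1)
      if (i %% 4 == 2) st <- c(st, "nad[c]" = -1, "nadh[c]" = 1)
      m <- add_reaction(m, paste0("R", i), st, "forward", gpr = paste0("g", i))
    }
    m <- add_reaction(m, "REGEN_ATP", c("adp[c]" = -1, "atp[c]" = 1), "forward")
    m <- add_reaction(m, "REGEN_NAD", c("nadh[c]" = -1, "nad[c]" = 1), "forward")
    m <- add_reaction(m, "BIO", stats::setNames(c(-1, 1),
                                                c(met_key(chain[n], "c"), "bm[c]")),
                      "forward")
    if (via_periplasm) {
      m <- addm(m, "bm", "p")
      m <- add_reaction(m, "T_bm1", c("bm[c]" = -1, "bm[p]" = 1), "forward")
      m <- add_reaction(m, "T_bm2", c("bm[p]" = -1, "bm[e]" = 1), "forward")
    } else {
      m <- add_reaction(m, "T_bm", c("bm[c]" = -1, "bm[e]" = 1), "forward")
    }
    m <- add_reaction(m, "EX_bm", c("bm[e]" = -1), "forward", is_boundary = TRUE)
    m$biomass_reaction_id <- "BIO"
    for (j in seq_len(spec$n_branch)) {
      bmet <- paste0("BR", j)
      m <- addm(m, bmet)
      i <- branch_in[j]
      m <- add_reaction(m, paste0("BRin", j),
                        stats::setNames(c(-1, 1), c(met_key(chain[i], "c"),
                                                    met_key(bmet, "c"))),
                        "forward", gpr = paste0("gb", j))
      m <- add_reaction(m, paste0("BRout", j),
                        stats::setNames(c(-1, 1), c(met_key(bmet, "c"),
                                                    met_key(chain[i + 2], "c"))),
                        "forward", gpr = paste0("gb", j))
    }
    m
  }

  a <- build_core(base, via_periplasm = spec$split_compartments)
  b0 <- new_model("B")
  b0 <- add_compartment(b0, "e", "extracellular", TRUE)
  b0 <- add_compartment(b0, "c", "cytosol")
  b <- build_core(b0, via_periplasm = FALSE)

  truth <- list(synonyms = NULL, stoich_variants = list(), polymer_variants = list(),
                proton_duplicates = list(), redox_twins = list(), nested = NULL,
                lumped = list(), alt_transport = list(), invalid_transport = character(),
                invalid_boundary = character(), unknown = NULL)

  # synonym metabolites: rename branch metabolites of B
  if (spec$synonyms > 0) {
    picked <- paste0("BR", seq_len(spec$synonyms))
    pairs <- NULL
    for (id in picked) {
      syn <- paste0(id, "syn")
      i <- match(met_key(id, "c"), b$metabolites$key)
      b$metabolites$id[i] <- syn
      b$metabolites$key[i] <- met_key(syn, "c")
      for (rid in names(b$reactions)) {
        st <- b$reactions[[rid]]$stoich
        hit <- names(st) == met_key(id, "c")
        if (any(hit)) {
          names(st)[hit] <- met_key(syn, "c")
          b$reactions[[rid]]$stoich <- st[order(names(st), method = "radix")]
        }
      }
      pairs <- rbind(pairs, data.frame(met_a = met_key(id, "c"),
                                       met_b = met_key(syn, "c"),
                                       stringsAsFactors = FALSE))
    }
    truth$synonyms <- pairs
  }

  # resolvable stoichiometry variants: B doubles a substrate coefficient
  for (k in seq_len(spec$stoich_variants)) {
    sa <- paste0("SV", k, "a"); sb <- paste0("SV", k, "b")
    for (mm in c("a", "b")) {
      m <- if (mm == "a") a else b
      m <- add_metabolite(m, sa, "c", "C2H4O2")
      m <- add_metabolite(m, sb, "c", "C2H4O2")
      coef <- if (mm == "a") -1 else -2
      rid <- paste0("RSV", k, if (mm == "a") "" else "b")
      m <- add_reaction(m, rid, stats::setNames(c(coef, 1),
                                                c(met_key(sa, "c"), met_key(sb, "c"))),
                        "forward", gpr = paste0("gsv", k))
      m <- add_reaction(m, paste0("SRC_SV", k), stats::setNames(c(-1, 1),
                        c(met_key(chain[2], "c"), met_key(sa, "c"))), "forward")
      if (mm == "a") a <- m else b <- m
    }
    truth$stoich_variants[[k]] <- list(members = c(paste0("RSV", k), paste0("RSV", k, "b")),
                                       keep = paste0("RSV", k))
  }

  # polymer variants: different subunit counts, both unbalanced
  for (k in seq_len(spec$polymer_variants)) {
    mono <- paste0("MONO", k); poly <- paste0("POLY", k)
    for (mm in c("a", "b")) {
      m <- if (mm == "a") a else b
      m <- add_metabolite(m, mono, "c", "C3H6O3")
      m <- add_metabolite(m, poly, "c", "X")
      coef <- if (mm == "a") -4 else -5
      rid <- paste0("RPOLY", k, if (mm == "a") "" else "b")
      m <- add_reaction(m, rid, stats::setNames(c(coef, 1),
                        c(met_key(mono, "c"), met_key(poly, "c"))), "forward")
      m <- add_reaction(m, paste0("SRC_PL", k), stats::setNames(c(-1, 1),
                        c(met_key(chain[3], "c"), met_key(mono, "c"))), "forward")
      if (mm == "a") a <- m else b <- m
    }
    truth$polymer_variants[[k]] <- list(members = c(paste0("RPOLY", k),
                                                    paste0("RPOLY", k, "b")))
  }

  # cross-model duplicates differing only by a proton (merged when protons
  # are ignored, not in the strict BCM merge)
  for (k in seq_len(spec$proton_duplicates)) {
    i <- 3 + k
    st <- a$reactions[[paste0("R", i)]]$stoich
    st2 <- c(st, "h[c]" = 1)
    b$reactions[[paste0("R", i)]] <- NULL
    b <- add_reaction(b, paste0("R", i, "h"), st2, "forward", gpr = paste0("g", i))
    truth$proton_duplicates[[k]] <- c(paste0("R", i), paste0("R", i, "h"))
  }

  # redox twins: same conversion with NADH in A, NADPH in B
  for (k in seq_len(spec$redox_twins)) {
    ra <- paste0("RT", k, "a"); rb <- paste0("RT", k, "b")
    s1 <- paste0("RTs", k); s2 <- paste0("RTp", k)
    a <- add_metabolite(a, s1, "c"); a <- add_metabolite(a, s2, "c")
    b <- add_metabolite(b, s1, "c"); b <- add_metabolite(b, s2, "c")
    for (m_id in c("nadp", "nadph")) b <- add_metabolite(b, m_id, "c")
    a <- add_reaction(a, ra, stats::setNames(c(-1, 1, -1, 1),
            c(met_key(s1, "c"), met_key(s2, "c"), "nadh[c]", "nad[c]")),
            "forward", gpr = paste0("grt", k))
    b <- add_reaction(b, rb, stats::setNames(c(-1, 1, -1, 1),
            c(met_key(s1, "c"), met_key(s2, "c"), "nadph[c]", "nadp[c]")),
            "forward", gpr = paste0("grt", k))
    a <- add_reaction(a, paste0("SRC_RT", k), stats::setNames(c(-1, 1),
            c(met_key(chain[4], "c"), met_key(s1, "c"))), "forward")
    b <- add_reaction(b, paste0("SRC_RT", k), stats::setNames(c(-1, 1),
            c(met_key(chain[4], "c"), met_key(s1, "c"))), "forward")
    truth$redox_twins[[k]] <- c(ra, rb)
  }

  # nested pair: cofactor-optional reaction
  for (k in seq_len(spec$nested_pairs)) {
    s1 <- paste0("NPa", k); s2 <- paste0("NPb", k); s3 <- paste0("NPc", k)
    for (mm in c("a", "b")) {
      m <- if (mm == "a") a else b
      for (id in c(s1, s2, s3)) m <- add_metabolite(m, id, "c")
      m <- add_reaction(m, paste0("SRC_NP", k), stats::setNames(c(-1, 1, 1),
            c(met_key(chain[5], "c"), met_key(s1, "c"), met_key(s2, "c"))), "forward")
      if (mm == "a") a <- m else b <- m
    }
    inner <- paste0("NPinner", k); outer <- paste0("NPouter", k)
    b <- add_reaction(b, inner, stats::setNames(c(-1, -1, 1),
          c(met_key(s1, "c"), met_key(s2, "c"), met_key(s3, "c"))),
          "forward", gpr = paste0("gnp", k))
    a <- add_reaction(a, outer, stats::setNames(c(-1, -1, 1, -1, 1),
          c(met_key(s1, "c"), met_key(s2, "c"), met_key(s3, "c"),
            "nadh[c]", "nad[c]")), "forward", gpr = paste0("gnp", k))
    truth$nested <- rbind(truth$nested,
                          data.frame(inner = inner, outer = outer,
                                     stringsAsFactors = FALSE))
  }

  # lumped reaction in B vs explicit chain in A; the first planting also gets
  # an alternative chain so penalty-tripling must find both sets
  for (k in seq_len(spec$lumped_pairs)) {
    k1 <- paste0("LK", k, "a"); k2 <- paste0("LK", k, "b"); k3 <- paste0("LK", k, "c")
    g1 <- paste0("gl", k, "a"); g2 <- paste0("gl", k, "b")
    for (mm in c("a", "b")) {
      m <- if (mm == "a") a else b
      for (id in c(k1, k3)) m <- add_metabolite(m, id, "c")
      m <- add_reaction(m, paste0("SRC_LK", k), stats::setNames(c(-1, 1),
            c(met_key(chain[6], "c"), met_key(k1, "c"))), "forward")
      m <- add_reaction(m, paste0("SNK_LK", k), stats::setNames(c(-1, 1),
            c(met_key(k3, "c"), met_key(chain[7], "c"))), "forward")
      if (mm == "a") a <- m else b <- m
    }
    a <- add_metabolite(a, k2, "c")
    a <- add_reaction(a, paste0("L", k, "s1"), stats::setNames(c(-1, 1),
          c(met_key(k1, "c"), met_key(k2, "c"))), "forward", gpr = g1)
    a <- add_reaction(a, paste0("L", k, "s2"), stats::setNames(c(-1, 1),
          c(met_key(k2, "c"), met_key(k3, "c"))), "forward", gpr = g2)
    nl <- list(sort(c(paste0("L", k, "s1"), paste0("L", k, "s2"))))
    if (k == 1) {
      k4 <- paste0("LK", k, "d")
      a <- add_metabolite(a, k4, "c")
      a <- add_reaction(a, paste0("L", k, "t1"), stats::setNames(c(-1, 1),
            c(met_key(k1, "c"), met_key(k4, "c"))), "forward", gpr = g1)
      a <- add_reaction(a, paste0("L", k, "t2"), stats::setNames(c(-1, 1),
            c(met_key(k4, "c"), met_key(k3, "c"))), "forward", gpr = g2)
      nl <- c(nl, list(sort(c(paste0("L", k, "t1"), paste0("L", k, "t2")))))
    }
    lr <- paste0("LR", k)
    b <- add_reaction(b, lr, stats::setNames(c(-1, 1),
          c(met_key(k1, "c"), met_key(k3, "c"))), "forward",
          gpr = paste0(g1, " and ", g2))
    truth$lumped[[k]] <- list(candidate = lr, nl_sets = nl)
  }

  # alternative transporters for one metabolite across the same membrane
  for (k in seq_len(spec$alt_transporters)) {
    q <- paste0("Q", k)
    for (mm in c("a", "b")) {
      m <- if (mm == "a") a else b
      m <- add_metabolite(m, q, "e"); m <- add_metabolite(m, q, "c")
      m <- add_reaction(m, paste0("EX_", q), stats::setNames(-1, met_key(q, "e")),
                        "reversible", lb = -5, is_boundary = TRUE)
      m <- add_reaction(m, paste0("SNK_", q), stats::setNames(c(-1, 1),
            c(met_key(q, "c"), met_key(chain[2], "c"))), "forward")
      if (mm == "a") a <- m else b <- m
    }
    ta <- paste0("TQ", k, "a"); tb <- paste0("TQ", k, "b")
    a <- add_reaction(a, ta, stats::setNames(c(-1, 1),
          c(met_key(q, "e"), met_key(q, "c"))), "reversible", gpr = "gq")
    b <- add_reaction(b, tb, stats::setNames(c(-1, 1, -1, 1),
          c(met_key(q, "e"), met_key(q, "c"), "atp[c]", "adp[c]")),
          "forward", gpr = "gq")
    truth$alt_transport[[k]] <- list(metabolite = q, members = sort(c(ta, tb)))
  }

  # invalid transport: direct e-c shortcuts in the periplasm-bearing model A
  for (k in seq_len(spec$invalid_transports)) {
    w <- paste0("W", k)
    a <- add_metabolite(a, w, "e"); a <- add_metabolite(a, w, "c")
    a <- add_reaction(a, paste0("IVT", k), stats::setNames(c(-1, 1),
          c(met_key(w, "e"), met_key(w, "c"))), "reversible")
    a <- add_reaction(a, paste0("EX_", w), stats::setNames(-1, met_key(w, "e")),
                      "reversible", lb = 0, is_boundary = TRUE)
    a <- add_reaction(a, paste0("SNK_", w), stats::setNames(c(-1, 1),
          c(met_key(w, "c"), met_key(chain[3], "c"))), "forward")
    truth$invalid_transport <- c(truth$invalid_transport, paste0("IVT", k))
  }

  # invalid boundary: boundary reaction on a cytosolic metabolite of B
  for (k in seq_len(spec$invalid_boundaries)) {
    v <- paste0("V", k)
    b <- add_metabolite(b, v, "c")
    b <- add_reaction(b, paste0("EX_", v), stats::setNames(-1, met_key(v, "c")),
                      "reversible", lb = 0, is_boundary = TRUE)
    b <- add_reaction(b, paste0("SRC_", v), stats::setNames(c(-1, 1),
          c(met_key(chain[2], "c"), met_key(v, "c"))), "forward")
    truth$invalid_boundary <- c(truth$invalid_boundary, paste0("EX_", v))
  }

  # unknown-compartment reactions in B; all but the last have a cytosolic
  # twin in A and are therefore resolvable
  for (k in seq_len(spec$unknown_reactions)) {
    u <- paste0("U", k)
    resolvable <- k < spec$unknown_reactions || spec$unknown_reactions == 1
    b <- add_compartment(b, UNKNOWN_COMPARTMENT, "unknown")
    b <- add_metabolite(b, u, UNKNOWN_COMPARTMENT)
    rid <- paste0("RU", k)
    b <- add_reaction(b, rid, stats::setNames(c(-1, 1),
          c(met_key(chain[5], "c"), met_key(u, UNKNOWN_COMPARTMENT))), "forward")
    if (resolvable) {
      a <- add_metabolite(a, u, "c")
      a <- add_reaction(a, paste0("RU", k, "a"), stats::setNames(c(-1, 1),
            c(met_key(chain[5], "c"), met_key(u, "c"))), "forward")
    }
    truth$unknown <- rbind(truth$unknown, data.frame(
      reaction = rid, metabolite = met_key(u, UNKNOWN_COMPARTMENT),
      resolvable = resolvable, expected = if (resolvable) "c" else NA_character_,
      stringsAsFactors = FALSE))
  }

  validate_model(a); validate_model(b)
  list(a = a, b = b, truth = truth,
       medium = c(S = 10),
       knockout_genes = c("g0", "gT"))   # no bypass exists for these
}

#' Rename a fixture pair into per-model namespaces
#'
#' Prefixes every metabolite id of model A with `FIXA_` and of model B with
#' `FIXB_`, and emits the mapping table that maps both namespaces back to
#' the canonical ids — a self-contained input for the namespace-mapping
#' workflow.
#'
#' @param fix output of [generate_fixtures()].
#' @return list with renamed `a`, `b` and the `mapping` table.
#' @export
fixture_namespaced <- function(fix) {
  rename_model <- function(m, prefix) {
    old <- unique(m$metabolites$id)
    for (id in old) {
      rows <- which(m$metabolites$id == id)
      for (i in rows) {
        from <- m$metabolites$key[i]
        to <- met_key(paste0(prefix, id), m$metabolites$compartment[i])
        m$metabolites$id[i] <- paste0(prefix, id)
        m$metabolites$key[i] <- to
        for (rid in names(m$reactions)) {
          st <- m$reactions[[rid]]$stoich
          hit <- names(st) == from
          if (any(hit)) {
            names(st)[hit] <- to
            m$reactions[[rid]]$stoich <- st[order(names(st), method = "radix")]
          }
        }
      }
    }
    m
  }
  a <- rename_model(fix$a, "FIXA_")
  b <- rename_model(fix$b, "FIXB_")
  ids <- unique(c(fix$a$metabolites$id, fix$b$metabolites$id))
  mapping <- mapping_table(source_id = c(paste0("FIXA_", ids), paste0("FIXB_", ids)),
                           canonical_id = c(ids, ids),
                           source_ns = rep(c("FIXA", "FIXB"), each = length(ids)))
  list(a = a, b = b, mapping = mapping)
}

#' Hide a fraction of the matcher's network context
#'
#' Marks a random fraction of the attribute rows (shared metabolites and
#' genes) as hidden from the matcher, emulating incomplete network knowledge.
#' The models themselves are unchanged; [build_context()] honours the
#' attached `hidden_context_rows` attribute.
#'
#' @param merged merged model (see [naive_union()]).
#' @param fraction fraction of context rows to hide, in [0, 1].
#' @param seed RNG seed.
#' @return `merged` with attribute `hidden_context_rows` set.
#' @export
degrade_context <- function(merged, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  ctx <- build_context(merged)
  rows <- rownames(ctx$M)
  set.seed(seed)
  hidden <- if (fraction > 0) sample(rows, floor(fraction * length(rows))) else character()
  attr(merged, "hidden_context_rows") <- hidden
  merged
}
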