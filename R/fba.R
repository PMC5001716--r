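#' Flux balance analysis
#'
#' Maximises (or minimises) the flux through an objective reaction subject to
#' steady-state mass balance `S v = 0` and the model's flux bounds.
#'
#' @param model a `gsm_model`.
#' @param objective reaction id; defaults to the model's biomass reaction.
#' @param maximize logical.
#' @return list with `objval` (objective flux; 0 with `flagged = TRUE` when
#'   the LP is infeasible), `fluxes` (named vector) and `status`.
#' @export
fba <- function(model, objective = model$biomass_reaction_id, maximize = TRUE) {
  if (is.na(objective) || !(objective %in% names(model$reactions)))
    stop("objective reaction not found; set biomass_reaction_id or pass `objective`")
  rids <- names(model$reactions)
  S <- build_stoich_matrix(model)
  lb <- vapply(model$reactions, function(r) r$lb, numeric(1))
  ub <- vapply(model$reactions, function(r) r$ub, numeric(1))
  obj <- as.numeric(rids == objective)
  res <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, maximize = maximize)
  if (res$status != "optimal") {
    return(list(objval = 0, fluxes = stats::setNames(rep(NA_real_, length(rids)), rids),
                status = res$status, flagged = TRUE))
  }
  list(objval = res$objval, fluxes = stats::setNames(res$x, rids),
       status = res$status, flagged = FALSE)
}

#' Apply a growth medium to boundary reactions
#'
#' Closes all uptakes, then opens the uptake direction of each boundary
#' reaction whose metabolite id appears in `medium`, up to the stated maximal
#' uptake rate. Secretion stays open (up to 1000) for every boundary reaction.
#'
#' @param model a `gsm_model`.
#' @param medium named numeric vector: metabolite id (compartment-free) ->
#'   maximal uptake rate.
#' @return the model with adjusted boundary bounds.
#' @export
apply_medium <- function(model, medium) {
  for (rid in names(model$reactions)) {
    rxn <- model$reactions[[rid]]
    if (!rxn$is_boundary) next
    ids <- met_key_parts(names(rxn$stoich))$id
    uptake <- max(c(0, unname(medium[ids])), na.rm = TRUE)
    coef <- rxn$stoich[[1]]
    if (coef < 0) {           # positive flux removes the metabolite: secretion
      rxn$lb <- -uptake; rxn$ub <- 1000
    } else {                  # positive flux injects the metabolite: uptake
      rxn$lb <- -1000; rxn$ub <- uptake
    }
    model$reactions[[rid]] <- rxn
  }
  model
}

#' Maximal biomass flux for a medium and genotype
#'
#' Knocked-out genes are removed from the gene set; every reaction whose GPR
#' evaluates to `FALSE` without them (spontaneous reactions are unaffected)
#' has its bounds set to zero, then biomass flux is maximised by FBA.
#'
#' @param model a `gsm_model` with a designated biomass reaction.
#' @param medium named uptake map (see [apply_medium()]); `NULL` leaves the
#'   model's boundary bounds untouched.
#' @param knockouts character vector of deleted genes.
#' @return maximal biomass flux (numeric scalar).
#' @export
simulate_growth <- function(model, medium = NULL, knockouts = character()) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (length(knockouts)) {
    present <- setdiff(model$genes$id, knockouts)
    for (rid in names(model$reactions)) {
      rxn <- model$reactions[[rid]]
      if (is.null(rxn$gpr)) next
      if (!gpr_eval(rxn$gpr, present)) {
        model$reactions[[rid]]$lb <- 0
        model$reactions[[rid]]$ub <- 0
      }
    }
  }
  fba(model)$objval
}

#' Binary growth call from simulated fluxes
#'
#' The wild type grows iff its maximal biomass flux exceeds 1e-6. A mutant
#' grows iff its flux reaches 30\% of the wild-type flux. Both cutoffs are
#' configurable.
#'
#' @param wildtype_flux wild-type maximal biomass flux.
#' @param mutant_flux mutant flux, or `NULL` for a wild-type call.
#' @param config tunables (see [default_config()]).
#' @return `"growth"` or `"no-growth"`; a mutant call against a non-growing
#'   wild type returns `"no-growth"` with attribute `flagged = TRUE`.
#' @export
call_growth <- function(wildtype_flux, mutant_flux = NULL, config = default_config()) {
  wt_grows <- wildtype_flux > config$wt_cutoff
  if (is.null(mutant_flux)) return(if (wt_grows) "growth" else "no-growth")
  if (!wt_grows) return(structure("no-growth", flagged = TRUE))
  if (mutant_flux >= config$rel_growth * wildtype_flux) "growth" else "no-growth"
}

#' Evaluate growth-phenotype predictions against observations
#'
#' Runs [simulate_growth()] for every record of a phenotype dataset, calls
#' growth/no-growth with [call_growth()], and summarises the confusion matrix
#' (growth = positive class) as sensitivity, specificity, accuracy and the
#' Matthews correlation coefficient (0 when a denominator factor vanishes).
#'
#' @param model a `gsm_model`.
#' @param data a phenotype dataset: list with `records` (data.frame with
#'   columns `condition`, `genotype` — semicolon-separated deleted genes, empty
#'   for wild type — and `observed`, `"growth"`/`"no-growth"`) and `media`
#'   (named list: condition -> uptake map).
#' @param config tunables.
#' @return a `MetricsReport` list: TP, TN, FP, FN, sensitivity, specificity,
#'   accuracy, mcc, n_skipped (records with unresolvable genes/metabolites).
#' @export
evaluate_phenotypes <- function(model, data, config = default_config()) {
  rec <- data$records
  wt_cache <- list()
  TP <- TN <- FP <- FN <- 0L; skipped <- 0L
  for (i in seq_len(nrow(rec))) {
    cond <- rec$condition[i]
    medium <- data$media[[cond]]
    if (is.null(medium)) { skipped <- skipped + 1L; next }
    genes <- strsplit(rec$genotype[i], ";")[[1]]
    genes <- genes[nzchar(genes)]
    if (length(genes) && !all(genes %in% model$genes$id)) { skipped <- skipped + 1L; next }
    if (is.null(wt_cache[[cond]])) wt_cache[[cond]] <- simulate_growth(model, medium)
    wt <- wt_cache[[cond]]
    pred <- if (length(genes)) {
      call_growth(wt, simulate_growth(model, medium, genes), config)
    } else call_growth(wt, config = config)
    obs <- rec$observed[i]
    if (obs == "growth" && pred == "growth") TP <- TP + 1L
    else if (obs == "growth") FN <- FN + 1L
    else if (pred == "growth") FP <- FP + 1L
    else TN <- TN + 1L
  }
  metrics_report(TP, TN, FP, FN, skipped)
}

metrics_report <- function(TP, TN, FP, FN, skipped = 0L) {
  total <- TP + TN + FP + FN
  safe_div <- function(a, b) if (b > 0) a / b else 0
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       sensitivity = safe_div(TP, TP + FN),
       specificity = safe_div(TN, TN + FP),
       accuracy = safe_div(TP + TN, total),
       mcc = if (denom > 0) (TP * TN - FP * FN) / denom else 0,
       n_skipped = skipped)
}

#' Flux-variability classification of reactions as active or inactive
#'
#' A reaction is active iff it can carry nonzero flux in some steady-state
#' solution of the bounded flux space (maximum absolute flux over the feasible
#' space above `config$fva_tol`), with no objective imposed.
#'
#' @param model a `gsm_model`.
#' @param medium optional uptake map applied first.
#' @param config tunables.
#' @return named logical vector over reaction ids (`TRUE` = active).
#' @export
active_reactions <- function(model, medium = NULL, config = default_config()) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  rids <- names(model$reactions)
  S <- build_stoich_matrix(model)
  Sd <- as.matrix(S)
  lb <- vapply(model$reactions, function(r) r$lb, numeric(1))
  ub <- vapply(model$reactions, function(r) r$ub, numeric(1))
  b <- rep(0, nrow(Sd))
  out <- stats::setNames(logical(length(rids)), rids)
  for (j in seq_along(rids)) {
    obj <- numeric(length(rids)); obj[j] <- 1
    hi <- lp_solve(obj, Sd, b, lb, ub, maximize = TRUE)
    if (hi$status == "optimal" && abs(hi$objval) > config$fva_tol) { out[j] <- TRUE; next }
    lo <- lp_solve(obj, Sd, b, lb, ub, maximize = FALSE)
    out[j] <- lo$status == "optimal" && abs(lo$objval) > config$fva_tol
  }
  out
}

#' Read a phenotype dataset from delimited text
#'
#' The records file is TSV with columns `condition`, `genotype`
#' (semicolon-separated deleted genes; empty = wild type), `medium_file`, and
#' `observed` (`growth`/`no-growth`). Each referenced medium file is TSV with
#' columns `boundary_metabolite`, `max_uptake`.
#'
#' @param path records TSV path.
#' @param media_dir directory the `medium_file` column is relative to.
#' @return a dataset list consumable by [evaluate_phenotypes()].
#' @export
read_phenotype_dataset <- function(path, media_dir = dirname(path)) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("condition", "genotype", "medium_file", "observed") %in% names(rec)))
  media <- list()
  for (i in seq_len(nrow(rec))) {
    cond <- rec$condition[i]
    if (!is.null(media[[cond]])) next
    mf <- file.path(media_dir, rec$medium_file[i])
    mtab <- utils::read.delim(mf, stringsAsFactors = FALSE)
    media[[cond]] <- stats::setNames(as.numeric(mtab$max_uptake), mtab$boundary_metabolite)
  }
  list(records = rec[c("condition", "genotype", "observed")], media = media)
}
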