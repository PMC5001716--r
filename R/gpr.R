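#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers deciding whether a
#' reaction can be catalysed. AND joins subunits of a complex, OR joins
#' isozymes. Internally a rule is either \code{NULL} (spontaneous / unknown),
#' a character scalar (single gene), or a list \code{list(op = "and"|"or",
#' args = list(...))} of sub-rules.
#'
#' @param text rule string, e.g. \code{"(g1 and g2) or g3"}; \code{"&"} and
#'   \code{"|"} are accepted synonyms for \code{and} / \code{or}.
#' @return parsed rule object (class \code{gpr}).
#' @examples
#' gpr_genes(gpr_parse("(b001 & b002) | b003"))
#' @export
gpr_parse <- function(text) {
  if (is.null(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  env <- new.env()
  env$toks <- toks; env$pos <- 1L
  rule <- gpr_parse_or(env)
  if (env$pos <= length(env$toks))
    stop("GPR parse error: unexpected token '", env$toks[env$pos], "' in: ", text)
  rule
}

gpr_tokenize <- function(text) {
  text <- gsub("&&", " and ", text, fixed = TRUE)
  text <- gsub("||", " or ", text, fixed = TRUE)
  text <- gsub("&", " and ", text, fixed = TRUE)
  text <- gsub("|", " or ", text, fixed = TRUE)
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_parse_or <- function(env) {
  args <- list(gpr_parse_and(env))
  while (env$pos <= length(env$toks) && tolower(env$toks[env$pos]) == "or") {
    env$pos <- env$pos + 1L
    args <- c(args, list(gpr_parse_and(env)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(env) {
  args <- list(gpr_parse_atom(env))
  while (env$pos <= length(env$toks) && tolower(env$toks[env$pos]) == "and") {
    env$pos <- env$pos + 1L
    args <- c(args, list(gpr_parse_atom(env)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(env) {
  if (env$pos > length(env$toks)) stop("GPR parse error: unexpected end of rule")
  tok <- env$toks[env$pos]
  if (tok == "(") {
    env$pos <- env$pos + 1L
    inner <- gpr_parse_or(env)
    if (env$pos > length(env$toks) || env$toks[env$pos] != ")")
      stop("GPR parse error: missing ')'")
    env$pos <- env$pos + 1L
    return(inner)
  }
  if (tok %in% c(")", "and", "or")) stop("GPR parse error at '", tok, "'")
  env$pos <- env$pos + 1L
  tok
}

#' Genes referenced by a GPR rule
#' @param rule parsed rule (from [gpr_parse()]).
#' @return character vector of unique gene ids (empty for spontaneous).
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character())
  if (is.character(rule)) return(rule)
  sort(unique(unlist(lapply(rule$args, gpr_genes))))
}

#' Evaluate a GPR rule under a gene-presence assignment
#' @param rule parsed rule.
#' @param present character vector of genes considered present.
#' @return logical; empty rules evaluate \code{TRUE} (spontaneous).
#' @export
gpr_eval <- function(rule, present) {
  if (is.null(rule)) return(TRUE)
  if (is.character(rule)) return(rule %in% present)
  vals <- vapply(rule$args, gpr_eval, logical(1), present = present)
  if (rule$op == "and") all(vals) else any(vals)
}

#' Render a GPR rule as a string
#' @param rule parsed rule.
#' @return character scalar (\code{""} for spontaneous).
#' @export
gpr_to_string <- function(rule) {
  if (is.null(rule)) return("")
  if (is.character(rule)) return(rule)
  parts <- vapply(rule$args, function(a) {
    s <- gpr_to_string(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = if (rule$op == "and") " and " else " or ")
}

# Structural equality of two rules up to argument order.
gpr_equal <- function(a, b) {
  gpr_canon(a) == gpr_canon(b)
}

gpr_canon <- function(rule) {
  if (is.null(rule)) return("")
  if (is.character(rule)) return(rule)
  parts <- sort(vapply(rule$args, gpr_canon, character(1)))
  paste0(rule$op, "(", paste(parts, collapse = ","), ")")
}

# Merge GPRs of reactions being collapsed into one.
# union: OR of distinct rules; strict: identical gene sets keep one rule,
# subset keeps the superset rule (flagged), otherwise pending.
gpr_merge <- function(rules, mode = c("union", "strict")) {
  mode <- match.arg(mode)
  rules <- rules[!vapply(rules, is.null, logical(1))]
  if (!length(rules)) return(list(rule = NULL, status = "ok"))
  canon <- vapply(rules, gpr_canon, character(1))
  rules <- rules[!duplicated(canon)]
  if (length(rules) == 1L) return(list(rule = rules[[1L]], status = "ok"))
  if (mode == "union") {
    return(list(rule = list(op = "or", args = rules), status = "ok"))
  }
  gene_sets <- lapply(rules, gpr_genes)
  sizes <- lengths(gene_sets)
  o <- order(sizes, decreasing = TRUE)
  sup <- gene_sets[[o[1L]]]
  if (all(vapply(gene_sets, function(g) all(g %in% sup), logical(1)))) {
    same <- all(vapply(gene_sets, function(g) setequal(g, sup), logical(1)))
    return(list(rule = rules[[o[1L]]], status = if (same) "ok" else "flagged"))
  }
  list(rule = NULL, status = "pending")
}
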