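#' Parse a gene-protein-reaction rule into disjunctive normal form
#'
#' GPR rules are boolean expressions over gene identifiers with `and`, `or`
#' and parentheses. `or` separates isozymes (independent enzymes able to
#' carry the reaction), `and` genes of one enzyme complex. The parser
#' returns the rule as a list of isozymes, each a character vector of gene
#' ids, i.e. a disjunction of conjunctions. Absorbed isozymes (supersets of
#' another isozyme) and duplicates are removed, so the DNF is minimal in
#' the absorption sense while remaining logically equivalent to the input.
#'
#' `and` binds tighter than `or` when parentheses are absent, following the
#' usual flux-modeling convention.
#'
#' @param rule_text character scalar, e.g. `"(g1 or g2) and g3"`.
#' @return an object of class `gpr_rule`: list with `dnf` (list of sorted
#'   character vectors) and `text` (the input).
#' @examples
#' parse_gpr("g1 and g2")
#' parse_gpr("(g1 or g2) and g3")
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  toks <- gpr_tokenize(rule_text)
  if (nrow(toks) == 0L) stop("empty GPR rule")
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- rule_text
  dnf <- gpr_parse_or(st)
  if (st$pos <= nrow(st$toks))
    gpr_error(st, sprintf("unexpected token '%s'", st$toks$value[st$pos]))
  structure(list(dnf = gpr_minimize(dnf), text = rule_text), class = "gpr_rule")
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) return(data.frame(value = character(), pos = integer()))
  vals <- regmatches(text, gregexpr(pat, text))[[1]]
  data.frame(value = vals, pos = as.integer(m), stringsAsFactors = FALSE)
}

gpr_error <- function(st, msg) {
  pos <- if (st$pos <= nrow(st$toks)) st$toks$pos[st$pos] else nchar(st$text) + 1L
  stop(sprintf("GPR parse error at position %d: %s", pos, msg), call. = FALSE)
}

gpr_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$value[st$pos] else NA_character_

gpr_is_op <- function(tok, op) !is.na(tok) && tolower(tok) == op

# or-level: union of the term DNFs
gpr_parse_or <- function(st) {
  dnf <- gpr_parse_and(st)
  while (gpr_is_op(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    dnf <- c(dnf, gpr_parse_and(st))
  }
  dnf
}

# and-level: cartesian product of conjunctions
gpr_parse_and <- function(st) {
  dnf <- gpr_parse_atom(st)
  while (gpr_is_op(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    rhs <- gpr_parse_atom(st)
    dnf <- unlist(lapply(dnf, function(l)
      lapply(rhs, function(r) sort(unique(c(l, r))))), recursive = FALSE)
  }
  dnf
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) gpr_error(st, "unexpected end of rule")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    dnf <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) gpr_error(st, "expected ')'")
    st$pos <- st$pos + 1L
    return(dnf)
  }
  if (tok == ")" || gpr_is_op(tok, "and") || gpr_is_op(tok, "or"))
    gpr_error(st, sprintf("unexpected token '%s'", tok))
  st$pos <- st$pos + 1L
  list(tok)
}

# drop duplicate isozymes and any isozyme that is a superset of another
gpr_minimize <- function(dnf) {
  dnf <- lapply(dnf, function(s) sort(unique(s)))
  dnf <- dnf[!duplicated(vapply(dnf, paste, "", collapse = "\r"))]
  keep <- vapply(seq_along(dnf), function(i) {
    !any(vapply(seq_along(dnf), function(j)
      j != i && length(dnf[[j]]) < length(dnf[[i]]) && all(dnf[[j]] %in% dnf[[i]]),
      logical(1)))
  }, logical(1))
  # among equal-length sets duplicates are already gone; supersets removed
  dnf[keep]
}

#' Evaluate a GPR rule under a gene on/off assignment
#'
#' @param rule a `gpr_rule`.
#' @param active character vector of genes considered present/on.
#' @return logical: TRUE if at least one isozyme has all members active.
#' @export
gpr_eval <- function(rule, active) {
  stopifnot(inherits(rule, "gpr_rule"))
  any(vapply(rule$dnf, function(s) all(s %in% active), logical(1)))
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ",
      paste(vapply(x$dnf, function(s) paste0("(", paste(s, collapse = " and "), ")"), ""),
            collapse = " or "), "\n", sep = "")
  invisible(x)
}

#' All gene ids referenced by a GPR rule
#' @param rule a `gpr_rule`.
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(rule) sort(unique(unlist(rule$dnf)))
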