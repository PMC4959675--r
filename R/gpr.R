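#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' Rules combine gene ids with `and` (protein complex: all subunits
#' required), `or` (isozymes: any one suffices) and parentheses,
#' case-insensitively. An empty rule means the reaction has no associated
#' gene.
#'
#' Grammar (standard precedence, `and` binds tighter than `or`):
#' ```
#'   expr   := term ('or' term)*
#'   term   := factor ('and' factor)*
#'   factor := gene | '(' expr ')'
#' ```
#'
#' @param rule Character scalar (may be `""` or `NA` for no gene).
#' @return `NULL` for an empty rule, otherwise a tree of nested lists: a
#'   leaf is `list(op = "gene", gene = <id>)`, an inner node is
#'   `list(op = "and"|"or", children = list(...))`. The tree carries class
#'   `"gpr"`.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  if (length(rule) != 1L) stop("'rule' must be a single string")
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)

  # tokenize, remembering character positions for error messages
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", rule)[[1]]
  tokens <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- as.integer(m)
  kind <- ifelse(tokens == "(", "lparen",
          ifelse(tokens == ")", "rparen",
          ifelse(tolower(tokens) == "and", "and",
          ifelse(tolower(tokens) == "or", "or", "gene"))))
  i <- 0L
  peek <- function() if (i < length(tokens)) kind[i + 1L] else "eof"
  advance <- function() { i <<- i + 1L; tokens[i] }
  fail <- function(msg) {
    at <- if (i < length(tokens)) pos[i + 1L] else nchar(rule) + 1L
    stop("GPR parse error at position ", at, ": ", msg, " in rule '", rule, "'")
  }
  parse_factor <- function() {
    k <- peek()
    if (k == "gene") {
      list(op = "gene", gene = advance())
    } else if (k == "lparen") {
      advance()
      node <- parse_expr()
      if (peek() != "rparen") fail("expected ')'")
      advance()
      node
    } else fail(paste0("expected gene or '(', found ",
                       if (k == "eof") "end of rule" else paste0("'", tokens[i + 1L], "'")))
  }
  parse_term <- function() {
    children <- list(parse_factor())
    while (peek() == "and") { advance(); children <- c(children, list(parse_factor())) }
    if (length(children) == 1L) children[[1L]] else list(op = "and", children = children)
  }
  parse_expr <- function() {
    children <- list(parse_term())
    while (peek() == "or") { advance(); children <- c(children, list(parse_term())) }
    if (length(children) == 1L) children[[1L]] else list(op = "or", children = children)
  }
  tree <- parse_expr()
  if (peek() != "eof") fail(paste0("unexpected '", tokens[i + 1L], "'"))
  class(tree) <- c("gpr", class(tree))
  tree
}

#' Genes appearing in a GPR tree
#'
#' @param tree Output of [parse_gpr()] (`NULL` allowed).
#' @return Character vector of distinct gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}
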