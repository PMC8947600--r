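# Gene-protein-reaction (GPR) boolean rules.
#
# A GPR states which gene combinations sustain a reaction: AND joins the
# subunits of a complex (losing any one disables it), OR joins isozymes
# (all must be lost). Rules are monotone -- no negation -- so "minimal
# falsifying gene sets" are well defined and are exactly the prime
# implicants of the negated rule.

gpr_true <- function() structure(list(type = "true"), class = "gpr")
gpr_gene <- function(g) structure(list(type = "gene", gene = g), class = "gpr")

gpr_node <- function(op, args) {
  # flatten nested nodes of the same operator
  flat <- list()
  for (a in args) {
    if (a$type == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  if (length(flat) == 1L) return(flat[[1L]])
  structure(list(type = op, args = flat), class = "gpr")
}

#' Parse a gene-protein-reaction rule
#'
#' Accepts the usual GPR grammar: gene identifiers combined with `and` /
#' `or` (case-insensitive) and parentheses; `and` binds tighter than `or`.
#' An empty rule is the constant `TRUE`: the reaction has no gene
#' association and cannot be disabled by any knockout.
#'
#' @param rule character scalar, e.g. `"HPRT1 or PNP or (GMPS and XDH)"`.
#' @return a `gpr` parse tree.
#' @export
#' @examples
#' parse_gpr("g1 and g2")
#' parse_gpr("")
parse_gpr <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(gpr_true())

  m <- gregexpr("\\(|\\)|[^()[:space:]]+", rule)[[1L]]
  toks <- regmatches(rule, list(m))[[1L]]
  pos <- as.integer(m)
  i <- 1L
  fail <- function(what, at) {
    stop(sprintf("GPR parse error at position %d: %s (rule: %s)", at, what, rule),
         call. = FALSE)
  }
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  advance <- function() {
    t <- toks[i]
    i <<- i + 1L
    t
  }
  is_op <- function(t, op) !is.na(t) && tolower(t) == op

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) {
      advance()
      args <- c(args, list(parse_term()))
    }
    gpr_node("or", args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    gpr_node("and", args)
  }
  parse_factor <- function() {
    t <- peek()
    at <- if (i <= length(pos)) pos[i] else nchar(rule) + 1L
    if (is.na(t)) fail("unexpected end of rule", at)
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) fail("unbalanced parentheses", at)
      advance()
      return(e)
    }
    if (t == ")") fail("unbalanced parentheses", at)
    if (tolower(t) %in% c("and", "or")) fail(sprintf("misplaced operator '%s'", t), at)
    advance()
    gpr_gene(t)
  }

  out <- parse_expr()
  if (i <= length(toks)) fail(sprintf("unexpected token '%s'", toks[i]), pos[i])
  out
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Render a GPR tree back to rule text
#'
#' @param expr a `gpr` tree.
#' @return character scalar; the constant `TRUE` renders as `""`.
#' @export
gpr_to_string <- function(expr) {
  render <- function(e, parent_op = NULL) {
    switch(e$type,
      true = "",
      gene = e$gene,
      {
        joined <- paste(vapply(e$args, render, character(1), parent_op = e$type),
                        collapse = paste0(" ", e$type, " "))
        if (!is.null(parent_op) && parent_op != e$type) paste0("(", joined, ")") else joined
      }
    )
  }
  render(expr)
}

#' Genes referenced by a GPR tree
#'
#' @param expr a `gpr` tree.
#' @return character vector of unique gene identifiers (sorted).
#' @export
gpr_genes <- function(expr) {
  walk <- function(e) {
    switch(e$type,
      true = character(0),
      gene = e$gene,
      unlist(lapply(e$args, walk))
    )
  }
  sort(unique(walk(expr)), method = "radix")
}

#' Evaluate a GPR under a gene-knockout assignment
#'
#' @param expr a `gpr` tree.
#' @param inactive character vector of inactive (knocked-out / unexpressed)
#'   genes; all other genes are active.
#' @return logical: is the reaction still catalysable?
#' @export
eval_gpr <- function(expr, inactive = character(0)) {
  switch(expr$type,
    true = TRUE,
    gene = !(expr$gene %in% inactive),
    and = all(vapply(expr$args, eval_gpr, logical(1), inactive = inactive)),
    or = any(vapply(expr$args, eval_gpr, logical(1), inactive = inactive))
  )
}

is_gpr_true <- function(expr) identical(expr$type, "true")

# drop sets that are proper supersets of another set in the collection,
# and duplicates; sets are sorted character vectors
minimalize_sets <- function(sets) {
  if (length(sets) <= 1L) return(sets)
  keys <- vapply(sets, paste, character(1), collapse = ";")
  sets <- sets[!duplicated(keys)]
  sizes <- lengths(sets)
  ord <- order(sizes)
  sets <- sets[ord]
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    if (!keep[i]) next
    for (j in seq_along(sets)) {
      if (j >= i) break
      if (keep[j] && all(sets[[j]] %in% sets[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets[keep]
}

#' Minimal gene sets whose joint loss falsifies a GPR
#'
#' Computes the complete family of minimal falsifying gene sets (the prime
#' implicants of the negated rule) by recursive cross-product with subset
#' pruning: an AND is falsified by falsifying any argument, an OR by
#' falsifying all of them.
#'
#' @param expr a `gpr` tree; must not be the constant `TRUE`.
#' @param max_sets combinatorial guard: abort with an error if the working
#'   collection exceeds this many sets.
#' @return list of sorted character vectors; every falsifying gene set
#'   contains one of them, and no proper subset of any of them falsifies
#'   the rule.
#' @export
#' @examples
#' minimal_falsifying_sets(parse_gpr("g1 and g2"))
#' minimal_falsifying_sets(parse_gpr("g1 or g2"))
minimal_falsifying_sets <- function(expr, max_sets = 10000L) {
  if (is_gpr_true(expr)) {
    stop("reaction has no gene association (GPR is TRUE); it cannot be disabled by gene knockouts",
         call. = FALSE)
  }
  recur <- function(e) {
    switch(e$type,
      true = list(), # unfalsifiable branch contributes nothing
      gene = list(e$gene),
      and = {
        out <- list()
        for (a in e$args) out <- c(out, recur(a))
        if (length(out) > max_sets) {
          stop(sprintf("GPR expansion exceeds %d minimal sets; rule too complex", max_sets),
               call. = FALSE)
        }
        minimalize_sets(out)
      },
      or = {
        acc <- list(character(0))
        for (a in e$args) {
          sub <- recur(a)
          if (length(sub) == 0L) return(list()) # an always-true isozyme
          acc <- unlist(
            lapply(acc, function(s) lapply(sub, function(t) sort(unique(c(s, t))))),
            recursive = FALSE
          )
          if (length(acc) > max_sets) {
            stop(sprintf("GPR expansion exceeds %d minimal sets; rule too complex", max_sets),
                 call. = FALSE)
          }
          acc <- minimalize_sets(acc)
        }
        acc
      }
    )
  }
  out <- recur(expr)
  if (length(out) == 0L) {
    stop("GPR cannot be falsified by any gene knockout", call. = FALSE)
  }
  out[order(lengths(out), vapply(out, paste, character(1), collapse = ";"))]
}

#' Exhaustive enumeration of minimal falsifying sets
#'
#' Independent check of [minimal_falsifying_sets()]: evaluates the rule
#' under every gene-inactivation assignment and keeps the minimal
#' falsifying ones. Exponential in the number of genes, so guarded.
#'
#' @param expr a `gpr` tree; must not be the constant `TRUE`.
#' @param max_genes refuse rules with more genes than this.
#' @return list of sorted character vectors, same ordering as
#'   [minimal_falsifying_sets()].
#' @export
falsifying_sets_exhaustive <- function(expr, max_genes = 15L) {
  if (is_gpr_true(expr)) {
    stop("reaction has no gene association (GPR is TRUE)", call. = FALSE)
  }
  genes <- gpr_genes(expr)
  ng <- length(genes)
  if (ng > max_genes) {
    stop(sprintf("exhaustive enumeration refused for %d genes (limit %d)", ng, max_genes),
         call. = FALSE)
  }
  n_masks <- bitwShiftL(1L, ng)
  falsifies <- logical(n_masks)
  for (mask in seq_len(n_masks - 1L)) {
    inactive <- genes[bitwAnd(bitwShiftR(mask, seq_len(ng) - 1L), 1L) == 1L]
    falsifies[mask + 1L] <- !eval_gpr(expr, inactive)
  }
  out <- list()
  for (mask in seq_len(n_masks - 1L)) {
    if (!falsifies[mask + 1L]) next
    # minimal iff removing any single member restores the rule (monotone)
    bits <- which(bitwAnd(bitwShiftR(mask, seq_len(ng) - 1L), 1L) == 1L)
    sub_ok <- vapply(bits, function(b) {
      falsifies[bitwAnd(mask, bitwNot(bitwShiftL(1L, b - 1L))) + 1L]
    }, logical(1))
    if (!any(sub_ok)) out <- c(out, list(sort(genes[bits])))
  }
  out[order(lengths(out), vapply(out, paste, character(1), collapse = ";"))]
}
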