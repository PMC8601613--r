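#' @title GPR Boolean expressions
#'
#' @description
#' A gene-protein-reaction (GPR) rule is a Boolean expression over gene
#' identifiers: `and` joins genes encoding subunits of one enzyme complex
#' (all jointly required), `or` joins alternative isoforms (any one
#' suffices). Expressions are stored as trees of class `"gpr"` with node
#' kinds `EMPTY`, `GENE`, `AND`, `OR`. Operator nodes always hold at least
#' two children and are kept normalized: associative nesting is flattened,
#' duplicate children removed, and children ordered canonically, so that
#' [gpr_serialize()] is deterministic.
#'
#' @name gpr
NULL

gpr_node <- function(kind, gene = NULL, children = NULL) {
  structure(list(kind = kind, gene = gene, children = children),
            class = "gpr")
}

#' Construct GPR expression nodes
#'
#' `gpr_empty()` is the empty (no-gene) rule; `gpr_gene()` a single-gene
#' leaf; `gpr_and()`/`gpr_or()` operator nodes over two or more
#' subexpressions or gene identifier strings. Operator constructors
#' normalize their result.
#'
#' @param ... child expressions (`"gpr"` objects) or gene identifier strings.
#' @return An object of class `"gpr"`.
#' @examples
#' gpr_or(gpr_and("g1", "g2"), "g3")
#' @export
gpr_empty <- function() gpr_node("EMPTY")

#' @rdname gpr_empty
#' @param identifier gene identifier token (no whitespace, parentheses, or
#'   the bare words "and"/"or"; comparison is case-preserving).
#' @export
gpr_gene <- function(identifier) {
  check_gene_token(identifier)
  gpr_node("GENE", gene = identifier)
}

check_gene_token <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop("gene identifier must be a single non-empty string", call. = FALSE)
  if (grepl("[()\\s]", x, perl = TRUE))
    stop("gene identifier '", x, "' contains whitespace or parentheses",
         call. = FALSE)
  if (tolower(x) %in% c("and", "or"))
    stop("gene identifier must not be the bare word 'and'/'or'", call. = FALSE)
  invisible(x)
}

as_gpr_child <- function(x) {
  if (inherits(x, "gpr")) x else gpr_gene(x)
}

#' @rdname gpr_empty
#' @export
gpr_and <- function(...) {
  gpr_normalize(gpr_node("AND", children = lapply(list(...), as_gpr_child)))
}

#' @rdname gpr_empty
#' @export
gpr_or <- function(...) {
  gpr_normalize(gpr_node("OR", children = lapply(list(...), as_gpr_child)))
}

#' @export
print.gpr <- function(x, ...) {
  s <- gpr_serialize(x)
  cat("<GPR> ", if (nzchar(s)) s else "(empty rule)", "\n", sep = "")
  invisible(x)
}

is_gpr_operator <- function(x) x$kind %in% c("AND", "OR")

#' Genes of a GPR expression
#'
#' @param expr a `"gpr"` expression.
#' @return Character vector of distinct gene identifiers (sorted).
#' @export
gpr_genes <- function(expr) {
  stopifnot(inherits(expr, "gpr"))
  walk <- function(x) {
    switch(x$kind,
           EMPTY = character(),
           GENE = x$gene,
           unlist(lapply(x$children, walk)))
  }
  sort(unique(walk(expr)))
}

## gene-set signature used for canonical child ordering
gpr_signature <- function(x) paste(gpr_genes(x), collapse = "\r")

#' Normalize a GPR expression
#'
#' Flattens associative nesting (an `AND` child of an `AND` node is merged
#' into its parent), removes duplicate children, orders children by their
#' gene-set signature (ties broken by serialized form), and collapses
#' single-child operator nodes. `EMPTY` never survives as a child.
#'
#' @param expr a `"gpr"` expression.
#' @return The normalized `"gpr"` expression.
#' @export
gpr_normalize <- function(expr) {
  stopifnot(inherits(expr, "gpr"))
  if (!is_gpr_operator(expr)) return(expr)
  kids <- lapply(expr$children, gpr_normalize)
  flat <- list()
  for (k in kids) {
    if (k$kind == "EMPTY") next
    if (k$kind == expr$kind) flat <- c(flat, k$children) else flat <- c(flat, list(k))
  }
  if (length(flat) == 0L) return(gpr_empty())
  ser <- vapply(flat, gpr_serialize, character(1))
  flat <- flat[!duplicated(ser)]
  ser <- ser[!duplicated(ser)]
  sig <- vapply(flat, gpr_signature, character(1))
  flat <- flat[order(sig, ser, method = "radix")]
  if (length(flat) == 1L) return(flat[[1L]])
  gpr_node(expr$kind, children = flat)
}

#' Serialize a GPR expression to its rule string
#'
#' Deterministic canonical text form: operator keywords are lowercase,
#' operator subexpressions are parenthesized inside a parent of the other
#' kind (so `and` groups inside an `or` rule carry parentheses), children
#' appear in the canonical order established by [gpr_normalize()], and the
#' empty rule serializes to the empty string.
#'
#' @param expr a `"gpr"` expression.
#' @return A single rule string.
#' @examples
#' gpr_serialize(gpr_or(gpr_and("g2", "g1"), "g3")) # "(g1 and g2) or g3"
#' @export
gpr_serialize <- function(expr) {
  stopifnot(inherits(expr, "gpr"))
  switch(expr$kind,
    EMPTY = "",
    GENE = expr$gene,
    {
      op <- if (expr$kind == "AND") " and " else " or "
      parts <- vapply(expr$children, function(ch) {
        s <- gpr_serialize(ch)
        if (is_gpr_operator(ch)) paste0("(", s, ")") else s
      }, character(1))
      paste(parts, collapse = op)
    })
}

## ---- parsing ---------------------------------------------------------------

gpr_tokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(token = character(), offset = integer()))
  data.frame(token = regmatches(text, list(m))[[1]],
             offset = as.integer(m),
             stringsAsFactors = FALSE)
}

gpr_parse_error <- function(msg, offset) {
  stop(sprintf("GPR parse error at offset %d: %s", offset, msg), call. = FALSE)
}

#' Parse a GPR rule string
#'
#' Grammar: gene tokens combined with the case-insensitive keywords `and`
#' and `or` (precedence `and` over `or`) and balanced parentheses. Empty or
#' whitespace-only text yields the empty rule. The result is normalized.
#'
#' @param text a rule string.
#' @return A `"gpr"` expression.
#' @examples
#' gpr_parse("(g1 and g2) or g3")
#' gpr_parse("g1 and g2 or g3")  # same expression: and binds tighter
#' @export
gpr_parse <- function(text) {
  if (length(text) != 1L || is.na(text)) stop("text must be a single string")
  toks <- gpr_tokenize(text)
  if (nrow(toks) == 0L) return(gpr_empty())
  pos <- 1L
  n <- nrow(toks)
  peek <- function() if (pos <= n) toks$token[pos] else NA_character_
  off <- function() if (pos <= n) toks$offset[pos] else nchar(text) + 1L
  kw <- function(tok) !is.na(tok) && tolower(tok) %in% c("and", "or")

  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) gpr_parse_error("empty operand", off())
    if (tok == "(") {
      open_at <- off()
      pos <<- pos + 1L
      e <- parse_or()
      if (is.na(peek()) || peek() != ")")
        gpr_parse_error("unbalanced parentheses (no match for '(')", open_at)
      pos <<- pos + 1L
      return(e)
    }
    if (tok == ")") gpr_parse_error("unbalanced parentheses (unexpected ')')", off())
    if (kw(tok)) gpr_parse_error(sprintf("dangling operator '%s'", tok), off())
    pos <<- pos + 1L
    gpr_gene(tok)
  }
  parse_and <- function() {
    kids <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      pos <<- pos + 1L
      kids <- c(kids, list(parse_atom()))
    }
    if (length(kids) == 1L) kids[[1L]] else gpr_node("AND", children = kids)
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      pos <<- pos + 1L
      kids <- c(kids, list(parse_and()))
    }
    if (length(kids) == 1L) kids[[1L]] else gpr_node("OR", children = kids)
  }
  out <- parse_or()
  if (!is.na(peek())) {
    if (peek() == ")")
      gpr_parse_error("unbalanced parentheses (unexpected ')')", off())
    gpr_parse_error(sprintf("unexpected token '%s'", peek()), off())
  }
  gpr_normalize(out)
}

## ---- evaluation and truth tables ------------------------------------------

#' Evaluate a GPR expression under a gene assignment
#'
#' Standard Boolean semantics; the empty rule evaluates to `FALSE` (a
#' no-gene reaction is handled upstream by the deletion logic, which never
#' constrains reactions carrying an empty rule).
#'
#' @param expr a `"gpr"` expression.
#' @param assignment named logical vector covering every gene of `expr`.
#' @return A single logical value.
#' @export
gpr_evaluate <- function(expr, assignment) {
  stopifnot(inherits(expr, "gpr"))
  rec <- function(x) {
    switch(x$kind,
      EMPTY = FALSE,
      GENE = {
        if (!x$gene %in% names(assignment))
          stop("assignment is missing gene '", x$gene, "'", call. = FALSE)
        isTRUE(unname(assignment[[x$gene]]))
      },
      AND = all(vapply(x$children, rec, logical(1))),
      OR = any(vapply(x$children, rec, logical(1))))
  }
  rec(expr)
}

## vectorized evaluation over a list of logical columns (one per gene)
gpr_evaluate_vec <- function(expr, cols, nrow) {
  rec <- function(x) {
    switch(x$kind,
      EMPTY = rep(FALSE, nrow),
      GENE = cols[[x$gene]],
      AND = Reduce(`&`, lapply(x$children, rec)),
      OR = Reduce(`|`, lapply(x$children, rec)))
  }
  rec(expr)
}

#' Truth table of a GPR expression
#'
#' Enumerates all `2^N` assignments of the `N` genes in `order`; in row
#' `i` (0-based) gene `j` (1-based) is true iff bit `j` of `i` is set.
#' The empty variable list yields the single all-false row.
#'
#' @param expr a `"gpr"` expression whose genes are all contained in `order`.
#' @param order ordered character vector of gene identifiers (the table
#'   variables); defaults to the sorted gene set of `expr`.
#' @param cap maximum admissible number of variables; tables above the cap
#'   raise a capacity error of class `"gpr_cap_error"` and callers must fall
#'   back to canonical comparison. Default 20.
#' @return An object of class `"gpr_truth_table"`: list with `variables`
#'   and the logical `outputs` vector of length `2^N`.
#' @export
gpr_truth_table <- function(expr, order = gpr_genes(expr), cap = 20L) {
  stopifnot(inherits(expr, "gpr"))
  order <- as.character(order)
  if (anyDuplicated(order)) stop("variable order contains duplicates")
  missing <- setdiff(gpr_genes(expr), order)
  if (length(missing))
    stop("variable order does not cover gene(s): ", paste(missing, collapse = ", "))
  n <- length(order)
  if (n > cap)
    stop(structure(class = c("gpr_cap_error", "error", "condition"),
                   list(message = sprintf(
                          "%d variables exceed the truth-table cap of %d", n, cap),
                        call = NULL)))
  rows <- 2L^n
  cols <- list()
  for (j in seq_len(n)) {
    cols[[order[j]]] <- rep(rep(c(FALSE, TRUE), each = 2L^(j - 1L)),
                            length.out = rows)
  }
  structure(list(variables = order,
                 outputs = gpr_evaluate_vec(expr, cols, rows)),
            class = "gpr_truth_table")
}

#' @export
print.gpr_truth_table <- function(x, ...) {
  cat("<GPR truth table> ", length(x$variables), " variable(s), ",
      length(x$outputs), " rows, ", sum(x$outputs), " true\n", sep = "")
  invisible(x)
}

## ---- classification --------------------------------------------------------

#' Classify a GPR rule
#'
#' Rules fall in five mutually exclusive classes: `NO_GENE` (empty rule),
#' `ONE_GENE` (a single gene), and the multi-gene classes `OR` (only `or`
#' operators), `AND` (only `and`), and `MIXED` (both).
#'
#' @param expr a `"gpr"` expression (normalized).
#' @return One of `"NO_GENE"`, `"ONE_GENE"`, `"OR"`, `"AND"`, `"MIXED"`.
#' @export
gpr_classify <- function(expr) {
  stopifnot(inherits(expr, "gpr"))
  expr <- gpr_normalize(expr)
  ops <- function(x) {
    if (!is_gpr_operator(x)) return(character())
    unique(c(x$kind, unlist(lapply(x$children, ops))))
  }
  o <- ops(expr)
  if (expr$kind == "EMPTY") "NO_GENE"
  else if (expr$kind == "GENE") "ONE_GENE"
  else if (setequal(o, "OR")) "OR"
  else if (setequal(o, "AND")) "AND"
  else "MIXED"
}

gpr_rule_classes <- c("NO_GENE", "ONE_GENE", "OR", "AND", "MIXED")

## ---- canonical form (above-cap comparison) ---------------------------------

## absorption over OR-of-(genes/AND-of-genes) and AND-of-(genes/OR-of-genes):
## x or (x and y) -> x ; x and (x or y) -> x
gpr_absorb <- function(expr) {
  if (!is_gpr_operator(expr)) return(expr)
  kids <- lapply(expr$children, gpr_absorb)
  pure_set <- function(x, op) {
    # gene set of a leaf or a pure op-of-genes node, else NULL
    if (x$kind == "GENE") return(x$gene)
    if (x$kind == op &&
        all(vapply(x$children, function(c) c$kind == "GENE", logical(1))))
      return(vapply(x$children, function(c) c$gene, character(1)))
    NULL
  }
  inner <- if (expr$kind == "OR") "AND" else "OR"
  sets <- lapply(kids, pure_set, op = inner)
  keep <- rep(TRUE, length(kids))
  for (i in seq_along(kids)) {
    if (is.null(sets[[i]])) next
    for (j in seq_along(kids)) {
      if (i == j || !keep[j] || is.null(sets[[j]])) next
      # child j absorbed by strictly smaller child i
      if (length(sets[[i]]) < length(sets[[j]]) && all(sets[[i]] %in% sets[[j]]))
        keep[j] <- FALSE
    }
  }
  out <- gpr_node(expr$kind, children = kids[keep])
  gpr_normalize(out)
}

#' Canonical form of a GPR expression
#'
#' Normalization plus absorption (`x or (x and y)` reduces to `x`, dually
#' for `and`). Used for syntactic comparison of rules whose gene count
#' exceeds the truth-table cap; exact for rules built from a single
#' operator kind, conservative otherwise.
#'
#' @param expr a `"gpr"` expression.
#' @return The canonical `"gpr"` expression.
#' @export
gpr_canonical <- function(expr) {
  gpr_absorb(gpr_normalize(expr))
}

## ---- comparison ------------------------------------------------------------

#' Decide equivalence of two GPR rules
#'
#' Below the gene cap, equivalence is decided exactly by comparing truth
#' tables over the union of the two gene sets. Above the cap the canonical
#' forms are compared syntactically: equal forms are equivalent, and
#' differing forms are called non-equivalent whenever both rules are free
#' of mixed operators (set comparison is exact there); only differing
#' mixed-operator pairs are left `"indeterminate"`.
#'
#' @param a,b `"gpr"` expressions.
#' @param cap gene-count cap for exhaustive truth-table comparison
#'   (default 20).
#' @return One of `"equivalent"`, `"not_equivalent"`, `"indeterminate"`.
#' @export
gpr_equivalent <- function(a, b, cap = 20L) {
  stopifnot(inherits(a, "gpr"), inherits(b, "gpr"))
  vars <- sort(union(gpr_genes(a), gpr_genes(b)))
  if (length(vars) <= cap) {
    ta <- gpr_truth_table(a, vars, cap = cap)
    tb <- gpr_truth_table(b, vars, cap = cap)
    return(if (identical(ta$outputs, tb$outputs)) "equivalent" else "not_equivalent")
  }
  ca <- gpr_canonical(a); cb <- gpr_canonical(b)
  if (identical(gpr_serialize(ca), gpr_serialize(cb))) return("equivalent")
  pure <- function(x) gpr_classify(x) != "MIXED"
  if (pure(ca) && pure(cb)) "not_equivalent" else "indeterminate"
}

#' Jaccard index between two gene sets
#'
#' The cardinality of the intersection over the cardinality of the union.
#' Two empty sets score 1 (full overlap: identical empty rules are never a
#' mismatch).
#'
#' @param a,b character vectors of gene identifiers (duplicates ignored).
#' @return A value in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Normalized Hamming similarity between two truth tables
#'
#' Fraction of rows on which the two output vectors agree: 1 when the
#' tables are identical, 0 when they are opposite. Both tables must be
#' built over the same variable order.
#'
#' @param a,b `"gpr_truth_table"` objects with identical variables.
#' @return A value in `[0, 1]`.
#' @export
hamming_similarity <- function(a, b) {
  stopifnot(inherits(a, "gpr_truth_table"), inherits(b, "gpr_truth_table"))
  if (!identical(a$variables, b$variables))
    stop("truth tables are built over different variable orders")
  mean(a$outputs == b$outputs)
}

#' Compare a reconstructed rule against its ground-truth counterpart
#'
#' Implements the benchmark comparison: a pair is a `PERFECT` match iff the
#' rules are equivalent (identical truth tables below the cap, canonical
#' identity above it). For negative matches the Jaccard index over the two
#' gene sets localizes the discrepancy; when the gene sets coincide
#' (Jaccard 1) and the shared gene count is within the cap, the normalized
#' Hamming similarity between the two truth tables quantifies the operator
#' mismatch. The rule class of each side is attached.
#'
#' @param original,generated `"gpr"` expressions (ground truth and
#'   reconstructed rule).
#' @param cap truth-table gene cap (default 20).
#' @return An object of class `"gpr_comparison"`: list with `status`
#'   (`"PERFECT"`, `"NEGATIVE"` or `"INDETERMINATE"`), `jaccard`,
#'   `hamming_similarity` (`NA` unless Jaccard is 1 and the status is
#'   `NEGATIVE`), `rule_class_original`, `rule_class_generated`.
#' @export
gpr_compare <- function(original, generated, cap = 20L) {
  eq <- gpr_equivalent(original, generated, cap = cap)
  ga <- gpr_genes(original); gb <- gpr_genes(generated)
  status <- switch(eq, equivalent = "PERFECT", not_equivalent = "NEGATIVE",
                   indeterminate = "INDETERMINATE")
  jac <- if (status == "PERFECT") 1 else jaccard_index(ga, gb)
  ham <- NA_real_
  if (status == "NEGATIVE" && jac == 1 && length(ga) <= cap) {
    vars <- sort(ga)
    ham <- hamming_similarity(gpr_truth_table(original, vars, cap = cap),
                              gpr_truth_table(generated, vars, cap = cap))
  }
  structure(list(status = status, jaccard = jac, hamming_similarity = ham,
                 rule_class_original = gpr_classify(original),
                 rule_class_generated = gpr_classify(generated)),
            class = "gpr_comparison")
}

#' @export
print.gpr_comparison <- function(x, ...) {
  cat("<GPR comparison> ", x$status,
      sprintf(" | Jaccard %.3f", x$jaccard),
      if (!is.na(x$hamming_similarity))
        sprintf(" | Hamming similarity %.3f", x$hamming_similarity) else "",
      " | ", x$rule_class_original, " vs ", x$rule_class_generated, "\n",
      sep = "")
  invisible(x)
}
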