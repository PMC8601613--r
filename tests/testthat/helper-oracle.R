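# Independent Boolean oracle: rule strings are translated to native R
# logical expressions (and -> &, or -> |) and evaluated with R's own
# parser, a code path entirely separate from the package's.
oracle_eval <- function(text, assignment) {
  if (!nzchar(trimws(text))) return(FALSE)
  expr <- gsub("\\band\\b", "&", text, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  isTRUE(eval(parse(text = expr), envir = as.list(assignment)))
}

# truth-table outputs under the package's bit encoding: in row i (0-based)
# variable j (1-based) is true iff bit j of i is set
oracle_truth_outputs <- function(text, vars) {
  n <- length(vars)
  if (!nzchar(trimws(text))) return(rep(FALSE, 2^n))
  expr <- gsub("\\band\\b", "&", text, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  parsed <- parse(text = expr)[[1]]
  vapply(0:(2^n - 1), function(i) {
    bits <- as.logical(bitwAnd(i, 2^(seq_len(n) - 1L)))
    isTRUE(eval(parsed, envir = as.list(stats::setNames(bits, vars))))
  }, logical(1))
}

oracle_equivalent <- function(a, b, vars) {
  identical(oracle_truth_outputs(a, vars), oracle_truth_outputs(b, vars))
}

# random rule string over R-symbol-safe gene names
random_rule_string <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) return(sample(genes, 1))
  op <- sample(c(" and ", " or "), 1)
  k <- sample(2:3, 1)
  kids <- vapply(seq_len(k), function(i) random_rule_string(genes, depth - 1),
                 character(1))
  paste0("(", paste(kids, collapse = op), ")")
}
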