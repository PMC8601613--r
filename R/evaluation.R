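#' @title Benchmark evaluation of reconstructed rules
#'
#' @description
#' Given a rules table pairing reconstructed rules with curated
#' ground-truth rules, the evaluation reproduces the benchmark
#' statistics: per-reaction truth-table comparison (perfect/negative
#' match), Jaccard indices over gene sets with the normalized Hamming
#' similarity for operator-only mismatches, per-class accounting of
#' perfect / corrected / not-automatic rules with the Automatic
#' percentage (perfect + corrected), the global Jaccard index, and the
#' histogram summaries of the mismatch distributions.
#'
#' @name evaluation
NULL

#' Global Jaccard index of a rules table
#'
#' Quantifies the overall extent to which expected genes are present
#' across all reactions. The pooled definition (default) takes the Jaccard
#' index between the union of genes over all original rules and the union
#' over all reconstructed rules; the `"mean"` alternative averages the
#' per-reaction Jaccard indices.
#'
#' @param table a `"gpr_rules_table"`.
#' @param method `"pooled"` or `"mean"`.
#' @return A value in `[0, 1]`.
#' @export
global_jaccard <- function(table, method = c("pooled", "mean")) {
  method <- match.arg(method)
  parse_safe <- function(s) tryCatch(gpr_parse(s), error = function(e) NULL)
  orig <- lapply(table$rule_original, parse_safe)
  gen <- lapply(table$rule_GPRuler, parse_safe)
  ok <- !vapply(orig, is.null, logical(1)) & !vapply(gen, is.null, logical(1))
  orig <- orig[ok]; gen <- gen[ok]
  if (method == "pooled") {
    jaccard_index(unlist(lapply(orig, gpr_genes)),
                  unlist(lapply(gen, gpr_genes)))
  } else {
    if (length(orig) == 0L) return(1)
    mean(vapply(seq_along(orig), function(i)
      jaccard_index(gpr_genes(orig[[i]]), gpr_genes(gen[[i]])),
      numeric(1)))
  }
}

hist_bins <- function(x, breaks = seq(0, 1, by = 0.1)) {
  x <- x[!is.na(x)]
  counts <- as.integer(table(cut(x, breaks = breaks, include.lowest = TRUE,
                                 right = TRUE)))
  data.frame(lower = utils::head(breaks, -1), upper = breaks[-1],
             count = counts)
}

#' Evaluate a rules table against its ground truth
#'
#' Parses each rule pair (unparseable rows are excluded and reported),
#' compares them with [gpr_compare()], and accounts results per rule class
#' of the original rule: total, perfect matches, and — when evaluation
#' labels are present — corrected and not-automatic counts, with
#' `Automatic = perfect + corrected`.
#'
#' @param table a `"gpr_rules_table"`.
#' @param cap truth-table gene cap (default 20).
#' @param jaccard_method pooled or mean global Jaccard, see
#'   [global_jaccard()].
#' @return An object of class `"gpr_evaluation"`: list with `per_reaction`
#'   (one row per comparable reaction), `counts` (per-class accounting
#'   plus a `TOTAL` row), `automatic_percent`, `global_jaccard`,
#'   `jaccard_histogram` and `hamming_histogram` (negative matches only,
#'   the latter restricted to Jaccard-1 rows), and `excluded`
#'   (parse-failure report).
#' @export
evaluate_rules_table <- function(table, cap = 20L,
                                 jaccard_method = c("pooled", "mean")) {
  jaccard_method <- match.arg(jaccard_method)
  n <- nrow(table)
  excluded <- data.frame(Rxn = character(), column = character(),
                         message = character(), stringsAsFactors = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    orig <- tryCatch(gpr_parse(table$rule_original[i]), error = identity)
    gen <- tryCatch(gpr_parse(table$rule_GPRuler[i]), error = identity)
    bad <- FALSE
    if (inherits(orig, "error")) {
      excluded <- rbind(excluded, data.frame(
        Rxn = table$Rxn[i], column = "rule_original",
        message = conditionMessage(orig), stringsAsFactors = FALSE))
      bad <- TRUE
    }
    if (inherits(gen, "error")) {
      excluded <- rbind(excluded, data.frame(
        Rxn = table$Rxn[i], column = "rule_GPRuler",
        message = conditionMessage(gen), stringsAsFactors = FALSE))
      bad <- TRUE
    }
    if (bad) next
    cmp <- gpr_compare(orig, gen, cap = cap)
    rows[[i]] <- data.frame(
      Rxn = table$Rxn[i], status = cmp$status, jaccard = cmp$jaccard,
      hamming_similarity = cmp$hamming_similarity,
      rule_class_original = cmp$rule_class_original,
      rule_class_generated = cmp$rule_class_generated,
      Evaluation = table$Evaluation[i], stringsAsFactors = FALSE)
  }
  per_reaction <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_reaction))
    per_reaction <- data.frame(Rxn = character(), status = character(),
                               jaccard = numeric(),
                               hamming_similarity = numeric(),
                               rule_class_original = character(),
                               rule_class_generated = character(),
                               Evaluation = character(),
                               stringsAsFactors = FALSE)
  rownames(per_reaction) <- NULL

  counts <- do.call(rbind, lapply(gpr_rule_classes, function(cl) {
    sub <- per_reaction[per_reaction$rule_class_original == cl, , drop = FALSE]
    data.frame(class = cl, total = nrow(sub),
               perfect = sum(sub$status == "PERFECT"),
               corrected = sum(sub$Evaluation == "Corrected by GPRuler"),
               not_automatic = sum(sub$Evaluation ==
                 "Not automatically reconstructed by GPRuler"),
               stringsAsFactors = FALSE)
  }))
  counts$automatic <- counts$perfect + counts$corrected
  totals <- lapply(counts[, -1], function(x) as.integer(sum(x)))
  counts <- rbind(counts, data.frame(class = "TOTAL", totals,
                                     stringsAsFactors = FALSE))
  rownames(counts) <- NULL
  n_eval <- counts$total[counts$class == "TOTAL"]
  automatic_percent <- if (n_eval > 0)
    100 * counts$automatic[counts$class == "TOTAL"] / n_eval else NA_real_

  negatives <- per_reaction[per_reaction$status == "NEGATIVE", , drop = FALSE]
  structure(list(
    per_reaction = per_reaction,
    counts = counts,
    automatic_percent = automatic_percent,
    global_jaccard = global_jaccard(table, jaccard_method),
    jaccard_histogram = hist_bins(negatives$jaccard),
    hamming_histogram = hist_bins(
      negatives$hamming_similarity[negatives$jaccard == 1]),
    excluded = excluded), class = "gpr_evaluation")
}

#' @export
print.gpr_evaluation <- function(x, ...) {
  tot <- x$counts[x$counts$class == "TOTAL", ]
  cat("<rules evaluation> ", tot$total, " reactions | ",
      tot$perfect, " perfect (", sprintf("%.1f%%",
        if (tot$total > 0) 100 * tot$perfect / tot$total else NA), ")",
      if (!is.na(x$automatic_percent))
        sprintf(" | Automatic %.1f%%", x$automatic_percent) else "",
      sprintf(" | global Jaccard %.3f", x$global_jaccard), "\n", sep = "")
  print(x$counts, row.names = FALSE)
  if (nrow(x$excluded))
    cat(nrow(x$excluded), "row(s) excluded for parse failures\n")
  invisible(x)
}
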