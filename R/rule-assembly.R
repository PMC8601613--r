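#' @title Assembling GPR expressions from pairwise relations
#'
#' @description
#' The final step of reconstruction: a reaction's gene set together with
#' its resolved pairwise subunit/isoform relations is turned into the
#' Boolean rule. Genes related by `SUBUNIT` edges form enzyme complexes
#' joined by `and` and enclosed in parentheses; the complexes and the
#' remaining genes (isoforms) are joined by `or`.
#'
#' @name rule-assembly
NULL

subunit_components <- function(genes, resolved) {
  sub <- resolved[resolved$relation == "SUBUNIT" &
                    resolved$gene_a %in% genes &
                    resolved$gene_b %in% genes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    sub[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

#' Assemble a GPR expression from genes and resolved relations
#'
#' Connected components of the subunit-edge subgraph become `and` groups;
#' components and subunit-isolated genes are joined by `or`. Pairs without
#' a resolved relation count as isoforms. When curated complex sets are
#' supplied, every complex complete within the gene set becomes its own
#' `and` group, and a gene shared between several complete complexes
#' appears in each of them (alternative oligomeric enzymes sharing a
#' common subunit — inexpressible through pairwise relations alone, which
#' would merge the complexes into one group); genes not covered by any
#' complete complex fall back to the component interpretation.
#'
#' @param genes character vector: the reaction's gene set.
#' @param graph optional [resolve_relations()] result covering `genes`.
#' @param complexes optional list of [complex_record()] objects.
#' @return A `"gpr"` expression: `EMPTY` for no genes, a leaf for one,
#'   otherwise an `or`-of-`and`-groups (at most that depth).
#' @export
assemble_gpr <- function(genes, graph = NULL, complexes = NULL) {
  genes <- sort(unique(as.character(genes)))
  if (length(genes) == 0L) return(gpr_empty())
  if (length(genes) == 1L) return(gpr_gene(genes))
  resolved <- if (is.null(graph)) {
    data.frame(gene_a = character(), gene_b = character(),
               relation = character(), stringsAsFactors = FALSE)
  } else graph$resolved

  groups <- list()
  remaining <- genes
  if (!is.null(complexes) && length(complexes)) {
    complete <- Filter(function(cx)
      length(cx$components) >= 2L && all(cx$components %in% genes), complexes)
    seen <- character()
    for (cx in complete) {
      key <- paste(sort(cx$components), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      groups <- c(groups, list(sort(cx$components)))
    }
    covered <- unique(unlist(lapply(complete, `[[`, "components")))
    remaining <- setdiff(genes, covered)
  }
  if (length(remaining)) {
    comps <- subunit_components(remaining, resolved)
    groups <- c(groups, unname(lapply(comps, sort)))
  }
  terms <- lapply(groups, function(g) {
    if (length(g) == 1L) gpr_gene(g)
    else do.call(gpr_and, as.list(g))
  })
  if (length(terms) == 1L) return(terms[[1L]])
  do.call(gpr_or, terms)
}

#' Assemble rules for every reaction
#'
#' Orchestrates relation resolution and assembly over a reaction-to-genes
#' map: per reaction the relevant evidence rows are resolved into a
#' relation graph and the rule assembled. Reactions with empty gene sets
#' map to the empty rule. Deterministic given identical inputs.
#'
#' @param reaction_to_genes named list: reaction id -> gene vector.
#' @param evidence evidence data frame covering all pairwise evidence
#'   mined for the involved genes (possibly empty).
#' @param priority evidence source priority, see [gpr_source_priority()].
#' @param complexes optional list of [complex_record()] objects, consulted
#'   per reaction for complete complexes.
#' @return Named list: reaction id -> `"gpr"` expression.
#' @export
assemble_all <- function(reaction_to_genes, evidence = empty_evidence(),
                         priority = gpr_source_priority(),
                         complexes = NULL) {
  out <- lapply(reaction_to_genes, function(genes) {
    graph <- resolve_relations(genes, evidence, priority)
    assemble_gpr(genes, graph, complexes)
  })
  out[order(names(out), method = "radix")]
}
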