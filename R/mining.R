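#' @title Subunit/isoform relationship mining
#'
#' @description
#' For each metabolic gene the pipeline collects pairwise relationship
#' evidence from five channels: free-text mining of protein annotation
#' ("Interaction" and "Function" sections), curated macromolecular complex
#' sets, interaction networks with functional-term annotations, and
#' orthology groups. Evidence is either `SUBUNIT` (the pair belongs to one
#' enzyme complex, joined by `and`) or `ISOFORM` (alternative catalysts,
#' joined by `or`).
#'
#' @name relationship-mining
NULL

evidence_sources <- c("complex_portal", "uniprot_interaction",
                      "uniprot_function", "string", "kegg_orthology")

#' Default conflict-resolution priority over evidence sources
#'
#' Manually curated structured complex data outranks annotation text, which
#' outranks network predictions and orthology grouping.
#'
#' @return Character vector of source labels, highest priority first.
#' @export
gpr_source_priority <- function() evidence_sources

empty_evidence <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             relation = character(), source = character(),
             qualifier = character(), stringsAsFactors = FALSE)
}

relation_evidence <- function(gene, partners, relation, source,
                              qualifier = "none") {
  partners <- setdiff(unique(partners), gene)
  if (length(partners) == 0L) return(empty_evidence())
  a <- pmin(gene, partners); b <- pmax(gene, partners)
  data.frame(gene_a = a, gene_b = b, relation = relation, source = source,
             qualifier = qualifier, stringsAsFactors = FALSE)
}

#' Protein annotation record
#'
#' @param gene gene identifier.
#' @param synonyms character vector of alternative symbols.
#' @param interaction_text,function_text free annotation text (may be empty).
#' @param complex_xrefs identifiers of curated complexes the product belongs to.
#' @param localizations data frame with columns `term` and `evidence`
#'   (`"manual"` or `"automatic"`).
#' @return An object of class `"protein_record"`.
#' @export
protein_record <- function(gene, synonyms = character(),
                           interaction_text = "", function_text = "",
                           complex_xrefs = character(),
                           localizations = data.frame(term = character(),
                                                      evidence = character())) {
  stopifnot(all(localizations$evidence %in% c("manual", "automatic")))
  structure(list(gene = gene, synonyms = as.character(synonyms),
                 interaction_text = interaction_text,
                 function_text = function_text,
                 complex_xrefs = as.character(complex_xrefs),
                 localizations = localizations),
            class = "protein_record")
}

#' Curated complex record
#'
#' @param complex_id complex identifier.
#' @param components character vector of member gene identifiers (>= 1).
#' @return An object of class `"complex_record"`.
#' @export
complex_record <- function(complex_id, components) {
  components <- unique(as.character(components))
  stopifnot(length(components) >= 1L)
  structure(list(complex_id = complex_id, components = components),
            class = "complex_record")
}

#' Default mining keyword list
#'
#' The key terms driving sentence selection in annotation text: the
#' monograms `complex`, `component`, `interact` (stem-tolerant, so
#' "interacts"/"interaction" match) plus the phrase `by similarity`, and
#' the n-grams `interact with`, `part of a complex with`, `consist of`,
#' `associate with`, `heteromerization with`.
#'
#' @return Character vector of keywords/phrases.
#' @export
gpr_default_keywords <- function() {
  c("complex", "component", "interact", "by similarity",
    "interact with", "part of a complex with", "consist of",
    "associate with", "heteromerization with")
}

#' Default stop-word list for frequency analysis
#'
#' @return Character vector of lowercase stop words.
#' @export
gpr_default_stopwords <- function() {
  c("a", "an", "the", "of", "and", "or", "in", "on", "at", "to", "by",
    "with", "is", "are", "was", "were", "be", "been", "it", "its", "this",
    "that", "these", "those", "as", "for", "from", "which", "but", "not",
    "may", "can", "has", "have", "via", "between", "into", "through", "also")
}

tokenize_words <- function(text) {
  m <- gregexpr("[A-Za-z0-9'_.-]+", text)[[1]]
  if (m[1] == -1L) return(character())
  toks <- regmatches(text, list(m))[[1]]
  # trim sentence punctuation stuck to tokens, keep interior dots/hyphens
  toks <- gsub("^[._'-]+|[._'-]+$", "", toks)
  toks[nzchar(toks)]
}

#' Term frequency profile of annotation texts
#'
#' Lowercases and tokenizes the texts, counts monograms (stop words
#' excluded) and consecutive n-grams up to `ngram_max`, and ranks terms by
#' count. This is the analysis that surfaced the default keyword list from
#' highly annotated organisms.
#'
#' @param texts character vector of free texts.
#' @param stop_words lowercase words excluded from the monogram ranking.
#' @param ngram_max maximal n-gram length (>= 1).
#' @return Data frame with columns `term`, `n_words`, `count`, ordered by
#'   decreasing count then term.
#' @export
frequency_profile <- function(texts, stop_words = gpr_default_stopwords(),
                              ngram_max = 1L) {
  stopifnot(ngram_max >= 1L)
  terms <- character()
  widths <- integer()
  for (txt in texts) {
    toks <- tolower(tokenize_words(txt))
    if (length(toks) == 0L) next
    keep <- toks[!toks %in% stop_words]
    terms <- c(terms, keep); widths <- c(widths, rep(1L, length(keep)))
    if (ngram_max >= 2L) {
      for (n in 2:min(ngram_max, length(toks))) {
        if (length(toks) < n) break
        grams <- vapply(seq_len(length(toks) - n + 1L), function(i)
          paste(toks[i:(i + n - 1L)], collapse = " "), character(1))
        terms <- c(terms, grams); widths <- c(widths, rep(n, length(grams)))
      }
    }
  }
  if (length(terms) == 0L)
    return(data.frame(term = character(), n_words = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  tab <- stats::aggregate(list(count = rep(1L, length(terms))),
                          by = list(term = terms, n_words = widths), FUN = sum)
  tab <- tab[order(-tab$count, tab$term, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

split_sentences <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  parts <- strsplit(text, "(?<=[.!?;])\\s+", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

keyword_regex <- function(kw) {
  # stem tolerance for the "interact" family (interacts, interaction, ...)
  if (identical(tolower(kw), "interact")) return("\\binteract")
  words <- strsplit(tolower(kw), "\\s+")[[1]]
  if (words[1] == "interact")
    words[1] <- "interact[a-z]*"
  paste0("\\b", paste(words, collapse = "\\s+"), "\\b")
}

#' Select keyword-bearing sentences from annotation text
#'
#' Splits text on sentence punctuation and keeps, in order of appearance,
#' every sentence containing at least one keyword. Matching is
#' case-insensitive; the `interact` stem matches its inflections.
#'
#' @param text free annotation text.
#' @param keywords keyword/phrase list, see [gpr_default_keywords()].
#' @return Character vector of matching sentences.
#' @export
keyword_sentences <- function(text, keywords = gpr_default_keywords()) {
  stopifnot(length(keywords) >= 1L)
  sents <- split_sentences(text)
  if (length(sents) == 0L) return(character())
  pats <- vapply(keywords, keyword_regex, character(1))
  hit <- vapply(sents, function(s)
    any(vapply(pats, function(p) grepl(p, s, ignore.case = TRUE), logical(1))),
    logical(1))
  unname(sents[hit])
}

#' Build a symbol universe from protein records
#'
#' Maps every gene symbol and synonym (lowercased) to its canonical gene
#' identifier; token recognition inside sentences is exact against this
#' universe, so text mining can never invent partners.
#'
#' @param proteins list of [protein_record()] objects.
#' @return Named character vector: lowercase token -> gene identifier.
#' @export
gene_universe <- function(proteins) {
  out <- character()
  for (p in proteins) {
    toks <- tolower(unique(c(p$gene, p$synonyms)))
    new <- setdiff(toks, names(out))
    out[new] <- p$gene
  }
  out
}

#' Extract complex-partner evidence from annotation text
#'
#' Runs [keyword_sentences()] over the record's "Interaction" and
#' "Function" texts; within each selected sentence every token resolvable
#' through the symbol universe (excluding the record's own gene and
#' synonyms) becomes one `SUBUNIT` evidence pair. Sentences carrying
#' "by similarity" set the `by_similarity` qualifier, recorded but not
#' changing the relation label.
#'
#' @param record a [protein_record()].
#' @param universe token map from [gene_universe()].
#' @param keywords keyword list.
#' @return Evidence data frame (columns `gene_a`, `gene_b`, `relation`,
#'   `source`, `qualifier`).
#' @export
extract_partners <- function(record, universe,
                             keywords = gpr_default_keywords()) {
  stopifnot(inherits(record, "protein_record"))
  out <- empty_evidence()
  own <- tolower(c(record$gene, record$synonyms))
  fields <- list(uniprot_interaction = record$interaction_text,
                 uniprot_function = record$function_text)
  for (src in names(fields)) {
    for (sent in keyword_sentences(fields[[src]], keywords)) {
      toks <- tolower(tokenize_words(sent))
      toks <- setdiff(toks, own)
      partners <- unname(universe[toks[toks %in% names(universe)]])
      partners <- setdiff(unique(partners), record$gene)
      if (length(partners) == 0L) next
      qual <- if (grepl("\\bby similarity\\b", sent, ignore.case = TRUE))
        "by_similarity" else "none"
      out <- rbind(out, relation_evidence(record$gene, partners, "SUBUNIT",
                                          src, qual))
    }
  }
  unique(out)
}

#' Complex-membership evidence
#'
#' Every curated complex containing the gene contributes `SUBUNIT`
#' evidence pairing it with each other component.
#'
#' @param gene gene identifier.
#' @param complexes list of [complex_record()] objects.
#' @return Evidence data frame.
#' @export
complex_partners <- function(gene, complexes) {
  out <- empty_evidence()
  for (cx in complexes) {
    if (!gene %in% cx$components) next
    out <- rbind(out, relation_evidence(gene, cx$components, "SUBUNIT",
                                        "complex_portal"))
  }
  unique(out)
}

#' Interaction network
#'
#' @param edges data frame with columns `gene_a`, `gene_b` (unordered pairs).
#' @param annotations data frame with columns `gene`, `term`, `is_complex`
#'   (logical flag marking protein-complex terms from functional enrichment).
#' @return An object of class `"interaction_network"`.
#' @export
interaction_network <- function(edges = data.frame(gene_a = character(),
                                                   gene_b = character()),
                                annotations = data.frame(gene = character(),
                                                         term = character(),
                                                         is_complex = logical())) {
  structure(list(edges = edges, annotations = annotations),
            class = "interaction_network")
}

#' Network-based complex-partner evidence
#'
#' From the gene's interaction neighbourhood, keeps the neighbours that
#' share at least one protein-complex-flagged functional term with the
#' queried gene; each yields `SUBUNIT` evidence. A gene absent from the
#' network yields no evidence (not an error).
#'
#' @param gene gene identifier.
#' @param network an [interaction_network()].
#' @return Evidence data frame.
#' @export
string_partners <- function(gene, network) {
  stopifnot(inherits(network, "interaction_network"))
  ann <- network$annotations
  if (!gene %in% ann$gene) return(empty_evidence())
  e <- network$edges
  nb <- unique(c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene]))
  nb <- setdiff(nb, gene)
  if (length(nb) == 0L) return(empty_evidence())
  own_terms <- ann$term[ann$gene == gene & ann$is_complex]
  hit <- vapply(nb, function(g)
    length(intersect(own_terms, ann$term[ann$gene == g & ann$is_complex])) > 0L,
    logical(1))
  unique(relation_evidence(gene, nb[hit], "SUBUNIT", "string"))
}

#' Orthology group
#'
#' @param group_id functional-ortholog group identifier.
#' @param members gene identifiers sharing the identifier within one
#'   organism (grouped by molecular-function similarity).
#' @return An object of class `"orthology_group"`.
#' @export
orthology_group <- function(group_id, members) {
  members <- unique(as.character(members))
  stopifnot(length(members) >= 1L)
  structure(list(group_id = group_id, members = members),
            class = "orthology_group")
}

#' Isoform evidence from orthology groups
#'
#' Genes sharing a functional-ortholog identifier are treated as isoforms:
#' each group containing the gene contributes `ISOFORM` evidence pairing
#' it with every other member.
#'
#' @param gene gene identifier.
#' @param groups list of [orthology_group()] objects.
#' @return Evidence data frame.
#' @export
isoform_partners <- function(gene, groups) {
  out <- empty_evidence()
  for (g in groups) {
    if (!gene %in% g$members) next
    out <- rbind(out, relation_evidence(gene, g$members, "ISOFORM",
                                        "kegg_orthology"))
  }
  unique(out)
}

#' Resolve pairwise evidence into a relation graph
#'
#' Each evidenced pair receives exactly one label. When a pair carries both
#' `SUBUNIT` and `ISOFORM` evidence the label of the highest-priority
#' source wins and the conflict is recorded. Pairs without any evidence are
#' not listed; downstream assembly treats them as `ISOFORM` (the default:
#' absent complex evidence means alternative catalysts).
#'
#' @param genes character vector: the reaction's gene set.
#' @param evidence evidence data frame (rows outside `genes` are dropped).
#' @param priority ordered source vector, highest priority first; must
#'   cover all five sources.
#' @return An object of class `"gpr_relation_graph"`: list with `genes`,
#'   `evidence`, `resolved` (one row per pair: `gene_a`, `gene_b`,
#'   `relation`) and `conflicts`.
#' @export
resolve_relations <- function(genes, evidence = empty_evidence(),
                              priority = gpr_source_priority()) {
  if (!all(evidence_sources %in% priority))
    stop("priority must cover all sources: ",
         paste(setdiff(evidence_sources, priority), collapse = ", "))
  genes <- unique(as.character(genes))
  ev <- evidence[evidence$gene_a %in% genes & evidence$gene_b %in% genes, ,
                 drop = FALSE]
  resolved <- data.frame(gene_a = character(), gene_b = character(),
                         relation = character(), stringsAsFactors = FALSE)
  conflicts <- resolved
  if (nrow(ev)) {
    key <- paste(ev$gene_a, ev$gene_b, sep = "\r")
    for (k in unique(key)) {
      rows <- ev[key == k, , drop = FALSE]
      rels <- unique(rows$relation)
      best <- rows[which.min(match(rows$source, priority)), , drop = FALSE]
      resolved <- rbind(resolved, best[, c("gene_a", "gene_b", "relation")])
      if (length(rels) > 1L)
        conflicts <- rbind(conflicts, best[, c("gene_a", "gene_b", "relation")])
    }
    rownames(resolved) <- NULL
  }
  structure(list(genes = genes, evidence = ev, resolved = resolved,
                 conflicts = conflicts),
            class = "gpr_relation_graph")
}

#' @export
print.gpr_relation_graph <- function(x, ...) {
  cat("<relation graph> ", length(x$genes), " gene(s), ",
      nrow(x$resolved), " resolved pair(s), ",
      nrow(x$conflicts), " conflict(s)\n", sep = "")
  invisible(x)
}
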