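#' @title Metabolite, reaction and gene identification
#'
#' @description
#' The first half of the reconstruction pipeline resolves model content
#' against merged database snapshots: metabolite names are matched to
#' compound records (aliases, exact names/synonyms, InChI strings, then
#' fuzzy scoring with an acceptance threshold of 91), reactions are matched
#' by canonical participant signature against a merged multi-source
#' reaction store (the "macro database"), transport reactions are matched
#' through transporter substrate annotations, and candidate genes are
#' filtered by subcellular localization with manual annotations taking
#' priority over automatic predictions.
#'
#' @name entity-resolution
NULL

#' Token-sort Levenshtein similarity score
#'
#' Lowercases both strings, sorts their word tokens, and scores
#' `100 * (1 - d / max(nchar))` where `d` is the Levenshtein distance
#' between the token-sorted forms. Robust to word-order differences in
#' metabolite synonyms.
#'
#' @param a query string.
#' @param b character vector of candidate strings.
#' @return Integer scores in `[0, 100]`, one per candidate.
#' @export
token_sort_score <- function(a, b) {
  norm <- function(x) {
    vapply(x, function(s) {
      toks <- sort(tokenize_words(tolower(s)))
      paste(toks, collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
  qa <- norm(a)
  qb <- norm(b)
  d <- as.integer(utils::adist(qa, qb))
  mx <- pmax(nchar(qa), nchar(qb), 1L)
  as.integer(round(100 * (1 - d / mx)))
}

#' Default metabolite alias table
#'
#' Manual aliases for model metabolites that cannot be traced to compound
#' records in their written form: acyl-carrier protein written `ACP1`,
#' ferredoxin-linked reaction entries resolved through their NADPH
#' dependence, electron-transfer flavoproteins resolved to their FAD /
#' FADH2 cofactors, and the generic `diglyceride` mapped to
#' 1,2-diacyl-sn-glycerol. User-extensible by row-binding.
#'
#' @return Data frame with columns `alias` and `target` (a compound name
#'   or identifier resolvable in the compound index).
#' @export
default_metabolite_aliases <- function() {
  data.frame(
    alias = c("ACP1", "ferredoxin", "adrenal ferredoxin",
              "electron transfer flavoprotein",
              "electron-transfer flavoprotein",
              "reduced electron transfer flavoprotein",
              "diglyceride"),
    target = c("ACP", "NADPH", "NADPH", "FAD", "FAD", "FADH2",
               "1,2-diacyl-sn-glycerol"),
    stringsAsFactors = FALSE)
}

#' Build a name index over compound records
#'
#' @param compounds data frame with columns `compound_id`, `source`,
#'   list-columns `names`, `xrefs`, `ontology_parents` and column `inchi`
#'   (see [read_snapshot()]).
#' @return Long data frame, one row per (name, compound): `name`,
#'   `name_lower`, `compound_id`, `inchi`.
#' @export
compound_index <- function(compounds) {
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    nms <- unique(c(compounds$compound_id[i], compounds$names[[i]]))
    data.frame(name = nms, name_lower = tolower(nms),
               compound_id = compounds$compound_id[i],
               inchi = if ("inchi" %in% names(compounds))
                 compounds$inchi[i] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match a metabolite name against the compound index
#'
#' Resolution order: alias-table hit, exact case-insensitive name/synonym
#' hit, InChI string hit (when the query carries one), then token-sort
#' Levenshtein scoring over all names. A candidate is accepted
#' automatically only when a unique best compound scores at or above the
#' threshold; otherwise the ranked shortlist is returned for confirmation.
#'
#' @param name metabolite name from the model (non-empty).
#' @param index compound index from [compound_index()].
#' @param threshold integer acceptance threshold in `[0, 100]`; default 91,
#'   the calibrated value that excludes clearly wrong matches.
#' @param aliases optional alias table (columns `alias`, `target`); see
#'   [default_metabolite_aliases()].
#' @param inchi optional InChI string carried by the query.
#' @param shortlist_n maximal shortlist length (default 10).
#' @return List with `accepted` (compound id or `NA`) and `shortlist`
#'   (data frame `compound_id`, `name`, `score`, `method`, descending
#'   score).
#' @export
match_metabolite <- function(name, index, threshold = 91L, aliases = NULL,
                             inchi = NULL, shortlist_n = 10L) {
  if (is.na(name) || !nzchar(trimws(name))) stop("empty metabolite name")
  stopifnot(threshold >= 0L, threshold <= 100L)
  query <- trimws(name)

  shortlist <- function(id, nm, score, method) {
    data.frame(compound_id = id, name = nm, score = as.integer(score),
               method = method, stringsAsFactors = FALSE)
  }
  accept <- function(sl) list(accepted = sl$compound_id[1], shortlist = sl)

  if (!is.null(aliases) && nrow(aliases)) {
    hit <- which(tolower(aliases$alias) == tolower(query))
    if (length(hit)) {
      target <- aliases$target[hit[1]]
      rows <- index[index$name_lower == tolower(target) |
                      index$compound_id == target, , drop = FALSE]
      if (nrow(rows))
        return(accept(shortlist(rows$compound_id[1], rows$name[1], 100L,
                                "alias")))
    }
  }

  exact <- index[index$name_lower == tolower(query), , drop = FALSE]
  if (nrow(exact)) {
    ids <- unique(exact$compound_id)
    sl <- shortlist(ids, exact$name[match(ids, exact$compound_id)], 100L,
                    "exact_name")
    if (length(ids) == 1L) return(accept(sl))
    return(list(accepted = NA_character_, shortlist = sl))
  }

  if (!is.null(inchi) && nzchar(inchi)) {
    rows <- index[!is.na(index$inchi) & index$inchi == inchi, , drop = FALSE]
    ids <- unique(rows$compound_id)
    if (length(ids) == 1L)
      return(accept(shortlist(ids, rows$name[1], 100L, "inchi")))
    if (length(ids) > 1L)
      return(list(accepted = NA_character_,
                  shortlist = shortlist(ids, rows$name[match(ids, rows$compound_id)],
                                        100L, "inchi")))
  }

  scores <- token_sort_score(query, index$name)
  best_per_cmp <- stats::aggregate(scores,
                                   by = list(compound_id = index$compound_id),
                                   FUN = max)
  names(best_per_cmp)[2] <- "score"
  ord <- order(-best_per_cmp$score, best_per_cmp$compound_id, method = "radix")
  best_per_cmp <- best_per_cmp[ord, , drop = FALSE]
  top <- utils::head(best_per_cmp, shortlist_n)
  top$name <- vapply(seq_len(nrow(top)), function(i) {
    cand <- index$name[index$compound_id == top$compound_id[i]]
    cand[which.max(scores[index$compound_id == top$compound_id[i]])]
  }, character(1))
  sl <- shortlist(top$compound_id, top$name, top$score, "fuzzy")
  unique_best <- nrow(sl) >= 1L &&
    (nrow(sl) == 1L || sl$score[1] > sl$score[2])
  if (unique_best && sl$score[1] >= threshold) return(accept(sl))
  list(accepted = NA_character_, shortlist = sl)
}

## ---- macro database --------------------------------------------------------

format_coef <- function(x) {
  # stable text form for stoichiometric coefficients
  s <- vapply(x, format, character(1), trim = TRUE, scientific = FALSE,
              digits = 10)
  has_dec <- grepl(".", s, fixed = TRUE)
  s[has_dec] <- sub("\\.?0+$", "", s[has_dec])
  s
}

side_signature <- function(side) {
  if (is.null(side) || nrow(side) == 0L) return("")
  parts <- paste0(format_coef(side$coef), "*", side$compound)
  paste(sort(parts), collapse = "+")
}

#' Canonical participant signature of a reaction
#'
#' Sorted participant-with-stoichiometry strings for each side; the
#' signature is the lexicographically smaller of the two side orderings,
#' so the written direction of the reaction does not matter (sources
#' disagree on direction; reversibility metadata is preserved elsewhere
#' but never used for matching).
#'
#' @param substrates,products data frames with columns `compound`, `coef`.
#' @return A single signature string.
#' @export
reaction_signature <- function(substrates, products) {
  a <- side_signature(substrates)
  b <- side_signature(products)
  fwd <- paste(a, b, sep = " => ")
  rev <- paste(b, a, sep = " => ")
  if (fwd <= rev) fwd else rev
}

#' Merge reaction records into a macro database
#'
#' The union of the reaction records of several source databases, with
#' records sharing one canonical participant signature (same participants
#' and stoichiometry, orientation-insensitive) merged into a single entry
#' carrying the union of sources, cross-references, EC numbers and
#' catalyzing genes.
#'
#' @param records data frame with columns `reaction_id`, list-columns
#'   `sources`, `ec_numbers`, `genes`, `xrefs`, and list-columns
#'   `substrates`/`products` of data frames (`compound`, `coef`);
#'   participant compound ids must already be canonicalized.
#' @return An object of class `"gpr_macrodb"`: list with `entries` (merged
#'   data frame, plus `signature` and `all_ids` columns) and `index`
#'   (signature -> entry row).
#' @export
build_macro_database <- function(records) {
  n <- nrow(records)
  sigs <- vapply(seq_len(n), function(i)
    reaction_signature(records$substrates[[i]], records$products[[i]]),
    character(1))
  groups <- split(seq_len(n), sigs)
  # deterministic entry order independent of input permutation
  groups <- groups[order(names(groups), method = "radix")]
  entries <- do.call(rbind, lapply(names(groups), function(sig) {
    idx <- groups[[sig]]
    ids <- sort(unique(unlist(records$reaction_id[idx])))
    rep_i <- idx[order(records$reaction_id[idx], method = "radix")][1]
    data.frame(reaction_id = ids[1],
               signature = sig,
               all_ids = I(list(ids)),
               sources = I(list(sort(unique(unlist(records$sources[idx]))))),
               substrates = I(records$substrates[rep_i]),
               products = I(records$products[rep_i]),
               ec_numbers = I(list(sort(unique(unlist(records$ec_numbers[idx]))))),
               genes = I(list(sort(unique(unlist(records$genes[idx]))))),
               xrefs = I(list(sort(unique(unlist(records$xrefs[idx]))))),
               stringsAsFactors = FALSE)
  }))
  rownames(entries) <- NULL
  index <- seq_len(nrow(entries))
  names(index) <- entries$signature
  structure(list(entries = entries, index = index), class = "gpr_macrodb")
}

#' @export
print.gpr_macrodb <- function(x, ...) {
  cat("<macro database> ", nrow(x$entries), " merged reaction entr",
      if (nrow(x$entries) == 1L) "y" else "ies", "\n", sep = "")
  invisible(x)
}

#' Look up an internal reaction in the macro database
#'
#' Signature lookup: the unique merged entry sharing the same reactants
#' and products with the same stoichiometry (either orientation), or
#' `NULL` when no entry matches.
#'
#' @param substrates,products participant data frames (`compound`, `coef`),
#'   canonicalized.
#' @param db a [build_macro_database()] result.
#' @return One-row entry data frame or `NULL`.
#' @export
match_internal_reaction <- function(substrates, products, db) {
  stopifnot(inherits(db, "gpr_macrodb"))
  sig <- reaction_signature(substrates, products)
  i <- db$index[sig]
  if (is.na(i)) return(NULL)
  db$entries[i, , drop = FALSE]
}

#' Genes for a transport reaction via transporter records
#'
#' Determines the transported compounds (same compound on both sides with
#' different compartment tags) and returns the union of the genes of every
#' transporter record whose annotated substrate set contains at least one
#' of them.
#'
#' @param participants data frame with columns `compound`, `coef`,
#'   `compartment`, `side` (`"substrate"`/`"product"`).
#' @param transporters data frame with column `tc_code` and list-columns
#'   `substrates`, `genes`.
#' @return Sorted character vector of gene identifiers (possibly empty).
#' @export
match_transport_reaction <- function(participants, transporters) {
  subs <- participants[participants$side == "substrate", , drop = FALSE]
  prods <- participants[participants$side == "product", , drop = FALSE]
  shared <- intersect(subs$compound, prods$compound)
  transported <- Filter(function(cmp) {
    length(setdiff(subs$compartment[subs$compound == cmp],
                   prods$compartment[prods$compound == cmp])) > 0L ||
      length(setdiff(prods$compartment[prods$compound == cmp],
                     subs$compartment[subs$compound == cmp])) > 0L
  }, shared)
  if (length(transported) == 0L)
    stop("not a transport reaction: no compound crosses compartments",
         call. = FALSE)
  hit <- vapply(seq_len(nrow(transporters)), function(i)
    length(intersect(transporters$substrates[[i]], transported)) > 0L,
    logical(1))
  sort(unique(unlist(transporters$genes[hit])))
}

#' Filter candidate genes by subcellular localization
#'
#' A gene's effective localization set is its manual annotations when any
#' exist, otherwise its automatic annotations, otherwise unknown. The gene
#' is kept when the effective set contains the reaction compartment or is
#' unknown (a gene without localization data is never dropped: the filter
#' is a refinement, not a hard gate).
#'
#' @param genes character vector of candidate genes.
#' @param compartment the reaction compartment, model-local tag or
#'   localization term.
#' @param proteins named list of [protein_record()] objects (by gene).
#' @param compartment_map optional data frame (`compartment`, `term`)
#'   translating model compartment tags into localization vocabulary.
#' @return Character vector, a subset of `genes`.
#' @export
filter_genes_by_localization <- function(genes, compartment, proteins,
                                         compartment_map = NULL) {
  terms <- compartment
  if (!is.null(compartment_map)) {
    extra <- compartment_map$term[tolower(compartment_map$compartment) ==
                                    tolower(compartment)]
    terms <- unique(c(terms, extra))
  }
  terms <- tolower(terms)
  keep <- vapply(genes, function(g) {
    rec <- proteins[[g]]
    if (is.null(rec)) return(TRUE)
    loc <- rec$localizations
    if (is.null(loc) || nrow(loc) == 0L) return(TRUE)
    manual <- loc$term[loc$evidence == "manual"]
    eff <- if (length(manual)) manual else loc$term[loc$evidence == "automatic"]
    if (length(eff) == 0L) return(TRUE)
    any(tolower(eff) %in% terms)
  }, logical(1))
  genes[keep]
}

#' Resolve an organism name to its code
#'
#' Case-insensitive substring matching over the organism index. A unique
#' match returns its code; several matches return, in non-interactive
#' mode, the lexicographically first matching name's code with a warning,
#' and in interactive mode the candidate table for disambiguation; zero
#' matches raise an error.
#'
#' @param name organism name or fragment.
#' @param organisms data frame with columns `code`, `name`.
#' @param interactive when `TRUE`, ambiguous queries return the candidate
#'   data frame instead of choosing.
#' @return Organism code (or candidate data frame in interactive mode).
#' @export
resolve_organism <- function(name, organisms, interactive = FALSE) {
  hit <- grepl(tolower(name), tolower(organisms$name), fixed = TRUE)
  cand <- organisms[hit, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no organism matches '", name, "'", call. = FALSE)
  if (nrow(cand) == 1L) return(cand$code[1])
  cand <- cand[order(cand$name, method = "radix"), , drop = FALSE]
  if (interactive) return(cand)
  warning(nrow(cand), " organisms match '", name, "'; using '",
          cand$name[1], "' (", cand$code[1], ")", call. = FALSE)
  cand$code[1]
}

#' Metabolic reactions and genes for an organism
#'
#' Restricts the organism's genes to metabolic branches of the functional
#' hierarchy, maps the surviving genes to their annotated reactions, and
#' associates each reaction with the union of those genes and the genes of
#' the corresponding macro-database entry when one exists.
#'
#' @param code organism code.
#' @param genome data frame (`code`, `gene`, `branch`).
#' @param hierarchy data frame (`branch`, `metabolic` logical).
#' @param reactions data frame (`gene`, `reaction_id`) mapping genes to
#'   reactions.
#' @param db optional macro database; entries are matched by reaction
#'   identifier (canonical id, merged ids, or cross-references).
#' @return Named list: reaction id -> sorted gene vector.
#' @export
metabolic_reactions_for_organism <- function(code, genome, hierarchy,
                                             reactions, db = NULL) {
  gen <- genome[genome$code == code, , drop = FALSE]
  if (nrow(gen) == 0L)
    stop("organism '", code, "' missing from snapshot", call. = FALSE)
  metab_branches <- hierarchy$branch[hierarchy$metabolic]
  genes <- unique(gen$gene[gen$branch %in% metab_branches])
  rx <- reactions[reactions$gene %in% genes, , drop = FALSE]
  out <- lapply(split(rx$gene, rx$reaction_id), function(g) sort(unique(g)))
  if (!is.null(db)) {
    for (rid in names(out)) {
      hit <- vapply(seq_len(nrow(db$entries)), function(i)
        rid %in% db$entries$all_ids[[i]] || rid %in% db$entries$xrefs[[i]],
        logical(1))
      if (any(hit))
        out[[rid]] <- sort(unique(c(out[[rid]],
                                    unlist(db$entries$genes[hit]))))
    }
  }
  out[order(names(out), method = "radix")]
}
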