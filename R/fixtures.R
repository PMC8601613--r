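#' @title Synthetic organism fixtures with known ground truth
#'
#' @description
#' Generates a complete synthetic organism snapshot — compounds with
#' synonyms, multi-source reaction records, protein annotation texts built
#' from the mining keyword templates, curated complex sets, an interaction
#' network, orthology groups — together with the matching model input and
#' the ground-truth rules, so every pipeline stage and the end-to-end
#' reconstruction can be tested offline. Generation is deterministic under
#' the seed. The generator emulates the statistical structure the pipeline
#' assumes (complexes, isoform groups, keyword-bearing sentences); it does
#' not emulate the heterogeneity of real annotation text, so fixture
#' recovery rates are a correctness ceiling, not a field-performance
#' estimate.
#'
#' @name synthetic-fixtures
NULL

#' Specification of a synthetic fixture
#'
#' Defaults mirror the gross rule-class composition of curated metabolic
#' models (about 30% no-gene and 45% one-gene rules, the multi-gene
#' remainder dominated by isoform-only rules).
#'
#' @param seed integer RNG seed.
#' @param n_reactions number of reactions.
#' @param n_genes optional cap on the gene pool; generation fails when the
#'   drawn classes demand more genes (infeasible specification).
#' @param class_mix named proportions over the five rule classes (sum 1).
#' @param complex_sizes,complex_probs distribution of enzyme-complex sizes.
#' @param isoform_sizes,isoform_probs distribution of isoform-group sizes.
#' @param evidence_completeness per-channel probability that a planted
#'   relation is witnessed by that channel; scalar or named vector over
#'   `uniprot_interaction`, `complex_portal`, `string`, `kegg_orthology`.
#' @param text_noise distractor sentences added per protein record.
#' @param name_perturbation per-character edit rate applied to the
#'   metabolite names referenced by the model (0 = exact names).
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_reactions = 100L, n_genes = NULL,
                         class_mix = c(NO_GENE = 0.30, ONE_GENE = 0.45,
                                       OR = 0.15, AND = 0.07, MIXED = 0.03),
                         complex_sizes = c(2L, 3L),
                         complex_probs = c(0.7, 0.3),
                         isoform_sizes = c(2L, 3L),
                         isoform_probs = c(0.7, 0.3),
                         evidence_completeness = 1,
                         text_noise = 0L, name_perturbation = 0) {
  stopifnot(setequal(names(class_mix), gpr_rule_classes) ||
              all(names(class_mix) %in% gpr_rule_classes))
  full_mix <- stats::setNames(numeric(5), gpr_rule_classes)
  full_mix[names(class_mix)] <- class_mix
  if (abs(sum(full_mix) - 1) > 1e-8)
    stop("class_mix proportions must sum to 1", call. = FALSE)
  channels <- c("uniprot_interaction", "complex_portal", "string",
                "kegg_orthology")
  if (length(evidence_completeness) == 1L && is.null(names(evidence_completeness)))
    evidence_completeness <- stats::setNames(rep(evidence_completeness, 4L),
                                             channels)
  stopifnot(all(channels %in% names(evidence_completeness)),
            all(evidence_completeness >= 0 & evidence_completeness <= 1),
            all(complex_sizes >= 2L), all(isoform_sizes >= 2L),
            name_perturbation >= 0, name_perturbation <= 1)
  structure(list(seed = as.integer(seed), n_reactions = as.integer(n_reactions),
                 n_genes = n_genes, class_mix = full_mix,
                 complex_sizes = complex_sizes, complex_probs = complex_probs,
                 isoform_sizes = isoform_sizes, isoform_probs = isoform_probs,
                 evidence_completeness = evidence_completeness[channels],
                 text_noise = as.integer(text_noise),
                 name_perturbation = name_perturbation),
            class = "fixture_spec")
}

join_gene_phrase <- function(genes) {
  if (length(genes) == 1L) return(genes)
  paste0(paste(utils::head(genes, -1), collapse = ", "), " and ",
         utils::tail(genes, 1))
}

subunit_sentence <- function(others, style) {
  phrase <- join_gene_phrase(others)
  switch(style,
         sprintf("Component of a complex composed of %s.", phrase),
         sprintf("Part of a complex with %s.", phrase),
         sprintf("Interacts with %s.", phrase),
         sprintf("Heteromerization with %s.", phrase),
         sprintf("Forms a heteromer with %s (By similarity).", phrase))
}

perturb_name <- function(name, rate) {
  if (rate <= 0) return(name)
  chars <- strsplit(name, "")[[1]]
  flip <- stats::runif(length(chars)) < rate
  chars[flip] <- sample(c(letters, "0":"9"), sum(flip), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a synthetic snapshot, model and ground truth
#'
#' Draws a rule class per reaction, builds the ground-truth expression and
#' its pairwise relations, and plants each subunit pair in the evidence
#' channels (annotation sentence from a keyword template, curated complex
#' record, network edges with a shared complex term) independently with
#' the per-channel completeness probability. Isoform groups become
#' orthology groups. Reactions use fresh compounds and genes, so reaction
#' signatures never collide. Distractor sentences reuse gene-like tokens
#' absent from the symbol universe, probing the universe gate.
#'
#' @param spec a [fixture_spec()].
#' @return List with `bundle` (a `"gpr_snapshot"`), `model` (a
#'   `"gpr_model"` whose compartment is cytosolic throughout), and `truth`
#'   (list with `rules`, `relations`, `classes`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_reactions
  classes <- sample(gpr_rule_classes, n, replace = TRUE,
                    prob = spec$class_mix)
  comp <- spec$evidence_completeness

  gene_count <- 0L
  next_genes <- function(k) {
    ids <- sprintf("G%04d", gene_count + seq_len(k))
    gene_count <<- gene_count + k
    if (!is.null(spec$n_genes) && gene_count > spec$n_genes)
      stop("infeasible fixture spec: class mix demands ", gene_count,
           " genes but n_genes = ", spec$n_genes, call. = FALSE)
    ids
  }
  cmp_count <- 0L
  next_compounds <- function(k) {
    ids <- sprintf("C%04d", cmp_count + seq_len(k))
    cmp_count <<- cmp_count + k
    ids
  }

  proteins <- list()
  complexes <- list()
  orthology <- list()
  net_edges <- data.frame(gene_a = character(), gene_b = character(),
                          stringsAsFactors = FALSE)
  net_ann <- data.frame(gene = character(), term = character(),
                        is_complex = logical(), stringsAsFactors = FALSE)
  truth_rules <- list()
  truth_rel <- list()
  compounds_rows <- list()
  reaction_rows <- list()
  model_rows <- list()

  add_protein <- function(gene) {
    if (is.null(proteins[[gene]]))
      proteins[[gene]] <<- list(interaction = character(),
                                functional = character(),
                                complex_xrefs = character())
    invisible(NULL)
  }
  plant_complex <- function(members, cx_id) {
    # per-channel witnessing of the subunit group
    if (stats::runif(1) < comp[["complex_portal"]]) {
      complexes[[length(complexes) + 1L]] <<- complex_record(cx_id, members)
      for (g in members)
        proteins[[g]]$complex_xrefs <<- c(proteins[[g]]$complex_xrefs, cx_id)
    }
    if (stats::runif(1) < comp[["uniprot_interaction"]]) {
      for (g in members) {
        style <- sample.int(5L, 1L)
        sent <- subunit_sentence(setdiff(members, g), style)
        proteins[[g]]$interaction <<- c(proteins[[g]]$interaction, sent)
      }
    }
    if (stats::runif(1) < comp[["string"]]) {
      prs <- utils::combn(sort(members), 2L)
      net_edges <<- rbind(net_edges, data.frame(
        gene_a = prs[1, ], gene_b = prs[2, ], stringsAsFactors = FALSE))
      term <- paste(cx_id, "complex")
      net_ann <<- rbind(net_ann, data.frame(
        gene = members, term = term, is_complex = TRUE,
        stringsAsFactors = FALSE))
    }
  }
  plant_isoforms <- function(members, grp_id) {
    if (length(members) >= 2L && stats::runif(1) < comp[["kegg_orthology"]])
      orthology[[length(orthology) + 1L]] <<- orthology_group(grp_id, members)
  }

  cx_n <- 0L; og_n <- 0L
  for (i in seq_len(n)) {
    cls <- classes[i]
    genes <- character()
    rel <- data.frame(gene_a = character(), gene_b = character(),
                      relation = character(), stringsAsFactors = FALSE)
    if (cls == "ONE_GENE") {
      genes <- next_genes(1L)
      rule <- gpr_gene(genes)
    } else if (cls == "OR") {
      k <- sample(spec$isoform_sizes, 1L, prob = spec$isoform_probs)
      genes <- next_genes(k)
      rule <- do.call(gpr_or, as.list(genes))
      prs <- utils::combn(genes, 2L)
      rel <- data.frame(gene_a = prs[1, ], gene_b = prs[2, ],
                        relation = "ISOFORM", stringsAsFactors = FALSE)
    } else if (cls == "AND") {
      s <- sample(spec$complex_sizes, 1L, prob = spec$complex_probs)
      genes <- next_genes(s)
      rule <- do.call(gpr_and, as.list(genes))
      prs <- utils::combn(genes, 2L)
      rel <- data.frame(gene_a = prs[1, ], gene_b = prs[2, ],
                        relation = "SUBUNIT", stringsAsFactors = FALSE)
    } else if (cls == "MIXED") {
      s <- sample(spec$complex_sizes, 1L, prob = spec$complex_probs)
      m <- sample(1:2, 1L)
      cx_genes <- next_genes(s)
      iso_genes <- next_genes(m)
      genes <- c(cx_genes, iso_genes)
      rule <- do.call(gpr_or, c(list(do.call(gpr_and, as.list(cx_genes))),
                                as.list(iso_genes)))
      prs <- utils::combn(cx_genes, 2L)
      rel <- data.frame(gene_a = prs[1, ], gene_b = prs[2, ],
                        relation = "SUBUNIT", stringsAsFactors = FALSE)
    } else {
      rule <- gpr_empty()
    }
    for (g in genes) add_protein(g)
    if (cls == "AND") {
      cx_n <- cx_n + 1L
      plant_complex(genes, sprintf("CPX-%03d", cx_n))
    }
    if (cls == "MIXED") {
      cx_n <- cx_n + 1L
      cx_genes <- gpr_genes(rule$children[[
        which(vapply(rule$children, function(x) x$kind == "AND", logical(1)))[1]]])
      plant_complex(cx_genes, sprintf("CPX-%03d", cx_n))
      iso <- setdiff(genes, cx_genes)
      if (length(iso) >= 2L) {
        og_n <- og_n + 1L
        plant_isoforms(iso, sprintf("K%05d", og_n))
      }
    }
    if (cls == "OR") {
      og_n <- og_n + 1L
      plant_isoforms(genes, sprintf("K%05d", og_n))
    }

    n_sub <- sample(1:2, 1L); n_prod <- sample(1:2, 1L)
    cmp_ids <- next_compounds(n_sub + n_prod)
    coefs <- sample(1:2, n_sub + n_prod, replace = TRUE)
    subs <- data.frame(compound = cmp_ids[seq_len(n_sub)],
                       coef = coefs[seq_len(n_sub)], stringsAsFactors = FALSE)
    prods <- data.frame(compound = cmp_ids[n_sub + seq_len(n_prod)],
                        coef = coefs[n_sub + seq_len(n_prod)],
                        stringsAsFactors = FALSE)
    for (ci in seq_along(cmp_ids)) {
      id <- cmp_ids[ci]
      primary <- sprintf("metabolite %s", substring(id, 2L))
      compounds_rows[[id]] <- data.frame(
        compound_id = id, source = "chebi", inchi = paste0("InChI=1S/", id),
        stringsAsFactors = FALSE)
      compounds_rows[[id]]$names <- list(c(primary,
                                           paste(primary, "synonym")))
      compounds_rows[[id]]$xrefs <- list(stats::setNames(id, "chebi"))
      compounds_rows[[id]]$ontology_parents <- list(character())
    }
    swap <- stats::runif(1) < 0.3  # database records a direction of its own
    reaction_rows[[i]] <- local({
      df <- data.frame(reaction_id = sprintf("RX%04d", i),
                       stringsAsFactors = FALSE)
      df$sources <- list(sort(sample(c("kegg", "metacyc", "rhea"),
                                     sample(1:2, 1L))))
      df$substrates <- if (swap) list(prods) else list(subs)
      df$products <- if (swap) list(subs) else list(prods)
      df$ec_numbers <- list(character())
      df$genes <- list(sort(genes))
      df$xrefs <- list(character())
      df
    })
    primary_of <- function(id) sprintf("metabolite %s", substring(id, 2L))
    part <- rbind(
      data.frame(compound = vapply(subs$compound, primary_of, character(1)),
                 coef = subs$coef, compartment = "c", side = "substrate",
                 stringsAsFactors = FALSE),
      data.frame(compound = vapply(prods$compound, primary_of, character(1)),
                 coef = prods$coef, compartment = "c", side = "product",
                 stringsAsFactors = FALSE))
    if (spec$name_perturbation > 0)
      part$compound <- vapply(part$compound, perturb_name, character(1),
                              rate = spec$name_perturbation)
    model_rows[[i]] <- list(reaction_id = sprintf("R%04d", i),
                            participants = part)
    truth_rules[[sprintf("R%04d", i)]] <- rule
    truth_rel[[sprintf("R%04d", i)]] <- rel
  }

  fake_tokens <- function(k) sprintf("ZZQ%04d", sample.int(9999L, k))
  protein_list <- lapply(names(proteins), function(g) {
    p <- proteins[[g]]
    interaction <- p$interaction
    if (spec$text_noise > 0L) {
      noise <- vapply(fake_tokens(spec$text_noise), function(tok)
        sprintf("Interacts with %s.", tok), character(1))
      interaction <- c(interaction, noise)
    }
    protein_record(
      gene = g, synonyms = paste0(tolower(g), "p"),
      interaction_text = paste(interaction, collapse = " "),
      function_text = paste(p$functional, collapse = " "),
      complex_xrefs = unique(p$complex_xrefs),
      localizations = data.frame(term = "cytosol", evidence = "manual",
                                 stringsAsFactors = FALSE))
  })
  names(protein_list) <- names(proteins)
  if (length(protein_list))
    protein_list <- protein_list[order(names(protein_list), method = "radix")]

  compounds <- do.call(rbind, compounds_rows[order(names(compounds_rows),
                                                   method = "radix")])
  rownames(compounds) <- NULL
  reactions <- do.call(rbind, reaction_rows)
  transporters <- data.frame(tc_code = character(), stringsAsFactors = FALSE)
  transporters$substrates <- list()
  transporters$genes <- list()

  model_df <- data.frame(
    reaction_id = vapply(model_rows, `[[`, character(1), "reaction_id"),
    rule = NA_character_, stringsAsFactors = FALSE)
  model_df$participants <- lapply(model_rows, `[[`, "participants")

  bundle <- snapshot_bundle(
    compounds = compounds, reactions = reactions,
    transporters = transporters, proteins = protein_list,
    complexes = complexes,
    network = interaction_network(net_edges, net_ann),
    orthology = orthology,
    organisms = data.frame(code = "syn", name = "Synthetica exempli",
                           stringsAsFactors = FALSE),
    manifest = c(organism = "syn", synthetic = "true",
                 access_date = "2021-02-08"))
  list(bundle = bundle, model = gpr_model(model_df),
       truth = list(rules = truth_rules, relations = truth_rel,
                    classes = stats::setNames(classes, names(truth_rules))))
}

#' Per-class recovery of ground-truth rules
#'
#' Fraction of reactions per ground-truth rule class whose produced rule
#' is equivalent to the planted rule, plus an overall row.
#'
#' @param truth the `truth` element of [generate_fixture()].
#' @param produced named list of `"gpr"` expressions (or rule strings)
#'   over the same reaction ids.
#' @param cap truth-table gene cap.
#' @return Data frame with columns `class`, `n`, `n_recovered`, `fraction`.
#' @export
recovery_report <- function(truth, produced, cap = 20L) {
  ids <- names(truth$rules)
  if (!setequal(ids, names(produced)))
    stop("reaction id sets differ between truth and produced rules",
         call. = FALSE)
  produced <- lapply(produced, function(r)
    if (inherits(r, "gpr")) r else gpr_parse(r))
  eq <- vapply(ids, function(id)
    gpr_equivalent(truth$rules[[id]], produced[[id]], cap = cap) ==
      "equivalent", logical(1))
  cls <- truth$classes[ids]
  per <- do.call(rbind, lapply(gpr_rule_classes, function(cl) {
    sel <- cls == cl
    data.frame(class = cl, n = sum(sel), n_recovered = sum(eq[sel]),
               fraction = if (any(sel)) mean(eq[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rbind(per, data.frame(class = "TOTAL", n = length(ids),
                        n_recovered = sum(eq), fraction = mean(eq),
                        stringsAsFactors = FALSE))
}
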