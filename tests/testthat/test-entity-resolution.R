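make_compounds <- function(ids, names_list, inchi = NA_character_) {
  df <- data.frame(compound_id = ids, source = "chebi",
                   inchi = rep_len(inchi, length(ids)),
                   stringsAsFactors = FALSE)
  df$names <- names_list
  df$xrefs <- rep(list(character()), length(ids))
  df$ontology_parents <- rep(list(character()), length(ids))
  df
}

test_that("metabolite matching resolves aliases, exact names and thresholds", {
  cmp <- make_compounds(
    c("CHEBI:15422", "CHEBI:16908", "CHEBI:246"),
    list(c("ATP", "adenosine triphosphate", "adenosine 5'-triphosphate"),
         c("NADH", "reduced nicotinamide adenine dinucleotide"),
         c("ACP", "acyl carrier protein")))
  idx <- compound_index(cmp)

  # exact synonym, case-insensitive
  res <- match_metabolite("Adenosine Triphosphate", idx)
  expect_identical(res$accepted, "CHEBI:15422")
  expect_identical(res$shortlist$score[1], 100L)
  expect_identical(res$shortlist$method[1], "exact_name")

  # word-order robustness of the token-sort scorer
  res <- match_metabolite("triphosphate adenosine", idx)
  expect_identical(res$accepted, "CHEBI:15422")

  # below-threshold best match is deferred to the shortlist
  res <- match_metabolite("nicotinamide dinucleotide", idx, threshold = 91L)
  expect_true(res$shortlist$score[1] < 91L)
  expect_true(is.na(res$accepted))
  expect_identical(res$shortlist$compound_id[1], "CHEBI:16908")

  # the alias table rescues names that do not exist in the written form
  res <- match_metabolite("ACP1", idx, aliases = default_metabolite_aliases())
  expect_identical(res$accepted, "CHEBI:246")
  expect_identical(res$shortlist$method[1], "alias")
  expect_true(is.na(match_metabolite("ACP1", idx)$accepted))

  expect_error(match_metabolite("  ", idx), "empty")
})

test_that("raising the threshold never accepts what a lower one shortlisted", {
  cmp <- make_compounds(c("C1", "C2"),
                        list(c("alpha-D-glucose"), c("alpha-D-galactose")))
  idx <- compound_index(cmp)
  for (q in c("alpha-D-glucose", "alpha D glucose", "alpha-D-glucos",
              "beta-D-glucose")) {
    lo <- match_metabolite(q, idx, threshold = 50L)
    hi <- match_metabolite(q, idx, threshold = 95L)
    # the shortlist front-runner is threshold-independent
    expect_identical(hi$shortlist$compound_id[1], lo$shortlist$compound_id[1],
                     info = q)
    if (!is.na(hi$accepted)) {
      expect_identical(hi$accepted, lo$accepted, info = q)
      expect_identical(hi$accepted, lo$shortlist$compound_id[1], info = q)
    }
  }
})

test_that("InChI strings resolve ambiguous names", {
  cmp <- make_compounds(c("C1", "C2"), list("L-alanine", "D-alanine"),
                        inchi = NA_character_)
  cmp$inchi <- c("InChI=1S/C3H7NO2/t2-/m0/s1", "InChI=1S/C3H7NO2/t2-/m1/s1")
  idx <- compound_index(cmp)
  res <- match_metabolite("alanine", idx,
                          inchi = "InChI=1S/C3H7NO2/t2-/m1/s1")
  expect_identical(res$accepted, "C2")
  expect_identical(res$shortlist$method[1], "inchi")
})

make_record <- function(id, subs, prods, sources, genes = character(),
                        ec = character()) {
  df <- data.frame(reaction_id = id, stringsAsFactors = FALSE)
  df$sources <- list(sources)
  df$substrates <- list(subs)
  df$products <- list(prods)
  df$ec_numbers <- list(ec)
  df$genes <- list(genes)
  df$xrefs <- list(character())
  df
}

test_that("macro database merges duplicate reactions across sources", {
  side <- function(...) {
    v <- c(...)
    data.frame(compound = names(v), coef = unname(v), stringsAsFactors = FALSE)
  }
  recs <- rbind(
    make_record("K1", side(atp = 1, glc = 1), side(adp = 1, g6p = 1),
                "kegg", genes = "HK1", ec = "2.7.1.1"),
    make_record("M1", side(glc = 1, atp = 1), side(g6p = 1, adp = 1),
                "metacyc", genes = c("HK1", "GCK")),
    # same participants, different stoichiometry: distinct entry
    make_record("K2", side(atp = 2, glc = 1), side(adp = 2, g6p = 1),
                "kegg"),
    # written in the opposite direction: still the same reaction
    make_record("R1", side(adp = 1, g6p = 1), side(atp = 1, glc = 1),
                "rhea", genes = "HK2"))
  db <- build_macro_database(recs)
  expect_identical(nrow(db$entries), 2L)
  merged <- db$entries[vapply(db$entries$all_ids, function(x) "K1" %in% x,
                              logical(1)), ]
  expect_identical(merged$sources[[1]], c("kegg", "metacyc", "rhea"))
  expect_identical(merged$genes[[1]], c("GCK", "HK1", "HK2"))
  expect_identical(merged$ec_numbers[[1]], "2.7.1.1")

  # idempotence: re-merging the merged entries changes nothing
  db2 <- build_macro_database(db$entries)
  expect_identical(db2$entries$signature, db$entries$signature)
  expect_identical(db2$entries$genes, db$entries$genes)

  # order independence
  db3 <- build_macro_database(recs[c(4, 2, 3, 1), ])
  expect_identical(db3$entries$signature, db$entries$signature)
  expect_identical(db3$entries$genes, db$entries$genes)

  # signature lookup, including the swapped orientation
  hit <- match_internal_reaction(side(atp = 1, glc = 1),
                                 side(adp = 1, g6p = 1), db)
  expect_identical(hit$genes[[1]], c("GCK", "HK1", "HK2"))
  hit_rev <- match_internal_reaction(side(adp = 1, g6p = 1),
                                     side(atp = 1, glc = 1), db)
  expect_identical(hit_rev$signature, hit$signature)
  expect_null(match_internal_reaction(side(foo = 1), side(bar = 1), db))
})

test_that("transport matching unions transporter genes over transported compounds", {
  tr <- data.frame(tc_code = c("2.A.1.1.1", "2.A.1.1.2", "3.A.1.2.1"),
                   stringsAsFactors = FALSE)
  tr$substrates <- list("glc", c("glc", "fru"), "rib")
  tr$genes <- list("HXT1", "HXT2", "RBSA")
  parts <- data.frame(compound = c("glc", "glc"), coef = 1,
                      compartment = c("e", "c"),
                      side = c("substrate", "product"),
                      stringsAsFactors = FALSE)
  expect_identical(match_transport_reaction(parts, tr), c("HXT1", "HXT2"))
  internal <- data.frame(compound = c("a", "b", "c"), coef = 1,
                         compartment = "c",
                         side = c("substrate", "substrate", "product"),
                         stringsAsFactors = FALSE)
  expect_error(match_transport_reaction(internal, tr), "not a transport")
})

test_that("localization filter prefers manual evidence and keeps unknowns", {
  loc <- function(terms, evid) data.frame(term = terms, evidence = evid,
                                          stringsAsFactors = FALSE)
  proteins <- list(
    mito = protein_record("mito", localizations = loc(
      c("mitochondrion", "nucleus"), c("manual", "automatic"))),
    nuc = protein_record("nuc", localizations = loc("nucleus", "manual")),
    auto = protein_record("auto", localizations = loc("cytosol", "automatic")),
    blank = protein_record("blank"))
  cmap <- default_compartment_map()
  genes <- c("mito", "nuc", "auto", "blank")
  expect_identical(
    filter_genes_by_localization(genes, "m", proteins, cmap),
    c("mito", "blank"))
  expect_identical(
    filter_genes_by_localization(genes, "c", proteins, cmap),
    c("auto", "blank"))
  # output is always a subset of the input
  expect_true(all(filter_genes_by_localization(genes, "e", proteins, cmap)
                  %in% genes))
})

test_that("organism resolution disambiguates substring matches", {
  orgs <- data.frame(code = c("sce", "sba", "eco"),
                     name = c("Saccharomyces cerevisiae S288C",
                              "Saccharomyces cerevisiae YJM789",
                              "Escherichia coli K-12"),
                     stringsAsFactors = FALSE)
  expect_identical(resolve_organism("escherichia", orgs), "eco")
  expect_warning(code <- resolve_organism("cerevisiae", orgs),
                 "2 organisms match")
  expect_identical(code, "sce")
  cand <- resolve_organism("cerevisiae", orgs, interactive = TRUE)
  expect_identical(nrow(cand), 2L)
  expect_error(resolve_organism("pan troglodytes", orgs), "no organism")
})

test_that("organism harvest filters non-metabolic genes and unions macro genes", {
  genome <- data.frame(code = "syn", gene = c("g1", "g2", "g3"),
                       branch = c("Carbohydrate metabolism",
                                  "Carbohydrate metabolism",
                                  "Membrane trafficking"),
                       stringsAsFactors = FALSE)
  hierarchy <- data.frame(branch = c("Carbohydrate metabolism",
                                     "Membrane trafficking"),
                          metabolic = c(TRUE, FALSE))
  gene_rx <- data.frame(gene = c("g1", "g2", "g3"),
                        reaction_id = c("RX1", "RX1", "RX2"),
                        stringsAsFactors = FALSE)
  side <- function(cmp) data.frame(compound = cmp, coef = 1,
                                   stringsAsFactors = FALSE)
  db <- build_macro_database(make_record("RX1", side("a"), side("b"),
                                         "kegg", genes = "g9"))
  out <- metabolic_reactions_for_organism("syn", genome, hierarchy, gene_rx, db)
  # the non-metabolic gene g3 is excluded everywhere (so RX2 vanishes)
  expect_identical(names(out), "RX1")
  expect_identical(out$RX1, c("g1", "g2", "g9"))
  expect_error(metabolic_reactions_for_organism("xxx", genome, hierarchy,
                                                gene_rx, db), "missing")
  empty <- metabolic_reactions_for_organism(
    "syn", genome, data.frame(branch = character(), metabolic = logical()),
    gene_rx, db)
  expect_length(empty, 0L)
})
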