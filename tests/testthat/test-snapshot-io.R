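test_that("snapshot bundles round-trip byte-identically through a directory", {
  fx <- generate_fixture(fixture_spec(seed = 5, n_reactions = 12,
                                      text_noise = 1L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_snapshot(fx$bundle, d1)
  b2 <- read_snapshot(d1)
  write_snapshot(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     info = f)
  }
  expect_identical(b2$manifest[["organism"]], "syn")
  expect_identical(b2$manifest[["synthetic"]], "true")
})

test_that("integrity validation reports dangling references", {
  fx <- generate_fixture(fixture_spec(seed = 5, n_reactions = 5))
  bundle <- fx$bundle
  bundle$reactions$genes[[1]] <- c(bundle$reactions$genes[[1]], "GHOST")
  expect_match(snapshot_integrity(bundle), "unknown gene id: GHOST",
               all = FALSE)
  d <- withr::local_tempdir()
  write_snapshot(bundle, d)
  expect_error(read_snapshot(d), "integrity violation")
  expect_error(read_snapshot(withr::local_tempdir()), "manifest")
})

test_that("empty optional tables load as empty structures", {
  fx <- generate_fixture(fixture_spec(seed = 9, n_reactions = 5,
                                      class_mix = c(NO_GENE = 0.5,
                                                    ONE_GENE = 0.5)))
  # one-gene-only fixtures have no network, complexes or orthology
  expect_identical(nrow(fx$bundle$network$edges), 0L)
  d <- withr::local_tempdir()
  write_snapshot(fx$bundle, d)
  b <- read_snapshot(d)
  expect_identical(nrow(b$network$edges), 0L)
  expect_length(b$complexes, 0L)
})

test_that("rules tables round-trip and tolerate semicolon delimiters", {
  tab <- rules_table(Rxn = c("r1", "r2", "r3"),
                     rule_original = c("g1 and g2", "", "g3"),
                     rule_GPRuler = c("g1 or g2", "", "g3"),
                     Evaluation = c("Not automatically reconstructed by GPRuler",
                                    "Perfect match", "Perfect match"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_rules_table(tab, p)
  back <- read_rules_table(p)
  expect_identical(as.data.frame(back), as.data.frame(tab))

  # semicolon dialect parses identically
  p2 <- withr::local_tempfile(fileext = ".csv")
  txt <- readLines(p)
  writeLines(gsub("\",\"", "\";\"", txt, fixed = TRUE), p2)
  back2 <- read_rules_table(p2)
  expect_identical(as.data.frame(back2), as.data.frame(tab))

  # empty rule strings parse as empty rules downstream
  expect_identical(gpr_parse(back$rule_original[2])$kind, "EMPTY")
  expect_warning(rules_table("r1", "g1", "g1", "Somewhat wrong"),
                 "unknown Evaluation label")
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("Rxn,rule_original\nr1,g1", p3)
  expect_error(read_rules_table(p3), "rule_GPRuler")
})

test_that("models round-trip through SBML with fbc gene associations", {
  fx <- generate_fixture(fixture_spec(seed = 2, n_reactions = 4))
  model <- fx$model
  rules <- list(R0001 = gpr_parse("(g1 and g2) or g3"),
                R0002 = gpr_parse("g4"),
                R0003 = gpr_empty())
  p <- withr::local_tempfile(fileext = ".xml")
  write_annotated_model(model, rules, p)
  back <- read_model(p)
  expect_identical(back$reactions$rule[match("R0001", back$reactions$reaction_id)],
                   "(g1 and g2) or g3")
  expect_identical(back$reactions$rule[match("R0002", back$reactions$reaction_id)],
                   "g4")
  # empty rule: no association captured
  expect_true(is.na(back$reactions$rule[match("R0003",
                                              back$reactions$reaction_id)]))
  for (i in seq_len(nrow(model$reactions))) {
    a <- model$reactions$participants[[i]]
    b <- back$reactions$participants[[match(model$reactions$reaction_id[i],
                                            back$reactions$reaction_id)]]
    a <- a[order(a$side, a$compound), c("compound", "coef", "compartment", "side")]
    b <- b[order(b$side, b$compound), c("compound", "coef", "compartment", "side")]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
  expect_error(write_annotated_model(model, list(NOPE = gpr_parse("g1")), p),
               "unknown reaction id.*NOPE")
  # byte-identical output for identical inputs
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_annotated_model(model, rules, p2)
  expect_identical(readLines(p2), readLines(p))
})

test_that("legacy GENE_ASSOCIATION notes are captured", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '  <model id="legacy">',
    '    <listOfCompartments><compartment id="c"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="M_a_c" name="a" compartment="c"/>',
    '      <species id="M_b_c" name="b" compartment="c"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="R1">',
    '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '          <p>GENE_ASSOCIATION: g1 or g2</p>',
    '        </body></notes>',
    '        <listOfReactants><speciesReference species="M_a_c"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="M_b_c" stoichiometry="2"/></listOfProducts>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), p)
  m <- read_model(p)
  expect_identical(m$reactions$rule, "g1 or g2")
  parts <- m$reactions$participants[[1]]
  expect_identical(parts$coef[parts$side == "product"], 2)
  # default stoichiometry is 1
  expect_identical(parts$coef[parts$side == "substrate"], 1)
})

test_that("the TSV model dialect enforces its column contract", {
  fx <- generate_fixture(fixture_spec(seed = 6, n_reactions = 3))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_model_tsv(fx$model, p)
  back <- read_model(p)
  expect_identical(back$reactions$reaction_id, fx$model$reactions$reaction_id)
  a <- fx$model$reactions$participants[[1]]
  b <- back$reactions$participants[[1]]
  expect_setequal(paste(a$compound, a$coef, a$compartment, a$side),
                  paste(b$compound, b$coef, b$compartment, b$side))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("reaction_id\tsubstrates\nR1\tglc[c]:1", p2)
  expect_error(read_model(p2), "missing required column 'products'")
  expect_error(read_model(withr::local_tempfile(fileext = ".xml")), "")
})
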