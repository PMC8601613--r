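test_that("parsing handles precedence, parentheses, case and whitespace", {
  cases <- list(
    list(text = "", serialized = ""),
    list(text = "   ", serialized = ""),
    list(text = "g5", serialized = "g5"),
    list(text = "(g1 and g2) or g3", serialized = "(g1 and g2) or g3"),
    # and binds tighter than or
    list(text = "g1 and g2 or g3", serialized = "(g1 and g2) or g3"),
    list(text = "G1 AND g2 Or g3", serialized = "(G1 and g2) or g3"),
    list(text = "  g1   and ( g2 or g3 ) ", serialized = "g1 and (g2 or g3)"),
    # flattening, dedup, canonical child order
    list(text = "(g1 and (g2 and g3))", serialized = "g1 and g2 and g3"),
    list(text = "g1 or g1", serialized = "g1"),
    list(text = "g3 or (g2 and g1)", serialized = "(g1 and g2) or g3"))
  for (cs in cases) {
    expect_identical(gpr_serialize(gpr_parse(cs$text)), cs$serialized,
                     info = cs$text)
  }
})

test_that("parse precedence agrees with a fully parenthesized oracle parse", {
  set.seed(11)
  genes <- paste0("g", 1:5)
  for (i in 1:50) {
    # random flat expression without parentheses
    k <- sample(3:6, 1)
    ops <- sample(c(" and ", " or "), k - 1, replace = TRUE)
    gs <- sample(genes, k, replace = TRUE)
    txt <- paste0(gs[1], paste0(ops, gs[-1], collapse = ""))
    vars <- sort(unique(gs))
    expect_identical(
      gpr_truth_table(gpr_parse(txt), vars)$outputs,
      oracle_truth_outputs(txt, vars),
      info = txt)
  }
})

test_that("parse errors name the offending offset", {
  expect_error(gpr_parse("(g1 and g2"), "offset 1.*unbalanced")
  expect_error(gpr_parse("g1 and g2)"), "offset 10.*unbalanced")
  expect_error(gpr_parse("g1 and or g2"), "offset 8.*dangling operator")
  expect_error(gpr_parse("g1 and"), "empty operand")
  expect_error(gpr_parse("and g1"), "dangling operator")
})

test_that("serialize -> parse -> serialize is a fixed point", {
  set.seed(23)
  genes <- paste0("g", 1:6)
  for (i in 1:60) {
    e <- gpr_parse(random_rule_string(genes))
    s1 <- gpr_serialize(e)
    s2 <- gpr_serialize(gpr_parse(s1))
    expect_identical(s1, s2)
  }
})

test_that("evaluation follows Boolean semantics and flags missing genes", {
  expect_false(gpr_evaluate(gpr_parse("g1 and g2"), c(g1 = TRUE, g2 = FALSE)))
  expect_true(gpr_evaluate(gpr_parse("g1 or g2"), c(g1 = TRUE, g2 = FALSE)))
  expect_true(gpr_evaluate(gpr_parse("(g1 and g2) or g3"),
                           c(g1 = FALSE, g2 = TRUE, g3 = TRUE)))
  expect_false(gpr_evaluate(gpr_empty(), c(g1 = TRUE)))
  expect_error(gpr_evaluate(gpr_parse("g1 and g2"), c(g1 = TRUE)),
               "missing gene 'g2'")
})

test_that("truth tables honour the bit encoding and the cap", {
  tt <- gpr_truth_table(gpr_parse("g1 and g2"), c("g1", "g2"))
  expect_identical(tt$outputs, c(FALSE, FALSE, FALSE, TRUE))
  tt <- gpr_truth_table(gpr_parse("g1"), "g1")
  expect_identical(tt$outputs, c(FALSE, TRUE))
  tt <- gpr_truth_table(gpr_empty(), character())
  expect_identical(tt$outputs, FALSE)
  expect_error(gpr_truth_table(gpr_parse(paste(paste0("g", 1:5),
                                               collapse = " or ")),
                               cap = 4L),
               class = "gpr_cap_error")
})

test_that("rule classification is exhaustive and invariant under renaming", {
  texts <- c("", "g1", "g1 or g2 or g3", "g1 and g2",
             "(g1 and g2) or g3", "(g1 or g2) and g3")
  classes <- c("NO_GENE", "ONE_GENE", "OR", "AND", "MIXED", "MIXED")
  for (i in seq_along(texts)) {
    expect_identical(gpr_classify(gpr_parse(texts[i])), classes[i],
                     info = texts[i])
    renamed <- gsub("g", "YFG", texts[i])
    expect_identical(gpr_classify(gpr_parse(renamed)), classes[i],
                     info = renamed)
  }
})

test_that("equivalence handles commutativity, inequivalence and the above-cap path", {
  expect_identical(gpr_equivalent(gpr_parse("g1 and g2"),
                                  gpr_parse("g2 and g1")), "equivalent")
  expect_identical(gpr_equivalent(gpr_parse("g1 and g2"),
                                  gpr_parse("g1 or g2")), "not_equivalent")
  # 25-gene OR rule in shuffled order: set comparison above the cap
  genes <- paste0("g", 1:25)
  a <- paste(genes, collapse = " or ")
  b <- paste(rev(genes), collapse = " or ")
  expect_identical(gpr_equivalent(gpr_parse(a), gpr_parse(b), cap = 20L),
                   "equivalent")
  b2 <- paste(c(genes[-1], "g99"), collapse = " or ")
  expect_identical(gpr_equivalent(gpr_parse(a), gpr_parse(b2), cap = 20L),
                   "not_equivalent")
  # mixed pairs above the cap may be indeterminate, never for pure pairs
  mixed_a <- paste0("(g1 and g2) or ", paste(genes[3:25], collapse = " or "))
  mixed_b <- paste0("(g1 and g3) or ", paste(genes[c(2, 4:25)], collapse = " or "))
  expect_identical(gpr_equivalent(gpr_parse(mixed_a), gpr_parse(mixed_b),
                                  cap = 20L), "indeterminate")
})

test_that("absorption makes canonical comparison exact for nested redundancy", {
  e <- gpr_parse("g1 or (g1 and g2)")
  expect_identical(gpr_serialize(gpr_canonical(e)), "g1")
  e2 <- gpr_parse("g1 and (g1 or g2)")
  expect_identical(gpr_serialize(gpr_canonical(e2)), "g1")
  expect_identical(gpr_equivalent(e, gpr_parse("g1")), "equivalent")
})

test_that("jaccard index matches the set formula with the empty-set convention", {
  expect_equal(jaccard_index(c("g1", "g2"), c("g2", "g3")), 1 / 3)
  expect_equal(jaccard_index(character(), character()), 1)
  expect_equal(jaccard_index("g1", "g2"), 0)
  # symmetry and the equality criterion
  set.seed(5)
  for (i in 1:20) {
    a <- sample(paste0("g", 1:8), sample(0:5, 1))
    b <- sample(paste0("g", 1:8), sample(0:5, 1))
    expect_equal(jaccard_index(a, b), jaccard_index(b, a))
    expect_identical(jaccard_index(a, b) == 1, setequal(a, b))
  }
})

test_that("hamming similarity is oriented as a similarity and symmetric", {
  ta <- gpr_truth_table(gpr_parse("g1 and g2"), c("g1", "g2"))
  tb <- gpr_truth_table(gpr_parse("g1 or g2"), c("g1", "g2"))
  expect_equal(hamming_similarity(ta, ta), 1)
  expect_equal(hamming_similarity(ta, tb), 0.5)
  expect_equal(hamming_similarity(ta, tb), hamming_similarity(tb, ta))
  # complementary tables score 0
  tc <- ta; tc$outputs <- !ta$outputs
  expect_equal(hamming_similarity(ta, tc), 0)
  td <- gpr_truth_table(gpr_parse("g1 and g3"), c("g1", "g3"))
  expect_error(hamming_similarity(ta, td), "different variable orders")
})

test_that("rule comparison wires equivalence, jaccard and hamming together", {
  r <- gpr_compare(gpr_parse("g1"), gpr_parse("g1"))
  expect_identical(r$status, "PERFECT")
  expect_equal(r$jaccard, 1)
  expect_true(is.na(r$hamming_similarity))

  r <- gpr_compare(gpr_parse("g1 and g2"), gpr_parse("g1 or g2"))
  expect_identical(r$status, "NEGATIVE")
  expect_equal(r$jaccard, 1)
  expect_equal(r$hamming_similarity, 0.5)
  expect_identical(r$rule_class_original, "AND")
  expect_identical(r$rule_class_generated, "OR")

  r <- gpr_compare(gpr_parse("g1 or g2"), gpr_parse("g1 or g3"))
  expect_identical(r$status, "NEGATIVE")
  expect_equal(r$jaccard, 1 / 3)
  expect_true(is.na(r$hamming_similarity))
})
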