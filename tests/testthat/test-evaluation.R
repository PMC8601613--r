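test_that("rules-table evaluation counts matches and labels per class", {
  tab <- rules_table(
    Rxn = paste0("r", 1:6),
    rule_original = c("g1", "g1 and g2", "g1 or g2", "", "g3", "(g1 and g2) or g3"),
    rule_GPRuler = c("g1", "g1 or g2", "g2 or g1", "", "g4", "g1 and g2 and g3"),
    Evaluation = c("Perfect match", "Corrected by GPRuler", "Perfect match",
                   "Perfect match",
                   "Not automatically reconstructed by GPRuler",
                   "Not automatically reconstructed by GPRuler"))
  ev <- evaluate_rules_table(tab)
  counts <- ev$counts
  tot <- counts[counts$class == "TOTAL", ]
  expect_identical(tot$total, 6L)
  expect_identical(tot$perfect, 3L)   # r1, r3, r4
  expect_identical(tot$corrected, 1L)
  expect_identical(tot$not_automatic, 2L)
  expect_identical(tot$automatic, 4L)
  expect_equal(ev$automatic_percent, 100 * 4 / 6)
  # classes are taken from the original rule
  expect_identical(counts$total[counts$class == "AND"], 1L)
  expect_identical(counts$perfect[counts$class == "NO_GENE"], 1L)
  expect_identical(counts$total[counts$class == "MIXED"], 1L)
  # per-class totals sum to the table row count
  expect_identical(sum(counts$total[counts$class != "TOTAL"]), 6L)
  # the operator-only mismatch carries jaccard 1 and hamming 0.5
  r2 <- ev$per_reaction[ev$per_reaction$Rxn == "r2", ]
  expect_identical(r2$status, "NEGATIVE")
  expect_equal(r2$jaccard, 1)
  expect_equal(r2$hamming_similarity, 0.5)
  # the gene mismatch has no hamming value
  r5 <- ev$per_reaction[ev$per_reaction$Rxn == "r5", ]
  expect_equal(r5$jaccard, 0)
  expect_true(is.na(r5$hamming_similarity))
})

test_that("automatic and not-automatic partition the labelled rows", {
  set.seed(77)
  n <- 40
  labels <- sample(c("Perfect match", "Corrected by GPRuler",
                     "Not automatically reconstructed by GPRuler"), n, TRUE)
  rules <- replicate(n, random_rule_string(paste0("g", 1:4), depth = 2))
  tab <- rules_table(paste0("r", 1:n), rules,
                     ifelse(labels == "Perfect match", rules, "g9"),
                     labels)
  ev <- evaluate_rules_table(tab)
  tot <- ev$counts[ev$counts$class == "TOTAL", ]
  labelled <- sum(labels != "Perfect match") + tot$perfect
  expect_identical(tot$automatic + tot$not_automatic, labelled)
})

test_that("unparseable rows are excluded and reported, not dropped silently", {
  tab <- rules_table(c("ok", "bad"), c("g1", "g1 and (g2"), c("g1", "g1"))
  ev <- evaluate_rules_table(tab)
  expect_identical(nrow(ev$per_reaction), 1L)
  expect_identical(ev$excluded$Rxn, "bad")
  expect_identical(ev$excluded$column, "rule_original")
  expect_match(ev$excluded$message, "unbalanced")
})

test_that("global jaccard follows the pooled gene-set definition", {
  same <- rules_table("r1", "g1 and g2", "g2 and g1")
  expect_equal(global_jaccard(same), 1)
  disjoint <- rules_table(c("r1", "r2"), c("g1", "g2"), c("g3", "g4"))
  expect_equal(global_jaccard(disjoint), 0)
  one_of_three <- rules_table("r1", "g1 or g2", "g2 or g3")
  expect_equal(global_jaccard(one_of_three), 1 / 3)
  # the per-reaction averaged alternative stays available behind a flag
  two <- rules_table(c("r1", "r2"), c("g1", "g2"), c("g1", "g3"))
  expect_equal(global_jaccard(two, method = "mean"), 0.5)
  expect_equal(global_jaccard(two, method = "pooled"), 1 / 3)
})

test_that("histograms bin the negative-match distributions on [0,1]", {
  tab <- rules_table(
    Rxn = paste0("r", 1:4),
    rule_original = c("g1 and g2", "g1 or g2", "g1 or g9", "g1"),
    rule_GPRuler = c("g1 or g2", "g2 and g1", "g1 or g2", "g1"))
  ev <- evaluate_rules_table(tab)
  expect_identical(nrow(ev$jaccard_histogram), 10L)
  negatives <- sum(ev$per_reaction$status == "NEGATIVE")
  expect_identical(sum(ev$jaccard_histogram$count), negatives)
  expect_identical(sum(ev$hamming_histogram$count),
                   sum(ev$per_reaction$status == "NEGATIVE" &
                         ev$per_reaction$jaccard == 1))
})

test_that("flux optimization solves the toy network", {
  model <- toy_fba_model()
  wt <- optimize_flux(model)
  expect_true(wt$feasible)
  expect_equal(wt$value, 10)
  # steady state holds at the optimum
  expect_equal(max(abs(model$S %*% wt$fluxes)), 0, tolerance = 1e-9)
})

test_that("gene deletions match the hand-solved linear programs", {
  model <- toy_fba_model()
  screen <- single_gene_deletions(model)
  expect_identical(stats::setNames(screen$predicted, screen$gene),
                   toy_expected_viability)
  # a gene absent from all rules never changes the model
  expect_identical(gene_deletion_viability(model, "g99"), "viable")
  # deletion is monotone: supersets never rescue a lethal deletion
  expect_identical(gene_deletion_viability(model, c("g1", "g2")), "viable")
  expect_identical(gene_deletion_viability(model, c("g1", "g2", "g3")),
                   "not_viable")
  expect_identical(gene_deletion_viability(model, c("g1", "g2", "g3", "g5")),
                   "not_viable")
  # no-gene reactions are never knocked out: deleting everything leaves EX_A
  expect_identical(gene_deletion_viability(model, paste0("g", 1:5)),
                   "not_viable")
})

test_that("the internal simplex agrees with an external LP solver when both apply", {
  # boot's simplex handles the non-degenerate wild-type program; use it as
  # an independent oracle for the optimum
  model <- toy_fba_model()
  S <- model$S
  ref <- boot::simplex(a = as.numeric(colnames(S) == "BIO"),
                       A1 = diag(ncol(S)), b1 = unname(model$ub),
                       A3 = S, b3 = rep(0, nrow(S)), maxi = TRUE)
  expect_identical(ref$solved, 1L)
  expect_equal(optimize_flux(model)$value, unname(ref$value))
  # random well-bounded networks: chain A -> B -> C with random capacities
  set.seed(19)
  for (i in 1:10) {
    caps <- stats::runif(5, 1, 20)
    m2 <- fba_model(S, lb = rep(0, 5), ub = caps, objective = "BIO",
                    rules = model$rules[c("R1", "R2", "R3")])
    ref2 <- boot::simplex(a = as.numeric(colnames(S) == "BIO"),
                          A1 = diag(5), b1 = caps, A3 = S,
                          b3 = rep(0, 3), maxi = TRUE)
    expect_equal(optimize_flux(m2)$value, unname(ref2$value), tolerance = 1e-8)
  }
})

test_that("infeasible wild types are rejected", {
  S <- matrix(c(1, -1), nrow = 1,
              dimnames = list("A", c("IN", "OUT")))
  dead <- fba_model(S, lb = c(0, 0), ub = c(0, 10), objective = "OUT")
  expect_error(single_gene_deletions(dead), "non-positive biomass")
})

test_that("confusion matrices report counts, relative frequencies and accuracy", {
  out <- data.frame(gene = paste0("g", 1:4),
                    predicted = c("viable", "viable", "not_viable", "viable"),
                    annotated = c("viable", "not_viable", "not_viable",
                                  "viable"))
  cm <- confusion_matrix(out)
  expect_identical(sum(cm$counts), 4L)
  expect_equal(cm$accuracy, 0.75)
  expect_equal(sum(cm$relative), 1)
  expect_identical(cm$counts["viable", "not_viable"], 1L)
  all_right <- data.frame(gene = "g", predicted = "viable",
                          annotated = "viable")
  expect_equal(confusion_matrix(all_right)$accuracy, 1)
  half <- data.frame(gene = paste0("g", 1:4),
                     predicted = rep("viable", 4),
                     annotated = c("viable", "viable", "not_viable",
                                   "not_viable"))
  expect_equal(confusion_matrix(half)$accuracy, 0.5)
  expect_error(confusion_matrix(out[0, ]), "no outcomes")
})

test_that("the deletion screen round-trips through the FBA table format", {
  model <- toy_fba_model()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fba_model_tsv(model, p)
  back <- read_fba_model_tsv(p)
  expect_equal(optimize_flux(back)$value, 10)
  screen <- single_gene_deletions(back)
  expect_identical(stats::setNames(screen$predicted, screen$gene),
                   toy_expected_viability)
})
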