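---
title: "Reconstructing and evaluating gene-protein-reaction rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and evaluating gene-protein-reaction rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gprules)
```

## The problem

A genome-scale metabolic model (GEM) lists the biochemical reactions an
organism can carry out. To simulate gene knockouts or integrate expression
data, each reaction needs a gene-protein-reaction (GPR) rule: a Boolean
expression over genes in which `and` joins genes encoding subunits of one
enzyme complex (all jointly required for catalysis) and `or` joins genes
encoding isoforms (alternative catalysts, any one sufficient). A reaction
catalyzed by a two-subunit complex or, alternatively, by a monomeric
isoenzyme carries a rule like `(g1 and g2) or g3`. Writing these rules is
traditionally manual; `gprules` reconstructs them automatically from
offline snapshots of the public evidence a curator would consult, and
ships the complete statistical machinery for benchmarking reconstructed
rules against curated models.

## Pipeline overview

Reconstruction proceeds in stages, each behind its own function:

1. **Metabolite identification** (`match_metabolite`). Model metabolite
   names are resolved against a compound dictionary (names, synonyms,
   InChI strings, cross-references). Resolution order: user-extensible
   alias table, exact case-insensitive name hit, InChI string hit, then
   fuzzy scoring. The fuzzy scorer is a token-sort Levenshtein ratio
   (`token_sort_score`): both strings are lowercased, word tokens sorted,
   and scored `100 * (1 - d/max(nchar))`. Sorting tokens first makes the
   score robust to word-order variation in metabolite synonyms
   ("adenosine triphosphate" vs "triphosphate adenosine"). A candidate is
   accepted automatically only when a *unique* best compound scores at or
   above the threshold (default **91**, a calibrated value that excludes
   clearly wrong matches while tolerating single-character variants, which
   score about 94 on typical name lengths). Anything else lands on a
   ranked shortlist for user confirmation; in non-interactive runs the
   shortlist is logged and the reaction skipped rather than guessed.
   The built-in alias table covers recurring curation cases: acyl-carrier
   protein written `ACP1`, ferredoxin entries resolved through their NADPH
   dependence, electron-transfer flavoproteins mapped to FAD/FADH2, and
   `diglyceride` mapped to 1,2-diacyl-sn-glycerol.

2. **Reaction identification** (`build_macro_database`,
   `match_internal_reaction`, `match_transport_reaction`). Reaction
   records from several source databases are merged into one "macro
   database" keyed by a canonical participant signature — the sorted
   participants with stoichiometry of both sides, taking the
   lexicographically smaller of the two side orderings so that the
   written direction does not matter (sources disagree on direction;
   reversibility is metadata, not identity). Records sharing a signature
   merge into one entry with the union of sources, cross-references, EC
   numbers and catalyzing genes. Internal reactions are then matched by
   signature lookup. Transport reactions (the same compound on both sides
   in different compartments) consult the transporter table: the union of
   the genes of every transporter annotated for at least one transported
   substrate. Protons and water are *not* excluded from signatures by
   default; nothing in the matching rules singles them out, and a user
   who wants looser matching can canonicalize them away upstream.

3. **Localization filtering** (`filter_genes_by_localization`). Candidate
   genes are kept when their subcellular localization is compatible with
   the reaction compartment. Manual annotations take priority over
   automatic predictions: the effective localization set is the manual
   terms when any exist, otherwise the automatic terms, otherwise
   unknown. A gene with no localization data is always kept — the filter
   is a refinement, and a false negative here silently deletes a gene
   from the final rule, which is worse than carrying a spurious one into
   the mining stage.

4. **Relationship mining** (`extract_partners`, `complex_partners`,
   `string_partners`, `isoform_partners`). For every candidate gene the
   pipeline collects pairwise evidence labelled `SUBUNIT` (complex
   co-membership, joined by `and`) or `ISOFORM` (alternative catalysts,
   joined by `or`) from four channels: keyword-guided mining of protein
   annotation text ("Interaction" and "Function" sections), curated
   complex sets, interaction-network neighbours sharing a
   complex-flagged functional term, and orthology groups (same
   functional-ortholog identifier implies isoforms). The default
   keywords are the terms that dominate a frequency analysis of
   annotation text from highly annotated organisms — `complex`,
   `component`, `interact` (stem-tolerant) and `by similarity`, plus the
   n-grams `interact with`, `part of a complex with`, `consist of`,
   `associate with`, `heteromerization with` — and are user-extensible.
   Token recognition inside sentences is exact (case-insensitive)
   against the organism's symbol universe; no approximate matching is
   attempted inside sentences, because a fuzzy hit on a near-miss token
   would fabricate a complex partner. Binary interaction statements
   ("Interacts with X") count as `SUBUNIT` evidence; a `by similarity`
   qualifier is recorded but does not change the label, since the
   evidence weighting between direct and propagated annotations is not
   specified anywhere we could anchor it.

5. **Relation resolution and rule assembly** (`resolve_relations`,
   `assemble_gpr`). Each evidenced pair gets exactly one label; on
   conflict the highest-priority source wins, with the default order
   `complex_portal > uniprot_interaction > uniprot_function > string >
   kegg_orthology` (manually curated structured data over annotation
   text over network predictions over orthology grouping). Pairs with no
   evidence default to `ISOFORM`: absence of complex evidence means the
   genes are alternative catalysts, which is the only default consistent
   with the strongly `or`-dominated composition of curated models.
   Assembly then takes connected components of the `SUBUNIT`-edge
   subgraph as `and` groups, parenthesizes them, and joins groups and
   isolated genes with `or`. Pairwise labels cannot express a gene shared
   between two alternative complexes, so when curated complex sets are
   available, every complex complete within the gene set becomes its own
   `and` group and a shared gene may appear in several groups; without
   complex sets the components interpretation merges them and the event
   is visible in the structured log. Output depth is at most
   `or`-of-`and`s.

## The Boolean algebra

`gpr_parse` implements the rule grammar: gene tokens, case-insensitive
`and`/`or` with `and` binding tighter, balanced parentheses. Expressions
are normalized on construction — associative nesting flattened, duplicate
children removed, children ordered by gene-set signature — so
`gpr_serialize` is canonical and deterministic, with `and` groups
parenthesized inside `or`.

Numerical and degenerate-input conventions:

- The empty rule evaluates to `FALSE` and its truth table is the single
  all-false row, but deletion analysis never constrains a reaction with
  an empty rule: a non-enzymatic reaction cannot be knocked out.
- Truth tables use the bit encoding "row *i*, gene *j* true iff bit *j*
  of *i* is set", and refuse to enumerate beyond the gene cap
  (default **20**, configurable), mirroring the point at which
  exhaustive comparison becomes unreasonable.
- Above the cap, `gpr_equivalent` compares canonical forms: flatten,
  deduplicate, apply absorption (`x or (x and y)` is `x`), sort. This is
  exact for rules built from one operator kind — the overwhelming
  majority of very large rules are flat `or` chains, where canonical
  identity is just set equality — and conservatively returns
  `indeterminate` for differing mixed-operator pairs rather than
  guessing.
- The Jaccard index of two empty gene sets is 1: two empty rules are
  identical and must not be scored as a mismatch.

## Evaluation machinery

`evaluate_rules_table` reproduces the benchmark workflow on a
four-column rules table (`Rxn`, `rule_original`, `rule_GPRuler`,
`Evaluation`). A pair is a *perfect match* only when the truth tables
over the union gene set are identical. For negative matches, the Jaccard
index between the two gene sets separates gene-set discrepancies from
operator discrepancies; only when the gene sets coincide (Jaccard 1) is
the normalized Hamming similarity between the truth tables computed —
oriented as a similarity, 1 for identical tables, 0 for opposite ones.
Rules are classed as `NO_GENE`, `ONE_GENE`, `OR`, `AND` or `MIXED` (class
taken from the original rule), and when curation labels are present,
`Automatic = Perfect match + Corrected` per class. One deliberate
convention: a pair proved equivalent reports Jaccard 1 even in the
degenerate absorption case (`g1` vs `g1 or (g1 and g2)`) where the raw
gene sets differ — equivalence implies full functional overlap, and the
invariant "perfect implies Jaccard 1" is kept.

The "global" Jaccard index is computed by pooling genes across all
original rules and across all reconstructed rules and taking one Jaccard
index of the two unions; a per-reaction mean is available behind
`method = "mean"` since the pooled definition is one of two defensible
readings. Histogram summaries use ten equal bins on `[0, 1]` — a
presentation choice only.

`single_gene_deletions` performs flux balance analysis: maximize the
biomass flux subject to the steady-state constraint `S v = 0` and flux
bounds. Deleting a gene sets it false in every rule; reactions whose
rule evaluates false get both bounds forced to zero. A mutant is
*viable* when the optimal biomass exceeds the positivity tolerance
(default `1e-9`, configurable). The linear programs are solved by an
internal two-phase simplex with Bland's anti-cycling rule. The solver is
deliberately written as a contract — any optimizer honouring bounds,
equalities and a linear objective is interchangeable within tolerance —
and the implementation choice is driven by robustness: deletion screens
produce many small, highly degenerate programs (entire pathways forced
to zero), where textbook tableau implementations without anti-cycling
pivoting fail outright; the test suite cross-checks the internal solver
against an independent simplex on non-degenerate instances and against
hand-solved programs on the toy network.

## The synthetic-fixture generator

`generate_fixture` builds a complete organism snapshot with known ground
truth: per reaction it draws a rule class, creates fresh genes and
compounds (fresh participants guarantee unique reaction signatures),
plants the subunit pairs in each evidence channel independently with the
per-channel `evidence_completeness` probability, turns isoform groups
into orthology groups, and writes annotation sentences instantiated from
the mining keyword templates. Distractor sentences (`text_noise`) reuse
gene-like tokens absent from the symbol universe, probing the universe
gate; `name_perturbation` applies per-character edits to the metabolite
names the *model* references, so the snapshot keeps clean names and the
fuzzy matcher is exercised exactly where a real model's nomenclature
drift would hit it.

The default class mix — 30% no-gene, 45% one-gene, with the multi-gene
remainder split 15/7/3 between `OR`, `AND` and `MIXED` — mirrors the
gross composition of curated metabolic models, whose rules are dominated
by empty and single-gene cases with `or`-only rules the most common
multi-gene class. Complex sizes default to 2–3 subunits and isoform
groups to 2–3 members, the typical scale in curated complex databases.

What the generator does *not* emulate: the heterogeneity and
inconsistency of real annotation prose, identifier drift across database
releases, incomplete or wrong ground-truth rules, and organism-specific
nomenclature. Fixture recovery is therefore a correctness ceiling for
the pipeline's logic — at full evidence and zero noise, recovery is
exactly 100% in every class — not an estimate of field performance on a
real organism, where accuracy is bounded by annotation quality.

Problem sizes used by the test suite and the acceptance script — a
300-reaction fixture for end-to-end recovery, 1000 random expression
pairs for the equivalence oracle, a 5-reaction hand-solvable network for
deletion analysis — are the package's chosen balance between coverage
and a suite that runs in seconds.

## Known limitations

- Text mining is keyword- and token-based by design; annotation
  statements that name partners without any keyword phrase, or through
  identifiers absent from the symbol universe, yield no evidence.
- Evidence channels are snapshots; the package never queries live
  services, so results are exactly as current as the snapshot files.
- Mined relations deeper than `or`-of-`and`s cannot be represented;
  evidence patterns that would require deeper nesting resolve to the
  flat interpretation.
- The organism-name mode requires the organism's genome, functional
  hierarchy and gene-reaction tables in the snapshot; organisms absent
  from the snapshot are an error, not a fallback to sequence search.

## A compact example

```{r example}
fx <- generate_fixture(fixture_spec(seed = 1, n_reactions = 30))
rec <- reconstruct_model_rules(fx$model, fx$bundle)
recovery_report(fx$truth, rec$rules)
```
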