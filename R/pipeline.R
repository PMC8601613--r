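#' @title End-to-end reconstruction pipeline
#'
#' @description
#' The two reconstruction modes share one core: resolve each reaction's
#' participants to compound identifiers, match the reaction (internal by
#' signature against the macro database, transport through transporter
#' substrate annotations), filter the candidate genes by localization,
#' mine pairwise subunit/isoform evidence for every gene, resolve the
#' relations and assemble the Boolean rule. Runs are fully deterministic:
#' identical configuration and snapshot yield identical outputs, and a
#' structured log records every automatic acceptance, shortlist deferral,
#' evidence conflict and parse failure.
#'
#' @name pipeline
NULL

#' Default compartment-to-localization vocabulary map
#'
#' @return Data frame (`compartment`, `term`).
#' @export
default_compartment_map <- function() {
  data.frame(
    compartment = c("c", "e", "m", "n", "x", "r", "g", "v"),
    term = c("cytosol", "extracellular", "mitochondrion", "nucleus",
             "peroxisome", "endoplasmic reticulum", "golgi", "vacuole"),
    stringsAsFactors = FALSE)
}

new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}
log_event <- function(log, stage, entity, message) {
  if (is.null(log)) return(invisible(NULL))
  log$rows[[length(log$rows) + 1L]] <-
    data.frame(stage = stage, entity = entity, message = message,
               stringsAsFactors = FALSE)
  invisible(NULL)
}
log_table <- function(log) {
  if (is.null(log) || length(log$rows) == 0L)
    return(data.frame(stage = character(), entity = character(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, log$rows)
  rownames(out) <- NULL
  out
}

#' Mine all relationship evidence for a set of genes
#'
#' Combines the text-mining, complex, network and orthology channels for
#' each gene against the snapshot bundle.
#'
#' @param genes character vector of gene identifiers.
#' @param bundle a `"gpr_snapshot"`.
#' @param keywords mining keyword list.
#' @return Evidence data frame.
#' @export
mine_all_evidence <- function(genes, bundle,
                              keywords = gpr_default_keywords()) {
  universe <- gene_universe(bundle$proteins)
  out <- lapply(genes, function(g) {
    rec <- bundle$proteins[[g]]
    rbind(
      if (!is.null(rec)) extract_partners(rec, universe, keywords)
      else empty_evidence(),
      complex_partners(g, bundle$complexes),
      string_partners(g, bundle$network),
      isoform_partners(g, bundle$orthology))
  })
  unique(do.call(rbind, c(list(empty_evidence()), out)))
}

#' Reconstruct GPR rules for a model against a snapshot
#'
#' The reaction-list reconstruction mode: metabolite resolution, macro
#' database matching (transport reactions consult the macro database and
#' the transporter table, taking the union), localization filtering,
#' evidence mining and rule assembly.
#'
#' @param model a `"gpr_model"`.
#' @param bundle a `"gpr_snapshot"`.
#' @param threshold metabolite acceptance threshold (default 91).
#' @param cap truth-table gene cap carried into downstream comparison.
#' @param aliases metabolite alias table; defaults to
#'   [default_metabolite_aliases()].
#' @param priority evidence source priority.
#' @param compartment_map compartment vocabulary map.
#' @param keywords mining keyword list.
#' @return List of class `"gpr_reconstruction"`: `rules` (named list of
#'   `"gpr"`), `table` (a `"gpr_rules_table"` with any model rules in
#'   `rule_original`), `genes` (reaction -> gene map), and `log`.
#' @export
reconstruct_model_rules <- function(model, bundle, threshold = 91L,
                                    cap = 20L,
                                    aliases = default_metabolite_aliases(),
                                    priority = gpr_source_priority(),
                                    compartment_map = default_compartment_map(),
                                    keywords = gpr_default_keywords()) {
  stopifnot(inherits(model, "gpr_model"), inherits(bundle, "gpr_snapshot"))
  log <- new_log()
  index <- compound_index(bundle$compounds)
  db <- build_macro_database(bundle$reactions)

  match_cache <- new.env(parent = emptyenv())
  resolve_name <- function(nm) {
    key <- tolower(nm)
    if (!is.null(match_cache[[key]])) return(match_cache[[key]])
    res <- match_metabolite(nm, index, threshold = threshold,
                            aliases = aliases)
    if (is.na(res$accepted)) {
      log_event(log, "metabolites", nm,
                paste0("unresolved; shortlist of ", nrow(res$shortlist),
                       " returned for confirmation"))
    } else {
      log_event(log, "metabolites", nm,
                paste0("accepted ", res$accepted, " (",
                       res$shortlist$method[1], ", score ",
                       res$shortlist$score[1], ")"))
    }
    match_cache[[key]] <- res$accepted
    res$accepted
  }

  rx <- model$reactions
  reaction_genes <- stats::setNames(vector("list", nrow(rx)), rx$reaction_id)
  for (i in seq_len(nrow(rx))) {
    rid <- rx$reaction_id[i]
    parts <- rx$participants[[i]]
    ids <- vapply(parts$compound, resolve_name, character(1))
    if (anyNA(ids)) {
      log_event(log, "reactions", rid,
                "skipped: unresolved metabolite(s)")
      reaction_genes[[rid]] <- character()
      next
    }
    parts$compound_id <- unname(ids)
    is_transport <- length(intersect(
      parts$compound_id[parts$side == "substrate"],
      parts$compound_id[parts$side == "product"])) > 0L &&
      length(unique(parts$compartment)) > 1L
    genes <- character()
    subs <- data.frame(compound = parts$compound_id[parts$side == "substrate"],
                       coef = parts$coef[parts$side == "substrate"],
                       stringsAsFactors = FALSE)
    prods <- data.frame(compound = parts$compound_id[parts$side == "product"],
                        coef = parts$coef[parts$side == "product"],
                        stringsAsFactors = FALSE)
    entry <- match_internal_reaction(subs, prods, db)
    if (!is.null(entry)) genes <- union(genes, entry$genes[[1]])
    if (is_transport) {
      tparts <- data.frame(compound = parts$compound_id, coef = parts$coef,
                           compartment = parts$compartment,
                           side = parts$side, stringsAsFactors = FALSE)
      tgenes <- tryCatch(
        match_transport_reaction(tparts, bundle$transporters),
        error = function(e) character())
      genes <- union(genes, tgenes)
    }
    if (is.null(entry) && !is_transport)
      log_event(log, "reactions", rid, "no macro-database entry matches")
    comp <- unique(parts$compartment)
    if (length(comp) == 1L)
      genes <- filter_genes_by_localization(genes, comp, bundle$proteins,
                                            compartment_map)
    reaction_genes[[rid]] <- sort(genes)
  }

  all_genes <- sort(unique(unlist(reaction_genes)))
  evidence <- mine_all_evidence(all_genes, bundle, keywords)
  rules <- stats::setNames(vector("list", nrow(rx)), rx$reaction_id)
  for (rid in rx$reaction_id) {
    graph <- resolve_relations(reaction_genes[[rid]], evidence, priority)
    if (nrow(graph$conflicts))
      log_event(log, "relations", rid,
                paste0(nrow(graph$conflicts),
                       " evidence conflict(s) resolved by source priority"))
    rules[[rid]] <- assemble_gpr(reaction_genes[[rid]], graph,
                                 bundle$complexes)
  }

  table <- rules_table(
    Rxn = rx$reaction_id,
    rule_original = ifelse(is.na(rx$rule), "", rx$rule),
    rule_GPRuler = vapply(rules[rx$reaction_id], gpr_serialize, character(1)))
  structure(list(rules = rules, table = table, genes = reaction_genes,
                 log = log_table(log)),
            class = "gpr_reconstruction")
}

#' @export
print.gpr_reconstruction <- function(x, ...) {
  cat("<reconstruction> ", length(x$rules), " reaction(s), ",
      sum(vapply(x$rules, function(r) r$kind != "EMPTY", logical(1))),
      " non-empty rule(s), ", nrow(x$log), " log event(s)\n", sep = "")
  invisible(x)
}

#' Reconstruct rules starting from an organism name
#'
#' Resolves the organism against the snapshot's organism index, harvests
#' its metabolic genes and reactions (functional-hierarchy filter, then
#' union with the macro-database genes), and runs the shared mining and
#' assembly core. The snapshot must carry `genome`, `hierarchy` and
#' `gene_reactions` auxiliary tables supplied through `organism_tables`.
#'
#' @param organism organism name or fragment.
#' @param bundle a `"gpr_snapshot"`.
#' @param organism_tables list with data frames `genome` (`code`, `gene`,
#'   `branch`), `hierarchy` (`branch`, `metabolic`), `gene_reactions`
#'   (`gene`, `reaction_id`).
#' @param interactive surface disambiguation candidates instead of
#'   choosing (see [resolve_organism()]).
#' @param priority,keywords,compartment_map see
#'   [reconstruct_model_rules()].
#' @return A `"gpr_reconstruction"` object (no `rule_original` column
#'   content).
#' @export
reconstruct_organism_rules <- function(organism, bundle, organism_tables,
                                       interactive = FALSE,
                                       priority = gpr_source_priority(),
                                       keywords = gpr_default_keywords(),
                                       compartment_map = default_compartment_map()) {
  log <- new_log()
  code <- resolve_organism(organism, bundle$organisms,
                           interactive = interactive)
  if (is.data.frame(code)) return(code)  # disambiguation surfaced
  log_event(log, "organism", organism, paste0("resolved to ", code))
  db <- build_macro_database(bundle$reactions)
  reaction_genes <- metabolic_reactions_for_organism(
    code, organism_tables$genome, organism_tables$hierarchy,
    organism_tables$gene_reactions, db)
  all_genes <- sort(unique(unlist(reaction_genes)))
  evidence <- mine_all_evidence(all_genes, bundle, keywords)
  rules <- lapply(names(reaction_genes), function(rid) {
    graph <- resolve_relations(reaction_genes[[rid]], evidence, priority)
    assemble_gpr(reaction_genes[[rid]], graph, bundle$complexes)
  })
  names(rules) <- names(reaction_genes)
  table <- rules_table(
    Rxn = names(rules), rule_original = "",
    rule_GPRuler = vapply(rules, gpr_serialize, character(1)))
  structure(list(rules = rules, table = table, genes = reaction_genes,
                 log = log_table(log)),
            class = "gpr_reconstruction")
}

#' Run configuration for the pipeline front end
#'
#' @param mode one of `from_model`, `from_list`, `from_organism`,
#'   `evaluate`, `deletions`, `make_fixture`.
#' @param snapshot_dir snapshot directory (reconstruction modes).
#' @param model_path SBML or TSV model path.
#' @param rules_path rules-table CSV (evaluate mode).
#' @param phenotype_path phenotype annotation TSV with columns `gene`,
#'   `annotated` (deletions mode).
#' @param organism organism name (from_organism mode).
#' @param out_dir output directory.
#' @param threshold metabolite acceptance threshold (default 91).
#' @param cap truth-table gene cap (default 20).
#' @param priority evidence source priority.
#' @param interactive surface disambiguation prompts; in non-interactive
#'   mode every would-be prompt resolves to the documented default and is
#'   logged.
#' @param seed integer seed (fixture mode).
#' @param n_reactions fixture size (fixture mode).
#' @return List of class `"gpr_run_config"`.
#' @export
run_config <- function(mode = c("from_model", "from_list", "from_organism",
                                "evaluate", "deletions", "make_fixture"),
                       snapshot_dir = NULL, model_path = NULL,
                       rules_path = NULL, phenotype_path = NULL,
                       organism = NULL,
                       out_dir = ".", threshold = 91L, cap = 20L,
                       priority = gpr_source_priority(),
                       interactive = FALSE, seed = 1L, n_reactions = 100L) {
  mode <- match.arg(mode)
  need <- switch(mode,
                 from_model = , from_list = c("snapshot_dir", "model_path"),
                 from_organism = c("snapshot_dir", "organism"),
                 evaluate = "rules_path",
                 deletions = c("model_path", "phenotype_path"),
                 make_fixture = character())
  vals <- list(snapshot_dir = snapshot_dir, model_path = model_path,
               rules_path = rules_path, phenotype_path = phenotype_path,
               organism = organism)
  missing <- need[vapply(vals[need], is.null, logical(1))]
  if (length(missing))
    stop("mode '", mode, "' requires: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(mode = mode, snapshot_dir = snapshot_dir,
                 model_path = model_path, rules_path = rules_path,
                 phenotype_path = phenotype_path,
                 organism = organism, out_dir = out_dir,
                 threshold = threshold, cap = cap, priority = priority,
                 interactive = interactive, seed = as.integer(seed),
                 n_reactions = as.integer(n_reactions)),
            class = "gpr_run_config")
}

#' Execute a configured pipeline run
#'
#' Dispatches on the configured mode and writes the mode's artifacts into
#' the output directory: reconstruction modes emit `rules.csv`, an
#' annotated SBML model and `report.tsv`; evaluate emits the per-reaction
#' comparison and class-count tables; make_fixture writes a snapshot
#' directory, the model TSV and the ground-truth rules CSV.
#'
#' @param config a [run_config()].
#' @return The mode's result object, invisibly (reconstruction object,
#'   evaluation summary, confusion matrix, or fixture file set).
#' @export
gpr_run <- function(config) {
  stopifnot(inherits(config, "gpr_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  res <- switch(config$mode,
    from_model = , from_list = {
      bundle <- read_snapshot(config$snapshot_dir)
      model <- read_model(config$model_path)
      rec <- reconstruct_model_rules(model, bundle,
                                     threshold = config$threshold,
                                     cap = config$cap,
                                     priority = config$priority)
      write_rules_table(rec$table, out("rules.csv"))
      write_annotated_model(model, rec$rules, out("annotated_model.xml"))
      write_tsv(rec$log, out("report.tsv"))
      rec
    },
    from_organism = {
      bundle <- read_snapshot(config$snapshot_dir)
      aux_dir <- config$snapshot_dir
      organism_tables <- list(
        genome = read_tsv(file.path(aux_dir, "genome.tsv")),
        hierarchy = local({
          h <- read_tsv(file.path(aux_dir, "hierarchy.tsv"))
          h$metabolic <- h$metabolic == "true"
          h
        }),
        gene_reactions = read_tsv(file.path(aux_dir, "gene_reactions.tsv")))
      rec <- reconstruct_organism_rules(config$organism, bundle,
                                        organism_tables,
                                        interactive = config$interactive,
                                        priority = config$priority)
      write_rules_table(rec$table, out("rules.csv"))
      write_tsv(rec$log, out("report.tsv"))
      rec
    },
    evaluate = {
      table <- read_rules_table(config$rules_path)
      ev <- evaluate_rules_table(table, cap = config$cap)
      write_tsv(ev$per_reaction, out("per_reaction.tsv"))
      write_tsv(ev$counts, out("class_counts.tsv"))
      ev
    },
    deletions = {
      model <- read_fba_model_tsv(config$model_path)
      pheno <- read_tsv(config$phenotype_path)
      screen <- single_gene_deletions(model)
      outcomes <- merge(screen, pheno[, c("gene", "annotated")], by = "gene")
      cm <- confusion_matrix(outcomes)
      write_tsv(outcomes, out("deletion_outcomes.tsv"))
      write_tsv(data.frame(predicted = rownames(cm$counts), cm$counts,
                           check.names = FALSE), out("confusion_matrix.tsv"))
      cm
    },
    make_fixture = {
      fx <- generate_fixture(fixture_spec(seed = config$seed,
                                          n_reactions = config$n_reactions))
      write_snapshot(fx$bundle, out("snapshot"))
      write_model_tsv(fx$model, out("model.tsv"))
      # organism-mode auxiliary tables over the same snapshot
      genes <- names(fx$bundle$proteins)
      write_tsv(data.frame(code = rep("syn", length(genes)), gene = genes,
                           branch = rep("Metabolism", length(genes))),
                out("snapshot", "genome.tsv"))
      write_tsv(data.frame(branch = "Metabolism", metabolic = "true"),
                out("snapshot", "hierarchy.tsv"))
      rx <- fx$bundle$reactions
      gene_rx <- do.call(rbind, lapply(seq_len(nrow(rx)), function(i) {
        g <- rx$genes[[i]]
        if (length(g) == 0L) return(NULL)
        data.frame(gene = g, reaction_id = rx$reaction_id[i],
                   stringsAsFactors = FALSE)
      }))
      if (is.null(gene_rx))
        gene_rx <- data.frame(gene = character(), reaction_id = character())
      write_tsv(gene_rx, out("snapshot", "gene_reactions.tsv"))
      write_rules_table(rules_table(
        Rxn = names(fx$truth$rules),
        rule_original = vapply(fx$truth$rules, gpr_serialize, character(1)),
        rule_GPRuler = ""), out("truth_rules.csv"))
      fx
    })
  invisible(res)
}
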