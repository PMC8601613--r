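#' @title Model input and output
#'
#' @description
#' Reconstruction starts from either an SBML model or a plain reaction
#' table. Both dialects load into the same `"gpr_model"` container: one
#' row per reaction with a participant table (compound, stoichiometric
#' coefficient, compartment, side) and any pre-existing gene-association
#' string captured verbatim. The annotated-model writer serializes
#' reconstructed rules back into the SBML gene-association slot.
#'
#' @name model-io
NULL

#' Construct a model input
#'
#' @param reactions data frame with columns `reaction_id`, `rule`
#'   (existing gene-association strings, `NA`/"" when absent), and
#'   list-column `participants` of data frames (`compound`, `coef`,
#'   `compartment`, `side`).
#' @param gene_namespace label of the gene identifier scheme
#'   (`"model-local"`, `"KEGG-gene"`, `"gene-symbol"`).
#' @return An object of class `"gpr_model"`.
#' @export
gpr_model <- function(reactions, gene_namespace = "model-local") {
  if (anyDuplicated(reactions$reaction_id))
    stop("reaction ids must be unique", call. = FALSE)
  structure(list(reactions = reactions, gene_namespace = gene_namespace),
            class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat("<model input> ", nrow(x$reactions), " reaction(s), gene namespace ",
      x$gene_namespace, "\n", sep = "")
  invisible(x)
}

## participants encoded in TSV as "compound[compartment]:coef|..."
parse_participants <- function(subs, prods, reaction_id) {
  one_side <- function(txt, side) {
    parts <- split_list(txt)[[1]]
    if (length(parts) == 0L)
      return(data.frame(compound = character(), coef = numeric(),
                        compartment = character(), side = character(),
                        stringsAsFactors = FALSE))
    m <- regmatches(parts, regexec("^(.*)\\[([^]]+)\\]:([0-9.]+)$", parts))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad))
      stop("reaction ", reaction_id, ": malformed participant '",
           parts[bad][1], "' (expected compound[compartment]:coef)",
           call. = FALSE)
    data.frame(compound = vapply(m, `[[`, character(1), 2L),
               compartment = vapply(m, `[[`, character(1), 3L),
               coef = as.numeric(vapply(m, `[[`, character(1), 4L)),
               side = side, stringsAsFactors = FALSE)
  }
  rbind(one_side(subs, "substrate"), one_side(prods, "product"))
}

format_participants <- function(df, side) {
  df <- df[df$side == side, , drop = FALSE]
  if (nrow(df) == 0L) return("")
  df <- df[order(df$compound, df$compartment, method = "radix"), , drop = FALSE]
  paste(paste0(df$compound, "[", df$compartment, "]:", format_coef(df$coef)),
        collapse = "|")
}

#' Read a model from SBML or a reaction table
#'
#' The TSV dialect has required columns `reaction_id`, `substrates`,
#' `products` (participants encoded `compound[compartment]:coef`,
#' pipe-separated) and an optional `gpr` column with existing rule
#' strings. The SBML dialect accepts any level, taking compartments from
#' the species, stoichiometry from the speciesReference entries, and gene
#' associations from either the fbc `geneProductAssociation` slot or
#' legacy `GENE_ASSOCIATION:` notes, captured verbatim as rule strings.
#'
#' @param path file path.
#' @param dialect `"sbml"` or `"tsv"`; default guessed from the extension.
#' @return A `"gpr_model"` object.
#' @export
read_model <- function(path, dialect = c("auto", "sbml", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (tolower(tools::file_ext(path)) %in% c("xml", "sbml"))
      "sbml" else "tsv"
  if (dialect == "sbml") return(read_sbml_model(path))
  raw <- read_tsv(path)
  for (col in c("reaction_id", "substrates", "products")) {
    if (!col %in% names(raw))
      stop("reaction table is missing required column '", col, "'",
           call. = FALSE)
  }
  reactions <- data.frame(reaction_id = raw$reaction_id,
                          rule = if ("gpr" %in% names(raw)) raw$gpr
                                 else NA_character_,
                          stringsAsFactors = FALSE)
  reactions$participants <- lapply(seq_len(nrow(raw)), function(i)
    parse_participants(raw$substrates[i], raw$products[i],
                       raw$reaction_id[i]))
  gpr_model(reactions)
}

#' Write a model to the TSV reaction-table dialect
#'
#' @param model a `"gpr_model"`.
#' @param path target file.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  stopifnot(inherits(model, "gpr_model"))
  rx <- model$reactions
  out <- data.frame(
    reaction_id = rx$reaction_id,
    substrates = vapply(rx$participants, format_participants, character(1),
                        side = "substrate"),
    products = vapply(rx$participants, format_participants, character(1),
                      side = "product"),
    gpr = ifelse(is.na(rx$rule), "", rx$rule),
    stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(path)
}

## ---- SBML ------------------------------------------------------------------

sbml_ns <- function(doc) {
  ns <- xml2::xml_ns(doc)
  # pick prefixes for the core and fbc namespaces whatever the document calls them
  core <- names(ns)[grepl("^http://www\\.sbml\\.org/sbml/", ns) &
                      !grepl("/fbc/", ns)]
  fbc <- names(ns)[grepl("/fbc/", ns)]
  list(ns = ns, core = if (length(core)) core[1] else NA,
       fbc = if (length(fbc)) fbc[1] else NA)
}

species_token <- function(species_id, compartment) {
  # recover the compound token from ids of the form M_<compound>_<comp>
  x <- sub("^M_", "", species_id)
  suffix <- paste0("_", compartment)
  if (endsWith(x, suffix)) x <- substr(x, 1L, nchar(x) - nchar(suffix))
  x
}

read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  nsinfo <- sbml_ns(doc)
  p <- nsinfo$core
  q <- function(tag) paste0(".//", p, ":", tag)

  sp_nodes <- xml2::xml_find_all(doc, q("listOfSpecies/*"))
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  if (any(is.na(sp_comp)))
    stop("species without compartment in '", path, "'", call. = FALSE)
  names(sp_comp) <- sp_id
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_name <- ifelse(is.na(sp_name) | !nzchar(sp_name),
                    vapply(seq_along(sp_id), function(i)
                      species_token(sp_id[i], sp_comp[i]), character(1)),
                    sp_name)
  names(sp_name) <- sp_id

  gp_label <- character()
  if (!is.na(nsinfo$fbc)) {
    gp_nodes <- xml2::xml_find_all(
      doc, paste0(".//", nsinfo$fbc, ":listOfGeneProducts/*"))
    gp_label <- stats::setNames(
      ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
             xml2::xml_attr(gp_nodes, "id"),
             xml2::xml_attr(gp_nodes, "label")),
      xml2::xml_attr(gp_nodes, "id"))
  }

  assoc_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lbl <- gp_label[ref]
      return(if (!is.na(lbl)) unname(lbl) else ref)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      s <- assoc_to_string(k)
      if (xml2::xml_name(k) %in% c("and", "or")) paste0("(", s, ")") else s
    }, character(1))
    op <- if (nm == "and") " and " else " or "
    paste(parts, collapse = op)
  }

  rx_nodes <- xml2::xml_find_all(doc, q("listOfReactions/*"))
  rows <- lapply(rx_nodes, function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    side <- function(list_tag, side_label) {
      refs <- xml2::xml_find_all(rx, paste0("./", p, ":", list_tag, "/*"))
      if (length(refs) == 0L)
        return(data.frame(compound = character(), coef = numeric(),
                          compartment = character(), side = character(),
                          stringsAsFactors = FALSE))
      sid <- xml2::xml_attr(refs, "species")
      if (any(!sid %in% names(sp_comp)))
        stop("reaction ", rid, " references unknown species", call. = FALSE)
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      comp <- unname(sp_comp[sid])
      data.frame(compound = unname(sp_name[sid]),
                 coef = st, compartment = comp, side = side_label,
                 stringsAsFactors = FALSE)
    }
    parts <- rbind(side("listOfReactants", "substrate"),
                   side("listOfProducts", "product"))
    rule <- NA_character_
    if (!is.na(nsinfo$fbc)) {
      gpa <- xml2::xml_find_first(rx, paste0("./", nsinfo$fbc,
                                             ":geneProductAssociation"))
      if (!inherits(gpa, "xml_missing")) {
        kids <- xml2::xml_children(gpa)
        if (length(kids)) rule <- assoc_to_string(kids[[1]])
      }
    }
    if (is.na(rule)) {
      notes <- xml2::xml_find_first(rx, paste0("./", p, ":notes"))
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexec("GENE_ASSOCIATION:\\s*([^\n]*)", txt))[[1]]
        if (length(m) == 2L) rule <- trimws(m[2])
      }
    }
    list(reaction_id = rid, rule = rule, participants = parts)
  })
  reactions <- data.frame(
    reaction_id = vapply(rows, `[[`, character(1), "reaction_id"),
    rule = vapply(rows, `[[`, character(1), "rule"),
    stringsAsFactors = FALSE)
  reactions$participants <- lapply(rows, `[[`, "participants")
  gpr_model(reactions)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

assoc_xml <- function(expr, indent) {
  pad <- strrep(" ", indent)
  switch(expr$kind,
    GENE = paste0(pad, "<fbc:geneProductRef fbc:geneProduct=\"G_",
                  sanitize_sid(expr$gene), "\"/>"),
    AND = ,
    OR = {
      tag <- if (expr$kind == "AND") "fbc:and" else "fbc:or"
      inner <- vapply(expr$children, assoc_xml, character(1),
                      indent = indent + 2L)
      paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"),
             "\n", pad, "</", tag, ">")
    })
}

#' Write a model with reconstructed rules as SBML
#'
#' Emits SBML level 3 version 1 with the fbc package: species per
#' (compound, compartment), stoichiometric speciesReference entries, a
#' `geneProductAssociation` per reaction carrying the serialized rule
#' (reactions with an empty rule carry no association), and the gene
#' product list. Output is byte-identical for identical inputs.
#'
#' @param model a `"gpr_model"`.
#' @param rules named list of `"gpr"` expressions (or rule strings) keyed
#'   by reaction id; every key must exist in the model.
#' @param path target file.
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
write_annotated_model <- function(model, rules, path,
                                  model_id = "reconstructed_model") {
  stopifnot(inherits(model, "gpr_model"))
  rules <- lapply(rules, function(r) if (inherits(r, "gpr")) r else gpr_parse(r))
  unknown <- setdiff(names(rules), model$reactions$reaction_id)
  if (length(unknown))
    stop("rules reference unknown reaction id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  rx <- model$reactions
  all_parts <- do.call(rbind, rx$participants)
  species <- unique(all_parts[, c("compound", "compartment")])
  species <- species[order(species$compound, species$compartment,
                           method = "radix"), , drop = FALSE]
  species$id <- paste0("M_", sanitize_sid(species$compound), "_",
                       species$compartment)
  comps <- sort(unique(species$compartment))
  genes <- sort(unique(unlist(lapply(rules, gpr_genes))))

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    paste0("  <model id=\"", xml_escape(model_id),
           "\" fbc:strict=\"false\">"),
    "    <listOfCompartments>",
    paste0("      <compartment id=\"", xml_escape(comps),
           "\" constant=\"true\"/>"),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  lines <- c(lines, vapply(seq_len(nrow(species)), function(i)
    paste0("      <species id=\"", species$id[i], "\" name=\"",
           xml_escape(species$compound[i]), "\" compartment=\"",
           species$compartment[i],
           "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
           " constant=\"false\"/>"), character(1)),
    "    </listOfSpecies>")

  sp_id <- function(compound, compartment)
    species$id[match(paste(compound, compartment),
                     paste(species$compound, species$compartment))]

  lines <- c(lines, "    <listOfReactions>")
  for (i in seq_len(nrow(rx))) {
    rid <- rx$reaction_id[i]
    parts <- rx$participants[[i]]
    lines <- c(lines, paste0("      <reaction id=\"", xml_escape(rid),
                             "\" reversible=\"false\" fast=\"false\">"))
    for (side in c("substrate", "product")) {
      df <- parts[parts$side == side, , drop = FALSE]
      if (nrow(df) == 0L) next
      df <- df[order(df$compound, df$compartment, method = "radix"), ,
               drop = FALSE]
      tag <- if (side == "substrate") "listOfReactants" else "listOfProducts"
      lines <- c(lines, paste0("        <", tag, ">"),
                 vapply(seq_len(nrow(df)), function(j)
                   paste0("          <speciesReference species=\"",
                          sp_id(df$compound[j], df$compartment[j]),
                          "\" stoichiometry=\"", format_coef(df$coef[j]),
                          "\" constant=\"true\"/>"), character(1)),
                 paste0("        </", tag, ">"))
    }
    rule <- rules[[rid]]
    if (!is.null(rule) && rule$kind != "EMPTY") {
      body <- assoc_xml(rule, 10L)
      lines <- c(lines, "        <fbc:geneProductAssociation>", body,
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (length(genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               vapply(genes, function(g)
                 paste0("      <fbc:geneProduct fbc:id=\"G_", sanitize_sid(g),
                        "\" fbc:label=\"", xml_escape(g), "\"/>"),
                 character(1)),
               "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
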