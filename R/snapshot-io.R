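#' @title Offline snapshot bundles
#'
#' @description
#' All database evidence the pipeline consumes lives in a snapshot
#' directory: one delimited UTF-8 table per data source (compounds,
#' reactions, transporters, proteins, complexes, interaction network,
#' orthology groups, organisms) plus a manifest. Tables have a one-line
#' header, one entity per row, and pipe-separated list-valued fields —
#' hand-editable and diffable. Referential integrity (every referenced
#' gene/compound id exists in its home table) is validated on read.
#'
#' @name snapshot-io
NULL

snapshot_tables <- c("compounds", "reactions", "transporters", "proteins",
                     "complexes", "network_edges", "network_annotations",
                     "orthology", "organisms")

join_list <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}
split_list <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}
join_pairs <- function(x) {
  # named character vectors -> "key:value|key:value"
  vapply(x, function(v) {
    if (length(v) == 0L) return("")
    paste(paste0(names(v), ":", v), collapse = "|")
  }, character(1))
}
split_pairs <- function(x) {
  lapply(split_list(x), function(parts) {
    if (length(parts) == 0L) return(stats::setNames(character(), character()))
    kv <- strsplit(parts, ":", fixed = TRUE)
    stats::setNames(vapply(kv, function(p) paste(p[-1], collapse = ":"),
                           character(1)),
                    vapply(kv, `[[`, character(1), 1L))
  })
}
join_side <- function(x) {
  # list of data.frame(compound, coef) -> "compound:coef|..."
  vapply(x, function(df) {
    if (is.null(df) || nrow(df) == 0L) return("")
    df <- df[order(df$compound, method = "radix"), , drop = FALSE]
    paste(paste0(df$compound, ":", format_coef(df$coef)), collapse = "|")
  }, character(1))
}
split_side <- function(x) {
  lapply(split_list(x), function(parts) {
    if (length(parts) == 0L)
      return(data.frame(compound = character(), coef = numeric(),
                        stringsAsFactors = FALSE))
    kv <- strsplit(parts, ":", fixed = TRUE)
    data.frame(compound = vapply(kv, `[[`, character(1), 1L),
               coef = as.numeric(vapply(kv, `[[`, character(1), 2L)),
               stringsAsFactors = FALSE)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
}
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                    stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Assemble an in-memory snapshot bundle
#'
#' @param compounds data frame: `compound_id`, `source`, `inchi`, plus
#'   list-columns `names`, `xrefs` (named), `ontology_parents`.
#' @param reactions data frame: `reaction_id`, plus list-columns `sources`,
#'   `substrates`/`products` (data frames `compound`, `coef`),
#'   `ec_numbers`, `genes`, `xrefs`.
#' @param transporters data frame: `tc_code`, list-columns `substrates`,
#'   `genes`.
#' @param proteins named list of [protein_record()] objects.
#' @param complexes list of [complex_record()] objects.
#' @param network an [interaction_network()].
#' @param orthology list of [orthology_group()] objects.
#' @param organisms data frame: `code`, `name`.
#' @param manifest named character vector of bundle metadata (must carry
#'   an `organism` entry; a `synthetic` flag marks generated bundles).
#' @return An object of class `"gpr_snapshot"`.
#' @export
snapshot_bundle <- function(compounds, reactions, transporters, proteins,
                            complexes, network, orthology, organisms,
                            manifest) {
  stopifnot("organism" %in% names(manifest))
  structure(list(compounds = compounds, reactions = reactions,
                 transporters = transporters, proteins = proteins,
                 complexes = complexes, network = network,
                 orthology = orthology, organisms = organisms,
                 manifest = manifest),
            class = "gpr_snapshot")
}

#' @export
print.gpr_snapshot <- function(x, ...) {
  cat("<snapshot bundle> organism ", x$manifest[["organism"]], ": ",
      nrow(x$compounds), " compounds, ", nrow(x$reactions), " reactions, ",
      length(x$proteins), " proteins, ", length(x$complexes), " complexes, ",
      length(x$orthology), " orthology groups\n", sep = "")
  invisible(x)
}

#' Validate referential integrity of a snapshot bundle
#'
#' Checks that every compound id referenced by reactions and transporters
#' exists in the compound table and every gene referenced by reactions,
#' complexes, the network and orthology groups exists in the protein
#' table.
#'
#' @param bundle a `"gpr_snapshot"`.
#' @return Character vector of dangling-reference messages (empty when the
#'   bundle is consistent).
#' @export
snapshot_integrity <- function(bundle) {
  probs <- character()
  cmp_ids <- bundle$compounds$compound_id
  gene_ids <- vapply(bundle$proteins, `[[`, character(1), "gene")
  ref_cmp <- unique(c(
    unlist(lapply(bundle$reactions$substrates, `[[`, "compound")),
    unlist(lapply(bundle$reactions$products, `[[`, "compound")),
    unlist(bundle$transporters$substrates)))
  bad <- setdiff(ref_cmp, cmp_ids)
  if (length(bad))
    probs <- c(probs, paste0("unknown compound id: ", bad))
  ref_gene <- unique(c(
    unlist(bundle$reactions$genes),
    unlist(bundle$transporters$genes),
    unlist(lapply(bundle$complexes, `[[`, "components")),
    unlist(lapply(bundle$orthology, `[[`, "members")),
    bundle$network$edges$gene_a, bundle$network$edges$gene_b,
    bundle$network$annotations$gene))
  bad <- setdiff(ref_gene, gene_ids)
  if (length(bad))
    probs <- c(probs, paste0("unknown gene id: ", bad))
  probs
}

#' Write a snapshot bundle to a directory
#'
#' One tab-separated table per data source plus `manifest.tsv`. Rows are
#' written in a stable sorted order and coefficients with fixed decimal
#' formatting, so identical bundles produce byte-identical directories.
#'
#' @param bundle a `"gpr_snapshot"`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_snapshot <- function(bundle, dir) {
  stopifnot(inherits(bundle, "gpr_snapshot"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- bundle$compounds
  cmp_out <- data.frame(compound_id = cmp$compound_id, source = cmp$source,
                        names = join_list(cmp$names), inchi = cmp$inchi,
                        xrefs = join_pairs(cmp$xrefs),
                        ontology_parents = join_list(cmp$ontology_parents),
                        stringsAsFactors = FALSE)
  write_tsv(cmp_out[order(cmp_out$compound_id, method = "radix"), ],
            file.path(dir, "compounds.tsv"))

  rx <- bundle$reactions
  rx_out <- data.frame(reaction_id = rx$reaction_id,
                       sources = join_list(rx$sources),
                       substrates = join_side(rx$substrates),
                       products = join_side(rx$products),
                       ec_numbers = join_list(rx$ec_numbers),
                       genes = join_list(rx$genes),
                       xrefs = join_list(rx$xrefs),
                       stringsAsFactors = FALSE)
  write_tsv(rx_out[order(rx_out$reaction_id, method = "radix"), ],
            file.path(dir, "reactions.tsv"))

  tr <- bundle$transporters
  tr_out <- data.frame(tc_code = tr$tc_code,
                       substrates = join_list(tr$substrates),
                       genes = join_list(tr$genes), stringsAsFactors = FALSE)
  write_tsv(tr_out[order(tr_out$tc_code, method = "radix"), ],
            file.path(dir, "transporters.tsv"))

  pr <- bundle$proteins
  pr_out <- do.call(rbind, lapply(pr, function(p) {
    loc <- p$localizations
    data.frame(gene = p$gene, synonyms = paste(p$synonyms, collapse = "|"),
               interaction_text = p$interaction_text,
               function_text = p$function_text,
               complex_xrefs = paste(p$complex_xrefs, collapse = "|"),
               localizations = if (nrow(loc))
                 paste(paste0(loc$term, ":", loc$evidence), collapse = "|")
               else "",
               stringsAsFactors = FALSE)
  }))
  if (is.null(pr_out))
    pr_out <- data.frame(gene = character(), synonyms = character(),
                         interaction_text = character(),
                         function_text = character(),
                         complex_xrefs = character(),
                         localizations = character())
  write_tsv(pr_out[order(pr_out$gene, method = "radix"), ],
            file.path(dir, "proteins.tsv"))

  cx_out <- do.call(rbind, lapply(bundle$complexes, function(cx)
    data.frame(complex_id = cx$complex_id,
               components = paste(sort(cx$components), collapse = "|"),
               stringsAsFactors = FALSE)))
  if (is.null(cx_out))
    cx_out <- data.frame(complex_id = character(), components = character())
  write_tsv(cx_out[order(cx_out$complex_id, method = "radix"), ],
            file.path(dir, "complexes.tsv"))

  ed <- bundle$network$edges
  ed_out <- data.frame(gene_a = pmin(ed$gene_a, ed$gene_b),
                       gene_b = pmax(ed$gene_a, ed$gene_b),
                       stringsAsFactors = FALSE)
  ed_out <- unique(ed_out)
  write_tsv(ed_out[order(ed_out$gene_a, ed_out$gene_b, method = "radix"), ],
            file.path(dir, "network_edges.tsv"))
  an <- bundle$network$annotations
  an_out <- data.frame(gene = an$gene, term = an$term,
                       is_complex = tolower(as.character(an$is_complex)),
                       stringsAsFactors = FALSE)
  write_tsv(an_out[order(an_out$gene, an_out$term, method = "radix"), ],
            file.path(dir, "network_annotations.tsv"))

  og_out <- do.call(rbind, lapply(bundle$orthology, function(g)
    data.frame(group_id = g$group_id,
               members = paste(sort(g$members), collapse = "|"),
               stringsAsFactors = FALSE)))
  if (is.null(og_out))
    og_out <- data.frame(group_id = character(), members = character())
  write_tsv(og_out[order(og_out$group_id, method = "radix"), ],
            file.path(dir, "orthology.tsv"))

  org <- bundle$organisms
  write_tsv(org[order(org$code, method = "radix"), c("code", "name")],
            file.path(dir, "organisms.tsv"))

  man <- bundle$manifest
  man <- man[!names(man) %in% "tables"]
  man["tables"] <- paste(snapshot_tables, collapse = "|")
  man_out <- data.frame(key = names(man), value = unname(man),
                        stringsAsFactors = FALSE)
  man_out <- man_out[order(man_out$key, method = "radix"), ]
  write_tsv(man_out, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Read a snapshot bundle from a directory
#'
#' Reads every table listed in the manifest and validates referential
#' integrity; dangling references raise an error carrying the full report.
#' An empty network table loads as an empty network.
#'
#' @param dir snapshot directory written by [write_snapshot()].
#' @return A `"gpr_snapshot"` object.
#' @export
read_snapshot <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path))
    stop("missing manifest.tsv in '", dir, "'", call. = FALSE)
  man_df <- read_tsv(man_path)
  manifest <- stats::setNames(man_df$value, man_df$key)
  for (tab in snapshot_tables) {
    if (!file.exists(file.path(dir, paste0(tab, ".tsv"))))
      stop("snapshot table missing: ", tab, ".tsv", call. = FALSE)
  }
  cmp_raw <- read_tsv(file.path(dir, "compounds.tsv"))
  compounds <- data.frame(compound_id = cmp_raw$compound_id,
                          source = cmp_raw$source, inchi = cmp_raw$inchi,
                          stringsAsFactors = FALSE)
  compounds$names <- split_list(cmp_raw$names)
  compounds$xrefs <- split_pairs(cmp_raw$xrefs)
  compounds$ontology_parents <- split_list(cmp_raw$ontology_parents)

  rx_raw <- read_tsv(file.path(dir, "reactions.tsv"))
  reactions <- data.frame(reaction_id = rx_raw$reaction_id,
                          stringsAsFactors = FALSE)
  reactions$sources <- split_list(rx_raw$sources)
  reactions$substrates <- split_side(rx_raw$substrates)
  reactions$products <- split_side(rx_raw$products)
  reactions$ec_numbers <- split_list(rx_raw$ec_numbers)
  reactions$genes <- split_list(rx_raw$genes)
  reactions$xrefs <- split_list(rx_raw$xrefs)

  tr_raw <- read_tsv(file.path(dir, "transporters.tsv"))
  transporters <- data.frame(tc_code = tr_raw$tc_code,
                             stringsAsFactors = FALSE)
  transporters$substrates <- split_list(tr_raw$substrates)
  transporters$genes <- split_list(tr_raw$genes)

  pr_raw <- read_tsv(file.path(dir, "proteins.tsv"))
  proteins <- lapply(seq_len(nrow(pr_raw)), function(i) {
    loc_parts <- split_list(pr_raw$localizations[i])[[1]]
    loc <- if (length(loc_parts)) {
      kv <- strsplit(loc_parts, ":", fixed = TRUE)
      data.frame(term = vapply(kv, `[[`, character(1), 1L),
                 evidence = vapply(kv, `[[`, character(1), 2L),
                 stringsAsFactors = FALSE)
    } else data.frame(term = character(), evidence = character())
    protein_record(gene = pr_raw$gene[i],
                   synonyms = split_list(pr_raw$synonyms[i])[[1]],
                   interaction_text = pr_raw$interaction_text[i],
                   function_text = pr_raw$function_text[i],
                   complex_xrefs = split_list(pr_raw$complex_xrefs[i])[[1]],
                   localizations = loc)
  })
  names(proteins) <- pr_raw$gene

  cx_raw <- read_tsv(file.path(dir, "complexes.tsv"))
  complexes <- lapply(seq_len(nrow(cx_raw)), function(i)
    complex_record(cx_raw$complex_id[i],
                   split_list(cx_raw$components[i])[[1]]))

  ed_raw <- read_tsv(file.path(dir, "network_edges.tsv"))
  an_raw <- read_tsv(file.path(dir, "network_annotations.tsv"))
  network <- interaction_network(
    edges = data.frame(gene_a = ed_raw$gene_a, gene_b = ed_raw$gene_b,
                       stringsAsFactors = FALSE),
    annotations = data.frame(gene = an_raw$gene, term = an_raw$term,
                             is_complex = an_raw$is_complex == "true",
                             stringsAsFactors = FALSE))

  og_raw <- read_tsv(file.path(dir, "orthology.tsv"))
  orthology <- lapply(seq_len(nrow(og_raw)), function(i)
    orthology_group(og_raw$group_id[i], split_list(og_raw$members[i])[[1]]))

  organisms <- read_tsv(file.path(dir, "organisms.tsv"))

  bundle <- snapshot_bundle(compounds, reactions, transporters, proteins,
                            complexes, network, orthology, organisms,
                            manifest)
  probs <- snapshot_integrity(bundle)
  if (length(probs))
    stop("snapshot integrity violation:\n  ",
         paste(probs, collapse = "\n  "), call. = FALSE)
  bundle
}
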