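#' @title Rules tables
#'
#' @description
#' The benchmark interchange format: one row per reaction with columns
#' `Rxn` (reaction id), `rule_original` (the curated ground-truth rule),
#' `rule_GPRuler` (the reconstructed rule) and `Evaluation` (the label
#' assigned after comparison: `Perfect match`, `Corrected by GPRuler`,
#' `Not automatically reconstructed by GPRuler`, or empty).
#'
#' @name rules-table
NULL

rules_table_labels <- c("Perfect match", "Corrected by GPRuler",
                        "Not automatically reconstructed by GPRuler", "")

#' Construct a rules table
#'
#' @param Rxn reaction ids (unique).
#' @param rule_original,rule_GPRuler rule strings (may be empty).
#' @param Evaluation evaluation labels (defaults to empty).
#' @return Data frame of class `"gpr_rules_table"`.
#' @export
rules_table <- function(Rxn, rule_original, rule_GPRuler,
                        Evaluation = rep("", length(Rxn))) {
  if (anyDuplicated(Rxn)) stop("Rxn ids must be unique", call. = FALSE)
  out <- data.frame(Rxn = as.character(Rxn),
                    rule_original = as.character(rule_original),
                    rule_GPRuler = as.character(rule_GPRuler),
                    Evaluation = as.character(Evaluation),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(out$Evaluation), rules_table_labels)
  if (length(unknown))
    warning("unknown Evaluation label(s) retained verbatim: ",
            paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  class(out) <- c("gpr_rules_table", "data.frame")
  out
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))) >
      lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))))
    ";" else ","
}

#' Read a rules table
#'
#' Delimiter-tolerant (comma or semicolon, autodetected from the header).
#' Requires the columns `Rxn`, `rule_original` and `rule_GPRuler`; a
#' missing `Evaluation` column loads as empty labels. Unknown evaluation
#' labels are retained verbatim with a warning. Empty rule strings parse
#' as empty rules downstream.
#'
#' @param path CSV file in the four-column schema.
#' @return A `"gpr_rules_table"` data frame.
#' @export
read_rules_table <- function(path) {
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  for (col in c("Rxn", "rule_original", "rule_GPRuler")) {
    if (!col %in% names(raw))
      stop("rules table is missing required column '", col, "'",
           call. = FALSE)
  }
  if (!"Evaluation" %in% names(raw)) raw$Evaluation <- ""
  raw$Evaluation[is.na(raw$Evaluation)] <- ""
  raw$rule_original[is.na(raw$rule_original)] <- ""
  raw$rule_GPRuler[is.na(raw$rule_GPRuler)] <- ""
  rules_table(raw$Rxn, raw$rule_original, raw$rule_GPRuler, raw$Evaluation)
}

#' Write a rules table
#'
#' Emits the exact four-column comma-separated schema.
#'
#' @param table a `"gpr_rules_table"` (or compatible data frame).
#' @param path target file.
#' @return `path`, invisibly.
#' @export
write_rules_table <- function(table, path) {
  out <- as.data.frame(table)[, c("Rxn", "rule_original", "rule_GPRuler",
                                  "Evaluation")]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
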