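# Compound-to-target association handling.
#
# An association table emulates reverse-pharmacophore output: one row per
# (compound, target) prediction with columns
#   compound     compound label
#   target       target label (gene symbol, e.g. TDP1, MAPT)
#   probability  prediction probability in [0, 1]
#   organism     source organism of the target (e.g. "Homo sapiens")
#
# A target annotation table emulates a protein classification export:
#   target         gene symbol, unique
#   protein_class  single class label (e.g. oxidoreductase, hydrolase)
#   processes      semicolon-separated biological-process labels (multi-label)

#' Read a compound-target association table
#'
#' @param path CSV/TSV file with header columns `compound`, `target`,
#'   `probability`, `organism`.
#' @return Validated data frame of associations.
#' @export
read_association_table <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) stop_input("association table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_associations(df)
}

validate_associations <- function(assocs) {
  if (!is.data.frame(assocs)) stop_input("'assocs' must be a data frame")
  require_columns(assocs, c("compound", "target", "probability"),
                  "association table")
  if (nrow(assocs) == 0L) return(assocs)
  assocs$compound <- norm_label(as.character(assocs$compound))
  assocs$target <- norm_label(as.character(assocs$target))
  empty <- !nzchar(assocs$compound) | !nzchar(assocs$target)
  if (any(empty)) {
    stop_input("empty compound/target label in association row(s): ",
               paste(which(empty), collapse = ", "))
  }
  p <- assocs$probability
  bad <- !is.finite(p) | p < 0 | p > 1
  if (any(bad)) {
    stop_input("probability outside [0, 1] in association row(s): ",
               paste(which(bad), collapse = ", "))
  }
  assocs
}

#' Filter associations by prediction probability
#'
#' Keeps associations with probability at or above the threshold (ties at
#' the threshold are retained). The upstream study kept only targets "with
#' higher estimated probability" without stating its cutoff, so the
#' threshold here is an explicit argument with a documented default of 0.5.
#'
#' @param assocs Association data frame (see [read_association_table()]).
#' @param min_probability Threshold in `[0, 1]`.
#' @return The qualifying rows, input order preserved.
#' @export
filter_by_probability <- function(assocs, min_probability = 0.5) {
  assocs <- validate_associations(assocs)
  check_number(min_probability, "min_probability", min = 0, max = 1)
  if (nrow(assocs) == 0L) return(assocs)
  assocs[assocs$probability >= min_probability, , drop = FALSE]
}

#' Restrict associations to one organism
#'
#' Keeps associations whose organism matches `organism` exactly after
#' case-folding. Compounds left without any association are reported (this
#' is how ascorbic acid left the study's network: druglike, but no
#' human-origin targets).
#'
#' @inheritParams filter_by_probability
#' @param organism Organism label, e.g. `"Homo sapiens"`.
#' @param drop_compounds_without_targets When `TRUE` (default), compounds
#'   with zero remaining associations are listed in the `dropped_compounds`
#'   attribute of the result and mentioned in a message.
#' @return Filtered association data frame; attribute `dropped_compounds`
#'   holds the labels of compounds that lost all their associations.
#' @export
restrict_organism <- function(assocs, organism,
                              drop_compounds_without_targets = TRUE) {
  assocs <- validate_associations(assocs)
  check_string(organism, "organism")
  check_flag(drop_compounds_without_targets, "drop_compounds_without_targets")
  require_columns(assocs, "organism", "association table")
  keep <- fold_label(as.character(assocs$organism)) == fold_label(organism)
  out <- assocs[keep, , drop = FALSE]
  dropped <- character(0)
  if (drop_compounds_without_targets && nrow(assocs)) {
    dropped <- setdiff(unique(assocs$compound), unique(out$compound))
    if (length(dropped)) {
      message("compound(s) without ", organism, " targets dropped: ",
              paste(dropped, collapse = ", "))
    }
  }
  attr(out, "dropped_compounds") <- dropped
  out
}

#' Read a target annotation table
#'
#' @param path CSV/TSV file with header columns `target`, `protein_class`,
#'   `processes` (semicolon-separated biological-process labels).
#' @return Data frame with `processes` as a list column.
#' @export
read_target_annotations <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) stop_input("annotation table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  require_columns(df, c("target", "protein_class", "processes"),
                  "annotation table")
  df$processes <- lapply(strsplit(as.character(df$processes), ";",
                                  fixed = TRUE),
                         function(p) norm_label(p[nzchar(trimws(p))]))
  validate_annotations(df)
}

validate_annotations <- function(annotations) {
  if (!is.data.frame(annotations)) {
    stop_input("'annotations' must be a data frame")
  }
  require_columns(annotations, c("target", "protein_class"),
                  "annotation table")
  if (nrow(annotations) == 0L) stop_input("annotation table is empty")
  annotations$target <- norm_label(as.character(annotations$target))
  dup <- duplicated(annotations$target)
  if (any(dup)) {
    stop_input("duplicate target(s) in annotation table: ",
               paste(unique(annotations$target[dup]), collapse = ", "))
  }
  annotations
}

#' Tabulate target protein classes
#'
#' One row per distinct protein class with its count and percentage of all
#' annotated targets. Single-label, so percentages sum to 100 within
#' rounding (half-even to `digits` decimals, matching the one-decimal style
#' of classification pie charts).
#'
#' @param annotations Annotation data frame (see
#'   [read_target_annotations()]).
#' @param digits Decimal places for the percentage; default 1.
#' @return Data frame with columns `label`, `count`, `percent`, sorted by
#'   descending count, ties by label.
#' @export
tabulate_target_classes <- function(annotations, digits = 1) {
  annotations <- validate_annotations(annotations)
  counts <- table(norm_label(as.character(annotations$protein_class)))
  build_tabulation(counts, nrow(annotations), digits)
}

#' Tabulate target biological processes
#'
#' Like [tabulate_target_classes()] but over the multi-label `processes`
#' column: a target can carry several process labels, so the percentages
#' (share of targets annotated with each process) may sum to more than 100.
#'
#' @inheritParams tabulate_target_classes
#' @export
tabulate_target_processes <- function(annotations, digits = 1) {
  annotations <- validate_annotations(annotations)
  require_columns(annotations, "processes", "annotation table")
  labels <- unlist(lapply(annotations$processes, unique))
  if (!length(labels)) stop_input("no process labels in annotation table")
  build_tabulation(table(labels), nrow(annotations), digits)
}

build_tabulation <- function(counts, n_total, digits) {
  check_count(digits, "digits")
  out <- data.frame(label = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$percent <- round(100 * out$count / n_total, digits)
  out <- out[order(-out$count, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct targets in an association table
#'
#' @inheritParams filter_by_probability
#' @return Character vector of unique target labels, order of appearance.
#' @export
unique_targets <- function(assocs) {
  assocs <- validate_associations(assocs)
  unique(assocs$target)
}
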