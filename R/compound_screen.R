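# Lipinski rule-of-five druglikeness screen.
#
# A compound table is an ordinary data frame with one row per phytochemical
# and columns:
#   name        compound label (nonempty, unique after trimming/case-folding)
#   source_id   opaque external identifier (optional)
#   logp        octanol-water partition coefficient (unitless)
#   mol_weight  molecular weight in Daltons, > 0
#   hbd         hydrogen-bond donor count, integer >= 0
#   hba         hydrogen-bond acceptor count, integer >= 0
#   druglike    optional curated verdict ("Yes"/"No" or logical), carried for
#               provenance and never consulted by the screen

# canonical rule-of-five limits; a descriptor beyond its limit is a violation
.ro5_limits <- c(MW = 500, LOGP = 5, HBD = 5, HBA = 10)

#' Read a compound descriptor table
#'
#' Reads a delimited table (comma or tab, sniffed from the header line) with
#' columns `name`, `logp`, `mol_weight`, `hbd`, `hba` and optionally
#' `source_id` and `druglike`, and validates it (see
#' [count_ro5_violations()] for the descriptor contract).
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @return A validated data frame of compound records.
#' @examples
#' compounds <- read_compound_table(netpharm_example("albizia_compounds.csv"))
#' nrow(compounds)
#' @export
read_compound_table <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) stop_input("compound table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  validate_compound_table(df)
}

# validate the CompoundRecord contract; returns the table with normalized
# (trimmed) names, original casing preserved
validate_compound_table <- function(compounds) {
  if (!is.data.frame(compounds)) {
    stop_input("'compounds' must be a data frame")
  }
  require_columns(compounds, c("name", "logp", "mol_weight", "hbd", "hba"),
                  "compound table")
  if (nrow(compounds) == 0L) return(compounds)
  compounds$name <- norm_label(as.character(compounds$name))
  if (any(!nzchar(compounds$name))) {
    stop_input("compound table has empty name(s) in row(s): ",
               paste(which(!nzchar(compounds$name)), collapse = ", "))
  }
  dup <- duplicated(fold_label(compounds$name))
  if (any(dup)) {
    stop_input("duplicate compound name(s) after normalization: ",
               paste(unique(compounds$name[dup]), collapse = ", "))
  }
  for (col in c("logp", "mol_weight", "hbd", "hba")) {
    v <- compounds[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop_input("non-finite or missing '", col, "' in compound table")
    }
  }
  if (any(compounds$mol_weight <= 0)) {
    stop_input("'mol_weight' must be > 0 for: ",
               paste(compounds$name[compounds$mol_weight <= 0], collapse = ", "))
  }
  for (col in c("hbd", "hba")) {
    v <- compounds[[col]]
    if (any(v < 0) || any(v != as.integer(v))) {
      stop_input("'", col, "' must be a non-negative integer count")
    }
  }
  compounds
}

# logical matrix of per-criterion violations, columns MW/LOGP/HBD/HBA;
# strict inequalities: a descriptor exactly at its limit does not violate
ro5_violation_matrix <- function(compounds) {
  cbind(MW   = compounds$mol_weight > .ro5_limits[["MW"]],
        LOGP = compounds$logp       > .ro5_limits[["LOGP"]],
        HBD  = compounds$hbd        > .ro5_limits[["HBD"]],
        HBA  = compounds$hba        > .ro5_limits[["HBA"]])
}

#' Count rule-of-five violations
#'
#' Counts, for each compound, how many of the four Lipinski criteria are
#' violated: molecular weight > 500 Da, logP > 5, more than 5 hydrogen-bond
#' donors, more than 10 hydrogen-bond acceptors. Comparisons are strict, so a
#' descriptor exactly at its limit is not a violation.
#'
#' @param compounds Data frame of compound records (see
#'   [read_compound_table()]); a single record is a one-row data frame.
#' @return Integer vector of violation counts in `[0, 4]`, named by compound.
#' @examples
#' quebrachitol <- data.frame(name = "Quebrachitol", logp = -2.26,
#'                            mol_weight = 194.18, hbd = 5, hba = 6)
#' count_ro5_violations(quebrachitol)  # 0
#' @export
count_ro5_violations <- function(compounds) {
  compounds <- validate_compound_table(compounds)
  if (nrow(compounds) == 0L) return(setNames(integer(0), character(0)))
  v <- as.integer(rowSums(ro5_violation_matrix(compounds)))
  setNames(v, compounds$name)
}

#' Druglikeness verdict under the rule of five
#'
#' A compound is called druglike when it has at most `max_violations`
#' rule-of-five violations (the study criterion is "no more than 1").
#'
#' @inheritParams count_ro5_violations
#' @param max_violations Maximum tolerated violation count, integer in
#'   `[0, 4]`; default 1.
#' @return Named logical vector.
#' @export
is_druglike <- function(compounds, max_violations = 1) {
  max_violations <- check_count(max_violations, "max_violations")
  check_number(max_violations, "max_violations", min = 0, max = 4)
  count_ro5_violations(compounds) <= max_violations
}

#' Screen a compound table for druglikeness
#'
#' Applies the rule-of-five screen to every record and reports, per compound,
#' the violation count, the violated criteria and the computed verdict. When
#' the input carries a curated `druglike` column it is never consulted by the
#' screen, but rows whose computed verdict disagrees with it are surfaced in
#' a discrepancy list (the packaged table has exactly one such row,
#' myricitrin, whose printed verdict is inconsistent with its own printed
#' descriptors).
#'
#' @inheritParams is_druglike
#' @return A list of class `ro5_screen` with elements
#'   \describe{
#'     \item{passing}{the druglike subset of the input, original order}
#'     \item{report}{data frame: name, violations, violated_criteria
#'       (comma-separated subset of MW/LOGP/HBD/HBA), druglike, and
#'       curated_verdict when supplied}
#'     \item{discrepancies}{character vector of compound names whose computed
#'       verdict disagrees with the curated one}
#'   }
#' @examples
#' compounds <- read_compound_table(netpharm_example("albizia_compounds.csv"))
#' scr <- screen_compounds(compounds)
#' nrow(scr$passing)   # 25
#' scr$discrepancies   # "Myricitrin"
#' @export
screen_compounds <- function(compounds, max_violations = 1) {
  compounds <- validate_compound_table(compounds)
  max_violations <- check_count(max_violations, "max_violations")
  check_number(max_violations, "max_violations", min = 0, max = 4)
  if (nrow(compounds) == 0L) {
    report <- data.frame(name = character(0), violations = integer(0),
                         violated_criteria = character(0),
                         druglike = logical(0), stringsAsFactors = FALSE)
    out <- list(passing = compounds, report = report,
                discrepancies = character(0))
    class(out) <- "ro5_screen"
    return(out)
  }
  vm <- ro5_violation_matrix(compounds)
  violations <- as.integer(rowSums(vm))
  druglike <- violations <= max_violations
  criteria <- apply(vm, 1L, function(r) paste(colnames(vm)[r], collapse = ","))
  report <- data.frame(name = compounds$name, violations = violations,
                       violated_criteria = criteria, druglike = druglike,
                       stringsAsFactors = FALSE)
  discrepancies <- character(0)
  if ("druglike" %in% names(compounds)) {
    curated <- parse_verdict(compounds$druglike)
    report$curated_verdict <- curated
    disagree <- !is.na(curated) & curated != druglike
    discrepancies <- compounds$name[disagree]
    if (length(discrepancies)) {
      message("rule-of-five verdict disagrees with curated verdict for: ",
              paste(discrepancies, collapse = ", "))
    }
  }
  out <- list(passing = compounds[druglike, , drop = FALSE],
              report = report, discrepancies = discrepancies)
  class(out) <- "ro5_screen"
  out
}

parse_verdict <- function(x) {
  if (is.logical(x)) return(x)
  v <- fold_label(as.character(x))
  out <- rep(NA, length(v))
  out[v %in% c("yes", "true", "1")] <- TRUE
  out[v %in% c("no", "false", "0")] <- FALSE
  out
}

#' @export
print.ro5_screen <- function(x, ...) {
  cat("Rule-of-five screen:", nrow(x$report), "compounds,",
      nrow(x$passing), "druglike\n")
  if (length(x$discrepancies)) {
    cat("Disagreement with curated verdict:",
        paste(x$discrepancies, collapse = ", "), "\n")
  }
  invisible(x)
}
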