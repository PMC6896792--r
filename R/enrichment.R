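# Pathway over-representation analysis (ORA) and enrichment-table handling.
#
# An enrichment table has one row per pathway:
#   pathway_id   KEGG-style identifier, kept as character (e.g. "00910")
#   description  pathway name
#   fdr          false discovery rate in [0, 1]
#   members      member target list (list column of gene symbols)
#
# The packaged fixture kegg_enrichment.tsv transcribes the 48 pathways
# enriched from the 132-target interactome, including their printed FDR
# values, so precomputed FDR columns flow through without recomputation.

#' Upper-tail hypergeometric probability
#'
#' P(X >= overlap) for X hypergeometric: draw `query_size` genes without
#' replacement from a background of `background_size` genes of which
#' `pathway_size` belong to the pathway. This is the standard one-sided
#' over-representation p-value; computed via [stats::phyper()], which works
#' on log scale and is numerically stable.
#'
#' @param overlap Observed overlap `x`, integer `>= 0` (vectorized).
#' @param query_size Query set size `n`.
#' @param pathway_size Pathway annotation size `K`.
#' @param background_size Background universe size `M`.
#' @return p-value(s) in `(0, 1]`; `overlap = 0` gives exactly 1.
#' @examples
#' hypergeom_tail_p(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
hypergeom_tail_p <- function(overlap, query_size, pathway_size,
                             background_size) {
  n <- max(length(overlap), length(query_size), length(pathway_size),
           length(background_size))
  overlap <- rep_len(overlap, n)
  query_size <- rep_len(query_size, n)
  pathway_size <- rep_len(pathway_size, n)
  background_size <- rep_len(background_size, n)
  ok <- is.finite(overlap) & is.finite(query_size) & is.finite(pathway_size) &
    is.finite(background_size) & overlap >= 0 &
    overlap <= pmin(query_size, pathway_size) &
    pathway_size <= background_size & query_size <= background_size
  if (any(!ok)) {
    stop_input("inconsistent hypergeometric parameters at position(s): ",
               paste(which(!ok), collapse = ", "),
               " (need 0 <= x <= min(n, K), K <= M, n <= M)")
  }
  phyper(overlap - 1, pathway_size, background_size - pathway_size,
         query_size, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, clipped at 1 and returned in
#' the original order. Delegates to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length and order; elementwise `q >= p`.
#' @export
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values)) stop_input("'p_values' must be numeric")
  if (length(p_values) == 0L) return(numeric(0))
  bad <- !is.finite(p_values) | p_values <= 0 | p_values > 1
  if (any(bad)) {
    stop_input("p-value(s) outside (0, 1] at position(s): ",
               paste(which(bad), collapse = ", "))
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each pathway for over-representation of a query set against an
#' explicit background universe size, then adjusts across pathways with
#' Benjamini-Hochberg. The background size is a required argument and is
#' never inferred from the annotation.
#'
#' @param query Character vector of query gene/target labels (deduplicated).
#' @param pathways Named list of pathway member vectors, or an enrichment
#'   table as returned by [read_enrichment_table()].
#' @param background_size Size of the background universe; must be at least
#'   as large as the query and every pathway.
#' @return Data frame with one row per pathway: `pathway_id`, `overlap`,
#'   `pathway_size`, `query_size`, `background_size`, `p_value`, `q_value`,
#'   in the input pathway order.
#' @export
run_ora <- function(query, pathways, background_size) {
  if (!is.character(query) || !length(query)) {
    stop_input("'query' must be a nonempty character vector")
  }
  query <- unique(norm_label(query))
  if (is.data.frame(pathways)) {
    members <- setNames(pathways$members, pathways$pathway_id)
  } else {
    members <- pathways
  }
  if (!is.list(members) || is.null(names(members)) ||
      any(!nzchar(names(members)))) {
    stop_input("'pathways' must be a named list of member vectors")
  }
  background_size <- check_count(background_size, "background_size", min = 1L)
  sizes <- lengths(members)
  if (any(sizes == 0L)) stop_input("pathway(s) with no members")
  if (length(query) > background_size || any(sizes > background_size)) {
    stop_input("'background_size' smaller than query or a pathway")
  }
  overlap <- vapply(members, function(m) length(intersect(query, m)),
                    integer(1))
  p <- hypergeom_tail_p(overlap, length(query), sizes, background_size)
  data.frame(pathway_id = names(members), overlap = as.integer(overlap),
             pathway_size = as.integer(sizes),
             query_size = length(query),
             background_size = background_size,
             p_value = p, q_value = adjust_bh(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse an enrichment table
#'
#' Reads a delimited enrichment export (tab-separated by default; the member
#' column itself is comma-separated) with columns `pathway_id`,
#' `description`, `fdr`, `members`. Member lists are split on commas,
#' trimmed, and deduplicated with a warning. Scientific-notation FDR values
#' are parsed as usual.
#'
#' @param path Path to the file; header row required.
#' @return Data frame with `members` as a list column; zero rows for a
#'   header-only file.
#' @examples
#' enr <- read_enrichment_table(netpharm_example("kegg_enrichment.tsv"))
#' nrow(enr)  # 48
#' @export
read_enrichment_table <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) stop_input("enrichment table not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(pathway_id = "character"))
  require_columns(df, c("pathway_id", "description", "fdr", "members"),
                  "enrichment table")
  if (nrow(df) == 0L) {
    df$members <- list()
    return(df)
  }
  fdr <- suppressWarnings(as.numeric(df$fdr))
  bad <- !is.finite(fdr) | fdr < 0 | fdr > 1
  if (any(bad)) {
    stop_input("malformed FDR in enrichment table row(s): ",
               paste(which(bad), collapse = ", "))
  }
  df$fdr <- fdr
  members <- strsplit(as.character(df$members), ",", fixed = TRUE)
  members <- lapply(members, function(m) norm_label(m[nzchar(trimws(m))]))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    stop_input("empty member list in enrichment table row(s): ",
               paste(which(empty), collapse = ", "))
  }
  deduped <- lapply(members, unique)
  if (any(lengths(deduped) != lengths(members))) {
    warning("duplicate members removed in enrichment table row(s): ",
            paste(which(lengths(deduped) != lengths(members)),
                  collapse = ", "))
  }
  df$members <- deduped
  df$pathway_id <- norm_label(df$pathway_id)
  df$description <- norm_label(df$description)
  df
}

#' Filter enrichment records by FDR
#'
#' Retains records with FDR strictly below the threshold, preserving input
#' order. The study's stated retention rule is "false discovery rate < 0.5";
#' whether that is a typographical variant of 0.05 cannot be decided (all 48
#' packaged rows pass either way), so the threshold is configurable and
#' defaults to the stated 0.5.
#'
#' @param records Enrichment data frame with an `fdr` column.
#' @param threshold Retention threshold in `(0, 1]`; default 0.5; strict `<`.
#' @return The qualifying rows, input order preserved.
#' @export
filter_by_fdr <- function(records, threshold = 0.5) {
  if (!is.data.frame(records)) stop_input("'records' must be a data frame")
  require_columns(records, "fdr", "enrichment table")
  check_number(threshold, "threshold", min = 0, max = 1)
  if (threshold <= 0) stop_input("'threshold' must be in (0, 1]")
  records[records$fdr < threshold, , drop = FALSE]
}

#' Member count of a pathway
#'
#' Looks a pathway up by its ID (exact) or description (case-insensitive)
#' and returns the length of its member list.
#'
#' @param records Enrichment data frame (see [read_enrichment_table()]).
#' @param query Pathway ID or description.
#' @return Integer member count.
#' @examples
#' enr <- read_enrichment_table(netpharm_example("kegg_enrichment.tsv"))
#' member_count(enr, "Metabolic pathways")  # 25
#' @export
member_count <- function(records, query) {
  if (!is.data.frame(records)) stop_input("'records' must be a data frame")
  require_columns(records, c("pathway_id", "description", "members"),
                  "enrichment table")
  check_string(query, "query")
  hit <- which(records$pathway_id == norm_label(query))
  if (!length(hit)) {
    hit <- which(fold_label(records$description) == fold_label(query))
  }
  if (!length(hit)) stop_input("no pathway matching '", query, "'")
  length(records$members[[hit[1L]]])
}
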