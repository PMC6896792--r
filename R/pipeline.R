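# End-to-end orchestration: screen -> map -> enrich -> network -> report.
#
# Stages communicate via files under the configured output directory, so a
# run is restartable and every intermediate is inspectable. All thresholds
# live in the config with the study's values as defaults; nothing is
# hard-coded inside the stages.

#' Build a pipeline configuration
#'
#' Collects input paths and thresholds for [run_pipeline()]. Only the
#' compound table is mandatory; stages whose input is `NULL` are skipped.
#' All paths are checked up front.
#'
#' @param compound_table Path to the compound descriptor table.
#' @param association_table Optional path to the compound-target
#'   association table.
#' @param annotation_table Optional path to the target annotation table.
#' @param enrichment_table Optional path to the pathway enrichment table.
#' @param disease_map Optional path to a `pathway_id`/`disease_system`
#'   link table (tab- or comma-separated).
#' @param out_dir Output directory; created if absent.
#' @param max_violations Rule-of-five tolerance; default 1.
#' @param min_probability Association probability threshold; default 0.5.
#' @param organism Organism restriction; default `"Homo sapiens"`.
#' @param fdr_threshold Enrichment retention threshold (strict `<`);
#'   default 0.5.
#' @param hub_min_degree Minimum hub degree; default 11 ("higher than 10").
#' @param seed RNG seed recorded in the summary (the pipeline stages are
#'   deterministic; the seed matters when generators produce the inputs).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(compound_table, association_table = NULL,
                            annotation_table = NULL,
                            enrichment_table = NULL, disease_map = NULL,
                            out_dir, max_violations = 1,
                            min_probability = 0.5,
                            organism = "Homo sapiens", fdr_threshold = 0.5,
                            hub_min_degree = 11, seed = 1) {
  check_string(compound_table, "compound_table")
  check_string(out_dir, "out_dir")
  paths <- list(compound_table = compound_table,
                association_table = association_table,
                annotation_table = annotation_table,
                enrichment_table = enrichment_table,
                disease_map = disease_map)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop_input("input '", nm, "' does not exist: ", p)
    }
  }
  cfg <- c(paths, list(
    out_dir = out_dir,
    max_violations = check_count(max_violations, "max_violations"),
    min_probability = check_number(min_probability, "min_probability",
                                   min = 0, max = 1),
    organism = check_string(organism, "organism"),
    fdr_threshold = check_number(fdr_threshold, "fdr_threshold",
                                 min = 0, max = 1),
    hub_min_degree = check_count(hub_min_degree, "hub_min_degree"),
    seed = check_count(seed, "seed")))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a plain YAML mapping whose keys are the arguments of
#' [pipeline_config()]; relative input paths are resolved against the
#' directory containing the YAML file.
#'
#' @param path Path to the YAML configuration.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) stop_input("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_input("config must be a YAML mapping")
  base <- dirname(normalizePath(path))
  for (nm in c("compound_table", "association_table", "annotation_table",
               "enrichment_table", "disease_map", "out_dir")) {
    if (!is.null(raw[[nm]]) && !grepl("^(/|[A-Za-z]:)", raw[[nm]])) {
      raw[[nm]] <- file.path(base, raw[[nm]])
    }
  }
  do.call(pipeline_config, raw)
}

read_disease_map <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = c(pathway_id = "character"))
  require_columns(df, c("pathway_id", "disease_system"), "disease map")
  df
}

#' Run the systems-pharmacology pipeline
#'
#' Executes, in order: the rule-of-five screen; probability and organism
#' filtering of associations restricted to the druglike compounds; FDR
#' filtering of the enrichment table; compound-target network construction
#' and topology; pathway-disease network construction and topology. Each
#' stage writes its table under `out_dir`, and a machine-readable summary
#' with the stage counts and network metrics is written to
#' `summary.json`. A rerun with the same config and inputs is
#' byte-identical.
#'
#' @param config A `pipeline_config` object (or a YAML path, which is read
#'   with [read_pipeline_config()]).
#' @return The run summary, invisibly a list of class `run_summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop_input("'config' must be a pipeline_config")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  summary <- list(seed = config$seed)

  ## stage 1: druglikeness screen
  compounds <- read_compound_table(config$compound_table)
  scr <- screen_compounds(compounds, config$max_violations)
  summary$n_compounds_in <- nrow(compounds)
  summary$n_druglike <- nrow(scr$passing)
  summary$screen_discrepancies <- as.list(scr$discrepancies)
  if (nrow(compounds) == 0L) {
    summary$stages_run <- "screen"
    write_report(summary, out("summary.json"))
    return(invisible(structure(summary, class = "run_summary")))
  }
  write.csv(scr$passing, out("compounds_druglike.csv"), row.names = FALSE)
  write.table(scr$report, out("screen_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages <- "screen"

  ## stage 2: target mapping
  assocs <- NULL
  if (!is.null(config$association_table)) {
    assocs <- read_association_table(config$association_table)
    summary$n_associations_in <- nrow(assocs)
    assocs <- assocs[assocs$compound %in% scr$passing$name, , drop = FALSE]
    assocs <- filter_by_probability(assocs, config$min_probability)
    if ("organism" %in% names(assocs)) {
      assocs <- restrict_organism(assocs, config$organism)
      summary$dropped_compounds <-
        as.list(attr(assocs, "dropped_compounds"))
    }
    summary$n_associations_retained <- nrow(assocs)
    summary$n_compounds_with_targets <- length(unique(assocs$compound))
    summary$n_unique_targets <- length(unique_targets(assocs))
    write.csv(assocs, out("associations_filtered.csv"), row.names = FALSE)
    stages <- c(stages, "map")
  }

  ## stage 3: enrichment filtering
  retained <- NULL
  if (!is.null(config$enrichment_table)) {
    enr <- read_enrichment_table(config$enrichment_table)
    retained <- filter_by_fdr(enr, config$fdr_threshold)
    summary$n_pathways_in <- nrow(enr)
    summary$n_pathways_retained <- nrow(retained)
    flat <- retained
    flat$members <- vapply(flat$members, paste, character(1),
                           collapse = ",")
    write.table(flat, out("pathways_retained.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stages <- c(stages, "enrich")
  }

  ## stage 4: compound-target network
  if (!is.null(assocs) && nrow(assocs)) {
    g <- build_compound_target_network(assocs)
    rep_ct <- topology_report(g)
    hubs <- hub_nodes(g, "all", config$hub_min_degree)
    summary$ct_nodes <- rep_ct$n_nodes
    summary$ct_edges <- rep_ct$n_edges
    summary$ct_heterogeneity <- rep_ct$heterogeneity
    summary$ct_centralization <- rep_ct$centralization
    summary$n_ct_hubs <- nrow(hubs)
    summary$n_ct_compound_hubs <-
      nrow(hub_nodes(g, "a", config$hub_min_degree))
    export_network(g, out("ct_network_edges.tsv"), "edgelist")
    write_node_attributes(rep_ct, out("ct_node_attributes.tsv"))
    write.table(hubs, out("ct_hubs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    stages <- c(stages, "ct_network")
  }

  ## stage 5: pathway-disease network
  if (!is.null(retained) && !is.null(config$disease_map)) {
    links <- read_disease_map(config$disease_map)
    gpd <- build_pathway_disease_network(retained, links)
    rep_pd <- topology_report(gpd)
    summary$pd_nodes <- rep_pd$n_nodes
    summary$pd_edges <- rep_pd$n_edges
    summary$pd_heterogeneity <- rep_pd$heterogeneity
    summary$pd_centralization <- rep_pd$centralization
    disease_rank <- hub_nodes(gpd, "b", min_degree = 1)
    export_network(gpd, out("pd_network_edges.tsv"), "edgelist")
    write_node_attributes(rep_pd, out("pd_node_attributes.tsv"))
    write.table(disease_rank, out("pd_disease_degrees.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stages <- c(stages, "pd_network")
  }

  summary$stages_run <- paste(stages, collapse = ",")
  write_report(summary, out("summary.json"))
  invisible(structure(summary, class = "run_summary"))
}

#' Write a run summary
#'
#' Serializes a pipeline summary as JSON (scalars unboxed, full numeric
#' precision). [read_report()] validates the file on re-read.
#'
#' @param summary A summary list as returned by [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path) {
  check_string(path, "path")
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and validate a run summary
#'
#' @param path Path to a `summary.json` written by [write_report()].
#' @return The summary list.
#' @export
read_report <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) stop_input("report not found: ", path)
  summary <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  required <- c("seed", "n_compounds_in", "n_druglike", "stages_run")
  missing <- setdiff(required, names(summary))
  if (length(missing)) {
    stop_input("report is missing key(s): ", paste(missing, collapse = ", "))
  }
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run (stages:", x$stages_run, ")\n")
  cat("  compounds:", x$n_compounds_in, "in,", x$n_druglike, "druglike\n")
  if (!is.null(x$ct_nodes)) {
    cat("  C-T network:", x$ct_nodes, "nodes,", x$ct_edges, "edges\n")
  }
  if (!is.null(x$pd_nodes)) {
    cat("  P-D network:", x$pd_nodes, "nodes,", x$pd_edges, "edges\n")
  }
  invisible(x)
}
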