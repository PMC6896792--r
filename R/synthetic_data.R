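# Seeded generators emulating every upstream web-service output, so the
# pipeline runs and is testable fully offline:
#   make_compound_table       - descriptor prediction (druglikeness input)
#   make_association_table    - reverse-pharmacophore target prediction
#   make_target_annotations   - protein classification export
#   make_enrichment_inputs    - background/pathway/query sets for ORA
#   make_disease_map          - pathway-to-disease-system indexing
#
# All generators restore the caller's RNG state and are byte-stable under a
# fixed seed.

#' Generate a compound descriptor table with planted violation counts
#'
#' Each generated compound realizes exactly its requested number of
#' rule-of-five violations: the violated criteria are sampled, violating
#' descriptors are drawn beyond the corresponding limit and the remaining
#' descriptors safely inside it. Construction is verified against the
#' screen's own thresholds before returning.
#'
#' @param violation_profile Integer vector in `[0, 4]`, one entry per
#'   compound to generate.
#' @param seed RNG seed.
#' @return Compound data frame as accepted by [screen_compounds()].
#' @examples
#' tbl <- make_compound_table(c(0, 1, 2, 3), seed = 7)
#' count_ro5_violations(tbl)  # 0 1 2 3
#' @export
make_compound_table <- function(violation_profile, seed = 1) {
  if (!is.numeric(violation_profile) || !length(violation_profile) ||
      anyNA(violation_profile) ||
      any(violation_profile < 0 | violation_profile > 4) ||
      any(violation_profile != as.integer(violation_profile))) {
    stop_input("'violation_profile' must be integers in [0, 4]")
  }
  seed <- check_count(seed, "seed")
  n <- length(violation_profile)
  out <- with_seed(seed, {
    out <- data.frame(
      name = sprintf("compound_%02d", seq_len(n)),
      source_id = sprintf("SYN-%04d", seq_len(n)),
      logp = round(runif(n, -2, 4.5), 2),
      mol_weight = round(runif(n, 150, 495), 2),
      hbd = sample(0:5, n, replace = TRUE),
      hba = sample(0:10, n, replace = TRUE),
      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      k <- violation_profile[i]
      if (k == 0) next
      for (crit in sample(c("MW", "LOGP", "HBD", "HBA"), k)) {
        switch(crit,
               MW = out$mol_weight[i] <- round(runif(1, 510, 900), 2),
               LOGP = out$logp[i] <- round(runif(1, 5.5, 9), 2),
               HBD = out$hbd[i] <- sample(6:12, 1),
               HBA = out$hba[i] <- sample(11:18, 1))
      }
    }
    out
  })
  stopifnot(identical(unname(count_ro5_violations(out)),
                      as.integer(violation_profile)))
  out
}

#' Generate a compound-target association table
#'
#' Emulates reverse-pharmacophore output as a bipartite incidence: exactly
#' `n_edges` distinct (compound, target) pairs in which every compound and
#' every target appears at least once, the targets named in `hub_spec`
#' attain exactly the requested degrees, and each association carries a
#' prediction probability drawn from the chosen model.
#'
#' The defaults reproduce the composition of the study's compound-target
#' network: 25 compounds, 132 targets, 321 edges, with TDP1 and MAPT
#' planted at degrees 11 and 9.
#'
#' @param n_compounds,n_targets Number of compound/target nodes.
#' @param n_edges Number of distinct associations; must lie in
#'   `[max(n_compounds, n_targets), n_compounds * n_targets]`.
#' @param hub_spec Named integer vector of planted target degrees (each
#'   `<= n_compounds`); names become target labels.
#' @param probability_model `"uniform"` on `[prob_min, prob_max]`, or
#'   `"beta"` rescaled to that interval. Probabilities emulate the retained,
#'   high-confidence end of a prediction run, hence the default support
#'   `[0.5, 1]`.
#' @param prob_min,prob_max Probability support.
#' @param shape1,shape2 Beta parameters (used when
#'   `probability_model = "beta"`).
#' @param organism Organism label stamped on every association.
#' @param compound_names,target_names Optional label vectors; generated
#'   labels are used when `NULL`. `hub_spec` names are prepended to the
#'   target labels.
#' @param seed RNG seed.
#' @return Association data frame (compound, target, probability, organism)
#'   sorted by compound then target.
#' @export
make_association_table <- function(n_compounds = 25, n_targets = 132,
                                   n_edges = 321,
                                   hub_spec = c(TDP1 = 11, MAPT = 9),
                                   probability_model = c("uniform", "beta"),
                                   prob_min = 0.5, prob_max = 1,
                                   shape1 = 2, shape2 = 2,
                                   organism = "Homo sapiens",
                                   compound_names = NULL,
                                   target_names = NULL, seed = 1) {
  n_compounds <- check_count(n_compounds, "n_compounds", min = 1L)
  n_targets <- check_count(n_targets, "n_targets", min = 1L)
  n_edges <- check_count(n_edges, "n_edges", min = 1L)
  probability_model <- match.arg(probability_model)
  check_number(prob_min, "prob_min", min = 0, max = 1)
  check_number(prob_max, "prob_max", min = prob_min, max = 1)
  seed <- check_count(seed, "seed")
  if (n_edges > n_compounds * n_targets) {
    stop_input("'n_edges' exceeds n_compounds * n_targets")
  }
  if (n_edges < max(n_compounds, n_targets)) {
    stop_input("'n_edges' must be at least max(n_compounds, n_targets) so ",
               "every node appears")
  }
  n_hubs <- length(hub_spec)
  if (n_hubs) {
    if (is.null(names(hub_spec)) || any(!nzchar(names(hub_spec)))) {
      stop_input("'hub_spec' must be a named vector of target degrees")
    }
    if (n_hubs > n_targets) stop_input("more hubs than targets")
    if (any(hub_spec < 1 | hub_spec > n_compounds)) {
      stop_input("hub degrees must lie in [1, n_compounds]")
    }
  }
  if (is.null(compound_names)) {
    compound_names <- sprintf("compound_%02d", seq_len(n_compounds))
  }
  if (length(compound_names) != n_compounds ||
      anyDuplicated(compound_names)) {
    stop_input("'compound_names' must be ", n_compounds, " unique labels")
  }
  if (is.null(target_names)) {
    generic <- sprintf("TG%03d", seq_len(n_targets))
    target_names <- c(names(hub_spec),
                      setdiff(generic, names(hub_spec))[
                        seq_len(n_targets - n_hubs)])
  } else if (n_hubs && !all(names(hub_spec) %in% target_names)) {
    target_names <- c(names(hub_spec), setdiff(target_names,
                                               names(hub_spec)))
  }
  target_names <- target_names[seq_len(n_targets)]
  if (length(target_names) != n_targets || anyDuplicated(target_names) ||
      anyNA(target_names)) {
    stop_input("'target_names' must provide ", n_targets, " unique labels")
  }

  # target degree sequence: hubs exact, every other target >= 1, remainder
  # spread at random subject to the per-target cap of n_compounds
  deg_t <- rep(1L, n_targets)
  names(deg_t) <- target_names
  if (n_hubs) deg_t[names(hub_spec)] <- as.integer(hub_spec)
  extra <- n_edges - sum(deg_t)
  if (extra < 0) {
    stop_input("'n_edges' too small for hub degrees plus one edge per ",
               "remaining target")
  }
  free <- setdiff(target_names, names(hub_spec))
  if (extra > length(free) * (n_compounds - 1L)) {
    stop_input("'n_edges' too large for the non-hub targets to absorb")
  }
  with_seed(seed, {
    while (extra > 0L) {
      open <- free[deg_t[free] < n_compounds]
      take <- sample(open, min(extra, length(open)))
      deg_t[take] <- deg_t[take] + 1L
      extra <- extra - length(take)
    }
    # realize the sequence: per target, sample compounds without
    # replacement, weighting toward compounds of low current degree
    deg_c <- setNames(rep(0L, n_compounds), compound_names)
    from <- character(n_edges)
    to <- character(n_edges)
    pos <- 1L
    for (t in target_names[order(-deg_t)]) {
      w <- 1 / (deg_c + 1)
      picked <- sample(compound_names, deg_t[[t]], prob = w)
      deg_c[picked] <- deg_c[picked] + 1L
      idx <- pos:(pos + deg_t[[t]] - 1L)
      from[idx] <- picked
      to[idx] <- t
      pos <- pos + deg_t[[t]]
    }
    # fix-up: reassign edges so that no compound is left uncovered; only
    # the compound endpoint moves, so target degrees (and hubs) are intact
    for (c0 in compound_names[deg_c == 0L]) {
      cand <- which(deg_c[from] >= 2L)
      ok <- FALSE
      for (i in sample(cand)) {
        if (!any(from == c0 & to == to[i])) {
          deg_c[from[i]] <- deg_c[from[i]] - 1L
          from[i] <- c0
          deg_c[c0] <- deg_c[c0] + 1L
          ok <- TRUE
          break
        }
      }
      if (!ok) stop_input("could not cover compound '", c0,
                          "'; relax the degree specification")
    }
    prob <- switch(probability_model,
                   uniform = runif(n_edges, prob_min, prob_max),
                   beta = prob_min + (prob_max - prob_min) *
                     rbeta(n_edges, shape1, shape2))
    out <- data.frame(compound = from, target = to,
                      probability = round(prob, 4), organism = organism,
                      stringsAsFactors = FALSE)
    out <- out[order(out$compound, out$target), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Emulated compound-target association fixture
#'
#' The study's 321-edge compound-target network is not published as an edge
#' list, so this emulated stand-in is synthesized to its printed marginals:
#' the 25 druglike compounds of the packaged descriptor table, 132 human
#' targets, 321 distinct associations, and TDP1/MAPT planted at degrees 11
#' and 9. Target labels other than TDP1 and MAPT are synthetic. This is an
#' emulation of the network's composition, never the study's real edge
#' list.
#'
#' @param seed RNG seed.
#' @return Association data frame.
#' @examples
#' g <- build_compound_target_network(emulated_ct_associations())
#' igraph::vcount(g)  # 157
#' @export
emulated_ct_associations <- function(seed = 1) {
  compounds <- read_compound_table(netpharm_example("albizia_compounds.csv"))
  passing <- screen_compounds(compounds, max_violations = 1)$passing
  make_association_table(n_compounds = nrow(passing), n_targets = 132,
                         n_edges = 321, hub_spec = c(TDP1 = 11, MAPT = 9),
                         compound_names = passing$name, seed = seed)
}

#' Generate a target annotation table
#'
#' Emulates a protein classification export: one protein class per target,
#' sampled with weights patterned on the class shares reported for the
#' 132-target interactome (oxidoreductases and G-protein-coupled receptors
#' most common), and independent multi-label biological-process flags whose
#' rates mirror the reported process involvement (cellular and metabolic
#' processes covering most targets). Both are emulations of summary
#' percentages, not a real classification.
#'
#' @param targets Character vector of target labels.
#' @param seed RNG seed.
#' @return Annotation data frame with `processes` as a list column.
#' @export
make_target_annotations <- function(targets, seed = 1) {
  if (!is.character(targets) || !length(targets) ||
      anyDuplicated(targets)) {
    stop_input("'targets' must be unique labels")
  }
  seed <- check_count(seed, "seed")
  classes <- c("oxidoreductase" = 20, "receptor (G-protein coupled)" = 17,
               "hydrolase" = 15, "nucleic acid binding" = 12,
               "transporter" = 11, "transcription factor" = 9,
               "transferase" = 6, "other" = 10)
  processes <- c("cellular process" = 0.74, "metabolic process" = 0.70,
                 "biological regulation" = 0.43,
                 "multicellular organismal process" = 0.35,
                 "response to stimulus" = 0.33,
                 "developmental process" = 0.19,
                 "immune system process" = 0.08, "localization" = 0.01)
  with_seed(seed, {
    cls <- sample(names(classes), length(targets), replace = TRUE,
                  prob = classes)
    proc <- lapply(seq_along(targets), function(i) {
      picked <- names(processes)[runif(length(processes)) < processes]
      if (!length(picked)) picked <- "cellular process"
      picked
    })
    df <- data.frame(target = targets, protein_class = cls,
                     stringsAsFactors = FALSE)
    df$processes <- proc
    df
  })
}

#' Generate background, pathway annotation and query sets for ORA
#'
#' Builds a gene universe of `background_size` labels, pathways sampled
#' uniformly from it, and a query set. With `planted_overlap > 0` the first
#' pathway is the planted signal: exactly `planted_overlap` query genes are
#' drawn from it and the remainder from outside it. With
#' `planted_overlap = 0` the query is drawn uniformly from the whole
#' background — the null configuration for type-I error testing.
#'
#' @param background_size Universe size.
#' @param pathway_sizes Integer vector of pathway sizes (first entry is the
#'   planted pathway when `planted_overlap > 0`).
#' @param query_size Query set size.
#' @param planted_overlap Forced overlap between the query and the first
#'   pathway; `0` for a pure null draw.
#' @param seed RNG seed.
#' @return List with elements `background` (character), `pathways` (named
#'   list of member vectors), `query` (character).
#' @export
make_enrichment_inputs <- function(background_size = 1000,
                                   pathway_sizes = rep(40L, 20L),
                                   query_size = 50,
                                   planted_overlap = 15, seed = 1) {
  background_size <- check_count(background_size, "background_size",
                                 min = 1L)
  query_size <- check_count(query_size, "query_size", min = 1L)
  planted_overlap <- check_count(planted_overlap, "planted_overlap")
  seed <- check_count(seed, "seed")
  if (!is.numeric(pathway_sizes) || !length(pathway_sizes) ||
      any(pathway_sizes < 1) || any(pathway_sizes > background_size)) {
    stop_input("'pathway_sizes' must be positive and at most the ",
               "background size")
  }
  pathway_sizes <- as.integer(pathway_sizes)
  if (query_size > background_size) {
    stop_input("'query_size' exceeds the background size")
  }
  if (planted_overlap > min(pathway_sizes[1L], query_size)) {
    stop_input("'planted_overlap' exceeds the planted pathway or query size")
  }
  if (planted_overlap > 0 &&
      query_size - planted_overlap > background_size - pathway_sizes[1L]) {
    stop_input("not enough background outside the planted pathway for the ",
               "off-pathway part of the query")
  }
  with_seed(seed, {
    background <- sprintf("G%05d", seq_len(background_size))
    pathways <- lapply(pathway_sizes,
                       function(k) sample(background, k))
    names(pathways) <- sprintf("PW%02d", seq_along(pathways))
    if (planted_overlap > 0) {
      inside <- sample(pathways[[1L]], planted_overlap)
      outside <- sample(setdiff(background, pathways[[1L]]),
                        query_size - planted_overlap)
      query <- c(inside, outside)
    } else {
      query <- sample(background, query_size)
    }
    list(background = background, pathways = pathways, query = query)
  })
}

#' Generate a pathway-to-disease-system map
#'
#' Emulates disease-database indexing of enriched pathways: each disease
#' system is linked to exactly the requested number of distinct pathways,
#' sampled without replacement, so the disease-node degree sequence of the
#' resulting pathway-disease network realizes the specification exactly.
#'
#' @param pathway_ids Character vector of pathway identifiers.
#' @param disease_spec Named integer vector: disease system -> number of
#'   linked pathways (each at most `length(pathway_ids)`).
#' @param seed RNG seed.
#' @return Data frame with columns `pathway_id`, `disease_system`.
#' @export
make_disease_map <- function(pathway_ids,
                             disease_spec = default_disease_spec(),
                             seed = 1) {
  if (!is.character(pathway_ids) || !length(pathway_ids) ||
      anyDuplicated(pathway_ids)) {
    stop_input("'pathway_ids' must be unique identifiers")
  }
  seed <- check_count(seed, "seed")
  if (!length(disease_spec)) {
    return(data.frame(pathway_id = character(0),
                      disease_system = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(disease_spec)) || any(!nzchar(names(disease_spec))) ||
      !is.numeric(disease_spec) || any(disease_spec < 1) ||
      any(disease_spec > length(pathway_ids))) {
    stop_input("'disease_spec' must be a named vector of counts in [1, ",
               length(pathway_ids), "]")
  }
  with_seed(seed, {
    rows <- lapply(names(disease_spec), function(d) {
      data.frame(pathway_id = sample(pathway_ids, disease_spec[[d]]),
                 disease_system = d, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default disease-system degree specification
#'
#' The study's pathway-disease network has 64 nodes (48 pathways and 16
#' disease systems) and 167 edges, but only seven disease-node degrees are
#' printed (congenital malformation 24, nervous system disease 21,
#' metabolic disease 21, endocrine disease 17, cancer 14, cardiovascular
#' disease 12, musculoskeletal disease 6). This default keeps those seven
#' as printed and completes the remaining nine organ systems with emulated
#' degrees summing to the missing 52 edges, so the default map reproduces
#' the 64-node / 167-edge composition. The nine completions are synthetic.
#'
#' @return Named integer vector of disease-node degrees (sums to 167).
#' @export
default_disease_spec <- function() {
  c("congenital malformation" = 24L,
    "nervous system disease" = 21L,
    "metabolic disease" = 21L,
    "endocrine disease" = 17L,
    "cancer" = 14L,
    "cardiovascular disease" = 12L,
    "musculoskeletal disease" = 6L,
    "immune system disease" = 6L,
    "digestive system disease" = 6L,
    "respiratory system disease" = 6L,
    "urinary system disease" = 6L,
    "skin and connective tissue disease" = 6L,
    "reproductive system disease" = 6L,
    "hematologic disease" = 6L,
    "infectious disease" = 5L,
    "eye and ear disease" = 5L)
}
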