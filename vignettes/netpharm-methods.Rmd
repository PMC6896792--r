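---
title: "Methods: network pharmacology of a multi-compound herbal extract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology of a multi-compound herbal extract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The analysis this package implements

Traditional multi-compound remedies act through many weak interactions
rather than one strong one, which makes the single-drug/single-target frame
uninformative. Network pharmacology replaces it with a bipartite
compound–target (C–T) graph: phytochemicals on one side, predicted protein
targets on the other, an edge for each predicted interaction. Topological
properties of that graph — which compounds reach many targets, which
targets are reached by many compounds — become the mechanistic statement.
`netpharm` implements this workflow for the seed extract of *Albizia
lebbeck*, a remedy with reported antioxidant and neuroprotective activity
studied in a haloperidol-catalepsy model of Parkinson's disease, and ships
the study's two published tables as plain-text fixtures: a 30-compound
descriptor/druglikeness table and a 48-pathway enrichment table.

The pipeline has five stages, each usable on its own:

1. **Druglikeness screen** (`screen_compounds`). The Lipinski rule of five
   with the canonical limits — molecular weight ≤ 500 Da, logP ≤ 5, ≤ 5
   H-bond donors, ≤ 10 H-bond acceptors — and a tolerance of at most one
   violation (`max_violations = 1`). Violations use strict inequalities: a
   descriptor exactly at its limit does not violate. The source names the
   rule but not the numeric limits or the boundary convention, so the
   canonical values and the standard strict convention are adopted.
2. **Target mapping** (`filter_by_probability`, `restrict_organism`).
   Reverse-pharmacophore predictions arrive as (compound, target,
   probability, organism) rows. The upstream study kept targets "with
   higher estimated probability" without stating a cutoff; here the cutoff
   is an explicit argument defaulting to 0.5, ties retained (≥). Organism
   matching is exact after case-folding; compounds left with no
   associations are reported as dropped rather than silently vanishing
   (this is how ascorbic acid left the published network).
3. **Pathway over-representation** (`run_ora`, `filter_by_fdr`). A
   one-sided hypergeometric tail per pathway against an explicit background
   size, Benjamini–Hochberg adjustment across pathways. Precomputed FDR
   columns (as in the packaged enrichment table) flow through
   unrecomputed. Retention is strict `fdr < threshold` with the stated
   default 0.5; whether that figure is a typographical variant of 0.05
   cannot be decided from the data (all 48 packaged rows pass either way),
   so both are one argument away.
4. **Network topology** (`topology_report`, `hub_nodes`). Metric
   definitions follow the Cytoscape NetworkAnalyzer conventions, the tool
   family such reports conventionally use: betweenness normalized by
   `(N−1)(N−2)/2` with cross-component pairs contributing zero;
   topological coefficient `TC(n) = mean_m(J(n,m)) / k_n` over partners m
   sharing at least one neighbour, with `TC = 0` below degree 2;
   heterogeneity as the coefficient of variation of degrees (population
   variance); Freeman degree centralization
   `(N/(N−2)) (k_max/(N−1) − density)`. Hubs are nodes with degree
   strictly greater than 10 (`min_degree = 11`), ranked by degree, then
   betweenness, then label, so reports are byte-stable.
5. **Assay calculators** (`gsh_content`, `sod_amount`, `cat_activity`,
   `protein_content`). The published formulas are printed without
   parentheses. The GSH expression is read as
   `((Y − 0.00314)/0.034) · DF · VU / BT`, because 0.00314/0.034 are
   evidently an intercept/slope calibration pair; the catalase expression
   is read with the extinction coefficient (0.071 mmol⁻¹ cm⁻¹), sample
   volume and protein all in the denominator, the standard per-mL,
   per-mg-protein normalization. Sub-intercept absorbances give negative
   amounts that are returned with a warning, never clipped. The SOD and
   protein standard curves are stated without units for x, so results are
   reported in standard-curve units.

## What the synthetic generators emulate

No machine-readable inputs are deposited with the study, so every upstream
web-service output is emulated by a seeded generator:

- `make_compound_table` plants exact rule-of-five violation counts, for
  screen testing against a known truth.
- `make_association_table` realizes a bipartite incidence with exact edge
  count, exact planted target degrees and full node coverage.
  `emulated_ct_associations()` instantiates the published marginals — the
  25 druglike compounds, 132 targets, 321 edges, TDP1 at degree 11 and
  MAPT at degree 9 — with association probabilities uniform on [0.5, 1],
  emulating the retained, high-confidence end of a prediction run.
- `make_enrichment_inputs` builds background/pathway/query sets with an
  exact planted overlap, or a uniform null query when the overlap is 0.
- `make_disease_map` realizes a requested disease-node degree sequence
  exactly. The published pathway–disease network has 64 nodes and 167
  edges but prints only seven of its sixteen disease-node degrees
  (24, 21, 21, 17, 14, 12, 6, summing to 115); `default_disease_spec()`
  keeps those seven and completes the other nine organ systems with
  emulated degrees 6,6,6,6,6,6,6,5,5 so the 64-node/167-edge composition
  is reproduced. The nine completions are synthetic.

What the generators do **not** emulate: chemical structure (descriptors are
drawn from ranges, not computed from molecules), correlated prediction
errors across similar compounds, protein–protein interaction structure
inside pathways, and any biology linking a specific compound to a specific
target. Passing tests therefore demonstrate that the statistics and graph
algorithms are correct and that the pipeline reproduces the published
composition and counts — not that the emulated edges are the study's real
edges. Two published network-level values, C–T heterogeneity 1.131 and
"centrality" 0.071, depend on the unpublished 321-edge list and cannot be
recomputed from marginals; they are treated as anchors for orientation,
not as reproduction targets (on the emulated network the same metrics are
computed and reported, and land in the same regime). Likewise the study's
prose counts "26 druglike compounds" although its own table prints
myricitrin with 8 donors and 12 acceptors (two violations); the screen
reports 25 and surfaces myricitrin in a discrepancy list rather than
guessing the intent.

## Numerical and statistical choices

- **Hypergeometric tail.** `P(X ≥ x)` via `stats::phyper(..., lower.tail
  = FALSE)`, which works in log space; an exhaustive `choose()`-sum oracle
  confirms it for every parameter combination with background ≤ 12.
- **Type-I calibration check.** The test suite draws 2000 null queries
  (background 1000, query 100) and requires the pooled fraction of
  pathway p-values ≤ 0.05 to sit within 3 binomial standard errors of
  0.05. Because the hypergeometric test is discrete, its achievable level
  is below 0.05 by an amount that depends on the pathway size; the check
  uses pathway sizes (49, 57, 97, 105, 148, 192, 201, 246) whose
  analytically computed achievable levels all lie in [0.042, 0.05], so
  the simulation verifies the p-value computation rather than the
  discreteness of small pathways. Small-pathway conservatism is expected
  behaviour, not an error.
- **Planted-signal recovery.** 500 replicates with a 40-gene pathway
  overlapping 15 of a 50-gene query in a background of 1000 (expected null
  overlap: 2) must rank the planted pathway first by q-value in ≥ 95% of
  runs.
- **Betweenness and topological coefficient** are validated against
  brute-force oracles (exhaustive simple-path enumeration;
  neighbour-set arithmetic) on 200 seeded connected graphs of up to 8
  nodes; centralization is cross-checked against the independent
  `igraph::centr_degree` implementation.
- **Percent rounding** in classification tabulations is half-even to one
  decimal, matching the one-decimal style of classification pie charts.
- **Determinism.** All generators take a seed, restore the caller's RNG
  state, and are byte-stable; pipeline reruns with the same config write
  byte-identical summaries. Problem sizes in the test suite (≤ 8-node
  oracle graphs, 2000 + 500 simulation replicates, 1000-gene backgrounds)
  keep the whole suite in the tens of seconds on one CPU while leaving
  the binomial error bands tight enough to be informative.

## Degenerate inputs and edge behaviour

Empty compound tables screen to empty results; empty association lists and
header-only enrichment files parse to empty tables. Graphs with fewer than
three nodes have no defined centralization (error), all-isolated graphs no
defined heterogeneity (error), and betweenness on graphs of fewer than
three nodes is zero. Duplicate edges collapse with a logged count;
duplicate compound names, probabilities outside [0, 1], malformed FDR
values and inconsistent hypergeometric parameters are rejected with the
offending row or field named. A label appearing on both sides of a
bipartite graph is an error, never a merge.

## A worked run

```{r pipeline, eval = FALSE}
dir <- tempfile()
dir.create(dir)
write.csv(emulated_ct_associations(seed = 1),
          file.path(dir, "associations.csv"), row.names = FALSE)
enr <- read_enrichment_table(netpharm_example("kegg_enrichment.tsv"))
write.table(make_disease_map(enr$pathway_id, seed = 1),
            file.path(dir, "disease_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cfg <- pipeline_config(
  compound_table = netpharm_example("albizia_compounds.csv"),
  association_table = file.path(dir, "associations.csv"),
  enrichment_table = netpharm_example("kegg_enrichment.tsv"),
  disease_map = file.path(dir, "disease_map.tsv"),
  out_dir = file.path(dir, "out"))
run_pipeline(cfg)
```

The summary reports 30 compounds in, 25 druglike (myricitrin flagged), 48
pathways retained, a 157-node/321-edge C–T network and a 64-node/167-edge
pathway–disease network, with per-stage tables under `out_dir`.

## Known limitations

- Descriptors are taken as given; there is no structure parsing or
  descriptor prediction, and no ADMET beyond the rule of five.
- Associations are input data; the package predicts no targets and infers
  no protein–protein interaction networks.
- The emulated C–T edge list matches the published marginals but not the
  unpublished edges; per-compound betweenness values on it are therefore
  illustrative, and the published per-compound betweenness figures
  (kaempferol 0.1243, okanin 0.1234, phytosterol 0.1083) are not
  reproduction targets.
- The "higher hit rate > 50%" phrase attached to the published network has
  no operational definition and is deliberately not implemented.
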