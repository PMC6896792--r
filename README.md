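# netpharm

Network pharmacology for multi-compound herbal remedies, at desk scale and
fully offline.

Plant extracts act through many compounds hitting many targets at once, so
their mechanism is best summarized as a bipartite **compound–target (C–T)
network** rather than a single dose–response curve. `netpharm` implements
that workflow for the seed extract of *Albizia lebbeck* — a traditional
remedy with antioxidant and neuroprotective activity studied in a
haloperidol-catalepsy model of Parkinson's disease — and generalizes it to
any compound/target/pathway tables you supply. It is aimed at
pharmacology and systems-biology analysts who have descriptor tables,
target-prediction exports and enrichment tables, and want a reproducible,
scriptable alternative to clicking through web tools.

The stages:

- **Rule-of-five screen** — a compound is druglike when at most one of
  MW > 500 Da, logP > 5, HBD > 5, HBA > 10 holds (strict inequalities).
  Curated verdicts are carried through but never consulted; disagreements
  are surfaced, not overridden.
- **Target mapping** — filter predicted associations by probability
  (p ≥ threshold, default 0.5) and organism; tabulate protein classes and
  multi-label biological processes.
- **Over-representation analysis** — hypergeometric tail
  P(X ≥ x) for overlap x between a query set and a pathway against an
  explicit background, Benjamini–Hochberg FDR across pathways, retention
  at fdr < threshold (default 0.5, the study's stated rule).
- **Network topology** — NetworkAnalyzer-convention metrics: normalized
  betweenness centrality, topological coefficient, heterogeneity
  (coefficient of variation of degrees), Freeman degree centralization
  ((N/(N−2))·(k_max/(N−1) − density)), and hub calls at degree > 10.
  Exports to edge list, SIF and GraphML.
- **Assay calculators** — exact inversions of the study's oxidative-stress
  standard curves: GSH = ((Y − 0.00314)/0.034)·DF·VU/BT, SOD from
  Y = 0.0095x + 0.1939, CAT = δOD/(0.071·V·mg protein), protein from
  Y = 0.00007571x + 0.0000476.
- **Synthetic generators** — seeded emulators for every upstream
  web-service output (descriptor tables, association tables, annotations,
  ORA inputs, disease maps), so the full pipeline runs with no network
  access.

Two published tables ship as plain-text fixtures: the 30-compound
descriptor/druglikeness table (`albizia_compounds.csv`) and the 48-pathway
enrichment table (`kegg_enrichment.tsv`).

## Worked example

```r
library(netpharm)

compounds <- read_compound_table(netpharm_example("albizia_compounds.csv"))
scr <- screen_compounds(compounds)        # at most 1 violation
scr
#> Rule-of-five screen: 30 compounds, 25 druglike
#> Disagreement with curated verdict: Myricitrin
```

30 compounds enter, 25 pass. Myricitrin is flagged: the table prints it
as druglike, but its own printed descriptors (8 donors, 12 acceptors)
violate two criteria — the screen reports the discrepancy instead of
silently taking either side.

```r
g <- build_compound_target_network(emulated_ct_associations(seed = 1))
topology_report(g)
#> Network topology: 157 nodes, 321 edges
#>   heterogeneity 0.979, centralization 0.084
#> Top nodes by degree:
#>             node partition degree betweenness topological_coefficient
#> 1 Albigenic acid         a     17  0.09388026              0.10216718
#> 2      Albigenin         a     17  0.08775088              0.08627451
#> 3    Melacacidin         a     15  0.08314362              0.10370370
#> 4    Epicatechin         a     15  0.07299532              0.12500000
#> 5  Triterpenoids         a     14  0.08316419              0.11428571
```

The emulated association table reproduces the published network
composition — 157 nodes (25 compounds + 132 targets), 321 edges, TDP1 at
degree 11 and MAPT at degree 9 — while the edges themselves are
synthesized (the real edge list is unpublished; see the methods
vignette).

```r
enr <- read_enrichment_table(netpharm_example("kegg_enrichment.tsv"))
nrow(filter_by_fdr(enr, 0.5))         # 48 pathways retained
member_count(enr, "Metabolic pathways")   # 25 interacting targets
```

An end-to-end run writes every stage table plus a JSON summary:

```r
cfg <- pipeline_config(
  compound_table = netpharm_example("albizia_compounds.csv"),
  association_table = "associations.csv",   # e.g. emulated_ct_associations()
  enrichment_table = netpharm_example("kegg_enrichment.tsv"),
  disease_map = "disease_map.tsv",          # e.g. make_disease_map()
  out_dir = "out")
run_pipeline(cfg)
```

A thin command-line wrapper with `screen` / `enrich` / `network` /
`simulate` / `run-all` subcommands lives at
`inst/scripts/netpharm-cli.R`.

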