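test_that("generated compound tables realize their violation profiles exactly", {
  profile <- c(0L, 1L, 2L, 3L, 4L, 0L, 2L)
  tbl <- make_compound_table(profile, seed = 21)
  expect_identical(unname(count_ro5_violations(tbl)), profile)

  all_clean <- make_compound_table(rep(0L, 10), seed = 3)
  expect_identical(nrow(screen_compounds(all_clean)$passing), 10L)

  graded <- make_compound_table(0:3, seed = 4)
  expect_identical(nrow(screen_compounds(graded, max_violations = 1)$passing),
                   2L)

  expect_identical(make_compound_table(profile, seed = 21), tbl)
  expect_error(make_compound_table(c(0, 5)), "\\[0, 4\\]")
})

test_that("association generator realizes edge counts, hubs and coverage", {
  a <- make_association_table(seed = 1)
  expect_identical(nrow(a), 321L)
  expect_identical(anyDuplicated(paste(a$compound, a$target)), 0L)
  expect_identical(length(unique(a$compound)), 25L)
  expect_identical(length(unique(a$target)), 132L)
  deg <- table(a$target)
  expect_identical(unname(deg[["TDP1"]]), 11L)
  expect_identical(unname(deg[["MAPT"]]), 9L)
  expect_true(all(a$probability >= 0.5 & a$probability <= 1))
  # generated tables pass the consuming module's validation untouched
  expect_identical(validate_associations(a), a)
  expect_identical(make_association_table(seed = 1), a)
  expect_false(identical(make_association_table(seed = 2), a))
})

test_that("association generator covers the complete-bipartite corner and rejects bad specs", {
  full <- make_association_table(n_compounds = 4, n_targets = 3,
                                 n_edges = 12, hub_spec = NULL, seed = 1)
  expect_identical(nrow(full), 12L)
  expect_identical(nrow(unique(full[c("compound", "target")])), 12L)

  expect_error(make_association_table(n_compounds = 3, n_targets = 3,
                                      n_edges = 10, hub_spec = NULL),
               "n_edges")
  expect_error(make_association_table(n_compounds = 5, n_targets = 4,
                                      n_edges = 4, hub_spec = NULL),
               "n_edges")
  expect_error(make_association_table(n_compounds = 5, n_targets = 4,
                                      n_edges = 10,
                                      hub_spec = c(H = 9)),
               "hub")
})

test_that("enrichment input generator plants the requested overlap", {
  inputs <- make_enrichment_inputs(background_size = 1000,
                                   pathway_sizes = c(40L, rep(30L, 5)),
                                   query_size = 50, planted_overlap = 15,
                                   seed = 8)
  expect_identical(length(inputs$background), 1000L)
  expect_identical(length(inputs$query), 50L)
  expect_identical(length(intersect(inputs$query, inputs$pathways[[1]])),
                   15L)
  expect_identical(make_enrichment_inputs(seed = 8)$query,
                   make_enrichment_inputs(seed = 8)$query)

  null_inputs <- make_enrichment_inputs(planted_overlap = 0, seed = 9)
  expect_identical(length(null_inputs$query), 50L)
  expect_error(make_enrichment_inputs(pathway_sizes = 10L,
                                      planted_overlap = 15),
               "planted_overlap")
})

test_that("disease map generator realizes degree sequences exactly", {
  ids <- sprintf("%05d", 1:48)
  spec <- c("nervous system disease" = 21L, "cancer" = 5L)
  map <- make_disease_map(ids, spec, seed = 2)
  expect_identical(as.integer(table(map$disease_system)[names(spec)]),
                   unname(spec))
  expect_identical(anyDuplicated(map), 0L)
  expect_identical(make_disease_map(ids, spec, seed = 2), map)

  empty <- make_disease_map(ids, setNames(integer(0), character(0)))
  expect_identical(nrow(empty), 0L)
  expect_error(make_disease_map(ids, c(x = 49L)), "disease_spec")
})

test_that("the default disease specification completes the printed degrees to 167 edges", {
  spec <- default_disease_spec()
  expect_identical(sum(spec), 167L)
  expect_identical(length(spec), 16L)
  expect_identical(spec[["congenital malformation"]], 24L)
  expect_identical(spec[["nervous system disease"]], 21L)
  expect_identical(spec[["musculoskeletal disease"]], 6L)

  enr <- read_enrichment_table(netpharm_example("kegg_enrichment.tsv"))
  g <- build_pathway_disease_network(enr,
                                     make_disease_map(enr$pathway_id,
                                                      seed = 5))
  expect_equal(igraph::vcount(g), 64L)
  expect_equal(igraph::ecount(g), 167L)
})

test_that("annotation generator emits valid multi-label annotations", {
  ann <- make_target_annotations(sprintf("T%03d", 1:50), seed = 6)
  expect_identical(nrow(ann), 50L)
  expect_silent(validate_annotations(ann))
  tab <- tabulate_target_classes(ann)
  expect_equal(sum(tab$percent), 100, tolerance = 0.3)
  expect_true(all(lengths(ann$processes) >= 1L))
  expect_identical(make_target_annotations(sprintf("T%03d", 1:50), seed = 6),
                   ann)
})
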