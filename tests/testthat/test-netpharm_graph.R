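test_that("compound-target construction dedups edges and keeps partitions apart", {
  single <- data.frame(compound = "c1", target = "t1", probability = 0.9)
  g <- build_compound_target_network(single)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)

  twice <- rbind(single, single)
  expect_message(g2 <- build_compound_target_network(twice), "1 duplicate")
  expect_equal(igraph::ecount(g2), 1L)

  clash <- data.frame(compound = c("x", "c2"), target = c("t1", "x"),
                      probability = 0.9)
  expect_error(build_compound_target_network(clash), "both partitions")
})

test_that("emulated association fixture reproduces the printed composition", {
  g <- build_compound_target_network(emulated_ct_associations(seed = 1))
  expect_equal(igraph::vcount(g), 157L)
  expect_equal(igraph::ecount(g), 321L)
  part <- igraph::V(g)$partition
  expect_identical(sum(part == "a"), 25L)
  expect_identical(sum(part == "b"), 132L)
  deg <- igraph::degree(g)
  expect_equal(sum(deg), 2 * 321)
  expect_identical(unname(deg[["TDP1"]]), 11)
  expect_identical(unname(deg[["MAPT"]]), 9)
  expect_true(igraph::is_bipartite(g))
})

test_that("betweenness matches hand-derived small cases", {
  path3 <- bipartite_network("b", c("a", "c"),
                             data.frame(from = c("b", "b"), to = c("a", "c")))
  bc <- betweenness_centrality(path3)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))

  star <- named_star(4)
  bc <- betweenness_centrality(star)
  expect_equal(unname(bc[["center"]]), 1)
  expect_true(all(bc[paste0("leaf", 1:4)] == 0))

  ring4 <- igraph::make_ring(4)
  igraph::V(ring4)$name <- paste0("n", 1:4)
  expect_equal(unname(betweenness_centrality(ring4)), rep(1 / 6, 4))
})

test_that("topological coefficient follows the shared-neighbour definition", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- paste0("n", 1:3)
  expect_equal(unname(topological_coefficient(tri)), rep(1, 3))

  # degree-one and isolated nodes score zero
  g <- bipartite_network(c("c1", "c2", "lonely"), c("t1", "t2"),
                         data.frame(from = c("c1", "c1", "c2"),
                                    to = c("t1", "t2", "t1")))
  tc <- topological_coefficient(g)
  expect_identical(unname(tc[["c2"]]), 0)
  expect_identical(unname(tc[["lonely"]]), 0)
})

test_that("heterogeneity and centralization match their closed forms", {
  star <- named_star(4)
  expect_equal(network_heterogeneity(star), 0.75)  # sqrt(1.44)/1.6
  expect_equal(network_centralization(star), 1)

  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- paste0("n", 1:4)
  expect_equal(network_heterogeneity(ring), 0)
  expect_equal(network_centralization(ring), 0)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("n", 1:5)
  expect_equal(network_centralization(k5), 0)

  path4 <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(network_centralization(path4), 1 / 3)

  iso <- bipartite_network("a", "b")
  expect_error(network_heterogeneity(iso), "mean degree")
  expect_error(network_centralization(iso), "fewer than 3")
})

test_that("centralization agrees with the igraph Freeman implementation", {
  for (i in 1:25) {
    g <- random_connected_graph(400 + i)
    expect_equal(network_centralization(g),
                 igraph::centr_degree(g, loops = FALSE)$centralization)
  }
})

test_that("hub ranking applies the degree-betweenness-label tie-break", {
  star <- named_star(4)
  hubs <- hub_nodes(star, min_degree = 2)
  expect_identical(hubs$node, "center")

  empty <- bipartite_network(character(0), character(0))
  expect_identical(nrow(hub_nodes(empty)), 0L)

  # planted degrees 12, 11 and 3; "higher than 10" keeps the first two
  a <- make_association_table(n_compounds = 20, n_targets = 3,
                              n_edges = 26,
                              hub_spec = c(H12 = 12, H11 = 11, LOW = 3),
                              seed = 5)
  g <- build_compound_target_network(a)
  hubs <- hub_nodes(g, partition = "b", min_degree = 11)
  expect_identical(hubs$node, c("H12", "H11"))
  expect_identical(hubs$degree, c(12L, 11L))
})

test_that("pathway-disease construction keeps unlinked pathways and warns on unknown links", {
  records <- data.frame(pathway_id = c("00001", "00002"))
  links <- data.frame(pathway_id = c("00001", "00002"),
                      disease_system = "nervous system disease")
  g <- build_pathway_disease_network(records, links)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_identical(
    unname(igraph::degree(g)[["nervous system disease"]]), 2)

  g0 <- build_pathway_disease_network(records, links[0, ])
  expect_equal(igraph::vcount(g0), 2L)
  expect_equal(igraph::ecount(g0), 0L)

  stray <- rbind(links, data.frame(pathway_id = "99999",
                                   disease_system = "cancer"))
  expect_warning(build_pathway_disease_network(records, stray), "99999")
})

test_that("a planted 21-pathway disease ranks at degree 21", {
  enr <- read_enrichment_table(netpharm_example("kegg_enrichment.tsv"))
  map <- make_disease_map(enr$pathway_id,
                          c("nervous system disease" = 21L), seed = 2)
  g <- build_pathway_disease_network(enr, map)
  rank <- hub_nodes(g, "b", min_degree = 1)
  expect_identical(rank$node[1], "nervous system disease")
  expect_identical(rank$degree[1], 21L)
})

test_that("exports round-trip and produce valid SIF and GraphML", {
  a <- emulated_ct_associations(seed = 1)
  g <- build_compound_target_network(a)

  el <- tempfile(fileext = ".tsv")
  export_network(g, el, "edgelist")
  g2 <- read_edge_list(el)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  canon <- function(x) {
    e <- igraph::as_edgelist(x)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(canon(g2), canon(g))

  sif <- tempfile(fileext = ".sif")
  one <- bipartite_network("c1", "t1",
                           data.frame(from = "c1", to = "t1"))
  export_network(one, sif, "sif")
  expect_identical(readLines(sif), "c1\tinteracts\tt1")

  gml <- tempfile(fileext = ".graphml")
  export_network(g, gml, "graphml")
  doc <- xml2::read_xml(gml)  # errors if not well-formed XML
  expect_identical(xml2::xml_name(doc), "graphml")
  g3 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g3), igraph::vcount(g))
  expect_equal(igraph::ecount(g3), igraph::ecount(g))

  expect_error(export_network(g, tempfile(), "dot"))
})
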