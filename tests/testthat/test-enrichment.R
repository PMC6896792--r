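fixture_enrichment <- function() {
  read_enrichment_table(netpharm_example("kegg_enrichment.tsv"))
}

test_that("hypergeometric tail matches closed forms and the enumeration oracle", {
  expect_identical(hypergeom_tail_p(0, 5, 3, 10), 1)
  expect_equal(hypergeom_tail_p(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeom_tail_p(2, 2, 3, 6), 0.2)
  # spot-check against the choose()-sum oracle
  for (case in list(c(3, 6, 5, 12), c(1, 4, 4, 9), c(2, 7, 3, 11))) {
    expect_equal(hypergeom_tail_p(case[1], case[2], case[3], case[4]),
                 brute_hyper_tail(case[1], case[2], case[3], case[4]))
  }
  expect_error(hypergeom_tail_p(3, 2, 5, 10), "inconsistent")
  expect_error(hypergeom_tail_p(1, 2, 11, 10), "inconsistent")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- adjust_bh(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(adjust_bh(c(0.5, 0)), "position")
  expect_error(adjust_bh(c(0.5, 1.2)), "position")
})

test_that("the packaged enrichment table parses to 48 validated pathways", {
  enr <- fixture_enrichment()
  expect_identical(nrow(enr), 48L)
  expect_identical(length(enr$members[[which(enr$pathway_id == "00910")]]),
                   12L)
  expect_true(all(enr$fdr > 0 & enr$fdr < 0.05))
  expect_equal(min(enr$fdr), 5.93e-21)
  expect_equal(max(enr$fdr), 0.0483)

  header_only <- tempfile(fileext = ".tsv")
  writeLines("pathway_id\tdescription\tfdr\tmembers", header_only)
  expect_identical(nrow(read_enrichment_table(header_only)), 0L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tdescription\tfdr\tmembers",
               "00001\tx\tnot-a-number\tA,B"), bad)
  expect_error(read_enrichment_table(bad), "row")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tdescription\tfdr\tmembers",
               "00001\tx\t0.01\tA, B ,A"), dup)
  expect_warning(tbl <- read_enrichment_table(dup), "duplicate")
  expect_identical(tbl$members[[1]], c("A", "B"))
})

test_that("FDR filtering is strict and nested across thresholds", {
  enr <- fixture_enrichment()
  expect_identical(nrow(filter_by_fdr(enr, 0.5)), 48L)
  expect_identical(nrow(filter_by_fdr(enr, 0.05)), 48L)
  expect_identical(nrow(filter_by_fdr(enr, 1e-30)), 0L)
  expect_identical(nrow(filter_by_fdr(enr[0, ], 0.5)), 0L)
  # strict <: a record exactly at the threshold is excluded
  at <- data.frame(fdr = c(0.05, 0.049))
  expect_identical(nrow(filter_by_fdr(at, 0.05)), 1L)
  for (pair in list(c(1e-10, 1e-5), c(1e-5, 0.01), c(0.01, 0.5))) {
    a <- filter_by_fdr(enr, pair[1])
    b <- filter_by_fdr(enr, pair[2])
    expect_true(all(a$pathway_id %in% b$pathway_id))
  }
})

test_that("member lookup works by ID and description", {
  enr <- fixture_enrichment()
  expect_identical(member_count(enr, "Metabolic pathways"), 25L)
  expect_identical(member_count(enr, "rap1 signalling pathway"), 13L)
  expect_identical(member_count(enr, "04151"), 17L)
  expect_identical(member_count(enr[1, ], "00910"), 12L)
  expect_error(member_count(enr, "No such pathway"), "No such pathway")
})

test_that("ORA ranks a strongly planted pathway first", {
  inputs <- make_enrichment_inputs(background_size = 1000,
                                   pathway_sizes = rep(40L, 10L),
                                   query_size = 50, planted_overlap = 15,
                                   seed = 99)
  res <- run_ora(inputs$query, inputs$pathways, 1000)
  expect_identical(res$pathway_id[which.min(res$q_value)], "PW01")
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$overlap <= pmin(res$pathway_size, res$query_size)))
  expect_error(run_ora(inputs$query, inputs$pathways, 30), "background")
})
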