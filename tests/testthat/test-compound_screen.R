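fixture_compounds <- function() {
  read_compound_table(netpharm_example("albizia_compounds.csv"))
}

test_that("violation counts follow the four strict thresholds", {
  compounds <- fixture_compounds()
  v <- count_ro5_violations(compounds)
  expect_identical(v[["Quebrachitol"]], 0L)
  expect_identical(v[["Digitoxin"]], 2L)   # MW and HBA exceeded
  expect_identical(v[["Rutin"]], 3L)       # MW, HBD and HBA exceeded
  # a record sitting exactly on every limit violates nothing
  boundary <- data.frame(name = "boundary", logp = 5, mol_weight = 500,
                         hbd = 5, hba = 10)
  expect_identical(unname(count_ro5_violations(boundary)), 0L)
  expect_true(unname(is_druglike(boundary)))
})

test_that("druglikeness verdict uses the at-most-one-violation rule", {
  compounds <- fixture_compounds()
  verdict <- is_druglike(compounds, max_violations = 1)
  expect_true(verdict[["Phytosterol"]])    # one logP violation tolerated
  expect_false(verdict[["Vicenin 2"]])
  expect_false(verdict[["Rutin"]])
})

test_that("screening the packaged table flags myricitrin as the sole discrepancy", {
  compounds <- fixture_compounds()
  scr <- suppressMessages(screen_compounds(compounds, max_violations = 1))
  expect_identical(nrow(scr$passing), 25L)
  expect_identical(scr$discrepancies, "Myricitrin")
  # agreement with the curated verdict column on 29 of 30 rows
  agree <- scr$report$druglike == scr$report$curated_verdict
  expect_identical(sum(agree), 29L)
  expect_true(all(scr$report$violations >= 0L & scr$report$violations <= 3L))
  # the four curated failures alone pass nowhere
  fails <- compounds[compounds$druglike == "No", , drop = FALSE]
  expect_setequal(fails$name,
                  c("Digitoxin", "Reynoutrin", "Vicenin 2", "Rutin"))
  expect_identical(nrow(screen_compounds(fails)$passing), 0L)
})

test_that("screen is monotone in the tolerance and idempotent", {
  compounds <- fixture_compounds()
  sizes <- vapply(0:4, function(k) {
    nrow(suppressMessages(screen_compounds(compounds, k))$passing)
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
  scr <- suppressMessages(screen_compounds(compounds))
  again <- suppressMessages(screen_compounds(scr$passing))
  expect_identical(again$passing, scr$passing)
  expect_identical(nrow(again$passing), nrow(scr$passing))
})

test_that("the curated verdict column is carried but never consulted", {
  compounds <- fixture_compounds()
  flipped <- compounds
  flipped$druglike <- "No"
  a <- suppressMessages(screen_compounds(compounds))
  b <- suppressMessages(screen_compounds(flipped))
  expect_identical(a$passing$name, b$passing$name)
})

test_that("invalid compound tables are rejected with informative errors", {
  expect_error(count_ro5_violations(
    data.frame(name = "x", logp = NaN, mol_weight = 1, hbd = 0, hba = 0)),
    "logp")
  expect_error(count_ro5_violations(
    data.frame(name = "x", logp = 1, mol_weight = Inf, hbd = 0, hba = 0)),
    "mol_weight")
  dup <- data.frame(name = c("Rutin", " rutin"), logp = c(1, 1),
                    mol_weight = c(10, 10), hbd = c(0, 0), hba = c(0, 0))
  expect_error(screen_compounds(dup), "duplicate")
  empty <- fixture_compounds()[0, ]
  scr <- screen_compounds(empty)
  expect_identical(nrow(scr$report), 0L)
  expect_identical(scr$discrepancies, character(0))
})

test_that("packaged fixtures have not drifted from their transcription", {
  sums <- tools::md5sum(c(netpharm_example("albizia_compounds.csv"),
                          netpharm_example("kegg_enrichment.tsv")))
  expect_identical(unname(sums),
                   c("4da60182226511465507eff559900ecf",
                     "a7c819ffb71d905dd2269e97824201fd"))
})
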