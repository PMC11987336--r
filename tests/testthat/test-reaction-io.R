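# Reaction parsing, multi-product decomposition, dataset round-trips.

test_that("parse_reaction splits roles and validates molecules", {
  raw <- parse_reaction("CCO.CC(=O)O>>CCOC(C)=O")
  expect_s3_class(raw, "rxn_raw")
  expect_length(raw$reactants, 2L)
  expect_length(raw$reagents, 0L)
  expect_length(raw$products, 1L)

  raw2 <- parse_reaction("CCO>[Na+]>CC")
  expect_length(raw2$reactants, 1L)
  expect_length(raw2$reagents, 1L)
  expect_length(raw2$products, 1L)

  expect_error(parse_reaction("CCO>>"), "no product")
  expect_error(parse_reaction("CCO>CC"), "3 '>'-separated")
  expect_error(parse_reaction("CCO.XX(>>CC"), "unparsable reactant")
})

test_that("atom maps are stripped and molecules canonicalized on ingest", {
  raw <- parse_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH2:2][OH:3]")
  expect_identical(raw$reactants, canonical_smiles("CCO"))
  rec <- reaction_record("x", "OCC", c("BrCC"))
  expect_identical(rec$product, canonical_smiles("CCO"))
})

test_that("multi-product decomposition preserves counts and reactants", {
  raw <- parse_reaction("CCO.CC(=O)O>>CCOC(C)=O.O.CC")
  recs <- decompose_multiproduct(raw, parent_id = "p")
  expect_length(recs, 3L)
  for (r in recs) {
    expect_identical(r$reactants, raw$reactants)
  }
  expect_equal(vapply(recs, function(r) r$record_id, ""),
               c("p_1", "p_2", "p_3"))

  # identity case
  one <- decompose_multiproduct(parse_reaction("CCO>>CC"), "q")
  expect_length(one, 1L)
  expect_identical(one[[1]]$record_id, "q")

  # duplicate products are preserved as duplicate records
  dup <- decompose_multiproduct(parse_reaction("CCO>>CC.CC"), "d")
  expect_length(dup, 2L)
  expect_identical(dup[[1]]$product, dup[[2]]$product)
})

test_that("record invariants are enforced", {
  expect_error(reaction_record("x", "CC.CC", c("CCO")), "single connected")
  expect_error(reaction_record("x", "CC", character(0)), "non-empty")
  expect_error(reaction_record("x", "CC", c("CCO"),
                               attributes = list(yield = Inf)), "non-finite")
})

test_that("CSV datasets read with decomposition, skip mode, empty files", {
  d <- withr::local_tempdir()
  csv <- file.path(d, "r.csv")
  writeLines(c("id,reaction,yield",
               "a,CCO.CC(=O)O>>CCOC(C)=O,90",
               "b,CCBr>O>CCO.CC,80",
               "c,CCN>>CCNC,"), csv)
  recs <- read_dataset(csv)
  expect_length(recs, 4L)   # 1 + 2 + 1 products
  expect_equal(vapply(recs, function(r) r$record_id, ""),
               c("a", "b_1", "b_2", "c"))
  expect_equal(recs[[1]]$attributes$yield, 90)
  expect_null(recs[[4]]$attributes$yield)

  empty <- file.path(d, "e.csv")
  writeLines("id,reaction", empty)
  expect_length(read_dataset(empty), 0L)

  bad <- file.path(d, "bad.csv")
  writeLines(c("id,reaction", "a,CCO>>CC", "b,not_a_smiles>>"), bad)
  expect_error(read_dataset(bad), "row 2")
  expect_warning(recs2 <- read_dataset(bad, on_error = "skip"), "skipped 1")
  expect_length(recs2, 1L)
})

test_that("serialization round-trips losslessly (CSV and JSONL)", {
  set.seed(5)
  recs <- small_dataset()[1:10]
  recs[[1]]$meta$note <- "unicode éß✓"
  for (fmt in c("csv", "jsonl")) {
    path <- file.path(withr::local_tempdir(), paste0("x.", fmt))
    write_dataset(recs, path, format = fmt)
    back <- read_dataset(path, format = fmt)
    expect_length(back, length(recs))
    for (i in seq_along(recs)) {
      expect_identical(back[[i]]$record_id, recs[[i]]$record_id)
      expect_identical(back[[i]]$product, recs[[i]]$product)
      expect_identical(back[[i]]$reactants, recs[[i]]$reactants)
      expect_identical(back[[i]]$reagents, recs[[i]]$reagents)
      a1 <- recs[[i]]$attributes
      a2 <- back[[i]]$attributes
      expect_equal(a2[sort(names(a2))], a1[sort(names(a1))])
      m1 <- recs[[i]]$meta; m2 <- back[[i]]$meta
      expect_equal(m2[sort(names(m2))], m1[sort(names(m1))])
    }
  }
})

test_that("no-reagent records serialize with an empty middle field", {
  r <- reaction_record("x", "CCOC(C)=O", c("CCO", "CC(=O)O"))
  expect_match(reaction_smiles(r), ">>", fixed = TRUE)
})

test_that("decomposition count always equals product count", {
  set.seed(11)
  mols <- c("CC", "CCO", "CCC", "c1ccccc1", "CCN", "CCOC")
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    prods <- sample(mols, k, replace = TRUE)
    raw <- parse_reaction(paste0("CCO>>", paste(prods, collapse = ".")))
    expect_length(decompose_multiproduct(raw, "z"), k)
  }
})
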