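# Index construction, query embedding, range filtering, top-K retrieval.

test_that("index rows compose embed -> project -> concat", {
  ts <- trained_small()
  db <- ts$db
  expect_equal(nrow(db$X), length(db$records))
  expect_equal(ncol(db$X), 2L * ts$basis$q)
  # compositional oracle on one record
  i <- 7L
  pair <- embed_record(db$records[[i]], ts$model)
  manual <- c(project(pair$z, ts$basis), project(pair$z_hat, ts$basis))
  expect_equal(as.numeric(db$X[i, ]), manual, tolerance = 1e-10)
  # determinism
  db2 <- build_index(db$records, ts$model, ts$basis)
  expect_identical(db2$X, db$X)
})

test_that("query embedding follows the fallback rules", {
  ts <- trained_small()
  rec <- ts$dat$train[[3]]
  # full query reproduces the record's row
  qfull <- query_spec(product = rec$product, reactants = rec$reactants,
                      reagents = rec$reagents)
  x <- embed_query(qfull, ts$model, ts$basis, ts$db)$x
  expect_equal(x, as.numeric(ts$db$X[3, ]), tolerance = 1e-8)
  # product-only: both halves identical
  q1 <- query_spec(product = rec$product)
  x1 <- embed_query(q1, ts$model, ts$basis, ts$db)$x
  q <- ts$basis$q
  expect_identical(x1[seq_len(q)], x1[q + seq_len(q)])
  # reactant-only: both halves identical
  q2 <- query_spec(reactants = rec$reactants)
  x2 <- embed_query(q2, ts$model, ts$basis, ts$db)$x
  expect_identical(x2[seq_len(q)], x2[q + seq_len(q)])
  expect_error(query_spec(), "at least one")
})

test_that("substructure queries anchor on stored embeddings", {
  ts <- trained_small()
  # a pattern matching exactly one product: that record's stored z' side
  prods <- vapply(ts$db$records, function(r) r$product, "")
  hit <- NULL
  for (i in seq_along(prods)) {
    if (sum(prods == prods[i]) == 1L) { hit <- i; break }
  }
  qs <- query_spec(product = prods[hit], match_mode = "substructure")
  out <- embed_query(qs, ts$model, ts$basis, ts$db)
  sel <- which(vapply(ts$db$records, function(r)
    set_has_substructure(prods[hit], r$product), TRUE))
  q <- ts$basis$q
  expect_equal(out$x[seq_len(q)],
               as.numeric(colMeans(ts$db$X[sel, seq_len(q), drop = FALSE])),
               tolerance = 1e-10)
  if (length(sel) == 1L) {
    expect_equal(out$x[seq_len(q)], as.numeric(ts$db$X[sel, seq_len(q)]))
  }
  # pattern matching nothing -> explicit error
  qz <- query_spec(product = "C(I)(I)C(I)(I)C", match_mode = "substructure")
  expect_error(embed_query(qz, ts$model, ts$basis, ts$db), "no anchor")
})

test_that("range filtering keeps only in-range records", {
  recs <- list(
    reaction_record("a", "CC", "CCO", attributes = list(yield = 75)),
    reaction_record("b", "CC", "CCO", attributes = list(yield = 85)),
    reaction_record("c", "CC", "CCO"))
  keep <- filter_by_ranges(recs, list(yield = c(80, 100)))
  expect_equal(keep, 2L)
  expect_equal(filter_by_ranges(recs, list()), 1:3)
  expect_equal(filter_by_ranges(recs, list(yield = c(85, 85))), 2L)
  expect_equal(filter_by_ranges(recs, list(yield = c(80, 100)),
                                keep_missing = TRUE), 2:3)
  expect_warning(filter_by_ranges(recs, list(pressure = c(0, 1))), "unknown")
})

test_that("top-K retrieval matches a brute-force full sort", {
  set.seed(41)
  N <- 100L; q2 <- 8L
  X <- matrix(rnorm(N * q2), N, q2)
  recs <- lapply(seq_len(N), function(i)
    reaction_record(sprintf("r%03d", i), "CC", "CCO"))
  db <- structure(list(records = recs, X = X, q = q2 / 2L, basis = NULL),
                  class = "rxn_index")
  x <- rnorm(q2)
  res <- retrieve_topk(x, db, K = 10L)
  d <- sqrt(colSums((t(X) - x)^2))
  ids <- sprintf("r%03d", seq_len(N))
  ord <- order(d, ids)
  expect_identical(res$hits$index, ord[1:10])
  expect_identical(res$hits$distance, d[ord[1:10]])
  expect_true(all(diff(res$hits$distance) >= 0))

  # query equal to a stored row retrieves it first at distance 0
  res2 <- retrieve_topk(X[33, ], db, K = 3L)
  expect_equal(res2$hits$index[1], 33L)
  expect_equal(res2$hits$distance[1], 0)

  # K larger than candidate count
  res3 <- retrieve_topk(x, db, candidates = 1:5, K = 50L)
  expect_equal(nrow(res3$hits), 5L)

  # empty candidate set -> empty result, not an error
  res4 <- retrieve_topk(x, db, candidates = integer(0), K = 5L)
  expect_equal(nrow(res4$hits), 0L)
})

test_that("filtering commutes with retrieval", {
  ts <- trained_small()
  db <- ts$db
  qry <- query_spec(product = ts$dat$test[[1]]$product, K = 10L,
                    attribute_ranges = list(yield = c(60, 95)))
  x <- embed_query(qry, ts$model, ts$basis, db)$x
  cand <- filter_by_ranges(db, qry$attribute_ranges)
  res <- retrieve_topk(x, db, cand, 10L)
  # retrieval over a pre-filtered copy of the matrix gives the same hits
  db_sub <- structure(list(records = db$records[cand],
                           X = db$X[cand, , drop = FALSE], q = db$q,
                           basis = db$basis), class = "rxn_index")
  res_sub <- retrieve_topk(x, db_sub, K = 10L)
  expect_identical(res$hits$record_id, res_sub$hits$record_id)
  expect_identical(res$hits$distance, res_sub$hits$distance)
})

test_that("exact mode post-filters to canonical equality", {
  ts <- trained_small()
  rec <- ts$dat$train[[5]]
  # the full query reproduces the record's stored vector, so the record
  # itself ranks first and survives the exactness filter
  qry <- query_spec(product = rec$product, reactants = rec$reactants,
                    reagents = rec$reagents, match_mode = "exact", K = 15L)
  res <- search_reactions(qry, ts$db, ts$model)
  expect_gte(nrow(res$hits), 1L)
  expect_identical(res$hits$record_id[1], rec$record_id)
  for (i in res$hits$index) {
    expect_identical(ts$db$records[[i]]$product, rec$product)
    expect_true(setequal(ts$db$records[[i]]$reactants, rec$reactants))
  }
})
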