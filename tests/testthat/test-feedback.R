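# Margin ranking loss, blended objective, fine-tuning, index refresh.

test_that("margin ranking loss matches hand cases", {
  # K=2, ratings (+1,-1), equal distances, delta=100:
  # term = 2*0 + 2*100, normalizer 2/(2*1) = 1 -> 200
  x <- c(0, 0)
  H <- rbind(c(1, 0), c(0, 1))
  expect_equal(margin_ranking_loss(x, H, c(1L, -1L), delta = 100), 200)
  # all ratings equal -> 0
  expect_equal(margin_ranking_loss(x, H, c(1L, 1L), delta = 100), 0)
  expect_equal(margin_ranking_loss(x, H, c(-1L, -1L), delta = 100), 0)
  # hinge inactive: positive closer than negative by more than 2*delta
  H2 <- rbind(c(0.5, 0), c(10, 0))
  expect_equal(margin_ranking_loss(x, H2, c(1L, -1L), delta = 2), 0)
  # K < 2 warns and returns 0
  expect_warning(l0 <- margin_ranking_loss(x, matrix(c(1, 0), 1), 1L, 1),
                 "fewer than 2")
  expect_equal(l0, 0)
})

test_that("margin ranking loss matches the brute-force pair loop", {
  set.seed(47)
  for (rep in 1:6) {
    K <- sample(3:8, 1)
    q2 <- 4L
    x <- rnorm(q2)
    H <- matrix(rnorm(K * q2), K, q2)
    r <- sample(c(-1L, 0L, 1L), K, replace = TRUE)
    delta <- stats::runif(1, 0, 3)
    expect_equal(margin_ranking_loss(x, H, r, delta),
                 oracle_margin(x, H, r, delta), tolerance = 1e-8)
  }
})

test_that("the blended objective reduces to J when the ranking term is off", {
  ts <- trained_small()
  recs <- ts$dat$train[1:16]
  qry <- query_spec(product = ts$dat$train[[1]]$product)
  hits <- ts$dat$train[2:5]
  fb_neutral <- list(feedback_entry(qry, hits, rep(0L, 4)))
  fb_mixed <- list(feedback_entry(qry, hits, c(1L, -1L, 0L, 1L)))
  tuples <- lapply(recs, featurize_record)
  fw <- rxnsearch:::model_forward_tuples(ts$model, tuples, train = FALSE)
  J <- batch_objective(list(Z = fw$Z, Zhat = fw$Zhat), 100)
  # lambda = 0
  expect_equal(combined_objective(recs, fb_mixed, 0, ts$model, ts$basis),
               J, tolerance = 1e-10)
  # all-neutral ratings: every pair term vanishes for any lambda
  expect_equal(combined_objective(recs, fb_neutral, 5, ts$model, ts$basis),
               J, tolerance = 1e-10)
  # compositional: J + lambda * mean(l_r)
  prep <- rxnsearch:::.entry_prepare(fb_mixed[[1]])
  ef <- rxnsearch:::.entry_forward(ts$model, ts$basis, fb_mixed[[1]], prep)
  lr <- margin_ranking_loss(ef$x, ef$Hx, fb_mixed[[1]]$ratings, 100)
  expect_equal(combined_objective(recs, fb_mixed, 0.25, ts$model, ts$basis),
               J + 0.25 * lr, tolerance = 1e-8)
})

test_that("fine-tuning pulls positively rated records closer", {
  ts <- trained_small()
  # pick two hits initially at similar distances from a product-only query
  qry <- query_spec(product = ts$dat$test[[2]]$product)
  x0 <- embed_query(qry, ts$model, ts$basis, ts$db)$x
  res <- retrieve_topk(x0, ts$db, K = 10L)
  i_pos <- res$hits$index[5]; i_neg <- res$hits$index[6]
  entry <- feedback_entry(qry, ts$db$records[c(i_pos, i_neg)], c(1L, -1L))
  # published update protocol: SGD 1e-4, momentum 0.9, 100 iterations,
  # lambda 0.01; the contrastive term draws from a 128-record sample of D
  cfg <- feedback_config(minibatch = 64L, seed = 3L)
  m2 <- finetune(ts$model, ts$dat$train[1:128], list(entry), cfg, ts$basis)
  # distances recomputed with the updated model, fixed basis
  db2 <- refresh_index(ts$db, m2)
  x2 <- embed_query(qry, m2, ts$basis, db2)$x
  d_pos <- sqrt(sum((x2 - db2$X[i_pos, ])^2))
  d_neg <- sqrt(sum((x2 - db2$X[i_neg, ])^2))
  expect_lt(d_pos, d_neg)
  expect_error(feedback_config(iterations = 0L))
})

test_that("refreshing the index with an unchanged model is a no-op", {
  ts <- trained_small()
  db2 <- refresh_index(ts$db, ts$model)
  expect_equal(db2$X, ts$db$X, tolerance = 1e-12)
  expect_equal(length(db2$records), length(ts$db$records))
  expect_identical(vapply(db2$records, function(r) r$record_id, ""),
                   vapply(ts$db$records, function(r) r$record_id, ""))
})

test_that("feedback entries validate ratings", {
  qry <- query_spec(product = "CCO")
  recs <- tiny_records()[1:2]
  expect_error(feedback_entry(qry, recs, c(1L, 2L)))
  expect_error(feedback_entry(qry, recs, c(1L)))
})
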