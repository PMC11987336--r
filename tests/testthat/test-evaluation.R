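# Product-prediction metrics and simulated preference scenarios.

test_that("rank summaries match hand computations", {
  m <- metrics_from_ranks(c(1L, 1L, 1L))
  expect_equal(m$mrr, 1)
  expect_equal(m$mr, 1)
  expect_true(all(m$hit_at == 1))

  m2 <- metrics_from_ranks(c(1L, 4L))
  expect_equal(m2$mrr, (1 + 0.25) / 2)
  expect_equal(m2$mr, 2.5)
  expect_equal(unname(m2$hit_at["hit@3"]), 0.5)
  expect_equal(unname(m2$hit_at["hit@1"]), 0.5)

  # invariants: Hit@k non-decreasing in k, Hit@1 <= MRR <= 1
  set.seed(53)
  for (rep in 1:10) {
    r <- sample(1:50, 20, replace = TRUE)
    mm <- metrics_from_ranks(r)
    expect_true(all(diff(mm$hit_at) >= 0))
    expect_gte(mm$mrr, unname(mm$hit_at["hit@1"]))
    expect_lte(mm$mrr, 1)
    expect_gte(mm$mr, 1)
  }
})

test_that("an untrained model yields near-uniform ranks (null check)", {
  dat <- memo("null_test", generate_fixture_datasets(
    n_train = 1, n_val = 1, n_test = 80, seed = 13))
  model <- init_model(encoder_config(gnn_layers = 2L, gnn_hidden = 32L,
                                     projection_hidden = 32L, p = 32L,
                                     seed = 99L))
  met <- product_prediction_metrics(model, dat$test)
  C <- met$n_candidates
  # MC standard error of the mean rank under the uniform null ~ C/sqrt(12 n)
  se <- C / sqrt(12 * met$n_queries)
  expect_lt(abs(met$mr - (C + 1) / 2), 4 * se)
})

test_that("missing ground truth in the pool errors", {
  ts <- trained_small()
  expect_error(product_prediction_metrics(ts$model, ts$dat$test[1:5],
                                          candidate_products = "CCO"),
               "missing from the candidate pool")
})

test_that("scenario raters implement the preference predicates", {
  sc1 <- scenario_spec(1)
  q_cl <- query_spec(product = "ClCCCO")
  hit_cl <- reaction_record("h1", "ClCCCCO", c("ClCCCCBr"))
  hit_clbr <- reaction_record("h2", "ClC(Br)CCO", c("ClC(Br)CCBr"))
  hit_plain <- reaction_record("h3", "CCCO", c("CCCBr"))
  expect_equal(rate_by_scenario(q_cl, hit_cl, sc1), 1L)
  expect_equal(rate_by_scenario(q_cl, hit_clbr, sc1), -1L)
  expect_equal(rate_by_scenario(q_cl, hit_plain, sc1), -1L)
  # empty == empty counts as a match
  q_plain <- query_spec(product = "CCCO")
  expect_equal(rate_by_scenario(q_plain, hit_plain, sc1), 1L)
  # count semantics distinguishes multiplicity
  sc1c <- scenario_spec(1, halogen_semantics = "count")
  hit_2cl <- reaction_record("h4", "ClCC(Cl)CO", c("ClCC(Cl)CBr"))
  expect_equal(rate_by_scenario(q_cl, hit_2cl, scenario_spec(1)), 1L)
  expect_equal(rate_by_scenario(q_cl, hit_2cl, sc1c), -1L)

  sc2 <- scenario_spec(2)
  two_r <- reaction_record("h5", "CCOC(C)=O", c("CCO", "CC(=O)O"))
  one_r <- reaction_record("h6", "CCCO", c("CCCBr"))
  # no reactants in the query -> the default count 2 applies
  expect_equal(rate_by_scenario(q_plain, two_r, sc2), 1L)
  expect_equal(rate_by_scenario(q_plain, one_r, sc2), -1L)
  q_one <- query_spec(product = "CCCO", reactants = c("CCCBr"))
  expect_equal(rate_by_scenario(q_one, one_r, sc2), 1L)

  sc3 <- scenario_spec(3)
  self_sim <- reaction_record("h7", "CCCO", c("CCCO", "O"))
  expect_equal(rate_by_scenario(q_plain, self_sim, sc3), 1L)
  lo_sim <- reaction_record("h8", "c1ccccc1C(=O)OCC", c("c1ccccc1C(=O)O",
                                                        "OCC"))
  expect_equal(rate_by_scenario(q_plain, lo_sim, sc3), -1L)

  # conjunctions
  expect_equal(rate_by_scenario(q_plain, two_r, scenario_spec(4)), 1L)
  expect_equal(rate_by_scenario(q_cl, two_r, scenario_spec(4)), -1L)
  expect_equal(rate_by_scenario(q_plain, self_sim, scenario_spec(5)), 1L)
  expect_equal(rate_by_scenario(q_cl, self_sim, scenario_spec(5)), -1L)
  expect_equal(rate_by_scenario(q_plain, lo_sim, scenario_spec(5)), -1L)

  # purity: repeated calls agree
  expect_identical(rate_by_scenario(q_cl, hit_cl, sc1),
                   rate_by_scenario(q_cl, hit_cl, sc1))
})

test_that("max_tanimoto bounds hold", {
  expect_equal(max_tanimoto("CCO", c("CCO")), 1)
  s <- max_tanimoto("CCO", c("c1ccccc1"))
  expect_gte(s, 0); expect_lt(s, 0.3)
})

test_that("feedback trajectories hit the floor and ceiling cases", {
  ts <- trained_small()
  recs <- ts$dat$train[1:30]
  # small index over records with known reactant counts
  db <- build_index(recs, ts$model, ts$basis)
  counts <- vapply(recs, function(r) length(r$reactants), 0L)
  qry <- query_spec(product = recs[[1]]$product)  # no reactants -> wants 2
  cfg <- feedback_config(iterations = 2L, minibatch = 8L, seed = 1L)
  # ceiling: restrict the db to 2-reactant records
  db_all2 <- build_index(recs[counts == 2L], ts$model, ts$basis)
  tr_hi <- simulate_feedback_loop(list(qry), db_all2, ts$model,
                                  ts$dat$train[1:16], scenario_spec(2),
                                  K = 5L, n_updates = 1L, config = cfg)
  expect_equal(tr_hi$hit_ratio, c(1, 1))
  # floor: no 2-reactant records at all
  db_no2 <- build_index(recs[counts != 2L], ts$model, ts$basis)
  tr_lo <- simulate_feedback_loop(list(qry), db_no2, ts$model,
                                  ts$dat$train[1:16], scenario_spec(2),
                                  K = 5L, n_updates = 1L, config = cfg)
  expect_equal(tr_lo$hit_ratio, c(0, 0))
  # round-0 value is independent of the feedback configuration
  tr_alt <- simulate_feedback_loop(list(qry), db_no2, ts$model,
                                   ts$dat$train[1:16], scenario_spec(2),
                                   K = 5L, n_updates = 0L,
                                   config = feedback_config(iterations = 50L,
                                                            seed = 77L))
  expect_equal(tr_alt$hit_ratio[1], tr_lo$hit_ratio[1])
})
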